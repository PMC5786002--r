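#' DMR test parameters
#'
#' Defaults follow the replicate DMR rules: significance requires an
#' absolute group difference above 10% and a p-value at or below 0.001; a
#' CpG enters the statistic only with coverage of at least one read in every
#' compared sample; replicates with a median CpG coverage of 4 or less are
#' excluded; PMRs overlapping a single gene to at least 75% are removed
#' before testing.
#'
#' @param min_diff minimum absolute methylation difference.
#' @param alpha p-value cutoff.
#' @param min_cov_per_cpg minimum per-sample coverage to keep a CpG.
#' @param max_median_cov_exclude replicates with median coverage at or below
#'   this are excluded.
#' @param pmr_gene_overlap_exclude single-gene overlap fraction above which
#'   a PMR is excluded.
#' @param min_test_cpgs regions with fewer kept CpGs are reported untestable.
#' @param stat `"ranksum"` (Mann-Whitney on pooled per-CpG, per-sample
#'   levels; default) or `"welch"` (Welch t on per-sample region means).
#' @return list of class `dmr_params`.
#' @export
dmr_params <- function(min_diff = 0.10, alpha = 0.001, min_cov_per_cpg = 1L,
                       max_median_cov_exclude = 4L,
                       pmr_gene_overlap_exclude = 0.75,
                       min_test_cpgs = 3L,
                       stat = c("ranksum", "welch")) {
  stat <- match.arg(stat)
  stopifnot(min_diff >= 0, min_diff < 1, alpha > 0, alpha < 1,
            min_cov_per_cpg >= 1L, min_test_cpgs >= 1L)
  structure(list(min_diff = min_diff, alpha = alpha,
                 min_cov_per_cpg = as.integer(min_cov_per_cpg),
                 max_median_cov_exclude = as.integer(max_median_cov_exclude),
                 pmr_gene_overlap_exclude = pmr_gene_overlap_exclude,
                 min_test_cpgs = as.integer(min_test_cpgs),
                 stat = stat),
            class = "dmr_params")
}

#' Filter replicates by median CpG coverage
#'
#' A biological replicate is retained only when its median CpG coverage
#' exceeds `max_median_cov_exclude` (default: median of 4 or less excludes).
#'
#' @param methylomes list of [methylome()]s.
#' @param params a [dmr_params()].
#' @return list with `retained` (filtered list) and `report` (data.frame of
#'   sample_id, median_cov, retained, reason).
#' @export
filter_replicates <- function(methylomes, params = dmr_params()) {
  med <- vapply(methylomes, function(m)
    if (nrow(m$cpgs)) stats::median(m$cpgs$total) else NA_real_, numeric(1))
  ids <- vapply(methylomes, function(m) m$sample_id, character(1))
  keep <- !is.na(med) & med > params$max_median_cov_exclude
  reason <- ifelse(is.na(med), "no CpGs",
                   ifelse(keep, "",
                          sprintf("median coverage <= %d",
                                  params$max_median_cov_exclude)))
  list(retained = methylomes[keep],
       report = data.frame(sample_id = ids, median_cov = med,
                           retained = keep, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Exclude PMRs largely contained in a single gene
#'
#' Genic regions downstream of gUMRs are frequently partially methylated
#' too, so a PMR is removed from differential testing when, for some single
#' gene, the overlap covers at least `pmr_gene_overlap_exclude` (default
#' 75%) of the PMR. Overlaps with different genes are not summed.
#'
#' @param pmrs PMR region data.frame.
#' @param genes gene-model data.frame.
#' @param params a [dmr_params()].
#' @return the PMR data.frame with excluded rows removed.
#' @export
exclude_gene_spanning_pmrs <- function(pmrs, genes, params = dmr_params()) {
  if (!nrow(pmrs) || !nrow(genes)) return(pmrs)
  pmr_gr <- regions_to_gr(pmrs)
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(pmr_gr, gene_gr)
  drop <- rep(FALSE, nrow(pmrs))
  if (length(hits)) {
    ov <- IRanges::width(IRanges::pintersect(pmr_gr[S4Vectors::queryHits(hits)],
                                             gene_gr[S4Vectors::subjectHits(hits)]))
    frac <- ov / IRanges::width(pmr_gr[S4Vectors::queryHits(hits)])
    bad <- unique(S4Vectors::queryHits(hits)[frac >= params$pmr_gene_overlap_exclude])
    drop[bad] <- TRUE
  }
  pmrs[!drop, , drop = FALSE]
}

# level and coverage matrices over the CpGs present (with required minimum
# coverage) in every sample of both groups
common_cpg_matrices <- function(samples, min_cov) {
  keys <- lapply(samples, function(m) {
    ok <- m$cpgs$total >= min_cov
    paste(m$cpgs$chrom[ok], m$cpgs$pos[ok])
  })
  common <- Reduce(intersect, keys)
  first <- samples[[1L]]$cpgs
  sel <- match(common, paste(first$chrom, first$pos))
  anchor <- first[sel, c("chrom", "pos"), drop = FALSE]
  ord <- order(anchor$chrom, anchor$pos)
  anchor <- anchor[ord, , drop = FALSE]
  key <- paste(anchor$chrom, anchor$pos)
  L <- W <- matrix(NA_real_, nrow = length(key), ncol = length(samples))
  for (j in seq_along(samples)) {
    m <- samples[[j]]$cpgs
    idx <- match(key, paste(m$chrom, m$pos))
    L[, j] <- m$level[idx]
    W[, j] <- m$total[idx]
  }
  list(anchor = anchor, level = L, cov = W)
}

#' Replicate-aware differential methylation over predefined regions
#'
#' For each region: CpGs are kept only when covered (at least
#' `min_cov_per_cpg` reads) in every retained sample of both groups; group
#' means are coverage-weighted over the kept CpGs; the p-value comes from a
#' two-sided Mann-Whitney rank-sum test comparing the pooled per-(CpG,
#' sample) levels of the two groups (or a Welch t on per-sample region means
#' when `stat = "welch"`). A region is significant when `|diff| > min_diff`
#' and `p <= alpha`. Regions with fewer than `min_test_cpgs` kept CpGs are
#' reported untestable with `p = 1`. A Benjamini-Hochberg q-value column is
#' included for transparency but does not gate significance.
#'
#' @param regions region data.frame to test.
#' @param group_a,group_b lists of [methylome()]s (replicates are filtered
#'   by [filter_replicates()] first; each group needs at least 2 retained).
#' @param params a [dmr_params()].
#' @return data.frame with one row per region: the region columns plus
#'   n_cpg_tested, mean_a, mean_b, diff (mean_b - mean_a), p_value, q_value,
#'   significant, untestable.
#' @export
region_dmr_test <- function(regions, group_a, group_b, params = dmr_params()) {
  stopifnot(nrow(regions) >= 1L)
  fa <- filter_replicates(group_a, params)
  fb <- filter_replicates(group_b, params)
  if (length(fa$retained) < 2L || length(fb$retained) < 2L)
    stop("fewer than 2 retained replicates in a group after coverage filtering")
  na <- length(fa$retained)
  samples <- c(fa$retained, fb$retained)
  mat <- common_cpg_matrices(samples, params$min_cov_per_cpg)
  ridx <- cpg_region_index(mat$anchor, regions)
  n <- nrow(regions)
  res <- regions
  res$n_cpg_tested <- 0L
  res$mean_a <- NA_real_; res$mean_b <- NA_real_
  res$diff <- 0; res$p_value <- 1; res$untestable <- TRUE
  a_cols <- seq_len(na)
  b_cols <- seq.int(na + 1L, length(samples))
  for (r in seq_len(n)) {
    rows <- which(ridx == r)
    k <- length(rows)
    res$n_cpg_tested[r] <- k
    if (k == 0L) next
    La <- mat$level[rows, a_cols, drop = FALSE]
    Lb <- mat$level[rows, b_cols, drop = FALSE]
    Wa <- mat$cov[rows, a_cols, drop = FALSE]
    Wb <- mat$cov[rows, b_cols, drop = FALSE]
    res$mean_a[r] <- sum(La * Wa) / sum(Wa)
    res$mean_b[r] <- sum(Lb * Wb) / sum(Wb)
    res$diff[r] <- res$mean_b[r] - res$mean_a[r]
    if (k < params$min_test_cpgs) next
    res$untestable[r] <- FALSE
    res$p_value[r] <- if (params$stat == "welch") {
      ma <- colSums(La * Wa) / colSums(Wa)
      mb <- colSums(Lb * Wb) / colSums(Wb)
      if (stats::sd(ma) == 0 && stats::sd(mb) == 0) {
        if (isTRUE(all.equal(mean(ma), mean(mb)))) 1 else 0
      } else stats::t.test(ma, mb)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(as.vector(La), as.vector(Lb),
                                          exact = FALSE)$p.value)
    }
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !res$untestable & abs(res$diff) > params$min_diff &
    res$p_value <= params$alpha
  res
}
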