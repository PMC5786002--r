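known_marks <- c("H3K27ac", "H3K9ac", "H3K4me3", "H3K4me1", "H3K36me3",
                 "H3K9me3", "H3K27me3", "5hmC", "input")
promoter_marks <- c("H3K27ac", "H3K9ac", "H3K4me3")

# quantification mode implied by the mark: promoter (TSS +/- 1 kb) for the
# acetylation/H3K4me3 marks, genic (TSS to TES) for the rest
mark_mode <- function(mark) {
  if (mark %in% promoter_marks) "promoter" else "genic"
}

#' Construct a chromatin-mark coverage track
#'
#' A step-wise non-negative coverage function over the genome (bedGraph
#' intervals, 0-based half-open), with its genome-wide total
#' (`sum(value * span)`) and a normalization scale factor (1 before
#' normalization).
#'
#' @param coverage data.frame with columns chrom, start, end, value.
#' @param sample_id sample identifier.
#' @param mark mark name (one of the histone marks, `5hmC` or `input`).
#' @return object of class `mark_track`.
#' @export
mark_track <- function(coverage, sample_id, mark) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(coverage)))
  if (!mark %in% known_marks) stop("unknown mark: ", mark)
  if (any(coverage$value < 0)) stop("coverage values must be non-negative")
  if (any(coverage$start >= coverage$end)) stop("empty coverage interval")
  coverage <- coverage[order(coverage$chrom, coverage$start), , drop = FALSE]
  for (chr in unique(coverage$chrom)) {
    sel <- coverage$chrom == chr
    s <- coverage$start[sel]; e <- coverage$end[sel]
    if (any(s[-1L] < e[-length(e)]))
      stop("overlapping coverage intervals on ", chr)
  }
  rownames(coverage) <- NULL
  structure(list(sample_id = sample_id, mark = mark, coverage = coverage,
                 genome_total = sum(coverage$value *
                                      (coverage$end - coverage$start)),
                 scale_factor = 1),
            class = "mark_track")
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph path (gzip-transparent); `track`/`#` lines skipped.
#' @param sample_id sample identifier.
#' @param mark mark name.
#' @return a [mark_track()].
#' @export
read_mark_track <- function(path, sample_id, mark) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(lines))
    return(mark_track(data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), value = numeric()),
                      sample_id, mark))
  tab <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  mark_track(data.frame(chrom = tab[[1L]], start = as.numeric(tab[[2L]]),
                        end = as.numeric(tab[[3L]]),
                        value = as.numeric(tab[[4L]])),
             sample_id, mark)
}

#' Normalize tracks to the geometric mean of genome-wide signal
#'
#' Sets each track's scale factor to `G / genome_total` where `G` is the
#' geometric mean of the genome-wide totals across tracks, so that scaled
#' totals are equalized while their log-sum is conserved.
#'
#' @param tracks list of [mark_track()]s to normalize jointly.
#' @return the list with `scale_factor` set on each track.
#' @export
normalize_to_geometric_mean <- function(tracks) {
  stopifnot(length(tracks) >= 2L)
  totals <- vapply(tracks, function(t) t$genome_total, numeric(1))
  if (any(totals <= 0))
    stop("all tracks must have positive genome-wide signal")
  g <- exp(mean(log(totals)))
  for (i in seq_along(tracks)) tracks[[i]]$scale_factor <- g / totals[i]
  tracks
}

#' Build quantification targets from gene models
#'
#' Promoter mode builds `[TSS - 1000, TSS + 1000)`; genic mode the genic
#' extent `[min(tss, tes), max(tss, tes))`.
#'
#' @param genes gene-model data.frame.
#' @param mode `"promoter"` or `"genic"`.
#' @param promoter_flank half-width of the promoter window in bp.
#' @return data.frame with gene_id, chrom, start, end.
#' @export
quantification_targets <- function(genes, mode = c("promoter", "genic"),
                                   promoter_flank = 1000) {
  mode <- match.arg(mode)
  if (mode == "promoter") {
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$tss - promoter_flank,
               end = genes$tss + promoter_flank,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start, end = genes$end,
               stringsAsFactors = FALSE)
  }
}

#' Quantify scaled mark signal over targets
#'
#' Signal per target is the sum over overlapping coverage steps of
#' `value * overlap span * scale_factor`. Targets are built from gene models
#' (mode auto-selected from the mark: promoters for H3K27ac/H3K9ac/H3K4me3,
#' genic intervals otherwise) or supplied explicitly (the path used for LMR
#' windows and 5hmC). Targets extending past chromosome bounds are clipped
#' with a warning when `chrom_sizes` is given.
#'
#' @param track a [mark_track()] (normalize first).
#' @param genes gene-model data.frame (ignored when `regions` given).
#' @param mode `"auto"`, `"promoter"` or `"genic"`.
#' @param regions explicit target data.frame with chrom, start, end and
#'   optionally an id column `gene_id`/`name`.
#' @param chrom_sizes optional named chromosome lengths used for clipping.
#' @return data.frame with target id, chrom, start, end and `signal`.
#' @export
quantify_region_signal <- function(track, genes = NULL,
                                   mode = c("auto", "promoter", "genic"),
                                   regions = NULL, chrom_sizes = NULL) {
  mode <- match.arg(mode)
  if (is.null(regions)) {
    if (is.null(genes)) stop("either genes or regions must be given")
    if (mode == "auto") mode <- mark_mode(track$mark)
    tgt <- quantification_targets(genes, mode)
  } else {
    id <- if ("gene_id" %in% names(regions)) regions$gene_id
    else if ("name" %in% names(regions)) regions$name
    else sprintf("region_%d", seq_len(nrow(regions)))
    tgt <- data.frame(gene_id = id, chrom = regions$chrom,
                      start = regions$start, end = regions$end,
                      stringsAsFactors = FALSE)
  }
  lim <- if (!is.null(chrom_sizes)) unname(chrom_sizes[tgt$chrom]) else Inf
  clip <- tgt$start < 0 | tgt$end > lim
  if (any(clip, na.rm = TRUE)) {
    warning(sum(clip, na.rm = TRUE), " target(s) clipped to chromosome bounds")
    tgt$start <- pmax(0, tgt$start)
    tgt$end <- pmin(tgt$end, lim)
  }
  cov <- track$coverage
  tgt$signal <- 0
  if (nrow(cov) && nrow(tgt)) {
    cov_gr <- GenomicRanges::GRanges(cov$chrom,
                                     IRanges::IRanges(cov$start + 1, cov$end))
    tgt_gr <- GenomicRanges::GRanges(tgt$chrom,
                                     IRanges::IRanges(tgt$start + 1, tgt$end))
    hits <- GenomicRanges::findOverlaps(tgt_gr, cov_gr)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        tgt_gr[S4Vectors::queryHits(hits)], cov_gr[S4Vectors::subjectHits(hits)]))
      contrib <- cov$value[S4Vectors::subjectHits(hits)] * ov
      agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
      tgt$signal[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  tgt$signal <- tgt$signal * track$scale_factor
  tgt
}

#' Log2 condition ratios of mark signal over targets
#'
#' Computes `log2((signal_b + pc) / (signal_a + pc))` per target from two
#' scaled tracks of the same mark. The pseudocount `pc` defaults to 1% of
#' the mark's genome-wide mean per-kb scaled signal (averaged over the two
#' tracks), bounding ratios at empty regions.
#'
#' @param track_a,track_b normalized [mark_track()]s (e.g. NF and F).
#' @param pseudocount override for the pseudocount (per kb of target).
#' @inheritParams quantify_region_signal
#' @return data.frame of targets with `signal_a`, `signal_b`, `log2_ratio`.
#' @export
mark_log2_ratios <- function(track_a, track_b, genes = NULL, mode = "auto",
                             regions = NULL, chrom_sizes = NULL,
                             pseudocount = NULL) {
  qa <- quantify_region_signal(track_a, genes, mode, regions, chrom_sizes)
  qb <- quantify_region_signal(track_b, genes, mode, regions, chrom_sizes)
  if (is.null(pseudocount)) {
    per_kb <- function(t) {
      span <- sum(t$coverage$end - t$coverage$start)
      if (span == 0) return(0)
      t$genome_total * t$scale_factor / (span / 1000)
    }
    pseudocount <- 0.01 * mean(c(per_kb(track_a), per_kb(track_b)))
  }
  span_kb <- (qa$end - qa$start) / 1000
  pc <- pseudocount * span_kb
  out <- qa[, c("gene_id", "chrom", "start", "end")]
  out$signal_a <- qa$signal
  out$signal_b <- qb$signal
  out$log2_ratio <- log2((qb$signal + pc) / (qa$signal + pc))
  out
}

#' Combine per-mark log2 ratios on the log scale
#'
#' The combined per-gene score is the arithmetic mean of the individual
#' marks' log2 ratios, i.e. the marks are averaged on a logarithmic scale.
#'
#' @param ratios matrix or data.frame of log2 ratios (genes x marks).
#' @return numeric vector of combined scores.
#' @export
combine_mark_ratios <- function(ratios) {
  m <- as.matrix(ratios)
  rowMeans(m)
}

#' Regress expression-change rank on mark ratios
#'
#' Differential genes are ranked by `log2fc` (rank 1..N). Each mark's log2
#' ratio is fit by a cubic polynomial of the rank and its R-squared
#' (`1 - SSres/SStot`) reported; a combined model regresses the rank on two
#' named marks' ratios with quadratic terms and reports R-squared on the
#' rank. A constant predictor yields R-squared 0 with a warning.
#'
#' @param de data.frame with `gene_id`, `log2fc` (differential genes only).
#' @param mark_ratios matrix/data.frame of per-gene per-mark log2 ratios,
#'   rownames = gene ids.
#' @param combine character vector of two mark names for the combined model
#'   (default the two best-predicting marks of the study design,
#'   H3K27ac and H3K36me3, when present).
#' @return list of class `rank_regression` with `per_mark_r2`,
#'   `combined_r2`, `combined_marks` and `ranked` (gene order).
#' @export
expression_rank_regression <- function(de, mark_ratios, combine = NULL) {
  m <- as.matrix(mark_ratios)
  common <- intersect(de$gene_id, rownames(m))
  if (length(common) < 10L)
    stop("need at least 10 differential genes with mark data")
  de <- de[match(common, de$gene_id), , drop = FALSE]
  m <- m[common, , drop = FALSE]
  ord <- order(de$log2fc)
  de <- de[ord, , drop = FALSE]
  m <- m[ord, , drop = FALSE]
  rank <- seq_len(nrow(de))
  fit_r2 <- function(y, X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(0)
    max(0, 1 - ss_res / ss_tot)
  }
  per_mark <- vapply(colnames(m), function(mk) {
    x <- m[, mk]
    if (stats::sd(x) == 0) {
      warning("constant predictor for mark ", mk, "; R2 set to 0")
      return(0)
    }
    fit_r2(x, cbind(rank, rank^2, rank^3))
  }, numeric(1))
  if (is.null(combine)) {
    cand <- intersect(c("H3K27ac", "H3K36me3"), colnames(m))
    combine <- if (length(cand) == 2L) cand else
      names(sort(per_mark, decreasing = TRUE))[seq_len(min(2L, ncol(m)))]
  }
  combined <- NA_real_
  if (length(combine) == 2L && all(combine %in% colnames(m))) {
    x1 <- m[, combine[1L]]; x2 <- m[, combine[2L]]
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
      warning("constant predictor in combined model; R2 set to 0")
      combined <- 0
    } else {
      combined <- fit_r2(rank, cbind(x1, x2, x1^2, x2^2))
    }
  }
  structure(list(per_mark_r2 = per_mark, combined_r2 = combined,
                 combined_marks = combine, ranked = de$gene_id),
            class = "rank_regression")
}

#' @export
print.rank_regression <- function(x, ...) {
  cat("<rank_regression>\n  per-mark R2:\n")
  for (mk in names(x$per_mark_r2))
    cat(sprintf("    %-10s %.3f\n", mk, x$per_mark_r2[mk]))
  cat(sprintf("  combined (%s): R2 = %.3f\n",
              paste(x$combined_marks, collapse = " + "), x$combined_r2))
  invisible(x)
}
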