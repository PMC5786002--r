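#' Default class methylation models
#'
#' Per-class Beta distributions for latent per-CpG methylation: FMR
#' Beta(17, 3) (mean 0.85), UMR Beta(2, 38) (mean 0.05), LMR Beta(6, 14)
#' (mean 0.30), CGI Beta(1, 49) (mean 0.02) and PMR Uniform(0, 1), mirroring
#' the empirical picture of polarized methylomes: fully methylated
#' background, near-zero UMRs/islands, 10-50% LMRs and disordered PMRs.
#'
#' @return named list mapping class to `c(alpha, beta)`; the PMR entry is
#'   `c(1, 1)` (uniform).
#' @export
class_methylation_model <- function() {
  list(FMR = c(17, 3), UMR = c(2, 38), LMR = c(6, 14),
       CGI = c(1, 49), PMR = c(1, 1))
}

#' Simulate a genome layout with planted methylation segments
#'
#' Builds a toy chromosome with geometric inter-CpG spacing (mean
#' `mean_gap`), plants non-overlapping PMR, UMR and LMR segments on a fully
#' methylated background, and places CpG islands (densified `cgi_density`-
#' fold) inside a subset of the UMRs. Every CpG is assigned to exactly one
#' methylation class; CGIs coincide with their host UMR in the methylation
#' layer but carry the CGI emission model.
#'
#' The default layout is a 5 Mb chromosome of roughly 50,000 CpGs with 40%
#' of the sequence in 8 PMR blocks, 120 LMRs of 800 bp and 10 UMRs of 4 kb
#' (6 of them hosting a 600 bp island).
#'
#' @param chrom_length chromosome length in bp.
#' @param mean_gap mean inter-CpG gap in bp outside islands.
#' @param n_pmr,pmr_length number and length of PMR blocks.
#' @param n_lmr,lmr_length number and length of LMR segments.
#' @param n_umr,umr_length number and length of UMR segments.
#' @param n_cgi,cgi_length number and length of CpG islands (placed inside
#'   the first `n_cgi` UMRs).
#' @param cgi_density CpG densification factor inside islands.
#' @param seed integer seed.
#' @return list of class `genome_layout` with `chrom_sizes`, `cpgs`
#'   (chrom, pos, class), and `truth` — planted zones plus the CpG-dyad
#'   span (`span_start`, `span_end`) of each segment.
#' @export
simulate_genome_layout <- function(chrom_length = 5e6, mean_gap = 100,
                                   n_pmr = 8L, pmr_length = 250e3,
                                   n_lmr = 120L, lmr_length = 800,
                                   n_umr = 10L, umr_length = 4000,
                                   n_cgi = 6L, cgi_length = 600,
                                   cgi_density = 5, seed = 1L) {
  stopifnot(n_cgi <= n_umr, cgi_length < umr_length)
  total_planted <- n_pmr * pmr_length + n_lmr * lmr_length + n_umr * umr_length
  if (total_planted >= chrom_length * 0.95)
    stop("planted segments exceed the chromosome")
  withr::with_seed(seed, {
    # place segments without overlap: shuffle a slot sequence with FMR spacers
    n_seg <- n_pmr + n_lmr + n_umr
    lens <- c(rep(pmr_length, n_pmr), rep(lmr_length, n_lmr),
              rep(umr_length, n_umr))
    cls <- c(rep("PMR", n_pmr), rep("LMR", n_lmr), rep("UMR", n_umr))
    ord <- sample(n_seg)
    lens <- lens[ord]; cls <- cls[ord]
    slack <- chrom_length - sum(lens)
    # FMR spacer before each segment and after the last one; a minimum
    # spacer keeps planted segments strictly separated
    min_spacer <- 1000
    if (slack <= (n_seg + 1) * min_spacer)
      stop("not enough slack for FMR spacers between planted segments")
    cuts <- sort(stats::runif(n_seg))
    gaps <- min_spacer + diff(c(0, cuts, 1)) * (slack - (n_seg + 1) * min_spacer)
    starts <- cumsum(gaps[seq_len(n_seg)] + c(0, lens[-n_seg]))
    starts <- round(starts)
    truth <- data.frame(chrom = "chrS", start = starts,
                        end = starts + lens, class = cls,
                        stringsAsFactors = FALSE)
    # islands inside the first n_cgi UMRs (centered)
    umr_rows <- which(truth$class == "UMR")
    cgi <- NULL
    if (n_cgi > 0L) {
      host <- umr_rows[seq_len(n_cgi)]
      cstart <- round((truth$start[host] + truth$end[host] - cgi_length) / 2)
      cgi <- data.frame(chrom = "chrS", start = cstart,
                        end = cstart + cgi_length, class = "CGI",
                        stringsAsFactors = FALSE)
    }
    # CpG positions: geometric gaps, densified inside islands
    n_draw <- ceiling(chrom_length / mean_gap * 1.4) + 1000L
    gaps_bp <- stats::rgeom(n_draw, 1 / mean_gap) + 1L
    pos <- cumsum(gaps_bp)
    pos <- pos[pos < chrom_length]
    if (!is.null(cgi)) {
      extra <- unlist(lapply(seq_len(nrow(cgi)), function(i) {
        n_extra <- ceiling(cgi_length / mean_gap * (cgi_density - 1))
        sort(sample(cgi$start[i]:(cgi$end[i] - 2L), n_extra))
      }))
      pos <- sort(unique(c(pos, extra)))
    }
    pos <- as.numeric(pos)
    cpgs <- data.frame(chrom = "chrS", pos = pos, stringsAsFactors = FALSE)
    cls_vec <- rep("FMR", nrow(cpgs))
    seg_idx <- cpg_region_index(cpgs, region_table(truth$chrom, truth$start,
                                                   truth$end, truth$class))
    cls_vec[!is.na(seg_idx)] <- truth$class[seg_idx[!is.na(seg_idx)]]
    if (!is.null(cgi)) {
      cgi_idx <- cpg_region_index(cpgs, region_table(cgi$chrom, cgi$start,
                                                     cgi$end, "CGI"))
      cls_vec[!is.na(cgi_idx)] <- "CGI"
    }
    cpgs$class <- cls_vec
    if (!is.null(cgi)) truth <- rbind(truth, cgi)
    truth <- truth[order(truth$start), , drop = FALSE]
    # CpG-dyad span of each planted segment (the truth used for recovery)
    truth$span_start <- NA_real_; truth$span_end <- NA_real_
    for (i in seq_len(nrow(truth))) {
      inside <- cpgs$pos >= truth$start[i] & cpgs$pos < truth$end[i]
      if (any(inside)) {
        truth$span_start[i] <- min(cpgs$pos[inside])
        truth$span_end[i] <- max(cpgs$pos[inside]) + 2
      }
    }
    rownames(truth) <- NULL
  })
  structure(list(chrom_sizes = c(chrS = chrom_length), cpgs = cpgs,
                 truth = truth),
            class = "genome_layout")
}

# latent methylation per CpG given its class
draw_latent <- function(classes, model) {
  m <- numeric(length(classes))
  for (cl in unique(classes)) {
    sel <- classes == cl
    ab <- model[[cl]]
    if (is.null(ab)) stop("no methylation model for class ", cl)
    m[sel] <- stats::rbeta(sum(sel), ab[1], ab[2])
  }
  m
}

rpois_pos <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

#' Simulate a WGBS methylome over a genome layout
#'
#' Per CpG: latent methylation drawn from its class Beta model, coverage
#' from a zero-truncated Poisson with the given mean, and the methylated
#' read count from a Binomial(coverage, latent). Bit-reproducible per seed.
#'
#' @param layout a [simulate_genome_layout()] result.
#' @param model class methylation models ([class_methylation_model()]).
#' @param mean_coverage mean sequencing coverage per CpG.
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @param coverage_model `"poisson"` (zero-truncated, default) or
#'   `"constant"` (every CpG at exactly `round(mean_coverage)` reads).
#' @return list with `methylome` (a [methylome()] whose cpgs carry the true
#'   `class` and `latent` columns stripped off) and `truth` (planted
#'   segments); the latent levels are returned in `latent`.
#' @export
simulate_methylome <- function(layout, model = class_methylation_model(),
                               mean_coverage = 30, seed = 1L,
                               sample_id = "synthetic",
                               coverage_model = c("poisson", "constant")) {
  coverage_model <- match.arg(coverage_model)
  cpgs <- layout$cpgs
  withr::with_seed(seed, {
    m <- draw_latent(cpgs$class, model)
    cov <- if (coverage_model == "constant")
      rep(max(1L, round(mean_coverage)), nrow(cpgs))
    else rpois_pos(nrow(cpgs), mean_coverage)
    meth <- stats::rbinom(nrow(cpgs), cov, m)
  })
  meth_obj <- methylome(data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                                   meth = meth, total = cov),
                        sample_id, layout$chrom_sizes)
  list(methylome = meth_obj, truth = layout$truth, latent = m,
       class = cpgs$class)
}

#' Simulate replicate groups with planted methylation differences
#'
#' Generates two groups of replicate methylomes sharing one latent
#' methylation landscape. Inside the regions of `dmr_spec`, group B's latent
#' methylation is shifted by `delta` (clipped to `[0, 1]`). Replicate noise
#' is beta-binomial: each replicate redraws its per-CpG methylation from a
#' Beta centered on the latent mean with the given concentration, so the
#' differential test faces realistic overdispersion.
#'
#' @param layout a [simulate_genome_layout()] result.
#' @param model class methylation models.
#' @param dmr_spec region data.frame of planted DMRs with a `delta` column
#'   (may be empty for a null simulation).
#' @param n_per_group replicates per group.
#' @param mean_coverage mean coverage per CpG and replicate.
#' @param concentration beta concentration of replicate noise.
#' @param seed integer seed.
#' @return list with `group_a`, `group_b` (lists of [methylome()]) and
#'   `truth` (the planted DMR table).
#' @export
simulate_replicate_groups <- function(layout, model = class_methylation_model(),
                                      dmr_spec = NULL, n_per_group = 3L,
                                      mean_coverage = 20, concentration = 50,
                                      seed = 1L) {
  cpgs <- layout$cpgs
  n <- nrow(cpgs)
  if (is.null(dmr_spec))
    dmr_spec <- cbind(region_table(), delta = numeric())
  withr::with_seed(seed, {
    latent <- draw_latent(cpgs$class, model)
    latent_b <- latent
    if (nrow(dmr_spec)) {
      idx <- cpg_region_index(cpgs, dmr_spec)
      hit <- !is.na(idx)
      latent_b[hit] <- pmin(1, pmax(0, latent[hit] + dmr_spec$delta[idx[hit]]))
    }
    draw_group <- function(latent_m, tag) {
      lapply(seq_len(n_per_group), function(r) {
        eps <- 1e-4
        mclip <- pmin(1 - eps, pmax(eps, latent_m))
        m_rep <- stats::rbeta(n, mclip * concentration,
                              (1 - mclip) * concentration)
        cov <- rpois_pos(n, mean_coverage)
        meth <- stats::rbinom(n, cov, m_rep)
        methylome(data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                             meth = meth, total = cov),
                  sprintf("%s_rep%d", tag, r), layout$chrom_sizes)
      })
    }
    group_a <- draw_group(latent, "groupA")
    group_b <- draw_group(latent_b, "groupB")
  })
  list(group_a = group_a, group_b = group_b, truth = dmr_spec)
}

#' Simulate chromatin-mark tracks coupled to expression changes
#'
#' For each gene, the mark's log2 condition ratio is
#' `rho * standardized(log2fc) + sqrt(1 - rho^2) * noise`, so the squared
#' coupling `rho^2` is the analytic variance share of the expression signal
#' in each mark. Coverage is rendered flat over each gene's quantification
#' target (promoter or genic interval by mark), with baseline 1 in the
#' reference condition and `2^log2ratio` in the other.
#'
#' @param genes gene-model data.frame ([gene_models()]).
#' @param de_table data.frame with `gene_id`, `log2fc`, `q_value` (and
#'   optional fpkm columns); see [simulate_de_table()].
#' @param marks character vector of mark names to render.
#' @param rho coupling between expression change and mark ratio, in [0, 1].
#' @param chrom_sizes named chromosome lengths (for track bounds).
#' @param seed integer seed.
#' @return list with `tracks` (list of [mark_track()]s named
#'   `<mark>.<condition>`, conditions `NF` and `F`), `de_table`, and
#'   `log2ratio` (gene x mark matrix of planted ratios).
#' @export
simulate_mark_tracks <- function(genes, de_table, marks = c("H3K27ac", "H3K36me3"),
                                 rho = 0.7, chrom_sizes, seed = 1L) {
  stopifnot(rho >= 0, rho <= 1)
  de_table <- de_table[match(genes$gene_id, de_table$gene_id), , drop = FALSE]
  z <- as.numeric(scale(de_table$log2fc))
  n <- nrow(genes)
  withr::with_seed(seed, {
    ratio <- sapply(marks, function(mk)
      rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  })
  ratio <- matrix(ratio, nrow = n, dimnames = list(genes$gene_id, marks))
  tracks <- list()
  for (mk in marks) {
    tgt <- quantification_targets(genes, mark_mode(mk))
    base <- data.frame(chrom = tgt$chrom, start = tgt$start, end = tgt$end,
                       value = 1)
    f <- base; f$value <- 2^ratio[, mk]
    tracks[[paste0(mk, ".NF")]] <- mark_track(base, paste0(mk, "_NF"), mk)
    tracks[[paste0(mk, ".F")]] <- mark_track(f, paste0(mk, "_F"), mk)
  }
  list(tracks = tracks, de_table = de_table, log2ratio = ratio)
}

#' Simulate a differential-expression table
#'
#' Gene log2 fold-changes are drawn from a normal distribution; q-values are
#' set below 0.05 (all genes "differential") and FPKM above the 3-FPKM floor,
#' matching the filters the expression input is assumed to have passed.
#'
#' @param genes gene-model data.frame.
#' @param sd_log2fc standard deviation of the fold-changes.
#' @param seed integer seed.
#' @return data.frame with gene_id, log2fc, q_value, fpkm_a, fpkm_b.
#' @export
simulate_de_table <- function(genes, sd_log2fc = 2, seed = 1L) {
  withr::with_seed(seed, {
    lfc <- stats::rnorm(nrow(genes), 0, sd_log2fc)
    fpkm_a <- stats::rlnorm(nrow(genes), log(20), 0.5) + 3
    qv <- stats::runif(nrow(genes), 0, 0.049)
  })
  data.frame(gene_id = genes$gene_id, log2fc = lfc, q_value = qv,
             fpkm_a = fpkm_a, fpkm_b = fpkm_a * 2^lfc)
}

#' Simulate trait SNP sets with a planted LMR enrichment
#'
#' Each SNP falls inside an LMR with probability `p_in = fold * f` where `f`
#' is the LMR fraction of the genome, so the expected fold enrichment over
#' uniform placement equals the requested fold. In-LMR SNPs pick an LMR with
#' probability proportional to its length and a uniform position inside it;
#' the rest are placed uniformly outside LMRs.
#'
#' @param lmrs LMR region data.frame.
#' @param chrom_sizes named chromosome lengths.
#' @param fold requested fold enrichment (must not exceed `1 / f`).
#' @param n_snps number of SNPs.
#' @param trait trait label.
#' @param seed integer seed.
#' @return data.frame with chrom, pos, trait, provenance plus the attribute
#'   `truth_fold`.
#' @export
simulate_snp_set <- function(lmrs, chrom_sizes, fold = 1, n_snps = 500L,
                             trait = "trait", seed = 1L) {
  lmr_bp <- sum(lmrs$end - lmrs$start)
  genome_bp <- sum(chrom_sizes)
  f <- lmr_bp / genome_bp
  p_in <- fold * f
  if (p_in > 1)
    stop(sprintf("requested fold %.2f exceeds 1/LMR-fraction = %.2f",
                 fold, 1 / f))
  withr::with_seed(seed, {
    inside <- stats::runif(n_snps) < p_in
    pos <- numeric(n_snps); chrom <- character(n_snps)
    if (any(inside)) {
      pick <- sample(nrow(lmrs), sum(inside), replace = TRUE,
                     prob = lmrs$end - lmrs$start)
      chrom[inside] <- lmrs$chrom[pick]
      pos[inside] <- floor(stats::runif(sum(inside), lmrs$start[pick],
                                        lmrs$end[pick]))
    }
    n_out <- sum(!inside)
    if (n_out) {
      # uniform over the genome, rejecting in-LMR draws
      lmr_gr <- regions_to_gr(lmrs)
      draw <- function(k) {
        chr <- sample(names(chrom_sizes), k, replace = TRUE,
                      prob = chrom_sizes)
        p <- floor(stats::runif(k, 0, chrom_sizes[chr]))
        list(chr = chr, p = p)
      }
      got_chr <- character(0); got_pos <- numeric(0)
      while (length(got_pos) < n_out) {
        d <- draw(n_out - length(got_pos))
        pts <- GenomicRanges::GRanges(d$chr, IRanges::IRanges(d$p + 1, width = 1))
        ok <- !IRanges::overlapsAny(pts, lmr_gr)
        got_chr <- c(got_chr, d$chr[ok]); got_pos <- c(got_pos, d$p[ok])
      }
      chrom[!inside] <- got_chr; pos[!inside] <- got_pos
    }
  })
  snps <- data.frame(chrom = chrom, pos = pos, trait = trait,
                     provenance = "lead", stringsAsFactors = FALSE)
  snps <- unique(snps)
  attr(snps, "truth_fold") <- fold
  snps
}
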