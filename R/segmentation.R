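#' Segmentation parameters
#'
#' Tunable parameters of the methylome segmentation. Defaults follow the
#' published procedure: a 101-CpG sliding disorder window with step 1, a
#' 3-CpG smoothing window, hypomethylated-region detection at >= 3 CpGs and
#' mean methylation <= 50%, a 30-CpG cutoff separating LMRs (< 30 CpGs) from
#' UMRs (>= 30 CpGs), and an FDR threshold of 5% for shuffle calibration.
#'
#' @param window_cpgs odd integer, width of the disorder window in CpGs.
#' @param window_step step of the sliding window in CpGs.
#' @param smooth_cpgs width of the post-masking smoothing window in CpGs.
#' @param min_cpgs minimum CpGs per hypomethylated region.
#' @param max_meth maximum smoothed methylation of a hypomethylated CpG run.
#' @param lmr_umr_cutoff CpG-count cutoff between LMR and UMR.
#' @param fdr_threshold target false discovery rate for calibration.
#' @param disorder_bounds open interval of levels counted as "disordered"
#'   by the window score. The default `(0.3, 0.7)` is the band around the
#'   antimode of the polarized methylation distribution: levels there are
#'   rare outside PMRs but common inside, which separates the two states
#'   far better at realistic coverage than a wide band that highly
#'   methylated CpGs blur into under binomial sampling noise.
#' @param fuse_gap_cpgs PMR runs separated by fewer than this many CpGs are
#'   fused; `NULL` (default) means one disorder window, the resolution
#'   limit of the score.
#' @param decoding `"posterior"` (default) or `"viterbi"` HMM decoding.
#' @param weighted_smooth logical; coverage-weight the smoothing window.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(window_cpgs = 101L, window_step = 1L,
                                smooth_cpgs = 3L, min_cpgs = 3L,
                                max_meth = 0.50, lmr_umr_cutoff = 30L,
                                fdr_threshold = 0.05,
                                disorder_bounds = c(0.3, 0.7),
                                fuse_gap_cpgs = NULL,
                                decoding = c("posterior", "viterbi"),
                                weighted_smooth = TRUE) {
  decoding <- match.arg(decoding)
  if (is.null(fuse_gap_cpgs)) fuse_gap_cpgs <- window_cpgs
  stopifnot(fuse_gap_cpgs >= 1L)
  stopifnot(window_cpgs %% 2L == 1L, window_cpgs >= 3L,
            window_step >= 1L, smooth_cpgs >= 1L, min_cpgs >= 1L,
            max_meth > 0, max_meth < 1, lmr_umr_cutoff > min_cpgs,
            fdr_threshold > 0, fdr_threshold < 1,
            length(disorder_bounds) == 2L,
            disorder_bounds[1] < disorder_bounds[2])
  structure(list(window_cpgs = as.integer(window_cpgs),
                 window_step = as.integer(window_step),
                 smooth_cpgs = as.integer(smooth_cpgs),
                 min_cpgs = as.integer(min_cpgs),
                 max_meth = max_meth,
                 lmr_umr_cutoff = as.integer(lmr_umr_cutoff),
                 fdr_threshold = fdr_threshold,
                 disorder_bounds = disorder_bounds,
                 fuse_gap_cpgs = as.integer(fuse_gap_cpgs),
                 decoding = decoding,
                 weighted_smooth = weighted_smooth),
            class = "segmentation_params")
}

#' Per-CpG methylation-disorder score
#'
#' Slides a centered window of `window_cpgs` CpGs (step 1) along each
#' chromosome and scores each CpG by the fraction of window CpGs whose level
#' falls strictly inside the disorder bounds (default `(0.3, 0.7)`), i.e. the
#' deviation from the polarized high/low methylation typical outside PMRs.
#' CpGs whose centered window would be truncated carry the score of the
#' nearest full window. Chromosomes with fewer CpGs than the window are
#' skipped (score `NA`) with a warning.
#'
#' @param meth a [methylome()].
#' @param params a [segmentation_params()].
#' @return numeric vector of scores aligned to `meth$cpgs` rows.
#' @export
disorder_score_track <- function(meth, params = segmentation_params()) {
  cpgs <- meth$cpgs
  w <- params$window_cpgs
  half <- (w - 1L) %/% 2L
  score <- rep(NA_real_, nrow(cpgs))
  inside <- cpgs$level > params$disorder_bounds[1] &
    cpgs$level < params$disorder_bounds[2]
  skipped <- character()
  for (chr in unique(cpgs$chrom)) {
    sel <- which(cpgs$chrom == chr)
    n <- length(sel)
    if (n < w) { skipped <- c(skipped, chr); next }
    cs <- cumsum(c(0, inside[sel]))
    full <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
    s <- c(rep(full[1L], half), full, rep(full[length(full)], half))
    score[sel] <- s
  }
  if (length(skipped))
    warning("chromosome(s) with fewer than ", w, " CpGs skipped: ",
            paste(skipped, collapse = ", "))
  score
}

# EM fit of a 2-state Gaussian-emission HMM on a score vector.
# Returns NULL when the fit degenerates (caller falls back to a threshold).
fit_hmm2 <- function(x, tol = 1e-4, max_iter = 100L) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- q
  if (diff(mu) < 1e-6) mu <- mu + c(-1e-3, 1e-3)
  sd0 <- max(stats::sd(x) / 2, 1e-3)
  sd <- c(sd0, sd0)
  trans <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  init <- c(0.5, 0.5)
  ll_old <- -Inf
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    fb <- hmm_forward_backward(x, mu, sd, trans, init)
    if (!is.finite(fb$loglik)) return(NULL)
    if (abs(fb$loglik - ll_old) < tol) break
    ll_old <- fb$loglik
    g <- fb$gamma
    ns <- colSums(g)
    if (any(ns < 1e-8)) return(NULL)
    mu <- colSums(g * x) / ns
    var <- colSums(g * (outer(x, mu, "-")^2)) / ns
    if (any(var < 1e-10)) return(NULL)
    sd <- sqrt(var)
    xi <- fb$xi
    trans <- xi / rowSums(xi)
    init <- pmax(g[1L, ], 1e-12)
    init <- init / sum(init)
  }
  list(mu = mu, sd = sd, trans = trans, init = init,
       loglik = fb$loglik, gamma = fb$gamma)
}

# turn a logical "in segment" vector over CpG indices into regions,
# fusing segments separated by fewer than `fuse_gap` intervening CpGs
runs_to_regions <- function(state, fuse_gap = 0L) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(seg)) return(seg)
  if (fuse_gap > 0L && nrow(seg) > 1L) {
    keep_start <- seg$start[1L]
    out <- list()
    for (i in seq_len(nrow(seg) - 1L)) {
      gap <- seg$start[i + 1L] - seg$end[i] - 1L
      if (gap >= fuse_gap) {
        out[[length(out) + 1L]] <- c(keep_start, seg$end[i])
        keep_start <- seg$start[i + 1L]
      }
    }
    out[[length(out) + 1L]] <- c(keep_start, seg$end[nrow(seg)])
    seg <- as.data.frame(do.call(rbind, out))
    names(seg) <- c("start", "end")
  }
  seg
}

#' Detect partially methylated regions (PMRs)
#'
#' Fits a two-state hidden Markov model with Gaussian emissions to the
#' disorder-score track of each chromosome (EM initialized from the 25th/75th
#' score percentiles; convergence when the log-likelihood change falls below
#' `1e-4` or after 100 iterations), decodes states (posterior by default) and
#' reports maximal runs of the high-score state as PMRs. Runs separated by a
#' gap of fewer than `fuse_gap_cpgs` CpGs (default: one disorder window,
#' the resolution limit of the score) are fused. Region coordinates span the first to
#' the last member CpG dyad (end exclusive).
#'
#' Two guards protect against spurious calls: when EM degenerates (vanishing
#' variance or empty state) the decoder falls back to a fixed score threshold
#' of 0.5 with a warning, and a two-state fit is only accepted when it beats
#' a single-Gaussian fit by the BIC penalty for its four extra parameters —
#' otherwise the chromosome is treated as single-state and yields no PMRs.
#'
#' @param track disorder scores from [disorder_score_track()].
#' @param meth the [methylome()] the track was computed on.
#' @param params a [segmentation_params()].
#' @return region data.frame of class PMR with `n_cpg` and coverage-weighted
#'   `mean_meth` filled in.
#' @export
detect_pmrs <- function(track, meth, params = segmentation_params()) {
  cpgs <- meth$cpgs
  stopifnot(length(track) == nrow(cpgs))
  out <- list()
  for (chr in unique(cpgs$chrom)) {
    sel <- which(cpgs$chrom == chr)
    x <- track[sel]
    if (anyNA(x)) next
    if (stats::var(x) < 1e-12) {
      state <- x > 0.5  # constant track: threshold decides, no 2-state model
    } else {
      fit <- fit_hmm2(x)
      if (is.null(fit)) {
        warning("degenerate HMM fit on ", chr,
                "; falling back to score threshold 0.5")
        state <- x > 0.5
      } else {
        # single-Gaussian reference: accept the HMM only if it clears the
        # BIC penalty for 4 extra parameters (mu2, sd2, 2 transitions)
        ll1 <- sum(stats::dnorm(x, mean(x), max(stats::sd(x), 1e-8), log = TRUE))
        if (2 * (fit$loglik - ll1) < 4 * log(length(x))) next
        hi <- which.max(fit$mu)
        state <- if (params$decoding == "viterbi") {
          hmm_viterbi(x, fit$mu, fit$sd, fit$trans, fit$init) == hi
        } else {
          fit$gamma[, hi] > 0.5
        }
      }
    }
    if (!any(state)) next
    seg <- runs_to_regions(state, fuse_gap = params$fuse_gap_cpgs)
    if (!nrow(seg)) next
    out[[chr]] <- data.frame(chrom = chr,
                             start = cpgs$pos[sel[seg$start]],
                             end = cpgs$pos[sel[seg$end]] + 2)
  }
  if (!length(out)) return(region_table())
  df <- do.call(rbind, out)
  regs <- region_table(df$chrom, df$start, df$end, "PMR")
  summarize_regions_from_cpgs(regs, cpgs)
}

# masked CpG table: rows of meth$cpgs outside the PMR set, with a `block`
# column that changes whenever masked CpGs (or a chromosome change) break
# adjacency in the original record order
mask_methylome_cpgs <- function(meth, pmrs) {
  cpgs <- meth$cpgs
  if (!nrow(cpgs)) { cpgs$block <- integer(); return(cpgs) }
  idx <- cpg_region_index(cpgs, pmrs[pmrs$class == "PMR", , drop = FALSE])
  keep <- which(is.na(idx))
  kept <- cpgs[keep, , drop = FALSE]
  if (!nrow(kept)) { kept$block <- integer(); return(kept) }
  newblk <- c(TRUE, diff(keep) > 1L | kept$chrom[-1L] != kept$chrom[-nrow(kept)])
  kept$block <- cumsum(newblk)
  rownames(kept) <- NULL
  kept
}

smooth_blocks <- function(kept, weighted = TRUE) {
  n <- nrow(kept)
  if (!n) { kept$smoothed <- numeric(); return(kept) }
  w <- if (weighted) kept$total else rep(1, n)
  lvl <- kept$level
  same_prev <- c(FALSE, kept$block[-1L] == kept$block[-n])
  same_next <- c(kept$block[-n] == kept$block[-1L], FALSE)
  wp <- c(0, w[-n]) * same_prev
  wn <- c(w[-1L], 0) * same_next
  lp <- c(0, lvl[-n]) * same_prev
  ln <- c(lvl[-1L], 0) * same_next
  kept$smoothed <- (wp * lp + w * lvl + wn * ln) / (wp + w + wn)
  kept
}

#' Mask PMRs and smooth the remaining methylation levels
#'
#' Removes CpGs inside PMRs and replaces each remaining CpG's level by the
#' coverage-weighted mean over a 3-CpG window (the CpG and its immediate
#' non-masked neighbors), truncated at chromosome and PMR boundaries so the
#' window never reaches across a masked stretch.
#'
#' @param meth a [methylome()].
#' @param pmrs PMR region data.frame (possibly empty).
#' @param params a [segmentation_params()].
#' @return data.frame of retained CpGs with columns of `meth$cpgs` plus
#'   `block` (contiguity group) and `smoothed` (smoothed level).
#' @export
mask_and_smooth <- function(meth, pmrs = region_table(),
                            params = segmentation_params()) {
  smooth_blocks(mask_methylome_cpgs(meth, pmrs), params$weighted_smooth)
}

#' Randomize a methylome
#'
#' Permutes the multiset of (level, counts) observations across the fixed CpG
#' positions of each chromosome. The CpG landscape (positions, per-chromosome
#' level distribution) is preserved; all spatial structure is destroyed.
#' Deterministic given the seed.
#'
#' @param meth a [methylome()].
#' @param seed integer seed.
#' @return a [methylome()] with shuffled observations.
#' @export
randomize_methylome <- function(meth, seed) {
  cpgs <- meth$cpgs
  withr::with_seed(seed, {
    for (chr in unique(cpgs$chrom)) {
      sel <- which(cpgs$chrom == chr)
      p <- sample(length(sel))
      cpgs[sel, c("meth", "total", "level")] <-
        cpgs[sel[p], c("meth", "total", "level")]
    }
  })
  methylome(cpgs, paste0(meth$sample_id, "_shuffled"), meth$chrom_sizes)
}

#' Detect hypomethylated regions
#'
#' Maximal runs of consecutive non-masked CpGs whose smoothed level is at
#' most `max_meth`, retained when the run spans at least `min_cpgs` CpGs
#' (defaults: 50% and 3 CpGs). Runs never cross chromosome or PMR-mask
#' boundaries. Region ends cover the last CpG dyad (last position + 2,
#' half-open); the region mean is the coverage-weighted mean of the raw
#' (unsmoothed) levels and `n_cpg` is the run length.
#'
#' @param smoothed output of [mask_and_smooth()].
#' @param min_cpgs,max_meth detection parameters.
#' @return region data.frame of class `raw`.
#' @export
detect_hypomethylated_regions <- function(smoothed, min_cpgs = 3L,
                                          max_meth = 0.50) {
  if (!nrow(smoothed)) return(region_table())
  low <- smoothed$smoothed <= max_meth
  out <- list()
  for (b in unique(smoothed$block)) {
    sel <- which(smoothed$block == b)
    seg <- runs_to_regions(low[sel], fuse_gap = 0L)
    if (!nrow(seg)) next
    seg <- seg[seg$end - seg$start + 1L >= min_cpgs, , drop = FALSE]
    if (!nrow(seg)) next
    first <- sel[seg$start]; last <- sel[seg$end]
    out[[length(out) + 1L]] <- data.frame(
      chrom = smoothed$chrom[first],
      start = smoothed$pos[first],
      end = smoothed$pos[last] + 2,
      n_cpg = seg$end - seg$start + 1L,
      mean_meth = vapply(seq_len(nrow(seg)), function(i) {
        j <- sel[seg$start[i]:seg$end[i]]
        stats::weighted.mean(smoothed$level[j], smoothed$total[j])
      }, numeric(1)))
  }
  if (!length(out)) return(region_table())
  df <- do.call(rbind, out)
  region_table(df$chrom, df$start, df$end, "raw", df$n_cpg, df$mean_meth)
}

#' Calibrate hypomethylated-region detection by methylome randomization
#'
#' For each candidate `(min_cpgs, max_meth)` pair, counts the regions
#' detected on the PMR-masked, smoothed methylome and on a randomized copy,
#' and estimates the false discovery rate as `randomized / original`
#' (defined as 1 when no region is found on the original). The randomized
#' copy permutes the per-CpG observations of the masked, smoothed methylome
#' across each chromosome's fixed positions, so the detector sees the same
#' marginal distribution of its input with all spatial structure destroyed.
#' (Re-smoothing a permuted raw methylome instead would convolve unrelated
#' single-CpG observations into composite intermediate values present in
#' neither dataset, and the null would measure that filter artifact rather
#' than the chance of spatial clustering; see the methods vignette.)
#' The chosen parameter pair is the default `(3, 0.50)` when its FDR is
#' below the threshold, otherwise the least stringent passing pair
#' (smallest `min_cpgs`, then largest `max_meth`).
#'
#' @param meth a [methylome()].
#' @param pmrs PMR regions used for masking (applied to both copies).
#' @param grid data.frame with columns `min_cpgs` and `max_meth`.
#' @param seed integer seed for the randomization.
#' @param params a [segmentation_params()].
#' @return list of class `fdr_calibration` with elements `table` (grid plus
#'   `n_original`, `n_randomized`, `fdr`), `chosen` (selected row) and
#'   `fdr_threshold`.
#' @export
calibrate_detection_params <- function(meth, pmrs, grid, seed,
                                       params = segmentation_params()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("min_cpgs", "max_meth") %in% names(grid)))
  masked <- mask_methylome_cpgs(meth, pmrs)
  sm_orig <- smooth_blocks(masked, params$weighted_smooth)
  sm_rand <- sm_orig
  perm_cols <- c("meth", "total", "level", "smoothed")
  withr::with_seed(seed, {
    for (chr in unique(sm_rand$chrom)) {
      sel <- which(sm_rand$chrom == chr)
      p <- sample(length(sel))
      sm_rand[sel, perm_cols] <- sm_rand[sel[p], perm_cols]
    }
  })
  n_orig <- n_rand <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n_orig[i] <- nrow(detect_hypomethylated_regions(
      sm_orig, grid$min_cpgs[i], grid$max_meth[i]))
    n_rand[i] <- nrow(detect_hypomethylated_regions(
      sm_rand, grid$min_cpgs[i], grid$max_meth[i]))
  }
  tab <- data.frame(min_cpgs = grid$min_cpgs, max_meth = grid$max_meth,
                    n_original = n_orig, n_randomized = n_rand,
                    fdr = ifelse(n_orig == 0, 1, n_rand / n_orig))
  pass <- tab$fdr < params$fdr_threshold
  if (!any(pass))
    stop(sprintf("no grid point reaches FDR < %g (best achieved: %.4f)",
                 params$fdr_threshold, min(tab$fdr)))
  default_row <- which(tab$min_cpgs == params$min_cpgs &
                         abs(tab$max_meth - params$max_meth) < 1e-12)
  chosen <- if (length(default_row) && pass[default_row[1L]]) {
    default_row[1L]
  } else {
    ord <- order(tab$min_cpgs, -tab$max_meth)
    ord[which(pass[ord])[1L]]
  }
  structure(list(table = tab, chosen = tab[chosen, , drop = FALSE],
                 fdr_threshold = params$fdr_threshold),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat("<fdr_calibration> chosen parameters:\n")
  print(x$chosen, row.names = FALSE)
  invisible(x)
}

#' Classify hypomethylated regions into LMR and UMR
#'
#' Regions with at least `cutoff` CpGs (default 30) are UMRs, the rest LMRs.
#' The partition is exhaustive and exclusive.
#'
#' @param regions region data.frame with `n_cpg` set.
#' @param cutoff CpG-count cutoff.
#' @return the region data.frame with `class` set to `LMR`/`UMR`.
#' @export
classify_segments <- function(regions, cutoff = 30L) {
  if (!nrow(regions)) return(regions)
  if (anyNA(regions$n_cpg)) stop("n_cpg must be set on every region")
  regions$class <- ifelse(regions$n_cpg >= cutoff, "UMR", "LMR")
  regions
}

#' Merge per-stage segmentations into a consensus set
#'
#' Within each class family — hypomethylated (LMR/UMR/raw) and PMR —
#' overlapping or book-ended intervals from all stages are merged. Merged
#' hypomethylated intervals are re-classified as LMR/UMR by their CpG count
#' in the union methylome, and CpG counts and coverage-weighted means are
#' recomputed from it for all classes.
#'
#' @param stage_sets list of region data.frames (one per stage).
#' @param meth union [methylome()] over all stages (replicate counts summed
#'   per CpG).
#' @param params a [segmentation_params()] (for the LMR/UMR cutoff).
#' @return consensus region data.frame.
#' @export
merge_stage_segmentations <- function(stage_sets, meth,
                                      params = segmentation_params()) {
  stopifnot(length(stage_sets) >= 1L)
  all_regs <- do.call(rbind, stage_sets)
  out <- list()
  hypo <- all_regs[all_regs$class %in% c("LMR", "UMR", "raw"), , drop = FALSE]
  if (nrow(hypo)) {
    merged <- gr_to_regions(GenomicRanges::reduce(regions_to_gr(hypo)))
    merged <- summarize_regions_from_cpgs(merged, meth$cpgs)
    out$hypo <- classify_segments(merged, params$lmr_umr_cutoff)
  }
  pmr <- all_regs[all_regs$class == "PMR", , drop = FALSE]
  if (nrow(pmr)) {
    merged <- gr_to_regions(GenomicRanges::reduce(regions_to_gr(pmr)), "PMR")
    out$pmr <- summarize_regions_from_cpgs(merged, meth$cpgs)
  }
  if (!length(out)) return(region_table())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Segment one stage methylome end to end
#'
#' Convenience wrapper running disorder scoring, PMR detection, masking and
#' smoothing, hypomethylated-region detection and LMR/UMR classification,
#' optionally preceded by shuffle-FDR calibration of the detection
#' parameters.
#'
#' @param meth a [methylome()] (replicates pooled).
#' @param params a [segmentation_params()].
#' @param seed seed for the calibration shuffle (required when `calibrate`).
#' @param calibrate logical; run [calibrate_detection_params()] on the
#'   default grid and use the chosen parameters for detection.
#' @param grid calibration grid (defaults to min_cpgs 3..6 crossed with
#'   max_meth 0.3/0.4/0.5).
#' @return list with elements `pmrs`, `segments` (LMR/UMR), `smoothed`,
#'   `track` and (when calibrated) `calibration`.
#' @export
segment_methylome <- function(meth, params = segmentation_params(),
                              seed = NULL, calibrate = FALSE,
                              grid = expand.grid(min_cpgs = 3:6,
                                                 max_meth = c(0.3, 0.4, 0.5))) {
  track <- disorder_score_track(meth, params)
  pmrs <- detect_pmrs(track, meth, params)
  sm <- mask_and_smooth(meth, pmrs, params)
  calib <- NULL
  min_cpgs <- params$min_cpgs
  max_meth <- params$max_meth
  if (calibrate) {
    if (is.null(seed)) stop("calibration requires a seed")
    calib <- calibrate_detection_params(meth, pmrs, grid, seed, params)
    min_cpgs <- calib$chosen$min_cpgs
    max_meth <- calib$chosen$max_meth
  }
  raw <- detect_hypomethylated_regions(sm, min_cpgs, max_meth)
  segments <- classify_segments(raw, params$lmr_umr_cutoff)
  list(pmrs = pmrs, segments = segments, smoothed = sm, track = track,
       calibration = calib)
}
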