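# small in-code builders shared across test files

# methylome on one chromosome from level/coverage vectors
mk_methylome <- function(levels, coverage = 10, pos = NULL, chrom = "chr1",
                         chrom_len = NULL, sample_id = "test") {
  n <- length(levels)
  coverage <- rep_len(coverage, n)
  if (is.null(pos)) pos <- seq(0, by = 100, length.out = n)
  if (is.null(chrom_len)) chrom_len <- max(pos) + 1000
  sizes <- stats::setNames(chrom_len, chrom)
  methylome(data.frame(chrom = chrom, pos = pos,
                       meth = round(levels * coverage), total = coverage),
            sample_id, sizes)
}

# independent brute-force enumeration of maximal qualifying runs of
# smoothed-low CpGs (per block), used as the oracle for
# detect_hypomethylated_regions
brute_force_hypo <- function(smoothed, min_cpgs, max_meth) {
  out <- list()
  for (b in unique(smoothed$block)) {
    sel <- which(smoothed$block == b)
    low <- smoothed$smoothed[sel] <= max_meth
    n <- length(sel)
    for (i in seq_len(n)) {
      if (!low[i]) next
      if (i > 1 && low[i - 1]) next      # not a run start
      j <- i
      while (j < n && low[j + 1]) j <- j + 1
      if (j - i + 1 >= min_cpgs) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = smoothed$chrom[sel[i]],
          start = smoothed$pos[sel[i]],
          end = smoothed$pos[sel[j]] + 2,
          n_cpg = j - i + 1)
      }
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), n_cpg = integer()))
  do.call(rbind, out)
}

# a tiny deterministic region table
mk_regions <- function(starts, ends, class = "raw", chrom = "chr1",
                       n_cpg = NA_integer_) {
  region_table(rep(chrom, length(starts)), starts, ends, class, n_cpg)
}
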