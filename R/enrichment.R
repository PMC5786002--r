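#' Expand a lead SNP set with precomputed LD proxies
#'
#' Unions lead SNPs with their proxies from a precomputed linkage table
#' (proxy retrieval itself is out of scope; the table's provenance is an
#' R-squared > 0.8 LD threshold). Duplicate positions are removed, leads
#' winning over proxies.
#'
#' @param leads data.frame with chrom, pos, trait (provenance defaults to
#'   `lead`).
#' @param proxy_table data.frame with lead_id (or lead chrom/pos),
#'   proxy_chrom, proxy_pos; may be empty.
#' @return SNP data.frame with chrom, pos, trait, provenance and (for
#'   proxies) the tagging lead in `lead_id`.
#' @export
expand_with_proxies <- function(leads, proxy_table = NULL) {
  leads <- as.data.frame(leads)
  if (!"provenance" %in% names(leads)) leads$provenance <- "lead"
  if (!"lead_id" %in% names(leads)) leads$lead_id <- NA_character_
  trait <- unique(leads$trait)
  if (length(trait) != 1L) stop("expand one trait at a time")
  leads <- leads[!duplicated(paste(leads$chrom, leads$pos)), , drop = FALSE]
  if (is.null(proxy_table) || !nrow(proxy_table)) return(leads)
  prox <- data.frame(chrom = proxy_table$proxy_chrom,
                     pos = proxy_table$proxy_pos,
                     trait = trait, provenance = "proxy",
                     lead_id = if ("lead_id" %in% names(proxy_table))
                       as.character(proxy_table$lead_id) else NA_character_,
                     stringsAsFactors = FALSE)
  prox <- prox[!duplicated(paste(prox$chrom, prox$pos)), , drop = FALSE]
  out <- rbind(leads[, c("chrom", "pos", "trait", "provenance", "lead_id")],
               prox)
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample length-matched random region sets
#'
#' Draws `n_iter` null region sets, each with the same number of regions
#' and the identical length multiset as the input set. Each region picks a
#' chromosome with probability proportional to length (among chromosomes
#' long enough to hold it) and a uniform start. An optional exclusion mask
#' is honored by rejection sampling with a bounded number of retries.
#' Deterministic per seed.
#'
#' @param regions region data.frame whose lengths are matched.
#' @param chrom_sizes named chromosome lengths.
#' @param n_iter number of null sets.
#' @param seed integer seed.
#' @param mask optional region data.frame the null regions must avoid.
#' @param max_retries rejection-sampling bound per draw round.
#' @return list of `n_iter` data.frames with chrom, start, end.
#' @export
sample_matched_regions <- function(regions, chrom_sizes, n_iter = 100L,
                                   seed = 1L, mask = NULL,
                                   max_retries = 1000L) {
  lens <- regions$end - regions$start
  if (any(lens > max(chrom_sizes)))
    stop("a region is longer than every chromosome")
  mask_gr <- if (!is.null(mask) && nrow(mask)) regions_to_gr(mask) else NULL
  chrom_names <- names(chrom_sizes)
  n_reg <- length(lens)
  withr::with_seed(seed, {
    all_fit <- all(chrom_sizes >= max(lens))
    draw_once <- function(len_vec) {
      k <- length(len_vec)
      if (all_fit) {
        chr_idx <- if (length(chrom_sizes) == 1L) rep(1L, k) else
          sample(seq_along(chrom_sizes), k, replace = TRUE,
                 prob = chrom_sizes)
      } else {
        chr_idx <- integer(k)
        for (i in seq_len(k)) {
          ok <- which(chrom_sizes >= len_vec[i])
          chr_idx[i] <- if (length(ok) == 1L) ok else
            sample(ok, 1L, prob = chrom_sizes[ok])
        }
      }
      start <- floor(stats::runif(length(len_vec), 0,
                                  chrom_sizes[chr_idx] - len_vec + 1))
      data.frame(chrom = chrom_names[chr_idx], start = start,
                 end = start + len_vec, stringsAsFactors = FALSE)
    }
    lapply(seq_len(n_iter), function(it) {
      out <- draw_once(lens)
      if (!is.null(mask_gr)) {
        tries <- 0L
        repeat {
          bad <- IRanges::overlapsAny(regions_to_gr(out), mask_gr)
          if (!any(bad)) break
          tries <- tries + 1L
          if (tries > max_retries)
            stop("could not place mask-avoiding regions after ",
                 max_retries, " retries")
          redo <- draw_once(lens[bad])
          out[bad, c("chrom", "start", "end")] <- redo
        }
      }
      out
    })
  })
}

count_snps_in <- function(snps, regions) {
  if (!nrow(regions) || !nrow(snps)) return(0L)
  pts <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos + 1, width = 1))
  sum(IRanges::overlapsAny(pts, regions_to_gr(regions)))
}

#' Test SNP enrichment in LMRs against matched random regions
#'
#' Counts trait SNPs falling inside any LMR (half-open: a SNP at a region
#' boundary is inside iff `start <= pos < end`), compares with the mean
#' count over length-matched null region sets, and reports the fold
#' enrichment with a chi-squared significance. The chi-squared (1 df, no
#' continuity correction) is computed on the 2x2 table of in/out counts,
#' observed versus pooled-null scaled to the observed total; an empirical
#' permutation p-value over the null draws is always reported alongside.
#' When no null draw captures a SNP the fold is undefined and only the
#' empirical p (`(1 + #null >= observed) / (1 + n_iter)`) is available.
#'
#' @param snps SNP data.frame with chrom, pos (and optionally trait).
#' @param lmrs LMR region data.frame.
#' @param null_sets list of null region sets from
#'   [sample_matched_regions()].
#' @return one-row data.frame of class columns: trait, n_snps, observed_in,
#'   expected_in, fold, chi2, p_value, neg_log10_p, p_empirical.
#' @export
snp_region_enrichment <- function(snps, lmrs, null_sets) {
  n_snps <- nrow(snps)
  obs_in <- count_snps_in(snps, lmrs)
  null_in <- vapply(null_sets, function(ns) count_snps_in(snps, ns),
                    integer(1))
  expected_in <- mean(null_in)
  n_iter <- length(null_sets)
  p_emp <- (1 + sum(null_in >= obs_in)) / (1 + n_iter)
  if (expected_in == 0) {
    res <- data.frame(trait = if ("trait" %in% names(snps) && n_snps)
      snps$trait[1L] else NA_character_,
      n_snps = n_snps, observed_in = obs_in,
      expected_in = 0, fold = NA_real_, chi2 = NA_real_,
      p_value = p_emp, neg_log10_p = -log10(p_emp),
      p_empirical = p_emp, stringsAsFactors = FALSE)
    return(res)
  }
  fold <- obs_in / expected_in
  chi <- chi2_2x2(obs_in, n_snps - obs_in, expected_in, n_snps - expected_in)
  data.frame(trait = if ("trait" %in% names(snps) && n_snps)
    snps$trait[1L] else NA_character_,
    n_snps = n_snps, observed_in = obs_in,
    expected_in = expected_in, fold = fold, chi2 = chi$stat,
    p_value = chi$p, neg_log10_p = -log10(chi$p),
    p_empirical = p_emp, stringsAsFactors = FALSE)
}

# Pearson chi-squared (1 df, no continuity correction) on a 2x2 table given
# by rows (a, b) and (c, d); counts may be non-integer (scaled expecteds)
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-trait SNP-bearing LMR sets and their intersections
#'
#' For each trait, collects the set of LMRs (keyed by chrom:start-end) that
#' contain at least one of the trait's SNPs, and reports intersection counts
#' for every pair and triple of traits (the Venn counts).
#'
#' @param snp_sets named list of SNP data.frames (one per trait) or one
#'   data.frame with a `trait` column.
#' @param lmrs LMR region data.frame.
#' @return list with `sets` (named list of LMR key vectors) and
#'   `intersections` (data.frame of trait combinations and counts).
#' @export
snp_lmr_overlap_sets <- function(snp_sets, lmrs) {
  if (is.data.frame(snp_sets))
    snp_sets <- split(snp_sets, snp_sets$trait)
  lmr_gr <- regions_to_gr(lmrs)
  keys <- sprintf("%s:%d-%d", lmrs$chrom, as.integer(lmrs$start),
                  as.integer(lmrs$end))
  sets <- lapply(snp_sets, function(s) {
    if (!nrow(s)) return(character())
    pts <- GenomicRanges::GRanges(s$chrom,
                                  IRanges::IRanges(s$pos + 1, width = 1))
    hit <- unique(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(pts, lmr_gr)))
    sort(keys[hit])
  })
  traits <- names(sets)
  combos <- list()
  for (k in 2:min(3, max(2, length(traits)))) {
    if (length(traits) < k) break
    cmb <- utils::combn(traits, k, simplify = FALSE)
    for (cc in cmb)
      combos[[paste(cc, collapse = " & ")]] <-
        length(Reduce(intersect, sets[cc]))
  }
  inter <- if (length(combos)) {
    data.frame(traits = names(combos),
               n_shared_lmrs = unlist(unname(combos)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(traits = character(), n_shared_lmrs = integer())
  }
  list(sets = sets, intersections = inter)
}
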