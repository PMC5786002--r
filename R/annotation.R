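#' Assign genic unmethylated regions (gUMRs)
#'
#' Genic demethylation is initiated at the TSS, so a gUMR is derived from
#' UMRs overlapping a gene's TSS: the assignment considers only genes whose
#' genic extent spans at least 1.5 kb outside CpG islands; the gUMR is the
#' TSS-overlapping UMR intersected with the genic extent, minus CGI
#' intervals; CpGs overlapping annotated islands are removed, and the gUMR
#' is kept only when at least 10 CpGs remain. Fragments of one gene form a
#' single logical unit (lengths summed) since all downstream criteria are
#' per-gene. A gene with several TSS-overlapping UMRs takes their union,
#' with a warning.
#'
#' "Overlap with the TSS" is the single-base test `start <= tss < end`.
#'
#' @param umrs region data.frame (class UMR rows are used).
#' @param genes gene-model data.frame ([gene_models()]).
#' @param cgis CpG-island region data.frame (may be empty).
#' @param meth a [methylome()] used to count CpGs and average methylation
#'   over the fragments; a list of stage methylomes gives one mean column
#'   per stage.
#' @param min_outside_cgi minimum genic length outside islands (bp).
#' @param min_cpgs minimum CpGs per gUMR after island removal.
#' @return data.frame with one row per assigned gene (gene_id, chrom,
#'   n_fragments, total_length, n_cpg, gene_length, gene_fraction, and one
#'   `mean_meth*` column per methylome) carrying the fragment intervals in
#'   `attr(, "fragments")`.
#' @export
assign_gumrs <- function(umrs, genes, cgis, meth,
                         min_outside_cgi = 1500, min_cpgs = 10L) {
  umrs <- umrs[umrs$class %in% c("UMR", "raw"), , drop = FALSE]
  meth_list <- if (inherits(meth, "methylome")) list(meth) else meth
  stopifnot(length(meth_list) >= 1L)
  cgi_gr <- if (nrow(cgis)) regions_to_gr(cgis) else GenomicRanges::GRanges()
  rows <- list(); frags <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gene_gr <- GenomicRanges::GRanges(g$chrom,
                                      IRanges::IRanges(g$start + 1, g$end))
    outside <- if (length(cgi_gr))
      sum(IRanges::width(GenomicRanges::setdiff(gene_gr, cgi_gr)))
    else g$end - g$start
    if (outside < min_outside_cgi) next
    hit <- umrs$chrom == g$chrom & umrs$start <= g$tss & umrs$end > g$tss
    if (!any(hit)) next
    if (sum(hit) > 1L)
      warning("gene ", g$gene_id, ": ", sum(hit),
              " TSS-overlapping UMRs; union taken")
    umr_gr <- GenomicRanges::reduce(regions_to_gr(umrs[hit, , drop = FALSE]))
    frag_gr <- GenomicRanges::intersect(umr_gr, gene_gr)
    if (length(cgi_gr))
      frag_gr <- GenomicRanges::setdiff(frag_gr, cgi_gr)
    if (!length(frag_gr)) next
    frag_df <- gr_to_regions(frag_gr, "gUMR")
    # CpGs inside the fragments; island-overlapping dyads are excluded
    stats_per <- lapply(meth_list, function(mm) {
      cpgs <- mm$cpgs[mm$cpgs$chrom == g$chrom, , drop = FALSE]
      if (!nrow(cpgs)) return(c(n = 0, mean = NA_real_))
      idx <- cpg_region_index(cpgs, frag_df)
      inside <- !is.na(idx)
      if (length(cgi_gr) && any(inside)) {
        dyads <- GenomicRanges::GRanges(
          cpgs$chrom[inside],
          IRanges::IRanges(cpgs$pos[inside] + 1, width = 2))
        inside[inside] <- !IRanges::overlapsAny(dyads, cgi_gr)
      }
      if (!any(inside)) return(c(n = 0, mean = NA_real_))
      c(n = sum(inside),
        mean = stats::weighted.mean(cpgs$level[inside], cpgs$total[inside]))
    })
    n_cpg <- max(vapply(stats_per, `[[`, numeric(1), "n"))
    if (n_cpg < min_cpgs) next
    total_len <- sum(frag_df$end - frag_df$start)
    row <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      n_fragments = nrow(frag_df),
                      total_length = total_len, n_cpg = n_cpg,
                      gene_length = g$end - g$start,
                      gene_fraction = total_len / (g$end - g$start),
                      stringsAsFactors = FALSE)
    for (k in seq_along(stats_per)) {
      nm <- if (length(meth_list) == 1L) "mean_meth"
      else paste0("mean_meth_", meth_list[[k]]$sample_id)
      row[[nm]] <- stats_per[[k]][["mean"]]
    }
    rows[[length(rows) + 1L]] <- row
    frag_df$gene_id <- g$gene_id
    frags[[length(frags) + 1L]] <- frag_df
  }
  if (!length(rows)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      n_fragments = integer(), total_length = numeric(),
                      n_cpg = numeric(), gene_length = numeric(),
                      gene_fraction = numeric(), mean_meth = numeric())
    attr(out, "fragments") <- region_table()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fragments") <- do.call(rbind, frags)
  out
}

#' Flag genes with extended genic demethylation
#'
#' A gene is flagged when its gUMR spans at least 5 kb and/or overlaps at
#' least 25% of the gene (the 10-CpG floor is already enforced during gUMR
#' assignment). The flag is monotone: enlarging a gUMR never un-flags.
#'
#' @param gumrs output of [assign_gumrs()].
#' @param min_length length criterion in bp.
#' @param min_fraction gene-fraction criterion.
#' @return data.frame with gene_id, flagged, reason
#'   (`length>=5kb`, `fraction>=25%`, `both` or `none`).
#' @export
flag_extended_demethylation <- function(gumrs, min_length = 5000,
                                        min_fraction = 0.25) {
  by_len <- gumrs$total_length >= min_length
  by_frac <- gumrs$gene_fraction >= min_fraction
  data.frame(gene_id = gumrs$gene_id,
             flagged = by_len | by_frac,
             reason = ifelse(by_len & by_frac, "both",
                             ifelse(by_len, "length>=5kb",
                                    ifelse(by_frac, "fraction>=25%", "none"))),
             stringsAsFactors = FALSE)
}

#' Compute fully methylated regions (FMRs)
#'
#' FMRs are the genome-wide, per-chromosome complement of the union of CpG
#' islands, LMRs, UMRs and PMRs: together the five classes partition every
#' chromosome.
#'
#' @param chrom_sizes named chromosome lengths.
#' @param cgis,lmrs,umrs,pmrs region data.frames (any may be empty).
#' @return region data.frame of class FMR.
#' @export
compute_fmrs <- function(chrom_sizes, cgis = region_table(),
                         lmrs = region_table(), umrs = region_table(),
                         pmrs = region_table()) {
  occupied <- rbind(cgis, lmrs, umrs, pmrs)
  out <- list()
  for (chr in names(chrom_sizes)) {
    chr_gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(1, chrom_sizes[[chr]]))
    occ <- occupied[occupied$chrom == chr, , drop = FALSE]
    free <- if (nrow(occ)) {
      GenomicRanges::setdiff(chr_gr, GenomicRanges::reduce(regions_to_gr(occ)))
    } else chr_gr
    if (length(free)) out[[chr]] <- gr_to_regions(free, "FMR")
  }
  if (!length(out)) return(region_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map regions to the nearest gene within a distance cutoff
#'
#' Each region is assigned the gene minimizing the distance from the region
#' boundary to the genic extent (0 when overlapping); regions farther than
#' `max_dist` from every gene map to `NA`. Ties are broken by the smaller
#' distance to the TSS, then by lexicographic gene id.
#'
#' @param regions region data.frame.
#' @param genes gene-model data.frame.
#' @param max_dist maximum distance in bp (default 10 kb).
#' @return data.frame with the region coordinates plus gene_id and distance.
#' @export
nearest_gene_within <- function(regions, genes, max_dist = 10000) {
  n <- nrow(regions)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    rs <- regions$start[i]; re <- regions$end[i]
    d <- pmax(0, g$start - re, rs - g$end)
    dmin <- min(d)
    if (dmin > max_dist) next
    cand <- which(d == dmin)
    if (length(cand) > 1L) {
      tss <- g$tss[cand]
      tss_d <- ifelse(tss >= rs & tss < re, 0,
                      pmin(abs(tss - rs), abs(tss - (re - 1))))
      cand <- cand[tss_d == min(tss_d)]
      if (length(cand) > 1L)
        cand <- cand[order(g$gene_id[cand])][1L]
    }
    gene_id[i] <- g$gene_id[cand[1L]]
    distance[i] <- dmin
  }
  cbind(regions, data.frame(gene_id = gene_id, distance = distance,
                            stringsAsFactors = FALSE))
}
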