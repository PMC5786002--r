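#' Construct a methylome object
#'
#' A methylome holds ordered per-CpG methylation calls for one WGBS sample
#' (or a pool of replicates). Positions are 0-based and refer to the C of the
#' CpG dyad on the plus strand; coordinates follow the BED half-open
#' convention throughout the package.
#'
#' @param cpgs data.frame with columns `chrom` (character), `pos` (integer,
#'   0-based), `meth` (methylated read count), `total` (total read count,
#'   positive) and optionally `level`; `level` is recomputed as `meth/total`
#'   when absent.
#' @param sample_id character scalar identifying the sample.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return An object of class `methylome` with elements `sample_id`, `cpgs`
#'   (sorted by chromosome then position) and `chrom_sizes`.
#' @export
methylome <- function(cpgs, sample_id, chrom_sizes) {
  stopifnot(is.data.frame(cpgs), is.character(sample_id), length(sample_id) == 1L)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  required <- c("chrom", "pos", "meth", "total")
  missing_cols <- setdiff(required, names(cpgs))
  if (length(missing_cols))
    stop("cpgs is missing columns: ", paste(missing_cols, collapse = ", "))
  cpgs <- cpgs[, intersect(c(required, "level"), names(cpgs)), drop = FALSE]
  if (nrow(cpgs)) {
    unknown <- setdiff(unique(cpgs$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("chromosome(s) not in chrom_sizes: ", paste(unknown, collapse = ", "))
    if (any(cpgs$total <= 0)) stop("total read count must be positive")
    if (any(cpgs$meth < 0) || any(cpgs$meth > cpgs$total))
      stop("meth counts must lie in [0, total]")
    if (any(cpgs$pos < 0) || any(cpgs$pos >= chrom_sizes[cpgs$chrom]))
      stop("CpG position outside chromosome bounds")
    cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
    if (anyDuplicated(paste(cpgs$chrom, cpgs$pos)))
      stop("duplicate (chrom, pos) records")
    cpgs$level <- cpgs$meth / cpgs$total
    rownames(cpgs) <- NULL
  } else {
    cpgs <- data.frame(chrom = character(), pos = integer(), meth = numeric(),
                       total = numeric(), level = numeric())
  }
  structure(list(sample_id = sample_id, cpgs = cpgs,
                 chrom_sizes = chrom_sizes),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s: %d CpGs on %d chromosome(s)\n",
              x$sample_id, nrow(x$cpgs), length(unique(x$cpgs$chrom))))
  if (nrow(x$cpgs))
    cat(sprintf("  mean level %.3f, median coverage %d\n",
                mean(x$cpgs$level), as.integer(stats::median(x$cpgs$total))))
  invisible(x)
}

#' Number of CpGs in a methylome
#' @param x a `methylome`.
#' @export
n_cpgs <- function(x) nrow(x$cpgs)

#' Read a per-CpG methylation call table
#'
#' Accepts the bedGraph-like tab-separated dialects produced by common
#' methylation extractors. The dialect is auto-detected from the column count:
#' 5 columns are `chrom start end meth_count unmeth_count`; 6 or more columns
#' are MethylDackel-style `chrom start end percent meth_count unmeth_count`
#' (counts are used, the percent column is ignored); 4 columns are
#' `chrom start end percent`, stored with unit pseudo-coverage (such input
#' cannot drive coverage-dependent filters). Files may be gzip-compressed.
#'
#' Records with zero total coverage are dropped with a warning reporting the
#' number removed; downstream statistics are coverage-weighted so there is
#' nothing to weight them by.
#'
#' @param path path to the table.
#' @param sample_id sample identifier stored on the methylome.
#' @param chrom_sizes named vector of chromosome lengths; a record on a
#'   chromosome absent from this map is an error.
#' @return A [methylome()].
#' @export
read_cpg_table <- function(path, sample_id, chrom_sizes) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", comment.char = "#",
                      quote = "", stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("failed to parse ", path, ": ", conditionMessage(e))
    })
  if (is.null(tab) || nrow(tab) == 0L)
    return(methylome(data.frame(chrom = character(), pos = integer(),
                                meth = numeric(), total = numeric()),
                     sample_id, chrom_sizes))
  nc <- ncol(tab)
  if (nc < 4L) stop("expected at least 4 tab-separated columns in ", path)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s at line %d of %s: '%s'",
                   what, bad[1L], path, tab[[col]][bad[1L]]))
    v
  }
  start <- num(2L, "start coordinate")
  if (any(start != floor(start))) {
    bad <- which(start != floor(start))[1L]
    stop(sprintf("non-integer start coordinate at line %d of %s", bad, path))
  }
  if (nc == 4L) {
    pct <- num(4L, "methylation value")
    if (any(pct > 1)) pct <- pct / 100
    if (any(pct < 0 | pct > 1)) stop("methylation fraction outside [0,1] in ", path)
    meth <- pct
    total <- rep(1, length(pct))
  } else {
    meth_col <- if (nc == 5L) 4L else 5L
    unmeth_col <- meth_col + 1L
    meth <- num(meth_col, "methylated count")
    unmeth <- num(unmeth_col, "unmethylated count")
    if (any(meth < 0) || any(unmeth < 0)) stop("negative read count in ", path)
    total <- meth + unmeth
    drop <- total == 0
    if (any(drop)) {
      warning(sum(drop), " zero-coverage record(s) dropped from ", path)
      meth <- meth[!drop]; total <- total[!drop]; start <- start[!drop]
      tab <- tab[!drop, , drop = FALSE]
    }
  }
  methylome(data.frame(chrom = tab[[1L]], pos = as.integer(start),
                       meth = meth, total = total),
            sample_id, chrom_sizes)
}

#' Write a per-CpG methylation call table (counts dialect)
#'
#' Emits `chrom start end meth_count unmeth_count`, the 5-column dialect
#' accepted by [read_cpg_table()]. The end coordinate is `pos + 1`.
#'
#' @param x a `methylome`.
#' @param path output path (a `.gz` suffix gzip-compresses the output).
#' @export
write_cpg_table <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  out <- data.frame(x$cpgs$chrom, x$cpgs$pos, x$cpgs$pos + 1L,
                    x$cpgs$meth, x$cpgs$total - x$cpgs$meth)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge plus- and minus-strand CpG calls into dyad records
#'
#' A CpG dyad is reported at the plus-strand C position; the paired
#' minus-strand record sits one base downstream. Counts of the two strands
#' are summed and the level recomputed. A minus-strand record without a
#' plus-strand partner is kept as its own dyad at `pos - 1` with a warning.
#' Total read counts are conserved.
#'
#' @param plus,minus data.frames with columns `chrom`, `pos`, `meth`, `total`.
#' @return data.frame of merged dyad records sorted by (chrom, pos).
#' @export
merge_strand_calls <- function(plus, minus) {
  cols <- c("chrom", "pos", "meth", "total")
  stopifnot(all(cols %in% names(plus)), all(cols %in% names(minus)))
  plus <- plus[, cols, drop = FALSE]
  minus <- minus[, cols, drop = FALSE]
  if (nrow(minus)) {
    key_plus <- paste(plus$chrom, plus$pos)
    key_minus <- paste(minus$chrom, minus$pos - 1L)
    idx <- match(key_minus, key_plus)
    paired <- !is.na(idx)
    if (any(paired)) {
      plus$meth[idx[paired]] <- plus$meth[idx[paired]] + minus$meth[paired]
      plus$total[idx[paired]] <- plus$total[idx[paired]] + minus$total[paired]
    }
    if (any(!paired)) {
      warning(sum(!paired), " unpaired minus-strand record(s) kept at pos - 1")
      orphan <- minus[!paired, , drop = FALSE]
      orphan$pos <- orphan$pos - 1L
      plus <- rbind(plus, orphan)
    }
  }
  plus <- plus[order(plus$chrom, plus$pos), , drop = FALSE]
  plus$level <- plus$meth / plus$total
  rownames(plus) <- NULL
  plus
}

region_classes <- c("PMR", "UMR", "LMR", "gUMR", "FMR", "CGI", "raw")

#' Construct a region table
#'
#' Regions are plain data.frames with 0-based half-open coordinates and a
#' class label; this constructor validates and normalizes the columns.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param class region class, one of PMR, UMR, LMR, gUMR, FMR, CGI or raw.
#' @param n_cpg CpG count per region (NA when unknown).
#' @param mean_meth mean methylation per region (NA when undefined).
#' @return data.frame with columns chrom, start, end, class, n_cpg, mean_meth.
#' @export
region_table <- function(chrom = character(), start = integer(),
                         end = integer(), class = "raw",
                         n_cpg = NA_integer_, mean_meth = NA_real_) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   class = rep_len(as.character(class), n),
                   n_cpg = rep_len(as.numeric(n_cpg), n),
                   mean_meth = rep_len(as.numeric(mean_meth), n),
                   stringsAsFactors = FALSE)
  if (n) {
    if (any(df$start < 0)) stop("negative start coordinate")
    if (any(df$start >= df$end)) stop("region start must be < end")
    if (any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
      stop("non-integer region coordinates")
    bad <- setdiff(unique(df$class), region_classes)
    if (length(bad)) stop("unknown region class: ", paste(bad, collapse = ", "))
    if (any(!is.na(df$mean_meth) & (df$mean_meth < 0 | df$mean_meth > 1)))
      stop("mean_meth outside [0,1]")
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a region BED file
#'
#' BED3 plus optional columns 4 (region class), 5 (CpG count) and 6 (mean
#' methylation; `.` for undefined). Gzip-transparent.
#'
#' @param path path to the BED file.
#' @return region data.frame as produced by [region_table()].
#' @export
read_regions_bed <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop("failed to parse ", path, ": ", conditionMessage(e))
    })
  if (is.null(tab)) return(region_table())
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns: ", path)
  start <- suppressWarnings(as.numeric(tab[[2L]]))
  end <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("non-integer coordinates in ", path)
  cls <- if (ncol(tab) >= 4L) tab[[4L]] else "raw"
  n_cpg <- if (ncol(tab) >= 5L)
    suppressWarnings(as.numeric(tab[[5L]])) else NA_real_
  mm <- if (ncol(tab) >= 6L) {
    v <- tab[[6L]]; v[v == "."] <- NA
    suppressWarnings(as.numeric(v))
  } else NA_real_
  region_table(tab[[1L]], start, end, cls, n_cpg, mm)
}

#' Write a region BED file
#'
#' Inverse of [read_regions_bed()]; mean methylation is written with six
#' decimals so the round-trip is lossless at that precision.
#'
#' @param regions region data.frame.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  mm <- ifelse(is.na(regions$mean_meth), ".",
               sprintf("%.6f", regions$mean_meth))
  nc <- ifelse(is.na(regions$n_cpg), 0, regions$n_cpg)
  out <- data.frame(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
                    format(regions$end, scientific = FALSE, trim = TRUE),
                    regions$class, nc, mm)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Five-column TSV: `gene_id chrom strand tss tes`. The TSS and TES are the
#' main transcription start and stop sites; for minus-strand genes the TSS
#' coordinate is numerically greater than the TES. A header line is detected
#' and skipped when column 4 is not numeric. Gzip-transparent.
#'
#' @param path path to the table.
#' @return data.frame with columns gene_id, chrom, strand, tss, tes, start,
#'   end, where `[start, end)` is the genic extent.
#' @export
read_gene_models <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop("failed to parse ", path, ": ", conditionMessage(e))
    })
  if (is.null(tab))
    return(gene_models(character(), character(), character(),
                       integer(), integer()))
  if (ncol(tab) < 5L) stop("gene model table needs 5 columns: ", path)
  if (is.na(suppressWarnings(as.numeric(tab[1L, 4L]))))
    tab <- tab[-1L, , drop = FALSE]
  gene_models(tab[[1L]], tab[[2L]], tab[[3L]],
              suppressWarnings(as.numeric(tab[[4L]])),
              suppressWarnings(as.numeric(tab[[5L]])))
}

#' Construct a gene-model table
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param strand `+` or `-`.
#' @param tss,tes transcription start/stop coordinates (0-based); a
#'   minus-strand gene has `tss > tes`.
#' @return validated data.frame with the genic extent `[start, end)` added.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tes) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tss = as.numeric(tss), tes = as.numeric(tes),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyNA(df$tss) || anyNA(df$tes)) stop("non-numeric TSS/TES")
    if (anyDuplicated(df$gene_id))
      stop("duplicate gene_id: ",
           paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(df$tss == df$tes)) stop("tss must differ from tes")
    bad <- (df$strand == "+" & df$tss > df$tes) |
      (df$strand == "-" & df$tss < df$tes)
    if (any(bad))
      stop("strand-inconsistent TSS/TES for: ",
           paste(df$gene_id[bad], collapse = ", "))
  }
  df$start <- pmin(df$tss, df$tes)
  df$end <- pmax(df$tss, df$tes)
  df
}

# --- internal interval helpers (0-based half-open <-> GRanges 1-based) ----

regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1,
                                          end = regions$end))
}

gr_to_regions <- function(gr, class = "raw") {
  region_table(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr), class)
}

cpg_points_gr <- function(cpgs) {
  GenomicRanges::GRanges(cpgs$chrom,
                         IRanges::IRanges(start = cpgs$pos + 1, width = 1))
}

# index of the region (row of `regions`) containing each CpG, NA if none
cpg_region_index <- function(cpgs, regions) {
  if (!nrow(regions) || !nrow(cpgs)) return(rep(NA_integer_, nrow(cpgs)))
  hits <- GenomicRanges::findOverlaps(cpg_points_gr(cpgs),
                                      regions_to_gr(regions), select = "first")
  as.integer(hits)
}

# CpG count and coverage-weighted mean level for each region
summarize_regions_from_cpgs <- function(regions, cpgs) {
  if (!nrow(regions)) return(regions)
  idx <- cpg_region_index(cpgs, regions)
  keep <- !is.na(idx)
  n <- tabulate(idx[keep], nbins = nrow(regions))
  wsum <- rep(0, nrow(regions)); lsum <- rep(0, nrow(regions))
  if (any(keep)) {
    wsum <- as.numeric(tapply(cpgs$total[keep], factor(idx[keep], levels = seq_len(nrow(regions))), sum))
    lsum <- as.numeric(tapply(cpgs$total[keep] * cpgs$level[keep],
                              factor(idx[keep], levels = seq_len(nrow(regions))), sum))
    wsum[is.na(wsum)] <- 0; lsum[is.na(lsum)] <- 0
  }
  regions$n_cpg <- n
  regions$mean_meth <- ifelse(wsum > 0, lsum / wsum, NA_real_)
  regions
}
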