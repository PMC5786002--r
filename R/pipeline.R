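#' Validate a pipeline configuration
#'
#' A configuration is a named list (or path to a YAML file) with an
#' `output_dir`, a mandatory `seed`, and per-stage blocks: `simulate`
#' (layout/coverage options), `samples` (list of `sample_id`, `file`,
#' `group`, `stage`), `segment`, `annotate` (`genes`, `cgi_bed`), `dmr`
#' (`group_a`, `group_b` stage labels), and `enrich` (`snps`, `n_iter`).
#' Validation checks that every referenced file exists and that stochastic
#' stages have a seed before anything runs.
#'
#' @param config named list or YAML path.
#' @return the normalized configuration list (invisibly on success);
#'   validation problems raise an error naming every issue.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character()
  if (is.null(config$output_dir)) problems <- c(problems, "output_dir missing")
  if (is.null(config$seed)) problems <- c(problems, "seed missing")
  for (s in config$samples) {
    if (is.null(s$file) || !file.exists(s$file))
      problems <- c(problems,
                    sprintf("sample file missing: %s", s$file %||% "<null>"))
  }
  for (f in c(config$annotate$genes, config$annotate$cgi_bed,
              config$enrich$snps)) {
    if (!is.null(f) && !file.exists(f))
      problems <- c(problems, sprintf("input file missing: %s", f))
  }
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages sequentially — simulate (optional),
#' per-stage segmentation, consensus merge, annotation, differential
#' methylation and SNP enrichment — writing every artifact under
#' `output_dir` and returning a manifest listing each output with its MD5
#' checksum. Reruns with an identical configuration and inputs produce
#' identical checksums. A stage failure aborts with the failing stage
#' named; artifacts of completed stages are retained.
#'
#' @param config named list or YAML path; see
#'   [validate_pipeline_config()].
#' @return data.frame manifest with stage, path and md5 columns.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, path)
    manifest[[length(manifest) + 1L]] <<-
    data.frame(stage = stage, path = path,
               md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- as.integer(config$seed)
  params <- do.call(segmentation_params,
                    config$segment_params %||% list())

  # --- simulate ----------------------------------------------------------
  chrom_sizes <- NULL
  samples <- config$samples %||% list()
  if (!is.null(config$simulate)) {
    run_stage("simulate", {
      sim_cfg <- config$simulate
      layout <- do.call(simulate_genome_layout,
                        c(sim_cfg$layout %||% list(), list(seed = seed)))
      sim <- simulate_methylome(layout,
                                mean_coverage = sim_cfg$mean_coverage %||% 30,
                                seed = seed + 1L)
      path <- file.path(outdir, "simulated_cpg.tsv")
      write_cpg_table(sim$methylome, path)
      truth_path <- file.path(outdir, "simulated_truth.bed")
      write_regions_bed(region_table(layout$truth$chrom, layout$truth$start,
                                     layout$truth$end, layout$truth$class),
                        truth_path)
      note("simulate", path); note("simulate", truth_path)
      chrom_sizes <- layout$chrom_sizes
      samples <- c(samples, list(list(sample_id = "simulated", file = path,
                                       stage = "simulated", group = "sim")))
    })
  }
  if (is.null(chrom_sizes)) {
    if (is.null(config$chrom_sizes))
      stop("pipeline stage 'segment' failed: chrom_sizes required when not simulating")
    chrom_sizes <- unlist(config$chrom_sizes)
  }

  # --- segment per stage -------------------------------------------------
  seg_results <- list()
  pooled <- list()
  if (isTRUE(config$segment %||% TRUE) && length(samples)) {
    run_stage("segment", {
      stages <- unique(vapply(samples, function(s) s$stage, character(1)))
      for (st in stages) {
        files <- vapply(Filter(function(s) s$stage == st, samples),
                        function(s) s$file, character(1))
        meths <- lapply(files, read_cpg_table, sample_id = st,
                        chrom_sizes = chrom_sizes)
        pooled_meth <- pool_methylomes(meths, sample_id = st)
        pooled[[st]] <- pooled_meth
        res <- segment_methylome(pooled_meth, params, seed = seed,
                                 calibrate = isTRUE(config$calibrate))
        seg_results[[st]] <- res
        for (cls in c("PMR", "LMR", "UMR")) {
          regs <- if (cls == "PMR") res$pmrs else
            res$segments[res$segments$class == cls, , drop = FALSE]
          p <- file.path(outdir, sprintf("%s_%s.bed", st, cls))
          write_regions_bed(regs, p)
          note("segment", p)
        }
        if (!is.null(res$calibration)) {
          p <- file.path(outdir, sprintf("%s_calibration.tsv", st))
          utils::write.table(res$calibration$table, p, sep = "\t",
                             quote = FALSE, row.names = FALSE)
          note("segment", p)
        }
      }
    })
  }

  # --- merge + annotate --------------------------------------------------
  consensus <- NULL
  if (length(seg_results)) {
    run_stage("merge", {
      union_meth <- pool_methylomes(pooled, sample_id = "union")
      consensus <- merge_stage_segmentations(
        lapply(seg_results, function(r) rbind(r$pmrs, r$segments)),
        union_meth, params)
      p <- file.path(outdir, "consensus_segments.bed")
      write_regions_bed(consensus, p)
      note("merge", p)
    })
  }
  if (!is.null(config$annotate) && !is.null(consensus)) {
    run_stage("annotate", {
      genes <- read_gene_models(config$annotate$genes)
      cgis <- if (!is.null(config$annotate$cgi_bed))
        read_regions_bed(config$annotate$cgi_bed) else region_table()
      union_meth <- pool_methylomes(pooled, sample_id = "union")
      umrs <- consensus[consensus$class == "UMR", , drop = FALSE]
      gumrs <- assign_gumrs(umrs, genes, cgis, union_meth)
      fl <- flag_extended_demethylation(gumrs)
      fmrs <- compute_fmrs(chrom_sizes, cgis,
                           consensus[consensus$class == "LMR", , drop = FALSE],
                           umrs,
                           consensus[consensus$class == "PMR", , drop = FALSE])
      prox <- nearest_gene_within(
        consensus[consensus$class == "LMR", , drop = FALSE], genes)
      paths <- c(gumr = file.path(outdir, "gumrs.tsv"),
                 flags = file.path(outdir, "extended_demethylation.tsv"),
                 fmr = file.path(outdir, "fmrs.bed"),
                 prox = file.path(outdir, "lmr_gene_proximity.tsv"))
      utils::write.table(gumrs, paths["gumr"], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(fl, paths["flags"], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_regions_bed(fmrs, paths["fmr"])
      utils::write.table(prox, paths["prox"], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      for (p in paths) note("annotate", p)
    })
  }

  # --- differential ------------------------------------------------------
  if (!is.null(config$dmr) && !is.null(consensus)) {
    run_stage("dmr", {
      pick <- function(grp) {
        sel <- Filter(function(s) s$group == grp, samples)
        lapply(sel, function(s)
          read_cpg_table(s$file, s$sample_id, chrom_sizes))
      }
      ga <- pick(config$dmr$group_a)
      gb <- pick(config$dmr$group_b)
      dparams <- do.call(dmr_params, config$dmr$params %||% list())
      test_regions <- consensus
      if (!is.null(config$annotate$genes)) {
        genes <- read_gene_models(config$annotate$genes)
        pm <- test_regions$class == "PMR"
        kept_pmrs <- exclude_gene_spanning_pmrs(
          test_regions[pm, , drop = FALSE], genes, dparams)
        test_regions <- rbind(test_regions[!pm, , drop = FALSE], kept_pmrs)
      }
      dm <- region_dmr_test(test_regions, ga, gb, dparams)
      p <- file.path(outdir, "dmr_results.tsv")
      utils::write.table(dm, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note("dmr", p)
    })
  }

  # --- enrichment --------------------------------------------------------
  if (!is.null(config$enrich) && !is.null(consensus)) {
    run_stage("enrich", {
      snps <- utils::read.table(config$enrich$snps, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
      lmrs <- consensus[consensus$class == "LMR", , drop = FALSE]
      nulls <- sample_matched_regions(lmrs, chrom_sizes,
                                      n_iter = config$enrich$n_iter %||% 100L,
                                      seed = seed)
      res <- do.call(rbind, lapply(split(snps, snps$trait), function(s)
        snp_region_enrichment(s, lmrs, nulls)))
      p <- file.path(outdir, "snp_enrichment.tsv")
      utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note("enrich", p)
    })
  }

  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  mpath <- file.path(outdir, "manifest.tsv")
  utils::write.table(out, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Pool replicate methylomes into one stage methylome
#'
#' Sums methylated and total counts per CpG over the replicates (the union
#' of covered CpGs) to increase effective coverage for segmentation.
#'
#' @param methylomes list of [methylome()]s on one chromosome set.
#' @param sample_id identifier for the pooled methylome.
#' @return a [methylome()].
#' @export
pool_methylomes <- function(methylomes, sample_id = "pooled") {
  stopifnot(length(methylomes) >= 1L)
  all_cpgs <- do.call(rbind, lapply(methylomes, function(m) m$cpgs))
  key <- paste(all_cpgs$chrom, all_cpgs$pos)
  meth <- tapply(all_cpgs$meth, key, sum)
  total <- tapply(all_cpgs$total, key, sum)
  first <- !duplicated(key)
  anchor <- all_cpgs[first, c("chrom", "pos"), drop = FALSE]
  k <- paste(anchor$chrom, anchor$pos)
  methylome(data.frame(chrom = anchor$chrom, pos = anchor$pos,
                       meth = as.numeric(meth[k]),
                       total = as.numeric(total[k])),
            sample_id, methylomes[[1L]]$chrom_sizes)
}
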