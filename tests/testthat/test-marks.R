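flat_track <- function(value, mark = "H3K27ac", chrom = "chr1",
                       span = c(0, 1e5), id = "s") {
  mark_track(data.frame(chrom = chrom, start = span[1], end = span[2],
                        value = value), id, mark)
}

test_that("geometric-mean normalization yields the closed-form factors", {
  tr <- normalize_to_geometric_mean(list(flat_track(100 / 1e5),
                                         flat_track(400 / 1e5)))
  expect_equal(sapply(tr, `[[`, "scale_factor"), c(2.0, 0.5))

  tr3 <- normalize_to_geometric_mean(list(flat_track(10 / 1e5),
                                          flat_track(100 / 1e5),
                                          flat_track(1000 / 1e5)))
  expect_equal(sapply(tr3, `[[`, "scale_factor"), c(10, 1, 0.1))

  same <- normalize_to_geometric_mean(list(flat_track(2), flat_track(2)))
  expect_equal(sapply(same, `[[`, "scale_factor"), c(1, 1))

  expect_error(normalize_to_geometric_mean(list(flat_track(0), flat_track(1))),
               "positive genome-wide signal")
})

test_that("scaled totals all equal the geometric mean (log-sum conserved)", {
  withr::with_seed(4, vals <- runif(4, 0.1, 5))
  tracks <- normalize_to_geometric_mean(lapply(vals, flat_track))
  scaled <- sapply(tracks, function(t) t$genome_total * t$scale_factor)
  g <- exp(mean(log(vals * 1e5)))
  expect_equal(scaled, rep(g, 4))
})

test_that("region signal is the scaled coverage area over the target", {
  genes <- gene_models("g1", "chr1", "+", tss = 2000, tes = 8000)
  tr <- flat_track(1.0)
  q <- quantify_region_signal(tr, genes, mode = "promoter")
  expect_equal(q$signal, 2000)          # flat 1.0 over TSS +/- 1 kb
  tr$scale_factor <- 0.5
  expect_equal(quantify_region_signal(tr, genes, mode = "promoter")$signal, 1000)

  # piecewise steps: 0-1kb at 2, 1-2kb at 4 over promoter [1000, 3000)
  steps <- mark_track(data.frame(chrom = "chr1", start = c(1000, 2000),
                                 end = c(2000, 3000), value = c(2, 4)),
                      "s", "H3K4me3")
  g2 <- gene_models("g2", "chr1", "+", tss = 2000, tes = 9000)
  expect_equal(quantify_region_signal(steps, g2, mode = "promoter")$signal, 6000)

  # auto mode: genic for H3K36me3 spans TSS..TES
  tr36 <- flat_track(1.0, mark = "H3K36me3")
  expect_equal(quantify_region_signal(tr36, genes)$signal, 6000)

  # targets past chromosome bounds are clipped with a warning
  g_edge <- gene_models("g3", "chr1", "+", tss = 500, tes = 9000)
  expect_warning(qc <- quantify_region_signal(flat_track(1), g_edge,
                                              mode = "promoter",
                                              chrom_sizes = c(chr1 = 1e5)),
                 "clipped")
  expect_equal(qc$signal, 1500)
})

test_that("log2 condition ratios are invariant to scaling one track", {
  genes <- gene_models(paste0("g", 1:5), "chr1", "+",
                       tss = seq(5000, 45000, by = 10000),
                       tes = seq(9000, 49000, by = 10000))
  withr::with_seed(6, vals <- runif(10, 0.5, 2))
  cov_df <- function(v) data.frame(chrom = "chr1",
                                   start = seq(0, 9e4, by = 1e4),
                                   end = seq(1e4, 1e5, by = 1e4), value = v)
  t_nf <- mark_track(cov_df(vals), "nf", "H3K27ac")
  t_f <- mark_track(cov_df(rev(vals)), "f", "H3K27ac")
  norm <- normalize_to_geometric_mean(list(t_nf, t_f))
  r1 <- mark_log2_ratios(norm[[1]], norm[[2]], genes, mode = "promoter")
  # multiply one track by a constant everywhere: ratios must not move
  t_f2 <- mark_track(cov_df(rev(vals) * 7), "f", "H3K27ac")
  norm2 <- normalize_to_geometric_mean(list(t_nf, t_f2))
  r2 <- mark_log2_ratios(norm2[[1]], norm2[[2]], genes, mode = "promoter")
  expect_equal(r1$log2_ratio, r2$log2_ratio, tolerance = 1e-12)
})

test_that("mark ratios combine as a plain mean on the log scale", {
  expect_equal(combine_mark_ratios(cbind(a = 1, b = -1)), 0)
  expect_equal(combine_mark_ratios(cbind(a = 2, b = 0, c = 1)), 1)
  expect_equal(combine_mark_ratios(cbind(a = c(1, 3))), c(1, 3))  # identity
})

test_that("rank regression recovers exact fits and rejects noise", {
  n <- 200
  de <- data.frame(gene_id = paste0("g", 1:n), log2fc = seq(-3, 3, length.out = n))
  rank <- seq_len(n)
  exact <- 0.5 * rank - 1e-4 * rank^2 + 2e-6 * rank^3
  m <- cbind(H3K27ac = exact)
  rownames(m) <- de$gene_id
  rr <- expression_rank_regression(de, m, combine = NULL)
  expect_equal(unname(rr$per_mark_r2["H3K27ac"]), 1.0, tolerance = 1e-8)

  # independent noise explains (almost) nothing, over several seeds
  r2s <- sapply(1:5, function(s) {
    withr::with_seed(s, noise <- rnorm(1000))
    de2 <- data.frame(gene_id = paste0("g", 1:1000),
                      log2fc = sort(rnorm(1000)))
    m2 <- cbind(H3K27ac = noise); rownames(m2) <- de2$gene_id
    expression_rank_regression(de2, m2)$per_mark_r2
  })
  expect_true(all(r2s < 0.02))

  # constant predictor -> r2 0 with a warning
  mc <- cbind(H3K27ac = rep(1, n)); rownames(mc) <- de$gene_id
  expect_warning(rc <- expression_rank_regression(de, mc), "constant")
  expect_equal(unname(rc$per_mark_r2["H3K27ac"]), 0)

  # r2 invariant under order-preserving relabeling of gene ids
  de3 <- de; de3$gene_id <- sprintf("zz%04d", 1:n)
  m3 <- m; rownames(m3) <- de3$gene_id
  rr3 <- expression_rank_regression(de3, m3)
  expect_equal(rr3$per_mark_r2, rr$per_mark_r2)
})

test_that("planted mark-expression coupling is recovered near its analytic value", {
  # per-mark R2 concentrates near rho^2; combined two-mark model near
  # 2 rho^2 / (1 + rho^2) (independent noise, shared latent signal)
  rho <- 0.7
  r2 <- sapply(1:8, function(s) {
    n <- 1000
    withr::with_seed(100 + s, {
      genes <- gene_models(paste0("g", 1:n), "chr1", "+",
                           tss = seq(0, by = 10000, length.out = n) + 2000,
                           tes = seq(0, by = 10000, length.out = n) + 8000)
      de <- simulate_de_table(genes, seed = 200 + s)
      z <- as.numeric(scale(de$log2fc))
      m <- sapply(c("H3K27ac", "H3K36me3"), function(mk)
        rho * z + sqrt(1 - rho^2) * rnorm(n))
      rownames(m) <- genes$gene_id
    })
    rr <- expression_rank_regression(de, m)
    c(rr$per_mark_r2, combined = rr$combined_r2)
  })
  means <- rowMeans(r2)
  expect_equal(unname(means["H3K27ac"]), rho^2, tolerance = 0.05)
  expect_equal(unname(means["H3K36me3"]), rho^2, tolerance = 0.05)
  expect_equal(unname(means["combined"]), 2 * rho^2 / (1 + rho^2),
               tolerance = 0.1)
})

test_that("simulated tracks round-trip through quantification", {
  n <- 40
  genes <- gene_models(paste0("g", 1:n), "chr1", "+",
                       tss = seq(0, by = 20000, length.out = n) + 5000,
                       tes = seq(0, by = 20000, length.out = n) + 15000)
  de <- simulate_de_table(genes, seed = 21)
  sim <- simulate_mark_tracks(genes, de, marks = "H3K27ac", rho = 1,
                              chrom_sizes = c(chr1 = 1e6), seed = 22)
  norm <- normalize_to_geometric_mean(sim$tracks)
  r <- mark_log2_ratios(norm[["H3K27ac.NF"]], norm[["H3K27ac.F"]], genes,
                        mode = "promoter", pseudocount = 0)
  # geometric-mean normalization shifts all log ratios by one constant
  shift <- r$log2_ratio - sim$log2ratio[, "H3K27ac"]
  expect_lt(diff(range(shift)), 1e-6)
})
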