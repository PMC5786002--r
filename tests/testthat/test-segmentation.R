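test_that("disorder score counts window levels inside the bounds", {
  # fully polarized window -> 0; fully intermediate -> 1
  m0 <- mk_methylome(rep(c(0, 1), length.out = 101), coverage = 1)
  p <- segmentation_params()
  expect_equal(unique(disorder_score_track(m0, p)), 0)

  m1 <- mk_methylome(rep(0.5, 101), coverage = 2)
  expect_equal(unique(disorder_score_track(m1, p)), 1)

  # 50 of 101 levels at 0.5, rest at 0.95 -> 50/101 (direct count)
  lv <- c(rep(0.5, 50), rep(0.95, 51))
  m2 <- mk_methylome(lv, coverage = 20)
  expect_equal(disorder_score_track(m2, p)[51], 50 / 101)
})

test_that("disorder score replicates edge windows and skips short chromosomes", {
  withr::with_seed(1, lv <- runif(150))
  m <- mk_methylome(lv, coverage = 10)
  s <- disorder_score_track(m)
  half <- 50
  expect_equal(s[1:half], rep(s[half + 1], half))
  expect_equal(s[(150 - half + 1):150], rep(s[150 - half], half))

  short <- mk_methylome(runif(50), coverage = 10)
  expect_warning(s2 <- disorder_score_track(short), "skipped")
  expect_true(all(is.na(s2)))
})

test_that("one-state methylomes yield zero PMRs", {
  withr::with_seed(3, lv <- sample(c(0.02, 0.97), 2000, replace = TRUE))
  m <- mk_methylome(lv, coverage = 20)
  tr <- disorder_score_track(m)
  expect_equal(nrow(detect_pmrs(tr, m)), 0L)
})

test_that("a planted disordered block is recovered and split blocks fuse", {
  withr::with_seed(101, {
    # polarized background, one 2000-CpG uniform block in the middle
    n <- 6000; block <- 2001:4000
    latent <- rbeta(n, 17, 3)
    latent[block] <- runif(length(block))
    cov <- pmax(1, rpois(n, 30))
    lv <- rbinom(n, cov, latent) / cov
    pos <- seq(0, by = 100, length.out = n)
    m <- methylome(data.frame(chrom = "chr1", pos = pos,
                              meth = round(lv * cov), total = cov),
                   "sim", c(chr1 = max(pos) + 1000))
    tr <- disorder_score_track(m)
    pmrs <- detect_pmrs(tr, m)
    expect_gte(nrow(pmrs), 1L)
    truth <- c(pos[block[1]], pos[block[length(block)]] + 2)
    ov <- sum(pmax(0, pmin(pmrs$end, truth[2]) - pmax(pmrs$start, truth[1])))
    jac <- ov / (sum(pmrs$end - pmrs$start) + diff(truth) - ov)
    expect_gte(ov / diff(truth), 0.9)
    expect_gte(jac, 0.8)

    # two blocks separated by < one window of polarized CpGs fuse into one
    latent2 <- rbeta(n, 17, 3)
    latent2[1001:2500] <- runif(1500)
    latent2[2551:4000] <- runif(1450)   # 50-CpG gap
    lv2 <- rbinom(n, cov, latent2) / cov
    m2 <- methylome(data.frame(chrom = "chr1", pos = pos,
                               meth = round(lv2 * cov), total = cov),
                    "sim2", c(chr1 = max(pos) + 1000))
    pmrs2 <- detect_pmrs(disorder_score_track(m2), m2)
    hit <- pmrs2$start <= pos[1001] + 2000 & pmrs2$end >= pos[4000] - 2000
    expect_equal(sum(hit), 1L)
  })
})

test_that("mask_and_smooth weights by coverage and truncates at boundaries", {
  m <- mk_methylome(c(0.0, 0.3, 0.6), coverage = 10)
  sm <- mask_and_smooth(m, region_table())
  expect_equal(sm$smoothed[2], 0.3)
  expect_equal(sm$smoothed[1], mean(c(0.0, 0.3)))   # truncated window

  m2 <- mk_methylome(c(0.2, 0.2, 0.8), coverage = c(10, 10, 20))
  sm2 <- mask_and_smooth(m2, region_table())
  expect_equal(sm2$smoothed[2], (2 + 2 + 16) / 40)

  # an isolated CpG between two masked stretches keeps its own level
  m3 <- mk_methylome(c(0.9, 0.9, 0.4, 0.9, 0.9), coverage = 10)
  pmrs <- mk_regions(c(0, 250), c(150, 450), "PMR")
  sm3 <- mask_and_smooth(m3, pmrs)
  expect_equal(nrow(sm3), 1L)
  expect_equal(sm3$smoothed, 0.4)
  expect_equal(length(unique(sm3$block)), 1L)

  # masked gaps split blocks so smoothing never reaches across a PMR
  m4 <- mk_methylome(c(0.1, 0.1, 0.9, 0.5, 0.5), coverage = 10)
  sm4 <- mask_and_smooth(m4, mk_regions(200, 250, "PMR"))
  expect_equal(sm4$block, c(1, 1, 2, 2))
  expect_equal(sm4$smoothed[2], 0.1)   # right neighbor is beyond the mask
})

test_that("randomize_methylome permutes per chromosome, deterministically", {
  withr::with_seed(5, lv <- runif(300))
  m <- mk_methylome(lv, coverage = sample(5:30, 300, replace = TRUE))
  r1 <- randomize_methylome(m, seed = 42)
  r2 <- randomize_methylome(m, seed = 42)
  expect_identical(r1$cpgs, r2$cpgs)
  expect_false(identical(r1$cpgs$level, m$cpgs$level))
  expect_equal(sort(r1$cpgs$level), sort(m$cpgs$level))
  expect_equal(sort(r1$cpgs$total), sort(m$cpgs$total))
  expect_equal(r1$cpgs$pos, m$cpgs$pos)

  single <- mk_methylome(0.5, coverage = 10)
  expect_equal(randomize_methylome(single, 1)$cpgs$level, 0.5)
})

test_that("hypomethylated region detection applies both thresholds", {
  m <- mk_methylome(c(0.9, 0.9, 0.2, 0.3, 0.4, 0.9), coverage = 10)
  sm <- mask_and_smooth(m, region_table())
  sm$smoothed <- c(0.9, 0.9, 0.2, 0.3, 0.4, 0.9)  # pin smoothed track
  regs <- detect_hypomethylated_regions(sm, 3, 0.5)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$n_cpg, 3L)
  expect_equal(regs$start, 200)
  expect_equal(regs$end, 402)

  # run of 2 below cutoff is rejected; all-high track yields nothing
  sm$smoothed <- c(0.9, 0.2, 0.2, 0.9, 0.9, 0.9)
  expect_equal(nrow(detect_hypomethylated_regions(sm, 3, 0.5)), 0L)
  sm$smoothed <- rep(0.9, 6)
  expect_equal(nrow(detect_hypomethylated_regions(sm, 3, 0.5)), 0L)
})

test_that("detection matches brute-force enumeration on small chromosomes", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      n <- sample(50:500, 1)
      lv <- pmin(1, pmax(0, rbeta(n, 2, 2)))
      cov <- sample(1:30, n, replace = TRUE)
      m <- mk_methylome(lv, coverage = cov)
      pmrs <- if (rep %% 2 == 0)
        mk_regions(sample(0:20, 1) * 100, sample(25:40, 1) * 100, "PMR")
      else region_table()
      sm <- mask_and_smooth(m, pmrs)
      min_cpgs <- sample(3:5, 1); max_meth <- runif(1, 0.3, 0.6)
      got <- detect_hypomethylated_regions(sm, min_cpgs, max_meth)
      want <- brute_force_hypo(sm, min_cpgs, max_meth)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$n_cpg, want$n_cpg)
      }
    }
  })
})

test_that("segment classification partitions at the 30-CpG cutoff", {
  regs <- mk_regions(c(0, 500, 1000), c(100, 900, 1500), "raw",
                     n_cpg = c(30, 29, 3))
  cls <- classify_segments(regs)
  expect_equal(cls$class, c("UMR", "LMR", "LMR"))
  expect_true(all(cls$class %in% c("LMR", "UMR")))
  expect_equal(nrow(classify_segments(region_table())), 0L)
  expect_error(classify_segments(mk_regions(0, 10, "raw")), "n_cpg")
})

test_that("stage merging unions intervals and re-classifies by CpG count", {
  m <- mk_methylome(rep(0.1, 40), coverage = 10, pos = seq(0, by = 10, length.out = 40))
  s1 <- mk_regions(0, 160, "LMR", n_cpg = 12)
  s2 <- mk_regions(150, 325, "LMR", n_cpg = 20)
  merged <- merge_stage_segmentations(list(s1, s2), m)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 325)
  expect_equal(merged$n_cpg, 33L)        # counted in the union methylome
  expect_equal(merged$class, "UMR")      # 33 >= 30 re-classifies

  # book-ended intervals merge; single stage is identity up to recount
  s3 <- mk_regions(c(0, 100), c(100, 150), "PMR")
  merged2 <- merge_stage_segmentations(list(s3), m)
  expect_equal(nrow(merged2), 1L)
  expect_equal(c(merged2$start, merged2$end), c(0, 150))
})

test_that("calibration reports the shuffle FDR and picks default params", {
  lay <- simulate_genome_layout(chrom_length = 1.5e6, n_pmr = 3L,
                                pmr_length = 150e3, n_lmr = 40L,
                                n_umr = 4L, umr_length = 3000,
                                n_cgi = 2L, seed = 7)
  sim <- simulate_methylome(lay, seed = 8)
  m <- sim$methylome
  tr <- disorder_score_track(m)
  pmrs <- detect_pmrs(tr, m)
  grid <- expand.grid(min_cpgs = c(3L, 4L), max_meth = c(0.5, 0.4))
  cal <- calibrate_detection_params(m, pmrs, grid, seed = 9)
  expect_s3_class(cal, "fdr_calibration")
  expect_equal(nrow(cal$table), 4L)
  expect_true(all(cal$table$fdr ==
                    ifelse(cal$table$n_original == 0, 1,
                           cal$table$n_randomized / cal$table$n_original)))
  expect_equal(cal$chosen$min_cpgs, 3L)
  expect_equal(cal$chosen$max_meth, 0.5)
  expect_lt(cal$chosen$fdr, 0.05)

  # unstructured noise never passes: counts comparable between copies
  withr::with_seed(31, {
    n <- 8000
    cov <- pmax(1, rpois(n, 30))
    meth <- rbinom(n, cov, 0.85)
  })
  noise <- methylome(data.frame(chrom = "chr1",
                                pos = seq(0, by = 100, length.out = 8000),
                                meth = meth, total = cov),
                     "noise", c(chr1 = 9e5))
  expect_error(
    calibrate_detection_params(noise, region_table(),
                               data.frame(min_cpgs = 3, max_meth = 0.5),
                               seed = 10),
    "no grid point")
})

test_that("segmentation is deterministic given input and seed", {
  lay <- simulate_genome_layout(chrom_length = 1e6, n_pmr = 2L,
                                pmr_length = 100e3, n_lmr = 20L,
                                n_umr = 2L, n_cgi = 1L, seed = 3)
  sim <- simulate_methylome(lay, seed = 4)
  a <- segment_methylome(sim$methylome, seed = 5)
  b <- segment_methylome(sim$methylome, seed = 5)
  expect_identical(a$pmrs, b$pmrs)
  expect_identical(a$segments, b$segments)
  expect_true(all(a$segments$class %in% c("LMR", "UMR")))
})
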