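meth_uniform_low <- function(from = 0, to = 10000, by = 100) {
  pos <- seq(from, to, by = by)
  mk_methylome(rep(0.05, length(pos)), coverage = 10, pos = pos,
               chrom_len = to + 5000)
}

test_that("gUMR assignment clips to the gene and removes island intervals", {
  umrs <- mk_regions(0, 4000, "UMR", n_cpg = 40)
  genes <- gene_models("g1", "chr1", "+", tss = 1000, tes = 9000)
  cgis <- mk_regions(1500, 2000, "CGI")
  m <- meth_uniform_low()
  g <- assign_gumrs(umrs, genes, cgis, m)
  expect_equal(nrow(g), 1L)
  frags <- attr(g, "fragments")
  expect_equal(frags$start, c(1000, 2000))
  expect_equal(frags$end, c(1500, 4000))
  expect_equal(g$total_length, 2500)
  expect_equal(g$gene_fraction, 2500 / 8000)
  # island CpGs do not count: dyads at 1500..1998 are excluded
  expect_equal(g$n_cpg, sum(seq(0, 10000, 100) >= 1000 &
                              seq(0, 10000, 100) < 4000) -
                 sum(seq(0, 10000, 100) >= 1499 & seq(0, 10000, 100) < 2000))
})

test_that("gUMR eligibility and CpG floor are enforced", {
  m <- meth_uniform_low()
  genes <- gene_models("g1", "chr1", "+", tss = 1000, tes = 2800)
  umrs <- mk_regions(0, 4000, "UMR", n_cpg = 40)
  # gene spans 1800 bp, islands cover all but 1300 -> excluded
  cgis <- mk_regions(2300, 2800, "CGI")
  expect_equal(nrow(assign_gumrs(umrs, genes, cgis, m)), 0L)
  # without islands the same gene qualifies (1800 >= 1500)
  expect_equal(nrow(assign_gumrs(umrs, genes, region_table(), m)), 1L)

  # fewer than 10 CpGs after island removal -> no gUMR
  genes2 <- gene_models("g2", "chr1", "+", tss = 1000, tes = 9000)
  sparse <- mk_methylome(rep(0.05, 9), coverage = 10,
                         pos = seq(1000, 2600, by = 200), chrom_len = 2e4)
  expect_equal(nrow(assign_gumrs(umrs, genes2, region_table(), sparse)), 0L)

  # UMR must contain the TSS
  genes3 <- gene_models("g3", "chr1", "+", tss = 4500, tes = 9000)
  expect_equal(nrow(assign_gumrs(umrs, genes3, region_table(), m)), 0L)

  # several TSS-overlapping UMRs are unioned with a warning
  umrs2 <- mk_regions(c(0, 900), c(800, 4000), "UMR", n_cpg = c(8, 31))
  genes4 <- gene_models("g4", "chr1", "-", tss = 700, tes = 100)
  umrs3 <- mk_regions(c(0, 600), c(650, 4000), "UMR")
  expect_warning(assign_gumrs(umrs3, gene_models("g5", "chr1", "+", 620, 9000),
                              region_table(), m),
                 "union")
})

test_that("extended-demethylation flags follow the length/fraction rules", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  total_length = c(5000, 2000, 2600, 6000),
                  gene_fraction = c(5000 / 40000, 0.20, 0.26, 0.30))
  fl <- flag_extended_demethylation(g)
  expect_equal(fl$flagged, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(fl$reason, c("length>=5kb", "none", "fraction>=25%", "both"))

  # monotone: enlarging the gUMR never un-flags
  withr::with_seed(2, {
    for (i in 1:20) {
      len <- runif(1, 0, 8000); frac <- runif(1, 0, 0.5)
      f1 <- flag_extended_demethylation(
        data.frame(gene_id = "x", total_length = len, gene_fraction = frac))
      f2 <- flag_extended_demethylation(
        data.frame(gene_id = "x", total_length = len * 1.5,
                   gene_fraction = min(1, frac * 1.5)))
      expect_true(!f1$flagged || f2$flagged)
    }
  })
})

test_that("FMRs are the exact complement of the other classes", {
  sizes <- c(chr1 = 1000)
  fmr <- compute_fmrs(sizes, lmrs = mk_regions(100, 200, "LMR"),
                      pmrs = mk_regions(500, 800, "PMR"))
  expect_equal(fmr$start, c(0, 200, 800))
  expect_equal(fmr$end, c(100, 500, 1000))

  expect_equal(compute_fmrs(sizes)$end, 1000)  # empty input -> whole chrom
  tiled <- compute_fmrs(sizes, lmrs = mk_regions(0, 600, "LMR"),
                        umrs = mk_regions(600, 1000, "UMR"))
  expect_equal(nrow(tiled), 0L)

  # partition property: classes + FMR cover each base exactly once
  withr::with_seed(8, {
    for (i in 1:10) {
      starts <- sort(sample(0:900, 4))
      ends <- pmin(1000, starts + sample(10:80, 4))
      keep <- ends > starts & c(TRUE, starts[-1] >= ends[-4])
      regs <- region_table("chr1", starts[keep], ends[keep],
                           sample(c("LMR", "UMR", "PMR", "CGI"), sum(keep),
                                  replace = TRUE))
      fmrs <- compute_fmrs(sizes,
                           cgis = regs[regs$class == "CGI", ],
                           lmrs = regs[regs$class == "LMR", ],
                           umrs = regs[regs$class == "UMR", ],
                           pmrs = regs[regs$class == "PMR", ])
      covered <- sum(regs$end - regs$start) + sum(fmrs$end - fmrs$start)
      expect_equal(covered, 1000)
    }
  })
})

test_that("gUMR fragments are always disjoint from islands", {
  withr::with_seed(13, {
    for (i in 1:10) {
      cgi_start <- sample(seq(1200, 3000, 100), 2)
      cgis <- mk_regions(cgi_start, cgi_start + sample(200:400, 2), "CGI")
      umrs <- mk_regions(0, 4000, "UMR")
      genes <- gene_models("g", "chr1", "+", 1000, 9000)
      g <- assign_gumrs(umrs, genes, cgis, meth_uniform_low())
      if (!nrow(g)) next
      frags <- attr(g, "fragments")
      for (k in seq_len(nrow(frags)))
        expect_true(all(frags$end[k] <= cgis$start |
                          frags$start[k] >= cgis$end))
    }
  })
})

test_that("nearest gene assignment honors the distance cutoff and ties", {
  genes <- gene_models(c("gB", "gA"), "chr1", "+",
                       tss = c(2000, 6000), tes = c(3000, 7000))
  inside <- mk_regions(2100, 2200, "LMR")
  got <- nearest_gene_within(inside, genes)
  expect_equal(got$gene_id, "gB")
  expect_equal(got$distance, 0)

  far <- nearest_gene_within(mk_regions(17001, 17100, "LMR"), genes)
  expect_true(is.na(far$gene_id))   # 10,001 bp from the nearest gene
  at_limit <- nearest_gene_within(mk_regions(17000, 17100, "LMR"), genes)
  expect_equal(at_limit$gene_id, "gA")
  expect_equal(at_limit$distance, 10000)

  # equidistant genes: closer TSS wins, then lexicographic id
  mid <- mk_regions(4000, 5000, "LMR")
  tie <- nearest_gene_within(mid, genes)
  expect_equal(tie$distance, 1000)
  expect_equal(tie$gene_id, "gA")  # gA TSS at 6000 is 1001 away; gB TSS 2001 away

  genes_eq <- gene_models(c("gZ", "gY"), "chr1", "+",
                          tss = c(6000, 6000), tes = c(7000, 7000))
  tie2 <- nearest_gene_within(mid, genes_eq)
  expect_equal(tie2$gene_id, "gY")  # TSS distances equal -> lexicographic
})
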