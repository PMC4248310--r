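test_that("annotation generator is seeded, non-overlapping and leaves intergenic space", {
  ann <- generate_annotation(200, 5e6, seed = 1)
  ann2 <- generate_annotation(200, 5e6, seed = 1)
  expect_identical(ann$genes, ann2$genes)
  expect_identical(ann$exons, ann2$exons)

  g <- ann$genes[order(ann$genes$start), ]
  expect_true(all(utils::head(g$end, -1) <= utils::tail(g$start, -1)))
  expect_true(all(g$exonic_length <= g$end - g$start))
  expect_true(all(g$exonic_length > 0))

  # interval-union oracle for the intergenic fraction
  covered <- sum(g$end - g$start)
  expect_gte(1 - covered / 5e6, 0.3)
  expect_equal(intergenic_fraction(ann), 1 - covered / 5e6)

  one <- generate_annotation(1, 1e4, seed = 3)
  expect_equal(nrow(one$genes), 1)
  expect_lte(one$genes$exonic_length, one$genes$end - one$genes$start)

  expect_error(generate_annotation(100, 1e4, seed = 1), "too small")
})

test_that("GTF round trip preserves gene models byte-for-byte content", {
  ann <- generate_annotation(50, 2e6, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f1)
  write_gtf(generate_annotation(50, 2e6, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_gtf(f1, chrom_lengths = ann$chrom_lengths)
  i <- match(ann$genes$gene_id, back$genes$gene_id)
  expect_equal(back$genes$start[i], ann$genes$start)
  expect_equal(back$genes$end[i], ann$genes$end)
  expect_equal(back$genes$tss[i], ann$genes$tss)
  expect_equal(back$genes$exonic_length[i], ann$genes$exonic_length)
})

test_that("bulk counts respect pi0, depth scaling, and stochastic ordering", {
  ann <- generate_annotation(10000, 3e8, seed = 2)
  all_null <- generate_bulk_counts(ann, pi0 = 1, seed = 4)
  expect_false(any(all_null$truth$expressed))

  half <- generate_bulk_counts(ann, pi0 = 0.5, seed = 5)
  p_hat <- mean(half$truth$expressed)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))

  # Poisson scaling oracle: doubling depth doubles expected counts
  d1 <- generate_bulk_counts(ann, pi0 = 0.5, depth = 1e7, seed = 6)
  d2 <- generate_bulk_counts(ann, pi0 = 0.5, depth = 2e7, seed = 6)
  expect_equal(sum(d2$counts) / sum(d1$counts), 2, tolerance = 0.02)

  # pi0 = 0 vs pi0 = 1 give stochastically ordered FPKM
  hi <- generate_bulk_counts(ann, pi0 = 0, seed = 7)
  lo <- generate_bulk_counts(ann, pi0 = 1, seed = 8)
  wt <- stats::wilcox.test(hi$truth$true_fpkm, lo$truth$true_fpkm,
                           alternative = "greater")
  expect_lt(wt$p.value, 1e-6)

  expect_error(generate_bulk_counts(ann, pi0 = 1.2), "pi0")
})

test_that("atlas generator plants restriction as requested and is seeded", {
  atl <- generate_atlas(2000, 64, 35, restricted_fraction = 0, seed = 11)
  expect_false(any(atl$truth$restricted))

  atl1 <- generate_atlas(500, 64, 35, restricted_fraction = 0.3, seed = 12)
  atl2 <- generate_atlas(500, 64, 35, restricted_fraction = 0.3, seed = 12)
  expect_identical(atl1$matrix, atl2$matrix)
  expect_true(all(atl1$truth$n_groups[atl1$truth$restricted] >= 1))
  expect_true(all(atl1$truth$n_groups[atl1$truth$restricted] <= 5))

  # noiseless limit: group-mean ratio approaches the planted fold
  q <- generate_atlas(300, 64, 35, restricted_fraction = 1, fold = 8,
                      max_groups = 1, noise_sd = 1e-4, seed = 13)
  i <- which(q$truth$n_groups == 1)[1]
  gid <- as.integer(q$truth$groups[i])
  v <- tapply(q$matrix[i, ], q$groups[colnames(q$matrix)], mean)
  expect_equal(unname(v[as.character(gid)] / stats::median(v[names(v) != gid])),
               8, tolerance = 0.01)

  expect_error(generate_atlas(100, restricted_fraction = 2), "restricted_fraction")
})

test_that("chip coverage places mark-specific enrichment at TSS only", {
  ann <- generate_annotation(300, 1e7, seed = 21)
  st <- assign_chromatin_states(ann, seed = 22)
  cc <- generate_chip_coverage(ann, st, enrichment = 4, bg_rate = 0.2,
                               gene_enrichment_sd = 0, seed = 23)
  win <- tss_windows(ann, 1000)
  e27 <- enrichment_over_input(cc$chip$H3K27me3, cc$input, win, chrom_len = 1e7)
  rep_genes <- st$gene_id[st$chromatin_state == "repressed"]
  act_genes <- st$gene_id[st$chromatin_state == "active"]
  # Poisson-mean oracle: the planted window rate ratio is the enrichment
  expect_equal(stats::median(e27$enrichment[e27$gene_id %in% rep_genes]),
               4, tolerance = 0.15)
  expect_equal(stats::median(e27$enrichment[e27$gene_id %in% act_genes]),
               1, tolerance = 0.15)

  flat <- generate_chip_coverage(ann, st, enrichment = 1, bg_rate = 0.2, seed = 24)
  ef <- enrichment_over_input(flat$chip$H3K4me3, flat$input, win, chrom_len = 1e7)
  expect_equal(stats::median(ef$enrichment), 1, tolerance = 0.1)

  expect_error(generate_chip_coverage(ann, st, marks = "H3K9me3"), "unknown mark")
})

test_that("single-cell generator reproduces on-frequency and burst truth", {
  cls <- data.frame(gene_id = sprintf("g%03d", 1:50),
                    class = rep("other", 50))
  truth <- assign_sc_truth(cls)
  truth$sc_on_frequency <- 0.01
  truth$sc_burst_level <- 16
  pop <- stats::setNames(rep(1, 50), cls$gene_id)
  sc <- generate_single_cells(pop, truth, n_cells = 1e4, noise_sd = 1e-6,
                              capture_efficiency = 1, capture_sdlog = 0, seed = 31)
  # binomial CI on the observed detection fraction
  frac <- mean(colMeans(sc$on))
  expect_lt(abs(frac - 0.01), 4 * sqrt(0.01 * 0.99 / 1e4))
  # law of large numbers: mean(on x burst) -> frequency x burst
  expect_equal(mean(sc$signal), 0.01 * 16, tolerance = 0.05)

  # frequency 1, burst 1, no noise: every cell at the population level
  truth2 <- truth; truth2$sc_on_frequency <- 1; truth2$sc_burst_level <- 1
  sc2 <- generate_single_cells(pop, truth2, n_cells = 20, noise_sd = 1e-9,
                               capture_efficiency = 1, capture_sdlog = 0, seed = 32)
  expect_equal(unname(sc2$signal), matrix(1, 20, 50), tolerance = 1e-6)

  expect_error(generate_single_cells(pop, truth, capture_efficiency = 0), "capture")
})
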