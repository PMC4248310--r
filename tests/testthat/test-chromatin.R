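test_that("TSS windows respect strand, width and chromosome edges", {
  ann <- tiny_annotation()
  win <- tss_windows(ann, 1000)
  expect_equal(win$start[win$gene_id == "gA"], 4500)
  expect_equal(win$end[win$gene_id == "gA"], 5500)
  # minus-strand gene: window centred on the right-hand 5' end
  expect_equal(win$start[win$gene_id == "gB"], 47500)
  expect_equal(win$end[win$gene_id == "gB"], 48500)
  w2 <- tss_windows(ann, 2)
  expect_equal(w2$end - w2$start, c(2, 2))
  expect_error(tss_windows(ann, 999), "even")
})

test_that("enrichment over input matches hand-computed window ratios", {
  ann <- tiny_annotation()
  win <- tss_windows(ann, 1000)
  inp <- flat_coverage(1e5, bin = 100, rate = 10)
  # chip identical to input: enrichment 1 everywhere
  e1 <- enrichment_over_input(inp, inp, win, chrom_len = 1e5)
  expect_equal(e1$enrichment, c(1, 1), tolerance = 1e-12)

  # 4x density in gA's window at equal library size
  chip <- inp
  in_win <- chip$start >= 4500 & chip$end <= 5500
  chip$score[in_win] <- 40
  chip$score[!in_win] <- chip$score[!in_win] *
    (sum(inp$score) - sum(chip$score[in_win])) / sum(inp$score[!in_win])
  e4 <- enrichment_over_input(chip, inp, win, chrom_len = 1e5)
  expect_equal(e4$enrichment[e4$gene_id == "gA"], 4, tolerance = 1e-6)

  # replicate averaging is the arithmetic mean
  chip_a <- inp; chip_a$score[in_win] <- 20
  chip_b <- inp; chip_b$score[in_win] <- 40
  lib_fix <- function(cc) { cc$score <- cc$score * sum(inp$score) / sum(cc$score); cc }
  em <- enrichment_over_input(list(lib_fix(chip_a), lib_fix(chip_b)), inp, win,
                              chrom_len = 1e5)
  ea <- enrichment_over_input(lib_fix(chip_a), inp, win, chrom_len = 1e5)
  eb <- enrichment_over_input(lib_fix(chip_b), inp, win, chrom_len = 1e5)
  expect_equal(em$enrichment, (ea$enrichment + eb$enrichment) / 2)

  # invariance to jointly scaling both libraries
  chip2 <- chip; chip2$score <- chip2$score * 3
  inp2 <- inp; inp2$score <- inp2$score * 3
  expect_equal(enrichment_over_input(chip2, inp2, win, chrom_len = 1e5)$enrichment,
               e4$enrichment)
  bad <- inp; bad$score <- 0
  expect_error(enrichment_over_input(chip, bad, win, chrom_len = 1e5),
               "zero input library")
})

test_that("metagene profiles are flat at 1 for identical tracks and strand-symmetric", {
  ann <- generate_annotation(100, 5e6, seed = 501)
  inp <- flat_coverage(5e6, bin = 100, rate = 5)
  mp <- metagene_profile(inp, inp, ann, ann$genes$gene_id, flank = 2000,
                         n_bins = 21, chrom_len = 5e6)
  expect_equal(mp$enrichment, rep(1, 21), tolerance = 1e-9)

  # symmetry oracle: flipping all strands mirrors the profile of
  # a strand-asymmetric signal
  chip <- inp
  for (i in seq_len(nrow(ann$genes))) {
    tss <- ann$genes$tss[i]
    dwn <- if (ann$genes$strand[i] == "+") chip$start >= tss & chip$start < tss + 500 else
      chip$start >= tss - 500 & chip$start < tss
    chip$score[dwn] <- chip$score[dwn] + 20
  }
  flipped <- ann
  flipped$genes$strand <- ifelse(ann$genes$strand == "+", "-", "+")
  flipped$genes$tss <- ifelse(flipped$genes$strand == "+",
                              flipped$genes$start, flipped$genes$end)
  m1 <- metagene_profile(chip, inp, ann, ann$genes$gene_id, flank = 2000,
                         n_bins = 20, chrom_len = 5e6)
  expect_gt(mean(m1$enrichment[m1$position > 0 & m1$position < 500]),
            mean(m1$enrichment[m1$position < 0]))
  expect_error(metagene_profile(chip, inp, ann, character(0)), "empty gene set")
})

test_that("peak overlap uses half-open intersection and matches coverage expectation", {
  ann <- tiny_annotation()
  win <- tss_windows(ann, 1000)
  # peak exactly covering gA's window counts; abutting peak does not
  peaks <- data.frame(chrom = "chr1", start = c(4500, 48500), end = c(5500, 49000))
  ov <- peak_overlap_fraction(list(all = c("gA", "gB")), peaks, win)
  expect_equal(unname(ov["all"]), 0.5)

  # Monte-Carlo oracle: random peaks covering ~10% of the genome
  set.seed(502)
  ann2 <- generate_annotation(400, 2e7, seed = 503)
  win2 <- tss_windows(ann2, 1000)
  pk_start <- seq(0, 2e7 - 1000, by = 1e4)
  peaks2 <- data.frame(chrom = "chr1", start = pk_start, end = pk_start + 1000)
  ov2 <- peak_overlap_fraction(list(all = ann2$genes$gene_id), peaks2, win2)
  # a 1 kb window hits a 1 kb peak every 10 kb if they come within 2 kb
  expect_equal(unname(ov2["all"]), 0.2, tolerance = 0.25)
  expect_error(peak_overlap_fraction(list(x = "nope"), peaks, win), "unknown gene")
})

test_that("fisher association equals hypergeometric enumeration", {
  # worked 2x2: [[8,2],[2,8]] over a 20-gene universe
  uni <- sprintf("u%02d", 1:20)
  A <- uni[1:10]
  B <- c(uni[1:8], uni[11:12])
  fa <- fisher_association(A, B, uni)
  expect_equal(fa$odds_ratio, 16)
  expect_equal(fa$pvalue, enum_fisher_p(fa$table), tolerance = 1e-12)
  expect_equal(fa$pvalue, 0.023, tolerance = 0.002)

  # random tables against the enumeration oracle
  set.seed(504)
  for (i in 1:10) {
    u <- sprintf("g%03d", 1:200)
    a <- sample(u, sample(20:100, 1))
    b <- sample(u, sample(20:100, 1))
    fa2 <- fisher_association(a, b, u)
    expect_equal(fa2$pvalue, enum_fisher_p(fa2$table), tolerance = 1e-9)
  }

  # perfect association: infinity-flagged odds ratio, minimal p
  fp <- fisher_association(A, A, uni)
  expect_true(fp$infinite)
  expect_equal(fp$pvalue, enum_fisher_p(fp$table), tolerance = 1e-12)
  expect_error(fisher_association(A, B, character(0)), "empty universe")
})

test_that("rank test exact branch equals full enumeration", {
  rt <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$U, 0)
  expect_equal(rt$pvalue, 0.1)
  expect_true(rt$exact)

  set.seed(505)
  for (i in 1:5) {
    a <- sample(1:100, sample(3:8, 1))
    b <- sample(setdiff(1:100, a), sample(3:8, 1))
    rt2 <- rank_test(a, b)
    expect_equal(rt2$pvalue, enum_rank_p(a, b), tolerance = 1e-9)
  }

  # exact and approximate branches agree at n = 8 vs 8
  a <- c(1, 4, 6, 9, 13, 17, 22, 30)
  b <- c(2, 5, 8, 12, 15, 19, 25, 33)
  p_ex <- rank_test(a, b)$pvalue
  p_ap <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  expect_equal(p_ap, p_ex, tolerance = 0.1 * p_ex + 0.05)

  same <- rank_test(c(1, 2, 3, 4) + 0.5, c(1, 2, 3, 4) + 0.25)
  expect_gt(same$pvalue, 0.5)
  expect_error(rank_test(numeric(0), 1), "empty")
})

test_that("bivalency analysis mirrors the two-mark TSS structure", {
  # identical enrichment vectors: r = 1
  e <- data.frame(gene_id = paste0("g", 1:50),
                  enrichment = stats::rlnorm(50, 0, 1))
  bv <- bivalency_analysis(e, e)
  expect_equal(bv$r_overall, 1)
  # boundary-inclusive bivalent gate
  e2 <- data.frame(gene_id = "g", enrichment = 2)
  bvb <- bivalency_analysis(e2, e2)
  expect_true(bvb$table$bivalent)

  # planted construction: bivalent TSS concentrated among Aire-up genes
  ann <- generate_annotation(800, 2.5e7, seed = 506)
  reg <- data.frame(gene_id = ann$genes$gene_id,
                    regulation_class = rep(c("dependent", "enhanced", "unchanged"),
                                           length.out = 800))
  st <- assign_chromatin_states(ann, reg, p_induced = c(0, 0.2, 0.8),
                                p_other = c(0.75, 0.2, 0.05), seed = 507)
  cc <- generate_chip_coverage(ann, st, enrichment = 4, bg_rate = 0.2, seed = 508)
  win <- tss_windows(ann, 1000)
  e4 <- enrichment_over_input(cc$chip$H3K4me3, cc$input, win, chrom_len = 2.5e7)
  e27 <- enrichment_over_input(cc$chip$H3K27me3, cc$input, win, chrom_len = 2.5e7)
  cls <- data.frame(gene_id = reg$gene_id, class = reg$regulation_class)
  bv2 <- bivalency_analysis(e4, e27, cls)
  expect_lt(bv2$r_overall, 0)
  expect_gt(bv2$r_aire_up, 0)

  # repressed vs active H3K27me3 contrast, Mann-Whitney
  rep_g <- st$gene_id[st$chromatin_state == "repressed"]
  act_g <- st$gene_id[st$chromatin_state == "active"]
  rt <- rank_test(e27$enrichment[e27$gene_id %in% rep_g],
                  e27$enrichment[e27$gene_id %in% act_g])
  expect_lt(rt$pvalue, 1e-6)
  expect_error(bivalency_analysis(e4, data.frame(gene_id = "zz", enrichment = 1)),
               "disjoint")
})
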