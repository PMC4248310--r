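test_that("nb test is symmetric, null-calibrated, and BH-monotone", {
  ann <- generate_annotation(2000, 6e7, seed = 401)
  ax <- generate_aire_experiment(ann, n_dependent = 100, n_enhanced = 300,
                                 n_repressed = 20, seed = 402)
  de <- nb_test(ax$counts_pos, ax$counts_ko)
  de_sw <- nb_test(ax$counts_ko, ax$counts_pos)
  expect_equal(de$pvalue, de_sw$pvalue)
  expect_equal(de$log2fc, -de_sw$log2fc)

  o <- order(de$pvalue)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))

  # identical matrices: no fold change, nothing significant
  same <- nb_test(ax$counts_pos, ax$counts_pos)
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$fdr > 0.9))

  # all-zero gene
  z <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
  z[2:3, ] <- 50
  dz <- nb_test(z, z + 0L)
  expect_equal(dz$pvalue[1], 1)
  expect_equal(dz$log2fc[1], 0)
})

test_that("nb test approaches the exact Poisson conditional test at low dispersion", {
  # enumeration oracle: conditional binomial test of the two condition sums
  exact_poisson_p <- function(ka, kb) {
    S <- ka + kb
    pr <- stats::dbinom(0:S, S, 0.5)
    sum(pr[pr <= pr[ka + 1] * (1 + 1e-9)])
  }
  set.seed(403)
  for (pair in list(c(3, 12), c(20, 35), c(8, 8), c(0, 9), c(25, 50))) {
    ka <- pair[1]; kb <- pair[2]
    p_pkg <- pgex:::.nb_cond_test(ka, kb, 2, 2, disp = 1e-9)
    expect_equal(p_pkg, exact_poisson_p(ka, kb), tolerance = 0.1)
  }
})

test_that("regulation classes follow the FDR, fold and KO-detection gates", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(2, 2, 3, -2),
                   fdr = c(0.01, 0.01, 0.2, 0.01))
  det <- data.frame(gene_id = c("a", "b", "c", "d"),
                    detected = c(FALSE, TRUE, TRUE, TRUE))
  reg <- classify_regulation(de, det)
  expect_equal(reg$table$class, c("dependent", "enhanced", "unchanged", "repressed"))
  expect_equal(unname(reg$counts), c(1, 1, 1, 1))
  # exhaustive and exclusive partition
  expect_true(all(reg$table$class %in% c("dependent", "enhanced",
                                         "repressed", "unchanged")))
  expect_error(classify_regulation(de, det[1:3, ]), "missing")
})

test_that("housekeeping control flags only genuinely biased sets", {
  ann <- generate_annotation(3000, 9e7, seed = 404)
  ax <- generate_aire_experiment(ann, n_dependent = 150, n_enhanced = 450,
                                 n_repressed = 30, seed = 405)
  de <- nb_test(ax$counts_pos, ax$counts_ko)
  unchanged <- ax$truth$gene_id[ax$truth$regulation_class == "unchanged"]
  hk <- sample(unchanged, 474)
  ctl <- housekeeping_control(de, hk)
  expect_false(ctl$bias_flag)
  expect_lt(ctl$median_abs_log2fc, 0.5)

  enh <- ax$truth$gene_id[ax$truth$regulation_class == "enhanced"]
  ctl2 <- housekeeping_control(de, sample(enh, 200))
  expect_true(ctl2$bias_flag)
  expect_error(housekeeping_control(de, character(0)), "empty")
})

test_that("specificity-dependence correlation recovers planted enrichment in narrow sets", {
  # two-point oracle
  bs <- list(sets = list(n1 = paste0("g", 1:20), n2 = paste0("h", 1:20)),
             nodes = data.frame(node = c("n1", "n2"), n_leaves = c(28, 7),
                                n_genes = c(20, 20)),
             total_leaves = 35)
  dp <- data.frame(gene_id = c(paste0("g", 1:20), paste0("h", 1:20)),
                   detected = TRUE)
  dk <- data.frame(gene_id = dp$gene_id,
                   detected = c(rep(c(TRUE, FALSE), c(18, 2)),
                                rep(c(TRUE, FALSE), c(2, 18))))
  out <- specificity_dependence_correlation(bs, dp, dk)
  expect_equal(out$r, 1)   # fractions (0.1, 0.9) vs specificities (0.2, 0.8)

  # degenerate: all fractions zero -> correlation undefined, not fabricated
  dk0 <- dp
  out0 <- specificity_dependence_correlation(bs, dp, dk0)
  expect_true(is.na(out0$r))

  # planted simulation: dependent genes preferentially in narrow sets
  set.seed(406)
  n_sets <- 30
  leaves <- sample(1:20, n_sets, replace = TRUE)
  sets <- lapply(seq_len(n_sets), function(i) sprintf("s%02d_g%02d", i, 1:15))
  frac_true <- 0.8 * (1 - leaves / 35) + stats::runif(n_sets, 0, 0.1)
  det_ko <- unlist(lapply(seq_len(n_sets), function(i)
    stats::runif(15) > frac_true[i]))
  bs2 <- list(sets = stats::setNames(sets, paste0("n", seq_len(n_sets))),
              nodes = data.frame(node = paste0("n", seq_len(n_sets)),
                                 n_leaves = leaves, n_genes = 15),
              total_leaves = 35)
  dp2 <- data.frame(gene_id = unlist(sets), detected = TRUE)
  dk2 <- data.frame(gene_id = unlist(sets), detected = det_ko)
  out2 <- specificity_dependence_correlation(bs2, dp2, dk2, min_members = 10)
  expect_gt(out2$r, 0)
  expect_lt(out2$pvalue, 0.05)
})
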