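make_sc <- function(n_cells = 80, n_genes = 400, seed = 601,
                    classes = c(dependent = 0.2, enhanced = 0.2,
                                tra = 0.2, other = 0.4), ...) {
  n_cls <- round(n_genes * classes)
  n_cls[1] <- n_genes - sum(n_cls[-1])
  cls <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                    class = rep(names(classes), n_cls))
  truth <- assign_sc_truth(cls)
  set.seed(seed)
  pop <- stats::setNames(stats::rlnorm(n_genes, log(5), 1), cls$gene_id)
  sc <- generate_single_cells(pop, truth, n_cells = n_cells, seed = seed + 1, ...)
  list(cls = cls, truth = truth, pop = pop, sc = sc)
}

test_that("spike-in curves are recovered exactly without noise and under shifts", {
  mol <- ercc_like_spikeins(40)$molecules
  sig <- matrix(rep(mol, each = 3), 3, 40,
                dimnames = list(paste0("c", 1:3), NULL))
  cur <- fit_spikein_curve(sig, mol)
  expect_equal(cur$slope, rep(1, 3), tolerance = 1e-10)
  expect_equal(cur$intercept, rep(0, 3), tolerance = 1e-10)
  expect_equal(cur$r2, rep(1, 3))

  # closed-form least squares: doubling signals shifts the intercept only
  cur2 <- fit_spikein_curve(sig * 2, mol)
  expect_equal(cur2$slope, cur$slope)
  expect_equal(cur2$intercept - cur$intercept, rep(log10(2), 3))

  # slope recovery under noise
  set.seed(602)
  noisy <- 10 ^ (0.9 * log10(rep(mol, each = 3)) + stats::rnorm(120, 0, 0.1))
  dim(noisy) <- c(3, 40)
  cur3 <- fit_spikein_curve(noisy, mol)
  expect_lt(max(abs(cur3$slope - 0.9)), 0.05)

  expect_error(fit_spikein_curve(sig[, 1:5], mol[1:5]), "cannot calibrate")
})

test_that("copy-number inversion matches hand calculation and recovers truth", {
  cur <- data.frame(cell = "c1", slope = 1, intercept = 1, r2 = 1, n_used = 40)
  sig <- matrix(c(100, 0), 1, 2, dimnames = list("c1", c("g1", "g2")))
  ds <- to_copy_numbers(sig, cur)
  expect_equal(unname(ds$copies[1, ]), c(10, 0))

  # noiseless identity curve: copies equal signal
  cur0 <- data.frame(cell = "c1", slope = 1, intercept = 0, r2 = 1, n_used = 40)
  expect_equal(to_copy_numbers(sig, cur0)$copies[1, 1], 100)
  expect_error(to_copy_numbers(sig, transform(cur, slope = -1)), "slope")

  # end-to-end: noiseless spike-ins invert the curve exactly
  x <- make_sc(n_cells = 20, n_genes = 200, seed = 603,
               noise_sd = 1e-9, capture_sdlog = 0.3)
  cur4 <- fit_spikein_curve(x$sc$spike_observed, x$sc$spike_table$molecules)
  ds4 <- to_copy_numbers(x$sc$signal, cur4)
  truth_copies <- x$sc$on * matrix(rep(x$truth$sc_burst_level * x$pop, each = 20),
                                   20, 200)
  on <- truth_copies > 0
  expect_equal(ds4$copies[on], truth_copies[on], tolerance = 1e-4)
})

test_that("QC gate is strict and counts only the requested genes", {
  m <- matrix(0, 3, 20, dimnames = list(paste0("c", 1:3), paste0("g", 1:20)))
  m[1, 1:10] <- 1   # exactly min_genes: removed
  m[2, 1:11] <- 1   # strictly above: retained
  m[3, 1:20] <- 1
  ds <- structure(list(copies = m, curves = data.frame(cell = paste0("c", 1:3)),
                       genes_detected = rowSums(m > 0)), class = "sc_dataset")
  kept <- qc_filter(ds, min_genes = 10)
  expect_setequal(rownames(kept$copies), c("c2", "c3"))

  # protein-coding restriction
  kept2 <- qc_filter(ds, min_genes = 10, coding_genes = paste0("g", 1:12))
  expect_setequal(rownames(kept2$copies), c("c2", "c3"))
  kept3 <- qc_filter(ds, min_genes = 0)
  expect_equal(nrow(kept3$copies), 3)
  expect_warning(qc_filter(ds, min_genes = 100), "no cell")
})

test_that("detection frequency and burst ratios recover the planted regime", {
  x <- make_sc(n_cells = 174, n_genes = 600, seed = 604)
  cur <- fit_spikein_curve(x$sc$spike_observed, x$sc$spike_table$molecules)
  ds <- to_copy_numbers(x$sc$signal, cur)
  gcl <- split(x$cls$gene_id, x$cls$class)
  fr <- detection_frequency(ds, gcl)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1))
  # worked example: 2 of 174 cells
  two <- names(which(abs(fr$frequency - 2 / 174) < 1e-9))[1]
  if (!is.na(two)) expect_equal(unname(fr$frequency[two]), 2 / 174)

  nrm <- normalize_to_population(ds, x$pop)
  expect_equal(nrm$mean_ratio, 1, tolerance = 0.01)
  # 2x single means halve the scale factor
  ds2 <- ds; ds2$copies <- ds$copies * 2
  nrm2 <- normalize_to_population(ds2, x$pop)
  expect_equal(nrm2$scale, nrm$scale / 2, tolerance = 1e-9)

  rt <- expression_ratio_when_detected(nrm$dataset, x$pop, gcl)
  cm <- rt$class_median
  expect_true(cm["dependent"] > cm["enhanced"])
  expect_true(cm["enhanced"] > cm["tra"])
  expect_error(normalize_to_population(ds, x$pop[1:20]), "co-detected")
})

test_that("single-gene ratio arithmetic follows the definition", {
  m <- matrix(0, 10, 2, dimnames = list(paste0("c", 1:10), c("g1", "g2")))
  m[1, 1] <- 10          # one cell at level 10, population level 1
  m[, 2] <- 5            # always on at the population level
  ds <- structure(list(copies = m, curves = NULL,
                       genes_detected = rowSums(m > 0)), class = "sc_dataset")
  pop <- c(g1 = 1, g2 = 5)
  rt <- expression_ratio_when_detected(ds, pop)
  expect_equal(unname(rt$ratio["g1"]), 10)
  expect_equal(unname(rt$ratio["g2"]), 1)
})

test_that("co-expression structure score separates noise from planted modules", {
  set.seed(605)
  m <- matrix(stats::runif(120 * 90) < 0.1, 120, 90,
              dimnames = list(sprintf("c%03d", 1:120), sprintf("g%03d", 1:90)))
  cx <- coexpression_clustering(m, min_cells = 3, n_perm = 100, seed = 606)
  expect_lt(abs(cx$z), 3)

  m2 <- matrix(stats::runif(120 * 90) < 0.02, 120, 90, dimnames = dimnames(m))
  m2[1:60, 1:45] <- stats::runif(60 * 45) < 0.25
  m2[61:120, 46:90] <- stats::runif(60 * 45) < 0.25
  cx2 <- coexpression_clustering(m2, min_cells = 3, n_perm = 100, seed = 607)
  expect_gt(cx2$z, 3)

  # min_cells filter: a gene seen in two cells is dropped
  m3 <- m2
  m3[, 1] <- FALSE; m3[1:2, 1] <- TRUE
  cx3 <- coexpression_clustering(m3, min_cells = 3, n_perm = 100, seed = 608)
  expect_false("g001" %in% cx3$gene_order)

  # optimal leaf ordering does not exceed the default order's path cost
  d <- stats::dist(t(m2 * 1), method = "binary")
  hc <- stats::hclust(d, method = "average")
  dm <- as.matrix(d)
  path_cost <- function(o) sum(dm[cbind(o[-length(o)], o[-1])])
  o_olo <- match(cx2$gene_order, colnames(m2))
  expect_lte(path_cost(o_olo), path_cost(hc$order))
})

test_that("per-cell gene count tracks the driver gene's level", {
  cls <- data.frame(gene_id = sprintf("g%04d", 1:500),
                    class = rep(c("dependent", "enhanced", "other"),
                                c(200, 200, 100)))
  truth <- assign_sc_truth(cls)
  truth$driver_responsive <- truth$class %in% c("dependent", "enhanced")
  set.seed(609)
  pop <- stats::setNames(stats::rlnorm(500, log(5), 1), cls$gene_id)
  sc <- generate_single_cells(pop, truth, n_cells = 174,
                              driver_gene = "g0500", seed = 610)
  cur <- fit_spikein_curve(sc$spike_observed, sc$spike_table$molecules)
  ds <- to_copy_numbers(sc$signal, cur)
  gv <- genes_vs_driver_correlation(ds, "g0500")
  expect_gt(gv$r, 0)
  expect_lt(gv$pvalue, 0.05)

  # constant driver: undefined, reported as NA
  ds0 <- ds; ds0$copies[, "g0001"] <- 3
  gv0 <- genes_vs_driver_correlation(ds0, "g0001")
  expect_true(is.na(gv0$r))
  expect_error(genes_vs_driver_correlation(ds, "nope"), "driver gene")
})
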