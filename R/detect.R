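#' Build a matched decoy set of gene models in intergenic space
#'
#' For every gene, its model (span, exon structure, strand, exonic length)
#' is shifted to a uniformly chosen position inside the intergenic gaps that
#' can host it, at least `min_distance` from any real gene and without
#' overlapping other decoys. Quantifying these decoys in a real library
#' yields the empirical null distribution of FPKM used for local-FDR
#' estimation.
#'
#' @param annotation A `gene_annotation`.
#' @param seed Integer seed.
#' @param min_distance Minimum distance (bp) from any annotated gene.
#' @param max_tries Attempt cap per gene before raising a placement error.
#' @return data.frame(null_gene_id, source_gene_id, chrom, start, end,
#'   strand, exonic_length).
#' @export
build_null_models <- function(annotation, seed = 1L, min_distance = 5000L,
                              max_tries = 1000L) {
  set.seed(seed)
  g <- annotation$genes
  chrom <- names(annotation$chrom_lengths)[1]
  L <- annotation$chrom_lengths[[1]]
  gs <- g[g$chrom == chrom, ]
  # free intervals = genome minus gene spans padded by min_distance
  occ_s <- pmax(0, gs$start - min_distance)
  o <- order(occ_s)
  occ_s <- occ_s[o]
  occ_e <- pmin(L, gs$end + min_distance)[o]
  free_s <- numeric(0); free_e <- numeric(0); cur <- 0
  for (i in seq_along(occ_s)) {
    if (occ_s[i] > cur) { free_s <- c(free_s, cur); free_e <- c(free_e, occ_s[i]) }
    cur <- max(cur, occ_e[i])
  }
  if (cur < L) { free_s <- c(free_s, cur); free_e <- c(free_e, L) }

  n <- nrow(g)
  out_start <- numeric(n)
  for (i in seq_len(n)) {
    span <- g$end[i] - g$start[i]
    feas <- pmax(0, (free_e - free_s) - span)
    if (sum(feas) <= 0)
      stop("no feasible intergenic placement for gene ", g$gene_id[i])
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      j <- sample.int(length(feas), 1L, prob = feas)
      pos <- free_s[j] + floor(stats::runif(1) * feas[j])
      placed <- TRUE
      break
    }
    if (!placed) stop("placement retries exhausted for gene ", g$gene_id[i])
    out_start[i] <- pos
    # split the chosen gap around the placement
    s0 <- free_s[j]; e0 <- free_e[j]
    free_s <- free_s[-j]; free_e <- free_e[-j]
    if (pos - s0 > 0) { free_s <- c(free_s, s0); free_e <- c(free_e, pos) }
    if (e0 - (pos + span) > 0) { free_s <- c(free_s, pos + span); free_e <- c(free_e, e0) }
  }
  data.frame(null_gene_id = paste0("NULL_", g$gene_id),
             source_gene_id = g$gene_id,
             chrom = chrom,
             start = out_start,
             end = out_start + (g$end - g$start),
             strand = g$strand,
             exonic_length = g$exonic_length,
             stringsAsFactors = FALSE)
}

#' Estimate the null mixing proportion from real and decoy FPKM
#'
#' Moment-matching estimator: the ratio of real to decoy empirical CDF mass
#' at the decoy median, pi0 = F_real(m0) / F_null(m0). In a two-component
#' mixture whose expressed component has negligible mass below the decoy
#' median, this recovers the fraction of real genes drawn from the null.
#'
#' @param real_fpkm,null_fpkm Non-empty numeric vectors.
#' @return Estimated pi0, clipped to [0, 1].
#' @export
estimate_pi0 <- function(real_fpkm, null_fpkm) {
  if (!length(real_fpkm) || !length(null_fpkm)) stop("empty input vector")
  if (all(null_fpkm == 0)) stop("degenerate null: all decoy FPKM are zero")
  m0 <- stats::median(null_fpkm)
  f_null <- mean(null_fpkm <= m0)
  f_real <- mean(real_fpkm <= m0)
  min(1, max(0, f_real / f_null))
}

#' Per-gene local false discovery rates against the decoy null
#'
#' lfdr(x) = min(1, pi0 f0(x) / f(x)), with f0 and f Gaussian kernel
#' densities of log10(FPKM + eps) for decoy and real genes (zeros handled as
#' point masses estimated separately), regularised to be non-increasing in
#' FPKM by an isotonic fit.
#'
#' @param real_fpkm,null_fpkm FPKM vectors.
#' @param pi0 Null mixing proportion in [0, 1]; estimated with
#'   [estimate_pi0()] when NULL.
#' @param eps Pseudovalue added before the log transform.
#' @param bw Kernel bandwidth; Silverman's rule when NULL.
#' @param n_grid Density grid size.
#' @return Numeric vector of lfdr values in [0, 1] aligned with `real_fpkm`.
#' @export
local_fdr <- function(real_fpkm, null_fpkm, pi0 = NULL, eps = 1e-3,
                      bw = NULL, n_grid = 512L) {
  if (!is.null(bw) && bw <= 0) stop("bandwidth must be > 0")
  if (is.null(pi0)) pi0 <- estimate_pi0(real_fpkm, null_fpkm)
  if (pi0 < 0 || pi0 > 1) stop("pi0 must be in [0, 1]")
  if (all(null_fpkm == 0)) stop("degenerate null: all decoy FPKM are zero")
  p0_real <- mean(real_fpkm == 0)
  p0_null <- mean(null_fpkm == 0)
  lx <- log10(real_fpkm[real_fpkm > 0] + eps)
  ln <- log10(null_fpkm[null_fpkm > 0] + eps)
  lim <- range(c(lx, ln))
  # a common bandwidth for both densities: with component-specific
  # bandwidths the narrow null density can exceed the real-mixture density
  # in the overlap region, which breaks the ratio
  b <- if (is.null(bw)) stats::bw.nrd0(c(lx, ln)) else bw
  dens <- function(v) stats::density(v, bw = b, from = lim[1], to = lim[2],
                                     n = n_grid)
  d0 <- dens(ln); d1 <- dens(lx)
  at <- function(d, x) stats::approx(d$x, d$y, xout = x, yleft = 0, yright = 0)$y
  lfdr <- numeric(length(real_fpkm))
  nz <- real_fpkm > 0
  xs <- log10(real_fpkm[nz] + eps)
  f0 <- (1 - p0_null) * at(d0, xs)
  f1 <- pmax((1 - p0_real) * at(d1, xs), 1e-12)
  lfdr[nz] <- pmin(1, pi0 * f0 / f1)
  if (any(!nz))
    lfdr[!nz] <- min(1, pi0 * p0_null / max(p0_real, 1e-12))
  # enforce non-increasing lfdr in FPKM
  o <- order(real_fpkm)
  iso <- stats::isoreg(seq_along(o), -lfdr[o])
  out <- numeric(length(lfdr))
  out[o] <- pmin(1, pmax(0, -iso$yf))
  out
}

#' Call detected genes at an lfdr threshold
#'
#' A gene is detected when its lfdr is strictly below the threshold. Also
#' reports the smallest FPKM among detected genes, the sample's effective
#' detection threshold on the expression scale.
#'
#' @param table data.frame with columns `gene_id`, `fpkm`, `lfdr`.
#' @param lfdr_threshold Detection threshold in (0, 1).
#' @return List with `table` (input plus logical `detected`),
#'   `fpkm_at_threshold`, and `n_detected`.
#' @export
call_detected <- function(table, lfdr_threshold = 0.05) {
  if (lfdr_threshold <= 0 || lfdr_threshold >= 1)
    stop("lfdr_threshold must be inside (0, 1)")
  stopifnot(all(c("gene_id", "fpkm", "lfdr") %in% names(table)))
  table$detected <- table$lfdr < lfdr_threshold
  fpkm_thr <- if (any(table$detected)) min(table$fpkm[table$detected]) else NA_real_
  list(table = table, fpkm_at_threshold = fpkm_thr,
       n_detected = sum(table$detected))
}

#' Full detection analysis for one sample (pooled replicates)
#'
#' Convenience wrapper: estimates pi0, computes lfdr against the decoy
#' null, and calls detected genes.
#'
#' @param gene_id Gene identifiers.
#' @param real_fpkm,null_fpkm FPKM of real genes and decoy models.
#' @param lfdr_threshold Detection threshold.
#' @param ... Passed to [local_fdr()].
#' @return As [call_detected()], plus `pi0`.
#' @export
detect_population <- function(gene_id, real_fpkm, null_fpkm,
                              lfdr_threshold = 0.05, ...) {
  pi0 <- estimate_pi0(real_fpkm, null_fpkm)
  lfdr <- local_fdr(real_fpkm, null_fpkm, pi0 = pi0, ...)
  res <- call_detected(data.frame(gene_id = gene_id, fpkm = real_fpkm,
                                  lfdr = lfdr, stringsAsFactors = FALSE),
                       lfdr_threshold)
  res$pi0 <- pi0
  res
}

#' Genes detected per sample across a grid of FPKM thresholds
#'
#' @param expr Gene x sample FPKM matrix.
#' @param thresholds Strictly increasing FPKM grid.
#' @return Matrix (threshold x sample) of gene counts with FPKM at or above
#'   each threshold (zeros never count).
#' @export
detection_curve <- function(expr, thresholds) {
  if (!length(thresholds)) stop("empty threshold grid")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  expr <- as.matrix(expr)
  out <- vapply(seq_len(ncol(expr)), function(j)
    vapply(thresholds, function(t) sum(expr[, j] >= t & expr[, j] > 0), numeric(1)),
    numeric(length(thresholds)))
  out <- matrix(out, nrow = length(thresholds),
                dimnames = list(format(thresholds, trim = TRUE), colnames(expr)))
  out
}
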