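#' Fit per-cell spike-in normalisation curves
#'
#' Least-squares line on (log10 known molecules, log10 observed signal) over
#' the spike-ins detected in each cell (observed signal > 0); dropouts are
#' excluded from the fit.
#'
#' @param spike_observed Cell x spike matrix of observed signal.
#' @param known_molecules Molecule count per spike-in (matching columns).
#' @param min_points Minimum usable spike-ins per cell.
#' @return data.frame(cell, slope, intercept, r2, n_used).
#' @export
fit_spikein_curve <- function(spike_observed, known_molecules, min_points = 8L) {
  spike_observed <- as.matrix(spike_observed)
  if (ncol(spike_observed) != length(known_molecules))
    stop("spike table does not match the observed matrix")
  if (is.null(rownames(spike_observed)))
    rownames(spike_observed) <- paste0("cell", seq_len(nrow(spike_observed)))
  lm_known <- log10(known_molecules)
  out <- lapply(seq_len(nrow(spike_observed)), function(i) {
    y <- spike_observed[i, ]
    use <- y > 0
    if (sum(use) < min_points)
      stop("cell ", rownames(spike_observed)[i], ": only ", sum(use),
           " spike-ins with signal; cannot calibrate")
    fit <- stats::lm(log10(y[use]) ~ lm_known[use])
    co <- stats::coef(fit)
    data.frame(cell = rownames(spike_observed)[i],
               slope = unname(co[2]), intercept = unname(co[1]),
               r2 = stats::cor(lm_known[use], log10(y[use]))^2,
               n_used = sum(use))
  })
  do.call(rbind, out)
}

#' Convert observed signal to absolute copy numbers
#'
#' Inverts each cell's spike-in curve: copies = 10^((log10 signal -
#' intercept) / slope); zero signal maps to zero copies.
#'
#' @param signal Cell x gene matrix of observed signal.
#' @param curves Output of [fit_spikein_curve()] (one row per cell, in row
#'   order of `signal`).
#' @return Object of class `sc_dataset`: list with `copies` (cell x gene),
#'   `curves`, `genes_detected` (per-cell count of genes with copies > 0).
#' @export
to_copy_numbers <- function(signal, curves) {
  signal <- as.matrix(signal)
  if (nrow(signal) != nrow(curves)) stop("curve missing for some cells")
  if (any(curves$slope <= 0)) stop("non-positive calibration slope for cell(s): ",
                                   paste(curves$cell[curves$slope <= 0], collapse = ", "))
  copies <- signal
  for (i in seq_len(nrow(signal))) {
    nz <- signal[i, ] > 0
    copies[i, nz] <- 10 ^ ((log10(signal[i, nz]) - curves$intercept[i]) / curves$slope[i])
  }
  structure(list(copies = copies, curves = curves,
                 genes_detected = rowSums(copies > 0)),
            class = "sc_dataset")
}

#' Filter cells by the number of genes they express
#'
#' Retains cells expressing strictly more than `min_genes` genes (counted on
#' `coding_genes` when given, mirroring the protein-coding gate of the
#' study's ">3000 protein-coding genes" criterion).
#'
#' @param dataset An `sc_dataset`.
#' @param min_genes Strict lower bound on genes detected.
#' @param coding_genes Optional gene ids to count; all genes when NULL.
#' @return The filtered `sc_dataset` (warns when no cell survives).
#' @export
qc_filter <- function(dataset, min_genes = 3000L, coding_genes = NULL) {
  m <- dataset$copies
  cols <- if (is.null(coding_genes)) seq_len(ncol(m)) else
    which(colnames(m) %in% coding_genes)
  ng <- rowSums(m[, cols, drop = FALSE] > 0)
  keep <- ng > min_genes
  if (!any(keep)) warning("no cell passes the QC gate")
  structure(list(copies = m[keep, , drop = FALSE],
                 curves = dataset$curves[keep, , drop = FALSE],
                 genes_detected = ng[keep]),
            class = "sc_dataset")
}

#' Per-gene expression frequency across cells
#'
#' The fraction of cells in which each gene is detected (copies > 0), and
#' the median fraction per gene class.
#'
#' @param dataset An `sc_dataset` (QC-filtered).
#' @param gene_classes Optional named list class -> gene ids.
#' @param min_copies Detection gate on copy number (strictly above).
#' @return List: `frequency` (named per-gene vector), `class_median`
#'   (named vector; empty classes skipped with a warning).
#' @export
detection_frequency <- function(dataset, gene_classes = NULL, min_copies = 0) {
  freq <- colMeans(dataset$copies > min_copies)
  cm <- NULL
  if (!is.null(gene_classes)) {
    cm <- vapply(names(gene_classes), function(cl) {
      gs <- intersect(gene_classes[[cl]], names(freq))
      if (!length(gs)) { warning("empty class: ", cl); return(NA_real_) }
      stats::median(freq[gs])
    }, numeric(1))
  }
  list(frequency = freq, class_median = cm)
}

#' Normalise single-cell copy numbers against the population level
#'
#' Fits a first-order linear model log(single-cell mean) ~ log(population
#' level) over co-detected genes, then rescales all single-cell values by a
#' global factor chosen so that the mean per-gene ratio (single-cell mean /
#' population level) equals one.
#'
#' @param dataset An `sc_dataset`.
#' @param population Named per-gene population expression vector.
#' @param min_genes Minimum co-detected genes for the fit.
#' @return List: `dataset` (rescaled copy of the input), `scale`, `slope`,
#'   `intercept`, `n_genes`, `mean_ratio` (post-normalisation, = 1).
#' @export
normalize_to_population <- function(dataset, population, min_genes = 100L) {
  sm <- colMeans(dataset$copies)
  pop <- population[colnames(dataset$copies)]
  co <- !is.na(pop) & pop > 0 & sm > 0
  if (sum(co) < min_genes)
    stop("only ", sum(co), " co-detected genes; need >= ", min_genes)
  fit <- stats::lm(log(sm[co]) ~ log(pop[co]))
  scale <- 1 / mean(sm[co] / pop[co])
  out <- dataset
  out$copies <- dataset$copies * scale
  list(dataset = out, scale = scale,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_genes = sum(co),
       mean_ratio = mean(colMeans(out$copies)[co] / pop[co]))
}

#' Expression ratio to the population level among expressing cells
#'
#' Per gene, the median over expressing cells of (cell copy number /
#' population level); per class, the median of those per-gene ratios. Genes
#' never detected are excluded from their class median.
#'
#' @param dataset An `sc_dataset`, normalised with
#'   [normalize_to_population()].
#' @param population Named per-gene population expression vector.
#' @param gene_classes Optional named list class -> gene ids.
#' @return List: `ratio` (named per-gene vector, NA when never detected),
#'   `class_median`.
#' @export
expression_ratio_when_detected <- function(dataset, population,
                                           gene_classes = NULL) {
  m <- dataset$copies
  pop <- population[colnames(m)]
  ratio <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v <- v[v > 0]
    if (!length(v) || is.na(pop[j]) || pop[j] <= 0) return(NA_real_)
    stats::median(v / pop[j])
  }, numeric(1))
  names(ratio) <- colnames(m)
  cm <- NULL
  if (!is.null(gene_classes)) {
    cm <- vapply(names(gene_classes), function(cl) {
      v <- ratio[intersect(gene_classes[[cl]], names(ratio))]
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      stats::median(v)
    }, numeric(1))
  }
  list(ratio = ratio, class_median = cm)
}

# optimal leaf ordering (Bar-Joseph): order hclust leaves to minimise the
# sum of distances between adjacent leaves
.optimal_leaf_order <- function(hc, d) {
  d <- as.matrix(d)
  n <- nrow(d)
  leaves <- vector("list", nrow(hc$merge))
  Ms <- vector("list", nrow(hc$merge))
  leaf_M <- function(x) {
    m <- matrix(0, 1, 1, dimnames = list(x, x)); m
  }
  get <- function(v) {
    if (v < 0) list(leaves = -v, M = leaf_M(-v))
    else list(leaves = leaves[[v]], M = Ms[[v]])
  }
  for (i in seq_len(nrow(hc$merge))) {
    c1 <- get(hc$merge[i, 1]); c2 <- get(hc$merge[i, 2])
    A <- c1$leaves; B <- c2$leaves
    MA <- c1$M; MB <- c2$M
    dAB <- d[A, B, drop = FALSE]
    # T[k, j] = min_l d[k, l] + MB[l, j]
    Tm <- matrix(Inf, length(A), length(B))
    for (k in seq_along(A))
      Tm[k, ] <- apply(MB + dAB[k, ], 2, min)
    M1 <- matrix(Inf, length(A), length(B))
    for (ii in seq_along(A))
      M1[ii, ] <- apply(Tm + MA[ii, ], 2, min)
    L <- c(A, B)
    M <- matrix(Inf, length(L), length(L), dimnames = list(L, L))
    M[seq_along(A), length(A) + seq_along(B)] <- M1
    M[length(A) + seq_along(B), seq_along(A)] <- t(M1)
    leaves[[i]] <- L
    Ms[[i]] <- M
  }
  # reconstruct the optimal order top-down
  rebuild <- function(v, i_leaf, j_leaf) {
    if (v < 0) return(-v)
    A <- get(hc$merge[v, 1])$leaves
    B <- get(hc$merge[v, 2])$leaves
    if (i_leaf %in% B) { tmp <- A; A <- B; B <- tmp }
    MA <- if (i_leaf %in% get(hc$merge[v, 1])$leaves) get(hc$merge[v, 1])$M else get(hc$merge[v, 2])$M
    MB <- if (i_leaf %in% get(hc$merge[v, 1])$leaves) get(hc$merge[v, 2])$M else get(hc$merge[v, 1])$M
    ia <- match(i_leaf, A); jb <- match(j_leaf, B)
    cost <- outer(MA[ia, ], MB[, jb], "+") + d[A, B, drop = FALSE]
    kl <- arrayInd(which.min(cost), dim(cost))
    left <- rebuild(if (i_leaf %in% get(hc$merge[v, 1])$leaves) hc$merge[v, 1] else hc$merge[v, 2],
                    i_leaf, A[kl[1]])
    right <- rebuild(if (i_leaf %in% get(hc$merge[v, 1])$leaves) hc$merge[v, 2] else hc$merge[v, 1],
                     B[kl[2]], j_leaf)
    c(left, right)
  }
  root <- nrow(hc$merge)
  Mr <- Ms[[root]]
  best <- arrayInd(which.min(Mr), dim(Mr))
  Lr <- leaves[[root]]
  rebuild(root, Lr[best[1]], Lr[best[2]])
}

#' Co-expression clustering of single cells with a structure score
#'
#' Binary detection matrices (cells and genes) are clustered on Jaccard
#' distance with average linkage and optimal leaf ordering. The structure
#' score asks whether genes fall into co-detection modules: after cutting
#' the gene tree in two, it is the mean within-module minus between-module
#' Jaccard similarity, expressed as a z-score against a null in which every
#' gene's detection vector is independently permuted across cells.
#'
#' @param dataset An `sc_dataset` (or a logical cell x gene matrix).
#' @param genes Gene ids to cluster (e.g. the Aire-up set).
#' @param min_cells Genes detected in fewer cells are dropped.
#' @param n_perm Permutations for the null (>= 100 recommended).
#' @param seed Integer seed.
#' @return List: `gene_order`, `cell_order` (optimally ordered labels),
#'   `detection` (filtered binary matrix), `score`, `z`, `perm_mean`,
#'   `perm_sd`.
#' @export
coexpression_clustering <- function(dataset, genes = NULL, min_cells = 3L,
                                    n_perm = 100L, seed = 1L) {
  m <- if (inherits(dataset, "sc_dataset")) dataset$copies > 0 else dataset > 0
  if (!is.null(genes)) m <- m[, colnames(m) %in% genes, drop = FALSE]
  m <- m[, colSums(m) >= min_cells, drop = FALSE]
  if (ncol(m) < 2) stop("fewer than 2 genes retained")
  m <- m[rowSums(m) > 0, , drop = FALSE]  # Jaccard undefined for empty cells
  set.seed(seed)
  score_of <- function(mm) {
    dg <- stats::dist(t(mm), method = "binary")
    hcg <- stats::hclust(dg, method = "average")
    cl <- stats::cutree(hcg, k = 2)
    s <- 1 - as.matrix(dg)
    same <- outer(cl, cl, "==")
    diag(same) <- NA
    mean(s[same & !is.na(same)]) - mean(s[!same & !is.na(same)])
  }
  obs <- score_of(m)
  perm <- vapply(seq_len(n_perm), function(b) {
    mp <- apply(m, 2, sample)
    score_of(mp)
  }, numeric(1))
  z <- (obs - mean(perm)) / stats::sd(perm)

  dg <- stats::dist(t(m * 1), method = "binary")
  hg <- stats::hclust(dg, method = "average")
  og <- .optimal_leaf_order(hg, dg)
  dc <- stats::dist(m * 1, method = "binary")
  hcl <- stats::hclust(dc, method = "average")
  oc <- .optimal_leaf_order(hcl, dc)
  list(gene_order = colnames(m)[og], cell_order = rownames(m)[oc],
       detection = m, score = obs, z = z,
       perm_mean = mean(perm), perm_sd = stats::sd(perm))
}

#' Correlation between per-cell gene count and a driver gene's level
#'
#' Spearman correlation between the number of genes detected per cell and
#' the per-cell expression of a driver gene (e.g. Aire), with tie-corrected
#' p-value.
#'
#' @param dataset An `sc_dataset`.
#' @param driver_gene Gene id present in the matrix.
#' @return List: r, pvalue (both NA when the driver is constant).
#' @export
genes_vs_driver_correlation <- function(dataset, driver_gene) {
  m <- dataset$copies
  if (!driver_gene %in% colnames(m)) stop("driver gene not in matrix: ", driver_gene)
  drv <- m[, driver_gene]
  ng <- dataset$genes_detected
  if (is.null(ng)) ng <- rowSums(m > 0)
  if (stats::sd(drv) == 0) return(list(r = NA_real_, pvalue = NA_real_))
  ct <- suppressWarnings(stats::cor.test(ng, drv, method = "spearman"))
  list(r = unname(ct$estimate), pvalue = ct$p.value)
}
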