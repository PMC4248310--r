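#' Upper-quartile normalised FPKM from gene-level counts
#'
#' Raw FPKM is counts / (exonic kb x library millions), with library size
#' taken as each sample's total assigned counts. Each sample is then
#' rescaled so that its upper quartile of FPKM over genes with non-zero
#' counts equals the across-sample mean of those upper quartiles; for a
#' single sample the rescaling is the identity.
#'
#' @param counts Gene x sample matrix of (possibly fractional) counts.
#' @param annotation A `gene_annotation` covering every row of `counts`.
#' @param library_size Optional per-sample library sizes overriding the
#'   column totals (used to quantify decoy models against the real
#'   libraries they were sequenced with).
#' @return Gene x sample FPKM matrix.
#' @export
compute_fpkm <- function(counts, annotation, library_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  len <- annotation$genes$exonic_length[match(rownames(counts),
                                              annotation$genes$gene_id)]
  if (anyNA(len))
    stop("gene(s) missing from annotation: ",
         paste(utils::head(rownames(counts)[is.na(len)]), collapse = ", "))
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size <= 0)) stop("zero library size")
  raw <- sweep(counts / (len / 1e3), 2, library_size / 1e6, "/")
  if (ncol(raw) > 1) {
    uq <- vapply(seq_len(ncol(raw)), function(j) {
      nz <- counts[, j] > 0
      if (!any(nz)) return(NA_real_)
      stats::quantile(raw[nz, j], 0.75, names = FALSE)
    }, numeric(1))
    target <- mean(uq, na.rm = TRUE)
    fac <- ifelse(is.na(uq) | uq == 0, 1, target / uq)
    raw <- sweep(raw, 2, fac, "*")
  }
  raw
}

# all sample subsets ("clades") of an hclust tree, as sorted label vectors
.hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- hc$merge[i, ]
    take <- function(v) if (v < 0) hc$labels[-v] else members[[v]]
    members[[i]] <- sort(c(take(m[1]), take(m[2])))
  }
  members
}

.cor_dist <- function(m, pseudo = 0.1) {
  lm_ <- log2(m + pseudo)
  v <- apply(lm_, 2, stats::sd)
  if (any(v == 0)) stop("constant sample profile: correlation undefined for ",
                        paste(colnames(m)[v == 0], collapse = ", "))
  stats::as.dist(1 - stats::cor(lm_))
}

#' Cluster expression profiles with bootstrap support
#'
#' Average-linkage hierarchical clustering of samples on correlation
#' distance (1 - Pearson r of log2(FPKM + 0.1)). Cluster support is the
#' fraction of gene-resampling bootstrap trees that contain each cluster;
#' clusters with support above `signif` are flagged significant.
#'
#' @param expr Gene x sample FPKM matrix (>= 3 samples).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param signif Support level above which a cluster is called significant.
#' @return List with `tree` (hclust), `support` (data.frame: cluster members,
#'   size, support, significant).
#' @export
cluster_populations <- function(expr, n_boot = 200L, seed = 1L, signif = 0.95) {
  if (ncol(expr) < 3) stop("need at least 3 samples")
  if (n_boot < 100) stop("n_boot must be >= 100")
  set.seed(seed)
  hc <- stats::hclust(.cor_dist(expr), method = "average")
  clades <- .hclust_clades(hc)
  keys <- vapply(clades, paste, "", collapse = "|")
  hits <- stats::setNames(numeric(length(keys)), keys)
  n_g <- nrow(expr)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_g, n_g, replace = TRUE)
    bh <- tryCatch(stats::hclust(.cor_dist(expr[idx, , drop = FALSE]),
                                 method = "average"),
                   error = function(e) NULL)
    if (is.null(bh)) next
    bk <- vapply(.hclust_clades(bh), paste, "", collapse = "|")
    hits[keys %in% bk] <- hits[keys %in% bk] + 1
  }
  support <- hits / n_boot
  list(tree = hc,
       support = data.frame(
         members = keys,
         size = lengths(clades),
         support = unname(support),
         significant = unname(support > signif),
         stringsAsFactors = FALSE))
}

#' Write an hclust tree as Newick, optionally annotated with support values
#' @param hc An `hclust` object.
#' @param path Output file.
#' @param support Optional numeric vector, one per internal node (merge row).
#' @export
write_newick <- function(hc, path, support = NULL) {
  lab <- hc$labels
  node_str <- function(i) {
    m <- hc$merge[i, ]
    part <- function(v) if (v < 0) lab[-v] else node_str(v)
    s <- if (is.null(support)) "" else sprintf("%.3f", support[i])
    sprintf("(%s,%s)%s:%.5f", part(m[1]), part(m[2]), s, hc$height[i])
  }
  writeLines(paste0(node_str(nrow(hc$merge)), ";"), path)
  invisible(path)
}
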