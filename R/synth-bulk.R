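#' Simulate bulk RNA-seq count tables with known expression truth
#'
#' Each population's transcriptome is a two-component mixture: a fraction
#' `pi0` of genes carry only background (intergenic-like) signal drawn from
#' `null_law`, the rest are expressed with FPKM drawn from `expressed_law`.
#' Counts are drawn per replicate around depth-scaled true abundances,
#' Poisson by default or negative binomial with the given dispersion.
#'
#' @param annotation A `gene_annotation`.
#' @param populations Character vector of population names.
#' @param pi0 Fraction of genes that are unexpressed (null component).
#' @param expressed_law,null_law Lists with `meanlog`, `sdlog` of the
#'   log-normal FPKM law for expressed and background genes. The expressed
#'   law must sit above the null law.
#' @param depth Sequenced reads per replicate library.
#' @param n_reps Replicates per population (the study design uses 2).
#' @param noise "poisson" or "nb".
#' @param dispersion NB dispersion when `noise = "nb"`.
#' @param seed Integer seed.
#' @return List with `counts` (gene x sample matrix), `sample_meta`
#'   (sample, population, replicate), and `truth` (long data.frame:
#'   gene_id, population, expressed, true_fpkm).
#' @export
generate_bulk_counts <- function(annotation, populations = "popA", pi0 = 0.5,
                                 expressed_law = list(meanlog = log(10), sdlog = 2),
                                 null_law = list(meanlog = log(0.02), sdlog = 0.75),
                                 depth = 2e7, n_reps = 2L,
                                 noise = c("poisson", "nb"), dispersion = 0.05,
                                 seed = 1L) {
  noise <- match.arg(noise)
  if (pi0 < 0 || pi0 > 1) stop("pi0 must be in [0, 1]")
  if (expressed_law$meanlog <= null_law$meanlog)
    stop("expressed_law must stochastically dominate null_law")
  set.seed(seed)
  g <- annotation$genes
  n <- nrow(g)
  truth <- list(); cols <- list(); meta <- list()
  for (p in populations) {
    expressed <- stats::runif(n) >= pi0
    fpkm <- ifelse(expressed,
                   stats::rlnorm(n, expressed_law$meanlog, expressed_law$sdlog),
                   stats::rlnorm(n, null_law$meanlog, null_law$sdlog))
    truth[[p]] <- data.frame(gene_id = g$gene_id, population = p,
                             expressed = expressed, true_fpkm = fpkm)
    mu <- fpkm * (g$exonic_length / 1e3) * (depth / 1e6)
    for (r in seq_len(n_reps)) {
      cnt <- if (noise == "poisson") stats::rpois(n, mu)
             else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
      cols[[paste0(p, "_rep", r)]] <- cnt
      meta[[paste0(p, "_rep", r)]] <-
        data.frame(sample = paste0(p, "_rep", r), population = p, replicate = r)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- g$gene_id
  list(counts = counts,
       sample_meta = do.call(rbind, unname(meta)),
       truth = do.call(rbind, unname(truth)))
}

#' Simulate background counts on decoy (null) gene models
#'
#' Decoy models placed in intergenic space receive only background signal:
#' abundances from `null_law`, counts with the same noise model and depth as
#' the real libraries.
#'
#' @param null_models data.frame as returned by [build_null_models()]
#'   (columns `null_gene_id`, `exonic_length`).
#' @param n_samples Number of replicate libraries to simulate.
#' @inheritParams generate_bulk_counts
#' @return Count matrix (null model x sample).
#' @export
generate_null_counts <- function(null_models, n_samples = 2L,
                                 null_law = list(meanlog = log(0.02), sdlog = 0.75),
                                 depth = 2e7, noise = c("poisson", "nb"),
                                 dispersion = 0.05, seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  n <- nrow(null_models)
  out <- matrix(0, n, n_samples,
                dimnames = list(null_models$null_gene_id,
                                paste0("null_rep", seq_len(n_samples))))
  # one background abundance per decoy model, shared across replicate
  # libraries: replicates of a population re-measure the same abundances
  fpkm <- stats::rlnorm(n, null_law$meanlog, null_law$sdlog)
  mu <- fpkm * (null_models$exonic_length / 1e3) * (depth / 1e6)
  for (r in seq_len(n_samples)) {
    out[, r] <- if (noise == "poisson") stats::rpois(n, mu)
                else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  out
}

#' Simulate an Aire-positive vs Aire-knockout experiment
#'
#' Plants four regulation classes. "dependent" genes are expressed only in the
#' Aire-positive population (background in the KO); "enhanced" genes are
#' expressed in both but `fold` times higher with Aire; "repressed" genes are
#' `fold` times lower with Aire; the rest are unchanged (a fraction
#' `pi0_background` of them unexpressed in both).
#'
#' @param annotation A `gene_annotation`.
#' @param n_dependent,n_enhanced,n_repressed Planted class sizes.
#' @param fold True fold change for enhanced/repressed genes (> 1).
#' @param pi0_background Fraction of unchanged genes that are unexpressed.
#' @param expressed_law,null_law,depth,n_reps,noise,dispersion,seed As in
#'   [generate_bulk_counts()].
#' @param dependent_law Log-normal law for the Aire-positive level of
#'   dependent genes; the default centres near 1 FPKM, the typical level to
#'   which Aire elevates its targets in the population.
#' @param classes Optional per-gene class vector (values in dependent,
#'   enhanced, repressed, unchanged; aligned with the annotation) overriding
#'   the random class assignment, e.g. to couple Aire dependence to tissue
#'   restriction.
#' @return List with `counts_pos`, `counts_ko` (gene x replicate matrices),
#'   `truth` (gene_id, regulation_class, true_fpkm_pos, true_fpkm_ko).
#' @export
generate_aire_experiment <- function(annotation, n_dependent = 500L,
                                     n_enhanced = 1500L, n_repressed = 100L,
                                     fold = 4, pi0_background = 0.3,
                                     expressed_law = list(meanlog = log(10), sdlog = 2),
                                     dependent_law = list(meanlog = log(2), sdlog = 1),
                                     null_law = list(meanlog = log(0.02), sdlog = 0.75),
                                     depth = 2e7, n_reps = 2L,
                                     noise = c("poisson", "nb"), dispersion = 0.05,
                                     seed = 1L, classes = NULL) {
  noise <- match.arg(noise)
  if (fold <= 1) stop("fold must be > 1")
  set.seed(seed)
  g <- annotation$genes
  n <- nrow(g)
  if (is.null(classes)) {
    if (n_dependent + n_enhanced + n_repressed > n)
      stop("planted classes exceed the number of genes")
    cls <- rep("unchanged", n)
    idx <- sample.int(n, n_dependent + n_enhanced + n_repressed)
    cls[idx[seq_len(n_dependent)]] <- "dependent"
    cls[idx[n_dependent + seq_len(n_enhanced)]] <- "enhanced"
    cls[idx[n_dependent + n_enhanced + seq_len(n_repressed)]] <- "repressed"
  } else {
    if (length(classes) != n) stop("classes must align with the annotation")
    bad <- setdiff(unique(classes),
                   c("dependent", "enhanced", "repressed", "unchanged"))
    if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
    cls <- classes
  }

  base <- stats::rlnorm(n, expressed_law$meanlog, expressed_law$sdlog)
  bg <- function(k) stats::rlnorm(k, null_law$meanlog, null_law$sdlog)
  fpkm_ko <- base
  fpkm_pos <- base
  i <- cls == "dependent"
  fpkm_ko[i] <- bg(sum(i))
  fpkm_pos[i] <- stats::rlnorm(sum(i), dependent_law$meanlog, dependent_law$sdlog)
  i <- cls == "enhanced"
  fpkm_pos[i] <- base[i] * fold
  i <- cls == "repressed"
  fpkm_pos[i] <- base[i] / fold
  i <- cls == "unchanged" & stats::runif(n) < pi0_background
  fpkm_ko[i] <- bg(sum(i))
  fpkm_pos[i] <- fpkm_ko[i]

  draw <- function(fpkm, label) {
    mu <- fpkm * (g$exonic_length / 1e3) * (depth / 1e6)
    m <- vapply(seq_len(n_reps), function(r)
      if (noise == "poisson") stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / dispersion),
      numeric(n))
    dimnames(m) <- list(g$gene_id, paste0(label, "_rep", seq_len(n_reps)))
    m
  }
  list(counts_pos = draw(fpkm_pos, "airepos"),
       counts_ko = draw(fpkm_ko, "aireko"),
       truth = data.frame(gene_id = g$gene_id, regulation_class = cls,
                          true_fpkm_pos = fpkm_pos, true_fpkm_ko = fpkm_ko))
}
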