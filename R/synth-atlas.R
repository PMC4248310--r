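#' Simulate a multi-tissue expression atlas with planted restricted genes
#'
#' Emulates a microarray-style tissue compendium: `n_samples` arrays fall
#' into `n_groups` tissue groups; a fraction of genes is tissue-restricted,
#' i.e. elevated `fold`-fold in 1..`max_groups` groups over a flat per-gene
#' baseline; every value carries multiplicative log-normal noise.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of arrays (study design: 64).
#' @param n_groups Number of tissue groups (study design: 35).
#' @param restricted_fraction Fraction of genes planted as restricted.
#' @param fold Elevation of a restricted gene in its groups (> 1).
#' @param max_groups Maximum breadth of a restricted gene (1..max_groups).
#' @param noise_sd Log-scale (natural log) noise sd per array.
#' @param base_meanlog,base_sdlog Log-normal law of per-gene baseline signal.
#' @param related_groups When TRUE (default), a gene restricted to several
#'   groups occupies a contiguous run of a latent tissue-similarity
#'   ordering, so its groups are related (as brain regions or gut segments
#'   are) and shared restriction makes those groups cluster as neighbours;
#'   when FALSE, groups are drawn uniformly.
#' @param seed Integer seed.
#' @return List with `matrix` (gene x sample), `groups` (sample -> group id),
#'   and `truth` (gene_id, restricted, n_groups, groups as comma-joined ids).
#' @export
generate_atlas <- function(n_genes, n_samples = 64L, n_groups = 35L,
                           restricted_fraction = 0.2, fold = 8,
                           max_groups = 5L, noise_sd = 0.5,
                           base_meanlog = log(100), base_sdlog = 1,
                           related_groups = TRUE, seed = 1L) {
  if (restricted_fraction < 0 || restricted_fraction > 1)
    stop("restricted_fraction must be in [0, 1]")
  if (fold <= 1) stop("fold must be > 1")
  if (max_groups < 1 || max_groups >= n_groups)
    stop("need 1 <= max_groups < n_groups")
  set.seed(seed)
  # balanced allocation, mirroring a compendium of duplicate arrays per
  # tissue: every group gets its second sample before any gets a third
  grp <- rep(seq_len(n_groups), length.out = n_samples)
  grp <- grp[sample.int(n_samples)]
  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  restricted <- stats::runif(n_genes) < restricted_fraction
  k <- ifelse(restricted, sample.int(max_groups, n_genes, replace = TRUE), 0L)
  latent <- sample.int(n_groups)   # latent tissue-similarity ordering
  gene_groups <- lapply(seq_len(n_genes), function(i) {
    if (k[i] == 0) return(integer(0))
    if (!related_groups) return(sort(sample.int(n_groups, k[i])))
    s <- sample.int(n_groups - k[i] + 1L, 1L)
    sort(latent[s:(s + k[i] - 1L)])
  })
  mult <- matrix(1, n_genes, n_samples)
  for (i in which(restricted))
    mult[i, grp %in% gene_groups[[i]]] <- fold
  m <- base * mult * matrix(stats::rlnorm(n_genes * n_samples, 0, noise_sd),
                            n_genes, n_samples)
  dimnames(m) <- list(sprintf("G%05d", seq_len(n_genes)),
                      sprintf("S%02d", seq_len(n_samples)))
  list(matrix = m,
       groups = stats::setNames(grp, colnames(m)),
       truth = data.frame(gene_id = rownames(m), restricted = restricted,
                          n_groups = k,
                          groups = vapply(gene_groups, paste, "", collapse = ","),
                          stringsAsFactors = FALSE))
}
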