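#' Median-of-ratios size factors
#' @param counts Gene x sample count matrix.
#' @return Per-sample size factors (geometric-mean reference).
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg)
  ok <- is.finite(ref)
  if (!any(ok)) stop("no gene with non-zero counts in all samples")
  apply(counts, 2, function(cl) exp(stats::median(log(cl[ok]) - ref[ok], na.rm = TRUE)))
}

# conditional two-sided NB test of equal means between two groups of
# replicates, given the summed normalised counts and a dispersion
.nb_cond_test <- function(ka, kb, na, nb, disp, enum_cap = 20000L) {
  S <- ka + kb
  if (S == 0) return(1)
  q <- S / (na + nb)
  if (S <= enum_cap) {
    a <- 0:S
    if (disp < 1e-8) {
      lp <- stats::dbinom(a, S, na / (na + nb), log = TRUE)
    } else {
      lp <- stats::dnbinom(a, mu = na * q, size = na / disp, log = TRUE) +
        stats::dnbinom(S - a, mu = nb * q, size = nb / disp, log = TRUE)
    }
    lp <- lp - max(lp)
    p <- exp(lp)
    min(1, sum(p[p <= p[ka + 1] * (1 + 1e-7)]) / sum(p))
  } else {
    # normal approximation to the conditional law of ka given S
    va <- na * q + disp * na * q^2
    vb <- nb * q + disp * nb * q^2
    mu_a <- S * na / (na + nb)
    sd_a <- sqrt(va * vb / (va + vb))
    min(1, 2 * stats::pnorm(-abs(ka - mu_a) / sd_a))
  }
}

#' Minimal negative-binomial differential expression test
#'
#' Size-factor normalisation (median-of-ratios), per-gene method-of-moments
#' dispersion shrunk half-way towards a mean-dispersion trend, and a
#' two-sided conditional test comparing the two conditions' summed
#' normalised counts under the NB law; Benjamini-Hochberg FDR across genes.
#' Log2 fold changes are ratios of normalised condition means with a
#' pseudocount of one normalised count.
#'
#' @param counts_A,counts_B Gene x replicate count matrices (same genes,
#'   >= 2 replicates each).
#' @param pseudocount Added to normalised means for the fold change.
#' @return data.frame(gene_id, base_mean_A, base_mean_B, log2fc, dispersion,
#'   pvalue, fdr).
#' @export
nb_test <- function(counts_A, counts_B, pseudocount = 1) {
  counts_A <- as.matrix(counts_A); counts_B <- as.matrix(counts_B)
  if (nrow(counts_A) != nrow(counts_B)) stop("gene universes differ")
  if (ncol(counts_A) < 2 || ncol(counts_B) < 2)
    stop("need >= 2 replicates per condition")
  nA <- ncol(counts_A); nB <- ncol(counts_B)
  all_counts <- cbind(counts_A, counts_B)
  sf <- size_factors(all_counts)
  normed <- sweep(all_counts, 2, sf, "/")
  a <- normed[, seq_len(nA), drop = FALSE]
  b <- normed[, nA + seq_len(nB), drop = FALSE]
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)

  # method-of-moments dispersion per gene, pooled over conditions
  v_a <- apply(a, 1, stats::var); v_b <- apply(b, 1, stats::var)
  mu_pool <- (mu_a + mu_b) / 2
  v_pool <- (v_a + v_b) / 2
  d_gene <- pmax(0, (v_pool - mu_pool) / mu_pool^2)
  d_gene[!is.finite(d_gene)] <- 0
  # gamma-family trend d(mu) = a0 + a1/mu, least squares on expressed genes
  use <- mu_pool > 1
  if (sum(use) >= 10) {
    fit <- stats::lm(d_gene[use] ~ I(1 / mu_pool[use]))
    d_trend <- pmax(1e-8, fit$coefficients[1] + fit$coefficients[2] / mu_pool)
  } else d_trend <- rep(mean(d_gene[use], na.rm = TRUE) + 1e-8, length(mu_pool))
  disp <- pmax(1e-8, (d_gene + d_trend) / 2)

  ka <- round(rowSums(a)); kb <- round(rowSums(b))
  pval <- vapply(seq_len(nrow(all_counts)), function(i) {
    if (ka[i] + kb[i] == 0) return(1)
    .nb_cond_test(ka[i], kb[i], nA, nB, disp[i])
  }, numeric(1))
  data.frame(gene_id = rownames(all_counts),
             base_mean_A = mu_a, base_mean_B = mu_b,
             log2fc = log2((mu_a + pseudocount) / (mu_b + pseudocount)),
             dispersion = disp,
             pvalue = pval,
             fdr = stats::p.adjust(pval, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify genes by their dependence on Aire expression
#'
#' Using the differential test (Aire-positive vs Aire-KO) and the KO
#' detection table: significantly up-regulated genes (fdr below
#' `fdr_threshold`, fold change above `fold`) are "dependent" when not
#' detected in the KO and "enhanced" when detected; significantly
#' down-regulated genes are "repressed"; everything else "unchanged".
#'
#' @param de Output of [nb_test()] with A = Aire-positive, B = Aire-KO.
#' @param detection_ko data.frame(gene_id, detected) for the KO population.
#' @param fold Fold-change gate (the study uses "more than twofold").
#' @param fdr_threshold FDR gate.
#' @return List with `table` (gene_id, log2fc, fdr, detected_ko, class) and
#'   `counts` (named class tally).
#' @export
classify_regulation <- function(de, detection_ko, fold = 2, fdr_threshold = 0.05) {
  i <- match(de$gene_id, detection_ko$gene_id)
  if (anyNA(i))
    stop("genes missing from KO detection table: ",
         paste(utils::head(de$gene_id[is.na(i)]), collapse = ", "))
  det_ko <- detection_ko$detected[i]
  lfc <- log2(fold)
  up <- de$fdr < fdr_threshold & de$log2fc > lfc
  down <- de$fdr < fdr_threshold & de$log2fc < -lfc
  class <- rep("unchanged", nrow(de))
  class[up & !det_ko] <- "dependent"
  class[up & det_ko] <- "enhanced"
  class[down] <- "repressed"
  tab <- data.frame(gene_id = de$gene_id, log2fc = de$log2fc, fdr = de$fdr,
                    detected_ko = det_ko, class = class,
                    stringsAsFactors = FALSE)
  counts <- table(factor(class, levels = c("dependent", "enhanced",
                                           "repressed", "unchanged")))
  list(table = tab, counts = c(counts))
}

#' Housekeeping-gene bias control
#'
#' Summarises the fold-change distribution of a housekeeping set; a
#' systematic shift (median |log2fc| above `bias_limit`) flags normalisation
#' bias.
#'
#' @param de Output of [nb_test()].
#' @param hk_genes Housekeeping gene ids (subset of the tested universe).
#' @param fdr_threshold Significance gate for the "fraction significant".
#' @param bias_limit Median |log2fc| above which bias is flagged.
#' @return List: median_abs_log2fc, median_log2fc, fraction_significant,
#'   bias_flag, n.
#' @export
housekeeping_control <- function(de, hk_genes, fdr_threshold = 0.05,
                                 bias_limit = 0.5) {
  if (!length(hk_genes)) stop("empty housekeeping set")
  sub <- de[de$gene_id %in% hk_genes, ]
  if (!nrow(sub)) stop("housekeeping genes not in the tested universe")
  med_abs <- stats::median(abs(sub$log2fc))
  list(median_abs_log2fc = med_abs,
       median_log2fc = stats::median(sub$log2fc),
       fraction_significant = mean(sub$fdr < fdr_threshold),
       bias_flag = med_abs > bias_limit,
       n = nrow(sub))
}

#' Correlation between tissue specificity and Aire dependence
#'
#' For every restriction-breadth gene set (>= `min_members` members), the
#' fraction of member genes requiring Aire for detection (detected in the
#' Aire-positive but not the KO population) is correlated with the set's
#' specificity score, 1 - n_leaves / total_leaves.
#'
#' @param bsets Output of [breadth_sets()].
#' @param detection_pos,detection_ko data.frames (gene_id, detected).
#' @param min_members Minimum set size.
#' @return List with `sets` (node, n_leaves, specificity, n,
#'   fraction_requiring_aire), `r`, `pvalue` (NA when undefined).
#' @export
specificity_dependence_correlation <- function(bsets, detection_pos,
                                               detection_ko, min_members = 10L) {
  info <- bsets$nodes[bsets$nodes$n_genes >= min_members, , drop = FALSE]
  if (!nrow(info)) stop("no gene set with >= min_members members")
  pos <- stats::setNames(detection_pos$detected, detection_pos$gene_id)
  ko <- stats::setNames(detection_ko$detected, detection_ko$gene_id)
  frac <- vapply(info$node, function(nd) {
    gs <- bsets$sets[[nd]]
    mean(pos[gs] & !ko[gs], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  spec <- 1 - info$n_leaves / bsets$total_leaves
  out <- data.frame(node = info$node, n_leaves = info$n_leaves,
                    specificity = spec, n = info$n_genes,
                    fraction_requiring_aire = frac,
                    stringsAsFactors = FALSE)
  if (nrow(out) < 2 || stats::sd(frac) == 0 || stats::sd(spec) == 0)
    return(list(sets = out, r = NA_real_, pvalue = NA_real_))
  r <- stats::cor(spec, frac)
  p <- if (nrow(out) >= 3) stats::cor.test(spec, frac)$p.value else NA_real_
  list(sets = out, r = r, pvalue = p)
}
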