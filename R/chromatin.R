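# Coverage tracks are bedGraph-style data.frames (chrom, start, end, score;
# 0-based half-open), interpreted as read counts per record. For window
# arithmetic they are expanded to a per-bp rate Rle.

.cov_rle <- function(cov, chrom_len) {
  w <- cov$end - cov$start
  IRanges::coverage(IRanges::IRanges(cov$start + 1L, cov$end),
                    weight = cov$score / w, width = chrom_len)
}

.cov_library <- function(cov) sum(cov$score)

# sums of per-bp rate over 0-based half-open [start, end) windows
.window_sums <- function(rle, start, end) {
  start <- pmax(0L, start); end <- pmin(length(rle), end)
  v <- IRanges::Views(rle, start = start + 1L, end = pmax(end, start + 1L))
  out <- IRanges::viewSums(v)
  out[end <= start] <- 0
  out
}

#' TSS-centred windows for every gene
#'
#' Half-open windows of the given width centred on each gene's 5' TSS
#' (strand respected), clipped at chromosome edges.
#'
#' @param annotation A `gene_annotation`.
#' @param width Window width in bp (even, > 0; default 1 kb).
#' @return data.frame(gene_id, chrom, start, end, strand, tss).
#' @export
tss_windows <- function(annotation, width = 1000L) {
  if (width <= 0 || width %% 2 != 0) stop("width must be even and > 0")
  g <- annotation$genes
  L <- annotation$chrom_lengths[g$chrom]
  if (any(g$tss < 0 | g$tss > L)) stop("TSS outside chromosome")
  half <- width %/% 2L
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(0L, g$tss - half),
             end = pmin(as.numeric(L), g$tss + half),
             strand = g$strand, tss = g$tss,
             stringsAsFactors = FALSE)
}

#' ChIP enrichment over input in TSS windows
#'
#' Per window and replicate: (ChIP reads in window / ChIP library size)
#' divided by (input reads in window / input library size), then averaged
#' over replicates. Windows with zero input reads receive a pseudocount of
#' one read so the ratio stays finite.
#'
#' @param chip_cov A coverage data.frame or list of replicate data.frames.
#' @param input_cov Input coverage (data.frame or list; recycled across
#'   ChIP replicates if a single track).
#' @param windows Output of [tss_windows()].
#' @param chrom_len Chromosome length; inferred from the tracks when NULL.
#' @param input_floor Minimum input reads per window.
#' @return data.frame(gene_id, enrichment) with replicate-averaged values.
#' @export
enrichment_over_input <- function(chip_cov, input_cov, windows,
                                  chrom_len = NULL, input_floor = 1) {
  if (is.data.frame(chip_cov)) chip_cov <- list(chip_cov)
  if (is.data.frame(input_cov)) input_cov <- list(input_cov)
  if (length(input_cov) == 1) input_cov <- rep(input_cov, length(chip_cov))
  if (is.null(chrom_len))
    chrom_len <- max(vapply(c(chip_cov, input_cov), function(d) max(d$end), numeric(1)))
  enr <- matrix(0, nrow(windows), length(chip_cov))
  for (r in seq_along(chip_cov)) {
    lib_c <- .cov_library(chip_cov[[r]])
    lib_i <- .cov_library(input_cov[[r]])
    if (lib_i <= 0) stop("zero input library")
    rc <- .window_sums(.cov_rle(chip_cov[[r]], chrom_len), windows$start, windows$end)
    ri <- .window_sums(.cov_rle(input_cov[[r]], chrom_len), windows$start, windows$end)
    enr[, r] <- (rc / lib_c) / (pmax(ri, input_floor) / lib_i)
  }
  data.frame(gene_id = windows$gene_id, enrichment = rowMeans(enr),
             stringsAsFactors = FALSE)
}

#' Metagene profile of normalised enrichment around the TSS
#'
#' Each gene's TSS +/- `flank` is divided into `n_bins` bins oriented so
#' that downstream of transcription is rightward; per bin, the
#' library-normalised ChIP signal summed over genes is divided by the
#' corresponding input signal, and replicate profiles are averaged.
#'
#' @param chip_cov,input_cov Coverage tracks as in [enrichment_over_input()].
#' @param annotation A `gene_annotation`.
#' @param genes Gene ids to profile (non-empty).
#' @param flank Flank size in bp on each side of the TSS.
#' @param n_bins Number of bins (>= 3).
#' @param chrom_len Chromosome length; inferred when NULL.
#' @return data.frame(bin, position, enrichment); position is the bin
#'   centre's offset from the TSS.
#' @export
metagene_profile <- function(chip_cov, input_cov, annotation, genes,
                             flank = 5000L, n_bins = 101L, chrom_len = NULL) {
  if (!length(genes)) stop("empty gene set")
  if (n_bins < 3) stop("n_bins must be >= 3")
  if (is.data.frame(chip_cov)) chip_cov <- list(chip_cov)
  if (is.data.frame(input_cov)) input_cov <- list(input_cov)
  if (length(input_cov) == 1) input_cov <- rep(input_cov, length(chip_cov))
  if (is.null(chrom_len))
    chrom_len <- max(vapply(c(chip_cov, input_cov), function(d) max(d$end), numeric(1)))
  g <- annotation$genes[match(genes, annotation$genes$gene_id), ]
  if (anyNA(g$tss)) stop("unknown genes: ",
                         paste(genes[is.na(g$tss)], collapse = ", "))
  edges <- seq(-flank, flank, length.out = n_bins + 1L)
  # strand-oriented bin intervals, one row per gene x bin
  n_g <- nrow(g)
  lo <- rep(edges[-length(edges)], each = n_g)
  hi <- rep(edges[-1], each = n_g)
  tss <- rep(g$tss, n_bins)
  minus <- rep(g$strand == "-", n_bins)
  b_start <- ifelse(minus, tss - hi, tss + lo)
  b_end <- ifelse(minus, tss - lo, tss + hi)
  b_start <- pmax(0, round(b_start)); b_end <- pmin(chrom_len, round(b_end))

  profile <- matrix(0, n_bins, length(chip_cov))
  for (r in seq_along(chip_cov)) {
    lib_c <- .cov_library(chip_cov[[r]])
    lib_i <- .cov_library(input_cov[[r]])
    sc <- .window_sums(.cov_rle(chip_cov[[r]], chrom_len), b_start, b_end)
    si <- .window_sums(.cov_rle(input_cov[[r]], chrom_len), b_start, b_end)
    mc <- colSums(matrix(sc, n_g, n_bins)) / lib_c
    mi <- colSums(matrix(si, n_g, n_bins)) / lib_i
    profile[, r] <- mc / pmax(mi, .Machine$double.xmin)
  }
  data.frame(bin = seq_len(n_bins),
             position = (edges[-1] + edges[-length(edges)]) / 2,
             enrichment = rowMeans(profile))
}

#' Fraction of each gene set whose TSS window overlaps a peak
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param peaks data.frame(chrom, start, end), 0-based half-open.
#' @param windows Output of [tss_windows()].
#' @return Named numeric vector of overlap fractions.
#' @export
peak_overlap_fraction <- function(gene_sets, peaks, windows) {
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L, windows$end))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1L, peaks$end))
  hit <- IRanges::overlapsAny(wgr, pgr)
  names(hit) <- windows$gene_id
  vapply(gene_sets, function(gs) {
    if (!all(gs %in% windows$gene_id))
      stop("unknown gene(s) in set: ",
           paste(utils::head(setdiff(gs, windows$gene_id)), collapse = ", "))
    mean(hit[gs])
  }, numeric(1))
}

#' Fisher association between two gene sets over a universe
#'
#' Builds the 2x2 membership table over the universe. The odds ratio is the
#' sample cross-product (n11 n00)/(n10 n01), with a Haldane correction of
#' 0.5 and an infinity flag when a cell is zero; the two-sided p-value is
#' Fisher's exact (hypergeometric) test.
#'
#' @param set_A,set_B Gene-id vectors (subsets of `universe`).
#' @param universe Gene-id vector.
#' @return List: odds_ratio, infinite (flag), pvalue, table (2x2 matrix).
#' @export
fisher_association <- function(set_A, set_B, universe) {
  if (!length(universe)) stop("empty universe")
  in_a <- universe %in% set_A
  in_b <- universe %in% set_B
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  zero <- any(tab == 0)
  t2 <- if (zero) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, infinite = zero && (tab[1, 2] == 0 || tab[2, 1] == 0),
       pvalue = p, table = tab)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value when the smaller group has at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param values_A,values_B Non-empty numeric vectors.
#' @param exact_max Largest min-group size for the exact branch.
#' @return List: U (statistic of the first sample), pvalue, exact (flag).
#' @export
rank_test <- function(values_A, values_B, exact_max = 8L) {
  if (!length(values_A) || !length(values_B)) stop("empty input vector")
  ties <- anyDuplicated(c(values_A, values_B)) > 0
  use_exact <- !ties && min(length(values_A), length(values_B)) <= exact_max
  wt <- stats::wilcox.test(values_A, values_B, exact = use_exact,
                           correct = !use_exact)
  list(U = unname(wt$statistic), pvalue = wt$p.value, exact = use_exact)
}

#' Joint H3K4me3/H3K27me3 TSS state and bivalency
#'
#' Pairs the two marks' TSS enrichments per gene, reports Pearson
#' correlations of the log2 enrichments overall and within the Aire
#' up-regulated subset, and flags genes with both marks at or above the
#' `bivalent_gate` as bivalent.
#'
#' @param enr_k4,enr_k27 data.frames (gene_id, enrichment) for H3K4me3 and
#'   H3K27me3.
#' @param regulation Optional regulation table (gene_id, class); the Aire-up
#'   subset is class dependent or enhanced.
#' @param bivalent_gate Fold gate, inclusive (the study uses "twofold or
#'   greater").
#' @return List: table (gene_id, k4, k27, bivalent, aire_up), r_overall,
#'   r_aire_up.
#' @export
bivalency_analysis <- function(enr_k4, enr_k27, regulation = NULL,
                               bivalent_gate = 2) {
  common <- intersect(enr_k4$gene_id, enr_k27$gene_id)
  if (!length(common)) stop("disjoint gene universes")
  k4 <- enr_k4$enrichment[match(common, enr_k4$gene_id)]
  k27 <- enr_k27$enrichment[match(common, enr_k27$gene_id)]
  aire_up <- rep(FALSE, length(common))
  if (!is.null(regulation)) {
    cls <- regulation$class[match(common, regulation$gene_id)]
    aire_up <- cls %in% c("dependent", "enhanced")
  }
  l4 <- log2(pmax(k4, 1e-3)); l27 <- log2(pmax(k27, 1e-3))
  r_all <- stats::cor(l4, l27)
  r_up <- if (sum(aire_up) >= 3) stats::cor(l4[aire_up], l27[aire_up]) else NA_real_
  list(table = data.frame(gene_id = common, k4 = k4, k27 = k27,
                          bivalent = k4 >= bivalent_gate & k27 >= bivalent_gate,
                          aire_up = aire_up, stringsAsFactors = FALSE),
       r_overall = r_all, r_aire_up = r_up)
}
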