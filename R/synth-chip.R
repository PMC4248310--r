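#' Assign chromatin states to genes
#'
#' Gives every gene one of three TSS chromatin states. When a regulation
#' truth table is supplied, Aire-induced genes (dependent/enhanced) are
#' biased towards the Polycomb-repressed and bivalent states, mirroring the
#' biology the pipeline is built to detect; other genes are mostly active.
#'
#' @param annotation A `gene_annotation`.
#' @param regulation Optional data.frame with `gene_id`, `regulation_class`.
#' @param p_induced Probabilities (active, repressed, bivalent) for
#'   Aire-induced genes.
#' @param p_other Probabilities for all other genes.
#' @param seed Integer seed.
#' @return data.frame(gene_id, chromatin_state).
#' @export
assign_chromatin_states <- function(annotation, regulation = NULL,
                                    p_induced = c(0.1, 0.6, 0.3),
                                    p_other = c(0.7, 0.2, 0.1),
                                    seed = 1L) {
  set.seed(seed)
  ids <- annotation$genes$gene_id
  states <- c("active", "repressed", "bivalent")
  induced <- rep(FALSE, length(ids))
  if (!is.null(regulation)) {
    cls <- regulation$regulation_class[match(ids, regulation$gene_id)]
    induced <- cls %in% c("dependent", "enhanced")
  }
  st <- character(length(ids))
  st[induced] <- sample(states, sum(induced), replace = TRUE, prob = p_induced)
  st[!induced] <- sample(states, sum(!induced), replace = TRUE, prob = p_other)
  data.frame(gene_id = ids, chromatin_state = st, stringsAsFactors = FALSE)
}

#' Simulate ChIP and input coverage with TSS-localised enrichment
#'
#' Background is homogeneous Poisson over fixed-width bins. Genes in the
#' "active" state receive `enrichment`-fold H3K4me3 signal in a window around
#' their TSS, "repressed" genes receive H3K27me3, "bivalent" genes both;
#' input tracks carry background only. Two replicate tracks per mark and two
#' input replicates are produced, matching the n = 2 ChIP design.
#'
#' @param annotation A `gene_annotation`.
#' @param states data.frame(gene_id, chromatin_state) as from
#'   [assign_chromatin_states()].
#' @param marks Mark names; only H3K4me3 and H3K27me3 are understood.
#' @param enrichment Fold signal over background at marked TSS (>= 1).
#' @param window_width Width (bp) of the enriched TSS window.
#' @param bin Bin width (bp) of the emitted coverage.
#' @param bg_rate Background reads per bp.
#' @param n_reps Replicates per track.
#' @param gene_enrichment_sd Log-sd of a per-gene enrichment factor shared
#'   by both marks at the same TSS (locus-to-locus variation in signal
#'   strength; it is what correlates the two marks at bivalent TSS).
#' @param seed Integer seed.
#' @return List with `chip` (list mark -> list of replicate coverage
#'   data.frames), `input` (list of replicate coverage data.frames). Coverage
#'   data.frames have columns chrom, start, end, score (0-based half-open).
#' @export
generate_chip_coverage <- function(annotation, states,
                                   marks = c("H3K4me3", "H3K27me3"),
                                   enrichment = 4, window_width = 1000L,
                                   bin = 10L, bg_rate = 0.05, n_reps = 2L,
                                   gene_enrichment_sd = 0.3, seed = 1L) {
  if (!all(marks %in% c("H3K4me3", "H3K27me3")))
    stop("unknown mark: ", paste(setdiff(marks, c("H3K4me3", "H3K27me3")), collapse = ", "))
  if (enrichment < 1) stop("enrichment must be >= 1")
  set.seed(seed)
  chrom <- names(annotation$chrom_lengths)[1]
  L <- annotation$chrom_lengths[[1]]
  n_bins <- ceiling(L / bin)
  g <- annotation$genes
  st <- states$chromatin_state[match(g$gene_id, states$gene_id)]
  gene_factor <- stats::rlnorm(nrow(g), 0, gene_enrichment_sd)

  mark_bins <- function(mark) {
    want <- switch(mark,
                   H3K4me3 = st %in% c("active", "bivalent"),
                   H3K27me3 = st %in% c("repressed", "bivalent"))
    rate <- rep(1, n_bins)
    half <- window_width %/% 2L
    for (i in which(want)) {
      b0 <- max(0L, g$tss[i] - half) %/% bin + 1L
      b1 <- min(n_bins, (min(L, g$tss[i] + half) - 1L) %/% bin + 1L)
      rate[b0:b1] <- 1 + (enrichment - 1) * gene_factor[i]
    }
    rate
  }
  as_cov <- function(counts) {
    data.frame(chrom = chrom,
               start = (seq_len(n_bins) - 1L) * bin,
               end = pmin(L, seq_len(n_bins) * bin),
               score = counts)
  }
  mu_bg <- bg_rate * bin
  chip <- lapply(stats::setNames(marks, marks), function(mk) {
    rate <- mark_bins(mk)
    lapply(seq_len(n_reps), function(r) as_cov(stats::rpois(n_bins, mu_bg * rate)))
  })
  input <- lapply(seq_len(n_reps), function(r) as_cov(stats::rpois(n_bins, mu_bg)))
  list(chip = chip, input = input, bin = bin)
}
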