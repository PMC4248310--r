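#' ERCC-like spike-in table
#'
#' 92 control species with known molecule counts spanning the 2^0..2^22
#' dynamic range of the external RNA control mixes.
#'
#' @param n Number of spike-in species.
#' @return data.frame(spike_id, molecules).
#' @export
ercc_like_spikeins <- function(n = 92L) {
  molecules <- round(2 ^ seq(0, 22, length.out = n))
  data.frame(spike_id = sprintf("SPIKE-%03d", seq_len(n)),
             molecules = molecules)
}

#' Per-class single-cell expression frequency and burst level
#'
#' Gives every gene an "on" frequency (fraction of cells transcribing it)
#' and a burst level (its expression when on, as a multiple of the
#' population level), by regulation class. Class defaults are the observed
#' single-cell regime for mature mTEC: Aire-dependent genes on in ~1.1% of
#' cells at ~16x the population level, enhanced 2.3%/9x, Aire-independent
#' TRA 9.2%/5x, and broadly expressed genes 1/3 of cells at 3x (frequency
#' times burst = 1, i.e. consistent with their population level).
#'
#' @param gene_classes data.frame(gene_id, class) with class in
#'   {dependent, enhanced, tra, other}.
#' @param class_params data.frame(class, frequency, burst) overriding the
#'   defaults.
#' @return data.frame(gene_id, class, sc_on_frequency, sc_burst_level).
#' @export
assign_sc_truth <- function(gene_classes,
                            class_params = data.frame(
                              class = c("dependent", "enhanced", "tra", "other"),
                              frequency = c(0.011, 0.023, 0.092, 1 / 3),
                              burst = c(16, 9, 5, 3))) {
  i <- match(gene_classes$class, class_params$class)
  if (anyNA(i)) stop("unknown class: ",
                     paste(unique(gene_classes$class[is.na(i)]), collapse = ", "))
  data.frame(gene_id = gene_classes$gene_id, class = gene_classes$class,
             sc_on_frequency = class_params$frequency[i],
             sc_burst_level = class_params$burst[i],
             stringsAsFactors = FALSE)
}

#' Simulate single-cell expression with spike-ins of known molecule counts
#'
#' Each gene turns on in a cell with probability `sc_on_frequency`
#' (independently across cells unless a driver gene couples them); when on,
#' its true copy number is `sc_burst_level` times its population level. The
#' observed signal for genes and spike-ins alike is the true quantity times
#' a per-cell capture factor with multiplicative noise (or Poisson counting
#' noise), so spike-in regression can recover absolute copy numbers.
#'
#' @param population_profile Named numeric vector: per-gene population-level
#'   expression (e.g. pooled FPKM).
#' @param truth data.frame(gene_id, sc_on_frequency, sc_burst_level) as from
#'   [assign_sc_truth()]; extra columns are carried through.
#' @param n_cells Number of cells.
#' @param spikein_table data.frame(spike_id, molecules), molecule counts > 0.
#' @param capture_efficiency Mean per-cell capture factor (> 0).
#' @param capture_sdlog Log-sd of the per-cell capture factor.
#' @param noise "lognormal" (sd `noise_sd`, mean 1) or "poisson".
#' @param noise_sd Log-scale sd of measurement noise (lognormal mode).
#' @param driver_gene Optional gene whose per-cell level scales the on
#'   probability of genes flagged `driver_responsive` in `truth`, emulating
#'   the coupling between Aire level and the breadth of promiscuous
#'   transcription in a cell.
#' @param driver_sdlog Log-sd of the per-cell driver activity.
#' @param seed Integer seed.
#' @return List with `signal` (cell x gene observed signal), `on` (logical
#'   cell x gene truth), `spike_observed` (cell x spike signal),
#'   `spike_table`, `capture` (true per-cell factors), `truth`.
#' @export
generate_single_cells <- function(population_profile, truth, n_cells = 174L,
                                  spikein_table = ercc_like_spikeins(),
                                  capture_efficiency = 0.1, capture_sdlog = 0.3,
                                  noise = c("lognormal", "poisson"),
                                  noise_sd = 0.2,
                                  driver_gene = NULL, driver_sdlog = 0.5,
                                  seed = 1L) {
  noise <- match.arg(noise)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (any(spikein_table$molecules <= 0)) stop("spike-in molecule counts must be > 0")
  if (capture_efficiency <= 0) stop("capture_efficiency must be > 0")
  if (any(truth$sc_on_frequency < 0 | truth$sc_on_frequency > 1))
    stop("sc_on_frequency must be in [0, 1]")
  set.seed(seed)
  genes <- truth$gene_id
  pop <- population_profile[genes]
  if (anyNA(pop)) stop("population_profile missing genes: ",
                       paste(utils::head(genes[is.na(pop)]), collapse = ", "))
  n_g <- length(genes)
  capture <- capture_efficiency * stats::rlnorm(n_cells, 0, capture_sdlog)

  driver_act <- rep(1, n_cells)
  responsive <- rep(FALSE, n_g)
  if (!is.null(driver_gene)) {
    driver_act <- stats::rlnorm(n_cells, 0, driver_sdlog)
    if (!is.null(truth$driver_responsive)) responsive <- truth$driver_responsive
  }
  pfreq <- matrix(rep(truth$sc_on_frequency, each = n_cells), n_cells, n_g)
  if (any(responsive))
    pfreq[, responsive] <- pmin(1, pfreq[, responsive] * driver_act)

  on <- matrix(stats::runif(n_cells * n_g) < pfreq, n_cells, n_g)
  true_copies <- on * matrix(rep(truth$sc_burst_level * pop, each = n_cells),
                             n_cells, n_g)
  if (!is.null(driver_gene)) {
    j <- match(driver_gene, genes)
    if (is.na(j)) stop("driver_gene not in truth: ", driver_gene)
    on[, j] <- TRUE
    true_copies[, j] <- pop[j] * driver_act
  }
  meas <- function(x_true, capt) {
    lam <- x_true * capt
    if (noise == "poisson") matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    else lam * matrix(stats::rlnorm(length(lam), -noise_sd^2 / 2, noise_sd),
                      nrow(lam), ncol(lam))
  }
  signal <- meas(true_copies, capture)
  spike_true <- matrix(rep(spikein_table$molecules, each = n_cells),
                       n_cells, nrow(spikein_table))
  spike_obs <- meas(spike_true, capture)
  cells <- sprintf("cell%03d", seq_len(n_cells))
  dimnames(signal) <- list(cells, genes)
  dimnames(on) <- list(cells, genes)
  dimnames(spike_obs) <- list(cells, spikein_table$spike_id)
  list(signal = signal, on = on, spike_observed = spike_obs,
       spike_table = spikein_table, capture = capture, truth = truth)
}
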