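#' Default pipeline configuration
#'
#' Demo-scale settings for the full synthetic workflow; every stage can be
#' toggled and every parameter overridden. Per-stage seeds are derived from
#' the single base seed.
#'
#' @param out_dir Output directory.
#' @param seed Base seed.
#' @return Nested list of stage blocks.
#' @export
pge_default_config <- function(out_dir = "pge_run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    annotation = list(enabled = TRUE, n_genes = 2000, genome_length = 6e7),
    bulk = list(enabled = TRUE, populations = c("cTEC", "mTEC_aire_pos"),
                pi0 = 0.5, depth = 2e7, n_reps = 2),
    detect = list(enabled = TRUE, lfdr_threshold = 0.05),
    atlas = list(enabled = TRUE, n_samples = 64, n_groups = 35,
                 restricted_fraction = 0.2, fold = 8, max_groups = 5),
    aire = list(enabled = TRUE, n_dependent = 100, n_enhanced = 300,
                n_repressed = 20, fold = 4),
    chip = list(enabled = TRUE, enrichment = 4, window = 1000),
    singlecell = list(enabled = TRUE, n_cells = 174)
  )
}

.stage_seed <- function(seed, k) (as.integer(seed) + 1000L * k) %% .Machine$integer.max

#' Run the synthetic PGE pipeline end to end
#'
#' Executes the enabled stages in dependency order (annotation -> bulk
#' counts -> detection -> atlas -> Aire regulation -> chromatin ->
#' single-cell), writing plain-text outputs under the configured directory
#' and a JSON manifest listing every output file with its checksum,
#' parameters and seeds. Reruns with the same config are bit-identical.
#'
#' @param config A config list (see [pge_default_config()]) or the path of
#'   a YAML file holding one.
#' @return The manifest (invisibly), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = pge_default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir) || is.null(config$seed))
    stop("config must name out_dir and seed")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  on_stage <- function(s) isTRUE(config[[s]]$enabled)
  outputs <- character(0)
  stage_log <- list()
  emit <- function(path) { outputs <<- c(outputs, path); path }
  t_all <- Sys.time()

  ann <- NULL; bulk <- NULL; det <- list()
  if (on_stage("annotation")) {
    p <- config$annotation
    ann <- generate_annotation(p$n_genes, p$genome_length,
                               seed = .stage_seed(config$seed, 1))
    emit(write_gtf(ann, file.path(config$out_dir, "annotation.gtf")))
    stage_log$annotation <- list(n_genes = p$n_genes)
  }
  if (on_stage("bulk")) {
    if (is.null(ann)) stop("bulk stage requires the annotation stage")
    p <- config$bulk
    bulk <- generate_bulk_counts(ann, populations = p$populations,
                                 pi0 = p$pi0, depth = p$depth,
                                 n_reps = p$n_reps,
                                 seed = .stage_seed(config$seed, 2))
    emit(write_tsv_matrix(bulk$counts, file.path(config$out_dir, "counts.tsv")))
    utils::write.table(bulk$truth, file.path(config$out_dir, "bulk_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "bulk_truth.tsv"))
    stage_log$bulk <- list(populations = p$populations, pi0 = p$pi0)
  }
  if (on_stage("detect")) {
    if (is.null(bulk)) stop("detect stage requires the bulk stage")
    p <- config$detect
    nm <- build_null_models(ann, seed = .stage_seed(config$seed, 3))
    pops <- unique(bulk$sample_meta$population)
    det_tabs <- list()
    for (pp in pops) {
      cols <- bulk$sample_meta$sample[bulk$sample_meta$population == pp]
      pooled <- rowSums(bulk$counts[, cols, drop = FALSE])
      fpkm <- compute_fpkm(cbind(pool = pooled), ann)[, 1]
      ncnt <- generate_null_counts(nm, n_samples = length(cols),
                                   depth = config$bulk$depth,
                                   seed = .stage_seed(config$seed, 4))
      nfpkm <- rowSums(ncnt) / (nm$exonic_length / 1e3) / (sum(pooled) / 1e6)
      res <- detect_population(ann$genes$gene_id, fpkm, nfpkm,
                               lfdr_threshold = p$lfdr_threshold)
      res$table$population <- pp
      det[[pp]] <- res
      det_tabs[[pp]] <- res$table
    }
    dt <- do.call(rbind, det_tabs)
    utils::write.table(dt, file.path(config$out_dir, "detection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "detection.tsv"))
    stage_log$detect <- lapply(det, function(r)
      list(pi0 = r$pi0, n_detected = r$n_detected,
           fpkm_at_threshold = r$fpkm_at_threshold))
  }
  if (on_stage("atlas")) {
    p <- config$atlas
    n_genes <- if (!is.null(ann)) nrow(ann$genes) else 2000
    atl <- generate_atlas(n_genes, p$n_samples, p$n_groups,
                          p$restricted_fraction, p$fold, p$max_groups,
                          seed = .stage_seed(config$seed, 5))
    grouping <- cluster_atlas_samples(atl$matrix, p$n_groups)
    ge <- group_summarise(atl$matrix, grouping)
    calls <- dynamic_step_classify(ge, max_groups = p$max_groups)
    emit(write_tsv_matrix(atl$matrix, file.path(config$out_dir, "atlas.tsv")))
    utils::write.table(calls, file.path(config$out_dir, "tissue_restriction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "tissue_restriction.tsv"))
    stage_log$atlas <- list(n_restricted = sum(calls$restricted))
  }
  if (on_stage("aire")) {
    if (is.null(ann)) stop("aire stage requires the annotation stage")
    p <- config$aire
    ax <- generate_aire_experiment(ann, n_dependent = p$n_dependent,
                                   n_enhanced = p$n_enhanced,
                                   n_repressed = p$n_repressed, fold = p$fold,
                                   seed = .stage_seed(config$seed, 6))
    de <- nb_test(ax$counts_pos, ax$counts_ko)
    nm <- build_null_models(ann, seed = .stage_seed(config$seed, 7))
    ko_pooled <- rowSums(ax$counts_ko)
    ko_fpkm <- compute_fpkm(cbind(pool = ko_pooled), ann)[, 1]
    ncnt <- generate_null_counts(nm, n_samples = 2,
                                 seed = .stage_seed(config$seed, 8))
    nfpkm <- rowSums(ncnt) / (nm$exonic_length / 1e3) / (sum(ko_pooled) / 1e6)
    det_ko <- detect_population(ann$genes$gene_id, ko_fpkm, nfpkm)
    reg <- classify_regulation(de, det_ko$table)
    utils::write.table(reg$table, file.path(config$out_dir, "regulation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "regulation.tsv"))
    stage_log$aire <- as.list(reg$counts)
    det$aire_reg <- reg
  }
  if (on_stage("chip")) {
    if (is.null(ann)) stop("chip stage requires the annotation stage")
    p <- config$chip
    regt <- if (!is.null(det$aire_reg))
      data.frame(gene_id = det$aire_reg$table$gene_id,
                 regulation_class = det$aire_reg$table$class) else NULL
    st <- assign_chromatin_states(ann, regt, seed = .stage_seed(config$seed, 9))
    cc <- generate_chip_coverage(ann, st, enrichment = p$enrichment,
                                 seed = .stage_seed(config$seed, 10))
    win <- tss_windows(ann, width = p$window)
    for (mk in names(cc$chip)) {
      e <- enrichment_over_input(cc$chip[[mk]], cc$input, win,
                                 chrom_len = ann$chrom_lengths[[1]])
      utils::write.table(e, file.path(config$out_dir, paste0("tss_", mk, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(file.path(config$out_dir, paste0("tss_", mk, ".tsv")))
    }
    emit(write_bedgraph(cc$input[[1]], file.path(config$out_dir, "input_rep1.bedgraph")))
    stage_log$chip <- list(marks = names(cc$chip))
  }
  if (on_stage("singlecell")) {
    p <- config$singlecell
    n_genes <- if (!is.null(ann)) min(2000, nrow(ann$genes)) else 2000
    ids <- if (!is.null(ann)) ann$genes$gene_id[seq_len(n_genes)]
           else sprintf("G%05d", seq_len(n_genes))
    cls <- rep(c("dependent", "enhanced", "tra", "other"),
               round(n_genes * c(0.05, 0.1, 0.15, 0.7)))[seq_len(n_genes)]
    truth <- assign_sc_truth(data.frame(gene_id = ids, class = cls))
    pop <- stats::setNames(stats::rlnorm(n_genes, log(5), 1), ids)
    sc <- generate_single_cells(pop, truth, n_cells = p$n_cells,
                                seed = .stage_seed(config$seed, 11))
    curves <- fit_spikein_curve(sc$spike_observed, sc$spike_table$molecules)
    ds <- to_copy_numbers(sc$signal, curves)
    nrm <- normalize_to_population(ds, pop)
    freq <- detection_frequency(nrm$dataset,
                                split(truth$gene_id, truth$class))
    prefix <- write_mtx(ds$copies, file.path(config$out_dir, "sc_copies"))
    for (suf in c(".mtx", ".rows.tsv", ".cols.tsv")) emit(paste0(prefix, suf))
    utils::write.table(data.frame(gene_id = names(freq$frequency),
                                  frequency = freq$frequency),
                       file.path(config$out_dir, "sc_frequency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "sc_frequency.tsv"))
    stage_log$singlecell <- list(n_cells = p$n_cells,
                                 class_median = as.list(freq$class_median))
  }

  outputs <- unique(outputs[file.exists(outputs)])
  manifest <- list(
    created = format(t_all, "%Y-%m-%d"),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("out_dir", "seed"))],
    stages = stage_log,
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
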