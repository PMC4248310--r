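#!/usr/bin/env Rscript
# Stage 1: build the synthetic study with known ground truth.
#
# Writes a gene annotation (GTF), bulk RNA-seq counts for three TEC
# populations plus an Aire-KO comparison, a 64-sample tissue atlas, ChIP
# and input coverage for two histone marks, and 174 single cells with
# spike-ins, all under results/data/.

library(pgex)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20140201L

message("annotation: 4000 genes on a 120 Mb chromosome")
ann <- generate_annotation(4000, 1.2e8, seed = seed)
write_gtf(ann, file.path(out, "annotation.gtf"))

message("bulk counts: cTEC, mTEC and Aire-positive mature mTEC (n = 2 each)")
bulk <- generate_bulk_counts(ann, c("cTEC", "mTEC", "mTEC_aire_pos"),
                             pi0 = 0.5, seed = seed + 1)
write_tsv_matrix(bulk$counts, file.path(out, "bulk_counts.tsv"))
write.table(bulk$truth, file.path(out, "bulk_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("tissue atlas: 64 arrays, 35 groups, 20% restricted genes at 8-fold")
atl <- generate_atlas(4000, 64, 35, restricted_fraction = 0.2, fold = 8,
                      seed = seed + 3)
rownames(atl$matrix) <- ann$genes$gene_id
atl$truth$gene_id <- ann$genes$gene_id
write_tsv_matrix(atl$matrix, file.path(out, "atlas.tsv"))
write.table(atl$truth, file.path(out, "atlas_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Aire-positive vs Aire-KO experiment, dependence coupled to restriction")
# full Aire dependence is most likely for the most narrowly restricted genes
set.seed(seed + 2)
k <- atl$truth$n_groups                 # 0 = broad, 1..5 = restriction breadth
p_dep <- rep(0.005, length(k))
p_dep[k > 0] <- c(0.80, 0.30, 0.05, 0.02, 0.01)[k[k > 0]]
u <- runif(4000)
cls <- ifelse(u < p_dep, "dependent",
              ifelse(k > 0 & u < p_dep + 0.5, "enhanced",
                     ifelse(k == 0 & u < 0.1, "enhanced", "unchanged")))
cls[sample(which(cls == "unchanged"), 40)] <- "repressed"
ax <- generate_aire_experiment(ann, fold = 4, seed = seed + 2, classes = cls)
write_tsv_matrix(cbind(ax$counts_pos, ax$counts_ko),
                 file.path(out, "aire_counts.tsv"))
write.table(ax$truth, file.path(out, "aire_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("ChIP coverage: H3K4me3 / H3K27me3 with input, 2 replicates each")
st <- assign_chromatin_states(ann, data.frame(gene_id = ax$truth$gene_id,
                                              regulation_class = ax$truth$regulation_class),
                              p_induced = c(0.02, 0.28, 0.7), seed = seed + 4)
write.table(st, file.path(out, "chromatin_states.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cc <- generate_chip_coverage(ann, st, enrichment = 4, bg_rate = 0.1,
                             seed = seed + 5)
for (mk in names(cc$chip))
  for (r in seq_along(cc$chip[[mk]]))
    write_bedgraph(cc$chip[[mk]][[r]],
                   file.path(out, sprintf("%s_rep%d.bedgraph", mk, r)))
for (r in seq_along(cc$input))
  write_bedgraph(cc$input[[r]], file.path(out, sprintf("input_rep%d.bedgraph", r)))

message("single cells: 174 cells over a 3000-gene panel with ERCC-style spike-ins")
n_cls <- c(dependent = 200, enhanced = 400, tra = 400, other = 2000)
panel <- ann$genes$gene_id[seq_len(sum(n_cls))]
cls <- data.frame(gene_id = panel, class = rep(names(n_cls), n_cls))
sct <- assign_sc_truth(cls)
sct$driver_responsive <- sct$class %in% c("dependent", "enhanced")
set.seed(seed + 6)
pop <- setNames(rlnorm(length(panel), log(5), 1), panel)
sc <- generate_single_cells(pop, sct, n_cells = 174,
                            driver_gene = panel[length(panel)],
                            seed = seed + 7)
write_mtx(sc$signal, file.path(out, "sc_signal"))
write_mtx(sc$spike_observed, file.path(out, "sc_spikes"))
write.table(sc$spike_table, file.path(out, "sc_spike_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sct, file.path(out, "sc_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(pop), population_fpkm = pop),
            file.path(out, "sc_population.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("done: inputs in ", out)
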