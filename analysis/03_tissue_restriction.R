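#!/usr/bin/env Rscript
# Stage 3: which genes are tissue-restricted in the atlas?
#
# Clusters the 64 atlas arrays into 35 tissue groups, calls restricted
# genes with the dynamic step classifier, compares against the
# simple-threshold baseline using the planted truth, and assigns restricted
# genes to restriction-breadth sets on the group tree.

library(pgex)

dat <- "results/data"
atlas <- read_tsv_matrix(file.path(dat, "atlas.tsv"))
truth <- read.delim(file.path(dat, "atlas_truth.tsv"))

grouping <- cluster_atlas_samples(atlas, 35)
ge <- group_summarise(atlas, grouping)
dyn <- dynamic_step_classify(ge)
base <- simple_threshold_classify(ge)

tr <- truth$restricted[match(dyn$gene_id, truth$gene_id)]
perf <- function(calls) c(sensitivity = mean(calls$restricted[tr]),
                          specificity = mean(!calls$restricted[!tr]))
pd <- perf(dyn); pb <- perf(base)
message(sprintf("dynamic step:     sens %.3f  spec %.3f  Youden %.3f",
                pd[1], pd[2], sum(pd) - 1))
message(sprintf("simple threshold: sens %.3f  spec %.3f  Youden %.3f",
                pb[1], pb[2], sum(pb) - 1))
message(sprintf("restricted genes called: %d (planted: %d); label mix: %s",
                sum(dyn$restricted), sum(tr),
                paste(names(table(dyn$label)), table(dyn$label),
                      sep = "=", collapse = ", ")))

write.table(dyn, "results/tissue_restriction_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_newick(grouping$tree, "results/atlas_sample_tree.nwk")

bs <- breadth_sets(dyn, grouping)
write.table(bs$nodes, "results/breadth_sets.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("breadth sets: %d nodes populated, %d with >= 10 members",
                nrow(bs$nodes), sum(!bs$nodes$small)))
write.table(data.frame(
  classifier = c("dynamic_step", "simple_threshold"),
  sensitivity = c(pd[1], pb[1]), specificity = c(pd[2], pb[2]),
  youden = c(sum(pd) - 1, sum(pb) - 1)),
  "results/restriction_performance.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
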