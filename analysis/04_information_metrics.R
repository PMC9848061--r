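#!/usr/bin/env Rscript
# Stage 4: phylogenetic-information and compositional-bias metrics.
#
# Computes the per-orthogroup criteria (alignment length, variable and
# parsimony-informative sites, mean bipartition support, long-branch
# scores, saturation, treeness, RCV, RCFV, chi-square homogeneity) and
# compares their distributions between orthogroups that passed and failed
# the clan filter with Wilcoxon rank-sum tests.

suppressMessages(library(orthosignal))

syn <- "results/synthetic"
out <- "results/metrics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

trees <- read_tree_list(file.path(syn, "gene_trees.nwk"))
names(trees) <- sprintf("OG%04d", seq_along(trees))
retained <- readLines("results/clan_filter/retained_orthogroups.txt")

rows <- lapply(names(trees), function(id) {
  aln <- read_alignment(file.path(syn, "alignments", paste0(id, ".fasta")))
  cbind(orthogroup = id, orthogroup_metrics(aln, trees[[id]]),
        passed = id %in% retained)
})
metrics <- do.call(rbind, rows)
write.table(metrics, file.path(out, "orthogroup_metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- compare_groups(metrics[metrics$passed, ], metrics[!metrics$passed, ])
write.table(cmp, file.path(out, "pass_vs_fail.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("metrics for %d orthogroups (%d passed the clan filter)\n",
            nrow(metrics), sum(metrics$passed)))
print(cmp[, c("metric", "median_pass", "median_fail", "p", "stars")],
      row.names = FALSE, digits = 3)
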