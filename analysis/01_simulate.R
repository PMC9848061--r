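#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# A six-clan species tree (five animal-phylum-like clans, one of them a
# singleton, plus an outgroup clan), 100 orthogroup gene trees with taxon
# dropout and clan-violating relocations, and one amino-acid alignment per
# gene tree with gamma rate heterogeneity and a compositional shift on the
# long-stemmed fast clan. Everything downstream reads these files.

suppressMessages(library(orthosignal))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(n_orthogroups = 100L, comp_shift = 0.3,
                       dropout = 0.25, violation_rate = 0.75,
                       n_violating_moves = 3L, seed = 2026L)

species <- simulate_species_tree(spec)
writeLines(write_newick(species), file.path(out, "species_tree.nwk"))
write_clans(default_clans(spec), file.path(out, "clans.tsv"))

gt <- simulate_gene_trees(species, spec)
writeLines(vapply(gt$trees, write_newick, character(1)),
           file.path(out, "gene_trees.nwk"))
write.table(gt$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dir.create(file.path(out, "alignments"), showWarnings = FALSE)
for (i in seq_along(gt$trees)) {
  aln <- simulate_alignment(gt$trees[[i]], spec,
                            seed = spec$seed + 100L + i)
  write_alignment(aln, file.path(out, "alignments",
                                 paste0(names(gt$trees)[i], ".fasta")))
}

cat(sprintf("simulated %d taxa, %d orthogroups (%d with violations, %d resampled)\n",
            length(species$tip.label), spec$n_orthogroups,
            sum(gt$truth$violating), sum(gt$truth$resamples > 0)))
cat("wrote species tree, gene trees, truth table and alignments under",
    out, "\n")
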