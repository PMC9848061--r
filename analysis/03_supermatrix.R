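#!/usr/bin/env Rscript
# Stage 3: supermatrix assembly.
#
# Concatenates the full and the clan-filtered orthogroup sets into
# partitioned supermatrices, removes constant sites (as done before
# site-heterogeneous Bayesian analysis), and writes an outgroup-restricted
# variant of the filtered matrix.

suppressMessages(library(orthosignal))

syn <- "results/synthetic"
out <- "results/supermatrix"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

retained <- readLines("results/clan_filter/retained_orthogroups.txt")
files <- list.files(file.path(syn, "alignments"), full.names = TRUE)
ogs <- lapply(files, read_alignment)
names(ogs) <- sub("\\.fasta$", "", basename(files))

build <- function(set, label) {
  sm <- concatenate(ogs[set])
  sm_dc <- remove_constant_sites(sm)
  write_alignment(sm_dc$alignment, file.path(out, paste0(label, ".fasta")))
  write_partitions(sm_dc, file.path(out, paste0(label, ".partitions")),
                   model = "LG")
  write_occupancy(sm_dc, file.path(out, paste0(label, "_occupancy.tsv")))
  cat(sprintf("%s: %d taxa x %d sites (%d before constant-site removal), %d partitions\n",
              label, nrow(sm_dc$alignment), ncol(sm_dc$alignment),
              ncol(sm$alignment), nrow(sm_dc$partitions)))
  sm_dc
}

full <- build(names(ogs), "original")
filt <- build(retained, "filtered")

# outgroup-restricted variant: drop the outgroup clan entirely
clans <- read_clans(file.path(syn, "clans.tsv"))
keep <- setdiff(rownames(filt$alignment), clans$Outgroup)
restricted <- subset_taxa(filt, keep)
write_alignment(restricted$alignment,
                file.path(out, "filtered_no_outgroup.fasta"))
cat(sprintf("outgroup-restricted matrix: %d taxa x %d sites\n",
            nrow(restricted$alignment), ncol(restricted$alignment)))
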