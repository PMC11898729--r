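#!/usr/bin/env Rscript

## Step 1: simulate the reference population and its long reads.
##
## Emits a truth-labelled population of streamlined genomes, each carrying a
## single O-antigen biosynthetic cluster (OBC) between the rRNA operon and
## the 5S gene, fragmented into completeness classes as in SAG assemblies,
## plus 23S-anchored CCS-style long reads. Everything downstream reads these
## files; the seed makes the whole workflow reproducible.

suppressMessages(library(obctools))

cfg <- sim_config(n_species = 3, genomes_per_species = 12,
                  n_island_types = 12, p_hgt = 0.05, n_reads = 250,
                  seed = 7)
pop <- simulate_population(cfg)
reads <- emit_long_reads(pop)

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
write_population(pop, "results/sim")
write_reads(reads, "results/sim")

cat("Simulated", length(pop$genomes), "genomes in",
    cfg$n_species, "genomospecies;",
    length(unique(pop$truth$genomes$type_id)), "island types in use;",
    nrow(pop$truth$hgt), "planted HGT event(s);",
    sum(reads$truth$anchored), "of", length(reads$seqs),
    "reads anchored on the 23S.\n")
cat("Fragmentation classes:\n")
print(table(pop$truth$genomes$frag_class))
cat("Files under results/sim/\n")
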