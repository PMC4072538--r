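#!/usr/bin/env Rscript
# Build the synthetic stand-in for the consortium's mutation discovery: an
# annotated genome plus a 580-SNP all-mutations table whose spectrum, effect
# classes and lineage partition match the published totals. Downstream
# scripts recompute every summary from these files.

suppressMessages(library(consortiumseq))
seed <- 20140626L
out <- "results/community"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

st <- simulate_study_mutations(seed)
write_genome(st$genome, file.path(out, "ancestor.fa"),
             file.path(out, "ancestor.gff3"))
write_truth(st$truth, file.path(out, "all_mutations.tsv"))
write.table(st$mutations, file.path(out, "mutations_by_strain.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d bp, %d genes\n", nchar(st$genome$seq),
            nrow(st$genome$genes)))
cat(sprintf("planted SNP loci: %d (per-strain rows: %d)\n",
            nrow(st$truth), nrow(st$mutations)))
cat("branch counts:\n")
print(st$lineage$branch_counts)
cat("outputs in", out, "\n")
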