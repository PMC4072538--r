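#!/usr/bin/env Rscript
# Annotate the all-mutations table and tabulate the substitution spectrum
# (directed and strand-collapsed classes), codon effects, and genes hit more
# than once. Run 01_simulate_community.R first.

suppressMessages(library(consortiumseq))
out <- "results/community"
st_genome <- read_genome(file.path(out, "ancestor.fa"),
                         file.path(out, "ancestor.gff3"))
truth <- read_truth(file.path(out, "all_mutations.tsv"))

ann <- annotate_mutations(st_genome, truth)
write.table(ann, file.path(out, "annotated_mutations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sp <- summarize_spectrum(ann)
write.table(sp, file.path(out, "spectrum.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("mutation spectrum (zero rows omitted):\n")
print(sp[sp$count > 0, ], row.names = FALSE)

hits <- multi_hit_report(annotate_mutations(st_genome,
                                            truth_by_strain(truth)))
write.table(hits$genes, file.path(out, "multi_hit_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\ngenes with more than one SNP: %d\n", nrow(hits$genes)))
print(head(hits$genes), row.names = FALSE)
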