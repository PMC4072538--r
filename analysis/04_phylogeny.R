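#!/usr/bin/env Rscript
# SNP-sharing structure of the four evolved clones: partition the loci by
# carrier set, search all 15 rooted topologies by Fitch parsimony with the
# ancestor fixed all-absent, and write the tree with per-branch SNP counts.
# Run 01_simulate_community.R first.

suppressMessages(library(consortiumseq))
out <- "results/community"
truth <- read_truth(file.path(out, "all_mutations.tsv"))

pm <- presence_matrix(truth_by_strain(truth))
pc <- partition_counts(pm)
write.table(pc, file.path(out, "partition.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("loci by carrier set:\n")
print(pc, row.names = FALSE)
cat(sprintf("\nprivate to CV103: %d; shared by all four: %d; CV115/CV116 differ by %d\n",
            partition_subset(pc, "CV103"),
            partition_subset(pc, c("CV101", "CV103", "CV115", "CV116")),
            partition_subset(pc, "CV115") + partition_subset(pc, "CV116")))

search <- best_topology(pm)
cat(sprintf("\nbest topology (of %d): %s, parsimony length %d on %d loci\n",
            length(search$scores), search$best$topology,
            search$best$total_length, search$best$n_loci))
if (length(search$ties) > 1) {
  cat("co-optimal topologies:\n"); print(search$ties)
}
print(search$best)
write_clado_newick(search$best, file.path(out, "tree.nwk"),
                   ancestor_name = "JA122")
writeLines(render_clado_tree(search$best, "JA122"),
           file.path(out, "tree.txt"))
cat("tree written to", file.path(out, "tree.nwk"), "\n")
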