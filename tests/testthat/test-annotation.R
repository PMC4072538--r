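# construct a genome by hand around known codons
hand_genome <- function(cds_codons, strand = "+", pad = 30,
                        chrom = "chr") {
  cds <- paste0(cds_codons, collapse = "")
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  }
  left <- strrep("A", pad); right <- strrep("A", pad)
  seq <- paste0(left, cds, right)
  genes <- data.frame(gene_id = "g001", strand = strand,
                      start = pad + 1L,
                      end = pad + nchar(cds),
                      stringsAsFactors = FALSE)
  structure(list(seq = seq, chrom = chrom, genes = genes),
            class = "ancestral_genome")
}

test_that("substitutions are classified by type, direction and collapse", {
  expect_equal(unlist(classify_substitution("G", "A")),
               c(subst_type = "transition", ref_strand_class = "G->A",
                 collapsed_class = "G:C->A:T"))
  expect_equal(unlist(classify_substitution("G", "T")),
               c(subst_type = "transversion", ref_strand_class = "G->T",
                 collapsed_class = "G:C->T:A"))
  # strand symmetry: C->A collapses with G->T
  expect_equal(classify_substitution("C", "A")$collapsed_class, "G:C->T:A")
  expect_equal(classify_substitution("C", "A")$subst_type, "transversion")
  # transitions iff A<->G or C<->T
  for (pair in list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))) {
    expect_equal(classify_substitution(pair[1], pair[2])$subst_type,
                 "transition")
  }
  expect_error(classify_substitution("G", "G"), "differ")
  expect_error(classify_substitution("X", "A"), "invalid")
})

test_that("an amber nonsense in codon 26 annotates as E26*, GAG->TAG", {
  codons <- c("ATG", rep("GCT", 24), "GAG", rep("CTT", 10), "TAA")
  g <- hand_genome(codons)
  pos <- g$genes$start + 25 * 3          # first base of codon 26
  expect_equal(genome_base(g, pos), "G")
  ann <- annotate_mutations(g, data.frame(chrom = "chr", pos = pos,
                                          ref = "G", alt = "T"))
  expect_equal(ann$region, "CDS")
  expect_equal(ann$effect, "nonsense")
  expect_equal(ann$aa_change, "E26*")
  expect_equal(ann$codon_change, "GAG->TAG")
  expect_equal(ann$collapsed_class, "G:C->T:A")
})

test_that("a third-position ACC->ACA change is synonymous (T12T)", {
  codons <- c("ATG", rep("GGT", 10), "ACC", rep("CTT", 5), "TGA")
  g <- hand_genome(codons)
  pos <- g$genes$start + 11 * 3 + 2      # third base of codon 12
  expect_equal(genome_base(g, pos), "C")
  ann <- annotate_mutations(g, data.frame(chrom = "chr", pos = pos,
                                          ref = "C", alt = "A"))
  expect_equal(ann$effect, "synonymous")
  expect_equal(ann$aa_change, "T12T")
  expect_equal(ann$codon_change, "ACC->ACA")
})

test_that("reverse-strand genes annotate on the gene strand", {
  codons <- c("ATG", rep("GCT", 24), "GAG", rep("CTT", 10), "TAA")
  g <- hand_genome(codons, strand = "-")
  # first base of codon 26 in gene space = complement base on the genome
  pos <- g$genes$end - 25 * 3
  expect_equal(genome_base(g, pos), "C")  # G on the gene strand
  ann <- annotate_mutations(g, data.frame(chrom = "chr", pos = pos,
                                          ref = "C", alt = "A"))
  expect_equal(ann$effect, "nonsense")
  expect_equal(ann$aa_change, "E26*")
  expect_equal(ann$codon_change, "GAG->TAG")
  # the reference-strand class still reads the genome strand
  expect_equal(ann$ref_strand_class, "C->A")
  expect_equal(ann$collapsed_class, "G:C->T:A")
})

test_that("annotating a minus-strand gene mirrors its plus-strand twin", {
  codons <- c("ATG", "GAA", "TGC", "CAT", "CCG", "TTC", "TAG")
  fwd <- hand_genome(codons, strand = "+", pad = 10)
  rev <- hand_genome(codons, strand = "-", pad = 10)
  L <- nchar(fwd$seq)
  for (off in 0:(3 * length(codons) - 1)) {
    pos_f <- fwd$genes$start + off
    ref_f <- genome_base(fwd, pos_f)
    alt_f <- setdiff(c("A", "C", "G", "T"), ref_f)[2]
    a_f <- annotate_mutations(fwd, data.frame(chrom = "chr", pos = pos_f,
                                              ref = ref_f, alt = alt_f))
    # mirrored coordinate on the reverse-complement construction
    pos_r <- rev$genes$end - off
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    a_r <- annotate_mutations(rev, data.frame(chrom = "chr", pos = pos_r,
                                              ref = comp[[ref_f]],
                                              alt = comp[[alt_f]]))
    expect_equal(a_r$effect, a_f$effect)
    expect_equal(a_r$aa_change, a_f$aa_change)
    expect_equal(a_r$codon_change, a_f$codon_change)
  }
})

test_that("CDS effects match brute-force translation of the mutant protein", {
  g <- generate_annotated_genome(30000, 12, 33)
  spec <- lineage_spec("(A,B);", c(A = 150, B = 150), gc_ta_weight = 0.5)
  pl <- plant_mutations(g, spec, seed = 19)
  ann <- annotate_mutations(g, pl$truth)
  cds <- ann[ann$region == "CDS", ]
  expect_gt(nrow(cds), 20)
  translate_gene <- function(seq, gene) {
    s <- substr(seq, gene$start, gene$end)
    d <- Biostrings::DNAString(s)
    if (gene$strand == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d))
  }
  gseq <- strsplit(g$seq, "")[[1]]
  for (i in seq_len(nrow(cds))) {
    gene <- g$genes[g$genes$gene_id == cds$gene_id[i], ]
    mut <- gseq; mut[cds$pos[i]] <- cds$alt[i]
    p0 <- translate_gene(g$seq, gene)
    p1 <- translate_gene(paste0(mut, collapse = ""), gene)
    diff_at <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
    effect <- if (length(diff_at) == 0) "synonymous"
      else if (substr(p1, diff_at, diff_at) == "*") "nonsense"
      else "missense"
    expect_equal(cds$effect[i], effect)
    if (length(diff_at) == 1) {
      expect_equal(cds$aa_change[i],
                   paste0(substr(p0, diff_at, diff_at), diff_at,
                          substr(p1, diff_at, diff_at)))
    }
  }
})

test_that("mutations outside the genome or off-reference are errors", {
  g <- generate_annotated_genome(1000, 0, 2)
  expect_error(annotate_mutations(g, data.frame(chrom = "chr", pos = 2000L,
                                                ref = "A", alt = "C")),
               "outside")
  ref <- genome_base(g, 10)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(ref, wrong))[1]
  expect_error(annotate_mutations(g, data.frame(chrom = "chr", pos = 10L,
                                                ref = wrong, alt = alt)),
               "ref mismatch")
})

test_that("spectrum tables satisfy their counting invariants", {
  g <- generate_annotated_genome(40000, 15, 44)
  spec <- lineage_spec("(A,B);", c(A = 200, B = 100), gc_ta_weight = 0.7)
  pl <- plant_mutations(g, spec, seed = 27)
  ann <- annotate_mutations(g, pl$truth)
  sp <- summarize_spectrum(ann)
  total <- spectrum_count(sp, "SNPs")
  expect_equal(total, 300L)
  directed <- sp$count[grepl(" to ", sp$row)]
  expect_equal(sum(directed), total)
  coding <- spectrum_count(sp, "SNPs in coding regions")
  expect_equal(spectrum_count(sp, "SNPs causing synonymous mutations") +
                 spectrum_count(sp, "SNPs causing missense mutations") +
                 spectrum_count(sp, "SNPs causing nonsense mutations"),
               coding)
  expect_equal(sp$pct, round(100 * sp$count / total, 1))
  # duplicate strain rows must not double-count loci
  sp2 <- summarize_spectrum(annotate_mutations(g, truth_by_strain(pl$truth)))
  expect_equal(sp2$count, sp$count)
})

test_that("an empty mutation table yields an all-zero spectrum", {
  g <- generate_annotated_genome(1000, 0, 2)
  ann <- annotate_mutations(g, data.frame(chrom = character(0),
                                          pos = integer(0),
                                          ref = character(0),
                                          alt = character(0)))
  sp <- summarize_spectrum(ann)
  expect_true(all(sp$count == 0))
})

test_that("multi-hit reports count genes and transcription units", {
  ann <- data.frame(strain = c("A", "A", "B", "A"),
                    chrom = "chr", pos = c(10L, 20L, 30L, 40L),
                    ref = "G", alt = "T",
                    gene_id = c("g1", "g1", "g2", "g3"),
                    stringsAsFactors = FALSE)
  rep1 <- multi_hit_report(ann)
  expect_equal(rep1$genes$gene_id, "g1")
  expect_equal(rep1$genes$n_snps, 2L)
  expect_equal(rep1$genes$n_A, 2L)
  expect_equal(rep1$genes$n_B, 0L)

  # a TU grouping two single-hit genes becomes a 2-hit TU
  tu <- data.frame(gene_id = c("g1", "g2", "g3"),
                   tu_id = c("tu1", "tu23", "tu23"),
                   stringsAsFactors = FALSE)
  rep2 <- multi_hit_report(ann[3:4, ], tu_map = tu)
  expect_equal(nrow(rep2$genes), 0)
  expect_equal(rep2$tus$tu_id, "tu23")
  expect_equal(rep2$tus$n_snps, 2L)

  # genes missing from the map fall back to their own TU, with a warning
  expect_warning(rep3 <- multi_hit_report(ann, tu_map = tu[-1, ]),
                 "missing from tu_map")
  expect_true("g1" %in% rep3$tus$tu_id)
})
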