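#' Generate a random annotated bacterial genome
#'
#' Builds a circular-agnostic DNA sequence with `n_genes` non-overlapping
#' protein-coding genes. Each CDS starts with ATG, ends with a stop codon on
#' its own strand, has length divisible by three, and is placed on a random
#' strand. The genome stands in for a reference chromosome when planting
#' mutations and simulating pileups.
#'
#' Placement partitions the sequence into `n_genes` equal windows and puts one
#' gene at a random offset inside each window, which guarantees
#' non-overlapping genes whenever the precondition
#' `length_bp >= 300 * n_genes` holds.
#'
#' @param length_bp total genome length in bp.
#' @param n_genes number of genes to place (may be 0).
#' @param seed integer seed; identical inputs give byte-identical output.
#' @param chrom chromosome name used in all downstream files.
#' @return an object of class `ancestral_genome`: list with `seq` (character
#'   scalar), `chrom`, and `genes` (data.frame: gene_id, strand, start, end;
#'   1-based closed coordinates, sorted by start).
#' @export
generate_annotated_genome <- function(length_bp, n_genes, seed,
                                      chrom = "chr") {
  stopifnot(length_bp >= 1, n_genes >= 0, n_genes == round(n_genes))
  if (n_genes > 0 && length_bp < 300 * n_genes) {
    stop(sprintf(
      "cannot place %d non-overlapping genes in %d bp (need >= %d bp)",
      n_genes, length_bp, 300 * n_genes), call. = FALSE)
  }
  set.seed(seed)
  seq <- sample(BASES, length_bp, replace = TRUE)

  genes <- data.frame(gene_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (n_genes > 0) {
    win <- floor(length_bp / n_genes)
    codon_tab <- all_codons()
    sense <- codon_tab$codon[!codon_tab$is_stop]
    stops <- codon_tab$codon[codon_tab$is_stop]
    for (i in seq_len(n_genes)) {
      win_start <- (i - 1L) * win + 1L
      # codons including start+stop; keep a 2 bp margin inside the window
      max_codons <- min(300L, (win - 2L) %/% 3L)
      n_codon <- sample(34:max_codons, 1L)
      len <- 3L * n_codon
      offset <- sample.int(win - len - 1L, 1L)
      start <- win_start + offset
      end <- start + len - 1L
      strand <- sample(c("+", "-"), 1L)
      cds <- c("ATG",
               sample(sense, n_codon - 2L, replace = TRUE),
               sample(stops, 1L))
      cds <- unlist(strsplit(paste0(cds, collapse = ""), ""), use.names = FALSE)
      if (strand == "-") cds <- rev(comp_base(cds))
      seq[start:end] <- cds
      genes[i, ] <- list(sprintf("g%03d", i), strand, start, end)
    }
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  }

  structure(list(seq = paste0(seq, collapse = ""), chrom = chrom,
                 genes = genes),
            class = "ancestral_genome")
}

all_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), aa = unname(gc), is_stop = gc == "*",
             stringsAsFactors = FALSE)
}

#' @export
print.ancestral_genome <- function(x, ...) {
  cat(sprintf("<ancestral_genome> %s: %d bp, %d genes\n",
              x$chrom, nchar(x$seq), nrow(x$genes)))
  invisible(x)
}

genome_length <- function(genome) nchar(genome$seq)

#' Extract bases from a genome sequence
#'
#' @param genome an `ancestral_genome` (or any list with a `seq` string).
#' @param pos 1-based positions.
#' @return character vector of bases.
#' @export
genome_base <- function(genome, pos) {
  if (length(pos) == 0) return(character(0))
  stopifnot(all(pos >= 1), all(pos <= nchar(genome$seq)))
  substring(genome$seq, pos, pos)
}

#' Write a genome as FASTA plus GFF3
#'
#' FASTA is written through Biostrings; gene models go out as `CDS` features
#' (frame 0, phase 0) through rtracklayer so any GFF3-aware tool can read
#' them back.
#'
#' @param genome an `ancestral_genome`.
#' @param fasta,gff3 output paths.
#' @return invisibly, `c(fasta, gff3)`.
#' @export
write_genome <- function(genome, fasta, gff3) {
  dna <- Biostrings::DNAStringSet(structure(genome$seq, names = genome$chrom))
  Biostrings::writeXStringSet(dna, fasta, width = 70L)
  if (nrow(genome$genes) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$chrom,
      ranges = IRanges::IRanges(genome$genes$start, genome$genes$end),
      strand = genome$genes$strand,
      type = "CDS", source = "consortiumseq", phase = 0L,
      ID = genome$genes$gene_id)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(c(fasta, gff3))
}

#' Read a genome from FASTA plus GFF3
#'
#' @param fasta,gff3 paths written by [write_genome()] (or equivalent files
#'   with `CDS` features carrying an `ID` attribute).
#' @return an `ancestral_genome`.
#' @export
read_genome <- function(fasta, gff3) {
  dna <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  genes <- data.frame(
    gene_id = as.character(gr$ID),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(seq = as.character(dna[[1]]),
                 chrom = sub("\\s.*$", "", names(dna)[1]),
                 genes = genes),
            class = "ancestral_genome")
}
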