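# Mutation annotation: genomic region, codon-level effect, and substitution
# spectrum. Effects use the standard genetic code (translation table 1);
# nonsense means the mutant codon is one of TAA/TAG/TGA. Directed substitution
# classes are reported by reference-strand base ("G->T" and "C->A" are
# distinct rows) together with the strand-collapsed base-pair class
# ("G:C->T:A" for both).

#' Classify a base substitution
#'
#' @param ref,alt reference and variant bases (vectors of A/C/G/T; `ref !=
#'   alt` elementwise).
#' @return data.frame: subst_type (`transition`/`transversion`),
#'   ref_strand_class (e.g. `"G->T"`), collapsed_class (strand-symmetric,
#'   e.g. `"G:C->T:A"`).
#' @export
classify_substitution <- function(ref, alt) {
  if (length(ref) == 0) {
    return(data.frame(subst_type = character(0),
                      ref_strand_class = character(0),
                      collapsed_class = character(0),
                      stringsAsFactors = FALSE))
  }
  ref <- toupper(ref); alt <- toupper(alt)
  assert_bases(ref, "ref"); assert_bases(alt, "alt")
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- c("A", "G")
  transition <- (ref %in% purine) == (alt %in% purine)
  # collapse to the pyrimidine-or-purine-pair representation anchored on G/A
  anchor_ref <- ifelse(ref %in% c("C", "T"), comp_base(ref), ref)
  anchor_alt <- ifelse(ref %in% c("C", "T"), comp_base(alt), alt)
  collapsed <- paste0(anchor_ref, ":", comp_base(anchor_ref), "->",
                      anchor_alt, ":", comp_base(anchor_alt))
  data.frame(subst_type = ifelse(transition, "transition", "transversion"),
             ref_strand_class = paste0(ref, "->", alt),
             collapsed_class = collapsed, stringsAsFactors = FALSE)
}

AA1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

translate_codon <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Annotate mutations against a genome's gene models
#'
#' For each SNP: locates the containing gene (genes are non-overlapping),
#' extracts the affected codon respecting gene strand (reverse-strand genes
#' read on the reverse complement), and reports the codon change, amino-acid
#' change with 1-based residue numbering (`*` = stop), and effect class
#' (synonymous / missense / nonsense). Intergenic SNPs get `region =
#' "intergenic"` and no effect. Substitution classes are always reported on
#' the reference strand.
#'
#' @param genome an `ancestral_genome`.
#' @param muts data.frame with columns chrom, pos, ref, alt (a `strain`
#'   column, if present, is carried through).
#' @return `muts` with annotation columns appended: region, gene_id, effect,
#'   aa_change, codon_change, subst_type, ref_strand_class, collapsed_class.
#' @export
annotate_mutations <- function(genome, muts) {
  stopifnot(inherits(genome, "ancestral_genome"),
            all(c("pos", "ref", "alt") %in% names(muts)))
  n <- nrow(muts)
  if (any(muts$pos < 1 | muts$pos > genome_length(genome))) {
    stop("mutation position outside genome", call. = FALSE)
  }
  obs_ref <- genome_base(genome, muts$pos)
  if (any(obs_ref != muts$ref)) {
    bad <- which(obs_ref != muts$ref)[1]
    stop(sprintf("ref mismatch at %d: genome has %s, table says %s",
                 muts$pos[bad], obs_ref[bad], muts$ref[bad]), call. = FALSE)
  }

  cls <- classify_substitution(muts$ref, muts$alt)
  genes <- genome$genes
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  effect <- rep(NA_character_, n)
  aa_change <- rep(NA_character_, n)
  codon_change <- rep(NA_character_, n)

  if (nrow(genes) > 0 && n > 0) {
    gi <- findInterval(muts$pos, genes$start)
    inside <- gi >= 1 & gi <= nrow(genes) & muts$pos <= genes$end[pmax(gi, 1)]
    idx <- which(inside)
    if (length(idx) > 0) {
      g <- genes[gi[idx], , drop = FALSE]
      region[idx] <- "CDS"
      gene_id[idx] <- g$gene_id
      # offset within the CDS in reading direction
      off <- ifelse(g$strand == "+", muts$pos[idx] - g$start,
                    g$end - muts$pos[idx])
      codon_i <- off %/% 3L            # 0-based codon index
      in_codon <- off %% 3L            # 0-based position within codon
      # genomic span of the codon, then orient by strand
      cstart <- ifelse(g$strand == "+", g$start + 3L * codon_i,
                       g$end - 3L * codon_i - 2L)
      c1 <- genome_base(genome, cstart)
      c2 <- genome_base(genome, cstart + 1L)
      c3 <- genome_base(genome, cstart + 2L)
      ref_codon <- ifelse(g$strand == "+", paste0(c1, c2, c3),
                          paste0(comp_base(c3), comp_base(c2), comp_base(c1)))
      alt_gene_strand <- ifelse(g$strand == "+", muts$alt[idx],
                                comp_base(muts$alt[idx]))
      mut_codon <- ref_codon
      substr(mut_codon, in_codon + 1L, in_codon + 1L) <- alt_gene_strand
      ref_aa <- translate_codon(ref_codon)
      alt_aa <- translate_codon(mut_codon)
      effect[idx] <- ifelse(alt_aa == ref_aa, "synonymous",
                            ifelse(alt_aa == "*", "nonsense", "missense"))
      aa_change[idx] <- paste0(ref_aa, codon_i + 1L, alt_aa)
      codon_change[idx] <- paste0(ref_codon, "->", mut_codon)
    }
  }

  out <- muts
  out$region <- region
  out$gene_id <- gene_id
  out$effect <- effect
  out$aa_change <- aa_change
  out$codon_change <- codon_change
  out$subst_type <- cls$subst_type
  out$ref_strand_class <- cls$ref_strand_class
  out$collapsed_class <- cls$collapsed_class
  out
}

#' @rdname annotate_mutations
#' @export
annotate_mutation <- annotate_mutations

#' Summarise a mutation table into a spectrum table
#'
#' Counts SNP loci (not per-strain occurrences: rows with identical
#' chrom/pos/ref/alt are one locus) by region, effect and directed
#' substitution class, with percentages of the SNP total to one decimal.
#'
#' @param ann annotated mutation data.frame from [annotate_mutations()].
#' @return a `spectrum_table`: data.frame with columns row, count, pct.
#' @export
summarize_spectrum <- function(ann) {
  key_cols <- intersect(c("chrom", "pos", "ref", "alt"), names(ann))
  loci <- ann[!duplicated(ann[, key_cols, drop = FALSE]), , drop = FALSE]
  total <- nrow(loci)
  cnt <- function(x) sum(x, na.rm = TRUE)
  rows <- c(
    "SNPs" = total,
    "SNPs in coding regions" = cnt(loci$region == "CDS"),
    "SNPs causing synonymous mutations" = cnt(loci$effect == "synonymous"),
    "SNPs causing missense mutations" = cnt(loci$effect == "missense"),
    "SNPs causing nonsense mutations" = cnt(loci$effect == "nonsense"))
  dir_counts <- vapply(DIRECTED_CLASSES,
                       function(cl) cnt(loci$ref_strand_class == cl), 0L)
  purine <- c("A", "G")
  dir_ref <- substr(DIRECTED_CLASSES, 1, 1)
  dir_alt <- substr(DIRECTED_CLASSES, 4, 4)
  kind <- ifelse((dir_ref %in% purine) == (dir_alt %in% purine),
                 "transitions", "transversions")
  names(dir_counts) <- sprintf("%s to %s %s", dir_ref, dir_alt, kind)
  rows <- c(rows, dir_counts)
  collapsed <- vapply(COLLAPSED_CLASSES,
                      function(cl) cnt(loci$collapsed_class == cl), 0L)
  names(collapsed) <- paste("collapsed", COLLAPSED_CLASSES)
  rows <- c(rows, collapsed)
  out <- data.frame(row = names(rows), count = as.integer(rows),
                    pct = if (total > 0) round(100 * rows / total, 1) else 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("spectrum_table", "data.frame")
  out
}

#' Look up one spectrum-table count
#' @param spectrum a [summarize_spectrum()] table.
#' @param row row label.
#' @return integer count.
#' @export
spectrum_count <- function(spectrum, row) {
  i <- match(row, spectrum$row)
  if (is.na(i)) stop("no spectrum row: ", row, call. = FALSE)
  spectrum$count[i]
}

#' Report genes and transcription units hit by more than one SNP
#'
#' @param ann annotated mutation data.frame; needs `gene_id` and, for
#'   per-strain columns, `strain`.
#' @param tu_map optional data.frame (gene_id, tu_id) assigning genes to
#'   transcription units. Genes absent from the map are treated as their own
#'   unit, with a warning.
#' @return list with `genes` (gene_id, n_snps, per-strain counts; only rows
#'   with n_snps >= 2) and, when `tu_map` is given, `tus` in the same shape.
#' @export
multi_hit_report <- function(ann, tu_map = NULL) {
  cds <- ann[!is.na(ann$gene_id), , drop = FALSE]
  count_by <- function(df, key) {
    if (nrow(df) == 0) {
      tb <- data.frame(key = character(0), n_snps = integer(0),
                       stringsAsFactors = FALSE)
      names(tb)[1] <- key
      return(tb)
    }
    tb <- as.data.frame(table(df[[key]]), stringsAsFactors = FALSE)
    names(tb) <- c(key, "n_snps")
    if ("strain" %in% names(df)) {
      per <- table(df[[key]], df$strain)
      for (s in colnames(per)) {
        tb[[paste0("n_", s)]] <- as.integer(per[tb[[key]], s])
      }
    }
    tb <- tb[tb$n_snps >= 2, , drop = FALSE]
    tb[order(-tb$n_snps, tb[[key]]), , drop = FALSE]
  }
  genes <- count_by(cds, "gene_id")
  rownames(genes) <- NULL
  out <- list(genes = genes)
  if (!is.null(tu_map)) {
    stopifnot(all(c("gene_id", "tu_id") %in% names(tu_map)))
    tu <- tu_map$tu_id[match(cds$gene_id, tu_map$gene_id)]
    missing <- is.na(tu)
    if (any(missing)) {
      warning(sprintf("%d gene(s) missing from tu_map; treated as own TU: %s",
                      length(unique(cds$gene_id[missing])),
                      paste(unique(cds$gene_id[missing]), collapse = ",")))
      tu[missing] <- cds$gene_id[missing]
    }
    cds$tu_id <- tu
    tus <- count_by(cds, "tu_id")
    rownames(tus) <- NULL
    out$tus <- tus
  }
  out
}
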