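# Study-shaped synthetic mutation set.
#
# The resequencing study this package emulates reports only summary counts of
# its mutation discovery (spectrum, effect classes, lineage partition); the
# underlying reads were not deposited. simulate_study_mutations() therefore
# generates a synthetic stand-in with exactly those marginal totals, planted
# on a synthetic genome, so every downstream tabulation can be recomputed
# from first principles: 580 SNP loci across four evolved strains and their
# ancestor, with a lineage partition of 428 private to the hypermutator
# strain, 1 SNP shared by all four strains, the two sister strains separated
# by exactly 2 SNPs; a spectrum of 293 G->T and 285 C->A transversions plus
# one G->A and one C->T transition (578/580 = 99.7% in the collapsed
# G:C->T:A class); and 502 coding SNPs comprising 335 missense, 39 nonsense
# and 128 synonymous changes.

STUDY_STRAINS <- c("CV101", "CV103", "CV115", "CV116")
STUDY_ANCESTOR <- "JA122"
STUDY_TOPOLOGY <- "(((CV115,CV116),CV101),CV103);"

#' Paper-shaped lineage specification
#'
#' The printed branch facts fix the hypermutator-private count (428), the
#' stem (1 SNP shared by all four strains) and the sister-pair symmetric
#' difference (2, one private SNP each); the three remaining branch counts
#' are not printed and are fixed here once at plausible values so the total
#' is 580.
#'
#' @param gc_ta_weight weight of the G:C->T:A class (0.997 in the study).
#' @return a [lineage_spec()].
#' @export
study_lineage_spec <- function(gc_ta_weight = 0.997) {
  lineage_spec(
    STUDY_TOPOLOGY,
    branch_counts = c(
      "CV103" = 428L,
      "CV101,CV103,CV115,CV116" = 1L,   # stem: shared by all four
      "CV101,CV115,CV116" = 25L,
      "CV115,CV116" = 64L,
      "CV101" = 60L,
      "CV115" = 1L,
      "CV116" = 1L),
    gc_ta_weight = gc_ta_weight)
}

# marginal targets of the synthetic all-mutations table
study_targets <- function() {
  list(
    directed = c("G->T" = 293L, "C->A" = 285L, "G->A" = 1L, "C->T" = 1L),
    effects = c(synonymous = 128L, missense = 335L, nonsense = 39L,
                intergenic = 78L))
}

# joint (class x effect) allocation consistent with both margins
study_allocation <- function() {
  alloc <- rbind(
    "G->T" = c(synonymous = 65L, missense = 169L, nonsense = 20L,
               intergenic = 39L),
    "C->A" = c(synonymous = 63L, missense = 164L, nonsense = 19L,
               intergenic = 39L),
    "G->A" = c(synonymous = 0L, missense = 1L, nonsense = 0L,
               intergenic = 0L),
    "C->T" = c(synonymous = 0L, missense = 1L, nonsense = 0L,
               intergenic = 0L))
  tg <- study_targets()
  stopifnot(all(rowSums(alloc) == tg$directed[rownames(alloc)]),
            all(colSums(alloc) == tg$effects[colnames(alloc)]))
  alloc
}

#' Generate the study-shaped synthetic mutation table
#'
#' Builds a synthetic annotated genome, then plants 580 SNPs whose joint
#' (substitution class x codon effect) composition and lineage partition
#' match the study's printed totals exactly. Three biologically anchored
#' placements are honoured: the single SNP shared by all four strains is
#' intergenic (a regulatory-operator analogue), and the two SNPs separating
#' the sister strains are one synonymous and one missense change.
#'
#' @param seed integer seed.
#' @param genome_length,n_genes synthetic genome dimensions; the defaults
#'   leave ample eligible sites for every class-effect cell.
#' @return list with `genome` (an `ancestral_genome`), `truth` (580-row
#'   locus table: chrom, pos, ref, alt, carriers), `mutations` (per-strain
#'   expansion: strain, chrom, pos, ref, alt) and `lineage` (the
#'   [study_lineage_spec()]).
#' @export
simulate_study_mutations <- function(seed, genome_length = 120000L,
                                     n_genes = 120L) {
  genome <- generate_annotated_genome(genome_length, n_genes,
                                      seed = stage_seed(seed, "study:genome"))
  set.seed(stage_seed(seed, "study:plant"))
  alloc <- study_allocation()

  # effect of every candidate substitution, per directed class
  gseq <- strsplit(genome$seq, "")[[1]]
  pools <- list()
  for (cl in rownames(alloc)) {
    ref <- substr(cl, 1, 1); alt <- substr(cl, 4, 4)
    pos <- which(gseq == ref)
    cand <- data.frame(chrom = genome$chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
    ann <- annotate_mutations(genome, cand)
    eff <- ifelse(ann$region == "intergenic", "intergenic", ann$effect)
    pools[[cl]] <- split(ann$pos, eff)
  }

  used <- logical(length(gseq))
  rows <- list()
  for (cl in rownames(alloc)) {
    for (eff in colnames(alloc)) {
      need <- alloc[cl, eff]
      if (need == 0L) next
      avail <- setdiff(pools[[cl]][[eff]], which(used))
      if (length(avail) < need) {
        stop(sprintf("not enough %s sites with effect %s: need %d, have %d",
                     cl, eff, need, length(avail)), call. = FALSE)
      }
      pick <- if (length(avail) == 1L) avail else sample(avail, need)
      pick <- pick[seq_len(need)]
      used[pick] <- TRUE
      rows[[paste(cl, eff)]] <- data.frame(
        chrom = genome$chrom, pos = pick,
        ref = substr(cl, 1, 1), alt = substr(cl, 4, 4),
        effect_planted = eff, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL

  # branch assignment: anchored placements first, the rest shuffled
  lineage <- study_lineage_spec()
  bc <- lineage$branch_counts
  branch <- rep(NA_character_, nrow(truth))
  pick_one <- function(pool) {
    free <- which(is.na(branch) & pool)
    free[sample.int(length(free), 1L)]
  }
  branch[pick_one(truth$effect_planted == "intergenic")] <-
    "CV101,CV103,CV115,CV116"                       # stem: operator analogue
  branch[pick_one(truth$effect_planted == "synonymous")] <- "CV115"
  branch[pick_one(truth$effect_planted == "missense")] <- "CV116"
  remaining <- bc
  for (b in c("CV101,CV103,CV115,CV116", "CV115", "CV116")) {
    remaining[b] <- remaining[b] - 1L
  }
  free <- which(is.na(branch))
  branch[sample(free)] <- rep(names(remaining), remaining)
  truth$carriers <- branch

  truth <- truth[order(truth$pos), c("chrom", "pos", "ref", "alt",
                                     "carriers"), drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, truth = truth,
       mutations = truth_by_strain(truth), lineage = lineage)
}
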