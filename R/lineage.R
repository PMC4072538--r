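# Lineage-structured mutation planting.
#
# A lineage spec describes a rooted clonal genealogy: the ancestor sits at the
# root, evolved strains at the tips, and every branch carries a number of
# mutations to plant. A mutation on a branch is inherited by exactly the tips
# below that branch, so each branch is identified by its carrier set. The
# substitution spectrum is parameterised by the weight of the strand-collapsed
# G:C->T:A transversion class, the signature of MutY/MutM base-excision-repair
# defects.

#' Construct a lineage specification
#'
#' @param newick rooted tree over the evolved strains, e.g.
#'   `"(((CV115,CV116),CV101),CV103);"`. The ancestor is implicit above the
#'   root, so a stem branch exists whose carrier set is all tips.
#' @param branch_counts named integer vector of mutations per branch; names
#'   are carrier sets as comma-joined sorted tip names (e.g. `"CV115,CV116"`,
#'   or `"CV101,CV103,CV115,CV116"` for the stem). Branches absent from the
#'   vector get 0.
#' @param gc_ta_weight spectrum weight of the G:C->T:A class; the remaining
#'   weight is spread uniformly over the other five collapsed classes unless
#'   `spectrum` is given.
#' @param spectrum optional full named weight vector over
#'   `COLLAPSED_CLASSES`; must sum to 1.
#' @return an object of class `lineage_spec`.
#' @export
lineage_spec <- function(newick, branch_counts, gc_ta_weight = 0.997,
                         spectrum = NULL) {
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse newick: ", newick, call. = FALSE)
  carriers <- tree_carrier_sets(tree)
  if (is.null(spectrum)) {
    spectrum <- setNames(rep((1 - gc_ta_weight) / 5, 6), COLLAPSED_CLASSES)
    spectrum["G:C->T:A"] <- gc_ta_weight
  }
  stopifnot(setequal(names(spectrum), COLLAPSED_CLASSES),
            abs(sum(spectrum) - 1) < 1e-9)
  unknown <- setdiff(names(branch_counts), carriers)
  if (length(unknown) > 0) {
    stop("branch_counts name(s) not a branch of the tree: ",
         paste(unknown, collapse = "; "), call. = FALSE)
  }
  counts <- setNames(rep(0L, length(carriers)), carriers)
  counts[names(branch_counts)] <- as.integer(branch_counts)
  structure(list(tree = tree, tips = sort(tree$tip.label),
                 branch_counts = counts,
                 spectrum = spectrum[COLLAPSED_CLASSES]),
            class = "lineage_spec")
}

# carrier set label for every branch of the rooted tree, including the stem
# branch from the (implicit) ancestor to the root of the evolved clade
tree_carrier_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, below)))
  }
  nodes <- c(seq_len(ntip), ntip + seq_len(tree$Nnode))
  labs <- vapply(nodes, function(n) paste(below(n), collapse = ","), "")
  unique(labs)  # root's label == stem branch (all tips)
}

carrier_label <- function(strains) {
  vapply(strains, function(s) paste(sort(s), collapse = ","), "")
}

#' @export
print.lineage_spec <- function(x, ...) {
  cat(sprintf("<lineage_spec> %d strains, %d planted mutations\n",
              length(x$tips), sum(x$branch_counts)))
  for (b in names(x$branch_counts)) {
    cat(sprintf("  {%s}: %d\n", b, x$branch_counts[[b]]))
  }
  invisible(x)
}

# ref bases eligible for a collapsed class, and the alt a given ref maps to
class_ref_alt <- function(collapsed) {
  tab <- list(
    "G:C->T:A" = c(G = "T", C = "A"),
    "G:C->A:T" = c(G = "A", C = "T"),
    "A:T->G:C" = c(A = "G", T = "C"),
    "A:T->C:G" = c(A = "C", T = "G"),
    "A:T->T:A" = c(A = "T", T = "A"),
    "G:C->C:G" = c(G = "C", C = "G"))
  tab[[collapsed]]
}

#' Plant lineage-structured mutations into a genome
#'
#' Draws, for every branch of the lineage, the requested number of mutations
#' at distinct genomic positions, with substitution classes sampled from the
#' spectrum. Mutations are tree-compatible by construction: a mutation's
#' carrier set is exactly the tips below its branch, so there is no homoplasy.
#'
#' @param genome an `ancestral_genome`.
#' @param spec a [lineage_spec()].
#' @param seed integer seed.
#' @return list with `truth` (data.frame: chrom, pos, ref, alt,
#'   collapsed_class, branch, carriers; one row per planted SNP, sorted by
#'   pos) and `strain_seqs` (named character vector of mutated genome
#'   sequences, one per tip).
#' @export
plant_mutations <- function(genome, spec, seed) {
  stopifnot(inherits(genome, "ancestral_genome"), inherits(spec, "lineage_spec"))
  set.seed(seed)
  total <- sum(spec$branch_counts)
  gseq <- strsplit(genome$seq, "")[[1]]

  # substitution class per mutation, sampled from the spectrum
  classes <- if (total > 0) {
    sample(COLLAPSED_CLASSES, total, replace = TRUE, prob = spec$spectrum)
  } else character(0)

  # distinct positions with a compatible reference base, per class
  pos <- integer(total)
  used <- logical(length(gseq))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    eligible <- which(gseq %in% names(class_ref_alt(cl)) & !used)
    if (length(eligible) < length(idx)) {
      stop(sprintf(
        "not enough eligible sites for class %s: need %d, have %d",
        cl, length(idx), length(eligible)), call. = FALSE)
    }
    pick <- eligible[sample.int(length(eligible), length(idx))]
    pos[idx] <- pick
    used[pick] <- TRUE
  }

  ref <- gseq[pos]
  alt <- vapply(seq_len(total),
                function(i) class_ref_alt(classes[i])[[ref[i]]], "")
  branch <- rep(names(spec$branch_counts), spec$branch_counts)

  truth <- data.frame(chrom = rep(genome$chrom, total), pos = pos, ref = ref,
                      alt = alt, collapsed_class = classes, branch = branch,
                      carriers = branch, stringsAsFactors = FALSE)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  strain_seqs <- vapply(spec$tips, function(s) {
    mine <- grepl(paste0("(^|,)", s, "(,|$)"), truth$carriers)
    sq <- gseq
    sq[truth$pos[mine]] <- truth$alt[mine]
    paste0(sq, collapse = "")
  }, "")

  list(truth = truth, strain_seqs = strain_seqs)
}

#' Write / read a truth set as TSV
#'
#' Columns: chrom, pos, ref, alt, carriers (comma-joined strain names).
#' @param truth truth data.frame from [plant_mutations()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth[, c("chrom", "pos", "ref", "alt", "carriers")], path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read_tsv(path)

#' Expand a truth/carrier table to one row per strain
#'
#' @param truth data.frame with a `carriers` column of comma-joined strains.
#' @return data.frame with a `strain` column, one row per (strain, locus).
#' @export
truth_by_strain <- function(truth) {
  carriers <- strsplit(truth$carriers, ",", fixed = TRUE)
  n <- lengths(carriers)
  out <- truth[rep(seq_len(nrow(truth)), n), , drop = FALSE]
  out$strain <- as.character(unlist(carriers))
  rownames(out) <- NULL
  out[, c("strain", setdiff(names(out), "strain"))]
}
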