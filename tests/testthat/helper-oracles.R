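# Independent oracles: deliberately naive re-implementations used only to
# cross-check the package's optimised code paths.

# -- rule-by-rule SNP filter checker from raw counts -------------------------
# Independent of call_sites_core: explicit per-rule logic, scalar arithmetic.
oracle_call_site <- function(anc, evo, params) {
  bases <- c("A", "C", "G", "T")
  cnt <- function(row, b, strand) row[[paste0(b, "_", strand)]]
  tot <- function(row, b) cnt(row, b, "fwd") + cnt(row, b, "rev")

  ref <- evo$ref
  alt <- NA_character_
  best <- 0L
  for (b in bases) {                        # alphabetical scan = tie-break
    if (b == ref) next
    if (tot(evo, b) > best) { best <- tot(evo, b); alt <- b }
  }
  reasons <- character(0)
  called_evo <- sum(vapply(bases, function(b) tot(evo, b), 0))
  called_anc <- sum(vapply(bases, function(b) tot(anc, b), 0))
  if (is.na(alt)) {
    reasons <- c(reasons, "NO_ALT")
  } else {
    evo_frac <- if (called_evo > 0) tot(evo, alt) / called_evo else 0
    anc_frac <- if (called_anc > 0) tot(anc, alt) / called_anc else 0
    if (evo_frac < params$min_evolved_frac) {
      reasons <- c(reasons, "LOW_EVOLVED_FRAC")
    }
    if (anc_frac > params$max_ancestor_frac) {
      reasons <- c(reasons, "HIGH_ANCESTOR_FRAC")
    }
    if (params$require_both_strands &&
        (cnt(evo, alt, "fwd") == 0 || cnt(evo, alt, "rev") == 0)) {
      reasons <- c(reasons, "STRAND_UNCONFIRMED")
    }
  }
  if (evo$depth < params$min_depth) reasons <- c(reasons, "LOW_DEPTH_EVOLVED")
  if (anc$depth < params$min_depth) reasons <- c(reasons, "LOW_DEPTH_ANCESTOR")
  if (evo$n_ambiguous > params$max_ambiguous ||
      anc$n_ambiguous > params$max_ambiguous) {
    reasons <- c(reasons, "EXCESS_AMBIGUOUS")
  }
  if (evo$n_deletion > params$max_deletion ||
      anc$n_deletion > params$max_deletion) {
    reasons <- c(reasons, "EXCESS_DELETION")
  }
  list(pass = length(reasons) == 0, reasons = sort(reasons), alt = alt)
}

# build a parsed-pileup site row from explicit counts
make_site <- function(ref, pos = 1L, chrom = "chr",
                      A_fwd = 0, A_rev = 0, C_fwd = 0, C_rev = 0,
                      G_fwd = 0, G_rev = 0, T_fwd = 0, T_rev = 0,
                      n_ambiguous = 0, n_deletion = 0) {
  depth <- A_fwd + A_rev + C_fwd + C_rev + G_fwd + G_rev + T_fwd + T_rev +
    n_ambiguous + n_deletion
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
             depth = as.integer(depth),
             A_fwd = as.integer(A_fwd), A_rev = as.integer(A_rev),
             C_fwd = as.integer(C_fwd), C_rev = as.integer(C_rev),
             G_fwd = as.integer(G_fwd), G_rev = as.integer(G_rev),
             T_fwd = as.integer(T_fwd), T_rev = as.integer(T_rev),
             n_ambiguous = as.integer(n_ambiguous),
             n_deletion = as.integer(n_deletion),
             stringsAsFactors = FALSE)
}

# a site where `frac_alt` of `depth` base-called reads show `alt`, split
# evenly across strands
make_alt_site <- function(ref, alt, n_alt, depth, pos = 1L,
                          alt_fwd = NULL, n_ambiguous = 0, n_deletion = 0) {
  alt_fwd <- if (is.null(alt_fwd)) n_alt %/% 2 else alt_fwd
  alt_rev <- n_alt - alt_fwd
  n_ref <- depth - n_alt
  args <- list(ref = ref, pos = pos,
               n_ambiguous = n_ambiguous, n_deletion = n_deletion)
  args[[paste0(ref, "_fwd")]] <- n_ref - n_ref %/% 2
  args[[paste0(ref, "_rev")]] <- n_ref %/% 2
  if (n_alt > 0) {
    args[[paste0(alt, "_fwd")]] <- alt_fwd
    args[[paste0(alt, "_rev")]] <- alt_rev
  }
  do.call(make_site, args)
}

# random parsed-pileup site pairs for the oracle-equivalence checks
random_site_pairs <- function(n, seed) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  rnd <- function(max) as.integer(rpois(n, 1.2) * rbinom(n, 1, 0.6))
  mk <- function() {
    df <- data.frame(chrom = "chr", pos = seq_len(n), ref = ref,
                     stringsAsFactors = FALSE)
    for (b in c("A", "C", "G", "T")) {
      df[[paste0(b, "_fwd")]] <- as.integer(rpois(n, 2))
      df[[paste0(b, "_rev")]] <- as.integer(rpois(n, 2))
    }
    df$n_ambiguous <- as.integer(rpois(n, 0.4))
    df$n_deletion <- as.integer(rpois(n, 0.4))
    cols <- setdiff(names(df), c("chrom", "pos", "ref"))
    df$depth <- as.integer(rowSums(df[, cols]))
    df[, c("chrom", "pos", "ref", "depth", cols)]
  }
  list(anc = mk(), evo = mk())
}

# vectorised but structurally independent re-derivation of the filter verdict
# (plain data-frame arithmetic rule by rule; no matrix argmax machinery)
oracle_call_frame <- function(anc, evo, params) {
  n <- nrow(evo)
  tot <- function(df, b) df[[paste0(b, "_fwd")]] + df[[paste0(b, "_rev")]]
  counts <- sapply(c("A", "C", "G", "T"), function(b) tot(evo, b))
  counts <- matrix(counts, nrow = n)
  colnames(counts) <- c("A", "C", "G", "T")
  alt <- character(n); altn <- integer(n)
  for (i in seq_len(n)) {                  # scalar scan, alphabetical ties
    best <- 0L; a <- NA_character_
    for (b in c("A", "C", "G", "T")) {
      if (b == evo$ref[i]) next
      if (counts[i, b] > best) { best <- counts[i, b]; a <- b }
    }
    alt[i] <- a; altn[i] <- best
  }
  called_evo <- rowSums(counts)
  called_anc <- tot(anc, "A") + tot(anc, "C") + tot(anc, "G") + tot(anc, "T")
  anc_altn <- ifelse(is.na(alt), 0,
                     mapply(function(i, a) if (is.na(a)) 0 else tot(anc, a)[i],
                            seq_len(n), alt))
  evo_frac <- ifelse(called_evo > 0, altn / called_evo, 0)
  anc_frac <- ifelse(called_anc > 0, anc_altn / called_anc, 0)
  evo_alt_fwd <- mapply(function(i, a) if (is.na(a)) 0L
                        else evo[[paste0(a, "_fwd")]][i], seq_len(n), alt)
  evo_alt_rev <- mapply(function(i, a) if (is.na(a)) 0L
                        else evo[[paste0(a, "_rev")]][i], seq_len(n), alt)

  fail <- cbind(
    NO_ALT = is.na(alt),
    LOW_EVOLVED_FRAC = !is.na(alt) & evo_frac < params$min_evolved_frac,
    HIGH_ANCESTOR_FRAC = !is.na(alt) & anc_frac > params$max_ancestor_frac,
    LOW_DEPTH_EVOLVED = evo$depth < params$min_depth,
    LOW_DEPTH_ANCESTOR = anc$depth < params$min_depth,
    STRAND_UNCONFIRMED = params$require_both_strands & !is.na(alt) &
      (evo_alt_fwd == 0 | evo_alt_rev == 0),
    EXCESS_AMBIGUOUS = evo$n_ambiguous > params$max_ambiguous |
      anc$n_ambiguous > params$max_ambiguous,
    EXCESS_DELETION = evo$n_deletion > params$max_deletion |
      anc$n_deletion > params$max_deletion)
  list(pass = rowSums(fail) == 0, fail = fail, alt = alt)
}

# -- brute-force small parsimony --------------------------------------------
# minimum changes for one presence/absence column on a rooted topology with
# the ancestor fixed absent, by exhaustive internal-state enumeration of an
# explicit parent table built from the newick string (independent of the
# package's topology indexing).
brute_force_fitch_column <- function(newick, states) {
  tr <- ape::read.tree(text = if (grepl(";", newick)) newick
                              else paste0(newick, ";"))
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L
  parent <- rep(NA_integer_, nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  k <- length(internal)
  tip_state <- states[match(tr$tip.label, names(states))]
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    st <- integer(nnode)
    st[seq_len(ntip)] <- tip_state
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    ch <- sum(st[tr$edge[, 2]] != st[tr$edge[, 1]])
    ch <- ch + (st[root] != 0L)            # stem from the all-absent ancestor
    best <- min(best, ch)
  }
  best
}

# -- misc --------------------------------------------------------------------
# cached study-shaped table (a few seconds to build; reused across tests)
study_cache <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) cache <<- simulate_study_mutations(seed)
    cache
  }
})

random_presence_matrix <- function(strains, n_loci, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(length(strains) * n_loci) < 0.5, length(strains),
                n_loci, dimnames = list(strains, paste0("chr:", seq_len(n_loci),
                                                        ":G>T")))
    if (all(colSums(m) > 0)) break
  }
  structure(m, class = c("presence_matrix", class(m)))
}
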