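# Ancestor-versus-evolved SNP calling on parsed pileups.
#
# A candidate variant at a site is the most frequent non-reference base in the
# evolved strain (ties broken alphabetically). The call passes when every
# heuristic filter holds; failures carry the full set of violated rules.
# Allele fractions are computed over base-called reads, i.e. excluding 'N'
# and '*' which carry no allele evidence; the per-symbol ambiguity caps
# (n_ambiguous <= max_ambiguous, n_deletion <= max_deletion) apply to both
# strains. Depth thresholds apply to the raw depth column (reads covering the
# position). Both allele-fraction thresholds are inclusive.

#' SNP-acceptance filter thresholds
#'
#' Defaults are the resequencing filter used for evolved-versus-ancestor
#' comparisons: the variant base must account for at least 40% of reads in
#' the evolved strain, at most 10% in the ancestor, with at least 5 reads
#' covering the position in both strains, a confirming variant read on each
#' strand, and no more than one ambiguous call (`N`) or deletion (`*`) per
#' strain at the position.
#'
#' @param min_evolved_frac minimum variant fraction in the evolved strain
#'   (inclusive).
#' @param max_ancestor_frac maximum variant fraction in the ancestor
#'   (inclusive).
#' @param min_depth minimum read depth in each strain.
#' @param require_both_strands require >= 1 variant read on each strand in
#'   the evolved strain.
#' @param max_ambiguous,max_deletion per-strain caps on `N` / `*` counts.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_evolved_frac = 0.40, max_ancestor_frac = 0.10,
                          min_depth = 5L, require_both_strands = TRUE,
                          max_ambiguous = 1L, max_deletion = 1L) {
  stopifnot(max_ancestor_frac >= 0, max_ancestor_frac < min_evolved_frac,
            min_evolved_frac <= 1, min_depth >= 1)
  structure(list(min_evolved_frac = min_evolved_frac,
                 max_ancestor_frac = max_ancestor_frac,
                 min_depth = as.integer(min_depth),
                 require_both_strands = isTRUE(require_both_strands),
                 max_ambiguous = as.integer(max_ambiguous),
                 max_deletion = as.integer(max_deletion)),
            class = "filter_params")
}

base_count_cols <- function(strand = c("fwd", "rev")) {
  as.vector(outer(BASES, strand, paste, sep = "_"))
}

# vectorised filter core over aligned ancestor/evolved site tables;
# returns a data.frame of per-site verdicts and candidate-allele statistics
call_sites_core <- function(anc, evo, params) {
  stopifnot(nrow(anc) == nrow(evo))
  if (nrow(anc) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      evolved_frac = numeric(0), ancestor_frac = numeric(0),
                      evolved_depth = integer(0), ancestor_depth = integer(0),
                      pass = logical(0), reasons = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(anc$pos != evo$pos) || any(anc$chrom != evo$chrom)) {
    stop("ancestor/evolved sites are not position-aligned", call. = FALSE)
  }
  if (any(anc$ref != evo$ref)) {
    stop("ancestor/evolved reference bases disagree at aligned positions",
         call. = FALSE)
  }
  fwd_cols <- paste0(BASES, "_fwd")
  rev_cols <- paste0(BASES, "_rev")
  evo_fwd <- as.matrix(evo[, fwd_cols]); evo_rev <- as.matrix(evo[, rev_cols])
  anc_fwd <- as.matrix(anc[, fwd_cols]); anc_rev <- as.matrix(anc[, rev_cols])
  evo_tot <- evo_fwd + evo_rev
  anc_tot <- anc_fwd + anc_rev

  ref_idx <- match(evo$ref, BASES)
  n <- nrow(evo)
  nonref <- evo_tot
  nonref[cbind(seq_len(n), ref_idx)] <- -1L     # exclude ref from argmax
  # most frequent non-reference base, alphabetical tie-break (max.col ties
  # are random, so resolve by strict comparison on a tie-biased score)
  score <- sweep(nonref, 2, c(4e-4, 3e-4, 2e-4, 1e-4), `+`)
  alt_idx <- max.col(score, ties.method = "first")
  alt_count <- nonref[cbind(seq_len(n), alt_idx)]
  has_alt <- alt_count > 0L

  called_evo <- rowSums(evo_tot)                 # base-called reads
  called_anc <- rowSums(anc_tot)
  evo_alt <- evo_tot[cbind(seq_len(n), alt_idx)]
  anc_alt <- anc_tot[cbind(seq_len(n), alt_idx)]
  evolved_frac <- ifelse(called_evo > 0, evo_alt / called_evo, 0)
  ancestor_frac <- ifelse(called_anc > 0, anc_alt / called_anc, 0)

  reasons <- matrix(FALSE, n, length(REASON_CODES),
                    dimnames = list(NULL, REASON_CODES))
  reasons[, "NO_ALT"] <- !has_alt
  reasons[, "LOW_DEPTH_EVOLVED"] <- evo$depth < params$min_depth
  reasons[, "LOW_DEPTH_ANCESTOR"] <- anc$depth < params$min_depth
  reasons[, "EXCESS_AMBIGUOUS"] <-
    evo$n_ambiguous > params$max_ambiguous |
    anc$n_ambiguous > params$max_ambiguous
  reasons[, "EXCESS_DELETION"] <-
    evo$n_deletion > params$max_deletion |
    anc$n_deletion > params$max_deletion
  # allele-dependent rules only apply when a candidate variant exists
  reasons[, "LOW_EVOLVED_FRAC"] <-
    has_alt & evolved_frac < params$min_evolved_frac
  reasons[, "HIGH_ANCESTOR_FRAC"] <-
    has_alt & ancestor_frac > params$max_ancestor_frac
  if (params$require_both_strands) {
    reasons[, "STRAND_UNCONFIRMED"] <- has_alt &
      (evo_fwd[cbind(seq_len(n), alt_idx)] < 1L |
       evo_rev[cbind(seq_len(n), alt_idx)] < 1L)
  }

  pass <- rowSums(reasons) == 0L
  reason_str <- vapply(seq_len(n), function(i) {
    paste(REASON_CODES[reasons[i, ]], collapse = ";")
  }, "")
  data.frame(chrom = evo$chrom, pos = evo$pos, ref = evo$ref,
             alt = ifelse(has_alt, BASES[alt_idx], NA_character_),
             evolved_frac = evolved_frac, ancestor_frac = ancestor_frac,
             evolved_depth = evo$depth, ancestor_depth = anc$depth,
             pass = pass, reasons = reason_str, stringsAsFactors = FALSE)
}

#' Apply the SNP filter to aligned ancestor/evolved site tables
#'
#' Vectorised form of [call_site()]: both inputs must be row-aligned on
#' (chrom, pos) with matching reference bases.
#'
#' @param anc,evo parsed pileup data.frames ([read_pileup()]) with equal row
#'   counts and aligned positions.
#' @param params a [filter_params()].
#' @return data.frame with one row per site: chrom, pos, ref, alt (NA when
#'   the evolved strain shows no non-reference base), evolved_frac,
#'   ancestor_frac, evolved_depth, ancestor_depth, pass, reasons
#'   (semicolon-joined codes, empty iff pass).
#' @export
call_sites <- function(anc, evo, params = filter_params()) {
  call_sites_core(anc, evo, params)
}

#' Apply the SNP filter to a single ancestor/evolved site pair
#'
#' @param anc,evo one-row data.frames in the layout of [read_pileup()]
#'   (same chrom, pos and ref).
#' @param params a [filter_params()].
#' @return list with `pass` (logical), `reasons` (character vector of
#'   violated-rule codes, empty iff pass) and `call` (one-row data.frame of
#'   the candidate variant, or NULL when no non-reference base was seen).
#' @export
call_site <- function(anc, evo, params = filter_params()) {
  res <- call_sites_core(anc, evo, params)
  reasons <- if (nzchar(res$reasons)) strsplit(res$reasons, ";")[[1]]
             else character(0)
  call <- NULL
  if (!is.na(res$alt)) {
    call <- res[, c("chrom", "pos", "ref", "alt", "evolved_frac",
                    "ancestor_frac", "evolved_depth", "ancestor_depth")]
  }
  list(pass = res$pass, reasons = reasons, call = call)
}

#' Call SNPs genome-wide from ancestor and evolved pileups
#'
#' Positions must be sorted by (chrom, pos) in both inputs; positions present
#' in only one input are skipped and tallied. Sites where the evolved strain
#' shows no non-reference base are tallied under `NO_ALT` rather than
#' reported.
#'
#' @param anc,evo parsed pileup data.frames ([read_pileup()]).
#' @param params a [filter_params()].
#' @param strain optional strain name recorded in the calls.
#' @return list with `calls` (data.frame of passing sites), `rejections`
#'   (data.frame of failing sites with a candidate variant, reason codes
#'   attached), `tally` (named integer: per-reason rejection counts plus
#'   `NO_ALT`, `ONLY_IN_ANCESTOR`, `ONLY_IN_EVOLVED`) and `n_compared`.
#' @export
call_genome <- function(anc, evo, params = filter_params(), strain = NA) {
  check_sorted <- function(df, what) {
    if (nrow(df) < 2) return(invisible())
    key <- order(df$chrom, df$pos)
    if (any(key != seq_len(nrow(df)))) {
      stop(sprintf("%s pileup is not sorted by (chrom, pos)", what),
           call. = FALSE)
    }
  }
  check_sorted(anc, "ancestor"); check_sorted(evo, "evolved")

  akey <- paste(anc$chrom, anc$pos)
  ekey <- paste(evo$chrom, evo$pos)
  shared <- intersect(akey, ekey)
  only_anc <- length(akey) - length(shared)
  only_evo <- length(ekey) - length(shared)
  a <- anc[match(shared, akey), , drop = FALSE]
  e <- evo[match(shared, ekey), , drop = FALSE]

  res <- call_sites_core(a, e, params)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL

  calls <- res[res$pass, c("chrom", "pos", "ref", "alt", "evolved_frac",
                           "ancestor_frac", "evolved_depth",
                           "ancestor_depth"), drop = FALSE]
  calls$strain <- rep(strain, nrow(calls))
  rownames(calls) <- NULL

  no_alt <- is.na(res$alt)
  rej <- res[!res$pass & !no_alt, , drop = FALSE]
  rownames(rej) <- NULL

  tally <- setNames(integer(length(REASON_CODES)), REASON_CODES)
  if (nrow(res) > 0) {
    hit <- unlist(strsplit(res$reasons[!res$pass], ";"), use.names = FALSE)
    tb <- table(hit)
    tally[names(tb)] <- as.integer(tb)
  }
  tally["ONLY_IN_ANCESTOR"] <- only_anc
  tally["ONLY_IN_EVOLVED"] <- only_evo

  list(calls = calls, rejections = rej, tally = tally,
       n_compared = nrow(res))
}

#' Write SNP calls as minimal VCF v4.2
#'
#' Eight columns (CHROM POS ID REF ALT QUAL FILTER INFO); passing sites get
#' `FILTER=PASS`, and with `emit_all = TRUE` rejected candidate sites are
#' included with semicolon-joined reason codes in FILTER.
#'
#' @param result a [call_genome()] result (or a data.frame of calls).
#' @param path output path.
#' @param emit_all also emit rejected candidate sites.
#' @param sample_name value for the INFO `STRAIN=` tag.
#' @export
write_vcf <- function(result, path, emit_all = FALSE, sample_name = NULL) {
  calls <- if (is.data.frame(result)) result else result$calls
  rows <- data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
                     alt = calls$alt,
                     filter = rep("PASS", nrow(calls)),
                     info = sprintf("EVOF=%.4f;ANCF=%.4f;DP=%d",
                                    calls$evolved_frac, calls$ancestor_frac,
                                    calls$evolved_depth),
                     stringsAsFactors = FALSE)
  if (emit_all && !is.data.frame(result) && nrow(result$rejections) > 0) {
    rej <- result$rejections
    rows <- rbind(rows, data.frame(
      chrom = rej$chrom, pos = rej$pos, ref = rej$ref, alt = rej$alt,
      filter = rej$reasons,
      info = sprintf("EVOF=%.4f;ANCF=%.4f;DP=%d", rej$evolved_frac,
                     rej$ancestor_frac, rej$evolved_depth),
      stringsAsFactors = FALSE))
    rows <- rows[order(rows$chrom, rows$pos), , drop = FALSE]
  }
  if (!is.null(sample_name) && nrow(rows) > 0) {
    rows$info <- paste0("STRAIN=", sample_name, ";", rows$info)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=consortiumseq",
           paste0("##FILTER=<ID=", REASON_CODES, ",Description=\"",
                  REASON_CODES, "\">"),
           "##INFO=<ID=STRAIN,Number=1,Type=String,Description=\"Strain\">",
           "##INFO=<ID=EVOF,Number=1,Type=Float,Description=\"Evolved variant fraction\">",
           "##INFO=<ID=ANCF,Number=1,Type=Float,Description=\"Ancestor variant fraction\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Evolved depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", rows$chrom, rows$pos,
                  rows$ref, rows$alt, rows$filter, rows$info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF back into a call table
#' @param path VCF path.
#' @param pass_only keep only FILTER == PASS records.
#' @return data.frame: chrom, pos, ref, alt, filter.
#' @export
read_vcf_calls <- function(path, pass_only = TRUE) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      filter = character(0), stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  out <- data.frame(chrom = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
                    alt = f[, 5], filter = f[, 7], stringsAsFactors = FALSE)
  if (pass_only) out <- out[out$filter == "PASS", , drop = FALSE]
  rownames(out) <- NULL
  out
}
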