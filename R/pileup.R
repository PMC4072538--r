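# Samtools pileup text: simulation and parsing.
#
# Six-column dialect: chrom, pos (1-based), ref base, depth, read bases,
# base qualities. In the base string '.'/',' are reference matches on the
# forward/reverse strand, 'ACGT'/'acgt' mismatches by strand, 'N'/'n'
# ambiguous calls, '*' a deleted base, '^X' marks a read start (X = mapping
# quality), '$' a read end, and '+n<seq>'/'-n<seq>' report indels attached to
# the preceding base (not themselves base calls).

#' Pileup simulation parameters
#'
#' @param mean_depth expected reads per site (Poisson).
#' @param error_rate per-base miscall probability; miscalls are uniform over
#'   the three non-template bases.
#' @param ambiguous_rate probability that a read reports `N`.
#' @param deletion_rate probability that a read reports `*`.
#' @param seed integer seed.
#' @return a `pileup_sim_params` list.
#' @export
pileup_sim_params <- function(mean_depth = 50, error_rate = 0.002,
                              ambiguous_rate = 0, deletion_rate = 0,
                              seed = 1L) {
  stopifnot(mean_depth > 0,
            error_rate >= 0, error_rate <= 1,
            ambiguous_rate >= 0, ambiguous_rate <= 1,
            deletion_rate >= 0, deletion_rate <= 1)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 ambiguous_rate = ambiguous_rate,
                 deletion_rate = deletion_rate, seed = as.integer(seed)),
            class = "pileup_sim_params")
}

#' Simulate a whole-genome pileup for one strain
#'
#' Reads are drawn per site: depth ~ Poisson(`mean_depth`), strand by fair
#' coin, and each read reports `N` (prob `ambiguous_rate`), `*`
#' (prob `deletion_rate`), a uniform miscall (prob `error_rate`) or the
#' strain's template base. The pileup is written *relative to the reference*
#' genome: sites where the strain carries a variant show mismatch letters.
#' Sites with zero depth are omitted, as samtools does.
#'
#' @param genome reference `ancestral_genome`.
#' @param params a [pileup_sim_params()].
#' @param strain_seq template sequence the reads are drawn from; defaults to
#'   the reference sequence itself.
#' @return data.frame: chrom, pos, ref, depth, bases, quals (placeholder `~`
#'   qualities; no base-quality model).
#' @export
simulate_pileup <- function(genome, params, strain_seq = NULL) {
  stopifnot(inherits(params, "pileup_sim_params"))
  strain_seq <- strain_seq %||% genome$seq
  stopifnot(nchar(strain_seq) == nchar(genome$seq))
  set.seed(params$seed)
  n <- nchar(genome$seq)
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), depth = integer(0),
                      bases = character(0), quals = character(0),
                      stringsAsFactors = FALSE))
  }
  depth <- rpois(n, params$mean_depth)
  keep <- depth > 0
  site <- rep.int(which(keep), depth[keep])       # site index per read
  nreads <- length(site)
  tmpl <- strsplit(strain_seq, "")[[1]][site]

  fwd <- runif(nreads) < 0.5
  u <- runif(nreads)
  p_amb <- params$ambiguous_rate
  p_del <- params$deletion_rate
  p_err <- params$error_rate
  is_amb <- u < p_amb
  is_del <- !is_amb & u < p_amb + p_del
  is_err <- !is_amb & !is_del & u < p_amb + p_del + p_err

  call <- tmpl
  if (any(is_err)) {
    # uniform over the three non-template bases
    shift <- sample.int(3L, sum(is_err), replace = TRUE)
    base_idx <- match(tmpl[is_err], BASES)
    call[is_err] <- BASES[((base_idx - 1L + shift) %% 4L) + 1L]
  }

  refs <- strsplit(genome$seq, "")[[1]]
  sym <- character(nreads)
  match_ref <- call == refs[site]
  sym[match_ref & fwd] <- "."
  sym[match_ref & !fwd] <- ","
  sym[!match_ref & fwd] <- call[!match_ref & fwd]
  sym[!match_ref & !fwd] <- tolower(call[!match_ref & !fwd])
  sym[is_amb & fwd] <- "N"
  sym[is_amb & !fwd] <- "n"
  sym[is_del] <- "*"

  bases <- vapply(split(sym, site), paste0, "", collapse = "")
  quals <- vapply(depth[keep], function(d) strrep("~", d), "")
  data.frame(chrom = genome$chrom, pos = which(keep), ref = refs[keep],
             depth = depth[keep], bases = bases, quals = quals,
             stringsAsFactors = FALSE)
}

#' Write a pileup data.frame as tab-separated text
#' @param pu data.frame from [simulate_pileup()].
#' @param path output path.
#' @export
write_pileup <- function(pu, path) {
  write.table(pu, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- parsing ---------------------------------------------------------------

#' Parse one pileup base string into strand-aware counts
#'
#' @param bases the base-string field of a pileup line.
#' @param ref the reference base at the site.
#' @param depth the depth field; the parse is validated against it.
#' @param line line number used in error messages.
#' @return named list: counts (4x2 matrix, rows A,C,G,T, cols fwd/rev),
#'   n_ambiguous, n_deletion.
#' @export
parse_base_string <- function(bases, ref, depth, line = NA) {
  chars <- strsplit(bases, "")[[1]]
  counts <- matrix(0L, 4, 2, dimnames = list(BASES, c("fwd", "rev")))
  n_amb <- 0L; n_del <- 0L
  i <- 1L; n <- length(chars)
  where <- if (is.na(line)) "" else sprintf(" at line %s", line)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > n) stop("dangling '^'", where, call. = FALSE)
      i <- i + 2L                     # skip mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L) stop("indel without length", where, call. = FALSE)
      len <- as.integer(paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) {
        stop("indel length mismatch", where, call. = FALSE)
      }
      i <- j + len                    # indel bases are not base calls
    } else if (ch == "*") {
      n_del <- n_del + 1L; i <- i + 1L
    } else if (ch %in% c("N", "n")) {
      n_amb <- n_amb + 1L; i <- i + 1L
    } else if (ch == ".") {
      counts[ref, "fwd"] <- counts[ref, "fwd"] + 1L; i <- i + 1L
    } else if (ch == ",") {
      counts[ref, "rev"] <- counts[ref, "rev"] + 1L; i <- i + 1L
    } else if (ch %in% BASES) {
      counts[ch, "fwd"] <- counts[ch, "fwd"] + 1L; i <- i + 1L
    } else if (ch %in% tolower(BASES)) {
      counts[toupper(ch), "rev"] <- counts[toupper(ch), "rev"] + 1L
      i <- i + 1L
    } else {
      stop(sprintf("unexpected pileup character '%s'%s", ch, where),
           call. = FALSE)
    }
  }
  got <- sum(counts) + n_amb + n_del
  if (!is.na(depth) && got != depth) {
    stop(sprintf("parsed %d calls but depth is %d%s", got, depth, where),
         call. = FALSE)
  }
  list(counts = counts, n_ambiguous = n_amb, n_deletion = n_del)
}

#' Parse a single pileup line
#'
#' @param line one tab-separated pileup line (>= 5 fields; a 6th base-quality
#'   field is tolerated and ignored).
#' @param line_no line number for error messages.
#' @return a one-row data.frame in the layout of [read_pileup()].
#' @export
parse_pileup_line <- function(line, line_no = NA) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 5) {
    stop(sprintf("pileup line %s has %d fields (need >= 5)",
                 line_no, length(f)), call. = FALSE)
  }
  ref <- toupper(f[3])
  assert_bases(ref, "reference")
  depth <- as.integer(f[4])
  p <- parse_base_string(f[5], ref, depth, line = line_no)
  cnt <- p$counts
  data.frame(chrom = f[1], pos = as.integer(f[2]), ref = ref, depth = depth,
             A_fwd = cnt["A", 1], A_rev = cnt["A", 2],
             C_fwd = cnt["C", 1], C_rev = cnt["C", 2],
             G_fwd = cnt["G", 1], G_rev = cnt["G", 2],
             T_fwd = cnt["T", 1], T_rev = cnt["T", 2],
             n_ambiguous = p$n_ambiguous, n_deletion = p$n_deletion,
             stringsAsFactors = FALSE)
}

#' Read and parse a whole pileup file
#'
#' Vectorised fast path for base strings free of `^`, `$` and indel runs;
#' lines containing those go through the character-level parser. Returns one
#' row per site with per-base, per-strand counts.
#'
#' @param path pileup file path.
#' @return data.frame: chrom, pos, ref, depth, `A_fwd` ... `T_rev`,
#'   n_ambiguous, n_deletion.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  parse_pileup_lines(lines)
}

#' @rdname read_pileup
#' @param lines character vector of pileup lines.
#' @export
parse_pileup_lines <- function(lines) {
  if (length(lines) == 0) return(empty_pileup_frame())
  dt <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                          fill = TRUE, colClasses = list(character = 5))
  if (ncol(dt) < 5) stop("pileup must have >= 5 tab-separated fields",
                         call. = FALSE)
  chrom <- as.character(dt[[1]]); pos <- as.integer(dt[[2]])
  ref <- toupper(as.character(dt[[3]])); depth <- as.integer(dt[[4]])
  bases <- as.character(dt[[5]])
  assert_bases(unique(ref), "reference")

  simple <- !grepl("[$^+-]", bases)
  nsite <- length(bases)
  out <- matrix(0L, nsite, 10,
                dimnames = list(NULL, c("A_fwd", "A_rev", "C_fwd", "C_rev",
                                        "G_fwd", "G_rev", "T_fwd", "T_rev",
                                        "n_ambiguous", "n_deletion")))
  if (any(simple)) {
    idx <- which(simple)
    chars <- strsplit(bases[idx], "")
    site <- rep.int(idx, lengths(chars))
    ch <- unlist(chars, use.names = FALSE)
    refch <- ref[site]
    symbol <- ch
    symbol[ch == "."] <- paste0(refch[ch == "."], "_fwd")
    symbol[ch == ","] <- paste0(refch[ch == ","], "_rev")
    up <- ch %in% BASES
    symbol[up] <- paste0(ch[up], "_fwd")
    lo <- ch %in% tolower(BASES)
    symbol[lo] <- paste0(toupper(ch[lo]), "_rev")
    symbol[ch %in% c("N", "n")] <- "n_ambiguous"
    symbol[ch == "*"] <- "n_deletion"
    bad <- !(symbol %in% colnames(out))
    if (any(bad)) {
      stop(sprintf("unexpected pileup character '%s' at line %d",
                   ch[bad][1], site[bad][1]), call. = FALSE)
    }
    tab <- data.table::data.table(site = site, symbol = symbol)
    agg <- tab[, .N, by = c("site", "symbol")]
    out[cbind(agg$site, match(agg$symbol, colnames(out)))] <- agg$N
    got <- rowSums(out[idx, , drop = FALSE])
    mism <- got != depth[idx]
    if (any(mism)) {
      stop(sprintf("parsed %d calls but depth is %d at line %d",
                   got[mism][1], depth[idx][mism][1], idx[mism][1]),
           call. = FALSE)
    }
  }
  for (i in which(!simple)) {
    p <- parse_base_string(bases[i], ref[i], depth[i], line = i)
    out[i, ] <- c(c(t(p$counts)), p$n_ambiguous, p$n_deletion)
  }
  res <- data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
                    stringsAsFactors = FALSE)
  cbind(res, as.data.frame(out))
}

empty_pileup_frame <- function() {
  cols <- c("A_fwd", "A_rev", "C_fwd", "C_rev", "G_fwd", "G_rev",
            "T_fwd", "T_rev", "n_ambiguous", "n_deletion")
  base <- data.frame(chrom = character(0), pos = integer(0),
                     ref = character(0), depth = integer(0),
                     stringsAsFactors = FALSE)
  for (cl in cols) base[[cl]] <- integer(0)
  base
}
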