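#' @importFrom stats optimize uniroot rpois runif rbinom setNames
#' @importFrom utils write.table read.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a master seed
#'
#' All stochastic stages of the pipeline draw their RNG state from one master
#' seed through named substreams, so a single stage can be re-run in isolation
#' and reproduce exactly what it did inside a full pipeline run.
#'
#' @param seed master seed (integer).
#' @param stage stage name, e.g. `"pileup:CV103"`.
#' @return an integer seed below 2^31, deterministic in `(seed, stage)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small string hash (polynomial rolling, modular) -- stable across platforms
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 1048573
  as.integer((as.numeric(seed) * 1048573 + h) %% 2147483629) + 1L
}

assert_bases <- function(x, what = "base") {
  bad <- !(x %in% BASES)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (must be one of A,C,G,T)",
                 what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

comp_base <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA, comment.char = "", ...)
}
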