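# Luria-Delbruck fluctuation analysis.
#
# The number of resistant colonies per parallel culture follows the
# Luria-Delbruck distribution with parameter m (expected mutations per
# culture). The probability mass function comes from the Ma-Sandri-Sarkar
# (MSS) recursion
#     p_0 = exp(-m),   p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1),
# which assumes deterministic doubling of mutant clones and full plating.
# The mutation rate per cell per generation is mu = m / Nt (the number of
# cell divisions in a culture grown from N0 << Nt cells is ~ Nt).

#' Luria-Delbruck probability mass function (MSS recursion)
#'
#' @param m expected mutations per culture (>= 0).
#' @param kmax highest count to evaluate.
#' @return an `ld_model`: list with `m` and `pmf` (numeric vector of
#'   p_0 .. p_kmax).
#' @export
ld_pmf <- function(m, kmax = 100L) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0) {
    stop("m must be a single non-negative number", call. = FALSE)
  }
  stopifnot(kmax >= 0)
  p <- numeric(kmax + 1L)
  p[1] <- exp(-m)
  if (kmax >= 1) {
    for (k in seq_len(kmax)) {
      i <- 0:(k - 1L)
      p[k + 1L] <- (m / k) * sum(p[i + 1L] / (k - i + 1))
    }
  }
  structure(list(m = m, pmf = p), class = "ld_model")
}

# log-likelihood of counts under LD(m); counts above `cap` are lumped into a
# right tail with probability 1 - sum_{k < cap} p_k, which keeps the MSS
# recursion O(cap^2) even in the presence of jackpot cultures.
ld_loglik <- function(m, counts, cap = 1000L) {
  if (m <= 0) return(if (all(counts == 0)) 0 else -Inf)
  kmax <- min(max(counts), cap)
  pmf <- ld_pmf(m, kmax)$pmf
  pmf <- pmax(pmf, 1e-300)
  ll <- sum(log(pmf[pmin(counts, cap) + 1L][counts < cap]))
  n_tail <- sum(counts >= cap)
  if (n_tail > 0) {                    # here kmax == cap, pmf has p_0..p_cap
    tail_p <- max(1 - sum(pmf[seq_len(cap)]), 1e-300)
    ll <- ll + n_tail * log(tail_p)
  }
  ll
}

#' Ma-Sandri-Sarkar maximum-likelihood mutation-rate estimate
#'
#' Maximises the Luria-Delbruck likelihood of the observed per-culture mutant
#' counts over m by bracketed one-dimensional search (relative tolerance
#' 1e-6), then converts to a per-cell-per-generation rate. The 95% confidence
#' interval comes from the profile likelihood at a log-likelihood drop of
#' 1.92 (chi-square, 1 df).
#'
#' @param counts non-negative integer vector of mutant colonies per culture.
#' @param Nt final cells per culture (from the titer).
#' @param N0 inoculum size; only used when `denominator = "Nt-N0"`.
#' @param denominator divisor converting m to mu: `"Nt"` (default, the
#'   FALCOR-style convention) or `"Nt-N0"` (equivalent when Nt >> N0).
#' @param cap counts above this are treated as a lumped right tail in the
#'   likelihood (keeps the O(kmax^2) recursion tractable under jackpots).
#' @return a `rate_estimate`: list with m_hat, mu_hat, ci95 (on m),
#'   ci95_mu, n_cultures, Nt, boundary (TRUE when all counts are zero and
#'   the MLE sits at m = 0 with a one-sided interval).
#' @export
mss_mle <- function(counts, Nt, N0 = NULL, denominator = c("Nt", "Nt-N0"),
                    cap = 1000L) {
  denominator <- match.arg(denominator)
  stopifnot(length(counts) >= 1, all(counts >= 0),
            all(counts == round(counts)), Nt > 0)
  counts <- as.integer(counts)
  div <- if (denominator == "Nt") Nt else {
    if (is.null(N0)) stop("N0 required for denominator Nt-N0", call. = FALSE)
    Nt - N0
  }
  n <- length(counts)
  drop95 <- 1.92

  if (all(counts == 0)) {
    # likelihood exp(-n m) is maximised at the boundary m = 0
    upper <- drop95 / n
    est <- list(m_hat = 0, mu_hat = 0, ci95 = c(0, upper),
                ci95_mu = c(0, upper / div), n_cultures = n, Nt = Nt,
                boundary = TRUE)
    class(est) <- "rate_estimate"
    return(est)
  }

  f <- function(logm) ld_loglik(exp(logm), counts, cap = cap)
  # bracket around the P0-method guess when zeros exist, else a wide window
  guess <- if (any(counts == 0)) -log(mean(counts == 0)) else
    max(mean(pmin(counts, cap)) / log(pmax(mean(pmin(counts, cap)), 2)), 0.5)
  lo <- log(guess) - 6; hi <- log(guess) + 6
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-7)
  m_hat <- exp(opt$maximum)
  llmax <- opt$objective

  g <- function(m) ld_loglik(m, counts, cap = cap) - (llmax - drop95)
  lo_m <- tryCatch(uniroot(g, c(m_hat * 1e-4, m_hat), tol = 1e-8)$root,
                   error = function(e) 0)
  hi_m <- tryCatch(uniroot(g, c(m_hat, m_hat * 1e4), tol = 1e-8)$root,
                   error = function(e) Inf)

  est <- list(m_hat = m_hat, mu_hat = m_hat / div,
              ci95 = c(lo_m, hi_m), ci95_mu = c(lo_m, hi_m) / div,
              n_cultures = n, Nt = Nt, boundary = FALSE)
  class(est) <- "rate_estimate"
  est
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> m = %.4g (95%% CI %.4g-%.4g), mu = %.4g /cell/gen, n = %d%s\n",
    x$m_hat, x$ci95[1], x$ci95[2], x$mu_hat, x$n_cultures,
    if (isTRUE(x$boundary)) " [boundary: all cultures mutant-free]" else ""))
  invisible(x)
}

#' Fold change between two mutation rates
#'
#' @param est_a,est_b `rate_estimate` objects or bare numeric rates
#'   (mu, per cell per generation).
#' @return fold change mu_a / mu_b.
#' @export
rate_and_fold <- function(est_a, est_b) {
  mu <- function(x) if (inherits(x, "rate_estimate")) x$mu_hat else x
  a <- mu(est_a); b <- mu(est_b)
  stopifnot(is.numeric(a), is.numeric(b))
  if (!(a > 0) || !(b > 0)) {
    stop("fold change undefined: both rates must be positive", call. = FALSE)
  }
  a / b
}

# ---- fluctuation-assay simulator ------------------------------------------

#' Fluctuation-assay design
#'
#' @param mu mutation rate per cell per generation.
#' @param N0 inoculum cells per culture.
#' @param Nt final cells per culture.
#' @param n_cultures number of parallel cultures (12 in the classical
#'   rifampicin design emulated here).
#' @param seed integer seed.
#' @return an `assay_design` list.
#' @export
assay_design <- function(mu, N0 = 1e4, Nt = 3e9, n_cultures = 12L,
                         seed = 1L) {
  stopifnot(mu >= 0, mu <= 1, N0 >= 1, Nt > N0, n_cultures >= 1)
  structure(list(mu = mu, N0 = N0, Nt = Nt,
                 n_cultures = as.integer(n_cultures),
                 seed = as.integer(seed)),
            class = "assay_design")
}

#' Simulate per-culture mutant counts for a fluctuation assay
#'
#' Classical Luria-Delbruck model with deterministic growth and full
#' plating: a culture grows from N0 to Nt cells (Nt - N0 divisions), each
#' division mutates with probability mu, so the number of mutations is
#' Poisson(mu * (Nt - N0)); a mutation arising when the population has N
#' cells founds a clone that doubles with the culture and reaches floor(Nt/N)
#' cells at plating. Mutation times are uniform over divisions. No
#' back-mutation, no fitness cost, no phenotypic lag.
#'
#' Each culture consumes an independent seed substream derived from
#' `design$seed` and the culture index, so counts do not depend on the order
#' in which cultures are drawn.
#'
#' @param design an [assay_design()].
#' @return integer vector of length `n_cultures`.
#' @export
simulate_fluctuation_assay <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  m <- design$mu * (design$Nt - design$N0)
  vapply(seq_len(design$n_cultures), function(j) {
    set.seed(stage_seed(design$seed, paste0("culture:", j)))
    n_mut <- rpois(1L, m)
    if (n_mut == 0L) return(0L)
    # population size at each mutation's division, uniform over divisions
    at <- design$N0 + runif(n_mut) * (design$Nt - design$N0)
    as.integer(sum(floor(design$Nt / at)))
  }, integer(1))
}

#' Read per-culture mutant counts with a titer
#'
#' The TSV carries one `count` column; Nt comes either from an `Nt` column
#' (constant) or from a separate titer table averaged as in plate-count
#' practice.
#'
#' @param path counts TSV (columns: culture, count, optionally Nt).
#' @param titer_path optional titer TSV (column: titer); Nt = mean(titer).
#' @return list with `counts` (integer vector) and `Nt`.
#' @export
read_assay_counts <- function(path, titer_path = NULL) {
  df <- read_tsv(path)
  stopifnot("count" %in% names(df))
  Nt <- if (!is.null(titer_path)) {
    mean(read_tsv(titer_path)$titer)
  } else if ("Nt" %in% names(df)) {
    unique(df$Nt)[1]
  } else {
    stop("no Nt column and no titer file", call. = FALSE)
  }
  list(counts = as.integer(df$count), Nt = Nt)
}

#' Write per-culture mutant counts as TSV
#' @param counts integer vector.
#' @param Nt final cells per culture.
#' @param path output path.
#' @export
write_assay_counts <- function(counts, Nt, path) {
  write_tsv(data.frame(culture = seq_along(counts), count = counts, Nt = Nt),
            path)
}
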