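#!/usr/bin/env Rscript
# Fluctuation analysis: simulate 12-culture rifampicin-resistance assays for
# an ancestor-like mutator and a hypermutator at the published rates,
# estimate m and mu by the MSS maximum-likelihood method, and tabulate fold
# relations between the published per-strain rates.

suppressMessages(library(consortiumseq))
seed <- 20140626L
out <- "results/rates"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# published per-strain rates (per cell per generation)
published <- c(K12 = 3.60e-9, JA122 = 1.00e-7, CV101 = 1.33e-7,
               CV103 = 9.20e-7, CV115 = 1.14e-7, CV116 = 1.10e-7)

# 12-culture bench-scale assays at the published rates
Nt <- 2e8; N0 <- 1e4
cat("12-culture assays (bench scale; estimates at n = 12 are noisy):\n")
ests <- list()
for (s in names(published)) {
  d <- assay_design(published[[s]], N0, Nt, n_cultures = 12,
                    seed = stage_seed(seed, paste0("assay:", s)))
  counts <- simulate_fluctuation_assay(d)
  write_assay_counts(counts, Nt, file.path(out, paste0(s, "_counts.tsv")))
  ests[[s]] <- mss_mle(counts, Nt = Nt)
  cat(sprintf("  %-6s counts = %-28s m_hat = %6.3f  mu_hat = %.3g\n", s,
              paste(counts, collapse = ","), ests[[s]]$m_hat,
              ests[[s]]$mu_hat))
}
rates <- data.frame(strain = names(ests),
                    mu_published = unname(published),
                    m_hat = vapply(ests, function(e) e$m_hat, 0),
                    mu_hat = vapply(ests, function(e) e$mu_hat, 0),
                    ci_lo = vapply(ests, function(e) e$ci95[1], 0),
                    ci_hi = vapply(ests, function(e) e$ci95[2], 0))
write.table(rates, file.path(out, "rates.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# estimator calibration at large n
d <- assay_design(2e-8, 1e3, 1e8, n_cultures = 1000,
                  seed = stage_seed(seed, "calib"))
est <- mss_mle(simulate_fluctuation_assay(d), Nt = 1e8)
cat(sprintf("\ncalibration: true m = 2, n = 1000 cultures: m_hat = %.3f (95%% CI %.3f-%.3f)\n",
            est$m_hat, est$ci95[1], est$ci95[2]))

# fold relations between published rates
cat(sprintf("\nfold JA122 / K12:  %.1f (a ~30-fold mutator ancestor)\n",
            rate_and_fold(published[["JA122"]], published[["K12"]])))
cat(sprintf("fold CV103 / JA122: %.1f (hypermutator, ~10-fold higher again)\n",
            rate_and_fold(published[["CV103"]], published[["JA122"]])))
folds <- outer(published, published, `/`)
write.table(round(folds, 3), file.path(out, "fold_table.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)
cat("rate tables written to", out, "\n")
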