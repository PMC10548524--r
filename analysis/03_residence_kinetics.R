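#!/usr/bin/env Rscript
## Stage 3: censored residence-time statistics and k_off^-1 estimation.
##
## Reproduces the residence-time bookkeeping at the study scale: O2-like
## batches (50 runs each) at the three side-chain conditions, and
## water-like batches (30 runs, 50 ns cutoff) where censoring matters.
## Both k_off^-1 estimators are reported, and the truncated-mean bridge
## links the fitted 15 ns to the ~13 ns mean of the events actually seen
## to escape.

library(oxykin)

out <- file.path("results", "residence")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929

conditions <- list(
  o2_trans = list(mean = 2.61, cutoff = Inf, n = 50),
  o2_plus = list(mean = 0.55, cutoff = Inf, n = 50),
  o2_ala = list(mean = 3.95, cutoff = Inf, n = 50),
  water_trans = list(mean = 15, cutoff = 50, n = 30),
  water_plus = list(mean = 720, cutoff = 50, n = 30),  # ~6.7% escapes
  water_ala = list(mean = 45, cutoff = 50, n = 30))    # ~2/3 escapes

rows <- list()
for (nm in names(conditions)) {
  cd <- conditions[[nm]]
  ev <- simulate_escape_events(escape_model(cd$mean, cd$cutoff, cd$n),
                               seed = seed + match(nm, names(conditions)))
  s <- summarize_events(ev)
  mle <- fit_koff(ev, "mle")
  cum <- fit_koff(ev, "cumulative")
  rows[[nm]] <- data.frame(
    condition = nm, true_mean_ns = cd$mean, cutoff_ns = cd$cutoff,
    n_runs = s$n_runs, n_escapes = s$n_escapes,
    escape_pct = round(s$escape_fraction_pct, 1),
    mean_ns = round(s$mean_ns, 2), sem_ns = round(s$sem_ns, 2),
    koff_inv_mle_ns = round(mle$koff_inv_ns, 2),
    koff_inv_cumfit_ns = round(cum$koff_inv_ns, 2))
  message(sprintf(
    "%-12s %2d/%2d escapes (%.1f%%), mean %.2f +/- %.2f ns, koff^-1 MLE %.2f / cum %.2f ns",
    nm, s$n_escapes, s$n_runs, s$escape_fraction_pct, s$mean_ns, s$sem_ns,
    mle$koff_inv_ns, cum$koff_inv_ns))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "residence_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tm <- truncated_mean(15, 50)
message(sprintf(
  "truncated-mean bridge: exponential 15 ns observed under a 50 ns cutoff -> %.2f ns uncensored mean",
  tm))
write_sidecar_json(list(seed = seed,
                        truncated_mean_15_50_ns = tm,
                        conditions = conditions),
                   file.path(out, "settings.json"))
message("wrote ", out)
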