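#!/usr/bin/env Rscript
# Stage 5 — diagnostics and summary tables.
#
# Computes Moran's I on city-mean HPA (k-nearest weights, permutation
# inference), runs the IQR-vs-2SE nonstationarity test, and writes the
# coefficient quantile summary and the pre/during-pandemic period averages.

suppressPackageStartupMessages(library(hpagtwr))

out <- "results/study"
panel <- read_panel(file.path(out, "panel.csv"))

sel_params <- jsonlite::fromJSON(file.path(out, "fit_summary.json"))
params <- st_kernel_params(sel_params$h_star, sel_params$lambda_s,
                           sel_params$mu_t)
gtwr <- fit_gtwr(panel, params)
ols <- fit_ols(panel)

report <- diagnostics_report(panel, gtwr, ols, k = 5, n_perm = 999,
                             seed = 45, split_year = 2020)
write_report(report, file.path(out, "diagnostics.json"))
write.csv(report$coefficient_summary,
          file.path(out, "coefficient_summary.csv"), row.names = FALSE)
write.csv(report$period_averages,
          file.path(out, "period_averages.csv"), row.names = FALSE)

print(report)
cat("\nCoefficient summary (local GTWR coefficients):\n")
print(report$coefficient_summary, digits = 3)
cat("\nPeriod averages (split at 2020):\n")
print(report$period_averages, digits = 3)
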