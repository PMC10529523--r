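#!/usr/bin/env Rscript
# Stage 4: physician-vs-DSS comparison statistics on the synthetic panel.
#
# From the synthetic observer table (stage 01 + DSS column from stage 03):
# the per-nodule variance-percentage table against the DSS, the
# classification match percentages under the default composition scheme,
# and the chi-squared test on observer x category counts.

suppressMessages(library(sonocyst))

obs_path <- "results/observer_table_synthetic.csv"
if (!file.exists(obs_path)) stop("run stages 01 and 03 first")
tab <- read_observer_csv(obs_path)
if (!"DSS" %in% names(tab)) stop("observer table has no DSS column; run stage 03")

vt <- variance_table(tab, reference_column = "DSS")
write_variance_csv(vt, "results/variance_table_synthetic.csv")
n_na <- sum(is.na(vt[setdiff(names(vt), "nodule_id")]))
cat(sprintf("variance table written (%d NA cells from the 0-denominator convention)\n",
            n_na))

sch <- composition_scheme()
phys <- setdiff(names(tab), c("nodule_id", "DSS"))
matches <- vapply(phys, classification_match_percentage, numeric(1),
                  table = tab, reference = "DSS", scheme = sch)
overall <- all_observer_match_percentage(tab, phys, "DSS", sch)
chi <- chi_squared_variance_test(tab, sch)

report <- c(
  "Observer comparison report (synthetic panel, default composition scheme)",
  sprintf("  match %% vs DSS: %s",
          paste(sprintf("%s=%.1f", phys, matches), collapse = ", ")),
  sprintf("  all observers agree with DSS: %.1f%% of nodules", overall$all_agree_pct),
  sprintf("  mean per-observer match: %.1f%%", overall$mean_pairwise_pct),
  sprintf("  chi-squared: X2=%.2f, df=%d, p=%.4g",
          chi$statistic, chi$df, chi$p_value))
writeLines(report, "results/observer_report.txt")
cat(report, sep = "\n")
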