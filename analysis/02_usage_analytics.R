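#!/usr/bin/env Rscript

# Usage analytics over the synthetic event log written by 01_simulate.R:
# conversion rates, annualised submission rates per practice, demographic
# shares, deprivation association and survey proportions.
# Writes results/practice_rates.csv and results/usage_metrics.json.

library(econsultcost)

events <- read_event_log("results/synthetic/events.csv")
rosters <- read_rosters("results/synthetic/rosters.csv")
survey <- read.csv("results/synthetic/survey.csv")

um <- usage_metrics(events, rosters, window_months = 5)
dep <- deprivation_association(um$per_practice, rosters,
                               n_perm = 999, seed = 1)
surv <- survey_summary(survey$satisfied, survey$responses,
                       recommend = survey$recommend,
                       submissions = survey$submissions)

cat(sprintf("pooled conversion rate: %.1f%% (%d submissions / %d visits)\n",
            100 * um$pooled_conversion_rate, um$n_submissions,
            sum(um$per_practice$site_visits)))
cat(sprintf("pooled submission rate: %.3f per adult per year (range %.3f-%.3f across practices)\n",
            um$pooled_rate_per_patient,
            min(um$per_practice$rate_per_patient),
            max(um$per_practice$rate_per_patient)))
cat(sprintf("female share of submissions: %.1f%%; 18-44 share: %.1f%%\n",
            100 * um$female_share, 100 * um$share_18_44))
cat("deprivation association (Spearman, permutation p):\n")
print(dep, row.names = FALSE)
cat("survey proportions (Wilson 95% CI):\n")
print(surv, row.names = FALSE)

dir.create("results", showWarnings = FALSE)
write.csv(um$per_practice, "results/practice_rates.csv", row.names = FALSE)
jsonlite::write_json(
  list(pooled_conversion_rate = um$pooled_conversion_rate,
       pooled_rate_per_patient = um$pooled_rate_per_patient,
       n_submissions = um$n_submissions,
       female_share = um$female_share,
       share_18_44 = um$share_18_44,
       age_band_shares = as.list(um$age_band_shares),
       category_shares = as.list(um$category_shares),
       deprivation = dep, survey = surv),
  "results/usage_metrics.json", auto_unbox = TRUE, digits = 10,
  dataframe = "rows", pretty = TRUE)
cat("written: results/practice_rates.csv, results/usage_metrics.json\n")
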