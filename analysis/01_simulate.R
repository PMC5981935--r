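#!/usr/bin/env Rscript

# Generate the synthetic pilot dataset: 11 practice rosters, a 5-month
# web-triage event log and voluntary survey counts, all from one seed.
# Writes results/synthetic/{rosters,events,survey}.csv.

library(econsultcost)

cfg <- generator_config(seed = 42)
out <- write_synthetic_dataset(cfg, "results/synthetic")

n_sub <- sum(out$events$kind == "submission")
cat(sprintf("practices: %d (roll %s patients, %s adults)\n",
            nrow(out$rosters),
            format(sum(out$rosters$list_size), big.mark = ","),
            format(sum(out$rosters$adult_list_size), big.mark = ",")))
cat(sprintf("events: %d site visits, %d submissions (window %s to %s)\n",
            sum(out$events$kind == "site_visit"), n_sub,
            cfg$window_start, cfg$window_end))
cat(sprintf("survey: %d responses (%d satisfied, %d would recommend)\n",
            out$survey$responses, out$survey$satisfied,
            out$survey$recommend))
cat("written:", paste(out$paths, collapse = ", "), "\n")
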