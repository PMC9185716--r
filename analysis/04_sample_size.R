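#!/usr/bin/env Rscript
# Stage 4: sample-size planning check.
#
# The design calculation behind the study: cases needed to estimate a
# sensitivity of 0.85 within a 0.10 margin at alpha = 0.05, inflated by
# the anticipated 40.9% condition prevalence.

suppressPackageStartupMessages(library(dascreen))

cases <- required_cases(p_hat = 0.85, d = 0.10, alpha = 0.05)
total <- required_total(cases, prevalence = 0.409)
cat("Cases required to estimate sensitivity 0.85 +/- 0.10:", cases, "\n")
cat("Total sample at 40.9% anticipated prevalence:", total, "\n")

jsonlite::write_json(list(cases = cases, total = total),
                     "results/sample_size.json", auto_unbox = TRUE)
cat("Wrote results/sample_size.json\n")
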