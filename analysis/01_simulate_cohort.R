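#!/usr/bin/env Rscript
## Step 1: simulate the study cohort.
##
## Generates a 26-patient virtual cohort mirroring the structure of a
## whole-cell vaccination trial in androgen-independent prostate cancer:
## roughly 58% of patients respond to vaccination (a_p > 0), PSA is
## measured monthly before treatment, at each of the 14 vaccinations and
## sporadically in between (up to 26 values per patient), with 5%
## multiplicative assay noise. Writes the PSA table and the ground-truth
## parameters under results/.

library(psavax)

dir.create("results", showWarnings = FALSE)
gp <- global_params()
prot <- make_standard_protocol()          # 2.4e7 cells; days 0,14,28,56..336
spec <- cohort_spec(n_patients = 26, responder_fraction = 15 / 26,
                    noise_cv = 0.05, seed = 42)
cohort <- generate_cohort(spec, gp, prot)
tab <- write_cohort(cohort, "results/cohort_psa.tsv",
                    "results/cohort_truth.tsv")
write_protocol(prot, "results/protocol.tsv")

n_resp <- sum(vapply(cohort, `[[`, TRUE, "responder_true"))
cat(sprintf("Simulated %d virtual patients (%d true responders), %d PSA rows.\n",
            spec$n_patients, n_resp, nrow(tab)))
cat(sprintf("Observations per patient: %s (max allowed 26).\n",
            paste(range(table(tab$patient_id)), collapse = "-")))
cat("Wrote results/cohort_psa.tsv, results/cohort_truth.tsv, results/protocol.tsv\n")
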