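#!/usr/bin/env Rscript
## Step 2: classify vaccination responders.
##
## A patient responds when the PSA velocity (slope of log PSA vs time)
## over the first four treatment cycles (through day 84) is lower than the
## pre-treatment velocity. Only responders move on to model fitting, as in
## the trial analysis.

library(psavax)

tab <- read_psa_table("results/cohort_psa.tsv")
prot <- read_protocol("results/protocol.tsv")
truth <- read.delim("results/cohort_truth.tsv")

rows <- lapply(split(tab, tab$patient_id), function(d) {
  d <- d[order(d$day), ]
  s <- psa_series(d$day, d$psa_ng_ml)
  data.frame(patient_id = d$patient_id[1],
             v_pre = psa_velocity(s, c(-Inf, 0)),
             v_treat = psa_velocity(s, c(0, 84)),
             responder = classify_responder(s, prot))
})
res <- do.call(rbind, rows)
res <- merge(res, truth[, c("patient_id", "responder_true")], by = "patient_id")
write.table(res, "results/responders.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("Classified %d/%d patients as responders (velocity drop on treatment).\n",
            sum(res$responder), nrow(res)))
cat(sprintf("Agreement with ground truth: %d/%d.\n",
            sum(res$responder == res$responder_true), nrow(res)))
cat("Wrote results/responders.tsv\n")
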