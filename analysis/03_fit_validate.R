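#!/usr/bin/env Rscript
## Step 3: personalize and validate the model for each responder.
##
## For every responder, the four patient-specific parameters (r, a_p, A, B)
## are calibrated by bounded multi-start least squares on the training set
## (the first 12 PSA values: all pre-treatment plus the initial
## in-treatment measurements); the calibrated model then predicts the
## held-out validation PSA values, scored by R^2 per patient and pooled
## over the whole cohort.

library(psavax)

tab <- read_psa_table("results/cohort_psa.tsv")
prot <- read_protocol("results/protocol.tsv")
resp <- read.delim("results/responders.tsv")
gp <- global_params()
imm <- immune_course(gp, prot)

ids <- resp$patient_id[resp$responder]
obs_all <- pred_all <- numeric(0)
rows <- list()
for (id in ids) {
  d <- tab[tab$patient_id == id, ]
  d <- d[order(d$day), ]
  s <- psa_series(d$day, d$psa_ng_ml, split_index = min(12, nrow(d)))
  fit <- fit_patient(s, prot, gp, n_starts = 16, seed = 7, immune = imm)
  val <- validation_set(s)
  pred <- predict_validation(fit, s, prot, gp)
  obs_all <- c(obs_all, val$psa); pred_all <- c(pred_all, pred)
  rows[[length(rows) + 1]] <- data.frame(
    patient_id = id, n_train = s$split_index, n_val = nrow(val),
    r = fit$params$r, a_p = fit$params$a_p, A = fit$params$A,
    B = fit$params$B, sse = fit$sse,
    validation_r2 = goodness_of_fit(val$psa, pred))
}
fits <- do.call(rbind, rows)
write.table(fits, "results/fits.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

pooled <- goodness_of_fit(obs_all, pred_all)
cat(sprintf("Fitted %d responders (12 training points each).\n", nrow(fits)))
cat(sprintf("Pooled validation R^2 over %d held-out PSA values: %.3f\n",
            length(obs_all), pooled))
cat(sprintf("Per-patient validation R^2: median %.3f, range %.3f to %.3f\n",
            median(fits$validation_r2), min(fits$validation_r2),
            max(fits$validation_r2)))
cat("Wrote results/fits.tsv\n")
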