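#!/usr/bin/env Rscript
## Step 4: find each responder's minimal training set.
##
## Starting from all pre-treatment points plus two in-treatment points,
## the training set grows one observation at a time until the mean
## absolute relative prediction error on the remaining (validation) points
## drops to 10%. Different patients need different numbers of
## measurements, and accuracy need not improve monotonically with more
## training data.

library(psavax)

tab <- read_psa_table("results/cohort_psa.tsv")
prot <- read_protocol("results/protocol.tsv")
resp <- read.delim("results/responders.tsv")
gp <- global_params()

rows <- list()
obs_all <- pred_all <- numeric(0)
for (id in resp$patient_id[resp$responder]) {
  d <- tab[tab$patient_id == id, ]
  d <- d[order(d$day), ]
  s <- psa_series(d$day, d$psa_ng_ml)
  it <- iterative_training(s, prot, gp, n_starts = 4, seed = 7)
  sk <- set_split(s, it$split_index)
  val <- validation_set(sk)
  if (nrow(val) > 0) {
    obs_all <- c(obs_all, val$psa)
    pred_all <- c(pred_all, it$fit$predicted_validation)
  }
  rows[[length(rows) + 1]] <- data.frame(
    patient_id = id, n_obs = length(s$day),
    minimal_training_points = it$split_index,
    met_criterion = it$met_criterion,
    iterations = nrow(it$trace),
    final_pred_error = it$trace$pred_error[nrow(it$trace)])
}
mt <- do.call(rbind, rows)
write.table(mt, "results/minimal_training.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("Minimal training sets over %d responders: median %d points (range %d-%d).\n",
            nrow(mt), as.integer(median(mt$minimal_training_points)),
            min(mt$minimal_training_points), max(mt$minimal_training_points)))
cat(sprintf("%d/%d patients reached the 10%% prediction-accuracy criterion.\n",
            sum(mt$met_criterion), nrow(mt)))
cat(sprintf("Pooled R^2 over the %d PSA values held out at the minimal splits: %.3f\n",
            length(obs_all), goodness_of_fit(obs_all, pred_all)))
cat("Wrote results/minimal_training.tsv\n")
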