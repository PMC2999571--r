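test_that("PSA series bookkeeping validates and splits correctly", {
  s <- psa_series(c(-30, -1, 5, 40), c(4, 4.2, 4.1, 5), split_index = 3)
  expect_equal(training_set(s)$day, c(-30, -1, 5))
  expect_equal(validation_set(s)$psa, 5)
  expect_equal(validation_set(set_split(s, 4))$day, numeric(0))
  expect_error(psa_series(c(0, 0), c(1, 1)), "increasing")
  expect_error(psa_series(c(0, 1), c(1, -1)), "> 0")
  expect_error(psa_series(c(0, 1), c(1, 1), split_index = 3), "split_index")
})

test_that("PSA velocity is the log-linear slope", {
  t <- c(-100, -60, -31, -5, 10, 44)
  s <- psa_series(t, 4 * exp(0.01 * t))
  expect_equal(psa_velocity(s, c(-Inf, 44)), 0.01, tolerance = 1e-12)
  s2 <- psa_series(c(0, 100), c(2, 2))
  expect_equal(psa_velocity(s2, c(-Inf, 100)), 0)
  expect_error(psa_velocity(s2, c(-Inf, 50)), "insufficient-data")
})

test_that("velocity on noisy data equals the normal-equations solution", {
  set.seed(21)
  t <- sort(c(-90, -40, runif(6, -30, 80)))
  y <- 5 * exp(0.004 * t) * exp(rnorm(8, 0, 0.1))
  s <- psa_series(t, y)
  ## closed-form OLS oracle
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% log(y))
  expect_equal(psa_velocity(s, c(-Inf, 100)), beta[2], tolerance = 1e-12)
})

test_that("responders are patients whose PSA velocity dropped on treatment", {
  pre_t <- c(-84, -56, -28, 0)
  in_t <- c(14, 28, 56, 84)
  resp <- psa_series(c(pre_t, in_t), c(4 * exp(0.010 * pre_t), 4 * exp(0.004 * in_t)))
  expect_true(classify_responder(resp, std_prot))
  same <- psa_series(c(pre_t, in_t), 4 * exp(0.010 * c(pre_t, in_t)))
  expect_false(classify_responder(same, std_prot))  # strict inequality
  ## the four-cycle window ends at the fifth dose (day 84) by default
  expect_equal(std_prot$times_days[5], 84)
  few <- psa_series(c(-10, 5, 20), c(4, 4.1, 4.2))
  expect_error(classify_responder(few, std_prot), "insufficient-data")
})

test_that("a simulated responder is classified as such from its series", {
  pp <- patient_params(r = 3e-4, a_p = 2e-9, A = 2e-7, B = 2)
  spec <- cohort_spec(n_patients = 1, noise_cv = 0, seed = 5)
  s <- generate_psa_series(pp, std_gp, std_prot, spec, 1)
  expect_true(classify_responder(s, std_prot))
})

test_that("R-squared follows its definition, including the hand example", {
  expect_equal(goodness_of_fit(c(1, 5, 9), c(1, 5, 9)), 1)
  obs <- c(2, 4, 9)
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 3)), 0)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)), 0.5)  # 1 - 1/2
  expect_lt(goodness_of_fit(c(1, 2, 3), c(5, -2, 7)), 0)
  expect_error(goodness_of_fit(c(1, 1), c(1, 2)), "undefined-statistic")
  expect_error(goodness_of_fit(1, 1), "invalid-input")
})

test_that("underdetermined or pre-treatment-free training sets are refused", {
  s3 <- psa_series(c(-10, 5, 20, 40, 60), c(4, 4.2, 4.4, 4.6, 5), split_index = 3)
  expect_error(fit_patient(s3, std_prot, std_gp), "insufficient-data")
  s_nopre <- psa_series(c(5, 20, 40, 60, 90), c(4, 4.2, 4.4, 4.6, 5))
  expect_error(fit_patient(s_nopre, std_prot, std_gp), "pre-treatment")
})

test_that("fitting is deterministic and improves with more starts", {
  spec <- cohort_spec(n_patients = 1, noise_cv = 0.05, seed = 9)
  pp <- sample_virtual_patient(spec, 1)
  s <- generate_psa_series(pp, std_gp, std_prot, spec, 1)
  imm <- std_immune()
  f1 <- fit_patient(s, std_prot, std_gp, n_starts = 4, seed = 3, immune = imm)
  f2 <- fit_patient(s, std_prot, std_gp, n_starts = 4, seed = 3, immune = imm)
  expect_identical(f1, f2)
  ## the single-start run shares its start with the multi-start design
  f_one <- fit_patient(s, std_prot, std_gp, n_starts = 1, seed = 3, immune = imm)
  expect_lte(f1$sse, f_one$sse + 1e-9)
})

test_that("a treatment-insensitive series yields r from the log-slope and a_p at the floor", {
  pp <- patient_params(r = 2.5e-4, a_p = 0, A = 2e-7, B = 1)
  spec <- cohort_spec(n_patients = 1, noise_cv = 0, seed = 13)
  s <- generate_psa_series(pp, std_gp, std_prot, spec, 1)
  f <- fit_patient(s, std_prot, std_gp, n_starts = 8, seed = 3, immune = std_immune())
  expect_lt(rel_err(f$params$r, 2.5e-4), 0.01)
  expect_lt(f$params$a_p, 1e-11)
})

test_that("validation predictions reproduce noiseless observations", {
  spec <- cohort_spec(n_patients = 1, noise_cv = 0, seed = 17)
  pp <- sample_virtual_patient(spec, 1)
  s <- generate_psa_series(pp, std_gp, std_prot, spec, 1)
  f <- fit_patient(s, std_prot, std_gp, n_starts = 8, seed = 3, immune = std_immune())
  pred <- predict_validation(f, s, std_prot, std_gp)
  val <- validation_set(s)
  expect_equal(pred, val$psa, tolerance = 1e-3)
  expect_gt(goodness_of_fit(val$psa, pred), 0.999)
  f_bad <- f
  f_bad$converged <- FALSE
  expect_error(predict_validation(f_bad, s, std_prot, std_gp), "converge")
})

test_that("iterative training stops immediately on noiseless data", {
  spec <- cohort_spec(n_patients = 1, noise_cv = 0, seed = 19)
  pp <- sample_virtual_patient(spec, 1)
  s <- generate_psa_series(pp, std_gp, std_prot, spec, 1)
  it <- iterative_training(s, std_prot, std_gp, n_starts = 4, seed = 3)
  expect_true(it$met_criterion)
  expect_equal(it$split_index, sum(s$day < 0) + 2)
  expect_equal(nrow(it$trace), 1)
  expect_error(iterative_training(s, std_prot, std_gp, initial_k = 3),
               "initial_k")
  expect_error(iterative_training(s, std_prot, std_gp,
                                  initial_k = length(s$day)),
               "insufficient-data")
})
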