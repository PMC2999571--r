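test_that("virtual-patient draws are deterministic and range-respecting", {
  spec <- cohort_spec(n_patients = 50, seed = 4)
  p1 <- sample_virtual_patient(spec, 7)
  p2 <- sample_virtual_patient(spec, 7)
  expect_identical(p1, p2)
  draws <- lapply(1:50, function(i) sample_virtual_patient(spec, i))
  rs <- vapply(draws, `[[`, 0, "r")
  expect_true(all(rs >= 4e-5 & rs <= 9.6e-4))
  aps <- vapply(draws, `[[`, 0, "a_p")
  expect_true(all(aps >= 1e-10 & aps <= 2e-9))
  expect_error(sample_virtual_patient(spec, 51), "index")
  ## degenerate point-mass range
  spec_pt <- cohort_spec(n_patients = 3,
                         param_ranges = list(r = c(2e-4, 2e-4),
                                             a_p = c(5e-10, 5e-10),
                                             A = c(2e-7, 2e-7), B = c(3, 3)),
                         seed = 1)
  pp <- sample_virtual_patient(spec_pt, 2)
  expect_equal(pp$r, 2e-4)
  expect_equal(pp$B, 3)
})

test_that("ranges outside the fitting bounds are rejected", {
  expect_error(cohort_spec(param_ranges = list(r = c(1e-6, 9e-4),
                                               a_p = c(1e-10, 2e-9),
                                               A = c(5e-8, 5e-7), B = c(1, 10))),
               "bounds")
})

test_that("noiseless series reproduce the simulator exactly and obey the caps", {
  spec <- cohort_spec(n_patients = 2, noise_cv = 0, seed = 6)
  pp <- sample_virtual_patient(spec, 1)
  s <- generate_psa_series(pp, std_gp, std_prot, spec, 1)
  expect_lte(length(s$day), 26)
  expect_gte(s$split_index, 10)
  expect_lte(s$split_index, 15)
  expect_equal(sum(s$day < 0), 4)
  expect_equal(s$psa, simulate_course(pp, std_gp, std_prot, s$day)$psa)
  expect_equal(s$psa, attr(s, "psa_true"))
})

test_that("multiplicative noise has the configured coefficient of variation", {
  spec <- cohort_spec(n_patients = 20, noise_cv = 0.05, seed = 8)
  ratios <- unlist(lapply(generate_cohort(spec, std_gp, std_prot), function(p) {
    p$series$psa / attr(p$series, "psa_true") - 1
  }))
  expect_gte(stats::sd(ratios), 0.04)
  expect_lte(stats::sd(ratios), 0.06)
  expect_gt(min(ratios), -1)  # observed PSA stays positive
})

test_that("cohorts contain the requested mix of responders", {
  spec_all <- cohort_spec(n_patients = 15, noise_cv = 0, seed = 10,
                          responder_fraction = 1)
  coh <- generate_cohort(spec_all, std_gp, std_prot)
  cls <- vapply(coh, function(p) classify_responder(p$series, std_prot), TRUE)
  expect_true(all(cls))
  spec_none <- cohort_spec(n_patients = 8, noise_cv = 0, seed = 10,
                           responder_fraction = 0)
  coh0 <- generate_cohort(spec_none, std_gp, std_prot)
  expect_true(all(vapply(coh0, function(p) p$params$a_p == 0, TRUE)))
  cls0 <- vapply(coh0, function(p) classify_responder(p$series, std_prot), TRUE)
  expect_false(any(cls0))
  ## different seed, same schema, different values
  coh_b <- generate_cohort(cohort_spec(n_patients = 8, noise_cv = 0, seed = 11,
                                       responder_fraction = 0),
                           std_gp, std_prot)
  expect_false(identical(coh0[[1]]$series$psa, coh_b[[1]]$series$psa))
  expect_identical(names(coh0[[1]]), names(coh_b[[1]]))
})
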