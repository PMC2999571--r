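test_that("the homogeneous system has the all-zero equilibrium", {
  d <- derivatives(state_vector(), std_gp, demo_patient())
  expect_equal(unname(d), rep(0, 7))
})

test_that("vaccine uptake moves cells from V to Dm at rate k_i", {
  d <- derivatives(state_vector(V = 1e7), std_gp, demo_patient())
  expect_equal(d[["V"]], -6e5)
  expect_equal(d[["Dm"]], 6e5)
  expect_equal(unname(d[c("DC", "DR", "R", "C")]), rep(0, 4))
})

test_that("without effectors the tumor grows at rate r regardless of a_p", {
  for (ap in c(0, 1e-6, 1e-3)) {
    pp <- patient_params(r = 1e-3, a_p = ap, A = 1e-8, B = 1)
    d <- derivatives(state_vector(P = 1e8), std_gp, pp)
    expect_equal(d[["P"]], 1e5)
  }
})

test_that("derivatives agree with independent term-by-term evaluation", {
  ## arithmetic oracle: every term written out from the rate constants
  gp <- std_gp
  pp <- patient_params(r = 3e-4, a_p = 2e-9, A = 1e-7, B = 2)
  set.seed(11)
  for (i in 1:10) {
    s <- state_vector(V = runif(1, 0, 3e7), Dm = runif(1, 0, 1e7),
                      DC = runif(1, 0, 1e6), DR = runif(1, 0, 1e6),
                      R = runif(1, 0, 1e5), C = runif(1, 0, 5e6),
                      P = runif(1, 1e6, 1e9))
    expected <- c(
      V  = -0.06 * s[["V"]],
      Dm = 0.06 * s[["V"]] - 0.027 * s[["Dm"]],
      DC = 0.03 * 0.027 * s[["Dm"]] - 0.027 * s[["DC"]],
      DR = 0.027 * s[["DC"]] - 0.014 * s[["DR"]],
      R  = 3e-3 * s[["DR"]] - 0.03 * s[["R"]],
      C  = 0.38 * s[["DC"]] - 0.007 * s[["C"]] - 6e-7 * s[["R"]] * s[["C"]],
      P  = 3e-4 * s[["P"]] - 2e-9 * s[["C"]] * s[["P"]] * 1e8 / (1e8 + s[["P"]]))
    expect_equal(derivatives(s, gp, pp), expected, tolerance = 1e-12)
  }
})

test_that("the effector-damping variant saturates in C instead of P", {
  pp <- patient_params(r = 1e-6, a_p = 1e-9, A = 1e-8, B = 0)
  s <- state_vector(C = 3e8, P = 1e6)
  d_tum <- derivatives(s, std_gp, pp)
  d_eff <- derivatives(s, std_gp, pp, model_options(killing_damping = "effector"))
  expect_equal(d_tum[["P"]], 1e-6 * 1e6 - 1e-9 * 3e8 * 1e6 * 1e8 / (1e8 + 1e6))
  expect_equal(d_eff[["P"]], 1e-6 * 1e6 - 1e-9 * 3e8 * 1e6 * 1e8 / (1e8 + 3e8))
  expect_equal(d_tum[1:6], d_eff[1:6])
})

test_that("invalid states and parameters are rejected", {
  expect_error(derivatives(c(rep(0, 6), NaN), std_gp, demo_patient()), "invalid-input")
  expect_error(state_vector(V = -1), "invalid-input")
  expect_error(global_params(k_i = -0.1), "invalid-input")
  expect_error(global_params(alpha_l = 1.5), "invalid-input")
  expect_error(patient_params(r = 0, a_p = 0, A = 1e-8, B = 0), "invalid-input")
  expect_error(patient_params(r = 1e-4, a_p = -1, A = 1e-8, B = 0), "invalid-input")
})

test_that("dosing is an additive impulse on the vaccine compartment only", {
  s <- state_vector(Dm = 5, P = 1e8)
  s1 <- apply_dose(s, 2.4e7)
  expect_equal(s1[["V"]], 2.4e7)
  expect_equal(s1[c("Dm", "DC", "DR", "R", "C", "P")],
               s[c("Dm", "DC", "DR", "R", "C", "P")])
  expect_equal(apply_dose(s, 0), s)
  expect_equal(apply_dose(apply_dose(s, 1e7), 1e7)[["V"]], 2e7)
  expect_error(apply_dose(s, -1), "invalid-input")
})

test_that("the PSA map is affine in tumor burden and increasing", {
  pp <- patient_params(r = 1e-4, a_p = 0, A = 1e-8, B = 1)
  expect_equal(psa_observation(0, pp), 1)
  expect_equal(psa_observation(1e9, pp), 11)
  set.seed(3)
  for (i in 1:20) {
    pp2 <- patient_params(r = 1e-4, a_p = 0, A = 10^runif(1, -10, -6),
                          B = runif(1, 0, 20))
    P <- sort(runif(2, 0, 1e10))
    expect_lt(psa_observation(P[1], pp2), psa_observation(P[2], pp2))
  }
  ## power-law variant
  popts <- model_options(psa_map = "power")
  ppw <- patient_params(r = 1e-4, a_p = 0, A = 1e-4, B = 0.6)
  expect_equal(psa_observation(1e8, ppw, popts), 1e-4 * 1e8^0.6)
})

test_that("packaged parameter file reproduces the default constants", {
  path <- system.file("extdata", "global_params.yaml", package = "psavax")
  expect_equal(read_global_params(path), std_gp)
  expect_error(read_global_params(textConnection("bogus_key: 1")))
})
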