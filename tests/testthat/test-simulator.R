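test_that("the standard schedule is 3 biweekly then 11 monthly doses", {
  p <- make_standard_protocol(2.4e7, 14)
  expect_length(p$times_days, 14)
  expect_equal(p$times_days, c(0, 14, 28, seq(56, 336, by = 28)))
  expect_equal(p$doses_cells, rep(2.4e7, 14))
  expect_equal(p$horizon_days, 364)
  expect_equal(make_standard_protocol(1e7, 1)$times_days, 0)
  expect_equal(make_standard_protocol(1e7, 3)$times_days, c(0, 14, 28))
})

test_that("protocol construction rejects malformed event lists", {
  expect_error(protocol(c(14, 28), 1e7), "day 0")
  expect_error(protocol(c(0, 28, 14), 1e7), "increasing")
  expect_error(protocol(c(0, 14), -1), ">= 0")
  expect_error(protocol(c(0, 14), 1e7, horizon_days = 7), "horizon")
})

test_that("modified schedules scale dose and spacing as requested", {
  expect_identical(make_modified_protocol(1.0, 28, 14, 2.4e7),
                   make_standard_protocol(2.4e7, 14))
  doubled <- make_modified_protocol(2.0, 28, 14, 2.4e7)
  expect_equal(doubled$times_days, make_standard_protocol()$times_days)
  expect_equal(doubled$doses_cells, rep(4.8e7, 14))
  expect_equal(make_modified_protocol(3.0, 28, 14, 2.4e7)$doses_cells,
               rep(7.2e7, 14))
  p21 <- make_modified_protocol(1.0, 21, 14, 2.4e7)
  expect_equal(diff(p21$times_days), c(14, 14, rep(21, 11)))
  p7 <- make_modified_protocol(1.0, 7, 14, 2.4e7)
  expect_equal(diff(p7$times_days), rep(7, 13))
  expect_error(make_modified_protocol(1.0, 0.5), "interval_days")
  ## duration-preserving variant keeps dosing over the ~1-year span
  pd <- make_modified_protocol(1.0, 14, 14, 2.4e7, preserve = "duration")
  expect_gt(length(pd$times_days), 14)
  expect_lte(utils::tail(pd$times_days, 1), 336)
})

test_that("with no killing the PSA course is the exponential closed form", {
  pp <- patient_params(r = 3e-4, a_p = 0, A = 1e-7, B = 3)
  tt <- c(-112, -56, -10, 0, 30, 100, 250, 364)
  tr <- simulate_course(pp, std_gp, std_prot, tt)
  expect_equal(tr$psa, 1e-7 * 1e8 * exp(3e-4 * 24 * tt) + 3, tolerance = 1e-7)
})

test_that("an all-zero-dose course leaves the immune system silent", {
  pp <- demo_patient()
  empty <- protocol(std_prot$times_days, 0, std_prot$horizon_days)
  tr <- simulate_course(pp, std_gp, empty, c(0, 50, 200, 364))
  expect_equal(max(abs(as.matrix(tr[, c("V", "Dm", "DC", "DR", "R", "C")]))), 0)
  expect_equal(tr$P, 1e8 * exp(pp$r * 24 * tr$day), tolerance = 1e-7)
})

test_that("immune dynamics are independent of the patient parameters", {
  tt <- c(10, 84, 200)
  tr1 <- simulate_course(demo_patient(), std_gp, std_prot, tt)
  tr2 <- simulate_course(patient_params(9e-4, 2e-9, 5e-7, 9), std_gp, std_prot, tt)
  expect_equal(tr1[, c("V", "Dm", "DC", "DR", "R", "C")],
               tr2[, c("V", "Dm", "DC", "DR", "R", "C")], tolerance = 1e-10)
})

test_that("one-call simulation equals manual segment-by-segment hand-off", {
  pp <- demo_patient()
  tr <- simulate_course(pp, std_gp, std_prot, c(100, 364))
  ## by hand: run to day 100, restart from the stored state
  tr_a <- simulate_course(pp, std_gp, std_prot, 100)
  y <- unlist(tr_a[1, c("V", "Dm", "DC", "DR", "R", "C", "P")])
  later <- std_prot$times_days[std_prot$times_days > 100]
  rhs <- function(t, yy, p) list(derivatives(yy, std_gp, pp))
  seg <- psavax:::.integrate_impulsive(y, 100 * 24, later * 24,
                                       rep(2.4e7, length(later)), 364 * 24,
                                       1e-8, 1e-6, func = rhs, parms = NULL)
  expect_equal(unname(seg$states[1, ]),
               unname(unlist(tr[2, c("V", "Dm", "DC", "DR", "R", "C", "P")])),
               tolerance = 1e-7)
})

test_that("halving solver tolerances moves PSA by far less than 0.1%", {
  pp <- demo_patient()
  tt <- c(-28, 14, 84, 180, 364)
  a <- simulate_course(pp, std_gp, std_prot, tt, rtol = 1e-8, atol = 1e-6)
  b <- simulate_course(pp, std_gp, std_prot, tt, rtol = 5e-9, atol = 5e-7)
  expect_lt(max(abs(a$psa / b$psa - 1)), 1e-3)
})

test_that("end-of-course tumor burden is non-increasing in the dose factor", {
  pp <- patient_params(r = 3e-4, a_p = 3e-10, A = 2e-7, B = 3)
  pend <- vapply(c(1, 1.5, 2, 3, 5, 8), function(f) {
    prot <- make_modified_protocol(f, 28, 14, 2.4e7)
    simulate_course(pp, std_gp, prot, 364)$P
  }, 0)
  expect_true(all(diff(pend) <= 0))
})

test_that("the decoupled fast path reproduces the whole-system solver", {
  pp <- demo_patient()
  tt <- c(-56, 0, 14, 84, 200, 364)
  full <- simulate_course(pp, std_gp, std_prot, tt)
  fast <- simulate_psa(pp, std_gp, std_prot, tt, immune = std_immune())
  expect_equal(fast, full$psa, tolerance = 1e-4)
})

test_that("observation times may be unsorted and duplicated", {
  pp <- demo_patient()
  tt <- c(100, -28, 364, 100)
  tr <- simulate_course(pp, std_gp, std_prot, tt)
  expect_equal(tr$day, tt)
  expect_equal(tr$psa[1], tr$psa[4])
  expect_error(simulate_course(pp, std_gp, std_prot, 400), "horizon")
  expect_error(simulate_course(pp, std_gp, std_prot, 10, pre_treatment_start = 5),
               "pre_treatment_start")
})
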