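## Shared fixtures. Expensive objects (fitted cohorts) are built once per
## test run and cached, because several acceptance properties examine the
## same calibrated virtual patients.

std_gp <- global_params()
std_prot <- make_standard_protocol()

.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

std_immune <- function() fixture("immune", function() immune_course(std_gp, std_prot))

## 20 virtual patients at a given noise level, each with a 12-point
## training set, fitted by the package's calibration routine.
fitted_cohort <- function(noise_cv, n = 20, seed = 42, n_starts = 16) {
  fixture(sprintf("fits_cv%g_n%d", noise_cv, n), function() {
    spec <- cohort_spec(n_patients = n, noise_cv = noise_cv, seed = seed)
    imm <- std_immune()
    lapply(seq_len(n), function(i) {
      pp <- sample_virtual_patient(spec, i)
      s <- generate_psa_series(pp, std_gp, std_prot, spec, i)
      fit <- fit_patient(s, std_prot, std_gp, n_starts = n_starts, seed = 7,
                         immune = imm)
      list(patient_id = i, truth = pp, series = s, fit = fit)
    })
  })
}

## a mid-strength virtual responder used by several construction-level tests
demo_patient <- function() patient_params(r = 2e-4, a_p = 5e-10, A = 2e-7, B = 2)

rel_err <- function(est, truth) abs(est / truth - 1)
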