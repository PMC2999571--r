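#' Specification of a virtual-patient cohort
#'
#' Describes how to draw patient-specific parameters and how to sample and
#' perturb each virtual patient's PSA series so that the cohort mimics the
#' statistical structure of a biochemical-relapse vaccination trial:
#' exponentially rising pre-treatment PSA (doubling times of roughly 1-24
#' months), a handful of monthly pre-treatment measurements, in-treatment
#' measurements at vaccinations plus sporadic mid-cycle draws, at most 26
#' observations per patient, and multiplicative (lognormal) assay noise.
#'
#' Parameters are drawn log-uniformly within `param_ranges` (scales span
#' orders of magnitude); a configurable fraction of patients are
#' non-responders with `a_p = 0` (vaccination without anti-tumor effect).
#'
#' @param n_patients cohort size.
#' @param param_ranges named list of `c(lower, upper)` ranges for `r`
#'   (h^-1), `a_p` (cell^-1 h^-1, responders), `A` ((ng/mL)/cell), `B`
#'   (ng/mL); must lie within [default_fit_bounds()].
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise (default 0.05).
#' @param n_pre number of pre-treatment measurements (monthly, default 4).
#' @param n_obs_max cap on total observations per patient (default 26).
#' @param n_train default training-set size (default 12).
#' @param responder_fraction fraction of patients with `a_p > 0`.
#' @param seed integer; all cohort randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 15,
                        param_ranges = list(r = c(4e-5, 9.6e-4),
                                            a_p = c(1e-10, 2e-9),
                                            A = c(5e-8, 5e-7),
                                            B = c(1, 10)),
                        noise_cv = 0.05, n_pre = 4, n_obs_max = 26,
                        n_train = 12, responder_fraction = 1, seed = 1L) {
  if (n_patients < 1) stop("invalid-input: n_patients must be >= 1", call. = FALSE)
  if (noise_cv < 0) stop("invalid-input: noise_cv must be >= 0", call. = FALSE)
  if (n_pre < 2) stop("invalid-input: n_pre must be >= 2", call. = FALSE)
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("invalid-input: responder_fraction must lie in [0, 1]", call. = FALSE)
  }
  fb <- default_fit_bounds()
  for (nm in c("r", "a_p", "A", "B")) {
    rg <- param_ranges[[nm]]
    if (is.null(rg) || length(rg) != 2 || rg[1] > rg[2]) {
      stop("invalid-input: param_ranges$", nm, " must be c(lower, upper)", call. = FALSE)
    }
    if (rg[1] < fb[[nm]][1] || rg[2] > fb[[nm]][2]) {
      stop("invalid-input: param_ranges$", nm, " outside the fitting bounds", call. = FALSE)
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 param_ranges = param_ranges, noise_cv = noise_cv,
                 n_pre = as.integer(n_pre), n_obs_max = as.integer(n_obs_max),
                 n_train = as.integer(n_train),
                 responder_fraction = responder_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Per-patient substream seed; keeps derived seeds well inside 32-bit range.
.patient_seed <- function(spec, index, salt = 0L) {
  (abs(spec$seed) %% 1000003L) * 1009L + 127L * index + salt
}

.log_uniform <- function(rg) {
  if (rg[1] == rg[2]) return(rg[1])
  10^stats::runif(1, log10(rg[1]), log10(rg[2]))
}

#' Draw one virtual patient's parameters
#'
#' Deterministic given `(spec$seed, index)`. Patients with
#' `index > responder_fraction * n_patients` are non-responders
#' (`a_p = 0`); responders draw `a_p` log-uniformly from its range. `P0`
#' is fixed at the package convention of `1e8` cells.
#'
#' @param spec a [cohort_spec()].
#' @param index patient index in `1:n_patients`.
#' @return A [patient_params()].
#' @export
sample_virtual_patient <- function(spec, index) {
  if (index < 1 || index > spec$n_patients) {
    stop("invalid-input: index out of range", call. = FALSE)
  }
  responder <- index <= round(spec$responder_fraction * spec$n_patients)
  with_local_seed(.patient_seed(spec, index), {
    patient_params(
      r = .log_uniform(spec$param_ranges$r),
      a_p = if (responder) .log_uniform(spec$param_ranges$a_p) else 0,
      A = .log_uniform(spec$param_ranges$A),
      B = stats::runif(1, spec$param_ranges$B[1], spec$param_ranges$B[2]))
  })
}

#' Generate one virtual patient's PSA series
#'
#' Observation times: `n_pre` monthly pre-treatment measurements (every 28
#' days back from day -28), a measurement at every vaccination day, and
#' sporadic mid-cycle/post-course measurements drawn at random until the
#' `n_obs_max` cap. The noiseless PSA comes from [simulate_course()]; the
#' observed PSA multiplies it by lognormal noise with unit mean and
#' coefficient of variation `noise_cv`. Deterministic given
#' `(spec$seed, index)`.
#'
#' @param pp the patient's [patient_params()].
#' @param gp [global_params()].
#' @param protocol the vaccination [protocol()].
#' @param spec a [cohort_spec()].
#' @param index patient index (selects the noise/sampling substream).
#' @return A [psa_series()] with `split_index = spec$n_train`; the
#'   noiseless PSA values are attached as attribute `"psa_true"`.
#' @export
generate_psa_series <- function(pp, gp, protocol, spec, index = 1L) {
  pre_days <- -rev(seq_len(spec$n_pre)) * 28
  dose_days <- protocol$times_days
  n_extra <- max(0, spec$n_obs_max - length(pre_days) - length(dose_days))
  gaps <- diff(c(protocol$times_days, protocol$horizon_days))
  candidates <- protocol$times_days + gaps / 2
  with_local_seed(.patient_seed(spec, index, salt = 31L), {
    extra <- if (n_extra > 0) {
      sample(candidates, min(n_extra, length(candidates)))
    } else numeric(0)
    days <- sort(unique(c(pre_days, dose_days, extra)))
    days <- utils::head(days, spec$n_obs_max)
    truth <- simulate_course(pp, gp, protocol, days)$psa
    obs <- if (spec$noise_cv > 0) {
      sigma <- sqrt(log(1 + spec$noise_cv^2))
      truth * stats::rlnorm(length(truth), meanlog = -sigma^2 / 2, sdlog = sigma)
    } else truth
    out <- psa_series(days, obs, split_index = min(spec$n_train, length(days)))
    attr(out, "psa_true") <- truth
    out
  })
}

#' Generate a full virtual cohort
#'
#' @param spec a [cohort_spec()].
#' @param gp [global_params()].
#' @param protocol the vaccination [protocol()]; default standard schedule.
#' @return A list of `n_patients` elements, each a list with `patient_id`,
#'   `params` (ground truth), `series`, and `responder_true` (whether the
#'   generating `a_p` is positive).
#' @export
generate_cohort <- function(spec, gp = global_params(),
                            protocol = make_standard_protocol()) {
  lapply(seq_len(spec$n_patients), function(i) {
    pp <- sample_virtual_patient(spec, i)
    list(patient_id = i,
         params = pp,
         series = generate_psa_series(pp, gp, protocol, spec, i),
         responder_true = pp$a_p > 0)
  })
}
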