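#' PSA stabilization criterion
#'
#' A regimen stabilizes a patient when the predicted in-treatment PSA never
#' rises more than `tolerance` (default 10%) above the pre-treatment level.
#' Two variants are provided: `"max"` (default) requires
#' `PSA(t) <= (1 + tolerance) * baseline_psa` at every reported time in
#' `(0, end of course]`; `"end"` requires it only at the end of the course.
#'
#' @param trajectory a `trajectory` from [simulate_course()] (or any data
#'   frame with `day` and `psa` columns) covering the treatment period.
#' @param baseline_psa pre-treatment PSA level, ng/mL (> 0).
#' @param tolerance allowed fractional elevation (default 0.10).
#' @param criterion `"max"` or `"end"`.
#' @return `TRUE` if the criterion is met.
#' @export
stabilization_ok <- function(trajectory, baseline_psa, tolerance = 0.10,
                             criterion = c("max", "end")) {
  criterion <- match.arg(criterion)
  if (!is.finite(baseline_psa) || baseline_psa <= 0) {
    stop("invalid-input: baseline_psa must be > 0", call. = FALSE)
  }
  sel <- trajectory$day > 0
  if (!any(sel)) stop("invalid-input: trajectory has no in-treatment points", call. = FALSE)
  cap <- (1 + tolerance) * baseline_psa
  if (criterion == "max") {
    all(trajectory$psa[sel] <= cap)
  } else {
    trajectory$psa[sel][which.max(trajectory$day[sel])] <= cap
  }
}

.fit_params <- function(fit) {
  if (inherits(fit, "fit_result")) {
    if (!fit$converged) stop("invalid-input: fit did not converge", call. = FALSE)
    fit$params
  } else if (inherits(fit, "patient_params")) {
    fit
  } else {
    stop("invalid-input: expected a fit_result or patient_params", call. = FALSE)
  }
}

.regimen_psa_pass <- function(pp, gp, protocol, immune, baseline, tolerance,
                              criterion, eval_step_days, opts, rtol, atol) {
  days <- sort(unique(c(seq(eval_step_days, protocol$horizon_days,
                            by = eval_step_days), protocol$horizon_days)))
  psa <- simulate_psa(pp, gp, protocol, days, immune = immune,
                      opts = opts, rtol = rtol, atol = atol)
  stabilization_ok(data.frame(day = days, psa = psa), baseline,
                   tolerance = tolerance, criterion = criterion)
}

.recommendation <- function(patient_id, type, value, achievable, criterion,
                            tolerance, baseline_psa, trace) {
  structure(list(patient_id = patient_id, type = type, value = value,
                 achievable = achievable,
                 criterion = sprintf(
                   "PSA %s over the course <= %.0f%% above pre-treatment (%s)",
                   if (criterion == "max") "at every day" else "at end of course",
                   100 * tolerance, criterion),
                 tolerance = tolerance, baseline_psa = baseline_psa,
                 search_trace = trace),
            class = "regimen_recommendation")
}

#' @export
print.regimen_recommendation <- function(x, ...) {
  what <- if (x$type == "dose") "minimal dose factor" else "maximal interval (days)"
  val <- if (x$achievable) format(signif(x$value, 3)) else "not achievable"
  cat(sprintf("Regimen recommendation%s: %s = %s\n  criterion: %s\n",
              if (is.null(x$patient_id)) "" else paste0(" (patient ", x$patient_id, ")"),
              what, val, x$criterion))
  invisible(x)
}

#' Minimal vaccine-dose increase that stabilizes PSA
#'
#' Scans graded dose increases (factors 1.0, 1.1, 1.2, ... of the standard
#' dose, at the standard spacing) for the individualized model, simulating
#' each candidate course, and returns the smallest factor whose predicted
#' PSA passes [stabilization_ok()]. With `refine = TRUE` the boundary
#' between the last failing and first passing grid factor is bisected to
#' about 3 significant figures. Not achievable if no factor up to
#' `factor_max` passes (in particular whenever `a_p = 0`: the vaccine then
#' has no effect at any dose).
#'
#' @param fit a converged [fit_patient()] result (or bare
#'   [patient_params()]).
#' @param gp [global_params()].
#' @param base_protocol the standard-schedule [protocol()] carrying the
#'   standard dose.
#' @param factor_step grid step for the dose factor (default 0.10).
#' @param factor_max largest factor scanned (default 30).
#' @param refine bisect between the bracketing grid factors (default TRUE).
#' @param tolerance,criterion see [stabilization_ok()].
#' @param eval_step_days spacing of the PSA evaluation grid, days.
#' @param patient_id optional label carried into the recommendation.
#' @param opts [model_options()].
#' @param rtol,atol solver tolerances.
#' @return A `regimen_recommendation`; field `value` is the minimal dose
#'   factor (NA when not achievable), `search_trace` the evaluated
#'   (factor, pass) pairs.
#' @export
find_min_dose_factor <- function(fit, gp, base_protocol,
                                 factor_step = 0.10, factor_max = 30,
                                 refine = TRUE, tolerance = 0.10,
                                 criterion = c("max", "end"),
                                 eval_step_days = 1, patient_id = NULL,
                                 opts = model_options(),
                                 rtol = 1e-8, atol = 1e-6) {
  criterion <- match.arg(criterion)
  pp <- .fit_params(fit)
  baseline <- psa_observation(pp$P0, pp, opts)
  eval_factor <- function(f) {
    imm <- immune_course(gp, base_protocol, dose_factor = f,
                         rtol = rtol, atol = atol)
    .regimen_psa_pass(pp, gp, base_protocol, imm, baseline, tolerance,
                      criterion, eval_step_days, opts, rtol, atol)
  }
  factors <- seq(1, factor_max, by = factor_step)
  trace <- data.frame(value = numeric(0), pass = logical(0))
  first_pass <- NA_real_
  last_fail <- NA_real_
  for (f in factors) {
    ok <- eval_factor(f)
    trace <- rbind(trace, data.frame(value = f, pass = ok))
    if (ok) { first_pass <- f; break }
    last_fail <- f
  }
  if (is.na(first_pass)) {
    return(.recommendation(patient_id, "dose", NA_real_, FALSE, criterion,
                           tolerance, baseline, trace))
  }
  value <- first_pass
  if (refine && !is.na(last_fail)) {
    lo <- last_fail; hi <- first_pass
    while ((hi - lo) > 1e-3 * hi) {
      mid <- (lo + hi) / 2
      ok <- eval_factor(mid)
      trace <- rbind(trace, data.frame(value = mid, pass = ok))
      if (ok) hi <- mid else lo <- mid
    }
    value <- hi
  }
  .recommendation(patient_id, "dose", value, TRUE, criterion, tolerance,
                  baseline, trace)
}

#' Maximal administration interval that stabilizes PSA
#'
#' Scans graded one-day reductions of the administration interval (28, 27,
#' ..., 1 days) at the standard dose, simulating each candidate schedule
#' built by [make_modified_protocol()], and returns the largest interval
#' whose predicted PSA passes [stabilization_ok()]. Not achievable if even
#' daily dosing fails.
#'
#' Stabilization is judged through the end of the *standard* treatment
#' span (day 364 for the 14-dose schedule), so a regimen cannot pass
#' merely by ending early. By default interval reduction keeps dosing over
#' that whole span (`preserve = "duration"`, adding doses as the interval
#' shrinks — daily dosing means daily for the year); with
#' `preserve = "n_doses"` the 14 doses compress and shorter intervals
#' rarely help, since the same total dose is followed by a long untreated
#' tail.
#'
#' @param fit a converged [fit_patient()] result (or bare
#'   [patient_params()]).
#' @param gp [global_params()].
#' @param base_dose standard per-dose cell count.
#' @param intervals candidate intervals, days, scanned in the given
#'   (descending) order.
#' @param n_doses doses per course (see [make_modified_protocol()]).
#' @param preserve `"n_doses"` or `"duration"`, see
#'   [make_modified_protocol()].
#' @param tolerance,criterion see [stabilization_ok()].
#' @param eval_step_days spacing of the PSA evaluation grid, days.
#' @param patient_id optional label.
#' @param opts [model_options()].
#' @param rtol,atol solver tolerances.
#' @return A `regimen_recommendation`; field `value` is the maximal
#'   interval in days (NA when not achievable).
#' @export
find_max_interval <- function(fit, gp, base_dose = 2.4e7, intervals = 28:1,
                              n_doses = 14, preserve = c("duration", "n_doses"),
                              tolerance = 0.10, criterion = c("max", "end"),
                              eval_step_days = 1, patient_id = NULL,
                              opts = model_options(),
                              rtol = 1e-8, atol = 1e-6) {
  criterion <- match.arg(criterion)
  preserve <- match.arg(preserve)
  pp <- .fit_params(fit)
  baseline <- psa_observation(pp$P0, pp, opts)
  eval_end <- make_standard_protocol(base_dose, n_doses)$horizon_days
  trace <- data.frame(value = numeric(0), pass = logical(0))
  for (iv in intervals) {
    prot <- make_modified_protocol(1, iv, n_doses, base_dose, preserve)
    prot$horizon_days <- max(prot$horizon_days, eval_end)
    imm <- immune_course(gp, prot, rtol = rtol, atol = atol)
    ok <- .regimen_psa_pass(pp, gp, prot, imm, baseline, tolerance,
                            criterion, eval_step_days, opts, rtol, atol)
    trace <- rbind(trace, data.frame(value = iv, pass = ok))
    if (ok) {
      return(.recommendation(patient_id, "interval", iv, TRUE, criterion,
                             tolerance, baseline, trace))
    }
  }
  .recommendation(patient_id, "interval", NA_real_, FALSE, criterion,
                  tolerance, baseline, trace)
}
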