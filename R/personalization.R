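#' A patient's PSA time series with a training/validation split
#'
#' Timestamped PSA observations for one patient, ordered in time, together
#' with `split_index`: the number of leading observations that form the
#' training set (used for calibration); the remainder is the validation
#' set (used only to score predictions).
#'
#' @param day observation times, days relative to the first vaccination
#'   (strictly increasing; negative = pre-treatment).
#' @param psa PSA values, ng/mL (> 0).
#' @param split_index integer in `[0, length(day)]`.
#' @return An object of class `psa_series`.
#' @export
psa_series <- function(day, psa, split_index = length(day)) {
  if (length(day) != length(psa)) {
    stop("invalid-input: day and psa lengths differ", call. = FALSE)
  }
  if (any(diff(day) <= 0)) {
    stop("invalid-input: observation times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(psa)) || any(psa <= 0)) {
    stop("invalid-input: PSA values must be finite and > 0", call. = FALSE)
  }
  split_index <- as.integer(split_index)
  if (split_index < 0 || split_index > length(day)) {
    stop("invalid-input: split_index out of range", call. = FALSE)
  }
  structure(list(day = as.numeric(day), psa = as.numeric(psa),
                 split_index = split_index),
            class = "psa_series")
}

#' @rdname psa_series
#' @param series a `psa_series`.
#' @export
training_set <- function(series) {
  idx <- seq_len(series$split_index)
  data.frame(day = series$day[idx], psa = series$psa[idx])
}

#' @rdname psa_series
#' @export
validation_set <- function(series) {
  n <- length(series$day)
  idx <- if (series$split_index < n) (series$split_index + 1):n else integer(0)
  data.frame(day = series$day[idx], psa = series$psa[idx])
}

#' @rdname psa_series
#' @export
set_split <- function(series, split_index) {
  psa_series(series$day, series$psa, split_index)
}

#' @export
print.psa_series <- function(x, ...) {
  cat(sprintf("PSA series: %d observations (%d training / %d validation), days %g to %g\n",
              length(x$day), x$split_index, length(x$day) - x$split_index,
              min(x$day), max(x$day)))
  invisible(x)
}

#' PSA velocity: log-linear slope over a time window
#'
#' Ordinary least-squares slope of `ln(PSA)` against time (days) over the
#' observations falling in the half-open window `(window[1], window[2]]`.
#' A positive velocity is rising PSA; an exponentially growing PSA with
#' rate `r` per hour has velocity `24 * r` per day.
#'
#' @param series a [psa_series()].
#' @param window numeric length-2, days; points with
#'   `day > window[1] & day <= window[2]` are used.
#' @return Slope in 1/day.
#' @export
psa_velocity <- function(series, window) {
  sel <- series$day > window[1] & series$day <= window[2]
  if (sum(sel) < 2) {
    stop("insufficient-data: need >= 2 observations in the window", call. = FALSE)
  }
  t <- series$day[sel]
  y <- log(series$psa[sel])
  unname(stats::cov(t, y) / stats::var(t))
}

#' Classify a patient as a vaccination responder
#'
#' A patient responds if vaccination reduced the PSA velocity: the
#' log-linear slope over the first `n_cycles` treatment cycles is strictly
#' smaller than the pre-treatment slope. The pre-treatment window is all
#' observations at day <= 0; the in-treatment window is `(0, end of the
#' n_cycles-th cycle]`, where cycle boundaries follow the protocol's dose
#' spacing (day 84 for four cycles of the standard 14/14/28/28-day
#' structure).
#'
#' @param series a [psa_series()].
#' @param protocol the vaccination [protocol()]; used to locate cycle
#'   boundaries.
#' @param n_cycles number of initial treatment cycles in the in-treatment
#'   window.
#' @param in_window_end optional explicit end of the in-treatment window
#'   (days), overriding the protocol-derived boundary.
#' @return `TRUE` if responder.
#' @export
classify_responder <- function(series, protocol = make_standard_protocol(),
                               n_cycles = 4, in_window_end = NULL) {
  if (is.null(in_window_end)) {
    tt <- protocol$times_days
    in_window_end <- if (length(tt) > n_cycles) tt[n_cycles + 1] else protocol$horizon_days
  }
  v_pre <- psa_velocity(series, c(-Inf, 0))
  v_in <- psa_velocity(series, c(0, in_window_end))
  v_in < v_pre
}

#' Coefficient of determination between observed and predicted PSA
#'
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the mean of the
#' observed values. Can be negative when predictions are worse than the
#' observed mean.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return R-squared (dimensionless).
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("invalid-input: need equal-length vectors with >= 2 values", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("undefined-statistic: observed values have zero variance", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Default box constraints for patient-parameter estimation
#'
#' `r` spans PSA doubling times from about six days to eight years; `a_p`
#' from no effect to far above any plausible killing efficacy; `A` and `B`
#' bracket the observable PSA scale. `r`, `a_p` and `A` are optimized in
#' log10 space (each spans orders of magnitude); `B` linearly. A zero lower
#' bound on `a_p` is represented in log space by the floor `1e-12`
#' cell^-1 h^-1, which is dynamically indistinguishable from zero.
#'
#' @return Named list of `c(lower, upper)` pairs for `r`, `a_p`, `A`, `B`.
#' @export
default_fit_bounds <- function() {
  list(r = c(1e-5, 5e-3), a_p = c(0, 1e-3), A = c(1e-12, 1e-4), B = c(0, 50))
}

.AP_LOG_FLOOR <- 1e-12

## transformed (optimizer) space: log10 r, log10 a_p, log10 A, B
.theta_to_pp <- function(th, P0 = 1e8) {
  patient_params(r = 10^th[1], a_p = 10^th[2], A = 10^th[3], B = th[4], P0 = P0)
}

.bounds_to_theta <- function(bounds) {
  lo <- c(log10(bounds$r[1]), log10(max(bounds$a_p[1], .AP_LOG_FLOOR)),
          log10(bounds$A[1]), bounds$B[1])
  hi <- c(log10(bounds$r[2]), log10(max(bounds$a_p[2], .AP_LOG_FLOOR)),
          log10(bounds$A[2]), bounds$B[2])
  list(lo = lo, hi = hi)
}

## Data-driven initial guess: growth rate from the pre-treatment log-slope,
## PSA scale from the observation nearest day 0, modest killing efficacy.
.smart_start <- function(train, tb, P0 = 1e8) {
  pre <- train[train$day <= 0, , drop = FALSE]
  sl <- if (nrow(pre) >= 2) {
    stats::cov(pre$day, log(pre$psa)) / stats::var(pre$day)
  } else {
    0.2 / 30
  }
  r0 <- min(max(sl / 24, 10^tb$lo[1] * 1.01), 10^tb$hi[1] * 0.99)
  B0 <- min(max(0.25 * min(train$psa), tb$lo[4]), tb$hi[4])
  i0 <- which.min(abs(train$day))
  psa0 <- train$psa[i0] / exp(r0 * 24 * train$day[i0])
  A0 <- min(max((psa0 - B0) / P0, 10^tb$lo[3] * 1.01), 10^tb$hi[3] * 0.99)
  c(log10(r0), log10(1e-10), log10(A0), B0)
}

## Exact box-constrained least squares for the PSA observation pair (A, B)
## given the unit-scale tumor curve x(t) and observations y: the linear
## subproblem of the variable-projection fit. Returns c(A, B).
.solve_AB <- function(x, y, Ab, Bb) {
  clamp <- function(v, b) min(max(v, b[1]), b[2])
  sxx <- sum((x - mean(x))^2)
  cand <- list()
  if (sxx > 0) {
    Au <- sum((x - mean(x)) * (y - mean(y))) / sxx
    Bu <- mean(y) - Au * mean(x)
    if (Au >= Ab[1] && Au <= Ab[2] && Bu >= Bb[1] && Bu <= Bb[2]) {
      return(c(Au, Bu))
    }
  }
  for (A in Ab) cand <- c(cand, list(c(A, clamp(mean(y - A * x), Bb))))
  for (B in Bb) {
    A <- if (sum(x^2) > 0) sum(x * (y - B)) / sum(x^2) else Ab[1]
    cand <- c(cand, list(c(clamp(A, Ab), B)))
  }
  sse <- vapply(cand, function(ab) sum((ab[1] * x + ab[2] - y)^2), 0)
  cand[[which.min(sse)]]
}

#' Calibrate the patient-specific parameters to a PSA training set
#'
#' Minimizes the sum of squared PSA residuals over the training set (the
#' first `split_index` observations) with respect to `(r, a_p, A, B)`,
#' subject to box constraints. Because the initial tumor burden is fixed by
#' convention, the tumor curve depends only on `(r, a_p)` and the default
#' linear PSA map enters the observation linearly, so the fit uses variable
#' projection: a bounded Levenberg-Marquardt search over
#' `(log10 r, log10 a_p)` in which the optimal `(A, B)` is obtained
#' exactly, by box-constrained linear least squares, at every step. The
#' search runs from one data-driven start plus `n_starts - 1` seeded
#' Latin-hypercube starts, and the best solution is polished by a final
#' Levenberg-Marquardt pass over all four parameters. Deterministic given
#' `seed`. (With the log-scale objective or the power-law PSA map the
#' linear subproblem is unavailable and all four parameters are searched
#' directly from the multi-start design.)
#'
#' @param series a [psa_series()]; the training set must have at least 5
#'   points including at least one pre-treatment (day < 0) observation.
#' @param protocol the patient's vaccination [protocol()].
#' @param gp [global_params()].
#' @param bounds parameter box, as [default_fit_bounds()].
#' @param n_starts number of local optimizations (>= 1).
#' @param seed integer seed for the start design.
#' @param objective `"linear"` (default): residuals on the PSA scale, the
#'   plain least-squares objective; `"log"`: residuals on log PSA.
#' @param opts [model_options()].
#' @param immune optional precomputed [immune_course()] for `protocol`.
#' @param rtol,atol solver tolerances.
#' @return An object of class `fit_result`: fields `params`
#'   ([patient_params()]), `sse` (sum of squared residuals, (ng/mL)^2),
#'   `n_train`, `predicted` (model PSA at all series times),
#'   `predicted_validation`, `converged`, `n_starts`, `seed`,
#'   `start_objectives` (best objective per start).
#' @export
fit_patient <- function(series, protocol, gp, bounds = default_fit_bounds(),
                        n_starts = 16, seed = 1L,
                        objective = c("linear", "log"),
                        opts = model_options(), immune = NULL,
                        rtol = 1e-8, atol = 1e-6) {
  objective <- match.arg(objective)
  train <- training_set(series)
  if (nrow(train) < 5) {
    stop("insufficient-data: training set must have >= 5 points", call. = FALSE)
  }
  if (!any(train$day < 0)) {
    stop("insufficient-data: training set needs >= 1 pre-treatment (day < 0) point",
         call. = FALSE)
  }
  if (is.null(immune)) immune <- immune_course(gp, protocol, rtol = rtol, atol = atol)
  tb <- .bounds_to_theta(bounds)
  ## epsfcn sets the finite-difference step well above the ODE-solver noise
  ## floor; with the default machine-epsilon step the Jacobian is dominated
  ## by integration error and the search stalls.
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13,
                                     maxiter = 200, epsfcn = 1e-12)

  obs <- train$psa
  resid_fn <- function(th) {
    pp <- .theta_to_pp(th)
    pred <- tryCatch(
      simulate_psa(pp, gp, protocol, train$day, immune = immune,
                   opts = opts, rtol = rtol, atol = atol),
      error = function(e) rep(NA_real_, length(obs)))
    if (any(!is.finite(pred))) return(rep(1e8, length(obs)))
    if (objective == "linear") pred - obs else log(pmax(pred, 1e-12)) - log(obs)
  }

  use_varpro <- objective == "linear" && opts$psa_map == "linear"
  ## unit-scale tumor curve at the training times (A = 1, B = 0)
  tumor_curve <- function(th2) {
    pp1 <- patient_params(r = 10^th2[1], a_p = 10^th2[2], A = 1, B = 0)
    tryCatch(simulate_psa(pp1, gp, protocol, train$day, immune = immune,
                          opts = opts, rtol = rtol, atol = atol),
             error = function(e) rep(NA_real_, length(obs)))
  }
  resid_varpro <- function(th2) {
    x <- tumor_curve(th2)
    if (any(!is.finite(x))) return(rep(1e8, length(obs)))
    ab <- .solve_AB(x, obs, bounds$A, bounds$B)
    ab[1] * x + ab[2] - obs
  }

  ndim <- if (use_varpro) 2L else 4L
  starts <- matrix(.smart_start(train, tb)[seq_len(ndim)], nrow = 1)
  if (n_starts > 1) {
    u <- with_local_seed(seed, lhs::randomLHS(n_starts - 1, ndim))
    box_lo <- tb$lo[seq_len(ndim)]
    box_hi <- tb$hi[seq_len(ndim)]
    starts <- rbind(starts, sweep(sweep(u, 2, box_hi - box_lo, `*`), 2, box_lo, `+`))
  }

  lo <- tb$lo[seq_len(ndim)]
  hi <- tb$hi[seq_len(ndim)]
  fn <- if (use_varpro) resid_varpro else resid_fn
  ends <- vector("list", nrow(starts))
  start_obj <- rep(NA_real_, nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    start_obj[i] <- res$deviance
    ends[[i]] <- res
  }
  if (all(vapply(ends, is.null, TRUE))) {
    stop("non-convergence: all optimization starts failed", call. = FALSE)
  }

  ## The objective has a curved, nearly flat valley in (r, a_p) — faster
  ## growth traded against stronger killing — where Levenberg-Marquardt
  ## stalls. Polish the most promising endpoints with a simplex descent,
  ## then re-run LM from the simplex floor.
  ok_idx <- which(!vapply(ends, is.null, TRUE))
  ord <- ok_idx[order(vapply(ends[ok_idx], `[[`, 0, "deviance"))]
  clamp_box <- function(th) pmin(pmax(th, lo), hi)
  best <- NULL
  for (i in utils::head(ord, 3L)) {
    nm <- stats::optim(ends[[i]]$par, function(th) sum(fn(clamp_box(th))^2),
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 600))
    res <- tryCatch(
      minpack.lm::nls.lm(par = clamp_box(nm$par), lower = lo, upper = hi,
                         fn = fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(res) || res$deviance > nm$value) {
      res <- list(par = clamp_box(nm$par), deviance = nm$value, info = 0L)
    }
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }

  if (use_varpro) {
    ## recover (A, B) at the best (r, a_p), then polish all four parameters
    x <- tumor_curve(best$par)
    ab <- .solve_AB(x, obs, bounds$A, bounds$B)
    th4 <- c(best$par, 0, 0)
    th4[3] <- min(max(log10(ab[1]), tb$lo[3]), tb$hi[3])
    th4[4] <- min(max(ab[2], tb$lo[4]), tb$hi[4])
    polish <- tryCatch(
      minpack.lm::nls.lm(par = th4, lower = tb$lo, upper = tb$hi,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (!is.null(polish) && polish$deviance <= best$deviance + 1e-12) {
      best <- polish
    } else {
      best$par <- th4
    }
  }

  pp <- .theta_to_pp(best$par)
  if (pp$a_p <= .AP_LOG_FLOOR) pp$a_p <- max(bounds$a_p[1], 0)
  pred_all <- simulate_psa(pp, gp, protocol, series$day, immune = immune,
                           opts = opts, rtol = rtol, atol = atol)
  n <- length(series$day)
  val_idx <- if (series$split_index < n) (series$split_index + 1):n else integer(0)
  lin_res <- pred_all[seq_len(nrow(train))] - obs
  structure(list(params = pp,
                 sse = sum(lin_res^2),
                 objective = objective,
                 objective_value = best$deviance,
                 n_train = nrow(train),
                 predicted = pred_all,
                 predicted_validation = pred_all[val_idx],
                 converged = best$info %in% 1:4,
                 n_starts = n_starts,
                 seed = seed,
                 start_objectives = start_obj),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Patient fit (%d training points, %d starts, seed %d):\n",
              x$n_train, x$n_starts, x$seed))
  print(x$params)
  cat(sprintf("  SSE = %.4g (ng/mL)^2, converged: %s\n", x$sse, x$converged))
  invisible(x)
}

#' Predict the validation set from a calibrated model
#'
#' Simulates the individualized model (fitted parameters, personal
#' vaccination schedule) at the validation-set times with the reference
#' whole-system solver. No refitting takes place.
#'
#' @param fit a [fit_patient()] result (must have converged).
#' @param series the patient's [psa_series()].
#' @param protocol the patient's [protocol()].
#' @param gp [global_params()].
#' @param opts [model_options()].
#' @param rtol,atol solver tolerances.
#' @return PSA (ng/mL) at the validation times.
#' @export
predict_validation <- function(fit, series, protocol, gp,
                               opts = model_options(),
                               rtol = 1e-8, atol = 1e-6) {
  if (!fit$converged) {
    stop("invalid-input: fit did not converge", call. = FALSE)
  }
  val <- validation_set(series)
  if (nrow(val) == 0) return(numeric(0))
  simulate_course(fit$params, gp, protocol, val$day,
                  pre_treatment_start = min(0, series$day),
                  opts = opts, rtol = rtol, atol = atol)$psa
}

#' Grow the training set until predictions are accurate
#'
#' Starting from a training set of the first `initial_k` observations
#' (all pre-treatment points plus at least two in-treatment points), fits
#' the model, predicts the remaining (validation) observations, and
#' evaluates the mean absolute relative prediction error. While the error
#' exceeds `accuracy_threshold`, the next observation is moved from the
#' validation set into the training set and the model is refitted. Returns
#' the first training-set size meeting the criterion, with the full
#' iteration trace. The accuracy trace need not be monotone in the
#' training-set size; only the first passing index is reported.
#'
#' @param series a [psa_series()] (its own `split_index` is ignored).
#' @param protocol the patient's [protocol()].
#' @param gp [global_params()].
#' @param initial_k first training-set size; default: all pre-treatment
#'   points plus two.
#' @param accuracy_threshold mean absolute relative prediction error on the
#'   current validation set required to stop (default 0.10).
#' @param n_starts,seed,bounds,objective,opts,rtol,atol passed to
#'   [fit_patient()]; each iteration's fit is independent and uses the
#'   same seed, so the procedure is deterministic and its result does not
#'   depend on the order in which split sizes are examined.
#' @return A list: `split_index` (first size meeting the criterion, or the
#'   full series size), `met_criterion`, `fit` (at the returned size), and
#'   `trace` (data frame of size and prediction error per iteration).
#' @export
iterative_training <- function(series, protocol, gp, initial_k = NULL,
                               accuracy_threshold = 0.10,
                               n_starts = 16, seed = 1L,
                               bounds = default_fit_bounds(),
                               objective = c("linear", "log"),
                               opts = model_options(),
                               rtol = 1e-8, atol = 1e-6) {
  objective <- match.arg(objective)
  n <- length(series$day)
  n_pre <- sum(series$day < 0)
  if (is.null(initial_k)) initial_k <- max(n_pre + 2L, 5L)
  if (initial_k < n_pre + 2) {
    stop("invalid-input: initial_k must include all pre-treatment points plus >= 2 in-treatment points",
         call. = FALSE)
  }
  if (initial_k >= n) {
    stop("insufficient-data: no validation points left at initial_k", call. = FALSE)
  }
  immune <- immune_course(gp, protocol, rtol = rtol, atol = atol)
  sizes <- err <- numeric(0)
  fits <- list()
  for (k in initial_k:(n - 1)) {
    sk <- set_split(series, k)
    fit <- fit_patient(sk, protocol, gp, bounds = bounds, n_starts = n_starts,
                       seed = seed, objective = objective, opts = opts,
                       immune = immune, rtol = rtol, atol = atol)
    val <- validation_set(sk)
    e <- mean(abs(fit$predicted_validation - val$psa) / val$psa)
    sizes <- c(sizes, k); err <- c(err, e); fits[[length(fits) + 1]] <- fit
    if (e <= accuracy_threshold) {
      return(list(split_index = k, met_criterion = TRUE, fit = fit,
                  trace = data.frame(split_index = sizes, pred_error = err)))
    }
  }
  full <- fit_patient(set_split(series, n), protocol, gp, bounds = bounds,
                      n_starts = n_starts, seed = seed, objective = objective,
                      opts = opts, immune = immune, rtol = rtol, atol = atol)
  list(split_index = n, met_criterion = FALSE, fit = full,
       trace = data.frame(split_index = sizes, pred_error = err))
}
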