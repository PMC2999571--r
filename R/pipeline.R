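#' Read a multi-patient PSA table
#'
#' Delimiter-separated text with a header and columns `patient_id`, `day`,
#' `psa_ng_ml` (days relative to each patient's first vaccination;
#' fractional days permitted). Malformed rows (non-finite day, missing or
#' non-positive PSA) are dropped with a per-row diagnostic message; parsing
#' continues for the valid rows.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return A data frame with the three columns, valid rows only.
#' @export
read_psa_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "psa_ng_ml")
  if (!all(need %in% names(df))) {
    stop("invalid-input: PSA table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$day <- suppressWarnings(as.numeric(df$day))
  df$psa_ng_ml <- suppressWarnings(as.numeric(df$psa_ng_ml))
  bad <- !is.finite(df$day) | !is.finite(df$psa_ng_ml) | df$psa_ng_ml <= 0
  if (any(bad)) {
    for (i in which(bad)) {
      message(sprintf("dropping malformed row %d (patient %s)", i,
                      df$patient_id[i]))
    }
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("invalid-input: no valid rows", call. = FALSE)
  df[need]
}

#' Read/write a vaccination protocol table
#'
#' Two columns, `day` and `dose_cells`, header required.
#'
#' @param path file path.
#' @param sep field separator.
#' @return [read_protocol()]: a [protocol()].
#' @export
read_protocol <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("day", "dose_cells") %in% names(df))) {
    stop("invalid-input: protocol table needs columns day, dose_cells", call. = FALSE)
  }
  protocol(df$day, df$dose_cells)
}

#' @rdname read_protocol
#' @param prot a [protocol()].
#' @export
write_protocol <- function(prot, path, sep = "\t") {
  utils::write.table(
    data.frame(day = prot$times_days, dose_cells = prot$doses_cells),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort as a PSA table plus ground-truth parameter table
#'
#' @param cohort result of [generate_cohort()].
#' @param psa_path,params_path output file paths (tab-separated text).
#' @return Invisibly, the PSA table data frame.
#' @export
write_cohort <- function(cohort, psa_path, params_path = NULL) {
  tab <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, day = p$series$day,
               psa_ng_ml = p$series$psa)
  }))
  utils::write.table(tab, psa_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(params_path)) {
    pt <- do.call(rbind, lapply(cohort, function(p) {
      data.frame(patient_id = p$patient_id, r = p$params$r, a_p = p$params$a_p,
                 A = p$params$A, B = p$params$B, P0 = p$params$P0,
                 responder_true = p$responder_true)
    }))
    utils::write.table(pt, params_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(tab)
}

#' Run the full personalization pipeline on a cohort
#'
#' Orchestrates the study workflow: classify responders by PSA velocity,
#' calibrate each responder's patient-specific parameters on the training
#' set, predict and score the validation set (individually and pooled),
#' and optionally search intensified regimens per patient. Non-responders
#' are reported but, by default, neither fitted nor optimized (set
#' `fit_all = TRUE` to override).
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{psa_table}{path to a PSA table ([read_psa_table()]); or}
#'     \item{cohort_spec}{arguments to [cohort_spec()] for a synthetic run}
#'     \item{protocol}{path to a protocol table; default standard schedule}
#'     \item{global_params}{named overrides to [global_params()]}
#'     \item{fit}{list: `n_starts`, `seed`, `objective`, `bounds`,
#'       `n_train` (split size when the input table carries none)}
#'     \item{optimize}{list: `mode` ("none", "dose", "interval", "both"),
#'       `tolerance`, `criterion`, `factor_max`}
#'     \item{fit_all}{also fit non-responders (default FALSE)}
#'     \item{out_dir}{optional directory for the report, per-patient
#'       trajectories and a config echo}
#'   }
#' @return A list: `report` (one row per patient), `pooled_r2` (validation
#'   R^2 pooled over all fitted patients), `fits`, `series`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  gp <- do.call(global_params, as.list(config$global_params %||% list()))
  prot <- if (!is.null(config$protocol) && is.character(config$protocol)) {
    read_protocol(config$protocol)
  } else {
    make_standard_protocol()
  }
  fitcfg <- config$fit %||% list()
  n_starts <- fitcfg$n_starts %||% 16
  seed <- as.integer(fitcfg$seed %||% 1L)
  objective <- fitcfg$objective %||% "linear"
  bounds <- fitcfg$bounds %||% default_fit_bounds()
  n_train <- fitcfg$n_train %||% 12L

  if (!is.null(config$psa_table)) {
    tab <- if (is.character(config$psa_table)) {
      read_psa_table(config$psa_table)
    } else config$psa_table
    ids <- unique(tab$patient_id)
    series <- lapply(ids, function(id) {
      d <- tab[tab$patient_id == id, ]
      d <- d[order(d$day), ]
      psa_series(d$day, d$psa_ng_ml,
                 split_index = min(n_train, nrow(d)))
    })
    names(series) <- as.character(ids)
  } else if (!is.null(config$cohort_spec)) {
    spec <- do.call(cohort_spec, as.list(config$cohort_spec))
    cohort <- generate_cohort(spec, gp, prot)
    series <- lapply(cohort, `[[`, "series")
    names(series) <- as.character(vapply(cohort, `[[`, 0, "patient_id"))
  } else {
    stop("invalid-input: config needs psa_table or cohort_spec", call. = FALSE)
  }
  if (length(series) == 0) stop("invalid-input: empty cohort", call. = FALSE)

  optcfg <- config$optimize %||% list()
  mode <- optcfg$mode %||% "none"
  immune <- immune_course(gp, prot)

  rows <- list()
  fits <- list()
  pooled_obs <- pooled_pred <- numeric(0)
  for (id in names(series)) {
    s <- series[[id]]
    responder <- tryCatch(classify_responder(s, prot), error = function(e) NA)
    row <- data.frame(patient_id = id, responder = responder,
                      n_obs = length(s$day), n_train = s$split_index,
                      r = NA_real_, a_p = NA_real_, A = NA_real_, B = NA_real_,
                      sse = NA_real_, validation_r2 = NA_real_,
                      min_dose_factor = NA_real_, max_interval_days = NA_real_)
    do_fit <- isTRUE(responder) || isTRUE(config$fit_all)
    if (do_fit) {
      fit <- fit_patient(s, prot, gp, bounds = bounds, n_starts = n_starts,
                         seed = seed, objective = objective, immune = immune)
      fits[[id]] <- fit
      val <- validation_set(s)
      pred <- predict_validation(fit, s, prot, gp)
      row$r <- fit$params$r; row$a_p <- fit$params$a_p
      row$A <- fit$params$A; row$B <- fit$params$B
      row$sse <- fit$sse
      if (nrow(val) >= 2) {
        row$validation_r2 <- goodness_of_fit(val$psa, pred)
        pooled_obs <- c(pooled_obs, val$psa)
        pooled_pred <- c(pooled_pred, pred)
      }
      if (mode %in% c("dose", "both")) {
        rec <- find_min_dose_factor(fit, gp, prot,
                                    factor_max = optcfg$factor_max %||% 30,
                                    tolerance = optcfg$tolerance %||% 0.10,
                                    criterion = optcfg$criterion %||% "max",
                                    patient_id = id)
        row$min_dose_factor <- if (rec$achievable) rec$value else NA_real_
      }
      if (mode %in% c("interval", "both")) {
        rec <- find_max_interval(fit, gp,
                                 base_dose = prot$doses_cells[1],
                                 tolerance = optcfg$tolerance %||% 0.10,
                                 criterion = optcfg$criterion %||% "max",
                                 patient_id = id)
        row$max_interval_days <- if (rec$achievable) rec$value else NA_real_
      }
    }
    rows[[id]] <- row
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  pooled_r2 <- if (length(pooled_obs) >= 2) {
    goodness_of_fit(pooled_obs, pooled_pred)
  } else NA_real_

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(config, file.path(config$out_dir, "config_echo.yaml"))
    for (id in names(fits)) {
      s <- series[[id]]
      traj <- simulate_course(fits[[id]]$params, gp, prot,
                              sort(unique(c(s$day, seq(0, prot$horizon_days, by = 7)))))
      utils::write.table(traj, file.path(config$out_dir,
                                         paste0("trajectory_", id, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list(report = report, pooled_r2 = pooled_r2, fits = fits,
       series = series, config = config)
}
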