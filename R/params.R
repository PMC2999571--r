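#' Shared (population-level) model parameters
#'
#' Constructs the set of kinetic constants shared by all patients: the
#' vaccine/dendritic-cell cascade, regulatory-cell and effector-cell
#' turnover, and the effector-efficacy damping coefficient. All rates are
#' per hour; the model integrates in hours internally and converts from
#' days only at its external interfaces.
#'
#' Defaults are literature-derived estimates for intradermal whole-cell
#' vaccination:
#' \describe{
#'   \item{k_i}{rate of DC maturation following vaccine uptake (h^-1)}
#'   \item{n_V}{vaccine cells required to mature one DC (dimensionless)}
#'   \item{V_p}{natural influx of mature DCs (cells/h)}
#'   \item{k_m}{rate of DC migration from skin to lymph node (h^-1)}
#'   \item{alpha_l}{fraction of antigen-presenting DCs entering the lymph node}
#'   \item{k_CR}{rate of exhaustion of mature DCs (h^-1)}
#'   \item{mu_D}{death rate of exhausted DCs (h^-1)}
#'   \item{a_R}{rate of regulatory/inhibitory-cell recruitment by exhausted DCs (h^-1)}
#'   \item{mu_R}{death rate of regulatory cells (h^-1)}
#'   \item{a_C}{rate of effector-cell recruitment by mature DCs (h^-1)}
#'   \item{mu_C}{effector-cell death rate (h^-1)}
#'   \item{k_R}{rate of effector inactivation by regulatory cells (cell^-1 h^-1)}
#'   \item{h_P}{effector-efficacy damping coefficient (cells)}
#' }
#'
#' @param k_i,n_V,V_p,k_m,alpha_l,k_CR,mu_D,a_R,mu_R,a_C,mu_C,k_R,h_P numeric
#'   scalars, see Details. Any subset may be overridden.
#' @return An object of class `global_params` (a validated named list).
#' @examples
#' gp <- global_params()
#' gp$k_i
#' global_params(k_R = 0)  # disable regulatory inactivation of effectors
#' @export
global_params <- function(k_i = 0.06, n_V = 1, V_p = 0, k_m = 0.027,
                          alpha_l = 0.03, k_CR = 0.027, mu_D = 0.014,
                          a_R = 3e-3, mu_R = 0.03, a_C = 0.38,
                          mu_C = 0.007, k_R = 6e-7, h_P = 1e8) {
  gp <- list(k_i = k_i, n_V = n_V, V_p = V_p, k_m = k_m, alpha_l = alpha_l,
             k_CR = k_CR, mu_D = mu_D, a_R = a_R, mu_R = mu_R, a_C = a_C,
             mu_C = mu_C, k_R = k_R, h_P = h_P)
  vals <- unlist(gp)
  if (!all(is.finite(vals))) {
    stop("invalid-input: all shared parameters must be finite", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("invalid-input: all shared parameters must be non-negative", call. = FALSE)
  }
  if (alpha_l > 1) stop("invalid-input: alpha_l must lie in [0, 1]", call. = FALSE)
  if (n_V < 1) stop("invalid-input: n_V must be >= 1", call. = FALSE)
  if (h_P <= 0) stop("invalid-input: h_P must be > 0", call. = FALSE)
  structure(gp, class = "global_params")
}

#' Read shared parameters from a key/value YAML file
#'
#' A flat YAML mapping of parameter names to numbers; keys absent from the
#' file keep their defaults. The packaged default file is
#' `system.file("extdata", "global_params.yaml", package = "psavax")`.
#'
#' @param path path to a YAML file with a flat `name: value` mapping.
#' @return A `global_params` object.
#' @export
read_global_params <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(global_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("invalid-input: unknown parameter key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(global_params, lapply(raw, as.numeric))
}

#' Patient-specific model parameters
#'
#' The four quantities calibrated per patient, plus the fixed initial tumor
#' burden convention:
#' \describe{
#'   \item{r}{tumor growth rate (h^-1)}
#'   \item{a_p}{maximal tumor-cell killing efficacy of effector cells
#'     (cell^-1 h^-1); 0 means vaccination has no effect on the tumor}
#'   \item{A}{PSA produced per tumor cell ((ng/mL)/cell)}
#'   \item{B}{tumor-independent PSA offset (ng/mL)}
#'   \item{P0}{tumor burden at the start of treatment (cells)}
#' }
#'
#' `A` and `P0` are multiplicatively confounded in the PSA observation
#' `A * P0 * exp(r*t) + B`, so `P0` is fixed by convention at `1e8` cells
#' (equal to the damping coefficient `h_P`) and `A` absorbs the scale; the
#' fitted `A` is therefore a composite quantity, not an absolute secretion
#' rate.
#'
#' @param r,a_p,A,B numeric scalars, see Details.
#' @param P0 initial tumor burden (cells); fixed convention, rarely changed.
#' @return An object of class `patient_params`.
#' @examples
#' patient_params(r = 2e-4, a_p = 5e-10, A = 2e-7, B = 2)
#' @export
patient_params <- function(r, a_p, A, B, P0 = 1e8) {
  vals <- c(r = r, a_p = a_p, A = A, B = B, P0 = P0)
  if (!all(is.finite(vals))) {
    stop("invalid-input: patient parameters must be finite", call. = FALSE)
  }
  if (r <= 0) stop("invalid-input: r must be > 0", call. = FALSE)
  if (a_p < 0) stop("invalid-input: a_p must be >= 0", call. = FALSE)
  if (A <= 0) stop("invalid-input: A must be > 0", call. = FALSE)
  if (B < 0) stop("invalid-input: B must be >= 0", call. = FALSE)
  if (P0 <= 0) stop("invalid-input: P0 must be > 0", call. = FALSE)
  structure(as.list(vals), class = "patient_params")
}

#' Structural model options
#'
#' Switches between the default model forms and their documented variants.
#'
#' @param killing_damping where the saturation of effector killing acts:
#'   `"tumor"` (default) damps in tumor burden,
#'   `a_p * C * P * h_P / (h_P + P)`; `"effector"` damps in effector number,
#'   `a_p * C * P * h_P / (h_P + C)`.
#' @param psa_map `"linear"` (default), `PSA = A*P + B`; or `"power"`,
#'   `PSA = A * P^B`.
#' @return An object of class `model_options`.
#' @export
model_options <- function(killing_damping = c("tumor", "effector"),
                          psa_map = c("linear", "power")) {
  structure(list(killing_damping = match.arg(killing_damping),
                 psa_map = match.arg(psa_map)),
            class = "model_options")
}

#' @export
print.global_params <- function(x, ...) {
  cat("Shared model parameters (rates per hour):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.patient_params <- function(x, ...) {
  cat(sprintf("Patient parameters: r = %.4g /h, a_p = %.4g /cell/h, A = %.4g (ng/mL)/cell, B = %.4g ng/mL (P0 = %.3g cells)\n",
              x$r, x$a_p, x$A, x$B, x$P0))
  invisible(x)
}
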