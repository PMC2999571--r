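## Model state layout. Order is load-bearing: the ODE integrator, the dosing
## impulse and the linear-subsystem matrix all index by it.
STATE_NAMES <- c("V", "Dm", "DC", "DR", "R", "C", "P")

#' Construct a model state vector
#'
#' The seven compartments, all in cells:
#' `V` vaccine cells at the injection site, `Dm` antigen-bearing dermal
#' dendritic cells, `DC` mature antigen-presenting dendritic cells in the
#' lymph node, `DR` exhausted dendritic cells, `R` regulatory/inhibitory
#' cells, `C` antigen-specific effector cells, `P` prostate-cancer cells.
#'
#' @param V,Dm,DC,DR,R,C,P non-negative cell counts.
#' @return A named numeric vector of length 7.
#' @export
state_vector <- function(V = 0, Dm = 0, DC = 0, DR = 0, R = 0, C = 0, P = 0) {
  s <- c(V = V, Dm = Dm, DC = DC, DR = DR, R = R, C = C, P = P)
  if (!all(is.finite(s))) stop("invalid-input: state must be finite", call. = FALSE)
  if (any(s < 0)) stop("invalid-input: state must be non-negative", call. = FALSE)
  s
}

#' Right-hand side of the vaccination model
#'
#' Instantaneous rates of change (cells/hour) of the seven compartments.
#' Injected vaccine cells `V` decay as dendritic cells take them up and
#' mature (`k_i`); matured dermal DCs `Dm` migrate to the lymph node
#' (`k_m`), of which a fraction `alpha_l` arrives as presenting DCs `DC`.
#' Presenting DCs recruit effectors `C` (rate `a_C`) until they exhaust
#' (`k_CR`) into `DR`, which recruit regulatory cells `R` (rate `a_R`);
#' regulatory cells inactivate effectors bilinearly (`k_R`). The tumor `P`
#' grows exponentially (rate `r`) and is killed by effectors with maximal
#' efficacy `a_p`, damped at high tumor burden by the coefficient `h_P`:
#'
#' \deqn{dP/dt = r P - a_p C P \frac{h_P}{h_P + P}}
#'
#' The immune cascade is feed-forward: `(V, Dm, DC, DR, R)` evolve
#' independently of `(C, P)`, and the tumor does not feed back on any
#' immune compartment.
#'
#' @param state named numeric state vector (see [state_vector()]).
#' @param gp [global_params()].
#' @param pp [patient_params()].
#' @param opts [model_options()]; selects the killing-damping variant.
#' @return Named numeric vector of derivatives, cells/hour.
#' @examples
#' derivatives(state_vector(V = 1e7), global_params(),
#'             patient_params(r = 1e-4, a_p = 0, A = 1e-8, B = 1))
#' @export
derivatives <- function(state, gp, pp, opts = model_options()) {
  if (!all(is.finite(state))) {
    stop("invalid-input: non-finite state", call. = FALSE)
  }
  s <- as.numeric(state)
  names(s) <- STATE_NAMES
  damp <- if (opts$killing_damping == "tumor") {
    gp$h_P / (gp$h_P + s["P"])
  } else {
    gp$h_P / (gp$h_P + s["C"])
  }
  d <- c(
    V  = -gp$k_i * s[["V"]],
    Dm = (gp$k_i / gp$n_V) * s[["V"]] - gp$k_m * s[["Dm"]],
    DC = gp$alpha_l * gp$k_m * s[["Dm"]] + gp$V_p - gp$k_CR * s[["DC"]],
    DR = gp$k_CR * s[["DC"]] - gp$mu_D * s[["DR"]],
    R  = gp$a_R * s[["DR"]] - gp$mu_R * s[["R"]],
    C  = gp$a_C * s[["DC"]] - gp$mu_C * s[["C"]] - gp$k_R * s[["R"]] * s[["C"]],
    P  = pp$r * s[["P"]] - pp$a_p * s[["C"]] * s[["P"]] * unname(damp)
  )
  if (!all(is.finite(d))) {
    stop("invalid-input: non-finite derivative (check parameters)", call. = FALSE)
  }
  d
}

#' Apply an impulsive vaccine dose
#'
#' An intradermal vaccination is modeled as an instantaneous jump of the
#' vaccine compartment; all other compartments are continuous across the
#' dose.
#'
#' @param state named numeric state vector.
#' @param dose_cells number of vaccine cells injected (>= 0).
#' @return The state with `V` incremented by `dose_cells`.
#' @export
apply_dose <- function(state, dose_cells) {
  if (!is.finite(dose_cells) || dose_cells < 0) {
    stop("invalid-input: dose_cells must be a non-negative number", call. = FALSE)
  }
  state[["V"]] <- state[["V"]] + dose_cells
  state
}

#' Map tumor burden to the PSA observable
#'
#' The default map is affine, `PSA = A * P + B` (ng/mL): PSA release
#' proportional to tumor burden plus a tumor-independent baseline. A
#' power-law variant `PSA = A * P^B` is selectable via
#' `model_options(psa_map = "power")`.
#'
#' @param P tumor burden, cells (vectorized).
#' @param pp [patient_params()].
#' @param opts [model_options()].
#' @return PSA in ng/mL.
#' @export
psa_observation <- function(P, pp, opts = model_options()) {
  if (any(P < 0)) stop("invalid-input: P must be >= 0", call. = FALSE)
  if (opts$psa_map == "linear") pp$A * P + pp$B else pp$A * P^pp$B
}
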