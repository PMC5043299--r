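# Governing ODEs, in reduced (Sg, Ig, Ip) and full (Sg, Ig, Sp, Ip, Z) form.
#
# With the police force held constant (Sp = P - Ip) and the justice system Z
# a pure sink, the dynamics are fully determined by the reduced 3-state
# system; the full form exists to verify the reduction and for simulation
# output in original coordinates.

reduced_names <- c("Sg", "Ig", "Ip")
full_names <- c("Sg", "Ig", "Sp", "Ip", "Z")

as_reduced_state <- function(state) {
  x <- unlist(state)
  if (!is.null(names(x)) && all(reduced_names %in% names(x))) {
    x <- x[reduced_names]
  } else if (length(x) == 3) {
    names(x) <- reduced_names
  } else {
    stop("reduced state must have components Sg, Ig, Ip")
  }
  x
}

as_full_state <- function(state) {
  x <- unlist(state)
  if (!is.null(names(x)) && all(full_names %in% names(x))) {
    x <- x[full_names]
  } else if (length(x) == 5) {
    names(x) <- full_names
  } else {
    stop("full state must have components Sg, Ig, Sp, Ip, Z")
  }
  x
}

# standard-incidence ratio Sg*Ig/Ng, defined as 0 in the empty-gang limit
incidence_ratio <- function(Sg, Ig) {
  Ng <- Sg + Ig
  if (Ng <= 0) 0 else Sg * Ig / Ng
}

#' Reduced right-hand side
#'
#' Time derivatives of the reduced system `(Sg, Ig, Ip)`:
#' \deqn{S_g' = b N_g - S_g N_g / K - \beta_1 S_g I_g / N_g - f_1 - \mu_1 S_g}
#' \deqn{I_g' = \beta_1 S_g I_g / N_g - I_g N_g / K - f_2 - \mu_1 I_g}
#' \deqn{I_p' = \beta_2 (P - I_p) I_g / P + \beta_3 (P - I_p) I_p / P - \mu_2 I_p}
#' where `Ng = Sg + Ig` and `f1`, `f2` are the capture fluxes of
#' [capture_rates()]. The standard-incidence ratio is defined as 0 at
#' `Ng = 0`, its continuous limit, so the origin is a genuine fixed point.
#'
#' @param state numeric vector `(Sg, Ig, Ip)` (named or positional).
#' @param params a `gang_params` object.
#' @return Named rate triple `(Sg, Ig, Ip)`.
#' @export
#' @examples
#' rhs_reduced(c(Sg = 0, Ig = 0, Ip = 0), default_parameters())  # E0
rhs_reduced <- function(state, params) {
  x <- as_reduced_state(state)
  Sg <- x[["Sg"]]; Ig <- x[["Ig"]]; Ip <- x[["Ip"]]
  Ng <- Sg + Ig
  P <- params$P
  cr <- capture_rates(Sg, Ig, Ip, params)
  inc <- params$beta1 * incidence_ratio(Sg, Ig)
  dSg <- params$b * Ng - Sg * Ng / params$K - inc -
    cr$flux_susceptible - params$mu1 * Sg
  dIg <- inc - Ig * Ng / params$K - cr$flux_core - params$mu1 * Ig
  dIp <- params$beta2 * (P - Ip) * Ig / P +
    params$beta3 * (P - Ip) * Ip / P - params$mu2 * Ip
  c(Sg = dSg, Ig = dIg, Ip = dIp)
}

#' Full right-hand side
#'
#' Adds the susceptible-police and justice-system equations to the reduced
#' rates: `Sp' = gamma P - beta2 Sp Ig / P - beta3 Sp Ip / P - mu2 Sp` and
#' `Z' = (total capture flux) - mu3 Z`. With `gamma = mu2` and `Sp = P - Ip`,
#' `Sp' + Ip' = 0` exactly, so the police force stays at `P`.
#'
#' @param state numeric vector `(Sg, Ig, Sp, Ip, Z)`.
#' @param params a `gang_params` object.
#' @return Named rate 5-vector.
#' @export
rhs_full <- function(state, params) {
  x <- as_full_state(state)
  red <- rhs_reduced(x[c("Sg", "Ig", "Ip")], params)
  Sp <- x[["Sp"]]; Ig <- x[["Ig"]]; Ip <- x[["Ip"]]
  P <- params$P
  cr <- capture_rates(x[["Sg"]], Ig, Ip, params)
  dSp <- params$gamma * P - params$beta2 * Sp * Ig / P -
    params$beta3 * Sp * Ip / P - params$mu2 * Sp
  dZ <- cr$flux_susceptible + cr$flux_core - params$mu3 * x[["Z"]]
  c(Sg = red[["Sg"]], Ig = red[["Ig"]], Sp = dSp, Ip = red[["Ip"]], Z = dZ)
}

#' Slaved justice-system equilibrium
#'
#' The unique `Z` with `dZ/dt = 0` at fixed `(Sg, Ig, Ip)`: total capture
#' flux divided by the processing rate `mu3`.
#'
#' @param Sg,Ig,Ip state components (persons).
#' @param params a `gang_params` object.
#' @return Equilibrium justice-system occupancy (persons).
#' @export
#' @examples
#' # at the coexistence state the justice system holds ~395 people
#' z_equilibrium(2124, 106.2, 176.5, default_parameters())
z_equilibrium <- function(Sg, Ig, Ip, params) {
  if (params$mu3 <= 0) stop("mu3 must be positive to slave Z")
  cr <- capture_rates(Sg, Ig, Ip, params)
  (cr$flux_susceptible + cr$flux_core) / params$mu3
}

#' Auxiliary logistic residual for the total gang population
#'
#' Evaluates `(b - mu1) Ng - Ng^2 / K` with `Ng = Sg + Ig`. This is the
#' model's auxiliary logistic expression for total gang growth; note it is
#' NOT equal to `dSg/dt + dIg/dt` of the governing equations whenever the
#' capture flux is nonzero (it omits predation losses), and is provided as a
#' diagnostic only. The identity
#' `ng_logistic_residual - (dSg + dIg) = total capture flux` holds exactly.
#'
#' @param Sg,Ig gang abundances (persons).
#' @param params a `gang_params` object.
#' @return The logistic rate (persons per unit time).
#' @export
ng_logistic_residual <- function(Sg, Ig, params) {
  stopifnot(Sg >= 0, Ig >= 0)
  Ng <- Sg + Ig
  (params$b - params$mu1) * Ng - Ng^2 / params$K
}
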