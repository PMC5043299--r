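# Cooperative Beddington-De Angelis capture terms.
#
# Police teams of size U search for gang members; handling an arrested member
# costs t_h (core members cost lam times more), and pre-operation cooperation
# saves a fraction c*P of the total operation time. The resulting per-officer
# capture rate is a * prey / (U * D) with the shared denominator
# D = 1 + h*(Sg + lam*Ig) - c*P, h = a*t_h.

#' Capture-rate denominator
#'
#' Evaluates `D = 1 + h (Sg + lam Ig) - c P`, the dimensionless denominator
#' shared by both capture terms. The derivation (total operation time =
#' search + handling - cooperation saving) requires `D > 0`; a non-positive
#' value means cooperation savings exceed total effort and the model breaks
#' down, so it is an error rather than a clamp.
#'
#' @param Sg,Ig gang-compartment abundances (persons), non-negative.
#' @param params a `gang_params` object.
#' @return The scalar denominator (vectorised over `Sg`/`Ig`).
#' @export
#' @examples
#' capture_denominator(0, 0, default_parameters())  # 1 - c*P = 0.7
capture_denominator <- function(Sg, Ig, params) {
  stopifnot(all(Sg >= 0), all(Ig >= 0))
  h <- params$a * params$t_h
  D <- 1 + h * (Sg + params$lam * Ig) - params$c * params$P
  if (any(D <= 0)) {
    stop("nonpositive capture denominator (cooperation saving exceeds effort)")
  }
  D
}

#' Effective predator abundance
#'
#' Corrupt officers hunt at reduced efficiency `r`, so the effective number
#' of predators is `P - (1 - r) Ip`.
#'
#' @param Ip corrupt police abundance, in `[0, P]`.
#' @param params a `gang_params` object.
#' @return Effective predator count (persons).
#' @export
effective_predators <- function(Ip, params) {
  if (any(Ip < 0) || any(Ip > params$P)) {
    stop("Ip must lie in [0, P]")
  }
  params$P - (1 - params$r) * Ip
}

#' Capture rates and fluxes
#'
#' Evaluates the cooperative Beddington-De Angelis response at a state:
#' per-capita arrest rate `a * P_eff / (U * D)` (identical for both gang
#' compartments, since the attack rate is shared and the vulnerability
#' asymmetry enters only through `lam` in `D`), and the two capture fluxes.
#'
#' @param Sg,Ig gang abundances (persons).
#' @param Ip corrupt police abundance (persons).
#' @param params a `gang_params` object.
#' @return List of class `capture_rates`: `D`, `P_eff`, `per_capita_s`,
#'   `per_capita_i`, `flux_susceptible`, `flux_core`.
#' @export
#' @examples
#' cr <- capture_rates(2124, 106.2, 176.5, default_parameters())
#' (cr$flux_susceptible + cr$flux_core) / 0.2  # justice-system load ~ 395
capture_rates <- function(Sg, Ig, Ip, params) {
  D <- capture_denominator(Sg, Ig, params)
  P_eff <- effective_predators(Ip, params)
  per_capita <- params$a * P_eff / (params$U * D)
  structure(
    list(
      D = D, P_eff = P_eff,
      per_capita_s = per_capita, per_capita_i = per_capita,
      flux_susceptible = per_capita * Sg,
      flux_core = per_capita * Ig
    ),
    class = "capture_rates"
  )
}
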