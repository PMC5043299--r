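# Linear stability analysis of the reduced (Sg, Ig, Ip) system.
#
# Z contributes a decoupled eigenvalue -mu3 and Sp is slaved to P - Ip, so
# classification rests on the 3x3 Jacobian of rhs_reduced. The analytic
# Jacobian is the primary path; a central finite-difference estimate is the
# test oracle, never a runtime fallback.

#' Analytic Jacobian of the reduced system
#'
#' Partial derivatives of [rhs_reduced()] with respect to `(Sg, Ig, Ip)`.
#' At an empty-gang state (`Ng = 0`) the standard-incidence terms and their
#' derivatives are taken as 0 (the same convention that makes the origin a
#' fixed point); elsewhere the expressions are exact, including the
#' corruption self-reinforcement derivative
#' `d(Ip')/dIp = -beta2 Ig / P + beta3 (P - 2 Ip)/P - mu2`.
#'
#' @param state numeric `(Sg, Ig, Ip)` vector.
#' @param params a `gang_params` object.
#' @return 3x3 matrix with dimnames `(Sg, Ig, Ip)`.
#' @export
jacobian_reduced <- function(state, params) {
  x <- as_reduced_state(state)
  Sg <- x[["Sg"]]; Ig <- x[["Ig"]]; Ip <- x[["Ip"]]
  Ng <- Sg + Ig
  P <- params$P; K <- params$K
  b <- params$b; beta1 <- params$beta1
  h <- params$a * params$t_h
  ap <- params$a / params$U
  lam <- params$lam
  D <- capture_denominator(Sg, Ig, params)
  Pe <- effective_predators(Ip, params)
  if (Ng > 0) {
    inc_s <- beta1 * Ig^2 / Ng^2   # d(beta1 Sg Ig / Ng)/dSg
    inc_i <- beta1 * Sg^2 / Ng^2   # d(beta1 Sg Ig / Ng)/dIg
  } else {
    inc_s <- inc_i <- 0
  }
  J <- matrix(0, 3, 3, dimnames = list(reduced_names, reduced_names))
  J["Sg", "Sg"] <- b - (Ng + Sg) / K - inc_s -
    ap * Pe * (D - h * Sg) / D^2 - params$mu1
  J["Sg", "Ig"] <- b - Sg / K - inc_i + ap * Sg * Pe * h * lam / D^2
  J["Sg", "Ip"] <- ap * (1 - params$r) * Sg / D
  J["Ig", "Sg"] <- inc_s - Ig / K + ap * Ig * Pe * h / D^2
  J["Ig", "Ig"] <- inc_i - (Ng + Ig) / K -
    ap * Pe * (D - h * lam * Ig) / D^2 - params$mu1
  J["Ig", "Ip"] <- ap * (1 - params$r) * Ig / D
  J["Ip", "Sg"] <- 0
  J["Ip", "Ig"] <- params$beta2 * (P - Ip) / P
  J["Ip", "Ip"] <- -params$beta2 * Ig / P +
    params$beta3 * (P - 2 * Ip) / P - params$mu2
  J
}

#' Characteristic-polynomial coefficients
#'
#' Coefficients `(a1, a2, a3)` of `lambda^3 + a1 lambda^2 + a2 lambda + a3`
#' for a 3x3 matrix: `a1 = -trace`, `a2` the sum of principal 2x2 minors,
#' `a3 = -det`.
#'
#' @param J 3x3 matrix.
#' @return Named numeric vector `(a1, a2, a3)`.
#' @export
char_poly_coefficients <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == c(3, 3)))
  minor <- function(i) det(J[-i, -i, drop = FALSE])
  c(a1 = -sum(diag(J)),
    a2 = minor(1) + minor(2) + minor(3),
    a3 = -det(J))
}

#' Stability report at an equilibrium
#'
#' Eigenvalues and classification of the reduced Jacobian at an equilibrium
#' state, plus Routh-Hurwitz quantities and, for boundary equilibria, the
#' applicable closed-form condition checks. Classification uses a marginal
#' tolerance of `tol` on the largest real part: `stable` below `-tol`,
#' `unstable` above `tol`, `marginal` in between (e.g. exactly at a detected
#' bifurcation point).
#'
#' @param state equilibrium state, reduced `(Sg, Ig, Ip)` or full 5-vector.
#' @param params a `gang_params` object.
#' @param label optional equilibrium label ("E0".."E4"); selects which
#'   closed-form conditions populate `condition_checks`.
#' @param tol marginal tolerance on real parts (default 1e-9).
#' @param residual_tol residual gate: the state must satisfy
#'   `max |rhs_reduced| < residual_tol * (1 + max state)` (default 1e-6).
#' @return A `stability_report`: `jacobian`, `eigenvalues`, `char_poly`,
#'   `routh_hurwitz`, `max_real`, `classification`, `condition_checks`.
#' @export
#' @examples
#' eq <- equilibrium_E4(default_parameters())[[1]]
#' stability_report(eq$state, default_parameters(), label = "E4")$classification
stability_report <- function(state, params, label = NULL, tol = 1e-9,
                             residual_tol = 1e-6) {
  x <- if (length(unlist(state)) == 5) {
    as_full_state(state)[reduced_names]
  } else {
    as_reduced_state(state)
  }
  res <- max(abs(rhs_reduced(x, params)))
  if (res > residual_tol * (1 + max(abs(x)))) {
    stop(sprintf("state is not an equilibrium (|residual| = %.3e)", res))
  }
  J <- jacobian_reduced(x, params)
  ev <- eigen(J, only.values = TRUE)$values
  cp <- char_poly_coefficients(J)
  rh <- c(a1 = unname(cp["a1"]) > 0,
          a2 = unname(cp["a2"]) > 0,
          a3 = unname(cp["a3"]) > 0,
          a1a2_minus_a3 = unname(cp["a1"] * cp["a2"] - cp["a3"]) > 0)
  mr <- max(Re(ev))
  classification <- if (mr < -tol) "stable" else if (mr > tol) "unstable" else "marginal"
  checks <- list()
  if (!is.null(label)) {
    checks <- switch(label,
      E0 = list(predation_dominates_growth = condition_E0(params)),
      E1 = list(predation_dominates_growth = condition_E1(params)),
      E2 = list(conditions_hold = condition_E2(params, x[["Sg"]])),
      E3 = list(conditions_hold = condition_E3(params, x[["Sg"]])),
      E4 = list(routh_hurwitz = all(rh)),
      list()
    )
  }
  structure(
    list(jacobian = J, eigenvalues = ev, char_poly = cp,
         routh_hurwitz = rh, max_real = mr,
         classification = classification, label = label,
         condition_checks = checks),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability%s: %s (max Re = %.4e)\n",
              if (is.null(x$label)) "" else paste0(" of ", x$label),
              x$classification, x$max_real))
  cat("eigenvalues:", paste(format(zapsmall(x$eigenvalues, 12)), collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form stability condition for E0
#'
#' The trivial equilibrium resists gang invasion iff predation outweighs net
#' gang growth: `a' P / (1 - c P) > b - mu1`. This captures the
#' gang-invasion eigenvalue `b - a' P/(1 - cP) - mu1`; when `beta3 > mu2`
#' the corruption-invasion eigenvalue `beta3 - mu2` additionally
#' destabilises E0 (see the package vignette), so the condition fully
#' characterises E0's stability in the `beta3 < mu2` regime.
#'
#' @param params a `gang_params` object.
#' @return Logical.
#' @export
condition_E0 <- function(params) {
  d <- derive_parameters(params)
  d$a_prime * params$P / (1 - params$c * params$P) > params$b - params$mu1
}

#' Closed-form stability condition for E1
#'
#' As [condition_E0()] with predation reduced by endemic corruption:
#' `a' P (1 - Omega (1 - r)) / (1 - c P) > b - mu1`. Requires
#' `beta3 > mu2`.
#'
#' @param params a `gang_params` object.
#' @return Logical.
#' @export
condition_E1 <- function(params) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) stop("Omega undefined (beta3 <= mu2)")
  d$a_prime * params$P * (1 - d$Omega * (1 - params$r)) /
    (1 - params$c * params$P) > params$b - params$mu1
}

#' Closed-form stability conditions for E2
#'
#' Conjunction of the saturation condition
#' `h a' P / (1 + h Sg - c P)^2 < 1/K` (logistic self-limitation beats the
#' destabilising handling saturation of the capture term) and `beta1 < b`
#' (core recruitment cannot invade). As for [condition_E0()], corruption
#' invasion (`beta3 > mu2`) is a separate destabilising route.
#'
#' @param params a `gang_params` object.
#' @param Sg_at_E2 the E2 abundance from [equilibrium_E2()].
#' @return Logical.
#' @export
condition_E2 <- function(params, Sg_at_E2) {
  d <- derive_parameters(params)
  D <- 1 + d$h * Sg_at_E2 - params$c * params$P
  (d$h * d$a_prime * params$P / D^2 < 1 / params$K) &&
    (params$beta1 < params$b)
}

#' Closed-form stability conditions for E3
#'
#' As [condition_E2()] with predation reduced by endemic corruption, using
#' `P_eff = P (mu2 + r beta3 - r mu2)/beta3 = P (1 - Omega (1 - r))`.
#'
#' @param params a `gang_params` object.
#' @param Sg_at_E3 the E3 abundance from [equilibrium_E3()].
#' @return Logical.
#' @export
condition_E3 <- function(params, Sg_at_E3) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) stop("Omega undefined (beta3 <= mu2)")
  D <- 1 + d$h * Sg_at_E3 - params$c * params$P
  (d$h * d$a_prime * params$P * (1 - d$Omega * (1 - params$r)) / D^2 <
     1 / params$K) && (params$beta1 < params$b)
}

#' Hopf exclusion at the no-criminals equilibria
#'
#' At E0 and E1 the `(Ig, Ip)` sub-block's characteristic trace term
#' `mu1 + mu2 + a'(P - (1-r) Ip)/(1 - cP) + 2 beta3 Ip / P` is a sum of
#' non-negative quantities with at least one positive, so a purely imaginary
#' eigenvalue pair -- hence a Hopf bifurcation -- is impossible there.
#'
#' @param params a `gang_params` object.
#' @return List with `excluded = TRUE` and the evaluated trace terms at E0
#'   and (when admissible) E1.
#' @export
hopf_excluded_no_criminal <- function(params) {
  d <- derive_parameters(params)
  trace_term <- function(Ip) {
    params$mu1 + params$mu2 +
      d$a_prime * (params$P - (1 - params$r) * Ip) /
        (1 - params$c * params$P) +
      2 * params$beta3 * Ip / params$P
  }
  traces <- c(E0 = trace_term(0))
  if (is.finite(d$Omega)) traces["E1"] <- trace_term(d$Omega * params$P)
  list(excluded = all(traces > 0), trace_terms = traces)
}

#' Hopf exclusion at the core-gang-free equilibria
#'
#' In the regime where E2/E3 can be stable (`beta1 < b`), the linear
#' coefficient `b - beta1 + mu2 + 2 beta3 Ip / P` of the `(Ig, Ip)`
#' sub-block is strictly positive, excluding imaginary pairs. Reports
#' not-applicable when `beta1 >= b`.
#'
#' @param params a `gang_params` object.
#' @return List with `applicable`, `excluded`, and the evaluated
#'   coefficients at E2 and (when admissible) E3.
#' @export
hopf_excluded_core_free <- function(params) {
  if (params$beta1 >= params$b) {
    return(list(applicable = FALSE, excluded = NA,
                coefficients = numeric(0)))
  }
  d <- derive_parameters(params)
  coef_at <- function(Ip) {
    params$b - params$beta1 + params$mu2 + 2 * params$beta3 * Ip / params$P
  }
  coefs <- c(E2 = coef_at(0))
  if (is.finite(d$Omega)) coefs["E3"] <- coef_at(d$Omega * params$P)
  list(applicable = TRUE, excluded = all(coefs > 0), coefficients = coefs)
}
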