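# Equilibria of the reduced system.
#
# Four boundary equilibria have no core gang members (Ig = 0):
#   E0 trivial; E1 criminal-free with endemic police corruption (Ip = Omega*P);
#   E2 core-gang-free and corruption-free (Sg > 0); E3 core-gang-free with
#   endemic corruption.
# E4 is the interior coexistence equilibrium, solved two independent ways
# (bracketed root finding and quartic elimination) that must agree.

#' Construct a labelled equilibrium record
#'
#' Packages a full 5-component state with its label, the maximum absolute
#' rate of [rhs_full()] at the state (`residual_norm`), and an admissibility
#' flag. Populations are kept real-valued; rounding to the printed integer
#' convention happens only in report formatting.
#'
#' @param label one of `"E0"`..`"E4"`.
#' @param state named 5-vector `(Sg, Ig, Sp, Ip, Z)`.
#' @param params a `gang_params` object.
#' @param admissible logical existence flag.
#' @return An `equilibrium_record` (list with `label`, `state`,
#'   `residual_norm`, `admissible`).
#' @export
equilibrium_record <- function(label, state, params, admissible = TRUE) {
  state <- as_full_state(state)
  res <- if (admissible) max(abs(rhs_full(state, params))) else NA_real_
  structure(
    list(label = label, state = state, residual_norm = res,
         admissible = admissible),
    class = "equilibrium_record"
  )
}

#' @export
print.equilibrium_record <- function(x, ...) {
  cat(sprintf("<%s%s> ", x$label, if (x$admissible) "" else " (inadmissible)"))
  cat(paste(sprintf("%s=%.6g", names(x$state), x$state), collapse = " "))
  if (is.finite(x$residual_norm)) cat(sprintf("  |residual|=%.2e", x$residual_norm))
  cat("\n")
  invisible(x)
}

#' Trivial equilibrium E0
#'
#' Everyone gone except a fully susceptible police force: all populations
#' zero, `Sp = P`. Always exists.
#'
#' @param params a `gang_params` object.
#' @return An `equilibrium_record`.
#' @export
equilibrium_E0 <- function(params) {
  stop_if_invalid(params)
  equilibrium_record("E0", c(Sg = 0, Ig = 0, Sp = params$P, Ip = 0, Z = 0),
                     params)
}

#' Criminal-free equilibrium E1
#'
#' No gang members, but corruption endemic in the force: `Ip = Omega * P`
#' with `Omega = (beta3 - mu2)/beta3`. Exists (admissible) only when
#' `beta3 > mu2`, i.e. corruption spreads faster among officers than they
#' leave the service.
#'
#' @param params a `gang_params` object.
#' @return An `equilibrium_record`; inadmissible when `beta3 <= mu2`.
#' @export
equilibrium_E1 <- function(params) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) {
    return(equilibrium_record(
      "E1", c(Sg = 0, Ig = 0, Sp = params$P, Ip = 0, Z = 0),
      params, admissible = FALSE
    ))
  }
  Ip <- d$Omega * params$P
  equilibrium_record(
    "E1", c(Sg = 0, Ig = 0, Sp = params$P - Ip, Ip = Ip, Z = 0), params
  )
}

# Positive admissible roots Sg of the gang-free balance
# ((b - mu1) - Sg/K) * (1 + h*Sg - c*P) = a' * P_eff,
# filtered so the capture denominator and the slaved Z are both positive.
gang_free_sg_roots <- function(params, P_eff) {
  d <- derive_parameters(params)
  h <- d$h
  growth <- params$b - params$mu1
  dfree <- 1 - params$c * params$P
  # coefficients in increasing powers of Sg
  co <- c(growth * dfree - d$a_prime * P_eff,
          growth * h - dfree / params$K,
          -h / params$K)
  if (abs(co[3]) < .Machine$double.eps * max(abs(co[1:2]), 1)) co <- co[1:2]
  if (length(co) == 2 && co[2] == 0) return(numeric(0))
  rt <- polyroot(co)
  rt <- Re(rt[abs(Im(rt)) < 1e-8 * (1 + abs(Re(rt)))])
  rt <- rt[rt > 0 & rt <= growth * params$K + 1e-12 * params$K]
  rt <- rt[1 + h * rt - params$c * params$P > 0]
  sort(rt)
}

gang_free_record <- function(label, Sg, Ip, params) {
  Z <- ((params$b - params$mu1) * Sg - Sg^2 / params$K) / params$mu3
  equilibrium_record(
    label, c(Sg = Sg, Ig = 0, Sp = params$P - Ip, Ip = Ip, Z = Z), params
  )
}

#' Core-gang-free, corruption-free equilibria E2
#'
#' Susceptible gang members persist under predation by a fully susceptible
#' force (`Ig = Ip = 0`); `Sg` solves the quadratic balance between logistic
#' growth and capture, and `Z` is slaved to the capture flux.
#'
#' @param params a `gang_params` object.
#' @return List of `equilibrium_record`s (possibly empty).
#' @export
#' @examples
#' equilibrium_E2(default_parameters())[[1]]$state["Sg"]  # ~1914
equilibrium_E2 <- function(params) {
  stop_if_invalid(params)
  roots <- gang_free_sg_roots(params, P_eff = params$P)
  lapply(roots, function(s) gang_free_record("E2", s, 0, params))
}

#' Core-gang-free equilibria E3
#'
#' As [equilibrium_E2()] but with corruption endemic (`Ip = Omega * P`), so
#' predation pressure is reduced to `P_eff = P (1 - Omega (1 - r))`.
#' Requires `beta3 > mu2`.
#'
#' @param params a `gang_params` object.
#' @return List of `equilibrium_record`s; empty when `beta3 <= mu2`.
#' @export
equilibrium_E3 <- function(params) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) return(list())
  Ip <- d$Omega * params$P
  P_eff <- params$P - (1 - params$r) * Ip
  roots <- gang_free_sg_roots(params, P_eff = P_eff)
  lapply(roots, function(s) gang_free_record("E3", s, Ip, params))
}

#' Coexistence relation: core gang members as a function of corrupt police
#'
#' At coexistence the corrupt-police balance gives
#' `Ig = ((mu2 P - beta3 (P - Ip)) / (beta2 (P - Ip))) * Ip`, positive
#' exactly when `Ip > Omega * P`.
#'
#' @param Ip corrupt police abundance, in `(0, P)`.
#' @param params a `gang_params` object.
#' @return Core gang abundance implied by the corruption balance.
#' @export
ig_of_ip <- function(Ip, params) {
  if (any(Ip >= params$P)) stop("Ip must be < P")
  P <- params$P
  ((params$mu2 * P - params$beta3 * (P - Ip)) /
     (params$beta2 * (P - Ip))) * Ip
}

#' Coexistence relation: susceptible gang members from core members
#'
#' At an interior equilibrium the per-capita growth of both gang
#' compartments must balance, forcing `b Ng / Sg = beta1` and hence
#' `Sg = b Ig / (beta1 - b)`. A positive coexistence state therefore needs
#' the core recruitment rate to exceed gang entry, `beta1 > b`.
#'
#' @param Ig core gang abundance (>= 0).
#' @param params a `gang_params` object.
#' @return Susceptible gang abundance.
#' @export
sg_of_ig <- function(Ig, params) {
  if (params$beta1 <= params$b) {
    stop("beta1 <= b: no positive coexistence equilibrium")
  }
  stopifnot(all(Ig >= 0))
  params$b * Ig / (params$beta1 - params$b)
}

# Per-capita Ig residual along the coexistence manifold, as a function of Ip.
# Using Sg/Ng = b/beta1 on the manifold, the residual reduces to
#   b - Ng/K - a' * P_eff / D - mu1.
coexistence_residual <- function(Ip, params) {
  h <- params$a * params$t_h
  Ig <- ig_of_ip(Ip, params)
  Sg <- sg_of_ig(Ig, params)
  Ng <- Sg + Ig
  D <- 1 + h * (Sg + params$lam * Ig) - params$c * params$P
  P_eff <- params$P - (1 - params$r) * Ip
  params$b - Ng / params$K - (params$a / params$U) * P_eff / D - params$mu1
}

# polynomial product, coefficients in increasing powers
poly_mul <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1)] <- out[i:(i + length(q) - 1)] + p[i] * q
  }
  out
}

# Quartic in Ip obtained by clearing denominators in coexistence_residual.
# With A = beta1/(beta1-b) (so Ng = A*Ig), B = h*(b/(beta1-b) + lam) (so
# D = 1 + B*Ig - c*P) and Ig = N1(Ip) / (beta2 (P - Ip)), where
# N1(Ip) = beta3*Ip^2 - (beta3-mu2)*P*Ip, multiplying the residual by
# beta2^2 (P-Ip)^2 gives
#   [ (b-mu1) beta2 (P-Ip) - (A/K) N1 ] * [ (1-cP) beta2 (P-Ip) + B N1 ]
#     - a' (P - (1-r) Ip) beta2^2 (P-Ip)^2  =  0,
# a quartic whose coefficients are returned in increasing powers of Ip.
coexistence_quartic <- function(params) {
  d <- derive_parameters(params)
  if (params$beta1 <= params$b) stop("beta1 <= b: no coexistence quartic")
  P <- params$P
  A <- params$beta1 / (params$beta1 - params$b)
  B <- d$h * (params$b / (params$beta1 - params$b) + params$lam)
  n1 <- c(0, -(params$beta3 - params$mu2) * P, params$beta3)
  lin <- c(P, -1)                       # (P - Ip)
  f1 <- (params$b - params$mu1) * params$beta2 * c(lin, 0) - (A / params$K) * n1
  f2 <- (1 - params$c * P) * params$beta2 * c(lin, 0) + B * n1
  pred <- d$a_prime * params$beta2^2 *
    poly_mul(c(P, -(1 - params$r)), poly_mul(lin, lin))
  lhs <- poly_mul(f1, f2)
  lhs - c(pred, numeric(length(lhs) - length(pred)))
}

e4_record <- function(Ip, params) {
  Ig <- ig_of_ip(Ip, params)
  Sg <- sg_of_ig(Ig, params)
  equilibrium_record(
    "E4",
    c(Sg = Sg, Ig = Ig, Sp = params$P - Ip,
      Ip = Ip, Z = z_equilibrium(Sg, Ig, Ip, params)),
    params
  )
}

#' Coexistence equilibria E4
#'
#' Solves for all interior equilibria. `Ip` is scanned on
#' `(Omega P, P)` (only there is `Ig > 0`) and each sign change of the
#' per-capita core-gang residual is bisected to relative tolerance 1e-12
#' (method A). Independently, the residual is cleared of denominators to a
#' quartic in `Ip` whose admissible roots are extracted with [polyroot()]
#' (method B). The two root sets must agree to 1e-6 relative; disagreement
#' is an internal error. Requires `beta1 > b` and `beta3 > mu2`; otherwise
#' the list is empty (degenerate equalities included).
#'
#' @param params a `gang_params` object.
#' @param n_grid number of scan points for bracketing (default 600).
#' @return List of admissible `equilibrium_record`s, ordered by `Ip`.
#' @export
#' @examples
#' eq <- equilibrium_E4(default_parameters())[[1]]
#' round(eq$state)  # Sg 2124, Ig 106, Sp 123, Ip 177, Z 395
equilibrium_E4 <- function(params, n_grid = 600) {
  stop_if_invalid(params)
  d <- derive_parameters(params)
  if (params$beta1 <= params$b || !is.finite(d$Omega)) return(list())
  P <- params$P
  lo <- d$Omega * P + 1e-9 * P
  hi <- P - 1e-9 * P
  if (lo >= hi) return(list())

  # method A: bracketed root finding on the per-capita residual
  xs <- seq(lo, hi, length.out = n_grid)
  rs <- vapply(xs, coexistence_residual, numeric(1), params = params)
  roots_a <- numeric(0)
  for (i in which(diff(sign(rs)) != 0)) {
    rt <- stats::uniroot(coexistence_residual, c(xs[i], xs[i + 1]),
                         params = params, tol = 1e-12 * P)$root
    roots_a <- c(roots_a, rt)
  }
  roots_a <- sort(unique(roots_a))

  # method B: quartic elimination. The leading coefficient is naturally
  # tiny (order h/K times rate constants): only exact zeros are stripped.
  co <- coexistence_quartic(params)
  while (length(co) > 1 && co[length(co)] == 0) co <- co[-length(co)]
  roots_b <- numeric(0)
  if (length(co) > 1) {
    rb <- polyroot(co)
    roots_b <- sort(Re(rb[abs(Im(rb)) < 1e-7 * (1 + Mod(rb))]))
  }

  # cross-check: every bracketed root must be confirmed by a quartic root;
  # every quartic root strictly inside (Omega P, P) must be confirmed by
  # the residual -- either via a locally refined sign change (pairs of
  # nearly coincident roots can hide inside one scan cell) or, at a
  # tangency, by a vanishing residual.
  rel_ok <- function(x, set) {
    length(set) && min(abs(set - x)) <= 1e-6 * (1 + abs(x))
  }
  margin <- 1e-7 * P
  roots_b_interior <- roots_b[roots_b > d$Omega * P + margin &
                                roots_b < P - margin]
  for (x in roots_b_interior) {
    if (rel_ok(x, roots_a)) next
    w <- max((hi - lo) / n_grid, 1e-6 * P)
    wlo <- max(x - w, lo); whi <- min(x + w, hi)
    fine <- seq(wlo, whi, length.out = 200)
    fr <- vapply(fine, coexistence_residual, numeric(1), params = params)
    found <- FALSE
    for (j in which(diff(sign(fr)) != 0)) {
      rt <- stats::uniroot(coexistence_residual, c(fine[j], fine[j + 1]),
                           params = params, tol = 1e-12 * P)$root
      roots_a <- c(roots_a, rt)
      found <- TRUE
    }
    if (!found && abs(coexistence_residual(x, params)) < 1e-10) {
      roots_a <- c(roots_a, x)  # tangency (double root)
      found <- TRUE
    }
    if (!found) {
      stop("internal error: quartic root ", signif(x, 10),
           " not confirmed by the residual")
    }
  }
  roots_a <- sort(roots_a)
  if (length(roots_a) > 1) {
    roots_a <- roots_a[c(TRUE, diff(roots_a) > 1e-8 * (1 + roots_a[-1]))]
  }
  if (!all(vapply(roots_a, rel_ok, logical(1), set = roots_b))) {
    stop("internal error: coexistence root-find and quartic disagree (",
         paste(signif(roots_a, 10), collapse = ","), " vs ",
         paste(signif(roots_b, 10), collapse = ","), ")")
  }
  lapply(roots_a, e4_record, params = params)
}

#' All equilibria of the model
#'
#' Aggregates the admissible records of E0-E4 for one parameter set.
#'
#' @param params a `gang_params` object.
#' @return List of admissible `equilibrium_record`s.
#' @export
#' @examples
#' length(find_all_equilibria(default_parameters()))  # 5 at the defaults
find_all_equilibria <- function(params) {
  recs <- c(
    list(equilibrium_E0(params)),
    Filter(function(r) r$admissible, list(equilibrium_E1(params))),
    equilibrium_E2(params),
    equilibrium_E3(params),
    equilibrium_E4(params)
  )
  recs
}

#' Equilibria as a data frame
#'
#' @param recs list of `equilibrium_record`s.
#' @return data.frame with label, the five state components and residual.
#' @export
equilibria_table <- function(recs) {
  do.call(rbind, lapply(recs, function(r) {
    data.frame(label = r$label, t(r$state), residual_norm = r$residual_norm)
  }))
}
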