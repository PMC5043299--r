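# Transcritical bifurcation thresholds and parameter scans.
#
# All five tipping points of the base parameterisation are transcritical:
# an equilibrium branch exchanges stability with a neighbour as one real
# eigenvalue crosses zero. Closed forms follow from the boundary-equilibrium
# stability conditions; scans + bisection provide the numerical cross-check.

#' Critical core-recruitment rate beta1
#'
#' The coexistence equilibrium exists (and the core-gang-free state E3 loses
#' stability) as `beta1` crosses `b`: below, the system tends to E3; above,
#' to E4.
#'
#' @param params a `gang_params` object.
#' @return The critical value (equal to `b`).
#' @export
critical_beta1 <- function(params) {
  stop_if_invalid(params)
  params$b
}

#' Critical gang exit rate mu1
#'
#' Solving the E1 stability condition as an equality for `mu1` gives
#' `mu1* = b - a' P (1 - Omega (1 - r)) / (1 - c P)`: above it the
#' criminal-free equilibrium E1 is the attractor, below it coexistence E4.
#'
#' @param params a `gang_params` object (requires `beta3 > mu2`).
#' @return The critical exit rate.
#' @export
#' @examples
#' critical_mu1(default_parameters())  # 0.1581429
critical_mu1 <- function(params) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) stop("Omega undefined (beta3 <= mu2)")
  params$b - d$a_prime * params$P * (1 - d$Omega * (1 - params$r)) /
    (1 - params$c * params$P)
}

#' Critical police force size P
#'
#' Solving `a' P (1 - Omega (1-r)) / (1 - c P) = b - mu1` for `P` gives
#' `P* = (b - mu1) / (a' (1 - Omega (1-r)) + c (b - mu1))`: a force larger
#' than `P*` drives the gang extinct (E1).
#'
#' @param params a `gang_params` object (requires `beta3 > mu2`, `b > mu1`).
#' @return The critical force size (persons).
#' @export
#' @examples
#' critical_P(default_parameters())  # 450.28143
critical_P <- function(params) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) stop("Omega undefined (beta3 <= mu2)")
  if (params$b <= params$mu1) stop("requires b > mu1")
  den <- d$a_prime * (1 - d$Omega * (1 - params$r)) +
    params$c * (params$b - params$mu1)
  if (den <= 0) stop("nonpositive denominator in critical P")
  (params$b - params$mu1) / den
}

#' Critical search rate a
#'
#' Solving the E1 stability condition for the search/attack rate:
#' `a* = U (b - mu1)(1 - c P) / (P (1 - Omega (1 - r)))`. Above `a*` the
#' police eradicate the gang (E1).
#'
#' @param params a `gang_params` object (requires `beta3 > mu2`).
#' @return The critical search rate.
#' @export
#' @examples
#' signif(critical_a(default_parameters()), 2)  # 0.0019
critical_a <- function(params) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) stop("Omega undefined (beta3 <= mu2)")
  params$U * (params$b - params$mu1) * (1 - params$c * params$P) /
    (params$P * (1 - d$Omega * (1 - params$r)))
}

#' Critical gang entry rates b
#'
#' The coexistence window in the gang entry rate: below
#' `lower = mu1 + a' P (1 - Omega (1-r)) / (1 - c P)` the criminal-free
#' equilibrium E1 is stable; above `upper = beta1` the core-gang-free
#' equilibrium E3 takes over (the `b = beta1` crossing of the E3 stability
#' clause). Coexistence (E4) requires `lower < b < upper`.
#'
#' @param params a `gang_params` object (requires `beta3 > mu2`).
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' critical_b(default_parameters())  # 0.1618571, 0.21
critical_b <- function(params) {
  d <- derive_parameters(params)
  if (!is.finite(d$Omega)) stop("Omega undefined (beta3 <= mu2)")
  c(lower = params$mu1 + d$a_prime * params$P *
      (1 - d$Omega * (1 - params$r)) / (1 - params$c * params$P),
    upper = params$beta1)
}

set_param <- function(params, name, value) {
  if (!name %in% param_fields()) stop("unknown parameter: ", name)
  p <- unclass(params)
  p[[name]] <- value
  if (name == "mu2") p$gamma <- value
  structure(p, class = "gang_params")
}

#' Regime label from linear stability
#'
#' Computes all admissible equilibria and classifies each by its reduced
#' Jacobian. The regime is the label of the unique stable admissible
#' equilibrium; rows with none or several stable equilibria, or with only
#' marginal ones, are flagged `"indeterminate"` rather than forced.
#'
#' @param params a `gang_params` object.
#' @return List with `regime` (label or "indeterminate") and `details`
#'   (data.frame: label, max_real, classification).
#' @export
classify_regime <- function(params) {
  recs <- find_all_equilibria(params)
  rows <- lapply(recs, function(r) {
    rep <- stability_report(r$state, params, label = r$label)
    data.frame(label = r$label, max_real = rep$max_real,
               classification = rep$classification)
  })
  details <- do.call(rbind, rows)
  stable <- details$label[details$classification == "stable"]
  regime <- if (length(stable) == 1) stable else "indeterminate"
  list(regime = regime, details = details)
}

#' Parameter scan
#'
#' Evaluates the equilibrium structure and regime label on a grid of one
#' parameter, holding the rest fixed. Every grid value must keep the
#' parameter set admissible (e.g. `c * P < 1`).
#'
#' @param params a `gang_params` object (the fixed baseline).
#' @param parameter name of the scanned field.
#' @param lo,hi scan range (`lo < hi`).
#' @param n number of grid points (>= 3).
#' @return A `gang_scan` data.frame: `value`, one `max_real_*` column per
#'   equilibrium label (smallest max-real-part among that label's admissible
#'   roots; `NA` when absent), `n_stable`, `regime`. The scanned parameter
#'   name and baseline are attached as attributes.
#' @export
#' @examples
#' sc <- scan_parameter(default_parameters(), "mu1", 0.05, 0.25, n = 9)
#' table(sc$regime)
scan_parameter <- function(params, parameter, lo, hi, n) {
  stop_if_invalid(params)
  if (!(lo < hi)) stop("requires lo < hi")
  if (n < 3) stop("need at least 3 grid points")
  grid <- seq(lo, hi, length.out = n)
  labels <- c("E0", "E1", "E2", "E3", "E4")
  rows <- lapply(grid, function(v) {
    p <- set_param(params, parameter, v)
    bad <- validate_parameters(p)
    if (length(bad)) {
      stop("scan leaves the admissible parameter region at ", parameter,
           " = ", v, ": ", bad[1])
    }
    cls <- classify_regime(p)
    mr <- sapply(labels, function(l) {
      m <- cls$details$max_real[cls$details$label == l]
      if (length(m)) min(m) else NA_real_
    })
    names(mr) <- paste0("max_real_", labels)
    data.frame(value = v, t(mr),
               n_stable = sum(cls$details$classification == "stable"),
               regime = cls$regime)
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "baseline") <- params
  class(out) <- c("gang_scan", "data.frame")
  out
}

# leading real part of the named boundary equilibrium's spectrum, or NA
# when that equilibrium does not exist at these parameters
boundary_max_real <- function(label, params) {
  recs <- switch(label,
    E0 = list(equilibrium_E0(params)),
    E1 = Filter(function(r) r$admissible, list(equilibrium_E1(params))),
    E2 = equilibrium_E2(params),
    E3 = equilibrium_E3(params),
    list()
  )
  if (!length(recs)) return(NA_real_)
  min(vapply(recs, function(r) {
    stability_report(r$state, params)$max_real
  }, numeric(1)))
}

#' Refine scan-detected regime transitions
#'
#' Transitions are bracketed between consecutive scan rows with different
#' determinate regime labels (rows flagged `"indeterminate"`, e.g. inside a
#' narrow bistable sliver beside a transcritical point, are skipped when
#' forming brackets). Each bracket is refined by bisection on the
#' stability-determining quantity -- the leading real eigenvalue part of
#' the boundary equilibrium that exchanges stability, which crosses zero
#' exactly at a transcritical point -- until the bracket is narrower than
#' `tol` (absolute, in the parameter's units). When no single boundary
#' equilibrium with a sign change identifies the crossing, the bracket
#' falls back to bisection on the regime label itself and the result is
#' marked `bracket_ok = FALSE` if the endpoint regimes are not reproduced.
#'
#' @param table a `gang_scan` from [scan_parameter()].
#' @param params baseline `gang_params` (defaults to the scan's baseline).
#' @param tol bisection tolerance (default 1e-8).
#' @return List of `bifurcation_result` records: `parameter`,
#'   `critical_value`, `regime_below`, `regime_above`, `method`,
#'   `bifurcation_type`.
#' @export
#' @examples
#' sc <- scan_parameter(default_parameters(), "mu1", 0.15, 0.17, n = 5)
#' detect_transitions(sc)[[1]]$critical_value  # ~0.1581429
detect_transitions <- function(table, params = attr(table, "baseline"),
                               tol = 1e-8) {
  parameter <- attr(table, "parameter")
  det <- which(table$regime != "indeterminate")
  out <- list()
  for (k in seq_len(length(det) - 1)) {
    i <- det[k]; j <- det[k + 1]
    r_lo <- table$regime[i]; r_hi <- table$regime[j]
    if (identical(r_lo, r_hi)) next
    lo <- table$value[i]; hi <- table$value[j]
    ok <- TRUE
    refined <- NA_real_

    # preferred path: bisect the losing/gaining boundary equilibrium's
    # leading eigenvalue through its zero crossing
    cand <- setdiff(c(r_lo, r_hi), "E4")
    if (length(cand) == 1 && cand %in% c("E0", "E1", "E2", "E3")) {
      f <- function(v) {
        boundary_max_real(cand, set_param(params, parameter, v))
      }
      flo <- f(lo); fhi <- f(hi)
      if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
        blo <- lo; bhi <- hi
        while (bhi - blo > tol) {
          mid <- (blo + bhi) / 2
          fm <- f(mid)
          if (!is.finite(fm)) break
          if (sign(fm) == sign(flo)) blo <- mid else bhi <- mid
        }
        refined <- (blo + bhi) / 2
      }
    }

    if (!is.finite(refined)) {
      # fallback: bisection on the regime label; indeterminate slivers are
      # lumped with the upper side
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        r_mid <- classify_regime(set_param(params, parameter, mid))$regime
        if (identical(r_mid, r_lo)) {
          lo <- mid
        } else if (identical(r_mid, r_hi) ||
                   identical(r_mid, "indeterminate")) {
          hi <- mid
        } else {
          ok <- FALSE
          break
        }
      }
      refined <- (lo + hi) / 2
    }

    out[[length(out) + 1]] <- structure(
      list(parameter = parameter, critical_value = refined,
           regime_below = r_lo, regime_above = r_hi,
           method = "scan", bifurcation_type = "transcritical",
           bracket_ok = ok),
      class = "bifurcation_result"
    )
  }
  out
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("Transcritical bifurcation in %s at %.8g: %s -> %s [%s]\n",
              x$parameter, x$critical_value, x$regime_below,
              x$regime_above, x$method))
  invisible(x)
}
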