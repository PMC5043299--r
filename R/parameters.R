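# Parameter handling for the police-gang eco-epidemiological model.
#
# The model has 15 rate/shape constants plus the constant police force size
# P. Populations: susceptible gang members Sg, committed core members Ig,
# susceptible police Sp, corrupt police Ip, and the justice-system sink Z.

#' Default model parameters
#'
#' Returns the baseline parameter set used throughout the package's numerical
#' work, as a `gang_params` object. Individual fields can be overridden by
#' name. The police entry rate `gamma` is constrained equal to the exit rate
#' `mu2` (the force is held at constant strength `P`), so `gamma` tracks any
#' `mu2` override unless explicitly supplied.
#'
#' @param ... named overrides of individual parameter fields.
#'
#' @details Fields and meanings (all rates per unit time, populations in
#' persons):
#' \describe{
#'   \item{b}{entry rate into the gang (susceptible recruits).}
#'   \item{mu1}{exit rate from the gang (both compartments).}
#'   \item{mu2}{rate at which police officers leave the service.}
#'   \item{mu3}{justice-system processing rate (jail/exoneration).}
#'   \item{gamma}{police academy graduation rate; equals `mu2`.}
#'   \item{beta1}{recruitment rate of susceptible youth into the core gang.}
#'   \item{beta2}{corruption rate of susceptible police by gang members.}
#'   \item{beta3}{corruption rate of susceptible police by corrupt police.}
#'   \item{a}{police search/attack rate.}
#'   \item{U}{police team size (>= 1).}
#'   \item{r}{relative hunting efficiency of corrupt police, in \[0, 1\].}
#'   \item{lam}{handling-time multiplier for core members (more resistant
#'     to arrest).}
#'   \item{t_h}{handling time per arrested gang member.}
#'   \item{c}{cooperation/communication time saving coefficient.}
#'   \item{K}{gang carrying-capacity parameter.}
#'   \item{P}{constant police force size.}
#' }
#'
#' @return A `gang_params` object (named list of the 16 fields).
#' @seealso [validate_parameters()], [derive_parameters()], [read_config()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$beta3 / p$mu2   # corruption spreads faster than officers leave
#' default_parameters(P = 500)$P
default_parameters <- function(...) {
  p <- list(
    b = 0.2, mu1 = 0.12, mu2 = 0.0476, mu3 = 0.2, gamma = 0.0476,
    beta1 = 0.21, beta2 = 0.105, beta3 = 0.0525,
    a = 0.001, U = 10, r = 0.75, lam = 1.5, t_h = 0.01, c = 0.001,
    K = 50000, P = 300
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    }
    # keep gamma slaved to mu2 unless the caller sets gamma explicitly
    if ("mu2" %in% names(over) && !("gamma" %in% names(over))) {
      over$gamma <- over$mu2
    }
    p[names(over)] <- over
  }
  structure(p, class = "gang_params")
}

#' @export
print.gang_params <- function(x, ...) {
  cat("Police-gang model parameters:\n")
  v <- unlist(x)
  print(signif(v, 6))
  invisible(x)
}

param_fields <- function() names(unclass(default_parameters()))

#' Validate a parameter set
#'
#' Checks the admissibility constraints of the model: non-negativity of all
#' rates, `U >= 1`, `r` in \[0, 1\], positive `K` and `P`, a positive
#' capture-rate denominator in the gang-free state (`c * P < 1`), and the
#' constant-force constraint `gamma == mu2`.
#'
#' @param params a `gang_params` object or compatible named list.
#' @return Character vector of violation messages; empty when valid.
#' @export
#' @examples
#' validate_parameters(default_parameters())                # character(0)
#' validate_parameters(default_parameters(c = 0.01))        # c*P = 3 >= 1
validate_parameters <- function(params) {
  v <- character(0)
  miss <- setdiff(param_fields(), names(params))
  if (length(miss)) {
    return(paste0("missing field(s): ", paste(miss, collapse = ", ")))
  }
  for (f in param_fields()) {
    x <- params[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      v <- c(v, paste0(f, ": must be a finite numeric scalar"))
    } else if (x < 0) {
      v <- c(v, paste0(f, ": must be non-negative"))
    }
  }
  if (length(v)) return(v)
  if (params$U < 1) v <- c(v, "U: team size must be >= 1")
  if (params$r > 1) v <- c(v, "r: must lie in [0, 1]")
  if (params$K <= 0) v <- c(v, "K: must be positive")
  if (params$P <= 0) v <- c(v, "P: must be positive")
  if (params$c * params$P >= 1) {
    v <- c(v, sprintf(
      "c: cooperation saving c*P = %g must be < 1 (capture denominator)",
      params$c * params$P
    ))
  }
  if (abs(params$gamma - params$mu2) > 1e-12 * (1 + params$mu2)) {
    v <- c(v, "gamma: must equal mu2 (constant police force)")
  }
  v
}

stop_if_invalid <- function(params) {
  v <- validate_parameters(params)
  if (length(v)) stop("invalid parameters: ", paste(v, collapse = "; "))
  invisible(params)
}

#' Derived composite parameters
#'
#' Computes the composite quantities used throughout the analysis:
#' the handling coefficient `h = a * t_h`, the per-officer attack coefficient
#' `a_prime = a / U`, the endemic corrupt fraction
#' `Omega = (beta3 - mu2) / beta3` (defined only when `beta3 > mu2`; `NA`
#' otherwise), and the logistic fixed point `k_cap = (b - mu1) * K` of the
#' total gang population.
#'
#' @param params a valid `gang_params` object.
#' @return List with fields `h`, `a_prime`, `Omega`, `k_cap`.
#' @export
#' @examples
#' derive_parameters(default_parameters())$Omega  # ~ 0.09333
derive_parameters <- function(params) {
  stop_if_invalid(params)
  Omega <- if (params$beta3 > params$mu2) {
    (params$beta3 - params$mu2) / params$beta3
  } else {
    NA_real_
  }
  list(
    h = params$a * params$t_h,
    a_prime = params$a / params$U,
    Omega = Omega,
    k_cap = (params$b - params$mu1) * params$K
  )
}

#' Default sampling bounds for random parameter sets
#'
#' Intervals around the baseline values, chosen so that independently drawn
#' sets are almost always admissible (in particular `c * P < 1` holds for the
#' whole box).
#'
#' @return Named list of `c(lower, upper)` intervals for each sampled field.
#' @export
default_bounds <- function() {
  list(
    b = c(0.10, 0.30), mu1 = c(0.02, 0.20), mu2 = c(0.01, 0.10),
    mu3 = c(0.05, 0.50), beta1 = c(0.05, 0.50), beta2 = c(0.02, 0.20),
    beta3 = c(0.01, 0.10), a = c(1e-4, 5e-3), U = c(5, 20),
    r = c(0.3, 1.0), lam = c(1.0, 3.0), t_h = c(0.001, 0.05),
    c = c(1e-4, 1e-3), K = c(1e4, 1e5), P = c(100, 500)
  )
}

#' Sample random admissible parameter sets
#'
#' Draws each field independently and uniformly from `bounds`, slaves `gamma`
#' to `mu2`, and rejects draws that fail [validate_parameters()]. Used by the
#' property-style test-suite; reproducible given `seed`.
#'
#' @param n number of sets to draw.
#' @param seed integer RNG seed.
#' @param bounds named list of `c(lower, upper)` intervals; defaults to
#'   [default_bounds()]. Fields absent from `bounds` stay at their baseline
#'   values.
#' @return List of `n` `gang_params` objects, all passing validation.
#' @export
#' @examples
#' ps <- sample_parameters(3, seed = 1)
#' all(vapply(ps, function(p) length(validate_parameters(p)) == 0, logical(1)))
sample_parameters <- function(n, seed, bounds = default_bounds()) {
  stopifnot(n >= 1)
  bad <- setdiff(names(bounds), param_fields())
  if (length(bad)) stop("bounds for unknown field(s): ", paste(bad, collapse = ", "))
  for (f in names(bounds)) {
    bb <- bounds[[f]]
    if (length(bb) != 2 || bb[1] > bb[2]) {
      stop("bounds for ", f, " must be c(lower, upper)")
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  draws <- 0L
  for (i in seq_len(n)) {
    repeat {
      draws <- draws + 1L
      if (draws > 1000L * n) stop("unsatisfiable bounds: rejection sampling stalled")
      p <- unclass(default_parameters())
      for (f in names(bounds)) {
        bb <- bounds[[f]]
        p[[f]] <- stats::runif(1, bb[1], bb[2])
      }
      p$gamma <- p$mu2
      p <- structure(p, class = "gang_params")
      if (length(validate_parameters(p)) == 0) break
    }
    out[[i]] <- p
  }
  out
}

#' Read a parameter configuration file
#'
#' Reads a YAML or JSON file with one key per parameter field. Missing keys
#' fall back to the package defaults; unknown keys are an error. `gamma`
#' follows an overridden `mu2` unless set explicitly.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `gang_params` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension '", ext, "' (use yaml or json)")
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of parameter fields")
  bad <- setdiff(names(raw), param_fields())
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  p <- do.call(default_parameters, raw)
  stop_if_invalid(p)
  p
}
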