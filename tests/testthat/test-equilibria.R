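p0 <- default_parameters()

test_that("boundary equilibria E0/E1 match their closed forms", {
  e0 <- equilibrium_E0(p0)
  expect_equal(unname(e0$state), c(0, 0, 300, 0, 0))
  expect_equal(e0$residual_norm, 0)
  expect_true(e0$admissible)

  e1 <- equilibrium_E1(p0)
  expect_equal(e1$state[["Ip"]], 28, tolerance = 0.1 / 28)
  expect_equal(e1$state[["Sp"]], p0$P - e1$state[["Ip"]])
  expect_lt(e1$residual_norm, 1e-10)
  # endemic corruption requires beta3 > mu2
  expect_false(equilibrium_E1(default_parameters(beta3 = 0.01))$admissible)
})

test_that("gang-persistence equilibria E2/E3 solve the quadratic balance", {
  e2 <- equilibrium_E2(p0)
  expect_length(e2, 1)
  expect_equal(e2[[1]]$state[["Sg"]], 1914, tolerance = 1 / 1914)
  expect_equal(e2[[1]]$state[["Z"]], 399, tolerance = 2 / 399)
  expect_lt(e2[[1]]$residual_norm, 1e-10)
  # no predation: logistic fixed point exactly
  e2a <- equilibrium_E2(default_parameters(a = 0))
  expect_equal(e2a[[1]]$state[["Sg"]], 4000)

  e3 <- equilibrium_E3(p0)
  expect_length(e3, 1)
  expect_equal(e3[[1]]$state[["Sg"]], 1964, tolerance = 2 / 1964)
  expect_equal(e3[[1]]$state[["Ip"]], 28, tolerance = 0.1 / 28)
  expect_lt(e3[[1]]$residual_norm, 1e-10)
  # corrupt police at full efficiency make E3's gang level coincide with E2's
  pr <- default_parameters(r = 1)
  expect_equal(equilibrium_E3(pr)[[1]]$state[["Sg"]],
               equilibrium_E2(pr)[[1]]$state[["Sg"]])
  expect_length(equilibrium_E3(default_parameters(beta3 = 0.01)), 0)
})

test_that("coexistence relations reproduce the published point", {
  expect_equal(ig_of_ip(177, p0), 107.2, tolerance = 0.2 / 107.2)
  d <- derive_parameters(p0)
  expect_equal(ig_of_ip(d$Omega * p0$P, p0), 0, tolerance = 1e-12)
  expect_equal(ig_of_ip(176.5, p0), 106, tolerance = 1 / 106)
  expect_error(ig_of_ip(300, p0), "< P")

  expect_equal(sg_of_ig(106.2, p0), 2124, tolerance = 0.5 / 2124)
  expect_equal(sg_of_ig(0, p0), 0)
  pb <- default_parameters(beta1 = 0.4)  # beta1 = 2b: symmetric split
  expect_equal(sg_of_ig(57, pb), 57)
  expect_error(sg_of_ig(10, default_parameters(beta1 = 0.19)), "beta1")
})

test_that("coexistence solver reproduces the published equilibrium", {
  e4 <- equilibrium_E4(p0)
  expect_length(e4, 1)
  expect_equal(unname(round(e4[[1]]$state)), c(2124, 106, 123, 177, 395))
  expect_lt(e4[[1]]$residual_norm, 1e-8)
  # below the recruitment threshold there is no interior equilibrium
  expect_length(equilibrium_E4(default_parameters(beta1 = 0.19)), 0)
  expect_length(equilibrium_E4(default_parameters(beta1 = 0.2)), 0)
  expect_length(equilibrium_E4(default_parameters(beta3 = 0.0476)), 0)
})

test_that("quartic elimination agrees with bracketed root finding across regimes", {
  sets <- sample_parameters(50, seed = 5, bounds = coexistence_bounds())
  n_found <- 0
  for (p in sets) {
    recs <- equilibrium_E4(p)  # internal A/B disagreement would error here
    for (r in recs) {
      expect_lt(r$residual_norm, 1e-8 * (1 + max(abs(r$state))))
      # sign-change verification around the root
      ip <- r$state[["Ip"]]
      w <- 1e-4 * p$P
      f <- function(x) gangdyn:::coexistence_residual(x, p)
      expect_lt(f(ip - w) * f(ip + w), 0)
    }
    n_found <- n_found + length(recs)
  }
  expect_gt(n_found, 10)  # the regime-forcing bounds do yield coexistence
})

test_that("no interior zero of the reduced system is missed by the solver", {
  # brute-force oracle: minimise |rhs|^2 from many starts and check every
  # converged interior zero is one of the returned E4 records
  sets <- sample_parameters(8, seed = 9, bounds = coexistence_bounds())
  total_hits <- 0
  for (p in sets) {
    recs <- equilibrium_E4(p)
    ips <- vapply(recs, function(r) r$state[["Ip"]], numeric(1))
    obj <- function(x) {
      if (x[1] <= 0 || x[2] <= 0 || x[3] <= 0 || x[3] >= p$P) return(1e12)
      d <- 1 + p$a * p$t_h * (x[1] + p$lam * x[2]) - p$c * p$P
      if (d <= 0) return(1e12)
      sum(rhs_reduced(x, p)^2)
    }
    set.seed(101)
    hits <- 0
    for (k in 1:12) {
      x0 <- c(runif(1, 1, 0.2 * p$K), runif(1, 1, 0.05 * p$K),
              runif(1, 1, p$P - 1))
      fit <- optim(x0, obj, control = list(maxit = 5000, reltol = 1e-14))
      fit <- optim(fit$par, obj, control = list(maxit = 5000, reltol = 1e-14))
      # converged to an interior zero (not a boundary Ig = 0 equilibrium)?
      if (fit$value < 1e-10 && fit$par[2] > 1) {
        hits <- hits + 1
        expect_true(length(ips) > 0 &&
                      min(abs(fit$par[3] - ips)) < 1e-3 * (1 + fit$par[3]))
      }
    }
    total_hits <- total_hits + hits
  }
  expect_gt(total_hits, 0)  # the oracle did exercise interior zeros
})

test_that("E4 branch collapses onto E3 as beta1 approaches b from above", {
  eps <- c(5e-3, 2e-3, 1e-3, 5e-4)
  igs <- vapply(0.2 + eps, function(b1) {
    equilibrium_E4(default_parameters(beta1 = b1))[[1]]$state[["Ig"]]
  }, numeric(1))
  expect_true(all(diff(igs) < 0))
  # the branch vanishes linearly in beta1 - b
  expect_equal(igs[1] / igs[4], eps[1] / eps[4], tolerance = 0.1)
})

test_that("the aggregator returns every admissible record with its residual", {
  recs <- find_all_equilibria(p0)
  expect_equal(vapply(recs, function(r) r$label, character(1)),
               c("E0", "E1", "E2", "E3", "E4"))
  for (r in recs) {
    expect_lt(r$residual_norm, 1e-8 * (1 + max(abs(r$state))))
  }
  # corruption dies and recruitment is weak: only E0 and E2 remain
  p <- default_parameters(beta3 = 0.01, beta1 = 0.15)
  labs <- vapply(find_all_equilibria(p), function(r) r$label, character(1))
  expect_equal(labs, c("E0", "E2"))
  tab <- equilibria_table(recs)
  expect_equal(nrow(tab), 5)
  expect_true(all(c("label", "Sg", "Z", "residual_norm") %in% names(tab)))
})
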