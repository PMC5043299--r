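p0 <- default_parameters()

test_that("analytic Jacobian matches the finite-difference oracle", {
  set.seed(21)
  sets <- sample_parameters(5, seed = 13)
  for (i in 1:20) {
    p <- sets[[1 + (i %% length(sets))]]
    st <- random_interior_state(p)
    expect_equal(jacobian_reduced(st, p), fd_jacobian(st, p),
                 tolerance = 1e-6)
  }
})

test_that("Jacobian entries reproduce the boundary-equilibrium eigenstructure", {
  # at E2 the core-recruitment direction grows at beta1 - b
  e2 <- equilibrium_E2(p0)[[1]]
  J2 <- jacobian_reduced(e2$state[c("Sg", "Ig", "Ip")], p0)
  expect_equal(J2["Ig", "Ig"], p0$beta1 - p0$b, tolerance = 1e-10)
  # at the origin the gang rows decouple: growth b - a'P/(1-cP) - mu1
  J0 <- jacobian_reduced(c(0, 0, 0), p0)
  ap <- p0$a / p0$U
  expect_equal(J0["Sg", "Sg"], p0$b - ap * p0$P / 0.7 - p0$mu1)
  expect_equal(J0["Ig", "Ig"], -ap * p0$P / 0.7 - p0$mu1)
  # corruption invades the origin at beta3 - mu2
  expect_equal(J0["Ip", "Ip"], p0$beta3 - p0$mu2)
})

test_that("characteristic coefficients are consistent with the spectrum", {
  set.seed(22)
  st <- random_interior_state(p0)
  J <- jacobian_reduced(st, p0)
  cp <- char_poly_coefficients(J)
  expect_equal(cp[["a1"]], -sum(diag(J)), tolerance = 1e-10)
  expect_equal(cp[["a3"]], -det(J), tolerance = 1e-10)
  # every eigenvalue is a root of the cubic
  for (ev in eigen(J, only.values = TRUE)$values) {
    expect_lt(Mod(ev^3 + cp[["a1"]] * ev^2 + cp[["a2"]] * ev + cp[["a3"]]),
              1e-8 * (1 + Mod(ev)^3))
  }
})

test_that("base-case classification: boundary states unstable, coexistence stable", {
  for (r in find_all_equilibria(p0)) {
    rep <- stability_report(r$state, p0, label = r$label)
    if (r$label == "E4") {
      expect_equal(rep$classification, "stable")
      expect_true(all(Re(rep$eigenvalues) < 0))
      expect_true(all(rep$routh_hurwitz))
    } else {
      expect_equal(rep$classification, "unstable")
    }
  }
  expect_error(stability_report(c(500, 50, 50), p0), "not an equilibrium")
})

test_that("closed-form conditions evaluate as the arithmetic dictates", {
  expect_false(condition_E0(p0))                       # 0.042857 < 0.08
  expect_true(condition_E0(default_parameters(P = 500)))  # 0.1 > 0.08
  expect_true(condition_E0(default_parameters(b = 0.12)))  # zero net growth

  expect_false(condition_E1(p0))                       # 0.0418571 < 0.08
  expect_true(condition_E1(default_parameters(P = 451)))  # past 450.28143
  pr <- default_parameters(r = 1)
  expect_identical(condition_E1(pr), condition_E0(pr))
  expect_error(condition_E1(default_parameters(beta3 = 0.01)), "Omega")

  expect_false(condition_E2(p0, 1914))                 # beta1 > b
  expect_true(condition_E2(default_parameters(beta1 = 0.15), 1914))
  expect_true(condition_E2(default_parameters(beta1 = 0.15, t_h = 0), 1914))

  expect_false(condition_E3(p0, 1964))                 # beta1 > b
  pb <- default_parameters(b = 0.25)
  sg3 <- equilibrium_E3(pb)[[1]]$state[["Sg"]]
  expect_true(condition_E3(pb, sg3))
  expect_equal(classify_regime(pb)$regime, "E3")
  pr <- default_parameters(r = 1, beta1 = 0.15)
  expect_identical(condition_E3(pr, 1914), condition_E2(pr, 1914))
})

test_that("Routh-Hurwitz sign pattern matches the eigenvalue classification", {
  sets <- c(sample_parameters(15, seed = 31, bounds = coexistence_bounds()),
            sample_parameters(10, seed = 32, bounds = corruption_free_bounds()))
  for (p in sets) {
    for (r in find_all_equilibria(p)) {
      rep <- stability_report(r$state, p, label = r$label)
      if (abs(rep$max_real) < 1e-6) next  # marginal: sign test undefined
      expect_equal(all(rep$routh_hurwitz), rep$classification == "stable",
                   info = paste(r$label, "at set with b =", p$b))
    }
  }
})

test_that("closed-form conditions agree with eigenvalues in their regimes", {
  # endemic-corruption regime: E1/E3 are the candidate gang-free attractors
  for (p in sample_parameters(25, seed = 41, bounds = coexistence_bounds())) {
    rep1 <- stability_report(equilibrium_E1(p)$state, p, label = "E1")
    if (abs(rep1$max_real) > 1e-6) {
      expect_equal(condition_E1(p), rep1$classification == "stable")
    }
    for (r in equilibrium_E3(p)) {
      rep3 <- stability_report(r$state, p, label = "E3")
      if (abs(rep3$max_real) > 1e-6) {
        expect_equal(condition_E3(p, r$state[["Sg"]]),
                     rep3$classification == "stable")
      }
    }
  }
  # corruption-free regime: E0/E2 are the candidates
  for (p in sample_parameters(25, seed = 42, bounds = corruption_free_bounds())) {
    rep0 <- stability_report(equilibrium_E0(p)$state, p, label = "E0")
    if (abs(rep0$max_real) > 1e-6) {
      expect_equal(condition_E0(p), rep0$classification == "stable")
    }
    for (r in equilibrium_E2(p)) {
      rep2 <- stability_report(r$state, p, label = "E2")
      if (abs(rep2$max_real) > 1e-6) {
        expect_equal(condition_E2(p, r$state[["Sg"]]),
                     rep2$classification == "stable")
      }
    }
  }
})

test_that("Hopf bifurcations are excluded at the gang-free equilibria", {
  he <- hopf_excluded_no_criminal(p0)
  expect_true(he$excluded)
  expect_equal(unname(he$trace_terms[["E0"]]),
               0.12 + 0.0476 + 0.042857, tolerance = 1e-4)
  expect_true(all(he$trace_terms > 0))

  expect_true(hopf_excluded_core_free(default_parameters(beta1 = 0.15))$excluded)
  expect_false(hopf_excluded_core_free(p0)$applicable)  # beta1 >= b

  for (p in sample_parameters(100, seed = 55)) {
    expect_true(hopf_excluded_no_criminal(p)$excluded)
    hc <- hopf_excluded_core_free(p)
    if (hc$applicable) expect_true(hc$excluded)
  }
})
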