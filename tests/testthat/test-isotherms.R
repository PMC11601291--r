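## The three printed isotherms are exact solutions of the two-species
## quadratic equilibrium; every closed form is checked against an
## independent numerical root-finder oracle.

test_that("titration_fraction: limits and oracle agreement", {
  ## K_D = 0: piecewise-linear titration f = f_max * min(r, n) / n
  r <- c(0.2, 0.7, 1, 1.8, 5)
  expect_equal(titration_fraction(r, 0, 1, 0.9), 0.9 * pmin(r, 1))
  ## saturation: r -> Inf gives f_max
  expect_equal(titration_fraction(1e9, 0.5, 1, 0.85), 0.85, tolerance = 1e-6)
  set.seed(7)
  for (i in 1:200) {
    rr <- runif(1, 0, 20); K <- runif(1, 0, 3); n <- runif(1, 0.05, 4)
    expect_equal(titration_fraction(rr, K, n, 1),
                 oracle_binding_fraction(rr, n, K), tolerance = 1e-10)
  }
})

test_that("binding_fraction: limits and oracle agreement", {
  expect_equal(binding_fraction(c(0.3, 2), 1, 0), pmin(c(0.3, 2), 1))
  ## ligand excess: f -> E/(E+K)
  expect_equal(binding_fraction(50, 1e-6, 5), 50 / 55, tolerance = 1e-4)
  set.seed(8)
  for (i in 1:200) {
    E <- runif(1, 0, 10); S <- runif(1, 0.01, 5); K <- runif(1, 0, 5)
    expect_equal(binding_fraction(E, S, K), oracle_binding_fraction(E, S, K),
                 tolerance = 1e-10)
  }
})

test_that("competition_fraction: reductions and monotonicity", {
  ## C_T = 0 reduces exactly to direct binding
  expect_identical(competition_fraction(1, 0.5, 0, 0.1, 7),
                   binding_fraction(1, 0.5, 0.1))
  ## inert competitor (K_C -> Inf) likewise
  expect_equal(competition_fraction(1, 0.5, 100, 0.1, 1e12),
               binding_fraction(1, 0.5, 0.1), tolerance = 1e-9)
  ## theta strictly decreasing in C_T
  ct <- 10^seq(-1, 4, length.out = 30)
  th <- competition_fraction(0.1, 0.1, ct, 0.002, 50)
  expect_true(all(diff(th) < 0))
  expect_true(all(th >= 0 & th <= 1))
  expect_error(competition_fraction(1, 1, 1, 1, 0), "K_C")
})

test_that("all closed forms agree with the equilibrium oracle on random draws", {
  set.seed(99)
  for (i in 1:100) {
    E <- runif(1, 0, 5); S <- runif(1, 0.05, 2); K <- runif(1, 1e-4, 2)
    C <- runif(1, 0, 100); KC <- runif(1, 0.1, 100)
    expect_equal(competition_fraction(E, S, C, K, KC),
                 oracle_binding_fraction(E, S, K * (1 + C / KC)),
                 tolerance = 1e-10)
  }
})

test_that("fit_isotherm recovers parameters (noiseless and noisy)", {
  ## titration, noiseless: exact recovery
  r <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.2, 1.6, 2, 3, 5)
  y <- titration_fraction(r, 0.1, 1, 0.9)
  fit <- fit_isotherm("titration", data.frame(x = r, fraction_bound = y))
  expect_equal(unname(fit$estimate), c(0.1, 1, 0.9), tolerance = 1e-6)
  ## direct binding, noiseless
  E <- 10^seq(-3.1, -0.1, length.out = 10)
  yd <- binding_fraction(E, 0.1, 0.005)
  fd <- fit_isotherm("direct", data.frame(x = E, fraction_bound = yd),
                     fixed = list(S_T = 0.1))
  expect_equal(unname(fd$estimate["K_D"]), 0.005, tolerance = 1e-6)
  ## competition at 2% noise over the printed competitor span
  set.seed(5)
  ct <- 10^seq(log10(0.5), 4, length.out = 12)
  th <- competition_fraction(0.1, 0.1, ct, 0.002, 50) *
    (1 + rnorm(12, 0, 0.02))
  fc <- fit_isotherm("competition", data.frame(x = ct, fraction_bound = th),
                     fixed = list(E_T = 0.1, S_T = 0.1, K_D = 0.002))
  expect_lt(abs(fc$estimate[["K_C"]] - 50) / 50, 0.15)
  ## fold-change reporting is a plain ratio of fitted constants
  fc2 <- fit_isotherm("competition",
                      data.frame(x = ct, fraction_bound =
                        competition_fraction(0.1, 0.1, ct, 0.002, 5500)),
                      fixed = list(E_T = 0.1, S_T = 0.1, K_D = 0.002))
  expect_equal(unname(fc2$estimate / fc$estimate), 110, tolerance = 0.2)
})

test_that("fit_isotherm validates its contract", {
  expect_error(fit_isotherm("direct", data.frame(x = 1, fraction_bound = 1)),
               "S_T")
  expect_error(fit_isotherm("competition",
                            data.frame(x = 1, fraction_bound = 1),
                            fixed = list(E_T = 1)), "S_T")
})
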