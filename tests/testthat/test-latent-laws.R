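catalog_laws <- function(theta0 = 1) {
  list(
    gamma = frailty_law("gamma", theta0),
    invgauss = frailty_law("invgauss", theta0),
    cpois = frailty_law("cpois", theta0),
    bhn = fix_bhn_harm(),
    degenerate = law_degenerate(1)
  )
}

test_that("Laplace transforms hit closed-form and limiting values", {
  for (law in catalog_laws()) {
    expect_equal(laplace(law, 0), 1, tolerance = 1e-14)
    expect_equal(laplace_deriv(law, 0), -law$mean, tolerance = 1e-12)
    expect_equal(survivor_mean(law, 0), law$mean, tolerance = 1e-12)
  }
  g <- fix_gamma1()
  expect_equal(laplace(g, 1), 0.5)
  expect_equal(laplace_deriv(g, 1), -0.25)
  expect_equal(survivor_mean(g, 1), 0.5)
  expect_equal(survivor_mean(law_invgauss(1, 1), 4), 1 / 3, tolerance = 1e-12)
  # compound Poisson: the transform tends to the nonsusceptible mass e^-rate
  cp <- law_cpois(3, 1 / 2, 2 / 3)
  expect_equal(laplace(cp, 1e15), exp(-3), tolerance = 1e-6)
  expect_equal(laplace_deriv(law_degenerate(1), 2), -exp(-2))
  expect_error(laplace(g, -1), "nonnegative")
  expect_error(survivor_mean(g, NaN), "finite")
})

test_that("gamma and inverse-Gaussian transforms match quadrature oracles", {
  cases <- list(
    list(law = law_gamma(0.5, 2), dens = function(u) dens_gamma(u, 0.5, 2)),
    list(law = law_gamma(2, 0.7), dens = function(u) dens_gamma(u, 2, 0.7)),
    list(law = law_invgauss(1, 1), dens = function(u) dens_invgauss(u, 1, 1)),
    list(law = law_invgauss(1, 2), dens = function(u) dens_invgauss(u, 1, 2))
  )
  for (cs in cases) {
    for (c in c(0.01, 0.1, 1, 10, 100)) {
      expect_equal(laplace(cs$law, c), oracle_laplace(cs$dens, c),
                   tolerance = 1e-6)
      expect_equal(survivor_mean(cs$law, c), oracle_survivor_mean(cs$dens, c),
                   tolerance = 1e-6)
    }
  }
})

test_that("laplace_deriv agrees with central finite differences", {
  for (law in catalog_laws(theta0 = 2)) {
    for (c in c(0.1, 1, 5)) {
      h <- 1e-5 * max(1, c)
      fd <- (laplace(law, c + h) - laplace(law, c - h)) / (2 * h)
      expect_equal(laplace_deriv(law, c), fd, tolerance = 1e-6)
    }
  }
})

test_that("L is one at zero, nonincreasing and convex on a grid", {
  cs <- seq(0, 20, length.out = 201)
  for (law in catalog_laws()) {
    lv <- laplace(law, cs)
    expect_equal(lv[1], 1)
    expect_true(all(diff(lv) <= 1e-14))
    expect_true(all(diff(diff(lv)) >= -1e-10))
  }
})

test_that("survivor-conditional mean declines monotonically with selection", {
  cs <- exp(seq(log(1e-3), log(1e3), length.out = 300))
  for (law in catalog_laws(theta0 = 0.5)) {
    sm <- survivor_mean(law, cs)
    expect_true(all(diff(sm) <= 1e-12))
    expect_true(all(sm <= law$mean + 1e-12))
  }
  # log-space evaluation survives extreme cumulative hazards
  deep <- survivor_mean(frailty_law("cpois", 1), 1e12)
  expect_true(is.finite(deep) && deep >= 0)
  expect_true(is.finite(survivor_mean(fix_bhn_benefit(), 1e12)))
})

test_that("analytic moments match the stated parameterizations", {
  for (th in c(0.5, 1, 2)) {
    for (fam in c("gamma", "invgauss", "cpois")) {
      m <- law_moments(frailty_law(fam, th))
      expect_equal(m$mean, 1, tolerance = 1e-12)
      expect_equal(m$variance, th, tolerance = 1e-12)
    }
  }
  # three-point law, direct sum (the rounded harm component of the catalog)
  m <- law_moments(fix_bhn_benefit())
  expect_equal(m$mean, 0.9 * 0.1 + 0.03 * 6 + 0.07)   # 0.34
  expect_equal(m$variance, 0.9 * 0.01 + 0.03 * 36 + 0.07 - 0.34^2)  # 1.0434
  # compound Poisson against Monte Carlo
  cp <- law_cpois(3, 1 / 2, 2 / 3)
  x <- law_sample(cp, 2e5, seed = 11)
  expect_lt(abs(mean(x) - 1), 4 * sd(x) / sqrt(length(x)))
})

test_that("samplers reproduce their moments, atoms and seeds", {
  n <- 1e5
  for (law in catalog_laws(theta0 = 1)[c("gamma", "invgauss", "cpois", "bhn")]) {
    x <- law_sample(law, n, seed = 42)
    expect_true(all(x >= 0))
    expect_lt(abs(mean(x) - law$mean), 4 * sqrt(law$variance / n))
    expect_identical(x, law_sample(law, n, seed = 42))
  }
  expect_identical(law_sample(law_degenerate(1), 5), rep(1, 5))
  # nonsusceptible fraction of the compound Poisson law
  z <- mean(law_sample(law_cpois(3, 1 / 2, 2 / 3), n, seed = 7) == 0)
  p0 <- exp(-3)
  expect_lt(abs(z - p0), 4 * sqrt(p0 * (1 - p0) / n))
  expect_error(law_sample(fix_gamma1(), 0), "positive count")
})

test_that("sampler and transform are mutually consistent", {
  n <- 1e5
  for (law in catalog_laws(theta0 = 1)[c("gamma", "invgauss", "cpois")]) {
    x <- law_sample(law, n, seed = 3)
    for (c in c(0.5, 2)) {
      e <- exp(-c * x)
      expect_lt(abs(mean(e) - laplace(law, c)), 4 * sd(e) / sqrt(n))
    }
  }
})

test_that("quantile functions invert the distribution functions", {
  p <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  ig <- law_invgauss(1, 2)
  q <- law_quantile(ig, p)
  emp <- law_sample(ig, 2e5, seed = 5)
  expect_equal(vapply(q, function(x) mean(emp <= x), numeric(1)), p,
               tolerance = 0.01)
  cp <- law_cpois(3, 1 / 2, 2 / 3)
  expect_identical(law_quantile(cp, c(0.01, exp(-3))), c(0, 0))  # atom at zero
  qc <- law_quantile(cp, 0.9)
  expect_equal(mean(law_sample(cp, 2e5, seed = 6) <= qc), 0.9, tolerance = 0.01)
  b <- fix_bhn_benefit()
  expect_identical(law_quantile(b, c(0.5, 0.95, 0.999)), c(0.1, 1, 6))
})

test_that("the BHN moment solver matches its closed form and round-trips", {
  # closed-form oracle computed directly in the test
  oracle <- function(p1, mu1, m, v) {
    m1 <- m - 1 - p1 * (mu1 - 1)
    m2 <- v + m^2 - 1 - p1 * (mu1^2 - 1)
    mu2 <- m2 / m1 - 1
    list(p2 = m1 / (mu2 - 1), mu2 = mu2)
  }
  for (cs in list(list(0.9, 0.1, 1 / 3, 1), list(0.05, 0.5, 3, 1),
                  list(0.3, 0.4, 1.2, 0.8))) {
    sol <- solve_bhn_parameters(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    ora <- oracle(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(sol$p2, ora$p2, tolerance = 1e-12)
    expect_equal(sol$mu2, ora$mu2, tolerance = 1e-12)
    m <- law_moments(law_bhn(cs[[1]], cs[[2]], sol$p2, sol$mu2))
    expect_equal(m$mean, cs[[3]], tolerance = 1e-10)
    expect_equal(m$variance, cs[[4]], tolerance = 1e-10)
  }
  expect_equal(solve_bhn_parameters(0.9, 0.1, 1 / 3, 1)$p2, 0.0287,
               tolerance = 1e-2)
  expect_equal(solve_bhn_parameters(0.05, 0.5, 3, 1)$mu2, 3.462963,
               tolerance = 1e-6)
  # all mass at mu <= 1: degenerate neutral harm component
  expect_equal(solve_bhn_parameters(1, 1, 1, 0), list(p2 = 0, mu2 = 1))
  expect_error(solve_bhn_parameters(0.9, 0.1, 0.15, 1), "Infeasible")
  expect_no_error(solve_bhn_parameters(0.05, 0.5, 3, 100))
  expect_error(solve_bhn_parameters(0.5, 1, 1.2, 0.01), "mu2|p2")
})
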