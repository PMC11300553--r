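test_that("the Gaussian-copula Kendall tau mapping is exact", {
  rhos <- c(-1, sin(-pi / 4), 0, sin(pi / 4), 1)
  expect_equal(kendall_tau_from_rho(rhos), c(-1, -1 / 2, 0, 1 / 2, 1))
  taus <- c(-1, -0.5, 0, 0.5, 1)
  expect_equal(kendall_tau_from_rho(rho_from_tau(taus)), taus,
               tolerance = 1e-12)
  expect_error(kendall_tau_from_rho(1.2), "\\[-1, 1\\]")
  expect_error(dep_gaussian(rho = 0.1, tau = 0.1), "exactly one")
})

test_that("copula sampling preserves marginals and the target concordance", {
  g <- law_gamma(2, 0.5)
  b <- fix_bhn_harm()
  n <- 2e4
  for (dep in list(dep_independent(), dep_gaussian(tau = 0.5),
                   dep_gaussian(rho = -0.6))) {
    uu <- sample_joint(g, b, dep, n = n, seed = 9)
    expect_lt(abs(mean(uu$u0) - 1), 4 * sqrt(g$variance / n))
    expect_lt(abs(mean(uu$u1) - b$mean), 4 * sqrt(b$variance / n))
    expect_true(all(uu$u1 %in% c(0.5, 3.5, 1)))
  }
  # continuous margins at tau = 1/2: empirical tau approaches the copula tau
  uu <- sample_joint(g, law_gamma(9, 1 / 3), dep_gaussian(tau = 0.5),
                     n = 3000, seed = 2)
  expect_lt(abs(stats::cor(uu$u0, uu$u1, method = "kendall") - 0.5), 0.05)
  # comonotone coupling of identical laws reproduces the same values
  same <- sample_joint(g, g, dep_gaussian(rho = 1), n = 1000, seed = 1)
  expect_equal(same$u0, same$u1, tolerance = 1e-9)
  # antithetic coupling is perfectly discordant for continuous margins
  anti <- sample_joint(g, law_gamma(9, 1 / 3), dep_gaussian(rho = -1),
                       n = 2000, seed = 3)
  expect_equal(stats::cor(anti$u0, anti$u1, method = "kendall"), -1)
  # independence: near-zero correlation
  ind <- sample_joint(g, g, dep_independent(), n = n, seed = 5)
  expect_lt(abs(stats::cor(ind$u0, ind$u1)), 4 / sqrt(n))
})

test_that("importance-weighted survivor expectations match the mixture oracle", {
  uu <- sample_joint(law_gamma(1, 1), fix_bhn_harm(), dep_independent(),
                     n = 1e5, seed = 21)
  # no selection at cumulative hazard zero
  ce0 <- conditional_expectation_weighted(function(u0, u1) u0 * u1, uu, 0)
  expect_equal(ce0$estimate, mean(uu$u0 * uu$u1), tolerance = 1e-12)
  # degenerate latents: the weighted mean is the plain function value
  dd <- tibble::tibble(u0 = rep(2, 10), u1 = rep(0.5, 10))
  expect_equal(conditional_expectation_weighted(
    function(u0, u1) u0 + u1, dd, 3)$estimate, 2.5)
  # analytic oracle from the mixture Laplace transform
  sc <- scenario(frailty = law_gamma(1, 1), modifier = fix_bhn_harm())
  for (L in c(0.5, 2)) {
    t <- (60 * L)^(1 / 3)
    num <- conditional_expectation_weighted(function(u0, u1) u0 * u1, uu, L,
                                            arm = 1)
    den <- conditional_expectation_weighted(function(u0, u1) u0, uu, L,
                                            arm = 0)
    est <- num$estimate / den$estimate
    an <- smchr_mixture(sc, t)
    se <- est * sqrt((num$se / num$estimate)^2 + (den$se / den$estimate)^2)
    expect_lt(abs(est - an), 4 * se)
  }
})

test_that("Monte Carlo SMCHR curves agree with the analytic engine", {
  ts <- seq(0, 8, length.out = 17)
  for (fam in c("gamma", "invgauss", "cpois")) {
    sc <- scenario(frailty = frailty_law(fam, 1), modifier = fix_bhn_harm())
    an <- smchr_at(sc, ts)
    mc <- smchr_mc(sc, times = ts, n = 5e4, seed = 13)
    expect_true(all(abs(mc$smchr - an) < 4 * mc$se + 1e-12))
  }
  # a tau = 0 Gaussian copula recovers the independent curve
  sc0 <- scenario(frailty = frailty_law("gamma", 1),
                  modifier = fix_bhn_harm(),
                  dependence = dep_gaussian(tau = 0))
  mc0 <- smchr_mc(sc0, times = ts, n = 5e4, seed = 14)
  an0 <- smchr_at(scenario(frailty = frailty_law("gamma", 1),
                           modifier = fix_bhn_harm()), ts)
  expect_true(all(abs(mc0$smchr - an0) < 4 * mc0$se + 1e-12))
  # zero-variance latents: flat curve at the effect
  flat <- smchr_mc(scenario(effect = 2), times = ts, n = 1e3, seed = 1)
  expect_equal(unique(flat$smchr), 2)
})

test_that("simulated potential outcomes obey the survival identity", {
  # with unit latents the inverse-transform time is (60 log 2)^{1/3} at median
  po1 <- sample_potential_outcomes(scenario(), n = 4e4, seed = 8)
  expect_equal(stats::median(po1$t0), (60 * log(2))^(1 / 3), tolerance = 0.01)
  expect_identical(po1$t0, po1$t1)  # no effect: rank-preserving coupling
  # P(T0 > t) = L(Lambda0(t)), written here in its gamma closed form
  sc <- scenario(frailty = frailty_law("gamma", 1))
  po <- sample_potential_outcomes(sc, n = 1e5, seed = 15)
  for (t in c(2, 4, 6)) {
    p <- (1 + t^3 / 60)^(-1)
    expect_lt(abs(mean(po$t0 > t) - p), 4 * sqrt(p * (1 - p) / 1e5))
  }
  # Kolmogorov-Smirnov distance against the marginal survival function
  cdf <- function(t) 1 - (1 + t^3 / 60)^(-1)
  ks <- suppressWarnings(stats::ks.test(po$t0, cdf))
  expect_gt(ks$p.value, 0.01)
  # nonsusceptible individuals never fail
  pocp <- sample_potential_outcomes(
    scenario(frailty = frailty_law("cpois", 1)), n = 2e4, seed = 16)
  expect_true(all(is.infinite(pocp$t0[pocp$u0 == 0])))
  expect_gt(mean(pocp$u0 == 0), 0)
})

test_that("randomization holds at baseline and breaks among survivors", {
  sc <- scenario(frailty = frailty_law("gamma", 1), effect = 3)
  n <- 1e5
  d <- sample_rct(sc, n = n, p_treat = 0.5, cens = censoring_scheme(10),
                  seed = 31, keep_latent = TRUE)
  expect_identical(d, sample_rct(sc, n = n, p_treat = 0.5,
                                 cens = censoring_scheme(10), seed = 31,
                                 keep_latent = TRUE))
  expect_lt(abs(mean(d$arm) - 0.5), 4 * sqrt(0.25 / n))
  # at baseline the arms are exchangeable in frailty
  z0 <- abs(mean(d$u0[d$arm == 1]) - mean(d$u0[d$arm == 0])) /
    sqrt(stats::var(d$u0) * (1 / sum(d$arm) + 1 / sum(1 - d$arm)))
  expect_lt(z0, 4)
  # conditioning on survival opens the collider: exposed survivors are
  # systematically less frail
  surv <- d$time > 4 | (d$status == 0 & d$time >= 4)
  s1 <- d$u0[surv & d$arm == 1]; s0 <- d$u0[surv & d$arm == 0]
  zt <- (mean(s0) - mean(s1)) /
    sqrt(stats::var(s1) / length(s1) + stats::var(s0) / length(s0))
  expect_gt(zt, 4)
  # uncensored design: every subject fails
  full <- sample_rct(sc, n = 500, seed = 2)
  expect_true(all(full$status == 1))
  # never-failing subjects demand a finite follow-up
  expect_error(sample_rct(scenario(frailty = frailty_law("cpois", 1)),
                          n = 2000, seed = 3), "finite")
  expect_no_error(sample_rct(scenario(frailty = frailty_law("cpois", 1)),
                             n = 2000, cens = censoring_scheme(follow_up = 8),
                             seed = 3))
})
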