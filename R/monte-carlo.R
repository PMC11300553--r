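#' Dependence between frailty and effect modifier
#'
#' Couples the marginal laws of \eqn{U_0} and \eqn{U_1} through a copula.
#' `dep_independent()` leaves them independent. `dep_gaussian()` uses a
#' Gaussian copula \eqn{C(x, y) = \Phi_{2,\rho}(\Phi^{-1}(x), \Phi^{-1}(y))}
#' parameterized by the correlation `rho`, or equivalently by Kendall's
#' `tau` through \eqn{\tau = (2/\pi)\arcsin\rho}. The extremes
#' \eqn{\rho = \pm 1} are the comonotone / comonotone-reversed couplings.
#'
#' @param rho Gaussian-copula correlation in `[-1, 1]`.
#' @param tau Alternatively, Kendall's tau in `[-1, 1]`.
#' @return An object of class `dependence_spec` with fields `family`, `rho`,
#'   `kendall_tau`.
#' @examples
#' dep_gaussian(tau = 0.5)  # rho = sin(pi/4)
#' @export
dep_independent <- function() {
  structure(list(family = "independent", rho = NULL, kendall_tau = 0),
            class = "dependence_spec")
}

#' @rdname dep_independent
#' @export
dep_gaussian <- function(rho = NULL, tau = NULL) {
  if (is.null(rho) == is.null(tau)) {
    stop("Supply exactly one of `rho` or `tau`.", call. = FALSE)
  }
  if (is.null(rho)) rho <- rho_from_tau(tau)
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1].", call. = FALSE)
  structure(list(family = "gaussian", rho = rho,
                 kendall_tau = kendall_tau_from_rho(rho)),
            class = "dependence_spec")
}

dep_digest <- function(dep) {
  if (dep$family == "independent") "independent"
  else sprintf("gaussian(rho=%.6g, tau=%.6g)", dep$rho, dep$kendall_tau)
}

#' Gaussian-copula Kendall's tau
#'
#' The population Kendall's tau of a Gaussian copula with correlation `rho`
#' is \eqn{\tau = (2/\pi)\arcsin(\rho)}; `rho_from_tau()` is the inverse
#' \eqn{\rho = \sin(\pi\tau/2)}. With a discrete margin the tie-corrected
#' empirical tau-b differs slightly; these functions report the copula-level
#' value.
#'
#' @param rho,tau Values in `[-1, 1]`.
#' @return Numeric vector.
#' @examples
#' kendall_tau_from_rho(sin(pi / 4))  # 0.5
#' @export
kendall_tau_from_rho <- function(rho) {
  if (any(abs(rho) > 1)) stop("`rho` must lie in [-1, 1].", call. = FALSE)
  (2 / pi) * asin(rho)
}

#' @rdname kendall_tau_from_rho
#' @export
rho_from_tau <- function(tau) {
  if (any(abs(tau) > 1)) stop("`tau` must lie in [-1, 1].", call. = FALSE)
  sin(pi * tau / 2)
}

#' Sample a coupled pair of latent laws
#'
#' Draws `n` pairs \eqn{(U_0, U_1)} whose marginals follow the given laws
#' and whose joint law follows the dependence specification. For the
#' Gaussian copula with \eqn{|\rho| < 1} a bivariate normal pair is pushed
#' through the marginal quantile functions; \eqn{\rho = 1} uses one shared
#' uniform and \eqn{\rho = -1} an antithetic pair (the corresponding
#' comonotone limits).
#'
#' @param u0_law,u1_law Marginal [latent_law]s.
#' @param dep A `dependence_spec`.
#' @param n Number of pairs.
#' @param seed Optional integer seed.
#' @return A tibble with columns `u0`, `u1`.
#' @export
sample_joint <- function(u0_law, u1_law, dep = dep_independent(), n,
                         seed = NULL) {
  stopifnot(inherits(u0_law, "latent_law"), inherits(u1_law, "latent_law"),
            inherits(dep, "dependence_spec"))
  if (n < 1) stop("`n` must be a positive count.", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    if (dep$family == "independent") {
      tibble::tibble(u0 = sample_impl(u0_law, n), u1 = sample_impl(u1_law, n))
    } else if (abs(dep$rho) == 1) {
      p <- stats::runif(n)
      q <- if (dep$rho > 0) p else 1 - p
      tibble::tibble(u0 = law_quantile(u0_law, p), u1 = law_quantile(u1_law, q))
    } else {
      z0 <- stats::rnorm(n)
      z1 <- dep$rho * z0 + sqrt(1 - dep$rho^2) * stats::rnorm(n)
      tibble::tibble(u0 = law_quantile(u0_law, stats::pnorm(z0)),
                     u1 = law_quantile(u1_law, stats::pnorm(z1)))
    }
  })
}

#' Survivor-conditional expectation by importance weighting
#'
#' Computes \eqn{E[g(U_0, U_1) \mid T^a \ge t]} from a latent sample using
#' the survival-probability weights \eqn{w = \exp(-u_0 u_1 \Lambda)} in the
#' exposed world (`arm = 1`) or \eqn{w = \exp(-u_0 \Lambda)} in the
#' unexposed world (`arm = 0`), where \eqn{\Lambda} is the cumulative hazard
#' per unit latent multiplier. All draws are reused (no rejection), and a
#' delta-method standard error of the weighted mean is returned.
#'
#' @param g Function of `(u0, u1)` returning a numeric vector.
#' @param samples Tibble/data frame with columns `u0`, `u1` (see
#'   [sample_joint()]).
#' @param cumhaz Nonnegative cumulative hazard \eqn{\Lambda}.
#' @param arm Exposure world, 0 or 1.
#' @return A list with `estimate` and `se`.
#' @export
conditional_expectation_weighted <- function(g, samples, cumhaz, arm = 1) {
  assert_nonneg(cumhaz, "cumhaz")
  u0 <- samples$u0; u1 <- samples$u1
  logw <- if (arm == 1) -u0 * u1 * cumhaz else -u0 * cumhaz
  m <- max(logw)
  if (!is.finite(m)) {
    stop("All survival weights underflowed; reduce the cumulative-hazard ",
         "grid or use the analytic log-space routes.", call. = FALSE)
  }
  w <- exp(logw - m)
  sw <- sum(w)
  gv <- g(u0, u1)
  est <- sum(w * gv) / sw
  se <- sqrt(sum((w / sw)^2 * (gv - est)^2))
  list(estimate = est, se = se)
}

#' Monte Carlo SMCHR curve
#'
#' Estimates the SMCHR over a time grid from a single coupled latent sample
#' (reused across the grid for a smooth curve) via importance-weighted
#' survivor expectations:
#' \eqn{\mathrm{SMCHR}(t) = f_1(t,1)\,E_w[U_0U_1]/E_w[U_0]} with exposed-
#' and unexposed-world survival weights. This is the only route for
#' copula-dependent latents or a continuous modifier joint with frailty.
#'
#' @inheritParams smchr_curve
#' @param n Latent sample size (default `1e5`).
#' @return An `hr_curve` tibble with columns `time`, `chr`, `smchr`, `se`
#'   (delta-method standard error of the SMCHR).
#' @export
smchr_mc <- function(model, times = seq(0, 10, length.out = 501), n = 1e5,
                     seed = NULL) {
  stopifnot(inherits(model, "scenario"))
  assert_nonneg(times, "times")
  uu <- sample_joint(model$frailty, model$modifier, model$dependence,
                     n = n, seed = seed)
  f <- effect_fn(model)
  L1 <- cumulative_hazard(model, times, a = 1)
  L0 <- cumulative_hazard(model, times, a = 0)
  f1v <- f(times, 1)
  est <- se <- numeric(length(times))
  for (i in seq_along(times)) {
    num <- conditional_expectation_weighted(function(u0, u1) u0 * u1, uu,
                                            L1[i], arm = 1)
    den <- conditional_expectation_weighted(function(u0, u1) u0, uu,
                                            L0[i], arm = 0)
    est[i] <- f1v[i] * num$estimate / den$estimate
    se[i] <- est[i] * sqrt((num$se / num$estimate)^2 + (den$se / den$estimate)^2)
  }
  chr <- f1v * mean(uu$u0 * uu$u1) / model$frailty$mean
  new_hr_curve(tibble::tibble(time = times, chr = chr, smchr = est, se = se),
               method = "monte-carlo", route = "importance-weighted",
               digest = scenario_digest(model))
}

#' Simulate potential outcomes from the structural model
#'
#' Draws latent pairs and, using a single shared uniform noise per
#' individual (rank-preserving cross-world coupling), inverts the survival
#' function in each world:
#' \eqn{T^a = \Lambda_a^{-1}\{-\log N_T / (u_0 u_1^a)\}} with
#' \eqn{\Lambda_a(t) = \int_0^t \lambda_0(s) f_1(s, a)\,ds} and
#' \eqn{N_T \sim \mathrm{Unif}(0,1)}. Individuals with \eqn{u_0 = 0}
#' (nonsusceptible, possible under compound Poisson frailty) never fail:
#' \eqn{T^a = \infty}.
#'
#' @inheritParams smchr_mc
#' @return A tibble with columns `u0`, `u1`, `t0`, `t1`.
#' @export
sample_potential_outcomes <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "scenario"))
  with_seed(seed, {
    uu <- sample_joint(model$frailty, model$modifier, model$dependence, n = n)
    e <- -log(stats::runif(n))
    tibble::tibble(
      u0 = uu$u0, u1 = uu$u1,
      t0 = invert_world(model, e, uu$u0, a = 0),
      t1 = invert_world(model, e, uu$u0 * uu$u1, a = 1)
    )
  })
}

# Solve Lambda_a(t) = e / m for t, where m is the individual's latent
# multiplier in world a; closed form when the effect is time-invariant.
invert_world <- function(model, e, m, a) {
  out <- rep(Inf, length(e))
  pos <- m > 0
  target <- e[pos] / m[pos]
  if (a == 0 || effect_is_constant(model)) {
    f1 <- if (a == 0) 1 else model$effect
    out[pos] <- model$baseline$inverse(target / f1)
  } else {
    out[pos] <- vapply(target, function(x) {
      hi <- 1
      while (cumulative_hazard(model, hi, a = 1) < x) hi <- hi * 2
      stats::uniroot(function(t) cumulative_hazard(model, t, a = 1) - x,
                     lower = 0, upper = hi, tol = 1e-10)$root
    }, numeric(1))
  }
  out
}

#' Censoring scheme for a simulated trial
#'
#' Administrative censoring at the follow-up time `follow_up` plus an
#' independent exponential loss-to-follow-up time with rate `loss_rate`
#' (mean `1/loss_rate`); both independent of the latent variables and event
#' times, so the observed hazard ratio equals the SMCHR.
#'
#' @param follow_up Administrative end of follow-up (`> 0`, possibly `Inf`).
#' @param loss_rate Exponential loss-to-follow-up rate (`>= 0`).
#' @return An object of class `censoring_scheme`.
#' @export
censoring_scheme <- function(follow_up = Inf, loss_rate = 0) {
  stopifnot(follow_up > 0, loss_rate >= 0)
  structure(list(follow_up = follow_up, loss_rate = loss_rate),
            class = "censoring_scheme")
}

#' Simulate a randomized controlled trial
#'
#' Assigns exposure by an independent Bernoulli(`p_treat`) draw, takes the
#' consistent factual time \eqn{T = T^A} from [sample_potential_outcomes()],
#' and applies independent censoring. Never-failing subjects require a
#' finite follow-up or positive loss rate.
#'
#' @inheritParams smchr_mc
#' @param p_treat Randomization probability of exposure.
#' @param cens A [censoring_scheme].
#' @param keep_latent Keep the latent columns `u0`, `u1`, `t0`, `t1`
#'   (oracle output for tests).
#' @return A tibble with columns `id`, `arm`, `time`, `status`
#'   (1 = event, 0 = censored), plus latent columns when requested.
#' @export
sample_rct <- function(model, n, p_treat = 0.5, cens = censoring_scheme(),
                       seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(model, "scenario"), inherits(cens, "censoring_scheme"))
  assert_scalar_prob(p_treat, "p_treat")
  if (p_treat <= 0 || p_treat >= 1) {
    stop("`p_treat` must be strictly between 0 and 1.", call. = FALSE)
  }
  with_seed(seed, {
    po <- sample_potential_outcomes(model, n)
    arm <- stats::rbinom(n, 1, p_treat)
    tt <- ifelse(arm == 1, po$t1, po$t0)
    tc <- if (cens$loss_rate > 0) stats::rexp(n, cens$loss_rate) else rep(Inf, n)
    obs <- pmin(tt, tc, cens$follow_up)
    if (any(!is.finite(obs))) {
      stop("Some subjects have infinite observed time; supply a finite ",
           "follow-up or a positive loss-to-follow-up rate.", call. = FALSE)
    }
    out <- tibble::tibble(id = seq_len(n), arm = arm, time = obs,
                          status = as.integer(tt <= pmin(tc, cens$follow_up)))
    if (keep_latent) {
      out <- dplyr::bind_cols(out, po[c("u0", "u1", "t0", "t1")])
    }
    out
  })
}
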