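#' Latent frailty and effect-modifier laws
#'
#' A latent law is a nonnegative distribution used either as a frailty
#' (a multiplier of the baseline hazard, usually written \eqn{U_0}) or as an
#' effect modifier (a multiplier of the exposure effect on the hazard,
#' \eqn{U_1}). Each law exposes its Laplace transform
#' \eqn{\mathcal{L}(c) = E[\exp(-cU)]}, the derivative
#' \eqn{\mathcal{L}'(c) = -E[U \exp(-cU)]}, analytic moments, a quantile
#' function and a sampler. The survivor-conditional mean
#' \eqn{E[U \mid T \ge t] = -\mathcal{L}'(\Lambda)/\mathcal{L}(\Lambda)}
#' (at cumulative hazard \eqn{\Lambda}) is the quantity that drives the
#' built-in selection bias of hazard ratios.
#'
#' Families:
#' \describe{
#'   \item{`law_gamma(shape, scale)`}{Gamma, \eqn{\mathcal{L}(c) = (1+sc)^{-k}}.}
#'   \item{`law_invgauss(mean, shape)`}{Inverse Gaussian with mean \eqn{m} and
#'     shape \eqn{\lambda}; \eqn{\mathcal{L}(c) = \exp\{(\lambda/m)(1 -
#'     \sqrt{1 + 2m^2c/\lambda})\}}.}
#'   \item{`law_cpois(rate, shape, scale)`}{Compound Poisson: a Poisson(rate)
#'     number of independent Gamma(shape, scale) jumps, with an atom at zero
#'     of mass \eqn{e^{-\mathrm{rate}}} (the nonsusceptible fraction);
#'     \eqn{\mathcal{L}(c) = \exp\{-\mathrm{rate}\,(1-(1+sc)^{-k})\}}.}
#'   \item{`law_bhn(p1, mu1, p2, mu2)`}{Benefit-Harm-Neutral: three-point law
#'     with mass `p1` at `mu1 <= 1` (benefit), `p2` at `mu2 >= 1` (harm) and
#'     the rest at 1 (neutral).}
#'   \item{`law_degenerate(value)`}{Point mass, used to switch a latent source
#'     of heterogeneity off.}
#' }
#'
#' @param shape,scale,rate,mean,value Positive family parameters (see above).
#' @param p1,p2 Probabilities of the benefit and harm components; `p1 + p2 <= 1`.
#' @param mu1,mu2 Benefit (`<= 1`) and harm (`>= 1`) hazard multipliers.
#' @return An object of class `latent_law`.
#' @examples
#' u0 <- law_gamma(shape = 1, scale = 1)
#' laplace(u0, 1)           # 0.5
#' survivor_mean(u0, 1)     # 0.5: survivors at cumulative hazard 1 are less frail
#' @name latent_law
NULL

new_latent_law <- function(family, params, mean, variance) {
  structure(
    list(family = family, params = params, mean = mean, variance = variance),
    class = c(paste0("law_", family), "latent_law")
  )
}

#' @rdname latent_law
#' @export
law_gamma <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  new_latent_law("gamma", list(shape = shape, scale = scale),
                 mean = shape * scale, variance = shape * scale^2)
}

#' @rdname latent_law
#' @export
law_invgauss <- function(mean, shape) {
  stopifnot(mean > 0, shape > 0)
  new_latent_law("invgauss", list(mean = mean, shape = shape),
                 mean = mean, variance = mean^3 / shape)
}

#' @rdname latent_law
#' @export
law_cpois <- function(rate, shape, scale) {
  stopifnot(rate > 0, shape > 0, scale > 0)
  new_latent_law("cpois", list(rate = rate, shape = shape, scale = scale),
                 mean = rate * shape * scale,
                 variance = rate * shape * (shape + 1) * scale^2)
}

#' @rdname latent_law
#' @export
law_bhn <- function(p1, mu1, p2, mu2) {
  assert_scalar_prob(p1, "p1")
  assert_scalar_prob(p2, "p2")
  if (p1 + p2 > 1 + 1e-12) stop("`p1 + p2` must not exceed 1.", call. = FALSE)
  if (mu1 < 0 || mu1 > 1) stop("`mu1` must lie in [0, 1].", call. = FALSE)
  if (mu2 < 1) stop("`mu2` must be at least 1.", call. = FALSE)
  p0 <- max(0, 1 - p1 - p2)
  m <- p1 * mu1 + p2 * mu2 + p0
  v <- p1 * mu1^2 + p2 * mu2^2 + p0 - m^2
  new_latent_law("bhn",
                 list(p1 = p1, mu1 = mu1, p2 = p2, mu2 = mu2,
                      support = c(mu1, mu2, 1), weights = c(p1, p2, p0)),
                 mean = m, variance = v)
}

#' @rdname latent_law
#' @export
law_degenerate <- function(value = 1) {
  stopifnot(value >= 0)
  new_latent_law("degenerate", list(value = value), mean = value, variance = 0)
}

#' The paper-standard frailty and modifier parameterizations
#'
#' `frailty_law()` builds a frailty distribution with mean 1 and variance
#' `theta0`: gamma \eqn{\Gamma(\theta_0^{-1}, \theta_0)}, inverse Gaussian
#' \eqn{IG(1, \theta_0^{-1})}, or compound Poisson
#' \eqn{CPoi(3\theta_0^{-1}, 1/2, \tfrac{2}{3}\theta_0)}. `modifier_law()`
#' builds an effect-modifier distribution with mean `mean` and variance
#' `variance` using the analogous moment-matched parameterizations; for the
#' `"bhn"` family the benefit component `(p1, mu1)` is fixed and the harm
#' component `(p2, mu2)` is solved from the two moment equations (see
#' [solve_bhn_parameters()]).
#'
#' @param family Distribution family name.
#' @param theta0 Frailty variance (mean is fixed at 1).
#' @param mean,variance Target moments of the modifier.
#' @param p1,mu1 Fixed benefit component for the `"bhn"` family.
#' @return A `latent_law`.
#' @examples
#' law_moments(frailty_law("cpois", theta0 = 2))   # mean 1, variance 2
#' modifier_law("bhn", mean = 3, variance = 1, p1 = 0.05, mu1 = 0.5)
#' @export
frailty_law <- function(family = c("gamma", "invgauss", "cpois"), theta0) {
  family <- match.arg(family)
  stopifnot(theta0 > 0)
  switch(family,
    gamma    = law_gamma(shape = 1 / theta0, scale = theta0),
    invgauss = law_invgauss(mean = 1, shape = 1 / theta0),
    cpois    = law_cpois(rate = 3 / theta0, shape = 1 / 2, scale = 2 / 3 * theta0)
  )
}

#' @rdname frailty_law
#' @export
modifier_law <- function(family = c("gamma", "invgauss", "cpois", "bhn"),
                         mean, variance, p1 = NULL, mu1 = NULL) {
  family <- match.arg(family)
  stopifnot(mean > 0, variance >= 0)
  if (variance == 0) return(law_degenerate(mean))
  switch(family,
    gamma    = law_gamma(shape = mean^2 / variance, scale = variance / mean),
    invgauss = law_invgauss(mean = mean, shape = mean^3 / variance),
    cpois    = law_cpois(rate = 3 * mean^2 / variance, shape = 1 / 2,
                         scale = 2 * variance / (3 * mean)),
    bhn      = {
      if (is.null(p1) || is.null(mu1)) {
        stop("The \"bhn\" family needs the fixed benefit component `p1`, `mu1`.",
             call. = FALSE)
      }
      sol <- solve_bhn_parameters(p1, mu1, mean, variance)
      law_bhn(p1, mu1, sol$p2, sol$mu2)
    }
  )
}

#' Solve the BHN harm component from target moments
#'
#' Given the benefit component (`p1`, `mu1`) of a Benefit-Harm-Neutral law
#' and target mean and variance, returns the unique harm component
#' (`p2`, `mu2`) matching both moments. Writing
#' \eqn{m_1 = \mathrm{mean} - 1 - p_1(\mu_1 - 1)} and
#' \eqn{m_2 = \mathrm{var} + \mathrm{mean}^2 - 1 - p_1(\mu_1^2 - 1)}, the
#' solution is \eqn{\mu_2 = m_2/m_1 - 1} and \eqn{p_2 = m_1/(\mu_2 - 1)}.
#'
#' @param p1 Probability of the benefit component.
#' @param mu1 Benefit multiplier (`<= 1`).
#' @param mean,variance Target moments.
#' @return A list with elements `p2` and `mu2`.
#' @examples
#' solve_bhn_parameters(0.9, 0.1, 1 / 3, 1)  # ~ (0.0287, 5.99)
#' @export
solve_bhn_parameters <- function(p1, mu1, mean, variance) {
  assert_scalar_prob(p1, "p1")
  stopifnot(mu1 >= 0, mu1 <= 1, mean > 0, variance >= 0)
  m1 <- mean - 1 - p1 * (mu1 - 1)
  m2 <- variance + mean^2 - 1 - p1 * (mu1^2 - 1)
  if (abs(m1) < 1e-14 && abs(m2) < 1e-14) {
    # Remaining mass sits at 1: degenerate harm component.
    return(list(p2 = 0, mu2 = 1))
  }
  if (m1 <= 0) {
    stop("Infeasible BHN moment system: requires p2*(mu2 - 1) = ",
         signif(m1, 4), " <= 0, but mu2 >= 1 and p2 >= 0.", call. = FALSE)
  }
  mu2 <- m2 / m1 - 1
  if (mu2 < 1) {
    stop("Infeasible BHN moment system: solved mu2 = ", signif(mu2, 6),
         " violates mu2 >= 1.", call. = FALSE)
  }
  p2 <- m1 / (mu2 - 1)
  if (p2 < 0 || p2 > 1 - p1 + 1e-12) {
    stop("Infeasible BHN moment system: solved p2 = ", signif(p2, 6),
         " violates 0 <= p2 <= 1 - p1 = ", signif(1 - p1, 6), ".", call. = FALSE)
  }
  list(p2 = p2, mu2 = mu2)
}

# ---- Laplace transform machinery --------------------------------------------

#' Laplace transform of a latent law
#'
#' `laplace()` evaluates \eqn{\mathcal{L}(c) = E[\exp(-cU)]};
#' `laplace_deriv()` its derivative \eqn{\mathcal{L}'(c) = -E[U\exp(-cU)]};
#' `survivor_mean()` the survivor-conditional mean
#' \eqn{-\mathcal{L}'(c)/\mathcal{L}(c)}, i.e. the expected latent value among
#' individuals still at risk once the cumulative hazard accrued (per unit of
#' latent multiplier) equals `c`. All three are computed in log space, so very
#' large cumulative hazards (deep in the right tail, where the transform
#' underflows) remain usable; set `log = TRUE` to obtain the log-scale value.
#'
#' @param law A [latent_law].
#' @param c Nonnegative argument(s) of the transform; for `survivor_mean()`
#'   this is the accrued cumulative hazard \eqn{\int_0^t \lambda_0(s) f_1(s,a)\,ds}.
#' @param log Return the natural logarithm of the (absolute) value.
#' @return Numeric vector the length of `c`.
#' @export
laplace <- function(law, c, log = FALSE) {
  assert_nonneg(c, "c")
  lv <- log_laplace(law, c)
  if (log) lv else exp(lv)
}

#' @rdname laplace
#' @export
laplace_deriv <- function(law, c, log = FALSE) {
  assert_nonneg(c, "c")
  lv <- log_neg_laplace_deriv(law, c)
  if (log) lv else -exp(lv)
}

#' @rdname laplace
#' @export
survivor_mean <- function(law, c) {
  assert_nonneg(c, "cumulative hazard")
  exp(log_neg_laplace_deriv(law, c) - log_laplace(law, c))
}

# log L(c) and log(-L'(c)), the internal dispatch surface.
log_laplace <- function(law, c) UseMethod("log_laplace")
log_neg_laplace_deriv <- function(law, c) UseMethod("log_neg_laplace_deriv")

#' @export
log_laplace.law_gamma <- function(law, c) {
  with(law$params, -shape * log1p(scale * c))
}
#' @export
log_neg_laplace_deriv.law_gamma <- function(law, c) {
  with(law$params, log(shape * scale) - (shape + 1) * log1p(scale * c))
}

#' @export
log_laplace.law_invgauss <- function(law, c) {
  with(law$params, (shape / mean) * (1 - sqrt(1 + 2 * mean^2 * c / shape)))
}
#' @export
log_neg_laplace_deriv.law_invgauss <- function(law, c) {
  with(law$params,
       log_laplace.law_invgauss(law, c) + log(mean) -
         0.5 * log1p(2 * mean^2 * c / shape))
}

#' @export
log_laplace.law_cpois <- function(law, c) {
  with(law$params, -rate * (1 - exp(-shape * log1p(scale * c))))
}
#' @export
log_neg_laplace_deriv.law_cpois <- function(law, c) {
  with(law$params,
       log_laplace.law_cpois(law, c) + log(rate * shape * scale) -
         (shape + 1) * log1p(scale * c))
}

#' @export
log_laplace.law_bhn <- function(law, c) {
  mix_logsumexp(law$params$weights, law$params$support, c, weight_by_support = FALSE)
}
#' @export
log_neg_laplace_deriv.law_bhn <- function(law, c) {
  mix_logsumexp(law$params$weights, law$params$support, c, weight_by_support = TRUE)
}

# log sum_k w_k [u_k] exp(-u_k c), vectorized over c; components with zero
# effective weight are dropped so log(0) never enters the sum.
mix_logsumexp <- function(w, u, c, weight_by_support) {
  eff <- if (weight_by_support) w * u else w
  keep <- eff > 0
  if (!any(keep)) return(rep(-Inf, length(c)))
  lw <- log(eff[keep])
  vapply(c, function(ci) logsumexp(lw - u[keep] * ci), numeric(1))
}

#' @export
log_laplace.law_degenerate <- function(law, c) -law$params$value * c
#' @export
log_neg_laplace_deriv.law_degenerate <- function(law, c) {
  v <- law$params$value
  if (v == 0) rep(-Inf, length(c)) else log(v) - v * c
}

# ---- Moments, quantiles, sampling -------------------------------------------

#' Analytic moments of a latent law
#'
#' @param law A [latent_law].
#' @return A one-row tibble with columns `mean` and `variance`, equal to
#'   \eqn{-\mathcal{L}'(0)} and \eqn{\mathcal{L}''(0) - \mathcal{L}'(0)^2}.
#' @export
law_moments <- function(law) {
  stopifnot(inherits(law, "latent_law"))
  tibble::tibble(mean = law$mean, variance = law$variance)
}

#' Quantile function of a latent law
#'
#' Generalized inverse of the distribution function, used for copula
#' coupling. Closed-form for gamma, degenerate and BHN laws; monotone
#' bracketed inversion of the closed-form distribution function for inverse
#' Gaussian and compound Poisson (the latter has an atom at zero of mass
#' \eqn{e^{-\mathrm{rate}}}).
#'
#' @param law A [latent_law].
#' @param p Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
law_quantile <- function(law, p) UseMethod("law_quantile")

#' @export
law_quantile.law_gamma <- function(law, p) {
  stats::qgamma(p, shape = law$params$shape, scale = law$params$scale)
}

#' @export
law_quantile.law_degenerate <- function(law, p) {
  rep(law$params$value, length(p))
}

#' @export
law_quantile.law_bhn <- function(law, p) {
  ord <- order(law$params$support)
  u <- law$params$support[ord]
  cw <- cumsum(law$params$weights[ord])
  idx <- findInterval(p, cw, left.open = TRUE) + 1L
  idx <- pmin(idx, length(u))
  u[idx]
}

# Inverse-Gaussian distribution function (closed form).
pinvgauss_ <- function(q, mean, shape) {
  out <- numeric(length(q))
  pos <- q > 0
  x <- q[pos]
  a <- sqrt(shape / x)
  out[pos] <- stats::pnorm(a * (x / mean - 1)) +
    exp(2 * shape / mean + stats::pnorm(-a * (x / mean + 1), log.p = TRUE))
  pmin(pmax(out, 0), 1)
}

#' @export
law_quantile.law_invgauss <- function(law, p) {
  m <- law$params$mean; s <- law$params$shape
  invert_cdf(p, function(q) pinvgauss_(q, m, s),
             lower_start = m * 1e-8, upper_start = m * 8,
             atom0 = 0)
}

# Compound-Poisson distribution function: atom exp(-rate) at 0 plus a
# Poisson mixture of Gamma(n*shape, scale) components.
pcpois_ <- function(q, rate, shape, scale) {
  nmax <- max(10, stats::qpois(1 - 1e-13, rate))
  n <- seq_len(nmax)
  lw <- stats::dpois(n, rate, log = TRUE)
  vapply(q, function(x) {
    if (x < 0) return(0)
    exp(-rate) + sum(exp(lw) * stats::pgamma(x, shape = n * shape, scale = scale))
  }, numeric(1))
}

#' @export
law_quantile.law_cpois <- function(law, p) {
  pr <- law$params
  invert_cdf(p, function(q) pcpois_(q, pr$rate, pr$shape, pr$scale),
             lower_start = pr$scale * 1e-10,
             upper_start = pr$rate * pr$shape * pr$scale * 8 + pr$scale,
             atom0 = exp(-pr$rate))
}

# Monotone inversion of a continuous (above an optional atom at zero) CDF.
invert_cdf <- function(p, cdf, lower_start, upper_start, atom0 = 0) {
  stopifnot(all(p >= 0 & p <= 1))
  vapply(p, function(pi) {
    if (pi <= atom0) return(0)
    if (pi >= 1) return(Inf)
    lo <- lower_start; hi <- upper_start
    while (cdf(hi) < pi) hi <- hi * 4
    while (cdf(lo) > pi) lo <- lo / 4
    stats::uniroot(function(q) cdf(q) - pi, lower = lo, upper = hi,
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Draw i.i.d. samples from a latent law
#'
#' Gamma, BHN and degenerate laws sample directly; inverse Gaussian uses the
#' Michael-Schucany-Haas two-root transformation; compound Poisson draws a
#' Poisson number of gamma jumps (summing to a single gamma draw with
#' proportional shape), producing exact zeros for the nonsusceptible fraction.
#'
#' @param law A [latent_law].
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed; the caller's RNG stream is restored.
#' @return Numeric vector of `n` nonnegative draws.
#' @export
law_sample <- function(law, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count.", call. = FALSE)
  }
  n <- as.integer(n)
  with_seed(seed, sample_impl(law, n))
}

sample_impl <- function(law, n) UseMethod("sample_impl")

#' @export
sample_impl.law_gamma <- function(law, n) {
  stats::rgamma(n, shape = law$params$shape, scale = law$params$scale)
}

#' @export
sample_impl.law_invgauss <- function(law, n) {
  m <- law$params$mean; l <- law$params$shape
  y <- stats::rnorm(n)^2
  x1 <- m + m^2 * y / (2 * l) - (m / (2 * l)) * sqrt(4 * m * l * y + m^2 * y^2)
  take_first <- stats::runif(n) <= m / (m + x1)
  ifelse(take_first, x1, m^2 / x1)
}

#' @export
sample_impl.law_cpois <- function(law, n) {
  pr <- law$params
  k <- stats::rpois(n, pr$rate)
  out <- numeric(n)
  pos <- k > 0
  out[pos] <- stats::rgamma(sum(pos), shape = k[pos] * pr$shape, scale = pr$scale)
  out
}

#' @export
sample_impl.law_bhn <- function(law, n) {
  sample(law$params$support, n, replace = TRUE, prob = law$params$weights)
}

#' @export
sample_impl.law_degenerate <- function(law, n) rep(law$params$value, n)

#' @export
print.latent_law <- function(x, ...) {
  pars <- x$params[!vapply(x$params, function(p) length(p) > 1, logical(1))]
  cat(sprintf("<latent_law: %s(%s)>  mean %.4g, variance %.4g\n",
              x$family,
              paste(sprintf("%s = %.4g", names(pars), unlist(pars)), collapse = ", "),
              x$mean, x$variance))
  invisible(x)
}
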