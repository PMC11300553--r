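#' Causal hazard ratio at a time point
#'
#' The causal hazard ratio (CHR) contrasts the population-expected hazard in
#' the everyone-exposed world with the everyone-unexposed world:
#' \eqn{E[\lambda_i^1(t)] / E[\lambda_i^0(t)]}. Under the multiplicative
#' structural model this equals
#' \eqn{f_1(t,1)\,E[U_0 U_1]/E[U_0]}, i.e.
#' \eqn{f_1(t,1)\,(E[U_1] + \mathrm{cov}(U_0, U_1))} when \eqn{E[U_0]=1}.
#' For a Gaussian-copula dependence the covariance has no closed form and is
#' estimated by Monte Carlo; the standard error is attached as attribute
#' `"se"` (0 for closed-form cases).
#'
#' @param model A [scenario].
#' @param t Time(s) at which to evaluate.
#' @param n_mc Monte Carlo sample size for the covariance under dependence.
#' @param seed Optional seed for the covariance Monte Carlo.
#' @return Positive numeric vector of CHR values (attribute `"se"` holds the
#'   Monte Carlo standard error of the latent-product mean).
#' @export
chr_at <- function(model, t, n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(model, "scenario"))
  assert_nonneg(t, "t")
  f <- effect_fn(model)
  pm <- latent_product_mean(model, n_mc = n_mc, seed = seed)
  out <- f(t, 1) * pm$value / model$frailty$mean
  attr(out, "se") <- pm$se / model$frailty$mean
  out
}

# E[U0 * U1] with a standard error when it must be estimated.
latent_product_mean <- function(model, n_mc = 1e5, seed = NULL) {
  m0 <- model$frailty$mean
  m1 <- model$modifier$mean
  indep <- model$dependence$family == "independent" ||
    model$frailty$variance == 0 || model$modifier$variance == 0
  if (indep) return(list(value = m0 * m1, se = 0))
  if (!is.finite(model$frailty$variance) || !is.finite(model$modifier$variance)) {
    stop("The latent covariance is undefined for an infinite-variance law.",
         call. = FALSE)
  }
  uu <- sample_joint(model$frailty, model$modifier, model$dependence,
                     n = n_mc, seed = seed)
  prod <- uu$u0 * uu$u1
  list(value = mean(prod), se = stats::sd(prod) / sqrt(length(prod)))
}

# ---- Analytic SMCHR routes --------------------------------------------------

# Which closed/log-space route applies; NA means Monte Carlo is required.
analytic_route <- function(model) {
  fr <- model$frailty; mo <- model$modifier
  if (fr$variance == 0 && mo$variance == 0 && fr$mean > 0 && mo$mean == 1) {
    return("homogeneous")
  }
  mod_neutral <- mo$family == "degenerate" && mo$params$value == 1
  if (mod_neutral) return("frailty")
  if (fr$family == "degenerate") return("modifier")
  indep <- model$dependence$family == "independent"
  if (indep && mo$family %in% c("bhn", "degenerate")) return("mixture")
  NA_character_
}

# Discrete modifier support/weights (mixture route).
modifier_support <- function(mo) {
  if (mo$family == "bhn") {
    keep <- mo$params$weights > 0
    list(u = mo$params$support[keep], w = mo$params$weights[keep])
  } else {
    list(u = mo$params$value, w = 1)
  }
}

# log SMCHR given exposed/unexposed cumulative hazards (per unit latent
# multiplier) and the effect values f1(t,1); fully in log space so that deep
# tails (cumulative hazard up to ~1e12) remain finite.
log_smchr_core <- function(model, L1, L0, f1v, route) {
  fr <- model$frailty
  switch(route,
    homogeneous = log(f1v),
    frailty = {
      log(f1v) +
        (log_neg_laplace_deriv(fr, L1) - log_laplace(fr, L1)) -
        (log_neg_laplace_deriv(fr, L0) - log_laplace(fr, L0))
    },
    modifier = {
      v <- fr$params$value
      mo <- model$modifier
      log(f1v) + log_neg_laplace_deriv(mo, v * L1) - log_laplace(mo, v * L1)
    },
    mixture = {
      ms <- modifier_support(model$modifier)
      num <- vapply(seq_along(ms$u), function(k) {
        log(ms$w[k] * ms$u[k]) + log_neg_laplace_deriv(fr, ms$u[k] * L1)
      }, numeric(length(L1)))
      den <- vapply(seq_along(ms$u), function(k) {
        log(ms$w[k]) + log_laplace(fr, ms$u[k] * L1)
      }, numeric(length(L1)))
      num <- matrix(num, nrow = length(L1))
      den <- matrix(den, nrow = length(L1))
      lnum <- apply(num, 1, logsumexp) - apply(den, 1, logsumexp)
      lden <- log_neg_laplace_deriv(fr, L0) - log_laplace(fr, L0)
      log(f1v) + lnum - lden
    },
    stop("No analytic route for this scenario; use smchr_mc().", call. = FALSE)
  )
}

log_smchr_at_times <- function(model, t, route) {
  f <- effect_fn(model)
  L1 <- cumulative_hazard(model, t, a = 1)
  L0 <- cumulative_hazard(model, t, a = 0)
  log_smchr_core(model, L1, L0, f(t, 1), route)
}

#' Survivor marginalized causal hazard ratio, analytic routes
#'
#' The SMCHR marginalizes each world's hazard over its own survivors:
#' \deqn{\mathrm{SMCHR}(t) = \frac{E[U_0 U_1 \mid T^1 \ge t]}
#'   {E[U_0 \mid T^0 \ge t]}\, f_1(t, 1).}
#' It equals the expected observed hazard ratio of a randomized trial with
#' independent censoring, and deviates from the CHR because conditioning on
#' survival selects favourable latent values differently in the two worlds.
#'
#' `smchr_at()` dispatches to the most specific analytic route:
#' \describe{
#'   \item{`smchr_frailty_only()`}{modifier degenerate at 1; the ratio of
#'     survivor-conditional frailty means times \eqn{f_1(t,1)}.}
#'   \item{`smchr_modifier_only()`}{frailty degenerate; the survivor-conditional
#'     modifier mean.}
#'   \item{`smchr_mixture()`}{independent frailty and discrete modifier; the
#'     Laplace transform of the product \eqn{U_0 U_1} is the finite mixture
#'     \eqn{\sum_k p_k \mathcal{L}_{U_0}(\mu_k c)}, evaluated with
#'     log-sum-exp.}
#' }
#' Scenarios with dependent latents or a continuous modifier joint with
#' frailty have no analytic route; use [smchr_mc()].
#'
#' @inheritParams chr_at
#' @param log Return the natural logarithm.
#' @return Positive numeric vector of SMCHR values.
#' @export
smchr_at <- function(model, t, log = FALSE) {
  stopifnot(inherits(model, "scenario"))
  assert_nonneg(t, "t")
  route <- analytic_route(model)
  if (is.na(route)) {
    stop("No analytic SMCHR route for this scenario (dependent latents or ",
         "continuous modifier with frailty); use smchr_mc().", call. = FALSE)
  }
  lv <- log_smchr_at_times(model, t, route)
  if (log) lv else exp(lv)
}

#' @rdname smchr_at
#' @export
smchr_frailty_only <- function(model, t, log = FALSE) {
  stopifnot(inherits(model, "scenario"))
  if (!(model$modifier$family == "degenerate" && model$modifier$params$value == 1)) {
    stop("smchr_frailty_only() requires the modifier degenerate at 1.",
         call. = FALSE)
  }
  lv <- log_smchr_at_times(model, t, "frailty")
  if (log) lv else exp(lv)
}

#' @rdname smchr_at
#' @export
smchr_modifier_only <- function(model, t, log = FALSE) {
  stopifnot(inherits(model, "scenario"))
  if (model$frailty$family != "degenerate") {
    stop("smchr_modifier_only() requires a degenerate frailty.", call. = FALSE)
  }
  lv <- log_smchr_at_times(model, t, "modifier")
  if (log) lv else exp(lv)
}

#' @rdname smchr_at
#' @export
smchr_mixture <- function(model, t, log = FALSE) {
  stopifnot(inherits(model, "scenario"))
  if (model$dependence$family != "independent") {
    stop("smchr_mixture() requires independent latents.", call. = FALSE)
  }
  if (!model$modifier$family %in% c("bhn", "degenerate")) {
    stop("smchr_mixture() requires a discrete (BHN or degenerate) modifier; ",
         "use smchr_mc() for continuous modifiers with frailty.", call. = FALSE)
  }
  lv <- log_smchr_at_times(model, t, "mixture")
  if (log) lv else exp(lv)
}

#' SMCHR and CHR over a time grid
#'
#' Evaluates the analytic SMCHR along `times` together with the CHR, and
#' returns them as a curve table. For scenarios without an analytic route an
#' error points to [smchr_mc()], which returns the same structure with a
#' Monte Carlo standard-error column.
#'
#' @inheritParams chr_at
#' @param times Increasing grid of nonnegative times; defaults to 501 points
#'   on `[0, 10]`.
#' @return A tibble of class `hr_curve` with columns `time`, `chr`, `smchr`
#'   and attributes `method` (`"analytic"`), `route`, and `digest`
#'   (scenario provenance).
#' @examples
#' sc <- scenario(frailty = frailty_law("gamma", 1), effect = 3)
#' curve <- smchr_curve(sc, times = seq(0, 10, length.out = 101))
#' head(curve)
#' @export
smchr_curve <- function(model, times = seq(0, 10, length.out = 501),
                        n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(model, "scenario"))
  if (length(times) < 1) stop("`times` must be a nonempty grid.", call. = FALSE)
  assert_nonneg(times, "times")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing.", call. = FALSE)
  }
  route <- analytic_route(model)
  if (is.na(route)) {
    stop("No analytic route for this scenario; use smchr_mc().", call. = FALSE)
  }
  smchr <- exp(log_smchr_at_times(model, times, route))
  chr <- as.numeric(chr_at(model, times, n_mc = n_mc, seed = seed))
  new_hr_curve(tibble::tibble(time = times, chr = chr, smchr = smchr),
               method = "analytic", route = route,
               digest = scenario_digest(model))
}

new_hr_curve <- function(tbl, method, route, digest) {
  stopifnot(all(is.finite(tbl$smchr)), all(tbl$smchr > 0))
  structure(tbl, class = c("hr_curve", class(tbl)),
            method = method, route = route, digest = digest)
}

#' Long-time limit of the SMCHR
#'
#' Evaluates \eqn{\lim_{t\to\infty} \mathrm{SMCHR}(t)} on a geometric ladder
#' of baseline cumulative-hazard values \eqn{\Lambda_0 \in \{10, 10^2, \dots,
#' 10^{20}\}}, stopping when the successive change in log SMCHR falls below
#' `tol`. All terms are evaluated in log space, which keeps the compound
#' Poisson and inverse Gaussian deep tails finite. When the scenario matches
#' the closed-form catalog the catalog value is attached as attribute
#' `"closed_form"`:
#' gamma frailty: 1 (with or without an independent discrete modifier);
#' inverse Gaussian: \eqn{\sqrt{\mu_{\min} f_1}} where \eqn{\mu_{\min}} is
#' the smallest modifier support point (1 when absent);
#' compound Poisson with jump shape \eqn{k}:
#' \eqn{f_1^{-k} \sum_j p_j \mu_j^{-k}};
#' modifier-only discrete: \eqn{f_1\,\mu_{\min}}; modifier-only continuous: 0.
#'
#' @inheritParams chr_at
#' @param tol Convergence tolerance on the change in log SMCHR.
#' @return The limiting SMCHR (a positive scalar), with attributes
#'   `"closed_form"` (catalog value or `NA`), `"converged"` and
#'   `"cumhaz_final"`.
#' @examples
#' smchr_limit(scenario(frailty = frailty_law("gamma", 1), effect = 3))  # 1
#' @export
smchr_limit <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "scenario"))
  route <- analytic_route(model)
  if (is.na(route)) {
    stop("smchr_limit() needs an analytic route; no closed/log-space form ",
         "exists for this scenario.", call. = FALSE)
  }
  if (!effect_is_constant(model)) {
    stop("smchr_limit() requires a time-invariant effect.", call. = FALSE)
  }
  mu <- model$effect
  ladder <- 10^(1:20)
  prev <- NA_real_
  converged <- FALSE
  lval <- NA_real_
  L_final <- NA_real_
  for (L0 in ladder) {
    lval <- log_smchr_core(model, L1 = mu * L0, L0 = L0, f1v = mu, route = route)
    L_final <- L0
    if (!is.na(prev) && abs(lval - prev) < tol) {
      converged <- TRUE
      break
    }
    prev <- lval
  }
  out <- exp(lval)
  attr(out, "closed_form") <- limit_closed_form(model, route)
  attr(out, "converged") <- converged
  attr(out, "cumhaz_final") <- L_final
  out
}

# Catalog closed-form limits (NA when the scenario is off-catalog).
limit_closed_form <- function(model, route) {
  mu <- model$effect
  if (route == "homogeneous") return(mu)
  if (route == "modifier") {
    mo <- model$modifier
    if (mo$family %in% c("gamma", "invgauss", "cpois")) return(0)
    ms <- modifier_support(mo)
    return(mu * min(ms$u))
  }
  fr <- model$frailty
  ms <- if (route == "frailty") list(u = 1, w = 1) else modifier_support(model$modifier)
  switch(fr$family,
    gamma = 1,
    invgauss = if (min(ms$u) == 0) NA_real_ else sqrt(min(ms$u) * mu),
    cpois = {
      k <- fr$params$shape
      if (min(ms$u) == 0) NA_real_ else mu^(-k) * sum(ms$w * ms$u^(-k))
    },
    NA_real_
  )
}
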