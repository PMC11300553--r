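#' Baseline hazard
#'
#' Bundles a baseline hazard \eqn{\lambda_0(t)} with its cumulative form
#' \eqn{\Lambda_0(t) = \int_0^t \lambda_0(s)\,ds} and the inverse
#' \eqn{\Lambda_0^{-1}}. When only `hazard` is supplied, the cumulative is
#' obtained by adaptive quadrature and the inverse by bracketed bisection on
#' the (strictly increasing) cumulative. A baseline whose cumulative is
#' non-finite on the requested range is rejected: the theory requires a
#' hazard without infinite discontinuity.
#'
#' @param hazard Vectorized function `t -> lambda0(t) >= 0`.
#' @param cumulative Optional closed-form cumulative hazard.
#' @param inverse Optional closed-form inverse of the cumulative.
#' @param name Label used in provenance digests.
#' @return An object of class `baseline_hazard`.
#' @examples
#' b <- baseline_power()      # lambda0(t) = t^2 / 20, the worked default
#' b$cumulative(60^(1/3))     # 1
#' @export
baseline_hazard <- function(hazard, cumulative = NULL, inverse = NULL,
                            name = "custom") {
  stopifnot(is.function(hazard))
  if (is.null(cumulative)) {
    cumulative <- function(t) {
      vapply(t, function(ti) {
        if (ti == 0) return(0)
        val <- stats::integrate(hazard, 0, ti, rel.tol = 1e-10,
                                subdivisions = 500L)$value
        if (!is.finite(val)) {
          stop("Baseline cumulative hazard is non-finite at t = ", ti,
               "; the hazard must not have an infinite discontinuity.",
               call. = FALSE)
        }
        val
      }, numeric(1))
    }
  }
  if (is.null(inverse)) {
    cum <- cumulative
    inverse <- function(x) {
      vapply(x, function(xi) {
        if (xi <= 0) return(0)
        if (!is.finite(xi)) return(Inf)
        hi <- 1
        while (cum(hi) < xi) hi <- hi * 2
        stats::uniroot(function(t) cum(t) - xi, lower = 0, upper = hi,
                       tol = 1e-10)$root
      }, numeric(1))
    }
  }
  structure(list(hazard = hazard, cumulative = cumulative, inverse = inverse,
                 name = name),
            class = "baseline_hazard")
}

#' @rdname baseline_hazard
#' @param coef,power Parameters of the power-law baseline
#'   \eqn{\lambda_0(t) = \mathrm{coef}\, t^{\mathrm{power}}}; the default
#'   `coef = 1/20`, `power = 2` gives \eqn{t^2/20} with closed forms
#'   \eqn{\Lambda_0(t) = t^3/60} and \eqn{\Lambda_0^{-1}(x) = (60x)^{1/3}}.
#' @export
baseline_power <- function(coef = 1 / 20, power = 2) {
  stopifnot(coef > 0, power > -1)
  baseline_hazard(
    hazard = function(t) coef * t^power,
    cumulative = function(t) coef * t^(power + 1) / (power + 1),
    inverse = function(x) ((power + 1) * x / coef)^(1 / (power + 1)),
    name = sprintf("power(coef = %g, power = %g)", coef, power)
  )
}

#' Structural scenario for a randomized time-to-event comparison
#'
#' Represents the restricted structural causal model
#' \deqn{\lambda_i^a(t) = U_{0i}\,(U_{1i})^a\,\lambda_0(t)\,f_1(t, a),}
#' where \eqn{U_0} is the latent frailty, \eqn{U_1} the latent effect
#' modifier, and \eqn{f_1(t, a)} a homogeneous effect function with
#' \eqn{f_1(t, 0) = 1}. The causal hazard ratio and its survivor-marginalized
#' counterpart are functionals of this object.
#'
#' @param baseline A [baseline_hazard]; defaults to [baseline_power()].
#' @param frailty Latent frailty law \eqn{U_0}.
#' @param modifier Latent effect-modifier law \eqn{U_1}.
#' @param dependence A dependence specification from [dep_independent()] or
#'   [dep_gaussian()], coupling \eqn{U_0} and \eqn{U_1}.
#' @param effect Homogeneous exposure effect: a positive constant
#'   \eqn{\mu} (so \eqn{f_1(t,1)=\mu}) or a positive vectorized function of
#'   `t` giving \eqn{f_1(t, 1)}.
#' @param name Scenario label used in provenance digests.
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario(frailty = frailty_law("gamma", theta0 = 1), effect = 3)
#' chr_at(sc, 1)           # 3 at all times
#' smchr_at(sc, 60^(1/3))  # 1.5: survivor selection halves the apparent effect
#' @export
scenario <- function(baseline = baseline_power(),
                     frailty = law_degenerate(1),
                     modifier = law_degenerate(1),
                     dependence = dep_independent(),
                     effect = 1,
                     name = NULL) {
  stopifnot(inherits(baseline, "baseline_hazard"),
            inherits(frailty, "latent_law"),
            inherits(modifier, "latent_law"),
            inherits(dependence, "dependence_spec"))
  if (is.numeric(effect)) {
    stopifnot(length(effect) == 1, effect > 0)
  } else if (!is.function(effect)) {
    stop("`effect` must be a positive constant or a function of t.",
         call. = FALSE)
  }
  structure(list(baseline = baseline, frailty = frailty, modifier = modifier,
                 dependence = dependence, effect = effect,
                 name = name %||% "scenario"),
            class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# f1(t, a); identity when unexposed.
effect_fn <- function(model) {
  eff <- model$effect
  function(t, a) {
    if (a == 0) return(rep(1, length(t)))
    if (is.numeric(eff)) rep(eff, length(t)) else eff(t)
  }
}

effect_is_constant <- function(model) is.numeric(model$effect)

#' Cumulative hazard of the scenario per unit latent multiplier
#'
#' Returns \eqn{\Lambda^a(t) = \int_0^t \lambda_0(s) f_1(s, a)\,ds}, closed
#' form when the effect is time-invariant (\eqn{f_1(\cdot,a)\Lambda_0(t)})
#' and by adaptive quadrature otherwise. The latent multipliers are not
#' included; an individual's cumulative hazard is \eqn{u_0 u_1^a \Lambda^a(t)}.
#'
#' @param model A [scenario].
#' @param t Nonnegative time(s).
#' @param a Exposure level, 0 or 1.
#' @return Numeric vector of cumulative hazards.
#' @export
cumulative_hazard <- function(model, t, a = 0) {
  stopifnot(inherits(model, "scenario"))
  assert_nonneg(t, "t")
  if (a == 0 || effect_is_constant(model)) {
    f1 <- if (a == 0) 1 else model$effect
    return(f1 * model$baseline$cumulative(t))
  }
  f <- effect_fn(model)
  h <- model$baseline$hazard
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(function(s) h(s) * f(s, 1), 0, ti, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }, numeric(1))
}

#' Individual hazard under the structural model
#'
#' Evaluates \eqn{u_0\,u_1^a\,\lambda_0(t)\,f_1(t,a)}: the hazard of the
#' potential outcome of an individual with latent values `(u0, u1)` under
#' exposure level `a`. Unexposed individuals are unaffected by `u1`.
#'
#' @inheritParams cumulative_hazard
#' @param u0,u1 Nonnegative latent frailty and modifier values.
#' @return Numeric vector of hazards.
#' @export
individual_hazard <- function(model, t, u0, u1 = 1, a = 0) {
  stopifnot(inherits(model, "scenario"))
  assert_nonneg(u0, "u0")
  assert_nonneg(u1, "u1")
  f <- effect_fn(model)
  u0 * u1^a * model$baseline$hazard(t) * f(t, a)
}

# One-line provenance string recorded in curve outputs.
scenario_digest <- function(model) {
  law_str <- function(law) {
    pars <- law$params[!vapply(law$params, function(p) length(p) > 1, logical(1))]
    sprintf("%s(%s)", law$family,
            paste(sprintf("%s=%.6g", names(pars), unlist(pars)), collapse = ","))
  }
  eff <- if (effect_is_constant(model)) sprintf("%.6g", model$effect) else "f(t)"
  sprintf("%s | baseline=%s frailty=%s modifier=%s dependence=%s effect=%s",
          model$name, model$baseline$name, law_str(model$frailty),
          law_str(model$modifier), dep_digest(model$dependence), eff)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", scenario_digest(x), "\n")
  invisible(x)
}
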