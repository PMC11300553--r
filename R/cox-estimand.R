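#' Log observed hazard ratio at a time point
#'
#' In a randomized trial with independent censoring the observed hazard
#' ratio equals the SMCHR, so its logarithm is taken from the analytic
#' engine when a route exists; otherwise it is estimated by Monte Carlo
#' (with attribute `"se"`).
#'
#' @inheritParams smchr_at
#' @param n_mc,seed Monte Carlo settings for the fallback route.
#' @return Numeric vector of log OHR values.
#' @export
log_ohr_at <- function(model, t, n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(model, "scenario"))
  route <- analytic_route(model)
  if (!is.na(route)) return(log_smchr_at_times(model, t, route))
  ts <- sort(unique(t))
  cv <- smchr_mc(model, times = ts, n = n_mc, seed = seed)
  out <- log(cv$smchr)[match(t, ts)]
  attr(out, "se") <- (cv$se / cv$smchr)[match(t, ts)]
  out
}

#' Estimand of a misspecified proportional-hazards fit
#'
#' When the hazard ratio varies over time, the log of a Cox estimate from a
#' randomized trial can be interpreted as the log observed hazard ratio
#' marginalized over the observed (uncensored) death times,
#' \eqn{E[\log \mathrm{OHR}(T) \mid C = 0]} (the Schemper interpretation).
#' This function simulates a trial under the given censoring scheme,
#' averages the analytic log SMCHR over the uncensored event times, and
#' exponentiates. Because censoring thins late times, heavier censoring
#' pulls the estimand toward the short-time OHR.
#'
#' @inheritParams sample_rct
#' @param n_rep Number of simulated subjects.
#' @return An object of class `cox_estimand`: a list with `estimand`,
#'   `log_estimand`, `mc_se` (standard error on the log scale), `n_events`,
#'   `n`, and the censoring description. `tidy()` and `glance()` methods
#'   are provided.
#' @examples
#' sc <- scenario(frailty = frailty_law("gamma", 1),
#'                modifier = modifier_law("bhn", 3, 1, p1 = 0.05, mu1 = 0.5))
#' expected_cox_estimand(sc, censoring_scheme(follow_up = 4),
#'                       n_rep = 2e4, seed = 1)
#' @export
expected_cox_estimand <- function(model, cens = censoring_scheme(),
                                  n_rep = 1e5, seed = NULL, p_treat = 0.5) {
  stopifnot(inherits(model, "scenario"))
  dat <- sample_rct(model, n = n_rep, p_treat = p_treat, cens = cens,
                    seed = seed)
  ev <- dat$time[dat$status == 1]
  if (length(ev) == 0) {
    stop("No uncensored events; the estimand is undefined.", call. = FALSE)
  }
  lo <- as.numeric(log_ohr_at(model, ev, seed = seed))
  m <- mean(lo)
  structure(
    list(estimand = exp(m), log_estimand = m,
         mc_se = stats::sd(lo) / sqrt(length(lo)),
         n_events = length(ev), n = n_rep, censoring = cens,
         digest = scenario_digest(model)),
    class = "cox_estimand"
  )
}

#' @export
print.cox_estimand <- function(x, ...) {
  cat(sprintf(
    "<cox_estimand> exp(E[log OHR(T) | uncensored]) = %.4f (log %.4f, se %.4f)\n",
    x$estimand, x$log_estimand, x$mc_se))
  cat(sprintf("  %d events of %d subjects; follow-up %s, loss rate %g\n",
              x$n_events, x$n,
              format(x$censoring$follow_up), x$censoring$loss_rate))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.cox_estimand <- function(x, ...) {
  tibble::tibble(term = "arm", estimate = x$log_estimand,
                 std.error = x$mc_se, estimand = x$estimand)
}

#' @export
glance.cox_estimand <- function(x, ...) {
  tibble::tibble(estimand = x$estimand, n = x$n, n_events = x$n_events,
                 follow_up = x$censoring$follow_up,
                 loss_rate = x$censoring$loss_rate)
}

#' Sweep the Cox estimand over censoring regimes
#'
#' Recomputes [expected_cox_estimand()] over a grid of administrative
#' follow-up times, optionally crossed with exponential loss-to-follow-up
#' means, yielding the table behind a follow-up-sensitivity figure.
#'
#' @inheritParams expected_cox_estimand
#' @param follow_up Vector of administrative follow-up times.
#' @param censoring_mean Vector of exponential censoring-time means
#'   (`Inf` = no loss to follow-up).
#' @return A tibble with columns `follow_up`, `censoring_mean`, `estimand`,
#'   `mc_se`, `n_events`.
#' @export
cox_sweep <- function(model, follow_up = c(0.5, 1, 2, 3, 4, 5, 7.5, 10),
                      censoring_mean = Inf, n_rep = 1e5, seed = NULL) {
  grid <- tidyr::expand_grid(follow_up = follow_up,
                             censoring_mean = censoring_mean)
  purrr::pmap_dfr(grid, function(follow_up, censoring_mean) {
    cens <- censoring_scheme(follow_up = follow_up,
                             loss_rate = if (is.finite(censoring_mean))
                               1 / censoring_mean else 0)
    res <- expected_cox_estimand(model, cens, n_rep = n_rep, seed = seed)
    tibble::tibble(follow_up = follow_up, censoring_mean = censoring_mean,
                   estimand = res$estimand, mc_se = res$mc_se,
                   n_events = res$n_events)
  })
}

#' Cox partial-likelihood fit for a binary arm
#'
#' Newton-Raphson maximization of the single-covariate Cox partial
#' likelihood with Breslow tie handling, used to cross-validate the
#' Schemper interpretation of the Cox estimand against simulated trials.
#' Convergence when the absolute score falls below `1e-10` (at most 50
#' iterations).
#'
#' @param data A data frame with columns `arm` (0/1), `time`, `status`
#'   (1 = event), as produced by [sample_rct()].
#' @return An object of class `smchr_coxfit` with elements `estimate` (log
#'   hazard ratio), `std.error`, `iter`, `loglik`, `n`, `n_events`; `tidy()`
#'   and `glance()` methods are provided.
#' @export
cox_fit_binary <- function(data) {
  stopifnot(all(c("arm", "time", "status") %in% names(data)))
  arm <- as.numeric(data$arm); time <- data$time; status <- data$status
  if (sum(status[arm == 1]) == 0 || sum(status[arm == 0]) == 0) {
    stop("Monotone partial likelihood: no events in one arm; the estimate ",
         "diverges.", call. = FALSE)
  }
  ord <- order(time)
  time <- time[ord]; arm <- arm[ord]; status <- status[ord]
  n <- length(time)
  # Risk-set counts by arm at each event time (ties share one risk set).
  at_risk1 <- rev(cumsum(rev(arm)))          # x = 1 subjects with time >= t_i
  at_risk  <- n - seq_len(n) + 1
  # For ties, the risk set is taken at the first index of the tie block.
  first_of_tie <- match(time, time)
  r1 <- at_risk1[first_of_tie]
  r0 <- at_risk[first_of_tie] - r1
  ev <- status == 1
  d1 <- arm[ev]; R1 <- r1[ev]; R0 <- r0[ev]

  beta <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eb <- exp(beta)
    p <- R1 * eb / (R0 + R1 * eb)
    score <- sum(d1 - p)
    info <- sum(p * (1 - p))
    if (info <= 0) stop("Degenerate information in the partial likelihood.",
                        call. = FALSE)
    beta <- beta + score / info
    if (abs(score) < 1e-10 || iter >= 50L) break
  }
  eb <- exp(beta)
  loglik <- sum(beta * d1 - log(R0 + R1 * eb))
  structure(list(estimate = beta, std.error = 1 / sqrt(info), iter = iter,
                 loglik = loglik, n = n, n_events = sum(ev)),
            class = "smchr_coxfit")
}

#' @export
print.smchr_coxfit <- function(x, ...) {
  cat(sprintf("<smchr_coxfit> log HR = %.4f (se %.4f), %d events / %d subjects\n",
              x$estimate, x$std.error, x$n_events, x$n))
  invisible(x)
}

#' @export
tidy.smchr_coxfit <- function(x, ...) {
  tibble::tibble(term = "arm", estimate = x$estimate, std.error = x$std.error,
                 statistic = x$estimate / x$std.error,
                 p.value = 2 * stats::pnorm(-abs(x$estimate / x$std.error)))
}

#' @export
glance.smchr_coxfit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 iter = x$iter)
}
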