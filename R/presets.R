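# Scenario preset catalog: the worked examples of the accompanying figures.
# All presets share the power-law baseline t^2/20; frailty laws have mean 1
# and variance theta0; BHN modifiers fix the benefit component (p1, mu1) at
# (0.9, 0.1) for mean 1/3 and (0.05, 0.5) for mean 3, solving the harm
# component from the two moment equations.

bhn_fixed <- function(mean) {
  if (isTRUE(all.equal(mean, 1 / 3))) list(p1 = 0.9, mu1 = 0.1)
  else if (isTRUE(all.equal(mean, 3))) list(p1 = 0.05, mu1 = 0.5)
  else stop("BHN presets are defined for means 1/3 and 3 only.", call. = FALSE)
}

label_num <- function(x) gsub("\\.", "p", gsub("-", "m", format(x)))

num_label <- function(x) {
  if (isTRUE(all.equal(x, 1 / 3))) "1o3" else label_num(x)
}

preset_catalog <- function() {
  out <- list()
  add <- function(name, figure, description, build) {
    out[[name]] <<- list(name = name, figure = figure,
                         description = description, build = build)
  }
  fams <- c("gamma", "invgauss", "cpois")
  mus <- c(3, 1 / 3)
  vars <- c(0.5, 1, 2)
  for (fam in fams) for (mu in mus) for (th in vars) {
    nm <- sprintf("fig1_%s_mu%s_th%s", fam, num_label(mu), label_num(th))
    local({
      fam <- fam; mu <- mu; th <- th; nm <- nm
      add(nm, "fig1",
          sprintf("frailty-only: %s frailty (var %g), homogeneous effect %g",
                  fam, th, mu),
          function() scenario(frailty = frailty_law(fam, th), effect = mu,
                              name = nm))
    })
  }
  for (fam in c("bhn", fams)) for (mu in mus) for (th in vars) {
    nm <- sprintf("fig2_%s_mu%s_th%s", fam, num_label(mu), label_num(th))
    local({
      fam <- fam; mu <- mu; th <- th; nm <- nm
      add(nm, "fig2",
          sprintf("modifier-only: %s modifier, mean %g, var %g", fam, mu, th),
          function() {
            mod <- if (fam == "bhn") {
              fx <- bhn_fixed(mu)
              modifier_law("bhn", mu, th, p1 = fx$p1, mu1 = fx$mu1)
            } else modifier_law(fam, mu, th)
            scenario(modifier = mod, name = nm)
          })
    })
  }
  for (fam in fams) for (mu in mus) for (th in vars) {
    nm <- sprintf("fig3_%s_mu%s_th%s", fam, num_label(mu), label_num(th))
    local({
      fam <- fam; mu <- mu; th <- th; nm <- nm
      add(nm, "fig3",
          sprintf("%s frailty (var %g) x independent unit-variance BHN, mean %g",
                  fam, th, mu),
          function() {
            fx <- bhn_fixed(mu)
            scenario(frailty = frailty_law(fam, th),
                     modifier = modifier_law("bhn", mu, 1,
                                             p1 = fx$p1, mu1 = fx$mu1),
                     name = nm)
          })
    })
  }
  taus <- c(-1, -0.5, 0, 0.5, 1)
  for (fam in fams) for (mu in mus) for (tau in taus) {
    nm <- sprintf("fig4_%s_mu%s_tau%s", fam, num_label(mu), label_num(tau))
    local({
      fam <- fam; mu <- mu; tau <- tau; nm <- nm
      add(nm, "fig4",
          sprintf("%s frailty (var 1) x BHN mean %g, Gaussian copula tau %g",
                  fam, mu, tau),
          function() {
            fx <- bhn_fixed(mu)
            scenario(frailty = frailty_law(fam, 1),
                     modifier = modifier_law("bhn", mu, 1,
                                             p1 = fx$p1, mu1 = fx$mu1),
                     dependence = dep_gaussian(tau = tau),
                     name = nm)
          })
    })
    nm5 <- sprintf("fig5_%s_mu%s_tau%s", fam, num_label(mu), label_num(tau))
    local({
      fam <- fam; mu <- mu; tau <- tau; nm5 <- nm5
      add(nm5, "fig5",
          sprintf("%s frailty (var 1) x gamma modifier mean %g (var 1), tau %g",
                  fam, mu, tau),
          function() scenario(frailty = frailty_law(fam, 1),
                              modifier = modifier_law("gamma", mu, 1),
                              dependence = dep_gaussian(tau = tau),
                              name = nm5))
    })
  }
  add("fig6_cox_sweep", "fig6",
      "Cox-estimand sweep: gamma frailty (var 1) x BHN(0.05, 0.5, ~0.82, ~3.5)",
      function() scenario(frailty = frailty_law("gamma", 1),
                          modifier = modifier_law("bhn", 3, 1,
                                                  p1 = 0.05, mu1 = 0.5),
                          name = "fig6_cox_sweep"))
  out
}

#' Scenario presets
#'
#' `scenario_presets()` lists the built-in scenario catalog (frailty-only,
#' modifier-only, combined, copula-dependent, and the Cox-sweep scenario);
#' `preset_scenario()` builds one by name.
#'
#' @param name Preset name as listed by `scenario_presets()`.
#' @return `scenario_presets()`: a tibble with columns `name`, `figure`,
#'   `description`. `preset_scenario()`: a [scenario].
#' @examples
#' dplyr::count(scenario_presets(), figure)
#' preset_scenario("fig1_gamma_mu3_th1")
#' @export
scenario_presets <- function() {
  cat <- preset_catalog()
  tibble::tibble(
    name = vapply(cat, `[[`, character(1), "name"),
    figure = vapply(cat, `[[`, character(1), "figure"),
    description = vapply(cat, `[[`, character(1), "description")
  )
}

#' @rdname scenario_presets
#' @export
preset_scenario <- function(name) {
  cat <- preset_catalog()
  if (!name %in% names(cat)) {
    stop("Unknown preset \"", name, "\"; see scenario_presets().",
         call. = FALSE)
  }
  cat[[name]]$build()
}
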