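# Independent quadrature oracles built from explicit densities; these never
# call the package's Laplace-transform code paths.

dens_gamma <- function(u, shape, scale) stats::dgamma(u, shape = shape, scale = scale)

dens_invgauss <- function(u, mean, shape) {
  ifelse(u > 0,
         sqrt(shape / (2 * pi * u^3)) *
           exp(-shape * (u - mean)^2 / (2 * mean^2 * u)),
         0)
}

# E[exp(-cU)] by adaptive quadrature over an explicit density.
oracle_laplace <- function(dens, c) {
  stats::integrate(function(u) dens(u) * exp(-c * u), 0, Inf,
                   rel.tol = 1e-10, subdivisions = 1000L)$value
}

# E[U exp(-cU)] / E[exp(-cU)] by quadrature.
oracle_survivor_mean <- function(dens, c) {
  num <- stats::integrate(function(u) u * dens(u) * exp(-c * u), 0, Inf,
                          rel.tol = 1e-10, subdivisions = 1000L)$value
  num / oracle_laplace(dens, c)
}

# Brute-force Cox partial log-likelihood (Breslow ties) for a binary arm,
# computed by direct risk-set enumeration.
brute_partial_loglik <- function(beta, arm, time, status) {
  ev <- which(status == 1)
  sum(vapply(ev, function(i) {
    risk <- time >= time[i]
    beta * arm[i] - log(sum(exp(beta * arm[risk])))
  }, numeric(1)))
}

# Common fixtures.
fix_gamma1 <- function() law_gamma(shape = 1, scale = 1)
fix_bhn_harm <- function() law_bhn(0.05, 0.5, 0.82, 3.5)
fix_bhn_benefit <- function() law_bhn(0.9, 0.1, 0.03, 6.0)
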