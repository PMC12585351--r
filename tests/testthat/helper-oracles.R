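# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the PMF oracle integrates the beta-mixed binomial
# directly, and the gamma-quantile oracle inverts pgamma by bisection.

# beta-binomial PMF by numerical integration of the beta mixing density
bb_pmf_oracle <- function(x, n, pi, theta) {
  if (theta == 0) return(dbinom(x, n, pi))
  a <- pi / theta
  b <- (1 - pi) / theta
  f <- function(p) dbinom(x, n, p) * dbeta(p, a, b)
  stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
}

# gamma quantile by inverting the CDF with uniroot (independent of qgamma)
qgamma_oracle <- function(prob, shape, scale = 2) {
  stats::uniroot(function(q) stats::pgamma(q, shape = shape, scale = scale) - prob,
                 lower = 0, upper = 1e4, tol = 1e-12)$root
}

# weighted beta-binomial log-likelihood, direct evaluation (for gradient
# finite-difference oracles and for checking that the cohort-specific model
# at equal dispersions reproduces the shared-model likelihood)
mixture_loglik_oracle <- function(d, se, phi, pi_het, th_control, th_case,
                                  th_hom) {
  x <- d$ref_count
  n <- d$ref_count + d$var_count
  th <- ifelse(d$group == "case", th_case, th_control)
  f1 <- dbetabinom(x, n, 1 - se, th_hom, log = FALSE)
  f2 <- dbetabinom(x, n, pi_het, th, log = FALSE)
  f3 <- dbetabinom(x, n, se, th_hom, log = FALSE)
  sum(log(phi[1] * f1 + phi[2] * f2 + phi[3] * f3))
}

# small simulated SNP at the default study conditions
quick_snp <- function(seed, n_control = 150, n_case = 150,
                      rho_control = 0.05, rho_case = rho_control, ...) {
  simulate_snp(sim_config(n_control = n_control, n_case = n_case,
                          rho_het_control = rho_control,
                          rho_het_case = rho_case, seed = seed, ...))
}
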