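# Beta-binomial genotype mixture EM: recovery, symmetry, constraints,
# degenerate inputs, leave-one-out outlier detection.

test_that("simulation recovery: parameters close to generative truth", {
  snp <- quick_snp(31, n_control = 200, n_case = 200, rho_control = 0.02)
  fit <- fit_ase_mixture(snp, se = 0.002)
  expect_lt(abs(fit$pi_het - 0.5), 0.02)
  expect_lt(abs(fit$rho_het[["shared"]] - 0.02) / 0.02, 0.5)
  truth <- attr(snp, "truth")
  expect_lt(max(abs(fit$phi - truth$phi)), 0.06)
  expect_true(fit$converged)
})

test_that("single-genotype data flags the heterozygote component", {
  d <- data.frame(ref_count = rep(30L, 20), var_count = rep(0L, 20),
                  group = rep(c("control", "case"), 10))
  fit <- fit_ase_mixture(d, se = 0.002)
  expect_gt(fit$phi[["rr"]], 0.95)
  expect_true("het_unidentifiable" %in% fit$flags)
})

test_that("mirroring the data maps pi_het to its complement", {
  snp <- quick_snp(11, rho_control = 0.05)
  fit <- fit_ase_mixture(snp, se = 0.002)
  mirrored <- snp
  mirrored$ref_count <- snp$var_count
  mirrored$var_count <- snp$ref_count
  fit_m <- fit_ase_mixture(mirrored, se = 0.002)
  expect_equal(fit_m$pi_het, 1 - fit$pi_het, tolerance = 1e-3)
  expect_equal(fit_m$theta_het[[1]], fit$theta_het[[1]], tolerance = 1e-3)
  expect_equal(fit_m$loglik, fit$loglik, tolerance = 1e-5)
  expect_equal(unname(fit_m$phi), unname(rev(fit$phi)), tolerance = 1e-3)
})

test_that("EM log-likelihood never decreases and fits converge", {
  for (s in 1:5) {
    fit <- fit_ase_mixture(quick_snp(s), se = 0.002)
    expect_false("loglik_decrease" %in% fit$flags)
    expect_true(fit$converged)
  }
})

test_that("cohort-specific model at equal dispersions matches the shared fit", {
  snp <- quick_snp(17, rho_control = 0.05)
  fit0 <- fit_ase_mixture(snp, se = 0.002)
  # evaluating the cohort-specific likelihood at the shared parameters
  ll_eq <- mixture_loglik_oracle(snp, 0.002, fit0$phi, fit0$pi_het,
                                 fit0$theta_het[[1]], fit0$theta_het[[1]],
                                 fit0$theta_hom)
  expect_equal(ll_eq, fit0$loglik, tolerance = 1e-6)
  # and the freely fitted cohort-specific model can only do better
  fit1 <- fit_ase_mixture(snp, se = 0.002, group_specific = TRUE)
  expect_gte(fit1$loglik, fit0$loglik - 1e-6)
})

test_that("accepted fits satisfy the unimodality constraint", {
  # strongly bimodal heterozygote data: latent fractions pushed to 0/1
  set.seed(5)
  S <- 120
  g <- sample.int(3, S, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  n <- pmax(rnbinom(S, mu = 40, size = 5), 1)
  frac <- ifelse(g == 1, 0.998, ifelse(g == 3, 0.002,
                                       rbeta(S, 0.15, 0.15)))
  d <- data.frame(ref_count = rbinom(S, n, frac), var_count = 0L,
                  group = rep(c("control", "case"), length.out = S))
  d$var_count <- n - d$ref_count
  fit <- fit_ase_mixture(d, se = 0.002)
  lim <- max(fit$pi_het, 1 - fit$pi_het)
  expect_true(all(fit$theta_het <= lim + 1e-8))
  expect_true(fit$constrained_refit)
})

test_that("warm starts and sample exclusion are honored", {
  snp <- quick_snp(23)
  fit <- fit_ase_mixture(snp, se = 0.002)
  warm <- list(pi_het = fit$pi_het, theta_het = fit$theta_het,
               theta_hom = fit$theta_hom, phi = fit$phi)
  drop_id <- snp$sample_id[1]
  fit2 <- fit_ase_mixture(snp, se = 0.002, exclude = drop_id, init = warm)
  expect_false(drop_id %in% fit2$data$sample_id)
  expect_equal(nrow(fit2$data), nrow(fit$data) - 1)
})

test_that("responsibilities sum to one and heterozygote counts split by cohort", {
  snp <- quick_snp(29)
  fit <- fit_ase_mixture(snp, se = 0.002)
  expect_equal(rowSums(fit$responsibilities), rep(1, nrow(fit$data)),
               tolerance = 1e-9)
  expect_equal(sum(fit$n_het), sum(fit$responsibilities[, 2]), tolerance = 1e-9)
  pr <- predict(fit)
  expect_equal(unname(pr), unname(fit$responsibilities), tolerance = 1e-9)
  sim <- simulate(fit, nsim = 1, seed = 1)[[1]]
  expect_equal(sim$ref_count + sim$var_count, fit$data$n)
})

test_that("planted influential sample is flagged by leave-one-out deletion", {
  # a deeply covered, strongly skewed heterozygote dominates the dispersion
  # estimate; an all-reference sample would be absorbed by the homozygote
  # component instead and carries no leverage on the heterozygote parameters
  set.seed(61)
  S <- 30
  n <- pmax(rnbinom(S, mu = 50, size = 5), 1)
  x <- rbetabinom(S, n, 0.5, rho_to_theta(0.02))
  d <- data.frame(sample_id = sprintf("s%02d", 1:(S + 1)),
                  ref_count = c(x, 240L), var_count = c(n - x, 60L))
  rep_out <- detect_outliers(d, se = 0.002)
  expect_true(sprintf("s%02d", S + 1) %in% rep_out$outliers)
})

test_that("exchangeable samples produce no outlier flags (zero-SD rule)", {
  d <- data.frame(sample_id = paste0("s", 1:12),
                  ref_count = rep(c(25L, 26L), 6),
                  var_count = rep(c(25L, 24L), 6))
  rep_out <- detect_outliers(d, se = 0.002)
  # deltas come in two exchangeable classes; nothing should exceed 5 SD
  expect_length(rep_out$outliers, 0)
  expect_error(detect_outliers(d[1:2, ], se = 0.002), ">= 3")
})

test_that("outlier removal is stable on homogeneous groups", {
  flagged_again <- vapply(1:10, function(s) {
    set.seed(400 + s)
    S <- 25
    n <- pmax(rnbinom(S, mu = 50, size = 5), 1)
    x <- rbetabinom(S, n, 0.5, rho_to_theta(0.03))
    d <- data.frame(sample_id = sprintf("s%02d", 1:S),
                    ref_count = x, var_count = n - x)
    r1 <- detect_outliers(d, se = 0.002)
    if (!length(r1$outliers)) return(FALSE)
    d2 <- d[!(d$sample_id %in% r1$outliers), ]
    r2 <- detect_outliers(d2, se = 0.002)
    length(r2$outliers) > 0
  }, logical(1))
  expect_gte(mean(!flagged_again), 0.8)
})
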