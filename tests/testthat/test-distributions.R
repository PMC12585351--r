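# Beta-binomial kernel: PMF forms, CMF, gradients, transforms.

test_that("log-PMF matches trivial closed forms and the integration oracle", {
  # single-trial product form collapses to 1 - pi, independent of theta
  expect_equal(dbetabinom(0, 1, 0.3, 0.7), log(0.7), tolerance = 1e-12)
  expect_equal(dbetabinom(0, 1, 0.3, 2.5), log(0.7), tolerance = 1e-12)
  # theta = 0 is the binomial exactly
  expect_identical(dbetabinom(2, 5, 0.5, 0, log = FALSE), dbinom(2, 5, 0.5))
  # interior case against an independent integration oracle and a frozen
  # exact-arithmetic reference value
  v <- dbetabinom(3, 10, 0.3, 0.2, log = FALSE)
  expect_equal(v, bb_pmf_oracle(3, 10, 0.3, 0.2), tolerance = 1e-9)
  expect_equal(v, 0.14785766601562486, tolerance = 1e-12)
})

test_that("PMF is normalized over the support for n up to 50", {
  for (pi in c(0.01, 0.1, 0.3, 0.5, 0.9, 0.99)) {
    for (theta in c(0, 1e-6, 1e-3, 0.05, 0.5, 2, 10)) {
      for (n in c(1, 2, 7, 23, 50)) {
        s <- sum(dbetabinom(0:n, n, pi, theta, log = FALSE))
        expect_true(abs(s - 1) < 1e-9,
                    label = sprintf("normalization at pi=%g theta=%g n=%d (sum=%.12f)",
                                    pi, theta, n, s))
      }
    }
  }
})

test_that("beta-function and product forms agree where both are finite", {
  grid <- expand.grid(x = c(0, 1, 5, 17, 40), n = 40,
                      pi = c(0.05, 0.4, 0.62), theta = c(1e-4, 0.1, 1.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    beta_form <- dbetabinom(g$x, g$n, g$pi, g$theta)
    prod_form <- diffAD:::.bb_logpmf_product1(g$x, g$n, g$pi, g$theta)
    expect_equal(beta_form, prod_form, tolerance = 1e-9)
  }
})

test_that("PMF has reflection symmetry and the theta->0 binomial limit", {
  for (x in 0:12) {
    expect_equal(dbetabinom(x, 12, 0.3, 0.4),
                 dbetabinom(12 - x, 12, 0.7, 0.4), tolerance = 1e-12)
  }
  expect_equal(dbetabinom(0:20, 20, 0.35, 1e-12, log = FALSE),
               dbinom(0:20, 20, 0.35), tolerance = 1e-8)
})

test_that("variance grows strictly with theta (enumeration, n <= 30)", {
  for (n in c(5, 14, 30)) {
    for (pi in c(0.2, 0.5)) {
      vars <- sapply(c(0.01, 0.1, 0.5, 2), function(th) {
        p <- dbetabinom(0:n, n, pi, th, log = FALSE)
        m <- sum((0:n) * p)
        sum((0:n)^2 * p) - m^2
      })
      expect_true(all(diff(vars) > 0))
    }
  }
})

test_that("invalid parameters and out-of-domain counts signal errors", {
  expect_error(dbetabinom(1, 2, -0.1, 0.5), "pi")
  expect_error(dbetabinom(1, 2, 0.5, -1), "theta")
  expect_error(dbetabinom(3, 2, 0.5, 0.5), "domain")
  expect_error(rho_to_theta(1), "rho")
})

test_that("cancellation fallback is counted and exact", {
  betabinom_fallback_count(reset = TRUE)
  v <- dbetabinom(2, 5, 0.5, 1e-12)
  expect_gte(betabinom_fallback_count(), 1)
  expect_equal(v, dbinom(2, 5, 0.5, log = TRUE), tolerance = 1e-8)
})

test_that("CMF sums the PMF, reaches 1, and splits symmetric odd-n support", {
  expect_equal(pbetabinom(10, 10, 0.3, 0.2), 1, tolerance = 1e-10)
  expect_equal(pbetabinom(9, 9, 0.77, 1.3), 1, tolerance = 1e-10)
  # pi = 0.5: mass below the midpoint of n = 9 is exactly half
  for (th in c(0, 0.1, 1)) {
    expect_equal(pbetabinom(4, 9, 0.5, th), 0.5, tolerance = 1e-10)
  }
  expect_equal(pbetabinom(3, 10, 0.3, 0.2),
               sum(sapply(0:3, bb_pmf_oracle, n = 10, pi = 0.3, theta = 0.2)),
               tolerance = 1e-9)
})

test_that("log-likelihood gradient is analytic-exact against finite differences", {
  # symmetric data: stationary in pi at 0.5
  g <- betabinom_loglik_grad(c(5, 5), c(10, 10), 0.5, 0.2)
  expect_equal(unname(g["dpi"]), 0, tolerance = 1e-10)
  # binomial MLE: stationary in pi at x/n
  g0 <- betabinom_loglik_grad(3, 10, 0.3, 0)
  expect_equal(unname(g0["dpi"]), 0, tolerance = 1e-10)
  # finite-difference oracle
  ll <- function(pi, th) sum(dbetabinom(c(3, 8), c(10, 10), pi, th))
  h <- 1e-6
  fd <- c((ll(0.55 + h, 0.1) - ll(0.55 - h, 0.1)) / (2 * h),
          (ll(0.55, 0.1 + h) - ll(0.55, 0.1 - h)) / (2 * h))
  g <- betabinom_loglik_grad(c(3, 8), c(10, 10), 0.55, 0.1)
  expect_equal(unname(g), fd, tolerance = 1e-6)
  expect_error(betabinom_loglik_grad(1, 2, 0.5, 0.1, w = 2), "weights")
})

test_that("theta/rho transforms are an exact bijection", {
  expect_identical(theta_to_rho(1), 0.5)
  expect_identical(theta_to_rho(0), 0)
  expect_equal(rho_to_theta(0.2), 0.25, tolerance = 1e-15)
  for (rho in c(0, 1e-8, 0.2, 0.5, 0.97)) {
    expect_equal(theta_to_rho(rho_to_theta(rho)), rho, tolerance = 1e-14)
  }
})

test_that("random deviates match the first two beta-binomial moments", {
  set.seed(42)
  x <- rbetabinom(20000, 40, 0.3, 0.25)
  rho <- theta_to_rho(0.25)
  expect_equal(mean(x), 40 * 0.3, tolerance = 0.02)
  expect_equal(var(x), 40 * 0.3 * 0.7 * (1 + 39 * rho), tolerance = 0.05)
})
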