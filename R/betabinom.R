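# Beta-binomial probability kernel.
#
# The mixture models parameterize the beta-binomial by a mean parameter pi in
# [0,1] and an overdispersion parameter theta in [0, Inf); theta = 0 is the
# binomial limit. The equivalent bounded overdispersion is
# rho = theta / (1 + theta) in [0, 1).
#
# Two algebraically identical PMF forms are implemented:
#  * the beta-function form   lchoose(n,x) + lbeta(x+a, n-x+b) - lbeta(a,b)
#    with a = pi/theta, b = (1-pi)/theta, fast but subject to catastrophic
#    cancellation of the two lbeta terms when theta is tiny;
#  * the ascending-product form, evaluated as a sum of logs of strictly
#    positive factors, exact up to one rounding per factor and O(n) per value.
# The policy is: beta form when stable, product form when cancellation of the
# lbeta terms is detected (leading digits agreeing beyond a relative gap of
# 1e-8) or when the beta form is non-finite. Because the product form is
# exact, no further escalation is required; a counter of fallback events is
# kept in a package-local environment for diagnostics.

.diffad_env <- new.env(parent = emptyenv())
.diffad_env$product_fallbacks <- 0L

#' Convert between theta and rho overdispersion scales
#'
#' `theta_to_rho()` maps theta in \[0, Inf) to rho = theta/(1+theta) in
#' \[0, 1); `rho_to_theta()` is its inverse. Both are exact monotone
#' bijections.
#'
#' @param theta Overdispersion on the unbounded scale, >= 0.
#' @param rho Overdispersion on the bounded scale, in \[0, 1).
#' @return The transformed value(s).
#' @examples
#' theta_to_rho(1)     # 0.5
#' rho_to_theta(0.2)   # 0.25
#' @export
theta_to_rho <- function(theta) {
  if (any(theta < 0)) stop("theta must be >= 0")
  theta / (1 + theta)
}

#' @rdname theta_to_rho
#' @export
rho_to_theta <- function(rho) {
  if (any(rho < 0 | rho >= 1)) stop("rho must be in [0, 1); rho = 1 implies infinite theta")
  rho / (1 - rho)
}

.check_bb_params <- function(pi, theta) {
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1))
    stop("invalid parameter: pi must be in [0, 1]")
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("invalid parameter: theta must be >= 0")
}

# product (ascending factorial) log-PMF for scalar x, n; exact in log space
.bb_logpmf_product1 <- function(x, n, pi, theta) {
  t1 <- if (x > 0) sum(log(pi + theta * (0:(x - 1)))) else 0
  t2 <- if (n - x > 0) sum(log(1 - pi + theta * (0:(n - x - 1)))) else 0
  t3 <- if (n > 1) sum(log1p(theta * (1:(n - 1)))) else 0
  lchoose(n, x) + t1 + t2 - t3
}

# vectorized product form for scalar (pi, theta), vector x and n, via
# cumulative sums of the shared log factors; exact like the scalar version
.bb_logpmf_product_vec <- function(x, n, pi, theta) {
  m <- max(n)
  k <- 0:(m - 1)
  cs_r <- c(0, cumsum(log(pi + theta * k)))
  cs_v <- c(0, cumsum(log(1 - pi + theta * k)))
  cs_d <- c(0, cumsum(log1p(theta * seq_len(max(m - 1, 1)))))
  lchoose(n, x) + cs_r[x + 1] + cs_v[n - x + 1] - cs_d[pmax(n, 1)]
}

#' Beta-binomial probability mass function
#'
#' Numerically robust log-PMF of the beta-binomial distribution with mean
#' parameter `pi` and overdispersion `theta` (`theta = 0` gives the binomial
#' PMF exactly). Vectorized over `x` and `n`; `pi` and `theta` are recycled.
#'
#' @param x Number of reference-allele reads, integer(ish) in \[0, n\].
#' @param n Total allelic count, integer(ish) >= 0.
#' @param pi Mean parameter in \[0, 1\].
#' @param theta Overdispersion parameter >= 0.
#' @param log Return log-probabilities? Default `TRUE`.
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' dbetabinom(2, 5, 0.5, 0)          # binomial mass
#' dbetabinom(3, 10, 0.3, 0.2)
#' @export
dbetabinom <- function(x, n, pi, theta, log = TRUE) {
  .check_bb_params(pi, theta)
  m <- max(length(x), length(n), length(pi), length(theta))
  x <- rep_len(x, m); n <- rep_len(n, m)
  pi <- rep_len(pi, m); theta <- rep_len(theta, m)
  if (any(x < 0 | x > n)) stop("domain error: x must satisfy 0 <= x <= n")

  out <- numeric(m)

  bin <- theta == 0 | pi == 0 | pi == 1
  if (any(bin)) out[bin] <- stats::dbinom(x[bin], n[bin], pi[bin], log = TRUE)

  bb <- !bin
  if (any(bb)) {
    a <- pi[bb] / theta[bb]
    b <- (1 - pi[bb]) / theta[bb]
    t1 <- lbeta(x[bb] + a, n[bb] - x[bb] + b)
    t2 <- lbeta(a, b)
    val <- lchoose(n[bb], x[bb]) + t1 - t2
    # cancellation of the lbeta terms: escalate when they agree in their
    # leading digits beyond a relative gap of 1e-8, when their magnitude
    # alone makes the absolute rounding error exceed ~1e-12 (|t| > 1e4), or
    # when the result is non-finite
    big <- pmax(abs(t1), abs(t2))
    unstable <- !is.finite(val) | big > 1e4 |
      (abs(t1 - t2) < 1e-8 * big & big > 1)
    if (any(unstable)) {
      idx <- which(bb)[unstable]
      .diffad_env$product_fallbacks <- .diffad_env$product_fallbacks + length(idx)
      # group by shared parameter values so the exact product form runs on
      # cumulative sums rather than per-element loops
      key <- paste(pi[idx], theta[idx])
      for (grp in split(idx, key)) {
        i1 <- grp[1]
        out[grp] <- .bb_logpmf_product_vec(x[grp], n[grp], pi[i1], theta[i1])
      }
      out[which(bb)[!unstable]] <- val[!unstable]
    } else {
      out[bb] <- val
    }
  }
  if (log) out else exp(out)
}

#' Beta-binomial cumulative mass function
#'
#' Lower-tail cumulative mass `P(X <= x)` of the beta-binomial, by direct
#' summation of the PMF over `0..x`.
#'
#' @inheritParams dbetabinom
#' @return Numeric vector of cumulative probabilities.
#' @export
pbetabinom <- function(x, n, pi, theta) {
  .check_bb_params(pi, theta)
  m <- max(length(x), length(n), length(pi), length(theta))
  x <- rep_len(x, m); n <- rep_len(n, m)
  pi <- rep_len(pi, m); theta <- rep_len(theta, m)
  if (any(x < 0 | x > n)) stop("domain error: x must satisfy 0 <= x <= n")
  vapply(seq_len(m), function(i) {
    sum(dbetabinom(0:x[i], n[i], pi[i], theta[i], log = FALSE))
  }, numeric(1))
}

# difference of digammas psi(a + k) - psi(a), stable for large a where direct
# subtraction cancels; k integer >= 0
.dg_diff <- function(a, k) {
  m <- max(length(a), length(k))
  a <- rep_len(a, m); k <- rep_len(k, m)
  out <- digamma(a + k) - digamma(a)
  big <- a > 1e8 & k > 0
  if (any(big)) {
    for (i in which(big)) out[i] <- sum(1 / (a[i] + seq_len(k[i]) - 1))
  }
  out
}

# difference of trigammas psi'(a + k) - psi'(a), same stabilization
.tg_diff <- function(a, k) {
  m <- max(length(a), length(k))
  a <- rep_len(a, m); k <- rep_len(k, m)
  out <- trigamma(a + k) - trigamma(a)
  big <- a > 1e6 & k > 0
  if (any(big)) {
    for (i in which(big)) out[i] <- -sum(1 / (a[i] + seq_len(k[i]) - 1)^2)
  }
  out
}

# Per-observation first derivatives of the beta-binomial log-PMF with respect
# to (pi, theta), analytic. Returns list(dpi, dtheta), each length of x.
# Requires theta > 0 (callers clamp); uses digamma-difference identities
# psi(a+x)-psi(a) = sum_{k=0}^{x-1} 1/(a+k) which are the derivatives of the
# ascending-product form, so the expressions stay exact for extreme theta.
.bb_dlog <- function(x, n, pi, theta) {
  a <- pi / theta
  b <- (1 - pi) / theta
  dLa <- .dg_diff(a, x) - .dg_diff(a + b, n)
  dLb <- .dg_diff(b, n - x) - .dg_diff(a + b, n)
  list(
    dpi    = (dLa - dLb) / theta,
    dtheta = -(a * dLa + b * dLb) / theta
  )
}

# Second derivatives of the log-PMF wrt (pi, theta): list(d2pi, dpidtheta,
# d2theta), analytic via trigamma differences.
.bb_d2log <- function(x, n, pi, theta) {
  a <- pi / theta
  b <- (1 - pi) / theta
  dLa <- .dg_diff(a, x) - .dg_diff(a + b, n)
  dLb <- .dg_diff(b, n - x) - .dg_diff(a + b, n)
  Laa <- .tg_diff(a, x) - .tg_diff(a + b, n)
  Lbb <- .tg_diff(b, n - x) - .tg_diff(a + b, n)
  Lab <- -.tg_diff(a + b, n)
  th2 <- theta^2
  d2pi <- (Laa - 2 * Lab + Lbb) / th2
  dpidtheta <- (-a * (Laa - Lab) - b * (Lab - Lbb) - (dLa - dLb)) / th2
  d2theta <- (2 * (a * dLa + b * dLb) +
                a^2 * Laa + 2 * a * b * Lab + b^2 * Lbb) / th2
  list(d2pi = d2pi, dpidtheta = dpidtheta, d2theta = d2theta)
}

#' Gradient of a weighted beta-binomial log-likelihood
#'
#' Analytic partial derivatives of `sum(w * dbetabinom(x, n, pi, theta))`
#' with respect to `(pi, theta)`. At `theta = 0` the limit expressions of the
#' ascending-product form are used.
#'
#' @inheritParams dbetabinom
#' @param w Per-observation weights in \[0, 1\] (default all 1).
#' @return Named numeric vector `c(dpi = ..., dtheta = ...)`.
#' @export
betabinom_loglik_grad <- function(x, n, pi, theta, w = NULL) {
  .check_bb_params(pi, theta)
  if (length(pi) != 1 || length(theta) != 1)
    stop("pi and theta must be scalars")
  if (is.null(w)) w <- rep(1, length(x))
  if (any(w < 0 | w > 1)) stop("weights must be in [0, 1]")
  if (any(x < 0 | x > n)) stop("domain error: x must satisfy 0 <= x <= n")
  if (theta == 0) {
    # limits of the product-form derivatives at theta -> 0
    dpi <- sum(w * (x / pi - (n - x) / (1 - pi)))
    dth <- sum(w * (x * (x - 1) / (2 * pi) +
                      (n - x) * (n - x - 1) / (2 * (1 - pi)) -
                      n * (n - 1) / 2))
    return(c(dpi = dpi, dtheta = dth))
  }
  d <- .bb_dlog(x, n, pi, theta)
  c(dpi = sum(w * d$dpi), dtheta = sum(w * d$dtheta))
}

#' Number of product-form fallback evaluations so far
#'
#' Diagnostic counter of how many PMF evaluations were escalated from the
#' beta-function form to the exact log-product form because catastrophic
#' cancellation was detected.
#'
#' @param reset Reset the counter to zero after reading?
#' @return Integer count (invisibly when `reset = TRUE`).
#' @export
betabinom_fallback_count <- function(reset = FALSE) {
  cnt <- .diffad_env$product_fallbacks
  if (reset) {
    .diffad_env$product_fallbacks <- 0L
    return(invisible(cnt))
  }
  cnt
}

#' Random beta-binomial deviates
#'
#' Draws `x ~ Binomial(n, p)` with `p ~ Beta(pi/theta, (1-pi)/theta)`;
#' `theta = 0` degenerates to the binomial.
#'
#' @param n_draws Number of deviates.
#' @inheritParams dbetabinom
#' @return Integer vector of length `n_draws`.
#' @export
rbetabinom <- function(n_draws, n, pi, theta) {
  .check_bb_params(pi, theta)
  n <- rep_len(n, n_draws)
  pi <- rep_len(pi, n_draws)
  theta <- rep_len(theta, n_draws)
  p <- pi
  bb <- theta > 0 & pi > 0 & pi < 1
  if (any(bb)) {
    p[bb] <- stats::rbeta(sum(bb), pi[bb] / theta[bb], (1 - pi[bb]) / theta[bb])
  }
  stats::rbinom(n_draws, n, p)
}
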