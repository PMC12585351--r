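# Moment (Kleinman-style) starting values for the heterozygote component.
#
# For beta-binomial samples with unequal totals, the mean parameter is
# estimated as a weighted mean of per-sample reference fractions and the
# overdispersion from a weighted sum of squares Q. Weights are fixed at 1
# (Kleinman's ideal weights for theta = 0); the estimate only has to be good
# enough to seed numerical optimization, which refines it.

#' Moment estimates of beta-binomial parameters with unequal totals
#'
#' Computes starting values `(pi_hat, theta_hat)` for the heterozygote
#' beta-binomial component from per-sample reference counts and totals, using
#' weighted moment estimators suited to samples with differing total counts.
#' A non-positive or non-finite `theta_hat` is clamped to `theta_floor` and
#' flagged.
#'
#' @param x_r Per-sample reference-allele counts.
#' @param n Per-sample total allelic counts (>= 1).
#' @param w Per-sample weights; default all 1.
#' @param theta_floor Lower clamp for the overdispersion estimate.
#' @return A list with `pi_hat`, `theta_hat`, `q` (the weighted sum of
#'   squares), and `clamped` (logical: was `theta_hat` floored?).
#' @examples
#' kleinman_estimate(c(9, 1), c(10, 10))
#' @export
kleinman_estimate <- function(x_r, n, w = NULL, theta_floor = 1e-6) {
  if (length(x_r) < 2) stop("need at least 2 observations")
  if (all(n == 0)) stop("all totals are zero")
  keep <- n >= 1
  x_r <- x_r[keep]; n <- n[keep]
  if (is.null(w)) w <- rep(1, length(n)) else w <- w[keep]
  p_hat <- x_r / n
  sw <- sum(w)
  pi_hat <- sum(w * p_hat) / sw
  z <- 1 - w / sw
  q <- sum(w * (p_hat - pi_hat)^2)
  pv <- pi_hat * (1 - pi_hat)
  num <- pv * (sum(w * z) - sum(w * z / n))
  den <- q - pv * sum(w * z / n)
  theta_hat <- 1 / (num / den - 1)
  clamped <- FALSE
  if (!is.finite(theta_hat) || theta_hat <= 0) {
    theta_hat <- theta_floor
    clamped <- TRUE
  }
  list(pi_hat = min(max(pi_hat, 0), 1), theta_hat = theta_hat,
       q = q, clamped = clamped)
}
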