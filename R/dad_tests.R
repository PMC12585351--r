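# Per-SNP differential allelic dispersion (dAD) tests.
#
# The likelihood-ratio test contrasts the shared-dispersion mixture (null)
# with the cohort-specific-dispersion mixture (alternative); both are
# chi-square with 1 df under the null. The score test needs only the null
# fit: the six model parameters tau = (pi_het, rho_hom, rho_het_control,
# rho_het_case, phi_rr, phi_rv) are scored at the null estimate (both group
# dispersions at the shared fitted value), with the negative observed Hessian
# standing in for the Fisher information. Because the null fit is
# label-invariant, the per-sample score/Hessian contributions can be
# precomputed once and re-summed for every relabeling, which makes
# permutations cheap.

#' Likelihood-ratio test for differential allelic dispersion
#'
#' @param fit_null Shared-dispersion fit (see [fit_ase_mixture()] with
#'   `group_specific = FALSE`).
#' @param fit_alt Cohort-specific-dispersion fit on the identical samples.
#' @return A list of class `"dad_result"`: `lambda_lrt`, `p_dad`,
#'   `rho_control`, `rho_case`, `pi_het`, `n_het_control`, `n_het_case`,
#'   `median_n_control`, `median_n_case`, and `filter_flags` (fit flags of
#'   both models).
#' @export
dad_lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "ase_fit"), inherits(fit_alt, "ase_fit"))
  if (fit_null$model != "shared" || fit_alt$model != "group")
    stop("dad_lrt() expects a shared-dispersion null fit and a group-specific alternative fit")
  if (!identical(sort(fit_null$data$sample_id), sort(fit_alt$data$sample_id)))
    stop("the two fits must use identical sample sets")
  lambda <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (lambda < -1e-3 * (abs(fit_null$loglik) + 1))
    warning("alternative fit has materially lower likelihood than the null; check convergence")
  lambda <- max(lambda, 0)
  d <- fit_alt$data
  is_case <- d$group == "case"
  structure(list(
    lambda_lrt = lambda,
    p_dad = stats::pchisq(lambda, df = 1, lower.tail = FALSE),
    rho_control = fit_alt$rho_het[["control"]],
    rho_case = fit_alt$rho_het[["case"]],
    pi_het = fit_alt$pi_het,
    n_het_control = fit_alt$n_het[["control"]],
    n_het_case = fit_alt$n_het[["case"]],
    median_n_control = stats::median(d$n[!is_case]),
    median_n_case = stats::median(d$n[is_case]),
    filter_flags = unique(c(fit_null$flags, fit_alt$flags))
  ), class = "dad_result")
}

#' @export
print.dad_result <- function(x, ...) {
  cat(sprintf("dAD likelihood-ratio test: lambda = %.4f, P = %.4g\n",
              x$lambda_lrt, x$p_dad))
  cat(sprintf("  rho_het control %.4f vs case %.4f (pi_het %.4f)\n",
              x$rho_control, x$rho_case, x$pi_het))
  if (length(x$filter_flags)) cat("  flags:", paste(x$filter_flags, collapse = ", "), "\n")
  invisible(x)
}

# rho-scale first/second log-PMF derivative bundles for one component
.bb_derivs_rho <- function(x, n, pi, theta) {
  th <- max(theta, 1e-12)
  d1 <- .bb_dlog(x, n, pi, th)
  d2 <- .bb_d2log(x, n, pi, th)
  J <- (1 + th)^2           # dtheta/drho
  J2 <- 2 * (1 + th)^3      # d2theta/drho2
  list(dpi = d1$dpi,
       drho = d1$dtheta * J,
       d2pipi = d2$d2pi,
       d2pirho = d2$dpidtheta * J,
       d2rhorho = d2$d2theta * J^2 + d1$dtheta * J2)
}

#' Precompute per-sample score and Hessian contributions at the null fit
#'
#' Evaluates every per-sample quantity needed to assemble the score vector
#' and observed Hessian of the cohort-specific-dispersion model at the null
#' parameter estimate, for any assignment of samples to cohorts. Used by
#' [dad_score_test()] and the permutation machinery.
#'
#' @param fit_null A shared-dispersion `"ase_fit"`.
#' @return An opaque list consumed by [dad_score_test()] /
#'   [permutation_covariance()].
#' @export
score_pieces <- function(fit_null) {
  stopifnot(inherits(fit_null, "ase_fit"))
  if (fit_null$model != "shared")
    stop("the score test is evaluated at the shared-dispersion (null) fit")
  d <- fit_null$data
  x <- d$ref_count; n <- d$n
  se <- fit_null$se
  phi <- fit_null$phi
  pi_het <- fit_null$pi_het
  th_het <- fit_null$theta_het[[1]]
  th_hom <- fit_null$theta_hom

  lf <- .ase_comp_logpmf(x, n, se, pi_het, rep(th_het, length(x)), th_hom)
  lp <- sweep(lf, 2, log(pmax(phi, 1e-300)), "+")
  mx <- pmax(lp[, 1], lp[, 2], lp[, 3])
  logP <- mx + log(rowSums(exp(lp - mx)))
  e1 <- exp(lf[, 1] - logP); e2 <- exp(lf[, 2] - logP); e3 <- exp(lf[, 3] - logP)

  c2 <- .bb_derivs_rho(x, n, pi_het, th_het)
  c1 <- .bb_derivs_rho(x, n, 1 - se, th_hom)
  c3 <- .bb_derivs_rho(x, n, se, th_hom)

  A_pi <- phi[[2]] * e2 * c2$dpi
  A_hom <- phi[[1]] * e1 * c1$drho + phi[[3]] * e3 * c3$drho
  a_rho <- phi[[2]] * e2 * c2$drho
  A_rr <- e1 - e3
  A_rv <- e2 - e3

  B_pp <- phi[[2]] * e2 * (c2$d2pipi + c2$dpi^2)
  B_pr <- phi[[2]] * e2 * (c2$d2pirho + c2$dpi * c2$drho)
  B_p_rv <- e2 * c2$dpi
  B_hh <- phi[[1]] * e1 * (c1$d2rhorho + c1$drho^2) +
    phi[[3]] * e3 * (c3$d2rhorho + c3$drho^2)
  B_h_rr <- e1 * c1$drho - e3 * c3$drho
  B_h_rv <- -e3 * c3$drho
  B_rhorho <- phi[[2]] * e2 * (c2$d2rhorho + c2$drho^2)
  B_r_rv <- e2 * c2$drho

  # nuisance directions whose observed information is non-concave (parameter
  # effectively pinned at a boundary, e.g., theta_hom at its floor) are
  # excluded from the quadratic form; the decision is label-free, so it is
  # shared by all permutations of the same fit
  h_pp <- sum(B_pp - A_pi^2)
  h_hh <- sum(B_hh - A_hom^2)
  h_rrrr <- sum(-A_rr^2)
  h_rvrv <- sum(-A_rv^2)
  active <- c(pi = h_pp < 0, hom = h_hh < 0, rho_c = TRUE, rho_a = TRUE,
              rr = h_rrrr < 0, rv = h_rvrv < 0)

  list(
    S = length(x),
    sample_id = d$sample_id,
    is_case = d$group == "case",
    active = active,
    # label-free per-sample score contributions
    A = cbind(pi = A_pi, hom = A_hom, rho = a_rho, rr = A_rr, rv = A_rv),
    # label-free Hessian blocks (summed over all samples)
    h_pp = h_pp,
    h_ph = sum(-A_pi * A_hom),
    h_prr = sum(-A_pi * A_rr),
    h_prv = sum(B_p_rv - A_pi * A_rv),
    h_hh = h_hh,
    h_hrr = sum(B_h_rr - A_hom * A_rr),
    h_hrv = sum(B_h_rv - A_hom * A_rv),
    h_rrrr = h_rrrr,
    h_rrrv = sum(-A_rr * A_rv),
    h_rvrv = h_rvrv,
    # label-dependent per-sample Hessian contributions (summed per cohort)
    v_rho_pi = B_pr - A_pi * a_rho,
    v_rho_hom = -A_hom * a_rho,
    v_rho_rho = B_rhorho - a_rho^2,
    v_rho_rr = -a_rho * A_rr,
    v_rho_rv = B_r_rv - a_rho * A_rv
  )
}

# assemble full-sample gradient and Hessian in the parameter order
# (pi_het, rho_hom, rho_het_control, rho_het_case, phi_rr, phi_rv)
# from piece sums; `cs` holds case-masked column sums of
# cbind(A, v_rho_pi, v_rho_hom, v_rho_rho, v_rho_rr, v_rho_rv)
.score_assemble <- function(p, tot, cs) {
  g <- c(tot[1], tot[2], tot[3] - cs[3], cs[3], tot[4], tot[5])
  H <- matrix(0, 6, 6)
  H[1, 1] <- p$h_pp
  H[1, 2] <- H[2, 1] <- p$h_ph
  H[1, 3] <- H[3, 1] <- tot[6] - cs[6]
  H[1, 4] <- H[4, 1] <- cs[6]
  H[1, 5] <- H[5, 1] <- p$h_prr
  H[1, 6] <- H[6, 1] <- p$h_prv
  H[2, 2] <- p$h_hh
  H[2, 3] <- H[3, 2] <- tot[7] - cs[7]
  H[2, 4] <- H[4, 2] <- cs[7]
  H[2, 5] <- H[5, 2] <- p$h_hrr
  H[2, 6] <- H[6, 2] <- p$h_hrv
  H[3, 3] <- tot[8] - cs[8]
  H[4, 4] <- cs[8]
  H[3, 5] <- H[5, 3] <- tot[9] - cs[9]
  H[4, 5] <- H[5, 4] <- cs[9]
  H[3, 6] <- H[6, 3] <- tot[10] - cs[10]
  H[4, 6] <- H[6, 4] <- cs[10]
  H[5, 5] <- p$h_rrrr
  H[5, 6] <- H[6, 5] <- p$h_rrrv
  H[6, 6] <- p$h_rvrv
  list(g = g, H = H)
}

.score_contrib_matrix <- function(p) {
  cbind(p$A, p$v_rho_pi, p$v_rho_hom, p$v_rho_rho, p$v_rho_rr, p$v_rho_rv)
}

.score_singular <- function() {
  stop(structure(class = c("diffad_singular_hessian", "error", "condition"),
                 list(message = "numerically singular Hessian in score test",
                      call = NULL)))
}

.score_lambda <- function(p, tot, cs, cond_max = 1e12) {
  gh <- .score_assemble(p, tot, cs)
  act <- p$active
  negH <- -gh$H[act, act, drop = FALSE]
  g <- gh$g[act]
  if (!all(is.finite(negH))) .score_singular()
  # the statistic is invariant to symmetric rescaling; equilibrate so the
  # condition check measures genuine flatness rather than parameter scale
  dg <- diag(negH)
  if (any(dg <= 0)) .score_singular()
  s <- 1 / sqrt(dg)
  Hs <- negH * tcrossprod(s)
  if (rcond(Hs) < 1 / cond_max) .score_singular()
  gs <- g * s
  lambda <- drop(crossprod(gs, solve(Hs, gs)))
  list(lambda = lambda, g = gh$g, H = gh$H)
}

#' Score test for differential allelic dispersion
#'
#' Evaluates the efficient-score statistic of the cohort-specific-dispersion
#' model at the shared-dispersion (null) fit, using the negative observed
#' Hessian in place of the Fisher information. The null fit is unchanged by
#' relabeling, so the same fit can be scored under any assignment of samples
#' to cohorts (`labels`).
#'
#' @param fit_null Shared-dispersion `"ase_fit"` (fitted without using
#'   labels).
#' @param labels Optional logical vector (`TRUE` = case) or character vector
#'   (`"control"`/`"case"`) covering the fitted samples; defaults to the
#'   groups stored with the fit.
#' @param pieces Optionally, the precomputed [score_pieces()] of `fit_null`
#'   (avoids recomputation in loops).
#' @return A list of class `"dad_score"`: `lambda_st`, `p_value`,
#'   `score_vector` (efficient scores, scaled by `1/sqrt(S)`), and `hessian`.
#'   Signals an error of class `"diffad_singular_hessian"` when the negative
#'   Hessian's condition number exceeds `1e12`.
#' @export
dad_score_test <- function(fit_null, labels = NULL, pieces = NULL) {
  p <- if (is.null(pieces)) score_pieces(fit_null) else pieces
  is_case <- if (is.null(labels)) p$is_case
  else if (is.character(labels)) labels == "case"
  else as.logical(labels)
  if (length(is_case) != p$S)
    stop("labels must cover all ", p$S, " fitted samples")
  M <- .score_contrib_matrix(p)
  tot <- colSums(M)
  cs <- colSums(M[is_case, , drop = FALSE])
  res <- .score_lambda(p, tot, cs)
  structure(list(
    lambda_st = res$lambda,
    p_value = stats::pchisq(res$lambda, df = 1, lower.tail = FALSE),
    score_vector = res$g / sqrt(p$S),
    hessian = res$H
  ), class = "dad_score")
}

#' @export
print.dad_score <- function(x, ...) {
  cat(sprintf("dAD score test: lambda = %.4f, P = %.4g\n",
              x$lambda_st, x$p_value))
  invisible(x)
}
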