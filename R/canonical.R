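# Canonical differential allelic dispersion.
#
# A dAD hit is "canonical" when the case samples contributing most to the
# increased dispersion (most skewed allelic expression under the fitted
# heterozygote component) are also the most extreme in expression — the
# pattern produced by an allele-specific event such as a copy-number loss
# (skew couples to low expression) or gain (skew couples to high expression).
# Per SNP this is a Spearman rank correlation between the inverse minimal
# tail area of each heterozygous case sample and its total allelic count.

#' A sample's contribution to increased allelic dispersion
#'
#' The inverse of the sample's minimal tail area under the fitted
#' heterozygote beta-binomial component:
#' `1 / min(CMF(x), 1 - CMF(x) + PMF(x))`. The PMF term makes the upper tail
#' comparable to the lower one, which by convention includes the observed
#' value for discrete distributions. Larger values mean a more extreme
#' allelic skew.
#'
#' @param x Reference-allele count(s).
#' @param n Total allelic count(s), >= 1.
#' @param pi,theta Fitted heterozygote component parameters.
#' @return Numeric vector of contributions (>= 1, at most `1/PMF`).
#' @export
minimal_tail_contribution <- function(x, n, pi, theta) {
  stopifnot(all(n >= 1))
  cmf <- pbetabinom(x, n, pi, theta)
  pmf <- dbetabinom(x, n, pi, theta, log = FALSE)
  tail_area <- pmin(cmf, 1 - cmf + pmf)
  if (any(tail_area <= 0))
    stop("non-positive minimal tail area (numerical failure in CMF)")
  1 / tail_area
}

#' Canonical-dAD test at one SNP
#'
#' Spearman rank correlation between heterozygous case samples' inverse
#' minimal tail areas (under the cohort-specific fit's heterozygote
#' component, at the case dispersion) and their total allelic counts. Only
#' case samples classified heterozygous (highest posterior responsibility)
#' with a total count above `min_n` contribute; with fewer than 3 such
#' samples, or no variation in either variable, the result is missing.
#'
#' @param fit Cohort-specific-dispersion `"ase_fit"` (see
#'   [fit_ase_mixture()] with `group_specific = TRUE`).
#' @param min_n Minimum total allelic count for a sample to enter the test.
#' @return List of class `"canon_result"`: `corr_canon`, `p_canon`,
#'   `n_samples_used`, `missing`.
#' @export
canonical_test <- function(fit, min_n = 20) {
  stopifnot(inherits(fit, "ase_fit"))
  if (fit$model != "group")
    stop("canonical dAD uses the cohort-specific-dispersion fit")
  d <- fit$data
  r <- fit$responsibilities
  het <- r[, 2] > r[, 1] & r[, 2] > r[, 3]
  use <- het & d$group == "case" & d$n > min_n
  miss <- function() structure(list(corr_canon = NA_real_, p_canon = NA_real_,
                                    n_samples_used = sum(use), missing = TRUE),
                               class = "canon_result")
  if (sum(use) < 3) return(miss())
  contrib <- minimal_tail_contribution(d$ref_count[use], d$n[use],
                                       fit$pi_het, fit$theta_het[["case"]])
  n_use <- d$n[use]
  if (stats::sd(n_use) == 0 || stats::sd(contrib) == 0) return(miss())
  exact <- sum(use) <= 9 && !anyDuplicated(contrib) && !anyDuplicated(n_use)
  ct <- suppressWarnings(stats::cor.test(contrib, n_use, method = "spearman",
                                         exact = exact))
  structure(list(corr_canon = unname(ct$estimate), p_canon = ct$p.value,
                 n_samples_used = sum(use), missing = FALSE),
            class = "canon_result")
}

#' @export
print.canon_result <- function(x, ...) {
  if (x$missing) {
    cat("Canonical dAD: not assessable (too few qualifying case heterozygotes)\n")
  } else {
    cat(sprintf("Canonical dAD: Spearman rho = %.3f, P = %.4g (%d case heterozygotes)\n",
                x$corr_canon, x$p_canon, x$n_samples_used))
  }
  invisible(x)
}

#' Gene-level canonical-dAD summary
#'
#' Holm-adjusts the canonical P values across a gene's SNPs and reports the
#' SNP with the smallest adjusted P. Adjusted-P ties are broken by the larger
#' Lancaster weight, then lexicographically by SNP id.
#'
#' @param snp_ids SNP identifiers.
#' @param corr,p Per-SNP canonical correlations and P values (`NA` =
#'   missing).
#' @param weights Optional Lancaster weights used for tie-breaking.
#' @return List: `snp_id`, `corr_canon`, `p_canon` (Holm-adjusted), `missing`
#'   (all SNPs missing?).
#' @export
gene_canonical_summary <- function(snp_ids, corr, p, weights = NULL) {
  ok <- !is.na(p)
  if (!any(ok)) {
    return(list(snp_id = NA_character_, corr_canon = NA_real_,
                p_canon = NA_real_, missing = TRUE))
  }
  adj <- rep(NA_real_, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = "holm")
  if (is.null(weights)) weights <- rep(1, length(p))
  ord <- order(adj, -weights, snp_ids, na.last = TRUE)
  best <- ord[1]
  list(snp_id = snp_ids[best], corr_canon = corr[best], p_canon = adj[best],
       missing = FALSE)
}
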