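# Cohort-level metaparameters: sequencing error SE and inbreeding F_inbr.
#
# A simplified binomial genotype mixture (balanced heterozygotes, no
# overdispersion) is fit per SNP by EM with closed-form M-steps. SE is the
# pooled fraction of wrong-allele reads in the two homozygote components; the
# cohort values are medians over loci surviving quality filters.

#' Fit the simplified binomial genotype mixture at one SNP
#'
#' EM fit of a three-component binomial mixture with success probabilities
#' `(1 - SE, 0.5, SE)` for reference-homozygote, heterozygote and
#' variant-homozygote genotypes. All M-steps are closed form: the mixture
#' weights are mean responsibilities and `SE` is the responsibility-weighted
#' fraction of erroneous reads pooled over both homozygote components.
#'
#' @param x_r Reference-allele counts, one per sample.
#' @param x_v Variant-allele counts, one per sample.
#' @param se_floor Lower clamp on SE inside EM (avoids log(0)).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum EM iterations.
#' @return A list of class `"binmix_fit"` with `phi` (named genotype
#'   frequencies), `se`, `loglik`, `n_iter`, `converged`, and `f_inbr` (the
#'   per-locus inbreeding coefficient implied by `phi`).
#' @export
fit_binomial_mixture <- function(x_r, x_v, se_floor = 1e-6,
                                 tol = 1e-10, maxit = 500L) {
  n <- x_r + x_v
  keep <- n >= 1
  x <- x_r[keep]; n <- n[keep]
  if (length(x) < 2) stop("need >= 2 samples with positive total count")
  S <- length(x)

  # deterministic init: hard-assign genotypes by reference fraction
  frac <- x / n
  g0 <- ifelse(frac > 0.85, 1L, ifelse(frac < 0.15, 3L, 2L))
  phi <- pmax(tabulate(g0, 3L) / S, 1e-3); phi <- phi / sum(phi)
  hom <- g0 != 2L
  se <- if (any(hom)) {
    err <- sum(ifelse(g0[hom] == 1L, x_v[keep][hom], x[hom]))
    max(err / sum(n[hom]), se_floor)
  } else 0.002

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  r <- matrix(0, S, 3)
  repeat {
    it <- it + 1L
    lp <- cbind(log(phi[1]) + stats::dbinom(x, n, 1 - se, log = TRUE),
                log(phi[2]) + stats::dbinom(x, n, 0.5, log = TRUE),
                log(phi[3]) + stats::dbinom(x, n, se, log = TRUE))
    mx <- pmax(lp[, 1], lp[, 2], lp[, 3])
    pe <- exp(lp - mx)
    rs <- rowSums(pe)
    ll <- sum(mx + log(rs))
    r <- pe / rs
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (it >= maxit) break
    ll_old <- ll
    phi <- pmax(colMeans(r), 1e-12); phi <- phi / sum(phi)
    err <- sum(r[, 1] * (n - x)) + sum(r[, 3] * x)
    tot <- sum((r[, 1] + r[, 3]) * n)
    se <- if (tot > 0) min(max(err / tot, se_floor), 0.5) else se_floor
  }
  if (!converged) warning("binomial mixture EM did not converge in ", maxit, " iterations")
  names(phi) <- c("rr", "rv", "vv")
  structure(list(phi = phi, se = se, loglik = ll, n_iter = it,
                 converged = converged, f_inbr = inbreeding_coefficient(phi),
                 responsibilities = r),
            class = "binmix_fit")
}

#' Inbreeding coefficient implied by genotype frequencies
#'
#' `1 - observed heterozygosity / heterozygosity expected under panmixis`,
#' computed from mixture weights `(phi_rr, phi_rv, phi_vv)`. Equals 0 exactly
#' at Hardy-Weinberg proportions and 1 when heterozygotes are absent while
#' both homozygotes are present.
#'
#' @param phi Numeric length-3 vector of genotype frequencies (rr, rv, vv).
#' @return Scalar inbreeding coefficient.
#' @export
inbreeding_coefficient <- function(phi) {
  p <- phi[[1]] + phi[[2]] / 2
  q <- phi[[3]] + phi[[2]] / 2
  exp_het <- 2 * p * q
  if (exp_het <= 0) return(NA_real_)
  unname(1 - phi[[2]] / exp_het)
}

#' Estimate cohort sequencing error and inbreeding coefficient
#'
#' Fits the simplified binomial genotype mixture to every SNP, retains
#' high-quality loci (per-locus SE below `se_max`, more than `min_samples`
#' covering samples, median per-sample coverage at least `min_median_cov`,
#' minor-allele count fraction at least `min_maf`), and reports the cohort
#' sequencing error and inbreeding coefficient as medians over retained loci.
#'
#' @param counts Long-format data frame with columns `sample_id`, `snp_id`,
#'   `ref_count`, `var_count` (a `group` column is ignored here: the mixture
#'   has no group structure, so cases and controls are pooled by default).
#' @param se_max Retain loci with estimated SE below this value.
#' @param min_samples Retain loci covered (total count >= 1) by more than
#'   this many samples.
#' @param min_median_cov Minimum median per-sample total count.
#' @param min_maf Minimum minor-allele count fraction over all samples.
#' @param se_floor Floor applied to the cohort SE estimate; the default keeps
#'   EM numerically safe, and values below 0.002 are not recommended for
#'   downstream fits.
#' @return A list of class `"meta_params"` with `se`, `f_inbr`,
#'   `n_loci_used`, and `per_locus` (data frame of per-locus estimates and
#'   filter status).
#' @export
estimate_metaparameters <- function(counts, se_max = 0.035, min_samples = 40L,
                                    min_median_cov = 10, min_maf = 0.15,
                                    se_floor = 1e-6) {
  counts <- validate_allele_counts(counts, require_group = FALSE)
  snps <- split(counts, counts$snp_id)
  per <- lapply(names(snps), function(id) {
    d <- snps[[id]]
    n <- d$ref_count + d$var_count
    covered <- sum(n >= 1)
    if (covered < 2) {
      return(data.frame(snp_id = id, se = NA_real_, f_inbr = NA_real_,
                        n_covered = covered, median_cov = NA_real_,
                        maf = NA_real_, retained = FALSE))
    }
    fit <- fit_binomial_mixture(d$ref_count, d$var_count, se_floor = se_floor)
    maf <- min(sum(d$ref_count), sum(d$var_count)) / sum(n)
    med <- stats::median(n[n >= 1])
    retained <- fit$se < se_max && covered > min_samples &&
      med >= min_median_cov && maf >= min_maf
    data.frame(snp_id = id, se = fit$se, f_inbr = fit$f_inbr,
               n_covered = covered, median_cov = med, maf = maf,
               retained = retained)
  })
  per <- do.call(rbind, per)
  if (!any(per$retained)) stop("no locus passes the metaparameter filters")
  kept <- per[per$retained, ]
  structure(list(se = max(stats::median(kept$se), se_floor),
                 f_inbr = stats::median(kept$f_inbr),
                 n_loci_used = nrow(kept),
                 per_locus = per),
            class = "meta_params")
}

#' Construct metaparameters directly
#'
#' Bypass empirical estimation when the sequencing error and inbreeding
#' coefficient are known, e.g., from the sequencing technology and the
#' population under study.
#'
#' @param se Sequencing-error rate in (0, 0.5\].
#' @param f_inbr Inbreeding coefficient in \[-1, 1\]; 0 means panmixis.
#' @return A `"meta_params"` object.
#' @export
meta_params <- function(se, f_inbr = 0) {
  stopifnot(is.numeric(se), se > 0, se <= 0.5, f_inbr >= -1, f_inbr <= 1)
  structure(list(se = se, f_inbr = f_inbr, n_loci_used = 0L,
                 per_locus = NULL),
            class = "meta_params")
}

#' @export
print.meta_params <- function(x, ...) {
  cat("Cohort metaparameters\n")
  cat(sprintf("  sequencing error (SE): %.5f\n", x$se))
  cat(sprintf("  inbreeding (F_inbr):   %.4f\n", x$f_inbr))
  if (x$n_loci_used > 0)
    cat(sprintf("  estimated from %d retained loci\n", x$n_loci_used))
  else
    cat("  user-supplied\n")
  invisible(x)
}
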