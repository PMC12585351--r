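# SNP quality filters, SNP-to-gene assignment, and dependence-corrected
# Lancaster aggregation of per-SNP dAD P values.
#
# The Lancaster statistic T = sum_i qgamma(1 - p_i; shape = w_i/2, scale = 2)
# is chi-square with sum(w_i) df only for independent tests. For SNPs of one
# gene, whose allele counts may derive from the same reads or mRNA molecules,
# a moment-matched correction is applied: with the between-SNP covariances of
# the gamma-transformed P values estimated from shared-label permutations of
# the score test, c * T ~ chi-square(v) with c = v / E[T],
# v = 2 E[T]^2 / var(T), E[T] = sum(w), var(T) = 2 sum(w) + 2 sum_{i<j} Cov_ij.

#' Chi-square test of Hardy-Weinberg equilibrium with inbreeding
#'
#' Compares (possibly fractional, responsibility-summed) genotype counts to
#' the frequencies expected under Hardy-Weinberg equilibrium at the observed
#' allele frequency and a fixed cohort inbreeding coefficient (1 df).
#'
#' @param counts Length-3 vector of genotype counts (rr, rv, vv); fractional
#'   counts from EM responsibilities are fine.
#' @param f_inbr Cohort inbreeding coefficient.
#' @return List with `statistic`, `p_value`, `expected`.
#' @export
hwe_test <- function(counts, f_inbr = 0) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  N <- sum(counts)
  if (N <= 0) return(list(statistic = NA_real_, p_value = NA_real_,
                          expected = rep(NA_real_, 3)))
  p <- (counts[[1]] + counts[[2]] / 2) / N
  q <- 1 - p
  expected <- N * c(p^2 + f_inbr * p * q, 2 * p * q * (1 - f_inbr),
                    q^2 + f_inbr * p * q)
  use <- expected > 0
  stat <- sum((counts[use] - expected[use])^2 / expected[use])
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Per-SNP quality and goodness-of-fit filters
#'
#' Evaluates the four retention criteria applied before SNP-to-gene
#' combination: a sample median total allelic count of at least
#' `min_median_count` in both cohorts; an estimated number of heterozygotes
#' of at least `min_het` (12 autosomal, 8 X-chromosomal) in both cohorts; a
#' fitted heterozygote allelic bias inside `pi_bounds` (more extreme values
#' indicate a failed fit); and conformity to Hardy-Weinberg equilibrium
#' (chi-square P > 0.001 in both cohorts, at the cohort inbreeding
#' coefficient). Outlying samples take part in the HWE genotype counts but in
#' nothing else.
#'
#' @param snp_stats Data frame with one row per SNP and columns
#'   `median_n_control`, `median_n_case`, `n_het_control`, `n_het_case`,
#'   `pi_het`, `hwe_p_control`, `hwe_p_case`.
#' @param stratum `"autosomal"` or `"X"` (recycled): selects the heterozygote
#'   threshold.
#' @param min_median_count,pi_bounds,hwe_alpha Filter thresholds.
#' @param min_het_autosomal,min_het_x Heterozygote-count thresholds.
#' @return Data frame of logical columns `pass_median_count`, `pass_n_het`,
#'   `pass_pi_bounds`, `pass_hwe`, and their conjunction `overall`.
#' @export
apply_snp_filters <- function(snp_stats, stratum = "autosomal",
                              min_median_count = 4,
                              min_het_autosomal = 12, min_het_x = 8,
                              pi_bounds = c(0.05, 0.95), hwe_alpha = 0.001) {
  stratum <- rep_len(stratum, nrow(snp_stats))
  min_het <- ifelse(stratum == "X", min_het_x, min_het_autosomal)
  out <- data.frame(
    pass_median_count = snp_stats$median_n_control >= min_median_count &
      snp_stats$median_n_case >= min_median_count,
    pass_n_het = snp_stats$n_het_control >= min_het &
      snp_stats$n_het_case >= min_het,
    pass_pi_bounds = snp_stats$pi_het >= pi_bounds[1] &
      snp_stats$pi_het <= pi_bounds[2],
    pass_hwe = snp_stats$hwe_p_control > hwe_alpha &
      snp_stats$hwe_p_case > hwe_alpha
  )
  out$overall <- out$pass_median_count & out$pass_n_het &
    out$pass_pi_bounds & out$pass_hwe
  if (!is.null(snp_stats$snp_id)) out <- cbind(snp_id = snp_stats$snp_id, out)
  out
}

# category vocabulary, highest priority first
.annotation_priority <- c(exonic = 1L, utr = 2L, noncoding = 2L,
                          intronic = 3L, splice = 3L,
                          upstream = 4L, downstream = 4L)

#' Resolve SNP-to-gene assignment by annotation hierarchy
#'
#' A SNP annotated to several genes is assigned to the gene where it most
#' likely sits in processed mRNA, by the category hierarchy exonic >
#' UTR/noncoding-transcript > intronic/splice > up-/downstream. SNPs without
#' annotation, or tied between multiple genes at their best level, are
#' dropped.
#'
#' @param annotations Data frame with columns `snp_id`, `gene_id`,
#'   `category`; categories must be one of `exonic`, `utr`, `noncoding`,
#'   `intronic`, `splice`, `upstream`, `downstream`.
#' @return Data frame (`snp_id`, `gene_id`) with one row per retained SNP.
#' @export
resolve_gene_assignment <- function(annotations) {
  bad <- setdiff(unique(annotations$category), names(.annotation_priority))
  if (length(bad)) stop("unknown annotation categor(ies): ",
                        paste(bad, collapse = ", "))
  prio <- .annotation_priority[annotations$category]
  keep <- lapply(split(seq_len(nrow(annotations)), annotations$snp_id),
                 function(ix) {
    best <- ix[prio[ix] == min(prio[ix])]
    genes <- unique(annotations$gene_id[best])
    if (length(genes) != 1L) return(NULL)
    data.frame(snp_id = annotations$snp_id[ix[1]], gene_id = genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, keep)
  if (is.null(out)) out <- data.frame(snp_id = character(0),
                                      gene_id = character(0))
  rownames(out) <- NULL
  out
}

#' Lancaster weights for a gene's SNPs
#'
#' The raw weight of a SNP is the smaller cohort's reliability, the estimated
#' number of heterozygotes times the median total allelic count; weights are
#' rescaled to sum to twice the number of SNPs, which makes equally weighted
#' SNPs reduce the Lancaster statistic to Fisher's method.
#'
#' @param n_het_control,n_het_case Estimated heterozygote counts per SNP.
#' @param median_n_control,median_n_case Median total allelic counts per SNP.
#' @return Numeric weight vector summing to `2 * length(n_het_control)`.
#' @export
lancaster_weights <- function(n_het_control, n_het_case,
                              median_n_control, median_n_case) {
  raw <- pmin(n_het_control * median_n_control, n_het_case * median_n_case)
  if (any(raw <= 0)) stop("zero raw Lancaster weight (no heterozygotes or no coverage)")
  2 * length(raw) * raw / sum(raw)
}

#' Weighted Lancaster combination statistic
#'
#' `T = sum_i qgamma(1 - p_i; shape = w_i/2, scale = 2)`. With all weights 2
#' this is Fisher's `-2 sum log p_i`. P values of exactly 0 are floored at
#' `p_min` (the gamma quantile diverges at 0).
#'
#' @param p P values in (0, 1\].
#' @param w Positive weights.
#' @param p_min Floor applied to the P values.
#' @return The statistic (scalar).
#' @export
lancaster_statistic <- function(p, w, p_min = 1e-15) {
  stopifnot(length(p) == length(w), all(w > 0), all(p >= 0), all(p <= 1))
  p <- pmax(p, p_min)
  sum(stats::qgamma(p, shape = w / 2, scale = 2, lower.tail = FALSE))
}

#' Permutation configuration for the covariance correction
#'
#' @param n_iter Number of label permutations (the reference analysis used
#'   10,000; smaller values are fine for desk-scale data).
#' @param seed Optional seed; a fixed seed makes the permutation stream
#'   reproducible.
#' @param min_het_per_group A permutation is redone when either reassigned
#'   cohort contains at most this many putative heterozygotes.
#' @param max_redos Upper bound on total redraws before giving up.
#' @return A list of class `"perm_config"`.
#' @export
perm_config <- function(n_iter = 10000L, seed = NULL, min_het_per_group = 6L,
                        max_redos = 20L * n_iter) {
  stopifnot(n_iter >= 100L)
  structure(list(n_iter = as.integer(n_iter), seed = seed,
                 min_het_per_group = as.integer(min_het_per_group),
                 max_redos = as.integer(max_redos)),
            class = "perm_config")
}

#' Permutation-estimated covariance of gamma-transformed P values
#'
#' For one gene, repeatedly reassigns the control/case labels at random —
#' one shared reassignment per iteration for all the gene's SNPs, so that
#' correlation due to inter-SNP dependence survives while label-linked
#' biology is broken — and computes each SNP's score-test P value under the
#' reassignment (the null fits are label-invariant and reused). A permutation
#' is redone when either reassigned cohort holds at most
#' `config$min_het_per_group` putative heterozygotes or any SNP's Hessian is
#' numerically singular. Each P value is pushed through its SNP's
#' inverse-gamma map; the pairwise covariances of the transformed values are
#' summed with negative terms set to zero (negative inter-SNP dependence is
#' biologically implausible for counts from one transcript).
#'
#' @param pieces_list List of [score_pieces()] objects, one per SNP of the
#'   gene (sample ids are matched across SNPs).
#' @param w Lancaster weights, same order as `pieces_list`.
#' @param putative_het Named logical vector over the union of sample ids:
#'   is the sample a putative heterozygote (classified by its own cohort's
#'   mixture fit)?
#' The procedure's premise is that permutation P values are Uniform(0,1).
#' The default `calibration = "empirical"` enforces that exactly by
#' converting each SNP's permutation statistics to mid-rank P values within
#' the permutation set, so the covariance measures pure inter-SNP dependence;
#' `"chisq"` uses the asymptotic chi-square(1) P values directly, whose
#' finite-sample tail error otherwise inflates the covariance estimate.
#'
#' @param labels Named character vector of observed group labels over the
#'   union of sample ids.
#' @param config A [perm_config()].
#' @param calibration How permutation statistics become P values (see above).
#' @return List with `covar_sum`, `covar` (the SNP-by-SNP covariance matrix),
#'   `transformed` (iterations x SNPs matrix), `n_redos`.
#' @export
permutation_covariance <- function(pieces_list, w, putative_het, labels,
                                   config = perm_config(),
                                   calibration = c("empirical", "chisq")) {
  calibration <- match.arg(calibration)
  N <- length(pieces_list)
  stopifnot(N >= 1, length(w) == N)
  if (!is.null(config$seed)) set.seed(config$seed)
  samples <- names(labels)
  het <- putative_het[samples]
  # per-SNP contribution matrices and index of its samples in the union
  Ms <- lapply(pieces_list, .score_contrib_matrix)
  tots <- lapply(Ms, colSums)
  idx <- lapply(pieces_list, function(p) match(p$sample_id, samples))
  if (any(vapply(idx, anyNA, logical(1))))
    stop("score pieces contain samples missing from 'labels'")

  B <- config$n_iter
  lmat <- matrix(NA_real_, B, N)
  redos <- 0L
  b <- 1L
  obs <- unname(labels)
  while (b <= B) {
    perm_case <- sample(obs) == "case"
    ok <- sum(het & perm_case) > config$min_het_per_group &&
      sum(het & !perm_case) > config$min_het_per_group
    if (ok) {
      lams <- numeric(N)
      for (j in seq_len(N)) {
        cs <- colSums(Ms[[j]][perm_case[idx[[j]]], , drop = FALSE])
        lam <- tryCatch(
          .score_lambda(pieces_list[[j]], tots[[j]], cs)$lambda,
          diffad_singular_hessian = function(e) NA_real_)
        if (is.na(lam)) { ok <- FALSE; break }
        lams[j] <- lam
      }
    }
    if (ok) {
      lmat[b, ] <- lams
      b <- b + 1L
    } else {
      redos <- redos + 1L
      if (redos > config$max_redos)
        stop(structure(class = c("diffad_max_redos", "error", "condition"),
                       list(message = "permutation redo limit exceeded",
                            call = NULL)))
    }
  }
  pmat <- if (calibration == "empirical") {
    # mid-rank P values within the permutation set: exactly uniform marginals
    apply(lmat, 2, function(l) 1 - (rank(l) - 0.5) / B)
  } else {
    stats::pchisq(lmat, df = 1, lower.tail = FALSE)
  }
  tmat <- vapply(seq_len(N), function(j) {
    stats::qgamma(pmax(pmat[, j], 1e-15), shape = w[j] / 2, scale = 2,
                  lower.tail = FALSE)
  }, numeric(B))
  cv <- if (N > 1) stats::cov(tmat) else matrix(0, 1, 1)
  covar_sum <- if (N > 1) sum(pmax(cv[upper.tri(cv)], 0)) else 0
  list(covar_sum = covar_sum, covar = cv, transformed = tmat, n_redos = redos)
}

#' Dependence-corrected combined P value for one gene
#'
#' Moment-matched modified Lancaster combination: with `E[T] = sum(w)` and
#' `var(T) = 2 sum(w) + 2 covar_sum`, the scaled statistic `c * T` is
#' referred to a chi-square distribution with `v = 2 E[T]^2 / var(T)` degrees
#' of freedom, `c = v / E[T]`. With `covar_sum = 0` this reduces to the
#' independent Lancaster (and, at equal weights, Fisher) combination.
#'
#' @param p Per-SNP dAD P values (LRT, real labels).
#' @param w Lancaster weights.
#' @param covar_sum Summed pairwise covariances from
#'   [permutation_covariance()].
#' @param p_min Floor for the P values.
#' @return List of class `"gene_combined"`: `t_lan`, `c`, `v`, `covar_sum`,
#'   `p_gene`, `n_snps`.
#' @export
combine_gene <- function(p, w, covar_sum = 0, p_min = 1e-15) {
  t_lan <- lancaster_statistic(p, w, p_min = p_min)
  e_t <- sum(w)
  var_t <- 2 * sum(w) + 2 * covar_sum
  if (var_t <= 0) stop("non-positive variance of the Lancaster statistic")
  v <- 2 * e_t^2 / var_t
  cc <- v / e_t
  structure(list(t_lan = t_lan, c = cc, v = v, covar_sum = covar_sum,
                 p_gene = stats::pchisq(cc * t_lan, df = v, lower.tail = FALSE),
                 n_snps = length(p)),
            class = "gene_combined")
}

#' @export
print.gene_combined <- function(x, ...) {
  cat(sprintf("Modified Lancaster combination over %d SNP(s): T = %.3f, c = %.3f, v = %.2f, P = %.4g\n",
              x$n_snps, x$t_lan, x$c, x$v, x$p_gene))
  invisible(x)
}

#' Stratified Benjamini-Hochberg correction
#'
#' BH adjustment applied independently within each stratum (e.g., autosomal
#' and X-chromosomal genes, which constitute effectively different data
#' sets).
#'
#' @param p P values.
#' @param strata Stratum labels (recycled); `NULL` means a single stratum.
#' @return Adjusted P values, same order as `p`.
#' @export
fdr_correct <- function(p, strata = NULL) {
  if (is.null(strata)) return(stats::p.adjust(p, method = "BH"))
  strata <- rep_len(strata, length(p))
  out <- p
  for (s in unique(strata)) {
    ix <- strata == s
    out[ix] <- stats::p.adjust(p[ix], method = "BH")
  }
  out
}
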