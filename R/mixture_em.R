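# Three-component beta-binomial genotype mixture, fit by EM.
#
# Components (reference homozygote, heterozygote, variant homozygote) share a
# fixed sequencing error SE: homozygotes have mean 1-SE or SE with a common
# nuisance overdispersion theta_hom; heterozygotes have mean pi_het and
# overdispersion theta_het, either shared across cohorts (null model) or
# cohort-specific (differential model). The E-step is exact; the M-step is
# closed-form for the mixture weights and quasi-Newton (BFGS on logit/log
# transformed parameters, analytic gradients) for the continuous parameters.
# Because the heterozygote and homozygote parameters enter disjoint
# components, the continuous M-step separates into two smaller problems.

#' EM control settings for mixture fits
#'
#' @param tol Relative log-likelihood change below which EM stops.
#' @param maxit Maximum EM iterations.
#' @param optim_maxit Maximum BFGS iterations per M-step.
#' @param theta_floor Smallest overdispersion the M-step reports.
#' @return A list of control settings.
#' @export
em_control <- function(tol = 1e-8, maxit = 200L, optim_maxit = 100L,
                       theta_floor = 1e-8) {
  list(tol = tol, maxit = maxit, optim_maxit = optim_maxit,
       theta_floor = theta_floor)
}

# component log-PMF matrix (S x 3) at given parameters; th_het is a
# per-sample vector (group-expanded)
.ase_comp_logpmf <- function(x, n, se, pi_het, th_het, th_hom) {
  cbind(dbetabinom(x, n, 1 - se, th_hom),
        dbetabinom(x, n, pi_het, th_het),
        dbetabinom(x, n, se, th_hom))
}

.logit <- stats::qlogis
.expit <- stats::plogis

#' Fit the beta-binomial genotype mixture at one SNP
#'
#' Fits the three-component genotype mixture to per-sample allele counts by
#' EM, with the sequencing error fixed at the cohort value. With
#' `group_specific = FALSE` the heterozygote overdispersion is shared between
#' cohorts (the null model of the dAD test); with `group_specific = TRUE`
#' control and case samples get separate heterozygote overdispersions while
#' all other parameters remain shared (the alternative model).
#'
#' If the accepted heterozygote component is bimodal
#' (`theta_het > max(pi_het, 1 - pi_het)`), the fit is rerun with the
#' heterozygote overdispersion reparameterized so the unimodality constraint
#' holds by construction, and the result is flagged `constrained_refit`.
#'
#' @param data Data frame with columns `ref_count`, `var_count`, and (when
#'   `group_specific` or outlier bookkeeping is wanted) `group` with values
#'   `"control"`/`"case"`; an optional `sample_id` column is carried through.
#' @param se Fixed cohort sequencing-error rate (see
#'   [estimate_metaparameters()]).
#' @param group_specific Fit cohort-specific heterozygote overdispersion?
#' @param exclude Character vector of `sample_id`s to leave out of the fit
#'   (e.g., flagged outliers).
#' @param init Optional warm-start list with elements `pi_het`, `theta_het`
#'   (length 1 or 2), `theta_hom`, `phi`.
#' @param control See [em_control()].
#' @return An object of class `"ase_fit"`: a list with genotype frequencies
#'   `phi`, `pi_het`, `theta_het` (named `shared` or `control`/`case`),
#'   `theta_hom`, the equivalent `rho_het`/`rho_hom`, `se`, `loglik`,
#'   `responsibilities`, per-group heterozygote counts `n_het`, and status
#'   flags.
#' @examples
#' cfg <- sim_config(n_control = 60, n_case = 60, seed = 1)
#' snp <- simulate_snp(cfg)
#' fit <- fit_ase_mixture(snp, se = cfg$se)
#' fit
#' @export
fit_ase_mixture <- function(data, se, group_specific = FALSE, exclude = NULL,
                            init = NULL, control = em_control()) {
  stopifnot(se > 0, se < 0.5)
  if (is.null(data$sample_id)) data$sample_id <- paste0("s", seq_len(nrow(data)))
  if (!is.null(exclude)) data <- data[!(data$sample_id %in% exclude), , drop = FALSE]
  n_all <- data$ref_count + data$var_count
  data <- data[n_all >= 1, , drop = FALSE]
  x <- data$ref_count
  n <- data$ref_count + data$var_count
  S <- length(x)
  if (S < 2) stop("need >= 2 non-excluded samples with positive total count")
  if (is.null(data$group)) {
    if (group_specific) stop("group_specific fit requires a 'group' column")
    is_case <- rep(FALSE, S)
  } else {
    is_case <- data$group == "case"
  }

  flags <- character(0)

  # --- initialization ------------------------------------------------------
  if (is.null(init)) {
    frac <- x / n
    putative_het <- frac >= 0.15 & frac <= 0.85
    g0 <- ifelse(frac > 0.85, 1L, ifelse(frac < 0.15, 3L, 2L))
    phi <- pmax(tabulate(g0, 3L) / S, 1e-3); phi <- phi / sum(phi)
    if (sum(putative_het) >= 2) {
      mom <- kleinman_estimate(x[putative_het], n[putative_het])
      pi_het <- min(max(mom$pi_hat, 0.02), 0.98)
      th0 <- min(max(mom$theta_hat, 1e-4), 2)
    } else {
      pi_het <- 0.5; th0 <- 0.01
      flags <- c(flags, "few_putative_heterozygotes")
    }
    th_het <- if (group_specific) c(control = th0, case = th0) else c(shared = th0)
    th_hom <- 0.005
  } else {
    phi <- init$phi
    pi_het <- min(max(init$pi_het, 0.02), 0.98)
    th0 <- init$theta_het
    th_het <- if (group_specific) {
      if (length(th0) == 2) c(control = th0[[1]], case = th0[[2]])
      else c(control = th0[[1]], case = th0[[1]])
    } else c(shared = if (length(th0) == 2) mean(unlist(th0)) else th0[[1]])
    th_hom <- init$theta_hom
  }

  res <- .ase_em_loop(x, n, is_case, se, phi, pi_het, th_het, th_hom,
                      group_specific, control, constrained = FALSE)

  # --- bimodality-constrained refit ---------------------------------------
  lim <- max(res$pi_het, 1 - res$pi_het)
  if (any(res$theta_het > lim + 1e-12)) {
    res <- .ase_em_loop(x, n, is_case, se, res$phi,
                        res$pi_het, pmin(res$theta_het, 0.95 * lim),
                        res$theta_hom, group_specific, control,
                        constrained = TRUE)
    res$constrained_refit <- TRUE
  } else {
    res$constrained_refit <- FALSE
  }

  r <- res$responsibilities
  n_het <- c(control = sum(r[!is_case, 2]), case = sum(r[is_case, 2]))
  if (sum(r[, 2]) < 1e-3) flags <- c(flags, "het_unidentifiable")
  if (any(res$theta_het <= control$theta_floor * 10) ||
      res$theta_hom <= control$theta_floor * 10)
    flags <- c(flags, "theta_at_floor")
  if (!res$converged) flags <- c(flags, "not_converged")

  structure(list(
    phi = stats::setNames(res$phi, c("rr", "rv", "vv")),
    pi_het = res$pi_het,
    theta_het = res$theta_het,
    rho_het = theta_to_rho(res$theta_het),
    theta_hom = res$theta_hom,
    rho_hom = theta_to_rho(res$theta_hom),
    se = se,
    loglik = res$loglik,
    n_iter = res$n_iter,
    converged = res$converged,
    constrained_refit = res$constrained_refit,
    responsibilities = r,
    n_het = n_het,
    flags = unique(c(flags, res$flags)),
    model = if (group_specific) "group" else "shared",
    data = data.frame(sample_id = data$sample_id, ref_count = x,
                      var_count = n - x, n = n,
                      group = if (is.null(data$group)) NA_character_ else data$group,
                      stringsAsFactors = FALSE),
    excluded = if (is.null(exclude)) character(0) else exclude
  ), class = "ase_fit")
}

# EM main loop. th_het is a named vector (shared, or control/case). When
# constrained = TRUE the heterozygote M-step optimizes u with
# theta = max(pi, 1-pi) * plogis(u), enforcing unimodality by construction.
.ase_em_loop <- function(x, n, is_case, se, phi, pi_het, th_het, th_hom,
                         group_specific, control, constrained) {
  S <- length(x)
  flags <- character(0)
  ll_old <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0L
  tf <- control$theta_floor
  r <- matrix(1 / 3, S, 3)
  th_sample <- function(th) if (group_specific) ifelse(is_case, th[["case"]], th[["control"]]) else rep(th[[1]], S)

  repeat {
    it <- it + 1L
    lp <- .ase_comp_logpmf(x, n, se, pi_het, th_sample(th_het), th_hom)
    lp <- sweep(lp, 2, log(pmax(phi, 1e-300)), "+")
    mx <- pmax(lp[, 1], lp[, 2], lp[, 3])
    pe <- exp(lp - mx)
    rs <- rowSums(pe)
    ll <- sum(mx + log(rs))
    r <- pe / rs
    if (ll < ll_old - 1e-6 * (abs(ll_old) + 1)) flags <- c(flags, "loglik_decrease")
    if (is.finite(ll_old) && abs(ll - ll_old) <= control$tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (it >= control$maxit) break
    ll_old <- ll

    # M-step: mixture weights
    phi <- pmax(colMeans(r), 1e-12); phi <- phi / sum(phi)

    # M-step: heterozygote parameters
    w2 <- r[, 2]
    if (sum(w2) > 1e-8) {
      if (!constrained) {
        het <- .mstep_het(x, n, is_case, w2, pi_het, th_het, group_specific,
                          control$optim_maxit, tf)
      } else {
        het <- .mstep_het_constrained(x, n, is_case, w2, pi_het, th_het,
                                      group_specific, control$optim_maxit, tf)
      }
      pi_het <- het$pi_het; th_het <- het$th_het
    }

    # M-step: homozygote nuisance overdispersion
    w13 <- r[, c(1, 3)]
    if (sum(w13) > 1e-8) {
      th_hom <- .mstep_hom(x, n, se, w13, th_hom, control$optim_maxit, tf)
    }
  }

  list(phi = phi, pi_het = pi_het, theta_het = th_het, theta_hom = th_hom,
       loglik = ll, n_iter = it, converged = converged,
       responsibilities = r, flags = unique(flags))
}

# unconstrained heterozygote M-step on (logit pi, log theta[, log theta]) with
# analytic gradients
.mstep_het <- function(x, n, is_case, w, pi_het, th_het, group_specific,
                       optim_maxit, tf) {
  clamp <- function(lt) exp(pmin(pmax(lt, -30), 12))
  if (group_specific) {
    par0 <- c(.logit(pi_het), log(pmax(th_het[["control"]], tf)),
              log(pmax(th_het[["case"]], tf)))
    fn <- function(p) {
      pi <- .expit(p[1]); th <- clamp(p[2:3])
      -sum(w * dbetabinom(x, n, pi, ifelse(is_case, th[2], th[1])))
    }
    gr <- function(p) {
      pi <- .expit(p[1]); th <- clamp(p[2:3])
      ths <- ifelse(is_case, th[2], th[1])
      d <- .bb_dlog(x, n, pi, pmax(ths, 1e-12))
      -c(sum(w * d$dpi) * pi * (1 - pi),
         sum(w[!is_case] * d$dtheta[!is_case]) * th[1],
         sum(w[is_case] * d$dtheta[is_case]) * th[2])
    }
  } else {
    par0 <- c(.logit(pi_het), log(pmax(th_het[[1]], tf)))
    fn <- function(p) {
      -sum(w * dbetabinom(x, n, .expit(p[1]), clamp(p[2])))
    }
    gr <- function(p) {
      pi <- .expit(p[1]); th <- clamp(p[2])
      d <- .bb_dlog(x, n, pi, max(th, 1e-12))
      -c(sum(w * d$dpi) * pi * (1 - pi), sum(w * d$dtheta) * th)
    }
  }
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = optim_maxit, reltol = 1e-10))
  pi_new <- .expit(opt$par[1])
  th_new <- pmax(clamp(opt$par[-1]), tf)
  names(th_new) <- names(th_het)
  list(pi_het = pi_new, th_het = th_new)
}

# constrained heterozygote M-step: theta = max(pi, 1-pi) * plogis(u) keeps
# the component unimodal; numerical gradient (the max() kink makes the
# analytic chain rule piecewise, and this path is rare)
.mstep_het_constrained <- function(x, n, is_case, w, pi_het, th_het,
                                   group_specific, optim_maxit, tf) {
  lim0 <- max(pi_het, 1 - pi_het)
  to_u <- function(th) .logit(min(max(th / lim0, 1e-6), 1 - 1e-6))
  if (group_specific) {
    par0 <- c(.logit(pi_het), to_u(th_het[["control"]]), to_u(th_het[["case"]]))
    fn <- function(p) {
      pi <- .expit(p[1]); lim <- max(pi, 1 - pi)
      th <- lim * .expit(p[2:3])
      -sum(w * dbetabinom(x, n, pi, pmax(ifelse(is_case, th[2], th[1]), tf)))
    }
  } else {
    par0 <- c(.logit(pi_het), to_u(th_het[[1]]))
    fn <- function(p) {
      pi <- .expit(p[1]); lim <- max(pi, 1 - pi)
      -sum(w * dbetabinom(x, n, pi, max(lim * .expit(p[2]), tf)))
    }
  }
  opt <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = optim_maxit, reltol = 1e-10))
  pi_new <- .expit(opt$par[1])
  lim <- max(pi_new, 1 - pi_new)
  th_new <- pmax(lim * .expit(opt$par[-1]), tf)
  names(th_new) <- names(th_het)
  list(pi_het = pi_new, th_het = th_new)
}

# homozygote M-step: single log-theta, both homozygote components; log-theta
# is clamped to [-30, 12] inside the objective so optimizer excursions on the
# flat shoulders cannot overflow
.mstep_hom <- function(x, n, se, w13, th_hom, optim_maxit, tf) {
  fn <- function(lt) {
    th <- exp(min(max(lt, -30), 12))
    -sum(w13[, 1] * dbetabinom(x, n, 1 - se, th)) -
      sum(w13[, 2] * dbetabinom(x, n, se, th))
  }
  gr <- function(lt) {
    th <- max(exp(min(max(lt, -30), 12)), 1e-12)
    d1 <- .bb_dlog(x, n, 1 - se, th)
    d3 <- .bb_dlog(x, n, se, th)
    -(sum(w13[, 1] * d1$dtheta) + sum(w13[, 2] * d3$dtheta)) * th
  }
  opt <- stats::optim(log(max(th_hom, tf)), fn, gr, method = "BFGS",
                      control = list(maxit = optim_maxit, reltol = 1e-10))
  min(max(exp(min(max(opt$par, -30), 12)), tf), 1e5)
}

#' Leave-one-out outlier detection for one cohort
#'
#' Fits the shared-dispersion mixture on one cohort's samples, refits leaving
#' out each sample in turn (warm-started from the full fit), and flags
#' samples whose deletion changes the heterozygote mean or overdispersion
#' estimate by more than `threshold` sample standard deviations of the
#' respective delta series. When a delta series has zero standard deviation
#' (exchangeable samples), no sample is flagged on that parameter.
#'
#' @param data One cohort's rows of the allele-count table (columns
#'   `sample_id`, `ref_count`, `var_count`).
#' @param se Fixed cohort sequencing-error rate.
#' @param threshold Flagging threshold in sample standard deviations.
#' @param control See [em_control()].
#' @return A list of class `"outlier_report"`: `outliers` (sample ids),
#'   `deltas` (per-sample data frame), `threshold`, and the full-cohort
#'   `fit`.
#' @export
detect_outliers <- function(data, se, threshold = 5, control = em_control()) {
  if (is.null(data$sample_id)) data$sample_id <- paste0("s", seq_len(nrow(data)))
  data <- data[data$ref_count + data$var_count >= 1, , drop = FALSE]
  if (nrow(data) < 3) stop("outlier detection needs >= 3 samples")
  full <- fit_ase_mixture(data, se, group_specific = FALSE, control = control)
  ids <- full$data$sample_id
  if (length(ids) < 3) stop("outlier detection needs >= 3 fitted samples")
  warm <- list(pi_het = full$pi_het, theta_het = full$theta_het,
               theta_hom = full$theta_hom, phi = full$phi)
  deltas <- vapply(ids, function(j) {
    fj <- fit_ase_mixture(data, se, group_specific = FALSE, exclude = j,
                          init = warm, control = control)
    c(full$pi_het - fj$pi_het, full$theta_het[[1]] - fj$theta_het[[1]])
  }, numeric(2))
  d_pi <- deltas[1, ]; d_th <- deltas[2, ]
  # deviations are centered: a common offset shared by all deletion deltas
  # carries no influence information, and exchangeable samples (zero spread)
  # must produce no flags
  sd_pi <- stats::sd(d_pi); sd_th <- stats::sd(d_th)
  flag <- rep(FALSE, length(ids))
  if (is.finite(sd_pi) && sd_pi > 1e-12)
    flag <- flag | abs(d_pi - mean(d_pi)) > threshold * sd_pi
  if (is.finite(sd_th) && sd_th > 1e-12)
    flag <- flag | abs(d_th - mean(d_th)) > threshold * sd_th
  structure(list(outliers = ids[flag],
                 deltas = data.frame(sample_id = ids, delta_pi = d_pi,
                                     delta_theta = d_th, flagged = flag,
                                     row.names = NULL),
                 threshold = threshold, fit = full),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Leave-one-out outlier report (threshold %.1f SD): %d flagged of %d samples\n",
              x$threshold, length(x$outliers), nrow(x$deltas)))
  if (length(x$outliers)) cat("  ", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

# ---- ase_fit S3 methods ----------------------------------------------------

#' @export
print.ase_fit <- function(x, ...) {
  cat(sprintf("Beta-binomial genotype mixture (%s heterozygote dispersion)\n",
              if (x$model == "group") "cohort-specific" else "shared"))
  cat(sprintf("  samples: %d (excluded: %d)   log-likelihood: %.3f\n",
              nrow(x$data), length(x$excluded), x$loglik))
  cat(sprintf("  phi: rr %.3f  rv %.3f  vv %.3f\n",
              x$phi[["rr"]], x$phi[["rv"]], x$phi[["vv"]]))
  cat(sprintf("  pi_het (allelic bias): %.4f\n", x$pi_het))
  rho <- x$rho_het
  cat("  rho_het (allelic dispersion):",
      paste(sprintf("%s %.4f", names(rho), rho), collapse = "  "), "\n")
  cat(sprintf("  rho_hom: %.5f   SE (fixed): %.5f\n", x$rho_hom, x$se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ase_fit <- function(object, ...) {
  th <- object$theta_het
  out <- c(phi_rr = object$phi[["rr"]], phi_rv = object$phi[["rv"]],
           phi_vv = object$phi[["vv"]], pi_het = object$pi_het)
  rho <- theta_to_rho(th)
  names(rho) <- paste0("rho_het_", names(th))
  c(out, rho, rho_hom = object$rho_hom)
}

#' @export
logLik.ase_fit <- function(object, ...) {
  df <- 3 + length(object$theta_het) + 1  # phi (2 free) + pi + thetas + theta_hom
  structure(object$loglik, df = df, nobs = nrow(object$data), class = "logLik")
}

#' @export
summary.ase_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ase_fit")
}

#' @export
print.summary.ase_fit <- function(x, ...) {
  print(x$fit)
  r <- x$fit$responsibilities
  map <- apply(r, 1, which.max)
  cat("  MAP genotype counts: rr", sum(map == 1), " rv", sum(map == 2),
      " vv", sum(map == 3), "\n")
  cat("  estimated heterozygotes: control", round(x$fit$n_het[["control"]], 1),
      " case", round(x$fit$n_het[["case"]], 1), "\n")
  invisible(x)
}

#' Posterior genotype responsibilities for new counts
#'
#' @param object An `"ase_fit"`.
#' @param newdata Data frame with `ref_count`, `var_count`, and (for
#'   cohort-specific fits) `group`; defaults to the fitted data.
#' @param ... Unused.
#' @return Matrix of posterior probabilities with columns `rr`, `rv`, `vv`.
#' @export
predict.ase_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  x <- d$ref_count; n <- d$ref_count + d$var_count
  th <- object$theta_het
  ths <- if (object$model == "group") {
    ifelse(d$group == "case", th[["case"]], th[["control"]])
  } else rep(th[[1]], length(x))
  lp <- .ase_comp_logpmf(x, n, object$se, object$pi_het, ths, object$theta_hom)
  lp <- sweep(lp, 2, log(pmax(object$phi, 1e-300)), "+")
  mx <- pmax(lp[, 1], lp[, 2], lp[, 3])
  pe <- exp(lp - mx)
  out <- pe / rowSums(pe)
  colnames(out) <- c("rr", "rv", "vv")
  out
}

#' Simulate allele counts from a fitted mixture
#'
#' Draws genotypes from the fitted frequencies and counts from the fitted
#' component distributions at the observed per-sample totals.
#'
#' @param object An `"ase_fit"`.
#' @param nsim Number of simulated data sets.
#' @param seed Optional seed passed to [set.seed()].
#' @param ... Unused.
#' @return A list of `nsim` data frames shaped like the fitted data.
#' @export
simulate.ase_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  S <- nrow(d)
  th <- object$theta_het
  lapply(seq_len(nsim), function(k) {
    g <- sample.int(3, S, replace = TRUE, prob = object$phi)
    ths <- if (object$model == "group") {
      ifelse(d$group == "case", th[["case"]], th[["control"]])
    } else rep(th[[1]], S)
    pi_g <- cbind(1 - object$se, object$pi_het, object$se)[cbind(1, g)]
    th_g <- ifelse(g == 2, ths, object$theta_hom)
    x <- rbetabinom(S, d$n, pi_g, th_g)
    data.frame(sample_id = d$sample_id, ref_count = x, var_count = d$n - x,
               group = d$group, genotype = c("rr", "rv", "vv")[g],
               stringsAsFactors = FALSE)
  })
}
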