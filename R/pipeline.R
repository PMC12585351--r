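# End-to-end differential allelic dispersion pipeline:
# metaparameter estimation -> per-SNP mixture fits and LRT (with optional
# leave-one-out outlier handling) -> quality/HWE filters -> SNP-to-gene
# assignment -> permutation-corrected Lancaster combination -> canonical dAD
# -> stratified BH correction.

#' Pipeline configuration
#'
#' @param se,f_inbr Metaparameters. `NULL` (default) estimates them from the
#'   data via [estimate_metaparameters()]; supplying `se` bypasses
#'   estimation (recommended not below 0.002).
#' @param prevalence_k Minimum number of covering samples per SNP.
#' @param outlier_detection Run leave-one-out outlier detection per cohort?
#'   Computationally heavy (one refit per sample); outliers are excluded from
#'   every fit and test but kept for the HWE filter.
#' @param outlier_threshold Flagging threshold in sample SDs.
#' @param permutations Label permutations per multi-SNP gene.
#' @param min_het_per_group Permutation redo threshold on putative
#'   heterozygotes.
#' @param min_median_count,min_het_autosomal,min_het_x,pi_bounds,hwe_alpha
#'   SNP filter thresholds (see [apply_snp_filters()]).
#' @param x_genes Character vector of X-chromosomal gene ids (separate
#'   stratum, lower heterozygote threshold, female samples only).
#' @param female_samples Sample ids to use for X-chromosomal SNPs; `NULL`
#'   uses all samples.
#' @param canonical_min_n Minimum total count for the canonical-dAD test.
#' @param seed Seed for the permutation stream (and any tie-breaking).
#' @param verbose Emit per-stage messages?
#' @return List of class `"ad_config"`.
#' @export
ad_config <- function(se = NULL, f_inbr = NULL, prevalence_k = 10L,
                      outlier_detection = FALSE, outlier_threshold = 5,
                      permutations = 10000L, min_het_per_group = 6L,
                      min_median_count = 4, min_het_autosomal = 12,
                      min_het_x = 8, pi_bounds = c(0.05, 0.95),
                      hwe_alpha = 0.001, x_genes = character(0),
                      female_samples = NULL, canonical_min_n = 20,
                      seed = NULL, verbose = FALSE) {
  structure(as.list(environment()), class = "ad_config")
}

#' Run the full differential allelic dispersion analysis
#'
#' @param counts Long-format allele-count table (see
#'   [validate_allele_counts()]).
#' @param annotations SNP-to-gene annotation table (`snp_id`, `gene_id`,
#'   `category`).
#' @param config An [ad_config()].
#' @return Object of class `"dad_run"`: `snp` (per-SNP results with an
#'   explicit disposition for every input SNP), `gene` (per-gene combined
#'   results), `meta` (the metaparameters used), and `log` (per-stage
#'   counts).
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_config(n_control = 60, n_case = 60,
#'                                   rho_het_control = 0.05),
#'                        n_null = 2, n_dad = 1, seed = 1)
#' res <- run_pipeline(sim$counts, sim$annotations,
#'                     ad_config(se = 0.002, permutations = 200, seed = 1))
#' res
#' }
#' @export
run_pipeline <- function(counts, annotations, config = ad_config()) {
  stopifnot(inherits(config, "ad_config"))
  counts <- validate_allele_counts(counts)
  log <- list(n_snps_input = length(unique(counts$snp_id)),
              n_samples = length(unique(counts$sample_id)))
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  if (!is.null(config$seed)) set.seed(config$seed)

  # ---- stage: prevalence filter ------------------------------------------
  counts <- prevalence_filter(counts, k = config$prevalence_k)
  snp_ids_all <- unique(counts$snp_id)
  log$n_snps_prevalent <- length(snp_ids_all)
  say("prevalence filter retained ", log$n_snps_prevalent, " of ",
      log$n_snps_input, " SNPs")
  if (!nrow(counts)) stop("stage prevalence_filter: no SNP left")

  # ---- stage: metaparameters ---------------------------------------------
  meta <- if (is.null(config$se)) {
    tryCatch(estimate_metaparameters(counts),
             error = function(e) stop("stage metaparameters: ",
                                      conditionMessage(e)))
  } else {
    meta_params(config$se, if (is.null(config$f_inbr)) 0 else config$f_inbr)
  }
  if (!is.null(config$f_inbr)) meta$f_inbr <- config$f_inbr
  say(sprintf("metaparameters: SE = %.5f, F_inbr = %.4f", meta$se, meta$f_inbr))

  # ---- stage: gene assignment --------------------------------------------
  assignment <- resolve_gene_assignment(annotations)
  gene_of <- stats::setNames(assignment$gene_id, assignment$snp_id)
  stratum_of <- function(gene) {
    if (gene %in% config$x_genes) "X" else "autosomal"
  }
  log$n_snps_assigned <- sum(snp_ids_all %in% names(gene_of))

  # ---- stage: per-SNP fits and tests -------------------------------------
  slices <- split(counts, counts$snp_id)
  snp_rows <- list()
  snp_objects <- list()
  putative_het <- list()
  for (id in snp_ids_all) {
    d <- slices[[id]]
    gene <- if (id %in% names(gene_of)) gene_of[[id]] else NA_character_
    stratum <- if (is.na(gene)) "autosomal" else stratum_of(gene)
    if (stratum == "X" && !is.null(config$female_samples))
      d <- d[d$sample_id %in% config$female_samples, , drop = FALSE]
    row <- data.frame(snp_id = id, gene_id = gene, stratum = stratum,
                      disposition = "analyzed", pi_het = NA_real_,
                      rho_control = NA_real_, rho_case = NA_real_,
                      lambda_lrt = NA_real_, p_dad = NA_real_,
                      n_het_control = NA_real_, n_het_case = NA_real_,
                      median_n_control = NA_real_, median_n_case = NA_real_,
                      hwe_p_control = NA_real_, hwe_p_case = NA_real_,
                      n_outliers = 0L, corr_canon = NA_real_,
                      p_canon = NA_real_, stringsAsFactors = FALSE)
    res <- tryCatch({
      .analyze_snp(d, meta, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$disposition <- paste0("fit_error: ", conditionMessage(res))
      snp_rows[[id]] <- row
      next
    }
    row[names(res$row)] <- res$row
    snp_rows[[id]] <- row
    snp_objects[[id]] <- res$objects
    putative_het[[id]] <- res$putative_het
  }
  snp_tab <- do.call(rbind, snp_rows)
  rownames(snp_tab) <- NULL
  log$n_snps_fit <- sum(snp_tab$disposition == "analyzed")
  say(log$n_snps_fit, " SNPs fit successfully")

  # ---- stage: SNP filters -------------------------------------------------
  fit_ok <- snp_tab$disposition == "analyzed"
  flags <- apply_snp_filters(snp_tab[fit_ok, , drop = FALSE],
                             stratum = snp_tab$stratum[fit_ok],
                             min_median_count = config$min_median_count,
                             min_het_autosomal = config$min_het_autosomal,
                             min_het_x = config$min_het_x,
                             pi_bounds = config$pi_bounds,
                             hwe_alpha = config$hwe_alpha)
  fail_reason <- function(fl) {
    reasons <- c("median_count", "n_het", "pi_bounds", "hwe")[
      !c(fl$pass_median_count, fl$pass_n_het, fl$pass_pi_bounds, fl$pass_hwe)]
    paste0("filtered: ", paste(reasons, collapse = "+"))
  }
  for (k in which(fit_ok)) {
    fl <- flags[match(snp_tab$snp_id[k], flags$snp_id), ]
    if (!fl$overall) snp_tab$disposition[k] <- fail_reason(fl)
  }
  snp_tab$pass_filters <- snp_tab$disposition == "analyzed"
  log$n_snps_pass <- sum(snp_tab$pass_filters)
  say(log$n_snps_pass, " SNPs pass quality/HWE filters")

  # SNP-level FDR within strata (on analyzed SNPs)
  snp_tab$p_dad_fdr <- NA_real_
  ok <- snp_tab$pass_filters
  snp_tab$p_dad_fdr[ok] <- fdr_correct(snp_tab$p_dad[ok], snp_tab$stratum[ok])

  # ---- stage: gene combination -------------------------------------------
  usable <- snp_tab[snp_tab$pass_filters & !is.na(snp_tab$gene_id), ,
                    drop = FALSE]
  gene_rows <- list()
  pcfg <- perm_config(n_iter = max(config$permutations, 100L),
                      min_het_per_group = config$min_het_per_group)
  for (gene in unique(usable$gene_id)) {
    sub <- usable[usable$gene_id == gene, , drop = FALSE]
    w <- lancaster_weights(sub$n_het_control, sub$n_het_case,
                           sub$median_n_control, sub$median_n_case)
    covar_sum <- 0
    if (nrow(sub) > 1) {
      pieces <- lapply(snp_objects[sub$snp_id], `[[`, "pieces")
      labels <- do.call(c, unname(lapply(snp_objects[sub$snp_id], `[[`, "labels")))
      labels <- labels[!duplicated(names(labels))]
      het <- do.call(c, unname(putative_het[sub$snp_id]))
      het <- het[!duplicated(names(het))]
      pc <- tryCatch(
        permutation_covariance(pieces, w, het, labels, pcfg),
        diffad_max_redos = function(e) e)
      if (inherits(pc, "error")) {
        warning("gene ", gene, " skipped: permutation redo limit exceeded")
        next
      }
      covar_sum <- pc$covar_sum
    }
    comb <- combine_gene(sub$p_dad, w, covar_sum)
    wc <- sqrt(sub$n_het_control * sub$median_n_control)
    wa <- sqrt(sub$n_het_case * sub$median_n_case)
    canon <- gene_canonical_summary(sub$snp_id, sub$corr_canon, sub$p_canon,
                                    weights = w)
    gene_rows[[gene]] <- data.frame(
      gene_id = gene, stratum = sub$stratum[1], n_snps = nrow(sub),
      rho_control = sum(wc * sub$rho_control) / sum(wc),
      rho_case = sum(wa * sub$rho_case) / sum(wa),
      n_het_control = sum(wc * sub$n_het_control) / sum(wc),
      n_het_case = sum(wa * sub$n_het_case) / sum(wa),
      median_n_control = sum(wc * sub$median_n_control) / sum(wc),
      median_n_case = sum(wa * sub$median_n_case) / sum(wa),
      t_lan = comb$t_lan, c = comb$c, v = comb$v,
      covar_sum = comb$covar_sum, p_dad = comb$p_gene,
      corr_canon = canon$corr_canon, p_canon = canon$p_canon,
      canon_snp = canon$snp_id, stringsAsFactors = FALSE)
  }
  gene_tab <- do.call(rbind, gene_rows)
  if (!is.null(gene_tab)) {
    rownames(gene_tab) <- NULL
    gene_tab$p_dad_fdr <- fdr_correct(gene_tab$p_dad, gene_tab$stratum)
    gene_tab <- gene_tab[order(gene_tab$p_dad), , drop = FALSE]
  } else {
    gene_tab <- data.frame()
  }
  log$n_genes <- nrow(gene_tab)
  say(log$n_genes, " genes combined")

  structure(list(snp = snp_tab, gene = gene_tab, meta = meta, log = log,
                 config = config),
            class = "dad_run")
}

# per-SNP analysis: per-cohort fits (putative heterozygotes, HWE counts,
# optional outlier detection), null and alternative joint fits, LRT,
# canonical dAD, score pieces for the permutation stage
.analyze_snp <- function(d, meta, config) {
  if (!any(d$group == "control") || !any(d$group == "case"))
    stop("SNP lacks one of the cohorts")
  outliers <- character(0)
  group_fit <- list()
  for (g in c("control", "case")) {
    dg <- d[d$group == g, , drop = FALSE]
    if (isTRUE(config$outlier_detection) && nrow(dg) >= 3) {
      rep_g <- detect_outliers(dg, meta$se,
                               threshold = config$outlier_threshold)
      group_fit[[g]] <- rep_g$fit
      outliers <- c(outliers, rep_g$outliers)
    } else {
      group_fit[[g]] <- fit_ase_mixture(dg, meta$se)
    }
  }
  # putative heterozygotes under the per-cohort fits
  het <- logical(0)
  hwe_p <- numeric(2); names(hwe_p) <- c("control", "case")
  for (g in c("control", "case")) {
    f <- group_fit[[g]]
    r <- f$responsibilities
    h <- r[, 2] > r[, 1] & r[, 2] > r[, 3]
    names(h) <- f$data$sample_id
    het <- c(het, h)
    # HWE on responsibility-summed genotype counts, outliers included
    hwe_p[[g]] <- hwe_test(colSums(r), meta$f_inbr)$p_value
  }

  fit0 <- fit_ase_mixture(d, meta$se, exclude = outliers)
  fit1 <- fit_ase_mixture(d, meta$se, group_specific = TRUE,
                          exclude = outliers)
  lrt <- dad_lrt(fit0, fit1)
  canon <- canonical_test(fit1, min_n = config$canonical_min_n)
  pieces <- score_pieces(fit0)
  labels <- stats::setNames(fit0$data$group, fit0$data$sample_id)

  list(
    row = list(pi_het = lrt$pi_het, rho_control = lrt$rho_control,
               rho_case = lrt$rho_case, lambda_lrt = lrt$lambda_lrt,
               p_dad = lrt$p_dad, n_het_control = lrt$n_het_control,
               n_het_case = lrt$n_het_case,
               median_n_control = lrt$median_n_control,
               median_n_case = lrt$median_n_case,
               hwe_p_control = hwe_p[["control"]],
               hwe_p_case = hwe_p[["case"]],
               n_outliers = length(outliers),
               corr_canon = canon$corr_canon, p_canon = canon$p_canon),
    objects = list(fit_null = fit0, fit_alt = fit1, pieces = pieces,
                   labels = labels),
    putative_het = het
  )
}

#' @export
print.dad_run <- function(x, ...) {
  cat("Differential allelic dispersion analysis\n")
  cat(sprintf("  SNPs: %d input, %d analyzed, %d pass filters\n",
              x$log$n_snps_input, x$log$n_snps_fit, x$log$n_snps_pass))
  cat(sprintf("  metaparameters: SE = %.5f, F_inbr = %.4f\n",
              x$meta$se, x$meta$f_inbr))
  cat(sprintf("  genes combined: %d\n", x$log$n_genes))
  if (nrow(x$gene)) {
    top <- utils::head(x$gene, 5)
    cat("  top genes by combined P:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-14s rho %.3f -> %.3f   P = %.3g (FDR %.3g)\n",
                  top$gene_id[i], top$rho_control[i], top$rho_case[i],
                  top$p_dad[i], top$p_dad_fdr[i]))
  }
  invisible(x)
}

#' Write pipeline results to TSV files
#'
#' @param x A `"dad_run"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "dad_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(snp = file.path(dir, "snp_results.tsv"),
             gene = file.path(dir, "gene_results.tsv"),
             meta = file.path(dir, "metaparameters.txt"))
  utils::write.table(x$snp, paths[["snp"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$gene, paths[["gene"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(sprintf("se=%.8f", x$meta$se),
               sprintf("f_inbr=%.8f", x$meta$f_inbr)), paths[["meta"]])
  invisible(paths)
}
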