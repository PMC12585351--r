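# Filters, gene assignment, Lancaster combination, permutation covariance.

test_that("HWE chi-square test matches hand-computed cases", {
  ok <- hwe_test(c(25, 50, 25), f_inbr = 0)
  expect_equal(ok$statistic, 0, tolerance = 1e-12)
  expect_equal(ok$p_value, 1)
  bad <- hwe_test(c(50, 0, 50), f_inbr = 0)
  expect_equal(bad$statistic, 100, tolerance = 1e-9)
  expect_lt(bad$p_value, 0.001)
  # inbreeding-adjusted expectation: counts exactly at F = 0.2 pass
  N <- 200; p <- 0.5
  counts <- N * c(p^2 + 0.2 * p^2, 2 * p^2 * 0.8, p^2 + 0.2 * p^2)
  adj <- hwe_test(counts, f_inbr = 0.2)
  expect_equal(adj$statistic, 0, tolerance = 1e-12)
})

test_that("SNP filters evaluate the four criteria and their conjunction", {
  stats <- data.frame(
    snp_id = c("ok", "low_cov", "few_het", "extreme_pi", "off_hwe"),
    median_n_control = c(10, 3, 10, 10, 10),
    median_n_case = c(10, 10, 10, 10, 10),
    n_het_control = c(20, 20, 5, 20, 20),
    n_het_case = c(20, 20, 20, 20, 20),
    pi_het = c(0.5, 0.5, 0.5, 0.97, 0.5),
    hwe_p_control = c(0.5, 0.5, 0.5, 0.5, 1e-4),
    hwe_p_case = c(0.5, 0.5, 0.5, 0.5, 0.5))
  fl <- apply_snp_filters(stats)
  expect_equal(fl$overall, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(fl$pass_median_count[2])
  expect_false(fl$pass_n_het[3])
  expect_false(fl$pass_pi_bounds[4])
  expect_false(fl$pass_hwe[5])
  expect_equal(fl$overall,
               fl$pass_median_count & fl$pass_n_het & fl$pass_pi_bounds & fl$pass_hwe)
  # X stratum lowers the heterozygote threshold
  fx <- apply_snp_filters(stats[3, ], stratum = "X")
  expect_false(fx$pass_n_het)  # 5 < 8 still fails
  stats$n_het_control[3] <- 9
  expect_true(apply_snp_filters(stats[3, ], stratum = "X")$pass_n_het)
})

test_that("gene assignment follows the category hierarchy and drops ties", {
  ann <- data.frame(
    snp_id = c("s1", "s1", "s2", "s2", "s3", "s4", "s4"),
    gene_id = c("geneA", "geneB", "geneA", "geneB", "geneC", "geneA", "geneB"),
    category = c("exonic", "intronic", "exonic", "exonic", "utr",
                 "upstream", "downstream"))
  res <- resolve_gene_assignment(ann)
  expect_equal(res$gene_id[res$snp_id == "s1"], "geneA")   # exonic wins
  expect_false("s2" %in% res$snp_id)                       # exonic tie dropped
  expect_equal(res$gene_id[res$snp_id == "s3"], "geneC")   # single annotation
  expect_false("s4" %in% res$snp_id)                       # same-level tie
  expect_error(resolve_gene_assignment(
    data.frame(snp_id = "s", gene_id = "g", category = "promoter")),
    "unknown annotation")
})

test_that("Lancaster weights rescale to twice the SNP count", {
  expect_equal(lancaster_weights(10, 10, 1, 1), 2)            # singleton
  w <- lancaster_weights(c(10, 10), c(20, 20), c(1, 1), c(1, 1))
  expect_equal(w, c(2, 2))                                    # equal raw weights
  # raw weights (10, 30) rescale proportionally to (1, 3)
  w2 <- lancaster_weights(c(10, 30), c(99, 99), c(1, 1), c(99, 99))
  expect_equal(w2, c(1, 3))
  expect_error(lancaster_weights(0, 10, 4, 4), "zero raw")
})

test_that("Lancaster statistic reduces to Fisher at weight 2 and matches the quantile oracle", {
  expect_equal(lancaster_statistic(c(1, 1), c(2, 2)), 0, tolerance = 1e-12)
  expect_equal(lancaster_statistic(c(0.5, 0.5), c(2, 2)),
               -2 * (log(0.5) + log(0.5)), tolerance = 1e-10)
  expect_equal(lancaster_statistic(c(0.01, 0.2), c(3, 1)),
               qgamma_oracle(0.99, 1.5) + qgamma_oracle(0.8, 0.5),
               tolerance = 1e-8)
})

test_that("combined gene P reduces to Fisher under independence and grows with covar_sum", {
  p <- c(0.03, 0.2, 0.6)
  comb <- combine_gene(p, w = c(2, 2, 2), covar_sum = 0)
  fisher <- pchisq(-2 * sum(log(p)), df = 6, lower.tail = FALSE)
  expect_equal(comb$p_gene, fisher, tolerance = 1e-10)
  expect_equal(comb$c, 1)
  expect_equal(comb$v, 6)
  # larger covariance strictly weakens the combined evidence
  p_at <- vapply(c(0, 1, 3, 6), function(cs) combine_gene(p, c(2, 2, 2), cs)$p_gene,
                 numeric(1))
  expect_true(all(diff(p_at) > 0))
  expect_error(combine_gene(0.5, 2, covar_sum = -10), "variance")
})

test_that("duplicated SNP is not double-counted after permutation correction", {
  # the reference pipeline removes influential samples before testing; a few
  # high-leverage samples otherwise dominate the permutation score tail
  snp <- quick_snp(40, rho_control = 0.1)
  outs <- unlist(lapply(c("control", "case"), function(g)
    detect_outliers(snp[snp$group == g, ], se = 0.002)$outliers))
  fit0 <- fit_ase_mixture(snp, se = 0.002, exclude = outs)
  fit1 <- fit_ase_mixture(snp, se = 0.002, group_specific = TRUE,
                          exclude = outs)
  p_single <- dad_lrt(fit0, fit1)$p_dad
  pieces <- score_pieces(fit0)
  r <- fit0$responsibilities
  het <- setNames(r[, 2] > pmax(r[, 1], r[, 3]), fit0$data$sample_id)
  labels <- setNames(fit0$data$group, fit0$data$sample_id)
  pc <- permutation_covariance(list(pieces, pieces), w = c(2, 2),
                               putative_het = het, labels = labels,
                               config = perm_config(500, seed = 99))
  # fully correlated chi-square(2) transforms: covariance = variance = 4
  expect_gt(pc$covar_sum, 2.5)
  comb <- combine_gene(c(p_single, p_single), w = c(2, 2), pc$covar_sum)
  expect_gt(comb$v, 1.8)
  expect_lt(comb$v, 2.4)
  # the combined P stays close to the single-SNP P (information not doubled)
  expect_lt(abs(log10(comb$p_gene) - log10(p_single)), 0.6)
})

test_that("independent SNPs have near-zero covariance and a reproducible stream", {
  g <- simulate_gene(sim_config(n_control = 120, n_case = 120,
                                rho_het_control = 0.05, seed = 77),
                     n_snps = 2, correlation = 0)
  fits <- lapply(split(g$counts, g$counts$snp_id), fit_ase_mixture, se = 0.002)
  pieces <- lapply(fits, score_pieces)
  f1 <- fits[[1]]
  r <- f1$responsibilities
  het <- setNames(r[, 2] > pmax(r[, 1], r[, 3]), f1$data$sample_id)
  labels <- setNames(f1$data$group, f1$data$sample_id)
  w <- c(2, 2)
  pc1 <- permutation_covariance(pieces, w, het, labels, perm_config(400, seed = 5))
  pc2 <- permutation_covariance(pieces, w, het, labels, perm_config(400, seed = 5))
  expect_identical(pc1$covar_sum, pc2$covar_sum)
  expect_identical(pc1$transformed, pc2$transformed)
  # combined P does not depend on the order of the gene's SNPs
  pc_rev <- permutation_covariance(rev(pieces), rev(w), het, labels,
                                   perm_config(400, seed = 5))
  p_fwd <- combine_gene(c(0.02, 0.3), w, pc1$covar_sum)$p_gene
  p_rev <- combine_gene(c(0.3, 0.02), rev(w), pc_rev$covar_sum)$p_gene
  expect_equal(p_fwd, p_rev, tolerance = 1e-12)
  # raw covariance within Monte-Carlo error of zero (cor of chi2(2) pairs)
  raw_cov <- pc1$covar[1, 2]
  se_cov <- sqrt(16 / 400)  # var of cov estimate ~ var1*var2/B
  expect_lt(abs(raw_cov), 3 * se_cov)
})

test_that("permutation redo limit signals a typed condition", {
  snp <- quick_snp(41, n_control = 20, n_case = 20)
  fit0 <- fit_ase_mixture(snp, se = 0.002)
  pieces <- score_pieces(fit0)
  labels <- setNames(fit0$data$group, fit0$data$sample_id)
  het <- setNames(rep(FALSE, nrow(fit0$data)), fit0$data$sample_id)
  expect_error(
    permutation_covariance(list(pieces), w = 2, putative_het = het,
                           labels = labels,
                           config = perm_config(100, seed = 1, max_redos = 50)),
    class = "diffad_max_redos")
})

test_that("stratified BH matches hand computation and respects strata", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.01, 0.02, 0.03, 0.04)
  two <- fdr_correct(c(p, p), strata = rep(c("a", "x"), each = 4))
  expect_equal(two[1:4], two[5:8])
  expect_equal(two[1:4], rep(0.04, 4))
})
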