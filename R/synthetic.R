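# Synthetic allele-count cohorts with the full generative structure assumed
# by the mixture models: Hardy-Weinberg genotypes (optionally with
# inbreeding), negative-binomial per-sample coverage, sequencing error in
# homozygotes, and group-specific heterozygote overdispersion. A "loss-type"
# differential-dispersion mechanism couples allelic skew to reduced coverage
# (the signature the canonical-dAD statistic targets); "gain-type" couples
# skew to increased coverage.

#' Configuration for synthetic allele-count cohorts
#'
#' Defaults describe a mid-sized bulk RNA-seq case-control cohort: 150
#' controls and 150 cases, a common biallelic SNP (reference-allele frequency
#' 0.5) in a panmictic population, sequencing error 0.002, balanced allelic
#' bias, moderate control-cohort allelic dispersion (rho 0.02) and small
#' homozygote nuisance dispersion, with negative-binomial coverage around 50
#' reads.
#'
#' @param n_control,n_case Cohort sizes.
#' @param allele_freq Population frequency of the reference allele.
#' @param f_inbr Inbreeding coefficient used for the genotype draw.
#' @param se Sequencing-error rate.
#' @param pi_het Heterozygote allelic bias (mean reference fraction).
#' @param rho_het_control,rho_het_case Heterozygote overdispersion per cohort.
#' @param rho_hom Homozygote nuisance overdispersion.
#' @param coverage_mean,coverage_disp Negative-binomial mean and size of
#'   per-sample totals (floored at 1).
#' @param mechanism Differential-dispersion mechanism: `"none"`,
#'   `"loss"` (skewed heterozygous case samples get `coverage_factor` times
#'   the coverage, `< 1`), or `"gain"` (`coverage_factor > 1`).
#' @param coverage_factor Multiplier applied to skewed case heterozygotes'
#'   totals under the loss/gain mechanisms.
#' @param skew_threshold Latent allelic fractions farther than this from
#'   `pi_het` count as skewed for the mechanism.
#' @param seed Optional seed; identical configurations with the same seed
#'   produce identical cohorts.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_control = 150L, n_case = 150L, allele_freq = 0.5,
                       f_inbr = 0, se = 0.002, pi_het = 0.5,
                       rho_het_control = 0.02, rho_het_case = rho_het_control,
                       rho_hom = 0.002, coverage_mean = 50, coverage_disp = 5,
                       mechanism = c("none", "loss", "gain"),
                       coverage_factor = 0.5, skew_threshold = 0.25,
                       seed = NULL) {
  mechanism <- match.arg(mechanism)
  cfg <- list(n_control = as.integer(n_control), n_case = as.integer(n_case),
              allele_freq = allele_freq, f_inbr = f_inbr, se = se,
              pi_het = pi_het, rho_het_control = rho_het_control,
              rho_het_case = rho_het_case, rho_hom = rho_hom,
              coverage_mean = coverage_mean, coverage_disp = coverage_disp,
              mechanism = mechanism, coverage_factor = coverage_factor,
              skew_threshold = skew_threshold, seed = seed)
  probs <- c(cfg$allele_freq, cfg$se, cfg$pi_het, cfg$rho_het_control,
             cfg$rho_het_case, cfg$rho_hom, cfg$f_inbr)
  if (any(probs[1:6] < 0 | probs[1:6] > 1) || cfg$f_inbr < -1 || cfg$f_inbr > 1)
    stop("invalid simulation config: probabilities must lie in [0, 1]")
  if (cfg$n_control < 1 || cfg$n_case < 1) stop("cohort sizes must be >= 1")
  structure(cfg, class = "sim_config")
}

# genotype frequencies implied by allele frequency and inbreeding
.genotype_freqs <- function(p, f) {
  q <- 1 - p
  phi <- c(rr = p^2 + f * p * q, rv = 2 * p * q * (1 - f), vv = q^2 + f * p * q)
  if (any(phi < -1e-12)) stop("allele_freq/f_inbr imply negative genotype frequencies")
  pmax(phi, 0) / sum(pmax(phi, 0))
}

# latent heterozygote reference fraction: Beta draw, or the fixed mean when
# rho = 0
.het_fraction <- function(k, pi, rho) {
  if (rho == 0) return(rep(pi, k))
  th <- rho_to_theta(rho)
  stats::rbeta(k, pi / th, (1 - pi) / th)
}

#' Simulate one SNP's allele counts
#'
#' Draws genotypes from the Hardy-Weinberg frequencies implied by
#' `allele_freq` and `f_inbr`, per-sample totals from the negative-binomial
#' coverage model, and reference counts from the genotype's beta-binomial
#' component. Under the loss/gain mechanisms, heterozygous case samples whose
#' latent allelic fraction is skewed get their totals rescaled by
#' `coverage_factor`, coupling allelic extremity to expression.
#'
#' @param config A [sim_config()].
#' @param snp_id SNP identifier written into the table.
#' @return Long-format data frame (`sample_id`, `snp_id`, `ref_count`,
#'   `var_count`, `group`) with a `"truth"` attribute recording latent
#'   genotypes, fractions, and the generative parameters.
#' @export
simulate_snp <- function(config, snp_id = "snp1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  .simulate_snp_impl(config, snp_id)
}

.simulate_snp_impl <- function(config, snp_id, genotype = NULL) {
  S <- config$n_control + config$n_case
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))
  phi <- .genotype_freqs(config$allele_freq, config$f_inbr)
  g <- if (is.null(genotype)) sample.int(3L, S, replace = TRUE, prob = phi) else genotype
  n <- pmax(stats::rnbinom(S, mu = config$coverage_mean,
                           size = config$coverage_disp), 1L)

  frac <- numeric(S)
  het <- g == 2L
  is_case <- group == "case"
  frac[het & !is_case] <- .het_fraction(sum(het & !is_case), config$pi_het,
                                        config$rho_het_control)
  frac[het & is_case] <- .het_fraction(sum(het & is_case), config$pi_het,
                                       config$rho_het_case)
  # homozygote mean fractions with nuisance dispersion
  hom_pi <- ifelse(g == 1L, 1 - config$se, config$se)
  if (config$rho_hom > 0) {
    th <- rho_to_theta(config$rho_hom)
    frac[!het] <- stats::rbeta(sum(!het), hom_pi[!het] / th,
                               (1 - hom_pi[!het]) / th)
  } else {
    frac[!het] <- hom_pi[!het]
  }

  if (config$mechanism != "none") {
    skewed <- het & is_case &
      abs(frac - config$pi_het) > config$skew_threshold
    n[skewed] <- pmax(as.integer(round(n[skewed] * config$coverage_factor)), 1L)
  }

  x <- stats::rbinom(S, n, frac)
  out <- data.frame(sample_id = sprintf("%s_%03d", group, stats::ave(
    seq_len(S), group, FUN = seq_along)),
    snp_id = snp_id, ref_count = x, var_count = n - x, group = group,
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(genotype = c("rr", "rv", "vv")[g],
                             fraction = frac, phi = phi, config = config)
  out
}

#' Simulate a multi-SNP gene with inter-SNP dependence
#'
#' Simulates `n_snps` SNPs for the same gene. Genotypes are shared across the
#' gene's SNPs (proximal SNPs in phase). Dependence between the SNPs'
#' allele counts mimics counts derived from the same sequencing reads or mRNA
#' molecules: each sample owns one shared count draw (total and reference
#' count, from a shared latent allelic fraction), and at every SNP the sample
#' reuses that draw with probability `correlation`, otherwise it gets a fully
#' independent draw. With `correlation = 1` all SNPs carry identical counts
#' and latent fractions per sample (the information of a single SNP); with
#' `0` the SNPs are independent given the genotype.
#'
#' @param config A [sim_config()]; group sizes and parameters apply to every
#'   SNP.
#' @param n_snps Number of SNPs.
#' @param correlation Probability that a sample's counts at a SNP reuse the
#'   sample's shared draw.
#' @param gene_id,snp_prefix Identifiers used in the output.
#' @return List with `counts` (stacked long-format table), `annotations`
#'   (snp_id, gene_id, category = "exonic"), and `truth`.
#' @export
simulate_gene <- function(config, n_snps = 2L, correlation = 0,
                          gene_id = "gene1", snp_prefix = gene_id) {
  stopifnot(correlation >= 0, correlation <= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- config$n_control + config$n_case
  phi <- .genotype_freqs(config$allele_freq, config$f_inbr)
  g <- sample.int(3L, S, replace = TRUE, prob = phi)
  shared <- .simulate_snp_impl(config, "shared", genotype = g)
  shared_truth <- attr(shared, "truth")
  slices <- lapply(seq_len(n_snps), function(i) {
    own <- .simulate_snp_impl(config, sprintf("%s_snp%d", snp_prefix, i),
                              genotype = g)
    tr <- attr(own, "truth")
    reuse <- stats::runif(S) < correlation
    own$ref_count[reuse] <- shared$ref_count[reuse]
    own$var_count[reuse] <- shared$var_count[reuse]
    tr$fraction[reuse] <- shared_truth$fraction[reuse]
    tr$shared_draw <- reuse
    attr(own, "truth") <- tr
    own
  })
  counts <- do.call(rbind, slices)
  rownames(counts) <- NULL
  ann <- data.frame(snp_id = vapply(slices, function(s) s$snp_id[1], ""),
                    gene_id = gene_id, category = "exonic",
                    stringsAsFactors = FALSE)
  list(counts = counts, annotations = ann,
       truth = list(genotype = c("rr", "rv", "vv")[g],
                    shared_fraction = shared_truth$fraction,
                    per_snp = lapply(slices, attr, "truth")))
}

#' Simulate a cohort of null and differential-dispersion genes
#'
#' Builds a full pipeline input: `n_null` genes simulated under equal
#' heterozygote dispersion in both cohorts and `n_dad` genes whose case
#' dispersion is `dad_rho_factor` times the control dispersion.
#'
#' @param config Baseline [sim_config()] (its `rho_het_case` is overridden:
#'   null genes get the control value, planted genes get the inflated one).
#' @param n_null,n_dad Numbers of null and planted differential genes.
#' @param snps_per_gene SNPs per gene.
#' @param correlation Shared-fraction correlation within genes.
#' @param dad_rho_factor Case/control dispersion ratio for planted genes.
#' @param seed Seed for the whole cohort.
#' @return List with `counts`, `annotations`, and `truth` (per-gene data
#'   frame with the planted status).
#' @export
simulate_cohort <- function(config, n_null = 20L, n_dad = 5L,
                            snps_per_gene = 1L, correlation = 0.5,
                            dad_rho_factor = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config$seed <- NULL
  genes <- c(sprintf("null_gene%02d", seq_len(n_null)),
             sprintf("dad_gene%02d", seq_len(n_dad)))
  planted <- rep(c(FALSE, TRUE), c(n_null, n_dad))
  parts <- lapply(seq_along(genes), function(i) {
    cfg <- config
    cfg$rho_het_case <- if (planted[i]) {
      min(config$rho_het_control * dad_rho_factor, 0.95)
    } else config$rho_het_control
    simulate_gene(cfg, n_snps = snps_per_gene, correlation = correlation,
                  gene_id = genes[i])
  })
  counts <- do.call(rbind, lapply(parts, `[[`, "counts"))
  rownames(counts) <- NULL
  ann <- do.call(rbind, lapply(parts, `[[`, "annotations"))
  list(counts = counts, annotations = ann,
       truth = data.frame(gene_id = genes, planted = planted,
                          stringsAsFactors = FALSE))
}
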