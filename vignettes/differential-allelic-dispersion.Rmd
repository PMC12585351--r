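---
title: "Modeling differential allelic dispersion from bulk RNA-seq allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling differential allelic dispersion from bulk RNA-seq allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffAD)
```

## The problem

Bulk RNA-seq measures the summed expression of a gene's two alleles. At a
heterozygous SNP the reads split into reference- and variant-allele counts,
so the *allelic fraction* of each sample becomes observable. Most
allele-specific expression (ASE) methods target cis-eQTL-like effects — a
consistent population-wide shift of the mean allelic fraction. This package
targets a different signal: **allelic dispersion (AD)**, the
*population-level variability* of heterozygotes' allelic fractions. A
clonally expanded allele-specific event (a copy-number loss or gain, an
allele-specific epimutation) skews the allelic fraction of the affected
sample in a random direction, so across a cohort of cases it inflates the
variance — not the mean — of the allelic fraction. A case-vs-control
increase in AD (**differential AD, dAD**) therefore flags genes dysregulated
allele-specifically early in disease, which plain differential expression
cannot separate from downstream response.

Crucially, no genotyping is needed: heterozygotes are identified
probabilistically inside the model.

## The model

For one SNP, let \(x_r, x_v\) be a sample's reference and variant counts and
\(n = x_r + x_v\). Counts follow a three-component beta-binomial genotype
mixture:

\[
P(x_r) \;=\; \phi_{rr}\,\mathrm{BB}(x_r \mid n,\ 1-\mathrm{SE},\ \rho_{hom})
\;+\; \phi_{rv}\,\mathrm{BB}(x_r \mid n,\ \pi_{het},\ \rho_{het})
\;+\; \phi_{vv}\,\mathrm{BB}(x_r \mid n,\ \mathrm{SE},\ \rho_{hom})
\]

* \(\phi = (\phi_{rr}, \phi_{rv}, \phi_{vv})\): genotype frequencies;
* \(\mathrm{SE}\): sequencing (and other technical) error, a cohort-level
  metaparameter — homozygotes' wrong-allele read fraction;
* \(\pi_{het}\): heterozygote allelic bias (AB), capturing cis-eQTL and
  technical shifts;
* \(\rho_{het}\): heterozygote overdispersion — **this is AD**. The
  equivalent unbounded parameter is \(\theta = \rho/(1-\rho)\); \(\theta = 0\)
  is the binomial;
* \(\rho_{hom}\): homozygote nuisance overdispersion.

Modeling AD as beta-binomial overdispersion automatically accounts for
coverage differences: raw fraction variances would overstate dispersion in
shallow samples.

The differential model gives cases and controls separate heterozygote
dispersions \(\rho_{het,\mathrm{control}} \ne \rho_{het,\mathrm{case}}\),
sharing every other parameter. dAD at a SNP is tested by the 1-df
likelihood-ratio test between the two fits.

## Numerical core

The beta-binomial log-PMF is computed from the beta-function form
(`lchoose(n,x) + lbeta(x+a, n-x+b) - lbeta(a,b)` with \(a = \pi/\theta\),
\(b = (1-\pi)/\theta\)). For tiny \(\theta\) the two `lbeta` terms agree to
many digits and cancel catastrophically; when their relative gap falls below
`1e-8` (or the result is non-finite) the evaluation escalates to the
ascending-product form computed as a sum of logarithms of strictly positive
factors. That form is exact up to one rounding per factor, so no further
escalation is needed; a counter of fallback events is available via
`betabinom_fallback_count()`. First and second derivatives use
digamma/trigamma differences with an exact-sum evaluation once the arguments
are large enough for the naive difference to cancel (\(a > 10^8\) and
\(10^6\) respectively) — these are the derivative analogues of the product
form and stay accurate for extreme parameters.

EM fitting alternates exact posterior genotype responsibilities with
closed-form mixture weights and quasi-Newton (BFGS) updates of
\((\mathrm{logit}\,\pi_{het}, \log\theta_{het}, \log\theta_{hom})\) with
analytic gradients; the transforms avoid bounded optimization. Because the
heterozygote and homozygote parameters enter disjoint components, the
continuous M-step separates into a 2-parameter (or 3-parameter,
cohort-specific) heterozygote problem and a 1-parameter homozygote problem.
Starting values come from moment estimators that handle unequal totals, with
all per-sample weights set to 1 (the ideal weights at \(\theta = 0\); the
estimate only seeds the optimizer). EM stops when the relative
log-likelihood change drops below `1e-8` (at most 200 iterations);
monotonicity is asserted each iteration.

A beta-binomial is bimodal when \(\theta > \max(\pi, 1-\pi)\). A bimodal
heterozygote component usually means the optimizer is abusing that component
to fit homozygote data, so bimodal accepted fits are rerun with
\(\theta_{het} = \max(\pi,1-\pi)\,\sigma(u)\), which enforces unimodality by
construction; such fits are flagged `constrained_refit`.

## Metaparameters

\(\mathrm{SE}\) is estimated by fitting, per SNP, a simplified binomial
mixture with balanced heterozygotes (\(p = 0.5\)) and error-driven
homozygotes; all its M-steps are closed form. Loci are retained for the
cohort estimate when the per-locus SE is below 0.035, more than 40 samples
are covered, median coverage is at least 10, and the minor-allele count
fraction is at least 0.15; the cohort SE is the median over retained loci
(recommended not below 0.002 — some error slack helps the EM assign
samples). The same fits yield the cohort inbreeding coefficient
\(F_{inbr} = 1 - \phi_{rv} / (2 p q)\) (median over loci), used later by the
Hardy-Weinberg filter. Both can instead be supplied directly
(`meta_params()`). Cases and controls are pooled for estimation — the
simplified mixture has no group structure — though the pipeline accepts
user-supplied values if separation is wanted.

## Outlier handling

A single deeply covered, strongly skewed sample can dominate the dispersion
estimate. `detect_outliers()` refits the mixture leaving out each sample of
a cohort in turn and flags samples whose deletion moves \(\hat\pi_{het}\) or
\(\hat\theta_{het}\) by more than 5 sample standard deviations of the
respective delta series. Deltas are centered before comparison: a common
offset shared by all deletion deltas carries no influence information, and
exchangeable samples (zero spread) must produce no flags. Flagged samples
are excluded from all fits and tests but retained for the Hardy-Weinberg
filter (they are mostly heterozygotes, and removing them would bias the
genotype-frequency test). The stage costs one refit per sample; it is
optional (`ad_config(outlier_detection = )`) but recommended — beyond
robustness of the estimates, the permutation machinery below relies on no
single sample dominating the dispersion score.

## The score test and the permutation covariance

Per-SNP P values of one gene cannot be combined as independent: proximal
SNPs' counts may come from the same reads or mRNA molecules. The correction
needs, per gene, the covariance of transformed P values under the null,
estimated by rerunning the dAD test on many random relabelings of the
samples — with the *same* relabeling applied to all the gene's SNPs, which
preserves inter-SNP dependence while destroying label-linked biology.

Refitting the differential model thousands of times per gene is infeasible,
so permuted statistics come from the **score test**: its only fit is the
shared-dispersion null model, which is label-invariant and thus computed
once. The six parameters \((\pi_{het}, \rho_{hom}, \rho_{het,\mathrm{control}},
\rho_{het,\mathrm{case}}, \phi_{rr}, \phi_{rv})\) are scored at the null
estimate (both cohort dispersions at the shared fitted value), and
\(\lambda_{ST} = g^\top(-H)^{-1}g\) with the observed Hessian \(H\) standing
in for the Fisher information. All per-sample score and Hessian
contributions are precomputed once per SNP; each relabeling only re-sums
them, so permutations cost vector sums rather than model fits.

Numerical points worth knowing:

* The quadratic form is solved after Jacobi equilibration, so the
  singularity check measures genuine flatness, not parameter scale. A
  condition number above \(10^{12}\) signals a typed error; the permutation
  loop redoes such draws, as it does draws leaving either cohort with 6 or
  fewer putative heterozygotes (classified by their own cohort's fit).
* A nuisance parameter pinned at a boundary by the null fit (typically
  \(\theta_{hom}\) at its floor when homozygotes show no excess variance)
  makes the observed information indefinite in that direction; such
  directions are excluded from the quadratic form. The decision uses only
  label-free sums, so all permutations of one fit share it. The tested
  dispersion directions are never dropped.
* The score/LRT asymptotic equivalence is a local property. Under extreme
  dispersion differences the observed information at the null fit can turn
  indefinite in the tested direction and the score test signals rather than
  returning a number; the pipeline only uses the score test under
  permutations, where relabeled data are null-like.
* **Calibration of permutation P values.** The covariance estimate rests on
  the premise that permutation P values are Uniform(0,1). The score
  statistic's chi-square(1) approximation has a finite-sample tail error
  that, squared into variances and covariances of the gamma transforms,
  systematically inflates the dependence estimate and overcorrects the
  combination. `permutation_covariance()` therefore defaults to *empirical*
  calibration: each SNP's permutation statistics are converted to mid-rank P
  values within its own permutation set, making the marginals exactly
  uniform so that the covariance measures pure inter-SNP dependence. The
  asymptotic chi-square map remains available (`calibration = "chisq"`).
* A few high-leverage samples can dominate the dispersion score and give its
  permutation distribution a heavy tail; leave-one-out outlier removal
  before testing (the reference order of the pipeline) is the intended
  mitigation.

## Gene-level combination

SNPs pass to the gene stage if: median total count \(\ge 4\) in both
cohorts; estimated heterozygotes \(\ge 12\) (autosomal) or \(\ge 8\) (X) in
both cohorts; \(0.05 \le \pi_{het} \le 0.95\) (more extreme values indicate
a failed fit); and both cohorts conform to Hardy-Weinberg equilibrium
(\(\chi^2\) P > 0.001 against expectations at the cohort \(F_{inbr}\), on
responsibility-summed genotype counts, outliers included). SNPs map to genes
by the annotation hierarchy exonic > UTR/noncoding > intronic/splice >
up-/downstream; unannotated SNPs and same-level ties are dropped.

The weighted Lancaster statistic
\(T = \sum_i \gamma^{-1}_{(w_i/2,\,2)}(1-p_i)\) uses as raw weight the
smaller cohort's (heterozygote count × median coverage), rescaled so
\(\sum w_i = 2N\) — at equal weights the method reduces exactly to Fisher's.
With \(\mathrm{E}[T] = \sum w_i\) and
\(\mathrm{var}(T) = 2\sum w_i + 2\sum_{i<j}\mathrm{Cov}_{ij}\) (covariances
from the permutations, negatives truncated to zero as negative inter-SNP
dependence is biologically implausible), \(cT \sim \chi^2_v\) with
\(v = 2\mathrm{E}[T]^2/\mathrm{var}(T)\), \(c = v/\mathrm{E}[T]\). P values
of exactly zero are floored at `1e-15` before the gamma transform (the
quantile diverges; the floor preserves ordering). Genes are BH-corrected
within strata — autosomal and X-chromosomal genes separately, as they are
effectively different data sets (X uses only the declared female samples).
If a gene exhausts the permutation redo budget it is skipped with a warning
rather than reported with an unreliable correction.

Single-SNP genes need no permutations: the covariance sum is zero by
construction and the combination is deterministic.

## Canonical dAD

A dAD hit is most interpretable when allelic extremity couples to
expression in the individual case samples — e.g., a clonal copy-number loss
both skews the allelic fraction and halves expression. Per SNP, each
heterozygous case sample with total count above 20 contributes
\(1/\min(\mathrm{CMF}(x_r),\ 1-\mathrm{CMF}(x_r)+\mathrm{PMF}(x_r))\) — the
inverse minimal tail area under the fitted heterozygote component (the PMF
term makes the two tails comparable for a discrete distribution) — and the
canonical statistic is the Spearman correlation of that contribution with
the total count. Holm correction across a gene's SNPs, reporting the SNP
with the smallest adjusted P (ties: larger Lancaster weight, then SNP id).
Spearman ties use midranks; the exact null distribution is used up to 9
untied pairs.

## The synthetic-data generator

`simulate_snp()` / `simulate_gene()` / `simulate_cohort()` produce cohorts
with exactly the generative structure the models assume: genotypes from
Hardy-Weinberg frequencies at a configurable allele frequency and
inbreeding coefficient; negative-binomial per-sample totals (floored at 1);
homozygote counts with sequencing error and nuisance dispersion;
heterozygote counts from a latent beta allelic fraction with cohort-specific
dispersion. Defaults describe a mid-sized bulk RNA-seq case-control study:
150 + 150 samples, allele frequency 0.5, panmixis, SE 0.002, balanced bias,
control dispersion \(\rho = 0.02\) (the order of magnitude seen in healthy
cohorts), homozygote nuisance dispersion 0.002, and negative-binomial
coverage with mean 50 and size 5.

Inter-SNP dependence within a gene emulates allele counts derived from the
same sequencing reads or mRNA molecules: each sample owns one shared count
draw (total and reference count from a shared latent fraction), and every
SNP reuses it with a configurable probability (1 = identical counts across
SNPs, i.e., the information of a single SNP; 0 = independent given the
genotype); genotypes are shared across the gene's SNPs (proximal SNPs in
phase). Sharing only the latent *fraction* was considered and rejected: the
independent count noise then dilutes the P-value dependence so much that the
dependence correction becomes nearly a no-op, and full sharing would not
collapse the gene's degrees of freedom to a single SNP's worth. The
"loss" mechanism multiplies the totals of skewed heterozygous case samples
(latent fraction further than a threshold from \(\pi_{het}\)) by a factor
below 1, producing the coupling the canonical statistic targets; "gain" uses
a factor above 1.

What the generator does **not** emulate: alignment bias toward the
reference allele, sample-specific error rates, tumor purity gradients,
copy-number mosaicism, partial read overlap (a SNP pair either shares a
sample's whole count draw or none of it), and LD structure beyond perfect
phase within a gene. Passing tests therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness to every
real-data artifact.

## Choices made where the design was open

* **Putative heterozygotes** (permutation redo rule) are samples whose
  heterozygote responsibility exceeds both homozygote responsibilities under
  their own cohort's fit — the fits produced anyway during outlier
  detection.
* **Moment-init seeding** uses samples with raw fraction in \([0.15, 0.85]\)
  as provisional heterozygotes; after outlier removal, refits warm-start
  from the pre-removal estimates.
* **Metaparameter pooling**: cases and controls are pooled (the simplified
  mixture has no group structure); supply `se`/`f_inbr` directly to
  override.
* **Canonical-dAD power depends on coverage**: halving a skewed sample's
  totals can push it under the method's own \(n > 20\) inclusion threshold.
  At baseline coverage ~50 a large share of the informative samples become
  inadmissible; power statements in the tests therefore use baseline
  coverage 100, where halved samples remain assessable.
* **Desk-scale problem sizes**: the test-suite simulations use cohorts of
  300 samples, hundreds of SNPs/genes and 300–500 permutations; the
  reference permutation count for real analyses remains 10,000
  (`perm_config()` default).

## Known limitations

* The LRT is unreliable against boundary hypotheses such as
  \(\theta = 0\); fits with dispersion at the clamp floor are flagged, and
  no boundary correction is applied.
* The score statistic's permutation distribution acquires a heavy right
  tail when a few high-leverage samples dominate the dispersion score;
  leave-one-out outlier removal is the intended mitigation and precedes the
  permutation stage in the reference pipeline order.
* Only biallelic SNPs are modeled; the two modeled alleles are chosen by
  summed counts (ties broken reproducibly at random), optionally restricted
  to a caller-supplied allele set.
* Gene assignment requires the provided annotation table; no
  coordinate-overlap fallback is attempted.
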