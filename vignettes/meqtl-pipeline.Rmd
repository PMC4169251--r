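---
title: "Mapping cis methylation QTLs: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis methylation QTLs: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismeth)
```

# The problem

DNA methylation at CpG dinucleotides varies between individuals, and part of
that variation is heritable in *cis*: a nearby SNP shifts the methylation
level of one or several CpGs. `cismeth` implements the full analysis chain
for detecting such methylation QTLs (meQTLs) from array data with matched
genotypes, quantifying how often QTLs for other regulatory phenotypes are
meQTLs as well, validating array signals in low-coverage whole-genome
bisulfite sequencing, and testing a mechanistic hypothesis: that SNPs which
change predicted transcription-factor (TF) binding affinity also shift
nearby methylation.

Every stage can be exercised on synthetic cohorts with planted, recorded
truth, so the package doubles as a test bed for the statistical behavior of
the pipeline itself.

# Models and procedures

## Normalization

Array beta values (the estimated fraction of methylated chromosomes,
in $[0,1]$) are strongly bimodal and non-Gaussian. The default `two_stage`
strategy of `quantile_normalize()` rank-transforms to a standard normal in
two passes: across all probes within each individual, then across all
individuals at each probe. The rank map is
$\Phi^{-1}\!\big((r - 0.5)/n\big)$ with average ranks for ties — the
standard offset that keeps the extremes finite. Ties (which arise in the
second stage because stage one emits a finite score set) receive average
ranks, so a probe column is an exact permutation of the normal scores only
when tie-free; with ties the column mean deviates from zero by a small
amount. The alternative strategies (`by_individual`, `by_probe`, `none`)
reproduce the robustness analyses a cautious analyst would run.

Missing beta values are a hard error rather than being imputed: imputation
choices change downstream dosage regressions in ways the caller should
control explicitly.

## Confounder removal

Hidden structure (batch, cell-line handling, ancestry) loads on the leading
principal components of the normalized matrix. `remove_pcs()` regresses
each probe on the top $k$ sample-space components and keeps the residuals;
`select_num_pcs()` chooses $k$ by rerunning the cis scan on a grid and
keeping the $k$ that maximizes the number of probes with an association at
FDR 10% (ties go to the smaller $k$). PC removal happens after the
two-stage normalization, in that order. The TF-expression analysis
deliberately skips PC removal: an abundant TF shifts methylation at many
sites simultaneously, which is exactly the kind of broad signal the removed
components absorb.

## The cis scan

`cis_scan()` tests every (probe, SNP) pair with
$|{\rm pos}_{\rm SNP} - {\rm pos}_{\rm CpG}| \le w$ (default $w = 3000$ bp,
boundary inclusive — a 6 kb window centered on the probe) and SNP minor
allele frequency strictly above 5%, by ordinary least squares of normalized
methylation on allelic dosage in $[0,2]$. The two-sided p-value uses the
$t_{n-2}$ reference. Zero-variance dosage vectors are skipped. No
covariates enter the regression; confounding is handled upstream by PC
removal.

FDR control uses Storey q-values (`estimate_qvalues()`): $\pi_0$ is
estimated on the grid $\lambda = 0.05, 0.10, \dots, 0.95$ from
$\hat\pi_0(\lambda) = \frac{\#\{p > \lambda\}}{m(1-\lambda)}$, smoothed
with a cubic smoothing spline (df = 3) and read off at the largest
$\lambda$, clipped to $(0, 1]$; q-values are the step-up tail minima
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. Forcing $\pi_0 = 1$
reproduces Benjamini–Hochberg exactly, which is the identity the tests pin
down. For inputs of fewer than 100 p-values the smoother is unstable and
$\pi_0$ defaults to 1 (plain BH) — this matters for the per-draw FDRs
inside the permutation machinery, where it applies identically to observed
and null draws.

q-values are pooled over all tests of a scan; probe-level counting (the
"one lead SNP per probe" rule of `call_meqtls()`, ties broken by distance
then position) happens afterwards. Per-foreground analyses compute an
independent FDR on their own tests only.

## Candidate causal SNPs

LD makes the causal variant behind a meQTL ambiguous. `find_candidate_causal()`
flags probes where, in a widened ±5 kb window, the best SNP's p-value is at
least two orders of magnitude below the second best (inclusive at exactly
two orders). Probes with a single tested SNP are excluded — there is no
second p-value to compare. On LD-structured synthetic fixtures with one
causal SNP per region, at least 80% of flagged candidates are the planted
variant, which is the property that makes the filter worth reporting.

## Cross-phenotype sharing

`test_foreground()` regresses methylation within 3 kb on each foreground
SNP (eQTLs, DNase/histone QTLs, GWAS hits, ...), computes q-values over the
foreground's tests, and reports the fraction of SNPs with at least one
association at FDR 10%. `matched_permutation_null()` draws $B$ SNP sets of
matched size, without replacement, from the universe of MAF-passing SNPs
within 3 kb of a probe, and reports
$\hat p = (b + 1)/(B + 1)$ where $b$ counts null draws at or above the
observed proportion — never exactly zero by construction. Matching is by
count and probe proximity only; no MAF or annotation matching is attempted.
The per-SNP regressions are computed once and cached; only the per-draw
q-values are recomputed, which is exactly equivalent to rescanning
(verified bit-for-bit in the tests). Direction calls multiply the sign of
the lead methylation slope by the foreground effect sign when the caller
provides one; otherwise the raw slope sign is reported and labeled as such.

## Bisulfite sequencing

Site levels are methylated reads over total coverage. Array concordance
compares, per site, the mean untransformed beta across all array samples
with the mean of per-sample sequencing levels over samples with ≥ 5 reads,
by Spearman correlation (the site means are far from normal). The
genotype-stratified aggregate (`genotype_stratified_aggregate()`) orients
each meQTL so "high" is the homozygote class with higher array methylation,
pools reads in 51 bp windows sliding at a 25 bp step across a span centered
on the associated CpG, computes the pooled level *sum-then-divide* within
each (meQTL, class, window), and averages those levels unweighted across
meQTLs, omitting empty windows. The window step is not dictated by the
procedure's definition; 25 bp (half-window overlap) is the package default
and the curve shape is insensitive to it at aggregate scale. Orientation by
methylation direction makes the curves invariant to allele relabeling.

## TF binding and methylation

`pwm_score()` is the standard log-odds score
$\sum_i \log_2 \big(p(b_i, i)/q(b_i)\big)$ with uniform background and a
$10^{-3}$ pseudocount by default (configurable; zero for exact toy
matrices). `allele_scores()` substitutes each allele at the SNP's offset in
the motif window and scores on the annotated strand (minus-strand windows
are reverse-complemented, which reverse-complements the substituted allele
with them). The association covariate is the dosage-weighted mean allele
score ${\rm score}_{\rm ref} + \tfrac{d}{2}\Delta$, affine in dosage — so
the test is numerically the dosage regression with the sign carried by the
predicted-affinity change. This additive coding is the least-assumptive
reading of scoring "each genotype"; a 3-level factor coding would change
degrees of freedom without adding information at $n = 64$. Per-TF summaries
count a SNP as significant when any probe within 500 bp passes the per-TF
FDR, with a matched permutation null drawn from binding-site SNPs that have
a CpG within 500 bp.

# The synthetic cohort

`sim_config()` defaults describe the study conditions the package emulates:
64 individuals; common variants (MAF drawn per LD block from
$U(0.1, 0.5)$); 2 kb LD blocks simulated as two-pool haplotype draws with
95% fidelity (pairwise within-block dosage correlation ≈ 0.9) — enough LD
to exercise the candidate-causal filter without a coalescent simulation;
bimodal probe baselines (logit-scale mixture at $\pm 2.5$); unit-sd latent
noise with planted effects in sd units; a 1.5 kb regional effect span with
boxcar decay (Gaussian optional), mirroring the 1.5–2 kb of correlated
methylation observed around real meQTLs; four weak hidden confounders; and
bisulfite reads at Poisson coverage (2.4× by default) with binomial
methylated counts, where conversion failure creates false-methylated calls
only, matching the chemistry.

Two design choices deserve a note:

* **MAF floor.** The generator must satisfy its own recoverability
  contract: a planted 1.5 sd latent effect at $n = 64$ should be recovered
  for ≥ 95% of causal probes at FDR 10%. The closed-form noncentral-$t$
  power at the scan's operating threshold is ≈ 0.85 for a SNP at MAF 0.05
  but ≈ 0.99 at MAF 0.1, so the default MAF range starts at 0.1. Users
  studying the power boundary can lower it per configuration.
* **Non-overlapping causal regions.** Causal probes are thinned so no two
  regional spans overlap. Overlapping opposite-sign effects would make the
  recorded truth ambiguous (the net effect at a probe could contradict its
  planted sign). Real meQTL loci are sparse — on the order of 4% of assayed
  probes — so the thinning also keeps the fixture realistic. The `affected`
  truth table records every probe inside a causal span, and recovery
  metrics count a called probe as correct when it lies in any planted
  region.

What the generator does **not** emulate: probe chemistry (type I/II
designs, dye bias), realistic recombination maps or allele-frequency
spectra, cell-composition heterogeneity, and trans effects other than the
low-rank confounders. Passing tests therefore demonstrate the statistical
machinery is correct under the stated model, not that any biological
conclusion transfers to a particular real cohort.

# Numerical and calibration notes

* The vectorized scan is checked against an independent textbook OLS +
  $t$-CDF computation to $10^{-10}$ on random instances.
* Under permuted genotype labels the scan's p-values are uniform to
  $D \approx 0.007$; the residual deviation is the finite-$n$
  $t$-approximation with discrete dosages, invisible in a QQ plot. A
  Kolmogorov–Smirnov check of uniformity assumes independent observations,
  which the dense cis design violates badly (many SNPs per window,
  regionally correlated probes); the calibration test therefore runs the
  KS check on a sparse layout (independent probes, ~2 SNPs per window)
  where its premise holds, and checks the zero-false-discovery property on
  the dense layout, where clustered dependence is the realistic condition.
* Empirical permutation p-values use the add-one estimator
  $(b+1)/(B+1)$; tests run $B = 999$ at desk scale, and the machinery
  accepts $B = 10^5$ for production-size analyses.
* Degenerate inputs: constant vectors rank-normalize to zeros with a
  warning; constant dosages and zero-delta affinity covariates are skipped
  as zero-variance; an empty MAF-passing SNP set yields an empty scan with
  a warning rather than an error.
* Problem sizes in the tests and the acceptance script (cohorts of 64
  samples, $10^3$–$6 \times 10^3$ probes, up to $8 \times 10^3$ SNPs,
  $B \le 999$) were chosen so the whole suite exercises every code path in
  minutes on a laptop; all of them scale linearly.

# Worked example

```{r example, eval = FALSE}
cfg  <- sim_config(seed = 1)
geno <- simulate_genotypes(cfg)
sim  <- simulate_methylation(geno, cfg)

norm  <- quantile_normalize(sim$beta, "two_stage")
sel   <- select_num_pcs(norm, geno, sim$manifest, k_grid = 0:6)
resid <- remove_pcs(norm, sel$k)

assoc <- cis_scan(resid, geno, sim$manifest, window = 3000, maf_min = 0.05)
mq    <- call_meqtls(assoc, fdr = 0.10)
mean(sim$truth$causal_pairs$probe_id %in% mq$probe_id)   # recall of planted truth
```

The `analysis/` directory holds the same pipeline as six numbered,
narrative scripts (simulation → preprocessing → scan → sharing → bisulfite
→ TF binding) whose tables land under `results/`.

# Known limitations

* The mappability filter accepts a flag set; the package does not re-run an
  aligner to decide which probes map uniquely.
* The probe-body SNP-overlap interval defaults to the 50 bp ending at the
  CpG and is configurable; array designs differ.
* Whether pooled FDR should be computed per test or per probe-minimum is a
  genuine ambiguity; the pooled-test convention is used, with probe-level
  counting applied afterwards.
* The counts reported by the correlated-neighbor audit are probes appearing
  in at least one significant pair, on both the normalized and the
  untransformed matrix, and are labeled as such — the two counts answer
  slightly different questions and neither is "the" number of redundant
  probes.
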