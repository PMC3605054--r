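---
title: "Trans-ethnic fine-mapping of quantitative trait loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-ethnic fine-mapping of quantitative trait loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transfine)
```

## The problem

Dense genotyping of established GWAS loci in several ancestry groups serves
two purposes. First, loci often harbour *allelic heterogeneity* — several
distinct trait-influencing variants — which single-marker scans conflate into
one signal. Second, linkage disequilibrium (LD) differs across ancestry
groups: African-ancestry samples in particular carry shorter haplotypes and
lower average pairwise $r^2$, so an association signal that spans hundreds of
kilobases in Europeans may be resolvable to a handful of variants, and
combining groups can narrow the candidate set further. `transfine`
implements the statistical machinery for this setting: per-study association,
fixed-effect meta-analysis, sequential conditional signal discovery, LD and
haplotype analysis, variance decomposition, region refinement, and power.

## Association model

For trait value $y_i$, effect-allele dosage $g_{ij} \in \{0,1,2\}$ of variant
$j$, and covariates $c_{ik}$ (age, sex, principal components, study
indicators), `run_association()` fits by ordinary least squares

$$ y_i = \alpha + \beta_j g_{ij} + \sum_k \gamma_k c_{ik} + \varepsilon_i, $$

the additive model, one variant at a time, and reports $\hat\beta_j$, its
standard error, and a two-sided $p$ from the $t$ distribution with residual
degrees of freedom (exact for OLS; indistinguishable from the normal at the
sample sizes of interest). Internally the scan residualizes $y$ and all
dosage columns against the base design once (Frisch–Waugh–Lovell), which is
algebraically identical to per-variant `lm()` fits. Skewed traits such as
triglycerides are natural-log transformed first (`transform = "log_e"`;
non-positive values are an error, not silently dropped).

Choices worth knowing:

* **Missing dosages are mean-imputed per variant** by default so that $n$ is
  constant across variants of a locus — the sequential conditional scan
  compares $p$ values across variants, which differing $n$ would distort.
  `missing = "complete"` restores complete-case behaviour.
* **Monomorphic variants yield no result row** (they are listed with reasons
  in the `"skipped"` attribute), mirroring the convention of printing `----`
  for untestable variants.
* A covariate that duplicates the tested variant makes the coefficient
  unidentifiable; the scan raises an error rather than absorbing it. During
  conditional scans exact duplicates of conditioned variants are skipped with
  a reason instead, and variants with $r^2 > 0.95$ to a conditioned variant
  are flagged but retained.
* $p$ values are floored at $10^{-300}$ so downstream $\log_{10}$ arithmetic
  never sees zero.

## Fixed-effect meta-analysis and heterogeneity

`ivw_meta()` combines per-study estimates with inverse-variance weights
$w_i = 1/\mathrm{se}_i^2$:

$$ \hat\beta = \frac{\sum_i w_i \hat\beta_i}{\sum_i w_i}, \qquad
   \mathrm{se} = \Big(\sum_i w_i\Big)^{-1/2}, $$

with a two-sided **normal** $p$ (the fixed-effect convention; the $t$ is
reserved for the within-study fits). Heterogeneity is summarized by
Cochran's $Q = \sum_i w_i(\hat\beta_i - \hat\beta)^2$ with $k-1$ degrees of
freedom, its $\chi^2$ tail $p_{het}$, and $I^2 = \max(0, (Q - df)/Q) \cdot
100$ (percent, floored at zero). IVW combination is associative: combining
11 study groups directly equals combining the three per-ancestry combinations
— this licenses reconstructing a trans-ethnic meta-analysis from published
ancestry-level statistics. For that reconstruction `se_from_beta_p()` inverts
the normal test, $\mathrm{se} = |\beta|/z_{p/2}$; with effect sizes printed
to 2 decimals and $p$ to 2 significant figures, the propagated uncertainty on
$-\log_{10} p_{meta}$ is roughly 0.3–0.5, which is why the bundled
reconstruction example is checked at $\pm 0.5$. `direction_string()` encodes
per-study effect signs as `+`/`-`/`?` in a fixed study order. No
genomic-control correction is applied before or after combination.

## Sequential conditional analysis

`sequential_conditional()` iterates: scan all regional variants conditioning
on the leads admitted so far; take the variant with the smallest conditional
$p$ (ties: smaller se, then lower position); admit it if

* $p < 10^{-4}$ (the threshold motivated as an approximate Bonferroni
  correction for a few hundred variants per locus), or
* $p < 10^{-2}$ **and** the variant is annotated nonsense or nonsynonymous —
  the annotation override that keeps a protein-altering variant narrowly
  missing the threshold in the signal list;

otherwise stop. The override is bounded by `functional_floor` because an
unbounded "looks functional" rule would never terminate; the default
$10^{-2}$ comfortably covers the motivating case of a conditional $p$ around
$5\times10^{-4}$. Admission uses strict inequality; $p$ exactly at the
threshold stops the scan. `max_signals` (default 10, above any plausible
real locus) guarantees termination and warns when reached.

Each signal is classified as *population-specific*
(`classify_population_specific()`) when its variant has effect-allele
frequency exactly 0 or 1 in the study panels of both other ancestry groups,
and — when reference pools are supplied — in those as well. A pair of
signals can be profiled with `dependence_report()`: conditioning can make a
partner's $p$ *larger* (shared signal), leave it within an order of magnitude
(independent), or make it *smaller* — the masked, repulsion-phase pattern in
which a trait-decreasing allele is carried on haplotypes bearing another
signal's trait-increasing allele.

## Haplotypes and LD

`em_haplotype_frequencies()` estimates multilocus (2–8 sites) haplotype
frequencies from unphased genotypes by EM under random mating: the E-step
assigns each individual's compatible diplotypes posterior probabilities
proportional to $f_j f_k$ (doubled for $j \neq k$), the M-step re-estimates
frequencies from expected counts. The log-likelihood trace is recorded and
must be nondecreasing; the default start is linkage equilibrium (the
two-locus likelihood is well behaved from there), with optional seeded
multi-start for three or more sites. Individuals missing any of the sites
are excluded. Haplotypes below $10^{-6}$ are pruned from the output.

`ld_stats()` derives $D = p_{AB} - p_A p_B$, $D' = |D|/D_{max}$ and
$r^2 = D^2 / (p_A q_A p_B q_B)$ from the two-locus EM frequencies and refuses
monomorphic variants ($r^2$ is undefined there). `haplotype_regression()`
regresses the trait on posterior expected copy counts of each non-reference
haplotype (haplotypes under `freq_floor` pooled into one rare column), so a
coefficient is the expected trait change per additional copy relative to the
reference (default: the most frequent haplotype; configurable). This is a
single-step expectation substitution rather than an iterated EM-GLM — a
documented approximation that is accurate at common haplotype frequencies.

## Variance explained, regions, and power

`delta_r2()` computes $R^2$ for covariates-only, covariates + lead, and
covariates + all signal SNPs on the complete cases shared by all three models
(so the subtraction is meaningful), reporting
$\Delta R^2_{lead}$, $\Delta R^2_{all}$ and their ratio (the *fold
increase*). Because signal SNPs are selected for significance in the same
data, these estimates carry winner's-curse inflation; this is surfaced as a
caveat, not corrected. `signal_region()` builds an association region either
from all variants with $p$ below a threshold or all variants with $r^2$ to
the lead above a cut; `transethnic_refinement()` intersects per-ancestry
regions and restricts the meta-analysis region's members to the
intersection, flagging disjoint regions (distinct signals) instead of
forcing an intersection.

`power_quantitative()` uses the noncentral $\chi^2_1$ with
$\lambda = n \cdot 2p(1-p)\beta^2/\sigma^2$: power is the mass beyond the
central critical value at level $\alpha$; at $\beta = 0$ it equals $\alpha$
exactly. The residual $\sigma$ is a user supplied assumption (no covariate
adjustment of $\lambda$); $\sigma = 0.5$ on a log-scale lipid trait
reproduces published low-frequency power figures in the 15%–55% range, but
that value is an inference, not a measured quantity.

## The synthetic-data generator

`sim_config()` + `make_multi_ancestry_study()` emulate a three-ancestry,
11-study design (five African-American, two East Asian, four European study
groups; 6,832 / 9,449 / 10,829 individuals by default — the within-ancestry
split is synthetic except for the two East Asian cohort sizes, which are
known). The LD model is a **block-mosaic founder-haplotype scheme**, not a
coalescent: each ancestry has $K$ founder haplotypes with a fixed frequency
vector; an individual haplotype copies one founder per block and switches
founders between blocks with probability `recomb`. Using a single frequency
vector per pool makes the founder-index chain's marginal identical at every
block, so pool allele frequencies are exact expectations of sampled ones.
Switch rates are high for every ancestry (0.95 / 0.9 / 0.8) so that LD is
concentrated within blocks — the haplotype-block regime, under which distant
blocks are effectively independent ($r^2 < 0.01$). The ancestry contrast is
carried by block length and founder count: African-American pools use
shorter blocks (8 vs 25 variants) and more founders (16 vs 5), plus a crude
0.8/0.2 two-subpool admixture in the founder frequencies — enough to create
the low-LD regime that drives trans-ethnic narrowing, without
local-ancestry tracts.

Variant targets span the full MAF spectrum (10% rare < 0.005, 20% less
common, 70% common by default). Common and less-common variants are placed
on greedy founder subsets whose total frequency approximates the target —
this is also what induces within-block LD. Rare targets cannot be
represented on founders with $K \le 16$, so they are drawn as independent
per-haplotype Bernoulli overlays: rare variants are therefore in linkage
equilibrium with everything, a deliberate simplification. A configurable
fraction of variants is restricted to one ancestry (effect-allele frequency
exactly 0 elsewhere), emulating population-specific variation.

Traits follow $y = \sum_j \beta_j g_j + \sum_k \gamma_k c_k + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, with simulated covariates age $\sim
U(30, 70)$ and sex $\sim$ Bernoulli(0.5) (default effects 0.01 per year and
0.1). `scale = "log_normal"` reports $\exp(y)$, so log transformation
recovers the linear model — the triglyceride convention.

What a green test on this generator does **not** establish: robustness to
genotyping error, family structure (related samples must be pre-pruned; no
mixed model is provided), imputation uncertainty, realistic demographic
history or selection, X-chromosome dosage, or case–control traits. The
generator exists to verify the statistical machinery against known truth,
not to imitate any particular cohort.

## Numerical and design choices

* Coordinates are 1-based; no liftover. Effect allele defaults to the VCF
  ALT allele (a minor-allele orientation flag exists) because published
  effect alleles are not always the minor allele.
* Multi-allelic VCF records are rejected by default (`"split"` emits one
  biallelic record per ALT allele).
* Strand/allele harmonization across cohorts is assumed done upstream:
  `ivw_meta()` refuses mismatched alleles rather than attempting to fix
  them.
* Covariates enter regressions directly (no pre-residualization of the
  trait).
* Ties in the conditional scan are broken by se, then genomic position, so
  the admitted sequence is deterministic.
* Per-locus Bonferroni thresholds can be expressed by passing a different
  `threshold` per locus; the default is the flat $10^{-4}$.
* All generator randomness flows from one integer seed; derived seeds stay
  within 32-bit range.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_loci = 1, variants_per_locus = 100, seed = 1)
pool <- build_haplotype_pool(cfg, "AFR_AM")
panel <- sample_genotypes(pool, 4000, seed = 2)
v <- c("L1_v003", "L1_v100")   # two uncorrelated common variants
spec <- causal_spec(data.frame(variant_id = v, beta = c(0.20, 0.15),
                               ancestries = "all"),
                    sigma = 1, trait = "LDL")
pheno <- simulate_phenotype(panel, spec, seed = 3)
sequential_conditional(panel, pheno, "LDL", c("age", "sex"))
```

## Limitations

Beyond the generator's simplifications listed above: the conditional
analysis requires individual-level genotypes (no summary-statistic
approximation with an LD reference); haplotype analysis is capped at 8 sites;
variance-explained estimates are winner's-curse inflated by design of the
procedure; and the power model ignores covariate adjustment, which makes it
slightly conservative when covariates explain trait variance.
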