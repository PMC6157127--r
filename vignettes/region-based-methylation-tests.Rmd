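---
title: "Region-based tests of methylation change in family studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based tests of methylation change in family studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methregion)
```

## The problem

Single-CpG epigenome-wide association scans of drug response are often
underpowered: many small, coordinated methylation changes across a gene can
matter even when no individual CpG reaches significance. `methregion`
implements region-level association testing of *methylation change* against a
*lipid-response* outcome in family cohorts, where relatedness must be
modelled rather than ignored.

The design it targets is a pre/post intervention study: beta-value
methylation matrices at two timepoints, pedigrees, and lipid measurements
before and after treatment. Regions are genes; a gene's region spans from
100 kb before its first transcript start site to 100 kb after its last one,
and contains every QC-passed CpG probe inside that window.

## Models and statistics

**Outcome.** The response is the signed log-ratio
$y_i = \log(\mathrm{lipid}^{pre}_i) - \log(\mathrm{lipid}^{post}_i)$.
A plain "log of the change" is undefined whenever the raw change is
negative — which happens for roughly half of HDL-C responses — so the
log-ratio is used: it is defined for all positive lipid pairs, monotone in
the raw change, and keeps the pre-minus-post orientation used for the
methylation changes. A global switch flips the orientation of all changes if
the opposite sign convention is preferred.

**Null model.** Covariates (age, sex, field centre, metabolic syndrome, two
smoking indicators, and any methylation principal components marginally
associated with the outcome at $\alpha = 0.05$) enter as fixed effects, and
family structure as a polygenic random effect:
$$ y = X\alpha + g + \varepsilon,\qquad
   g \sim N(0, \sigma_g^2 \, 2\Phi),\quad
   \varepsilon \sim N(0, \sigma_e^2 I), $$
where $\Phi$ is the pedigree kinship matrix computed by the standard
recursion (founders: $\phi_{ii} = 1/2$; otherwise
$\phi_{ii} = (1+\phi_{fm})/2$, $\phi_{ij} = (\phi_{fj}+\phi_{mj})/2$).
Estimation is REML after rotating by the eigenvectors of $A = 2\Phi$, which
reduces the problem to a one-dimensional search in the variance ratio
$\delta = \sigma_e^2/\sigma_g^2$. We bracket on a 100-point log-spaced grid
over $[10^{-5}, 10^{5}]$ and refine by golden-section search to $10^{-8}$
relative tolerance; the boundary solution $\sigma_g^2 = 0$ is always
evaluated explicitly (it is the OLS limit of the restricted likelihood) and
wins ties. The fit also reports a boundary LRT p-value for
$\sigma_g^2 > 0$ against the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture
reference; under a true zero polygenic variance the REML point estimate
lands exactly on the boundary only about half the time, so this LRT — not
the point estimate — is the meaningful boundary diagnostic.

**MMLT.** The median methylation level test summarises a region, per sample
and per timepoint, by the median beta across its CpGs, and tests the change
of medians as one extra fixed-effect covariate: the model is refitted by
REML with the median-change column appended and the Wald statistic
(estimate/SE against the standard normal) is reported.

**SKAT.** The set test uses per-CpG score statistics under the single global
null fit, $S_j = Z_j^\top P y$ with
$P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}$, and the statistic
$Q = \sum_j w_j^2 S_j^2$ — unweighted ($w_j = 1$) by default. Under the
null, $Q$ follows a mixture of 1-df chi-squares with weights equal to the
eigenvalues of $W^{1/2} (Z^\top P Z) W^{1/2}$, $W = \mathrm{diag}(w_j^2)$.
Nothing is refitted per region, so genome-wide scans cost one REML fit plus
cheap linear algebra per region.

**Mixture p-values.** The tail probability
$P(\sum_i \lambda_i \chi^2_{1,i} > Q)$ is computed by characteristic-function
inversion (Imhof's formula). The integrand oscillates with slowly decaying
amplitude, so the integral is evaluated panel-by-panel between consecutive
zeros of the oscillation, and the alternating tail series of panel integrals
is extrapolated by iterated averaging (Euler acceleration); when all
retained eigenvalues are equal the mixture is an exactly scaled chi-square
and is computed as such. Eigenvalues below $10^{-10}\,\lambda_{max}$ are
dropped as numerical rank control. The Liu–Tang–Zhang four-moment
approximation is the fallback whenever the inversion reports a fault or the
p-value is at the integration noise floor ($p \le 10^{-12}$).

**Dosage weighting.** The sensitivity variant maps each change
$\Delta \in [-1, 1]$ to a dosage $d = \Delta + 1 \in [0, 2]$ and computes a
per-CpG dosage frequency $f = \overline{d}/2$. The folded frequency
$f^* = \min(f, 1-f)$ plays the role of a minor allele frequency: $f^*$ near
0.5 means the CpG did not change, small $f^*$ means it changed consistently
in one direction. Folding is deliberate — a CpG whose methylation
consistently *dropped* ($\Delta$ near $-1$, $f$ near 0) and one that
consistently *rose* ($f$ near 1) are equally "changed" and should be
weighted alike. Weights are the Beta(1, 25) density at $f^*$ (the seqMeta
default for rare variants); both parameters are exposed. Only relative
weights matter: rescaling all $w_j$ by a constant rescales $Q$ and every
eigenvalue together and leaves the p-value unchanged.

**Multiplicity and diagnostics.** Benjamini–Hochberg q-values are computed
per method (via `p.adjust`). QQ summaries use $(i - 0.5)/m$ plotting
positions, and the genomic-control factor is
$\lambda_{GC} = \mathrm{median}\{\chi^2_1(1-p)\}/0.4549$, computed from
p-values so that Wald and mixture tests are comparable on one scale.
Stratified QQ bins regions by the quartiles of their CpG counts (breaks at
the 25/50/75 percentiles, ties to the lower bin).

## Key tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `flank` | 100 000 | bp added on each side of the TSS hull |
| `n_pcs` | 20 | PCs per timepoint offered to the covariate screen |
| `screen_alpha` | 0.05 | marginal p threshold for PC selection |
| `beta_a`, `beta_b` | 1, 25 | Beta density parameters for dosage weights |
| `fdr_threshold` | 0.05 | BH q-value significance level |
| `orientation` | pre − post | global sign convention for all changes |

## Design choices where the design was open

- **Region hull.** "100 kb of the first TSS" is read as 100 kb upstream of
  the smallest TSS coordinate; together with "100 kb downstream of the last
  TSS" the region is the strand-independent hull
  $[\min \mathrm{TSS} - 100\mathrm{kb},\ \max \mathrm{TSS} + 100\mathrm{kb}]$,
  clipped at position 1. A strand-aware reading is ill-defined once
  transcripts of both strands share a gene id; the hull is not.
- **Coordinates** are 1-based inclusive everywhere; BED input is shifted on
  read, GTF is native. Interval membership is inclusive at both ends.
- **Missing values** are never imputed upstream: NA probes are dropped per
  (sample, region) before medians, complete-case probes only enter the PCA,
  and only the score-test matrix mean-imputes per CpG (score tests need
  complete columns; the imputation is logged).
- **Medians of even-sized sets** are the mean of the two central values.
- **PC screening** uses simple marginal regressions, not mixed models: it is
  a cheap conventional screen, and the null model downstream re-adjusts for
  whatever is selected.
- **Wald, not LRT, for MMLT**, matching the effect/SE/p presentation of
  kinship-LMM software (`lmekin`-style output).
- **REML, not ML**, for variance components.
- **BH step-up** is delegated to `p.adjust(method = "BH")`; the test-suite
  cross-checks it against an independently written step-up implementation.

## The synthetic cohort generator

Restricted data cannot ship with the package, so `simulate_study()`
generates complete study inputs with known truth, used by every calibration
and power check:

- **Pedigrees**: 139 families by default, a mix of trios (80%) and
  two-child nuclear families (20%) averaging ~3.2 members — the scale of
  the motivating cohort (~446 individuals). Three-generation families are
  available.
- **Methylation**: logit-normal beta values (region mean + CpG offset +
  individual noise on the logit scale, default SDs 1 / 0.5 / 0.3); the post
  matrix adds a per-CpG treatment shift (SD 0.15) and per-observation noise
  (SD 0.12) on the same latent scale. The logit-normal form keeps values in
  $[0,1]$ with tunable per-CpG variance.
- **Covariates and lipids** are calibrated to the cohort's descriptive
  table: age $47 \pm 16$, ~52% women, ~55% Utah, 40% metabolic syndrome,
  smoking 71/22/7%. Raw lipids are back-constructed (`pre` log-normal,
  `post = pre · exp(−y)`) so the pipeline's log-ratio transform reproduces
  the generated outcome exactly.
- **Outcome**: $y = X\alpha + \sum_j \tau_j \Delta_j + g + \varepsilon$ with
  $g$ polygenic over the simulated kinship. Heritability defaults to
  $h^2 = 0.3$ with total random SD 0.4 on the log-ratio scale — a
  mid-range value for lipid-response traits at a realistic outcome scale.
- **Scenarios**: `null` (no effects); `concordant` / `opposing` (all causal
  CpGs share a sign / alternate signs of equal magnitude, with
  $\tau = 3$ calibrated once to give roughly 50% SKAT power at
  $\alpha = 0.05$ in the opposing design at $n \approx 300$);
  `sparse_change`, in which only ~20% of each region's CpGs receive a
  treatment shift (larger, SD 0.3, so their dosage frequencies separate
  from the background) while the unchanged majority carry shared batch
  offsets that also leak into the outcome — emulating the unmodelled
  technical confounding that inflates an unweighted set test and that
  dosage weighting is meant to damp.

What the generator does **not** emulate: probe-type chemistry (no BMIQ-type
normalisation is needed or modelled — the pipeline accepts already
normalised matrices), cell-type composition, genotypes, sex chromosomes,
and realistic 450K probe spacing. Passing calibration tests on synthetic
cohorts therefore demonstrates the statistical machinery, not robustness to
those real-data artefacts.

## Simulation sizes used by the checks

The packaged checks run null calibration on 1 000 regions pooled across five
independent cohorts of ~300 individuals (pooling matters: all regions of one
cohort share one outcome realisation, so a single cohort's empirical size
has conditional-on-outcome noise that pooling removes); power contrasts on
10 batches of 40 regions per scenario; the weighting comparison on five
sparse-change cohorts of 250 regions; variance-component recovery on 200
replicates of 100 nuclear families; and Monte-Carlo cross-checks of the
mixture engine at 200 000 draws. `scripts/acceptance.R` recomputes the same
quantities at slightly smaller sizes and writes them as JSON.

## Known limitations

- Gaussian outcome only; no binary or survival responses.
- One polygenic variance component; no genotype-based (empirical GRM)
  kinship, no extra random effects for batch or household.
- No SKAT-O or burden tests, and no small-sample (kurtosis-adjusted)
  corrections of the SKAT null — at a few hundred samples the asymptotic
  mixture is adequate, as the calibration checks confirm.
- The dosage-weighting conclusions depend on the weight parameters and on
  how sharply changed and unchanged CpGs separate in dosage frequency.

## A worked miniature

```{r example, eval = FALSE}
cfg <- scenario_config(n_families = 60, n_regions = 50,
                       scenario = "null", seed = 1)
study <- simulate_study(cfg)
run <- run_pipeline(pipeline_config(study = study, n_pcs = 5))
run$results          # gene, n_cpg, method, effect/se or Q, p, q
glance(run$fit)      # variance components and boundary LRT
autoplot(qq_summary(run$results[run$results$method == "SKAT", ],
                    stratify_by_ncpg = TRUE))
```
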