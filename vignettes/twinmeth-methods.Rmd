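---
title: "Methods: discordant MZ-twin EWAS of serum ALT with causal inference"
author: "twinmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discordant MZ-twin EWAS of serum ALT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

# The analysis problem

Serum alanine aminotransferase (ALT, U/L) marks hepatocyte injury and is
heritable. An epigenome-wide association study (EWAS) in unrelated subjects
confounds environmental methylation signals with genetic background; a
discordant monozygotic (MZ) twin design removes that confounding because
co-twins share their genome and much of their rearing environment. This
package implements the full analysis chain for such a design — per-CpG mixed
models, ICE FALCON causal inference, region detection, enrichment, power
simulation, and a matched-cohort validation stage — together with a
synthetic-cohort generator that plants known causal structure, so every
stage can be tested quantitatively without the original cohort.

# The synthetic twin cohort

`simulate_cohort()` draws, for each CpG $g$ and twin $j$ of pair $i$,

$$M_{gij} = \mu_g + a\,C_{gi} + (\text{cell term}) + e_{gij},$$

with a pair-shared standard-normal component $C_{gi}$ scaled so that
$a^2 = \texttt{familial\_var\_share}\cdot m\_sd^2$, and an individual
residual $e$ with within-pair correlation `rho_eps` and variance
$(1-\texttt{familial\_var\_share})\,m\_sd^2$. Thus the within-pair M-value
correlation at null CpGs is
$\texttt{familial\_var\_share} + (1-\texttt{familial\_var\_share})\,\rho_\varepsilon$
(0.55 at the defaults), a property the test-suite checks by Monte Carlo.
Baseline levels $\mu_g$ are drawn from a bimodal beta mixture, clipped away
from 0/1; beta-values are recovered by the inverse-logistic transform and
clipped to [0.001, 0.999].

ALT is generated on the log scale and exponentiated, so it is positive and
right-skewed (baseline median ≈ 17 U/L, log-sd 0.55, matching a 20 (12–26)
median/IQR after covariate contributions): a pair-shared heritable component
carries a fraction `h2` (default 0.6) of the log-scale baseline variance.
Onto this baseline the generator adds linear covariate contributions (age,
sex, BMI, alcohol, hypertension, diabetes — drawn with within-pair
correlation 0.3 where not pair-shared), the planted causal methylation
effects `effect_m_to_alt * (M - mu)`, and a shared-confounder contribution.
Pairs whose ALT difference falls below 1 U/L have their individual
phenotype residuals redrawn, mirroring the discordance inclusion rule.

Three planted CpG classes define the benchmarks:

* **causal** — M enters ALT directly with slope `effect_m_to_alt`
  (U/L per unit M);
* **reverse-causal** — after ALT is drawn, `effect_alt_to_m * (ALT -
  mean(ALT))` is added to M;
* **confounded** — a single pair-shared latent $C^*$ loads on the CpG's
  familial component *and* adds `confound_effect * C^*` to ALT, with no
  direct path. The default `confound_effect` is derived as
  `effect_m_to_alt * m_sd / sqrt(familial_var_share)`, which equates the
  confounded CpGs' marginal M–ALT covariance with the causal CpGs' — the
  two classes are equally tempting to a marginal test, which is exactly
  what a specificity benchmark requires.

The methylation–environment coupling `r2_me` (default 0.1) correlates the
phenotype's environmental residual with the causal CpG's individual
residual. Note its consequence: with `r2_me > 0` the marginal (and
within-pair) M–ALT slope exceeds the planted causal coefficient, because
part of the association is genuinely environmental confounding. Parameter
recovery is therefore assessed at `r2_me = 0`, where the causal coefficient
is the estimand.

What the generator does **not** emulate: read-level RRBS noise and coverage
(missingness is a Bernoulli mask, not coverage-driven), fine-scale
co-methylation decay along the chromosome (co-methylation is planted only
in clustered causal CpGs), non-Gaussian methylation residuals, and
cell-composition differences between twins' blood draws beyond a Dirichlet
per-sample mixture. Passing tests therefore demonstrate correctness of the
estimators under a well-specified generative model, not robustness to every
artefact of real bisulfite data.

CpGs are laid out in islands (10 CpGs, 50 bp spacing) separated by 10 kb
gaps, about eight islands per chromosome, so a chromosome's tested span —
which drives the DMR multiplicity correction — includes realistic
inter-island distances.

# Quality control and cell composition

`filter_cpgs()` removes CpGs with mean beta below 0.01 or above 0.99, or
with more than 10 missing observations; the rules are strict inequalities
(a CpG with exactly 10 missing stays), and each removed CpG is attributed
to the first filter it fails so the report counts are additive.
`beta_to_m()` is the usual $\log_2 \beta/(1-\beta)$.

`refactor_components()` implements the reference-free sparse-PCA-style
procedure: standardize CpGs, form the rank-$k$ SVD approximation, rank CpGs
by reconstruction distance, and take the first $k$ principal-component
scores of the top-$t$ CpGs ($k = 5$, $t = 500$ by default; $t$ is the
procedure's published default). Missing
entries are mean-imputed for component extraction only; the association
scan itself uses observed values per CpG.

# The per-CpG mixed model

Each CpG is tested with

`ALT ~ M + age + sex + alcohol + BMI + hypertension + diabetes +
components + (1 | pair)`

fitted by REML. Because clusters are twin pairs (size ≤ 2 after
missingness), the model is fitted by a specialized routine
(`fit_pair_lmm()`): the (sum, difference)/√2 transform of each complete
pair whitens the compound-symmetric covariance, REML reduces to a
one-dimensional profile optimization over the variance ratio, and
Satterthwaite degrees of freedom follow from the delta method with a
finite-difference REML Hessian — the same construction general
mixed-model software uses. The test suite verifies agreement with
`lmerTest::lmer` to ~1e-6 on coefficients and SEs and ~0.01 df on mixed
designs with singletons; the specialized fitter is far faster, which the
simulation suites (thousands of fits) depend on. At the boundary
(`sigma_a2` → 0) the fitter falls back to residual degrees of freedom
`n - p`.

Significance is controlled by Bonferroni over the tested CpGs
(`alpha / n_tests`; 0.05 over 233,720 CpGs gives the genome-wide threshold
2.14e-7). Nearest-gene annotation is purely local (a BED file), distance 0
inside a gene, ties broken deterministically by lower start coordinate.

# ICE FALCON

For each CpG and direction, the outcome of each twin is regressed on the
twin's own predictor (Model 1), the co-twin's predictor (Model 2), and both
(Model 3), over double-entered data (two role-swapped rows per pair).
Writing $\beta_{self}$, $\beta_{cotwin}$ for the marginal and
$\beta'_{self}$, $\beta'_{cotwin}$ for the conditional coefficients, the
changes $\Delta_{self} = \beta_{self}-\beta'_{self}$ and
$\Delta_{cotwin} = \beta_{cotwin}-\beta'_{cotwin}$ summarize what
conditioning on the co-twin does. Under causation the co-twin association
is an echo of the familial correlation and collapses once the self
predictor is held fixed ($\Delta_{cotwin}$ large, $\Delta_{self} \approx
0$); under familial confounding both coefficients attenuate alike. The
absolute value of the ratio, AVR $= |\Delta_{cotwin}|/|\Delta_{self}|$,
with threshold 1.5, separates the two.

Two implementation decisions deserve explanation.

**Working correlation.** The three models are estimating *marginal*
regressions; inference uses cluster-robust (sandwich) standard errors over
pairs. An exchangeable working correlation — the textbook choice for twin
data — is actively harmful here: in double-entered data the co-twin
predictor's within-pair contrast is the exact negative of the self
contrast, so the GLS step of an exchangeable fit mixes a sign-flipped
within-pair regression into Model 2 and can drive $\beta_{cotwin}$ to the
opposite sign of the marginal association it is meant to measure (we
observed exactly this on simulated causal CpGs). `gee_gaussian()` therefore
defaults to an independence working correlation (coefficients = OLS,
variance = cluster-robust sandwich), with exchangeable available as an
option.

**The causal verdict.** AVR alone is a ratio of two noisy quantities; on
null or weakly-informative CpGs it exceeds 1.5 about a quarter of the
time. `classify()` therefore requires the full causal pattern: AVR > 1.5,
the co-twin change sign-consistent with attenuation (not overshoot), the
co-twin change significant, and the self change *not* significant, at
level 0.05. Change significance uses influence-function (cluster-robust
Wald) standard errors that account for the joint estimation of Models 1–3;
a pair-level bootstrap (`bootstrap_change_p()`, B = 1000 by default) is
available for reported p-values where runtime permits. Measured on the
synthetic benchmarks at the calibrated effect (61 pairs, 200 replicates):
sensitivity ≈ 0.77 on causal CpGs, false-causal rate ≈ 0.12 on purely
confounded CpGs.

A caveat on directionality: with a strong familial phenotype correlation,
a truly reverse-causal CpG (ALT → M) also shows the attenuation pattern in
the M → ALT direction, because the co-twin's methylation proxies the shared
familial ALT path while being collinear with self methylation. The package
asserts detection of the true direction; it does not claim the two
directions are mutually exclusive.

# DMR detection

`call_dmrs()` follows the comb-p recipe on the EWAS p-value track:
estimate the autocorrelation of $z = \Phi^{-1}(1-p)$ in 50 bp distance
bins out to 500 bp; smooth each p-value by the Stouffer–Liptak–Kechris
combination of its 300 bp window using the ACF-derived correlation matrix
($z_{comb} = \sum z_i / \sqrt{\sum_{ij}\sigma_{ij}}$; negative estimated
autocorrelations are clamped at 0 and any remaining non-positive-definite
matrix is repaired by eigenvalue clipping, logged); grow candidate regions from runs
of smoothed p < 0.05 with inter-CpG gaps ≤ 300 bp and at least two members;
score each region by the Stouffer–Liptak combination of its members' *raw*
p-values (the slk p) and correct it for the number of possible same-sized
regions, $p_{Šidák} = 1-(1-p_{slk})^{L_{total}/L_{region}}$. The seed
threshold, gap, window and bin width are comb-p-style defaults and are
all exposed.

The `significant` flag defaults to the Šidák-corrected p < 0.05. Flagging
on the raw slk p would be anti-conservative by construction — on simulated
all-null tracks roughly half of the replicates produce at least one
slk < 0.05 region, while the Šidák rule leaves ≥ 95% of them clean — and
the Šidák step is precisely the multiplicity control of the region scan;
`sig_on = "slk"` restores the literal raw-slk rule if wanted. Region
direction is the 80% member-sign rule (positive / negative / uncertain),
our explicit operationalization of the positive/negative/uncertain
trichotomy such studies report.

# Enrichment

`build_domains()` constructs basal-plus-extension regulatory domains: a
basal window 5 kb upstream / 1 kb downstream of each TSS (strand-aware),
extended in each direction to the nearer of the neighbouring basal domain
or 1 Mb from the TSS. `binomial_enrichment()` tests each term by the exact
binomial tail: with $n$ query regions, annotated fraction $f$ (merged
domain width of the term's genes over the genome size — a required input,
never assumed), and $k$ hits, $p = P(\mathrm{Bin}(n, f) \ge k)$, fold
$= k/(nf)$, Bonferroni over terms. Published enrichment tables depend on
specific genome-annotation databases and are not reproducible at desk
scale; the module is tested against exact binomial sums and hand-computed
domain fixtures on synthetic annotations.

# Power

`estimate_power()` plants a single causal CpG under (h² = 0.6,
R²(M,E) = 0.1, ρε = 0.1), runs the same mixed-model fit as the association
scan, and counts rejections at α = 2.14e-7. The literature the design
draws on defines the per-CpG effect internally; the package therefore
calibrates it once — the smallest
effect reaching 80% power at 63 pairs under those parameters, found by
bisection at 4,000 replicates — and stores it as `calibrated_effect()`
(9.2 U/L per unit M-value). The 80%-at-63-pairs statement is then a
self-consistency property of the stored calibration, reproducible to the
digit under a fixed seed. ρε is applied to the methylation residual (the
ambiguity of which residual it describes is resolved by an exposed
parameter of the generator).

# Validation stage

`propensity_match()` fits a logistic model of abnormal-ALT status
(ALT > 40 U/L) on age and sex, then matches each case to up to three
controls by greedy nearest-neighbour search in a seed-randomized case
order, without replacement, with a caliper of 0.1 interpreted on the
probability scale. Cases with
no in-caliper control are dropped and logged. `conditional_logistic()`
maximizes the stratum-conditional likelihood (via the survival package's
conditional-logistic fit) of case status on a CpG or CpG-group methylation
measure, adjusted for BMI, alcohol, diabetes and hypertension; on 1:1
binary data this reduces exactly to the McNemar discordant-pair odds
ratio, which the tests assert to 1e-6. Complete separation and
zero-information strata are flagged, not estimated.

# Numerical choices and degenerate inputs

* REML profile optimization over log φ on [-14, 8], boundary φ = 0 checked
  explicitly; Satterthwaite df clamped to (0, n - p].
* Constant-M CpGs are an error ("degenerate predictor"); aliased covariate
  columns (e.g. an all-zero diabetes flag in a small cohort) are dropped
  silently per CpG.
* Probit transforms clip p to [1e-15, 1 - 1e-15].
* AVR with |Δ self| < 1e-12 is undefined and the verdict `inconclusive`.
* All stages take explicit integer seeds; the cohort generator derives its
  covariate / track / methylation / phenotype / missingness sub-streams
  from the global seed by fixed offsets, so any stage is reproducible in
  isolation.

# Problem sizes used by the shipped checks

The packaged test-suite and the acceptance script run, per replicate, 61
pairs with tracks of 5–1,000 CpGs; the discrimination suites use 200
replicates, DMR suites 50–100 replicates of 120-CpG tracks, and the power
check 1,000 replicates — sizes chosen so the full battery completes on a
single CPU in minutes while keeping Monte-Carlo error well inside the
asserted margins.

# Known limitations

* The generative model is linear-Gaussian on the M-value scale; real RRBS
  data have coverage-dependent precision that the mask does not mimic.
* ICE FALCON's directionality is informative, not decisive, under strong
  familial phenotype correlation (see above).
* The exchangeable GEE option is retained for completeness but should not
  be used for the double-entered co-twin models.
* Enrichment results on synthetic annotations demonstrate the machinery,
  not biology.
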