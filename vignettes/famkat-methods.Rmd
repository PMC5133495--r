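---
title: "Kernel score tests for quantitative traits in pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel score tests for quantitative traits in pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famkat)
```

## The model

famkat tests whether a *set* of SNPs — a gene, an LD block, a pathway
segment — is associated with a quantitative trait measured in families. The
trait model is the semiparametric mixed model

$$
\mathbf{Y} = \mathbf{X}\mathbf{b} + \mathbf{c} + \mathbf{h}(\mathbf{G}) + \mathbf{e},
$$

where $\mathbf{X}$ holds the fixed covariates (intercept, age, sex,
age × sex), $\mathbf{c}$ is a polygenic family effect with covariance
$s^2_{fam}\,\Phi_{kin}$ built from the pedigree kinship matrix,
$\mathbf{h}(\mathbf{G}) = \mathbf{K}\mathbf{a}$ captures the tested SNP set
through a kernel matrix $\mathbf{K}$ of genetic similarities with
$\mathbf{a} \sim N(0, \tau\mathbf{K})$, and
$\mathbf{e} \sim N(0, s^2_o \mathbf{I})$. Testing the SNP set is testing the
variance component $\tau = 0$, which avoids one-parameter-per-SNP
regression and the attendant multiple-testing burden.

Because quantitative traits such as systolic blood pressure are typically
right-skewed, the trait is first rank-normalized by the Blom transform
$y_i = \Phi^{-1}\{(r_i - 3/8)/(n + 1/4)\}$ (average ranks for ties),
applied once to the full analysis sample before any model fitting.
Covariates are not transformed.

Under the null ($\tau = 0$) the model is fit by REML, giving
$\hat{s}^2_o$, $\hat{s}^2_{fam}$,
$\mathbf{V}_0 = \hat{s}^2_o \mathbf{I} + \hat{s}^2_{fam}\Phi_{kin}$ and the
null projection
$\mathbf{P}_0 = \mathbf{V}_0^{-1} - \mathbf{V}_0^{-1}\mathbf{X}
(\mathbf{X}^T\mathbf{V}_0^{-1}\mathbf{X})^{-1}\mathbf{X}^T\mathbf{V}_0^{-1}$.
The score statistic is

$$
Q = \mathbf{R}^T \mathbf{M} \mathbf{R}, \qquad
\mathbf{R} = \mathbf{P}_0^{1/2}\mathbf{Y}, \qquad
\mathbf{M} = \tfrac12\, \mathbf{P}_0^{1/2} \mathbf{K} \mathbf{P}_0^{1/2},
$$

whose null distribution is the mixture $\sum_i \lambda_i \chi^2_{1,i}$ over
the eigenvalues of $\mathbf{M}$; tail probabilities come from Davies'
characteristic-function inversion. The familial covariance uses
$\Phi_{kin}$ itself rather than $2\Phi_{kin}$; the factor 2 is simply
absorbed into $s^2_{fam}$, so the fitted ratio
$h = s^2_{fam}/(s^2_{fam}+s^2_o)$ is *twice* the usual narrow-sense
heritability attributable to the polygenic term for non-inbred pedigrees.

## Kernels and SNP weights

Two kernels on minor-allele dosages $\mathbf{g}_i \in [0,2]^{N}$ are
provided, both weighted by a diagonal matrix $\mathbf{W}$ with
$W_{mm} = f(\nu_m)/\sum_m f(\nu_m)$ (so weights always sum to one within
the tested set):

* linear, $K_{ij} = \mathbf{g}_i^T \mathbf{W} \mathbf{g}_j$ — additive SNP
  effects, no interactions;
* RBF, $K_{ij} = \exp\{-\mu^{-1} (\mathbf{g}_i-\mathbf{g}_j)^T \mathbf{W}
  (\mathbf{g}_i-\mathbf{g}_j)\}$ — interactions of all orders. The scale
  $\mu$ is the average weighted squared genetic difference over all ordered
  subject pairs (including $i = j$, which contribute zero) multiplied by
  the effective number of independent SNPs.

Weight rules: `equal` ($f = 1$), `inverse_maf` ($f = 1/\nu$), and `beta`
($f = \mathrm{Beta}(\nu; 1, 25)$ density for $\nu \le 0.05$,
$\mathrm{Beta}(\nu; 0.5, 0.5)$ for $\nu > 0.05$). The Beta rule
distinguishes substantially different MAFs more moderately than $1/\nu$;
note this is a statement about well-separated MAFs — for nearly equal MAFs
just below the 5 % split the Beta(1, 25) density is locally the steeper of
the two (its log-derivative $-24/(1-\nu)$ exceeds $1/\nu$ in magnitude for
$\nu > 0.04$).

The effective number of independent SNPs uses the eigenvalue rule
$M_{eff} = \sum_i [\,1(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i
\rfloor)\,]$ on the SNP correlation spectrum (Li–Ji style). The estimator
is a convention rather than part of the kernel definition, so
`rbf_scale()` accepts any replacement through `m_eff_fun`. Eigenvalues are
rounded to 8 decimals before flooring because the rule is discontinuous at
integers and perfect-LD duplicates otherwise land at $N - \epsilon$.

## Joint testing of rare and common variants

SNPs surviving the inclusion filters are split at MAF 0.05 (boundary on the
rare side). Three joint strategies are available besides the separate
rare-only and common-only tests:

1. **K_all** — one kernel on all SNPs with a single weight normalization.
2. **Weighted sum (WS)** — $Q_{WS} = (1-\varphi) Q_{rare} + \varphi
   Q_{common}$ with $\varphi = \sqrt{\mathrm{tr}(M_r M_r) /
   (\mathrm{tr}(M_r M_r) + \mathrm{tr}(M_c M_c))}$, p-value by Davies on
   the eigenvalues of $(1-\varphi) M_r + \varphi M_c$. The trace-derived
   $\varphi$ is intended to balance the two variance contributions; note
   that under the null $\mathrm{Var}(Q) = 2\,\mathrm{tr}(M^2)$, so
   $(1-\varphi)^2\mathrm{tr}(M_r^2) = \varphi^2\mathrm{tr}(M_c^2)$ would
   require $\varphi$ with *squared* trace ratios — the printed square-root
   form does not algebraically equalize the two variances in general. The
   formula is implemented exactly as printed.
3. **Fisher pooling** — $Q_F = -2\ln p_{rare} - 2\ln p_{common}$, referred
   to a scaled chi-square with $16/(4 + cov)$ degrees of freedom and scale
   $1 + 0.25\,cov$, where $cov$ is a piecewise-quadratic function of the
   trace correlation $r = \mathrm{tr}(M_r M_c)/\sqrt{\mathrm{tr}(M_r^2)\,
   \mathrm{tr}(M_c^2)}$ ($r$ clipped to $[-0.5, 1]$, where the
   approximation is defined). These p-values are approximate; all others
   are Davies-based.

With independent SNP blocks the Fisher formula reduces to the classical
df-4 combination exactly at $r = 0$. In finite samples the *estimated* $r$
between genuinely independent blocks is $O(n^{-1/2})$ and positive (the two
test matrices share the null projection), so the reduction holds on
average rather than draw by draw; the test suite checks the exact identity
at $r = 0$ and a 1 % mean agreement over independent-block draws at
$n = 400$.

## SNP inclusion filters

A SNP enters testing if its Hardy–Weinberg chi-square p-value (computed on
dosages rounded to the nearest genotype; the rounding is used only for the
screens) is at least $10^{-5}$ and at least 7 copies of the minor allele
are observed. Both comparators are inclusive. The HWE screen is the 1-df
asymptotic test on all analyzed subjects, ignoring relatedness — a
pragmatic screen, not an inference. The minor-allele count is
$\min(s, 2n - s)$ with $s$ the rounded dosage sum, so a column whose
rounding pushes it past frequency 0.5 is still counted on the minor side.
MAFs are computed on the full analysis sample, related subjects included;
founder-weighted frequencies are not attempted, which biases MAF toward
the sampled families — acceptable for weighting and partitioning, where
only rough frequency classes matter.

## Null-model numerics

REML uses the reparameterization $(s^2_{tot}, h)$ with
$h = s^2_{fam}/s^2_{tot}$: after a one-time eigendecomposition
$\Phi_{kin} = U \Lambda U^T$, each profile-likelihood evaluation is $O(np)$,
the total variance is profiled out analytically, and $h$ is found by
bounded scalar search on $[0, 1-10^{-6}]$ with tolerance $10^{-8}$ —
deterministic and free of starting-value sensitivity. If the boundary
$h = 0$ matches the interior optimum to within $10^{-10}$ the boundary is
reported. $\mathbf{P}_0^{1/2}$ comes from an eigendecomposition of
$\mathbf{P}_0$ with eigenvalues below $10^{-10} \times \lambda_{max}$
clipped to zero ($\mathbf{P}_0$ is rank-deficient by construction, rank
$\le n - 4$). Sex is coded 0/1 with male reference; any full-rank coding
yields the identical $\mathbf{P}_0$, which the tests assert.

Degenerate inputs are handled explicitly: an all-constant trait fails the
Blom transform; a single-sex sample makes the age × sex column collinear
and errors; a kinship matrix with an eigenvalue below $-10^{-6}$ is
rejected; Davies inversion failures fall back to a Liu-type four-moment
chi-square approximation and are flagged `fallback` in the result.

## The synthetic-data generator

Because suitable family data are access-restricted, the package carries a
generator used by its own calibration studies:

* **Pedigrees** — `n_families` copies of a template; the default
  `three-generation-8` family (grandparental couple, two adult children,
  one married-in founder, three grandchildren) realizes kinship values
  exactly $\{0.5, 0.25, 0.125, 0\}$.
* **Haplotypes** — a Gaussian-copula pool: an AR(1) latent process with
  correlation `ld_rho` (default 0.5) thresholded at each SNP's target MAF
  quantile. Target MAFs are uniform on [0.01, 0.05] for the rare half and
  [0.05, 0.5] for the common half, 50 SNPs by default.
* **Gene drop** — founders draw two pool haplotypes; children inherit one
  whole haplotype per parent by fair coin (no recombination — the target
  is LD-block-sized loci).
* **Phenotypes** — ages uniform on (20, 80); sex from the pedigree; fixed
  effects $b = (0, 0.01, 0.5, 0.005)$ (a mild age trend, a sex offset and
  a small interaction, on the scale of a standardized trait);
  $s^2_{fam} = s^2_o = 0.5$; causal effects per SNP either constant,
  $\propto |\log_{10}\nu|$, or $\propto 1/\nu$.

Every draw is a pure function of (config, seed). The generator emulates the
features the method actually exercises — pedigree covariance, LD-correlated
rare and common dosages, covariate effects, polygenic background. It does
*not* emulate ascertainment, genotyping error, missingness patterns,
population stratification, or realistic age/family-size distributions, so
passing calibration here says nothing about robustness to those.

## Calibration results and the small-sample caveat

The test suite runs the whole pipeline as a type-I error study: 2,000 null
replicates of 20 families × 8 subjects (n = 160), 50 SNPs, linear kernel,
all three weight schemes, all five methods, checking each empirical
rejection rate at $\alpha = 0.05$ against the binomial 95 % band
[0.0405, 0.0595]. Under these conditions the plug-in of REML-estimated
variance components makes the quadratic-form tests measurably
*conservative*: ≈ 0.031–0.038 for the common, K_all, WS and Fisher tests,
while the rare-only test stays inside the band. Two diagnostic
experiments locate the cause precisely. With the *true* variance
components substituted for the REML estimates, the level is nominal
(0.052–0.059 in 1,000-replicate runs); with REML estimates taken from an
*independent* trait replicate of the same families, it is again nominal
(0.046). Only the same-data fit is conservative, and the deficit does not
disappear at 60 families (n = 480, K_all ≈ 0.037): when the tested kernel
is computed on genotypes dropped down the same pedigrees that define
$\Phi_{kin}$, the kernel directions remain aligned with the familial
covariance no matter how many families are added, so a null fluctuation
that inflates $Q$ also inflates $\hat{h}$ and is partially absorbed into
the projection. This variance-absorption coupling is a property of
fitting the null model on the same data that is tested — which is how the
method is defined — and the resulting test is valid but under-rejecting.
Small-sample/plug-in moment corrections exist in the set-test literature
but are deliberately out of scope; the level study is reported as
measured, not adjusted.

Other study sizes used by the suite and the acceptance script, chosen to
make the Monte-Carlo error small relative to what each check asserts:
kinship vs 200,000 single-locus gene drops on five pedigrees of ≤ 12;
Davies vs 200,000-draw quadratic-form Monte Carlo on 20 eigenvalue sets;
REML recovery over 200 datasets of 60 families × 8 (means of both
components in [0.4, 0.6]); rare-variant power over 500 replicates with ten
causal rare SNPs whose effects scale as $1/\nu$ and
`effect_scale = 0.02`, set so the causal block contributes roughly a
quarter of the trait variance.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_families = 20, seed = 42)
ds <- simulate_dataset(cfg)
kin <- kinship_matrix(ds$pedigree)
nm <- fit_null_reml(blom_transform(ds$phenotypes$trait),
                    build_design(ds$phenotypes), kin)
res <- run_region_tests(ds, region = NULL, null_model = nm,
                        kernel = "linear", weights = "inverse_maf")
res$K_all
```

## Limitations

* Quantitative traits only; no binary-trait variant, no ascertainment
  correction, no longitudinal structure.
* No small-sample moment correction (see above) and no adaptive
  rare/common combination (SKAT-O style $\rho$ search).
* The HWE screen ignores relatedness; with many large inbred families it
  will over-reject rare variants.
* Twin handling is the caller's responsibility: monozygotic twins are not
  detectable from a PED file and should be pruned from the phenotype table.
* The effective-SNP estimator is one convention among several; results
  using the RBF kernel depend on it through the scale $\mu$.
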