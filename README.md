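# famkat — family-based kernel association tests

famkat tests sets of SNPs (genes, LD blocks) for association with a
quantitative trait measured in pedigrees. It is aimed at genetic
epidemiologists working with family cohorts, where subjects are related and
ordinary SKAT-style tests are invalid without accounting for the polygenic
familial covariance.

## The method

The trait is rank-normalized (Blom transform) and modeled as

    Y = X b + c + h(G) + e,

with covariates X = (1, age, sex, age×sex), polygenic family effect
c ~ N(0, s²_fam Φ_kin) built from the pedigree kinship matrix Φ_kin,
kernel machine term h(G) = K a with a ~ N(0, τK), and residuals
e ~ N(0, s²_o I). Association of the SNP set is a score test of τ = 0:
after a REML fit of the null model,

    Q = Rᵀ M R,   R = P₀^{1/2} Y,   M = (P₀^{1/2} K P₀^{1/2}) / 2,

where P₀ is the null projection matrix. Under the null, Q is distributed
as Σᵢ λᵢ χ²₁ over the eigenvalues of M; p-values come from Davies'
characteristic-function inversion.

Kernels: linear (additive effects) and RBF (models SNP interactions), on
minor-allele dosages with equal, 1/MAF, or Beta-density SNP weights.
Rare (MAF ≤ 5%) and common variants can be tested separately or jointly by
three strategies: one combined kernel (K_all), a trace-weighted sum of the
rare and common statistics (WS), or Fisher pooling of the two p-values
with a correlation correction. SNPs are screened by Hardy–Weinberg
equilibrium (p ≥ 1e-5) and minor-allele count (≥ 7).

A gene-drop simulator (template pedigrees, AR(1) LD-structured haplotype
pools, the trait model above) supports calibration and power studies
without any external data.

## Worked example

```r
library(famkat)

cfg <- sim_config(n_families = 20, seed = 42)   # 160 subjects, 50 SNPs
ds  <- simulate_dataset(cfg)
kin <- kinship_matrix(ds$pedigree)
nm  <- fit_null_reml(blom_transform(ds$phenotypes$trait),
                     build_design(ds$phenotypes), kin)
nm
#> Polygenic null model (REML)
#>   s2_fam = 0.2121  s2_o = 0.6979  h = 0.233
#>   ...
res <- run_region_tests(ds, region = NULL, null_model = nm,
                        kernel = "linear", weights = "equal")
for (r in res) print(r)
#> [rare] Q = 4.113, p = 0.7531 (exact)
#> [common] Q = 30.78, p = 0.5488 (exact)
#> [K_all] Q = 21.89, p = 0.5832 (exact)
#> [WS] Q = 10.34, p = 0.6984 (exact)
#> [Fisher] Q = 1.767, p = 0.7463 (approx)
```

The null fit estimates a familial variance share h ≈ 0.23 on this draw
(the generating value is 0.5; a single 160-subject replicate carries wide
REML uncertainty). Each result holds the score statistic Q, its Davies
p-value, and the rare/common SNP counts; none of the five tests rejects
here, as expected for a null simulation.

File-based workflow (VCF + PED + phenotype TSV + BED in, results table
out), e.g. via the bundled CLI:

```sh
Rscript inst/cli/famkat simulate --out-dir sim/ --seed 7
Rscript inst/cli/famkat test --vcf sim/sim.vcf --ped sim/sim.ped \
    --pheno sim/sim.pheno.tsv --bed sim/sim.bed --out results.tsv \
    --kernel linear --weights inv-maf
Rscript inst/cli/famkat calibrate --out calib.tsv --replicates 50
```

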