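#' Simulation configuration
#'
#' Bundles every knob of the synthetic pedigree/genotype/phenotype generator.
#' Defaults describe the calibration setting used throughout the package's
#' own studies: 20 three-generation families of 8, 50 SNPs (half rare), an
#' AR(1) LD backbone, equal familial and residual variance, and no causal
#' SNPs (a null configuration).
#'
#' @param n_families Number of disjoint family copies.
#' @param family_template `"trio"` (3 subjects) or `"three-generation-8"`
#'   (grandparental couple, two adult children, one married-in spouse, three
#'   grandchildren; kinship values 0.5, 0.25, 0.125, 0).
#' @param n_snp Number of biallelic SNPs in the region.
#' @param rare_frac Fraction of SNPs drawn with a rare target MAF.
#' @param maf_rare,maf_common Uniform ranges for rare and common target MAFs.
#' @param ld_rho AR(1) correlation of the latent Gaussian generating
#'   haplotypes, in `[0, 1)`; 0 gives linkage equilibrium.
#' @param n_haplotypes Size of the founder haplotype pool.
#' @param causal_set Integer indices of causal SNPs (empty = null model).
#' @param effect_rule `"constant"` (`beta_m = effect_scale`),
#'   `"log_maf"` (`beta_m = effect_scale * |log10 nu_m|`), or
#'   `"inverse_maf"` (`beta_m = effect_scale / nu_m`), with `nu_m` the
#'   realized sample MAF of causal SNP m (monomorphic causal SNPs get 0).
#' @param effect_scale Scalar multiplier of the effect rule.
#' @param s2_fam,s2_o Familial and residual variance components.
#' @param b Fixed effects (intercept, age, sex, age x sex).
#' @param seed Base seed; all generator operations are pure functions of
#'   (config, seed).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_families = 20L,
                       family_template = "three-generation-8",
                       n_snp = 50L, rare_frac = 0.5,
                       maf_rare = c(0.01, 0.05), maf_common = c(0.05, 0.5),
                       ld_rho = 0.5, n_haplotypes = 10000L,
                       causal_set = integer(0L),
                       effect_rule = c("constant", "log_maf", "inverse_maf"),
                       effect_scale = 0,
                       s2_fam = 0.5, s2_o = 0.5,
                       b = c(0, 0.01, 0.5, 0.005), seed = 1L) {
  effect_rule <- match.arg(effect_rule)
  stopifnot(n_families >= 1L, n_snp >= 1L, s2_fam >= 0, s2_o > 0,
            ld_rho >= 0, ld_rho < 1, length(b) == 4L,
            all(causal_set >= 1L), all(causal_set <= n_snp))
  structure(list(n_families = as.integer(n_families),
                 family_template = family_template,
                 n_snp = as.integer(n_snp), rare_frac = rare_frac,
                 maf_rare = maf_rare, maf_common = maf_common,
                 ld_rho = ld_rho, n_haplotypes = as.integer(n_haplotypes),
                 causal_set = as.integer(causal_set),
                 effect_rule = effect_rule, effect_scale = effect_scale,
                 s2_fam = s2_fam, s2_o = s2_o, b = b,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# family templates: columns (id, father, mother, sex) with "0" = founder
pedigree_templates <- list(
  "trio" = data.frame(
    id = c("1", "2", "3"), father = c("0", "0", "1"),
    mother = c("0", "0", "2"), sex = c(1L, 2L, 1L),
    stringsAsFactors = FALSE),
  "three-generation-8" = data.frame(
    id     = c("1", "2", "3", "4", "5", "6", "7", "8"),
    father = c("0", "0", "1", "1", "0", "3", "3", "3"),
    mother = c("0", "0", "2", "2", "0", "5", "5", "5"),
    sex    = c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L),
    stringsAsFactors = FALSE)
)

#' Simulate a multi-family pedigree
#'
#' Replicates a family template `n_families` times with unique ids
#' (`F<k>_<id>`). Deterministic (no randomness is involved beyond the
#' template).
#'
#' @param cfg A [`SimConfig`][sim_config].
#' @return A `PedigreeTable`.
#' @export
simulate_pedigrees <- function(cfg) {
  tpl <- pedigree_templates[[cfg$family_template]]
  if (is.null(tpl))
    stop("unknown family template: ", cfg$family_template)
  fams <- lapply(seq_len(cfg$n_families), function(k) {
    pre <- paste0("F", k, "_")
    data.frame(
      family_id = paste0("F", k),
      subject_id = paste0(pre, tpl$id),
      father_id = ifelse(tpl$father == "0", NA_character_,
                         paste0(pre, tpl$father)),
      mother_id = ifelse(tpl$mother == "0", NA_character_,
                         paste0(pre, tpl$mother)),
      sex = tpl$sex, stringsAsFactors = FALSE)
  })
  ped <- do.call(rbind, fams)
  class(ped) <- c("PedigreeTable", "data.frame")
  ped
}

#' Simulate an LD-structured founder haplotype pool
#'
#' Draws `n_haplotypes` binary haplotypes over `n_snp` SNPs by thresholding
#' an AR(1)-correlated standard Gaussian at the quantile matching each SNP's
#' target minor allele frequency (a Gaussian-copula construction): adjacent
#' SNPs share latent correlation `ld_rho`, which induces positive dosage LD
#' decaying geometrically with distance.
#'
#' @param cfg A `SimConfig`.
#' @param seed Seed (default `cfg$seed`).
#' @return List of class `HaplotypePool`: `haplotypes` (H x N 0/1 matrix),
#'   `maf` (target MAFs), `chrom`, `pos`.
#' @export
simulate_haplotype_pool <- function(cfg, seed = cfg$seed) {
  withr::with_seed(seed, {
    N <- cfg$n_snp
    n_rare <- round(cfg$rare_frac * N)
    maf <- numeric(N)
    is_rare <- sample(rep(c(TRUE, FALSE), c(n_rare, N - n_rare)))
    maf[is_rare] <- stats::runif(sum(is_rare), cfg$maf_rare[1L],
                                 cfg$maf_rare[2L])
    maf[!is_rare] <- stats::runif(sum(!is_rare), cfg$maf_common[1L],
                                  cfg$maf_common[2L])
    H <- cfg$n_haplotypes
    Z <- matrix(0, H, N)
    Z[, 1L] <- stats::rnorm(H)
    if (N > 1L) {
      rho <- cfg$ld_rho
      for (j in 2:N)
        Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(H)
    }
    hap <- matrix(0L, H, N)
    for (j in seq_len(N))
      hap[, j] <- as.integer(Z[, j] < stats::qnorm(maf[j]))
    structure(list(haplotypes = hap, maf = maf,
                   chrom = rep("1", N),
                   pos = as.integer(seq_len(N) * 1000L)),
              class = "HaplotypePool")
  })
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders receive two haplotypes drawn uniformly with replacement from the
#' pool; every non-founder inherits one whole haplotype from each parent,
#' chosen by a fair coin per parent (no recombination within the region).
#' Dosage is the per-SNP sum of minor alleles.
#'
#' @param ped A `PedigreeTable`.
#' @param pool A `HaplotypePool`.
#' @param seed Integer seed.
#' @return A `DosageMatrix` in pedigree subject order.
#' @export
gene_drop <- function(ped, pool, seed) {
  if (!nrow(pool$haplotypes)) stop("empty haplotype pool")
  withr::with_seed(seed, {
    n <- nrow(ped)
    N <- ncol(pool$haplotypes)
    ord <- pedigree_topological_order(ped)
    fa <- match(ped$father_id, ped$subject_id)
    mo <- match(ped$mother_id, ped$subject_id)
    hap_f <- matrix(0L, n, N)  # haplotype inherited from father (or pool)
    hap_m <- matrix(0L, n, N)
    for (i in ord) {
      if (is.na(fa[i]) || is.na(mo[i])) {
        idx <- sample.int(nrow(pool$haplotypes), 2L, replace = TRUE)
        hap_f[i, ] <- pool$haplotypes[idx[1L], ]
        hap_m[i, ] <- pool$haplotypes[idx[2L], ]
      } else {
        hap_f[i, ] <- if (stats::runif(1) < 0.5) hap_f[fa[i], ] else
          hap_m[fa[i], ]
        hap_m[i, ] <- if (stats::runif(1) < 0.5) hap_f[mo[i], ] else
          hap_m[mo[i], ]
      }
    }
    dos <- hap_f + hap_m
    rownames(dos) <- ped$subject_id
    colnames(dos) <- paste0("snp", seq_len(N))
    dosage_matrix(dos, pool$chrom, pool$pos)
  })
}

#' Monte-Carlo kinship estimate by single-locus gene drops
#'
#' Drops uniquely labelled founder alleles down the pedigree many times and
#' estimates phi(i, j) as the empirical probability that one allele sampled
#' at random from i and one from j are identical by descent. Serves as a
#' simulation-based cross-check of the recursive [kinship_matrix()] (it
#' shares no code with the recursion).
#'
#' @param ped A `PedigreeTable`.
#' @param n_drops Number of independent gene drops.
#' @param seed Integer seed.
#' @return List with `phi` (empirical kinship matrix) and `se` (binomial
#'   Monte-Carlo standard errors, elementwise).
#' @export
ibd_gene_drop <- function(ped, n_drops, seed) {
  withr::with_seed(seed, {
    n <- nrow(ped)
    ord <- pedigree_topological_order(ped)
    fa <- match(ped$father_id, ped$subject_id)
    mo <- match(ped$mother_id, ped$subject_id)
    # allele labels: n x n_drops per allele slot
    a1 <- matrix(0L, n, n_drops); a2 <- matrix(0L, n, n_drops)
    next_label <- 1L
    for (i in ord) {
      if (is.na(fa[i]) || is.na(mo[i])) {
        a1[i, ] <- next_label; a2[i, ] <- next_label + 1L
        next_label <- next_label + 2L
      } else {
        pick1 <- stats::runif(n_drops) < 0.5
        a1[i, ] <- ifelse(pick1, a1[fa[i], ], a2[fa[i], ])
        pick2 <- stats::runif(n_drops) < 0.5
        a2[i, ] <- ifelse(pick2, a1[mo[i], ], a2[mo[i], ])
      }
    }
    phi <- matrix(0, n, n, dimnames = list(ped$subject_id, ped$subject_id))
    for (i in seq_len(n)) for (j in i:n) {
      pr <- (as.numeric(a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
               (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
      phi[i, j] <- phi[j, i] <- mean(pr)
    }
    se <- sqrt(phi * pmax(1 - phi, 0) / n_drops)
    list(phi = phi, se = se)
  })
}

#' Simulate phenotypes under the polygenic trait model
#'
#' Generates `Y = X b + g + c + e`: ages uniform on (20, 80), sex taken from
#' the pedigree (fair coin where unknown), design matrix as in
#' [build_design()], causal SNP effects `g = sum_m beta_m dosage_m` per the
#' configured effect rule, familial effect `c ~ MVN(0, s2_fam * Phi)` and
#' residual `e ~ N(0, s2_o)`.
#'
#' @param ped A `PedigreeTable`.
#' @param G A `DosageMatrix` aligned to the pedigree.
#' @param cfg A `SimConfig`.
#' @param seed Integer seed.
#' @param kin_chol Optional pre-computed factor `L` with `L %*% t(L) = Phi`
#'   (saves refactorizing across replicates).
#' @return A `PhenotypeTable` with columns `sample_id`, `trait`, `age`, `sex`.
#' @export
simulate_phenotype <- function(ped, G, cfg, seed = cfg$seed,
                               kin_chol = NULL) {
  if (is.null(kin_chol)) kin_chol <- kinship_cholesky(kinship_matrix(ped))
  withr::with_seed(seed, {
    n <- nrow(ped)
    age <- stats::runif(n, 20, 80)
    sex <- ped$sex
    sex[is.na(sex)] <- sample(c(1L, 2L), sum(is.na(sex)), replace = TRUE)
    sex01 <- as.numeric(sex == 2L)
    X <- cbind(1, age, sex01, age * sex01)
    g_eff <- numeric(n)
    if (length(cfg$causal_set) && cfg$effect_scale != 0) {
      Gc <- G$dosage[, cfg$causal_set, drop = FALSE]
      nu <- minor_allele_frequencies(Gc)
      beta <- switch(cfg$effect_rule,
        constant = rep(cfg$effect_scale, length(nu)),
        log_maf = cfg$effect_scale * abs(log10(pmax(nu, 1e-12))),
        inverse_maf = ifelse(nu > 0, cfg$effect_scale / nu, 0))
      beta[nu == 0] <- 0
      g_eff <- drop(Gc %*% beta)
    }
    c_eff <- if (cfg$s2_fam > 0)
      sqrt(cfg$s2_fam) * drop(kin_chol %*% stats::rnorm(n)) else numeric(n)
    e <- stats::rnorm(n, sd = sqrt(cfg$s2_o))
    phe <- data.frame(sample_id = ped$subject_id,
                      trait = drop(X %*% cfg$b) + g_eff + c_eff + e,
                      age = age, sex = sex, stringsAsFactors = FALSE)
    class(phe) <- c("PhenotypeTable", "data.frame")
    phe
  })
}

# Factor Phi = L L^T via eigendecomposition (Phi is PSD, often singular-free
# but pivoted Cholesky is avoided for determinism across BLAS builds).
kinship_cholesky <- function(kin) {
  eg <- eigen((unclass(kin) + t(unclass(kin))) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(lam), nrow = length(lam))
}

#' Simulate a complete analysis dataset
#'
#' Convenience wrapper: pedigree, haplotype pool (drawn once from
#' `cfg$seed`), gene-drop genotypes and phenotypes, assembled into an
#' `AnalysisDataset`. Pass `pool`/`kin_chol` to share them across study
#' replicates.
#'
#' @param cfg A `SimConfig`.
#' @param seed Seed for the gene drop and phenotype draw (default
#'   `cfg$seed`).
#' @param pool Optional pre-drawn `HaplotypePool`.
#' @param kin_chol Optional pre-computed kinship factor.
#' @return An `AnalysisDataset`.
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed, pool = NULL,
                             kin_chol = NULL) {
  ped <- simulate_pedigrees(cfg)
  if (is.null(pool)) pool <- simulate_haplotype_pool(cfg)
  G <- gene_drop(ped, pool, seed = seed)
  phe <- simulate_phenotype(ped, G, cfg, seed = seed + 500000000L,
                            kin_chol = kin_chol)
  structure(list(pedigree = ped, dosages = G, phenotypes = phe,
                 sample_ids = ped$subject_id),
            class = "AnalysisDataset")
}

#' Type-I error / power study
#'
#' Runs the full pipeline (gene drop, phenotype draw, Blom transform, REML
#' null fit, kernel score tests) on `n_replicates` study replicates of the
#' configured design and tabulates rejection fractions per method, weight
#' scheme and significance level, with binomial Monte-Carlo standard errors.
#' Under a null configuration (no causal SNPs) the table is the empirical
#' type-I error; with causal SNPs it is power.
#'
#' The pedigree, haplotype pool and kinship factor are drawn once and shared
#' across replicates; genotypes and phenotypes are redrawn each replicate
#' with seeds derived from `cfg$seed`.
#'
#' @param cfg A `SimConfig`.
#' @param n_replicates Number of study replicates.
#' @param alpha_levels Significance levels to tabulate.
#' @param kernel `"linear"` or `"rbf"`.
#' @param weight_schemes Character vector of weight schemes to evaluate on
#'   the same replicates.
#' @param methods Methods to run (see [run_region_tests()]).
#' @param maf_split,hwe_min_p,min_mac Filter/partition settings.
#' @return A data frame with columns `method`, `kernel`, `weights`, `alpha`,
#'   `n_reject`, `n_total`, `rate`, `mc_se`, plus attribute `pvalues` (long
#'   data frame of all per-replicate p-values).
#' @export
run_power_study <- function(cfg, n_replicates, alpha_levels = 0.05,
                            kernel = "linear",
                            weight_schemes = c("equal", "inverse_maf",
                                               "beta"),
                            methods = c("common", "rare", "K_all", "WS",
                                        "Fisher"),
                            maf_split = 0.05, hwe_min_p = 1e-5,
                            min_mac = 7L) {
  stopifnot(n_replicates >= 1L)
  ped <- simulate_pedigrees(cfg)
  pool <- simulate_haplotype_pool(cfg)
  kin <- kinship_matrix(ped)
  kin_chol <- kinship_cholesky(kin)
  recs <- vector("list", n_replicates * length(weight_schemes) * 5L)
  k <- 0L
  for (r in seq_len(n_replicates)) {
    seed_r <- (cfg$seed + 7919L * r) %% 2000000000L
    ds <- simulate_dataset(cfg, seed = seed_r, pool = pool,
                           kin_chol = kin_chol)
    Y <- blom_transform(ds$phenotypes$trait)
    X <- build_design(ds$phenotypes)
    nm <- fit_null_reml(Y, X, kin)
    for (sch in weight_schemes) {
      res <- suppressMessages(
        run_region_tests(ds, region = NULL, null_model = nm,
                         kernel = kernel, weights = sch,
                         maf_split = maf_split, hwe_min_p = hwe_min_p,
                         min_mac = min_mac, methods = methods))
      for (m in names(res)) {
        k <- k + 1L
        recs[[k]] <- data.frame(replicate = r, method = m, weights = sch,
                                p = res[[m]]$p_value)
      }
    }
  }
  pv <- do.call(rbind, recs[seq_len(k)])
  rows <- list()
  for (m in unique(pv$method)) for (sch in weight_schemes)
    for (a in alpha_levels) {
      p <- pv$p[pv$method == m & pv$weights == sch]
      nr <- sum(p <= a)
      rate <- nr / length(p)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, kernel = kernel, weights = sch, alpha = a,
        n_reject = nr, n_total = length(p), rate = rate,
        mc_se = sqrt(rate * (1 - rate) / length(p)))
    }
  out <- do.call(rbind, rows)
  attr(out, "pvalues") <- pv
  out
}
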