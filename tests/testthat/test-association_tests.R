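test_that("HWE chi-square test matches hand-checked counts", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)              # exact proportions
  # total heterozygote deficit: chi-square = n
  expect_equal(hwe_test(c(50, 0, 50)),
               pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(hwe_test(c(50, 0, 50)), 1e-5)
  expect_equal(hwe_test(c(10, 0, 0)), 1)                # monomorphic
})

test_that("SNP filters enforce the MAC and HWE thresholds inclusively", {
  n <- 100L
  col_of_mac <- function(mac) c(rep(1, mac), rep(0, n - mac))
  # HWE-violating column: 12 hom-minor, no hets (MAC 24 passes the MAC rule)
  hwe_bad <- c(rep(2, 12L), rep(0, n - 12L))
  G <- cbind(mac6 = col_of_mac(6L), mac7 = col_of_mac(7L), bad = hwe_bad)
  dos <- make_dos(G)
  out <- filter_snps(dos)
  expect_equal(out$report$kept_snp_ids, "mac7")
  expect_equal(out$report$n_input, 3L)
  expect_equal(out$report$n_mac_removed, 1L)
  expect_equal(out$report$n_hwe_removed, 1L)

  # boundary semantics: a SNP with HWE p exactly at the threshold is kept
  p_bad <- hwe_test(c(n - 12L, 0L, 12L))
  kept_at <- filter_snps(dos, hwe_min_p = p_bad)
  expect_true("bad" %in% kept_at$report$kept_snp_ids)
  kept_above <- filter_snps(dos, hwe_min_p = p_bad * (1 + 1e-9))
  expect_false("bad" %in% kept_above$report$kept_snp_ids)

  # rounding is only used for the screens: kept dosages stay fractional
  Gf <- cbind(frac = c(rep(1.2, 10L), rep(0.1, n - 10L)))
  outf <- filter_snps(make_dos(Gf))
  expect_equal(unname(outf$dosages$dosage[1L, 1L]), 1.2)

  mono <- make_dos(cbind(a = rep(0, n), b = rep(2, n)))
  outm <- filter_snps(mono)
  expect_equal(length(outm$report$kept_snp_ids), 0L)
  expect_equal(outm$report$n_mac_removed, 2L)
})

test_that("MAF partition puts the 5% boundary on the rare side", {
  n <- 10000L
  make_col <- function(maf) c(rep(1, round(2 * n * maf)),
                              rep(0, n - round(2 * n * maf)))
  G <- cbind(at = make_col(0.05), above = make_col(0.0500001),
             common = make_col(0.3))
  G[1L, 2L] <- 2  # push 'above' strictly past the split
  dos <- make_dos(G)
  part <- partition_by_maf(dos, split = 0.05)
  expect_equal(part$rare$snp_ids, "at")
  expect_setequal(part$common$snp_ids, c("above", "common"))
  # disjoint union of the input
  expect_setequal(c(part$rare$snp_ids, part$common$snp_ids), dos$snp_ids)
})

test_that("score statistic is the quadratic form R'MR", {
  expect_equal(score_statistic(c(1, 2), diag(2)), 5)
  expect_equal(score_statistic(c(0, 0), diag(2)), 0)
  set.seed(2)
  M <- crossprod(matrix(rnorm(16), 4))
  R <- rnorm(4)
  perm <- sample(4)
  expect_equal(score_statistic(R[perm], M[perm, perm]),
               score_statistic(R, M))
})

test_that("Davies p-values agree with chi-square tails and are monotone", {
  expect_equal(davies_pvalue(3.841459, 1)$p, 0.05, tolerance = 1e-4)
  expect_equal(davies_pvalue(5.991465, c(1, 1))$p, 0.05, tolerance = 1e-4)
  expect_equal(davies_pvalue(0, c(0.5, 0.2))$p, 1)
  expect_error(davies_pvalue(1, c(1e-12, 0)), "degenerate")

  lam <- c(2, 1, 0.5, 0.1)
  qs <- seq(0.1, 30, length.out = 40L)
  ps <- vapply(qs, function(q) davies_pvalue(q, lam)$p, numeric(1L))
  expect_true(all(diff(ps) <= 1e-12))

  # general chi-square mixture against scaled chi-square: lam = (c, c, c)
  expect_equal(davies_pvalue(3 * 7.814728, rep(3, 3))$p,
               pchisq(7.814728, df = 3, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("Davies matches a Monte-Carlo quadratic-form oracle", {
  set.seed(61)
  for (i in 1:4) {
    lam <- runif(sample(2:8, 1L), 0.1, 3)
    q <- sum(lam) * runif(1, 0.5, 2.5)
    mc <- mc_quadform_tail(q, lam, n_draws = 50000L, seed = 100L + i)
    p <- davies_pvalue(q, lam)$p
    expect_lt(abs(p - mc$p), 4 * mc$se + 1e-6)
  }
})

test_that("Liu fallback approximates the tail when invoked directly", {
  lam <- c(1.5, 1, 0.5)
  q <- 6
  exact <- davies_pvalue(q, lam)$p
  approx <- famkat:::liu_pvalue(q, lam)
  expect_lt(abs(exact - approx), 0.01)
})

test_that("weighted-sum test uses the trace-derived phi", {
  R <- c(1, -1, 0.5, 2)
  # diagonal test matrices with controlled squared traces
  Mr <- test_matrix(diag(4), 2 * diag(c(1, 1, 0, 0)))
  Mc <- test_matrix(diag(4), 2 * diag(c(0, 0, 1, 1)))
  # tr(MrMr) = tr(McMc) -> phi = sqrt(0.5)
  ws <- ws_test(Mr, Mc, R)
  expect_equal(ws$phi, sqrt(0.5))
  expect_equal(ws$Q, (1 - sqrt(0.5)) * score_statistic(R, Mr) +
                 sqrt(0.5) * score_statistic(R, Mc))

  # tr(MrMr) = 3 tr(McMc) -> phi = sqrt(0.75)
  Mr3 <- test_matrix(diag(4), 2 * diag(c(sqrt(3), sqrt(3), 0, 0)))
  expect_equal(ws_test(Mr3, Mc, R)$phi, sqrt(0.75))

  # identical partitions: Q_WS = Q and the p-value equals the single test
  M <- test_matrix(diag(4), crossprod(matrix(c(1, 0, 1, 2, 0, 1, 1, 0,
                                               2, 1, 0, 1, 0, 2, 1, 1),
                                             4)))
  ws_id <- ws_test(M, M, R)
  expect_equal(ws_id$Q, score_statistic(R, M))
  expect_equal(ws_id$p_value, davies_pvalue(ws_id$Q, M$eigenvalues)$p)
})

test_that("Fisher pooling reduces to the classical combination at r = 0", {
  Mr <- test_matrix(diag(4), diag(c(1, 1, 0, 0)))
  Mc <- test_matrix(diag(4), diag(c(0, 0, 1, 1)))  # tr(MrMc) = 0
  res <- fisher_test(0.03, 0.2, Mr, Mc)
  expect_equal(res$r_cov, 0)
  q <- -2 * log(0.03) - 2 * log(0.2)
  expect_equal(res$Q, q)
  expect_equal(res$p_value, pchisq(q, df = 4, lower.tail = FALSE))

  # r = 1: cov = 4, scale 2, df 2
  res1 <- fisher_test(0.03, 0.2, Mr, Mr)
  expect_equal(res1$r_cov, 1)
  expect_equal(res1$p_value, pchisq(q / 2, df = 2, lower.tail = FALSE))

  # boundary inputs
  expect_equal(fisher_test(1, 1, Mr, Mc)$p_value, 1)
  expect_warning(res0 <- fisher_test(0, 0.5, Mr, Mc), "clamped")
  expect_lte(res0$p_value, 1)
})

region_test_fixture <- function(seed = 5L, ...) {
  # rare target MAFs high enough that the MAC >= 7 screen keeps a non-empty
  # rare partition at this sample size
  cfg <- sim_config(n_families = 15L, maf_rare = c(0.035, 0.05),
                    seed = seed, ...)
  ds <- simulate_dataset(cfg)
  kin <- kinship_matrix(ds$pedigree)
  nm <- fit_null_reml(blom_transform(ds$phenotypes$trait),
                      build_design(ds$phenotypes), kin)
  list(ds = ds, nm = nm)
}

test_that("region testing returns all five methods with valid p-values", {
  fx <- region_test_fixture()
  res <- run_region_tests(fx$ds, NULL, fx$nm)
  expect_setequal(names(res), c("common", "rare", "K_all", "WS", "Fisher"))
  for (r in res) {
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
    expect_gte(r$Q, 0)
  }
  fr <- attr(res, "filter_report")
  expect_equal(fr$n_input,
               length(fr$kept_snp_ids) + fr$n_hwe_removed + fr$n_mac_removed)

  # determinism: identical inputs give bitwise-identical results
  res2 <- run_region_tests(fx$ds, NULL, fx$nm)
  expect_identical(res, res2)
})

test_that("with an empty rare partition K_all equals the common-only test bitwise", {
  # common target MAFs kept away from the 5% split so no SNP realizes a
  # sample MAF on the rare side
  fx <- region_test_fixture(seed = 8L, rare_frac = 0,
                            maf_common = c(0.15, 0.5))
  res <- suppressMessages(run_region_tests(fx$ds, NULL, fx$nm))
  expect_false("rare" %in% names(res))
  expect_false("WS" %in% names(res))
  expect_identical(res$K_all$Q, res$common$Q)
  expect_identical(res$K_all$p_value, res$common$p_value)
})

test_that("results tables carry one row per region and method", {
  fx <- region_test_fixture(seed = 13L)
  res <- run_region_tests(fx$ds, NULL, fx$nm)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_results(list(regA = res), path)
  expect_equal(nrow(df), 5L)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$p_value, df$p_value, tolerance = 1e-12)
})
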