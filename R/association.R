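#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df asymptotic goodness-of-fit test of genotype counts against the
#' proportions `p^2, 2pq, q^2` implied by the estimated allele frequency
#' `p = (2 n_AA + n_Aa) / (2 n)`. Monomorphic sites return p = 1 by
#' convention.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return P-value in (0, 1].
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0L) stop("no genotype observations")
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
}

#' SNP inclusion filters
#'
#' Keeps SNPs that (a) pass the Hardy-Weinberg screen at `p >= hwe_min_p`
#' computed on dosages rounded to the nearest integer genotype (rounding is
#' used for this test and the allele count only), and (b) show at least
#' `min_mac` observations of the minor allele among the rounded genotypes.
#' The minor-allele count is `min(s, 2n - s)` with `s` the rounded dosage
#' sum, guarding against rounding flipping the minor allele.
#'
#' @param dos A `DosageMatrix`.
#' @param hwe_min_p HWE p-value threshold (default 1e-5, inclusive).
#' @param min_mac Minimum minor-allele count (default 7, inclusive).
#' @return A list with elements `dosages` (filtered `DosageMatrix`) and
#'   `report` (a `FilterReport` list: `n_input`, `n_hwe_removed`,
#'   `n_mac_removed`, `kept_snp_ids`).
#' @export
filter_snps <- function(dos, hwe_min_p = 1e-5, min_mac = 7L) {
  G <- dos$dosage
  n <- nrow(G)
  rounded <- round(G)
  mac <- pmin(colSums(rounded), 2 * n - colSums(rounded))
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- rounded[, j]
    hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2)))
  }, numeric(1L))
  if (ncol(G) == 0L) hwe_p <- numeric(0L)
  fail_mac <- mac < min_mac
  fail_hwe <- hwe_p < hwe_min_p & !fail_mac  # attribute each removal once
  keep <- !fail_mac & hwe_p >= hwe_min_p
  report <- list(n_input = ncol(G),
                 n_hwe_removed = sum(fail_hwe),
                 n_mac_removed = sum(fail_mac),
                 kept_snp_ids = colnames(G)[keep])
  list(dosages = subset_snps(dos, which(keep)), report = report)
}

#' Partition SNPs into rare and common by MAF
#'
#' Rare is `MAF <= split`, common is `MAF > split`; MAFs are computed on the
#' matrix passed in (i.e. after filtering).
#'
#' @param dos A `DosageMatrix`.
#' @param split MAF threshold (default 0.05).
#' @return List with `rare` and `common` `DosageMatrix` components (either
#'   may have zero SNPs) and the `maf` vector.
#' @export
partition_by_maf <- function(dos, split = 0.05) {
  maf <- minor_allele_frequencies(dos)
  rare <- which(maf <= split)
  common <- which(maf > split)
  list(rare = subset_snps(dos, rare), common = subset_snps(dos, common),
       maf = maf)
}

#' Kernel score statistic
#'
#' `Q = R^T M R`, the variance-component score statistic for the genetic
#' covariance component.
#'
#' @param R Residual vector from the null model.
#' @param M A `TestMatrix` or bare symmetric matrix.
#' @return Scalar Q (>= 0 when M is PSD).
#' @export
score_statistic <- function(R, M) {
  Mm <- if (inherits(M, "TestMatrix")) M$M else as.matrix(M)
  drop(crossprod(R, Mm %*% R))
}

#' Tail probability of a weighted sum of chi-squares (Davies' method)
#'
#' Computes `P(sum_i lambda_i chi^2_1 > q)` by numerical inversion of the
#' characteristic function (Davies' algorithm, absolute accuracy target
#' 1e-9). If the inversion fails, falls back to a Liu-type four-moment
#' chi-square approximation and flags the result. Eigenvalues with
#' `|lambda| <= 1e-10` are dropped first. The returned p is clamped to
#' `(1e-16, 1]`.
#'
#' @param q Observed statistic.
#' @param eigenvalues Weights of the chi-square mixture (eigenvalues of the
#'   test matrix M).
#' @return List with `p` and `status` (`"exact"` or `"fallback"`).
#' @export
davies_pvalue <- function(q, eigenvalues) {
  lam <- eigenvalues[abs(eigenvalues) > 1e-10]
  if (!length(lam))
    stop("all eigenvalues are numerically zero: degenerate test")
  if (q <= 0) return(list(p = 1, status = "exact"))
  p <- tryCatch({
    val <- mgcv::psum.chisq(q, lb = lam, df = rep(1L, length(lam)),
                            lower.tail = FALSE, tol = 1e-9, nlim = 1e6)
    if (is.na(val) || val < -1e-9 || val > 1 + 1e-9) NA_real_ else val
  }, warning = function(w) NA_real_, error = function(e) NA_real_)
  status <- "exact"
  if (is.na(p)) {
    p <- liu_pvalue(q, lam)
    status <- "fallback"
  }
  list(p = min(max(p, 1e-16), 1), status = status)
}

# Liu et al. four-moment chi-square approximation to the distribution of a
# weighted sum of 1-df chi-squares; used only when Davies' inversion fails.
liu_pvalue <- function(q, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  t_star <- (q - mu_q) / sigma_q
  q_norm <- t_star * sqrt(2 * (l + 2 * delta)) + l + delta
  stats::pchisq(q_norm, df = l, ncp = delta, lower.tail = FALSE)
}

# tr(A %*% B) for symmetric A, B without forming the product.
trace_prod <- function(A, B) sum(A * B)

test_matrix_M <- function(M) if (inherits(M, "TestMatrix")) M$M else as.matrix(M)

# Assemble a TestResult record.
test_result <- function(method, Q, p, status, n_rare = NA_integer_,
                        n_common = NA_integer_, phi = NA_real_,
                        r_cov = NA_real_) {
  structure(list(method = method, Q = Q, p_value = p,
                 n_snps_rare = n_rare, n_snps_common = n_common,
                 phi = phi, r_cov = r_cov, davies_status = status),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("[%s] Q = %.4g, p = %.4g (%s)\n",
              x$method, x$Q, x$p_value, x$davies_status))
  invisible(x)
}

#' Weighted-sum joint test of rare and common variants
#'
#' Combines the rare- and common-SNP score statistics as
#' `Q_WS = (1 - phi) Q_rare + phi Q_common` with trace-derived weight
#' \deqn{\varphi = \sqrt{\mathrm{tr}(M_r M_r) /
#'       (\mathrm{tr}(M_r M_r) + \mathrm{tr}(M_c M_c))}.}
#' The p-value comes from Davies' method on the eigenvalues of
#' `(1 - phi) M_rare + phi M_common`.
#'
#' @param M_rare,M_common `TestMatrix` objects for the two partitions.
#' @param R Null-model residual vector.
#' @return A `TestResult` with `method = "WS"` and the `phi` used.
#' @export
ws_test <- function(M_rare, M_common, R) {
  Mr <- test_matrix_M(M_rare); Mc <- test_matrix_M(M_common)
  trr <- trace_prod(Mr, Mr); tcc <- trace_prod(Mc, Mc)
  if (trr + tcc <= 0) stop("degenerate test matrices (zero traces)")
  phi <- sqrt(trr / (trr + tcc))
  Q_ws <- (1 - phi) * score_statistic(R, Mr) + phi * score_statistic(R, Mc)
  M_comb <- (1 - phi) * Mr + phi * Mc
  ev <- eigen((M_comb + t(M_comb)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  dv <- davies_pvalue(Q_ws, ev)
  test_result("WS", Q_ws, dv$p, dv$status, phi = phi)
}

#' Fisher pooling of correlated rare/common p-values
#'
#' `Q_FISHER = -2 ln(p_rare) - 2 ln(p_common)`. Under the null,
#' `Q_FISHER / (1 + 0.25 cov)` is chi-square with `16 / (4 + cov)` degrees
#' of freedom, where the covariance between the two p-values is approximated
#' from the test-matrix correlation
#' `r = tr(M_r M_c) / sqrt(tr(M_r M_r) tr(M_c M_c))` as
#' `cov = r (3.25 + 0.75 r)` for `0 <= r <= 1` and
#' `cov = r (3.27 + 0.71 r)` for `-0.5 <= r <= 0` (r clipped to `[-0.5, 1]`
#' with a warning when outside). The resulting p-value is approximate, unlike
#' the Davies-based tests.
#'
#' @param p_rare,p_common P-values of the separate rare and common tests.
#' @param M_rare,M_common The corresponding `TestMatrix` objects.
#' @return A `TestResult` with `method = "Fisher"` and the `r_cov` used.
#' @export
fisher_test <- function(p_rare, p_common, M_rare, M_common) {
  for (p in c(p_rare, p_common))
    if (p > 1) stop("p-values must lie in (0, 1]")
  if (p_rare <= 0 || p_common <= 0) {
    warning("zero p-value input clamped to 1e-16")
    p_rare <- max(p_rare, 1e-16); p_common <- max(p_common, 1e-16)
  }
  Mr <- test_matrix_M(M_rare); Mc <- test_matrix_M(M_common)
  r <- trace_prod(Mr, Mc) / sqrt(trace_prod(Mr, Mr) * trace_prod(Mc, Mc))
  if (r > 1 || r < -0.5) {
    warning("test-matrix correlation r = ", format(r),
            " outside [-0.5, 1]; clipped")
    r <- min(max(r, -0.5), 1)
  }
  cov_p <- if (r >= 0) r * (3.25 + 0.75 * r) else r * (3.27 + 0.71 * r)
  Q_f <- -2 * log(p_rare) - 2 * log(p_common)
  scale <- 1 + 0.25 * cov_p
  df <- 16 / (4 + cov_p)
  p <- stats::pchisq(Q_f / scale, df = df, lower.tail = FALSE)
  test_result("Fisher", Q_f, min(max(p, 1e-16), 1), "approx", r_cov = r)
}

#' Run all kernel score tests for one region
#'
#' Restricts the dosages to the region, applies the SNP inclusion filters,
#' splits SNPs into rare (`MAF <= maf_split`) and common, and runs up to
#' five tests with the configured kernel and weight scheme: the single-
#' partition tests (`common`, `rare`), the default combined kernel on all
#' SNPs (`K_all`), the weighted-sum test (`WS`) and Fisher pooling
#' (`Fisher`). SNP weights are renormalized within each tested SNP set. The
#' null model is fit once per dataset and reused across regions; the residual
#' vector and projection machinery are identical for every test.
#'
#' When one partition is empty, only `K_all` and the non-empty single-
#' partition test are produced (and `K_all` then coincides with it). With no
#' SNPs surviving the filters an empty list is returned with a message.
#'
#' @param ds An `AnalysisDataset` (or `NULL` if `dos` given directly).
#' @param region One-row region data frame; `NULL` tests all SNPs present.
#' @param null_model A fitted `NullModel` for the dataset's samples.
#' @param kernel `"linear"` or `"rbf"`.
#' @param weights Weight scheme passed to [snp_weights()].
#' @param maf_split Rare/common MAF threshold (default 0.05).
#' @param hwe_min_p,min_mac Filter thresholds, see [filter_snps()].
#' @param methods Subset of `c("common", "rare", "K_all", "WS", "Fisher")`.
#' @return Named list of `TestResult` objects (subset of the five methods),
#'   with attributes `filter_report` and `n_rare`/`n_common` counts on each
#'   result.
#' @export
run_region_tests <- function(ds, region = NULL, null_model,
                             kernel = c("linear", "rbf"),
                             weights = c("equal", "inverse_maf", "beta"),
                             maf_split = 0.05, hwe_min_p = 1e-5,
                             min_mac = 7L,
                             methods = c("common", "rare", "K_all", "WS",
                                         "Fisher")) {
  kernel <- match.arg(kernel)
  weights <- match.arg(weights)
  methods <- match.arg(methods, several.ok = TRUE)
  dos <- ds$dosages
  if (!is.null(region)) {
    j <- which(dos$chrom == region$chromosome &
                 dos$pos >= region$start & dos$pos <= region$end)
    dos <- subset_snps(dos, j)
  }
  flt <- filter_snps(dos, hwe_min_p = hwe_min_p, min_mac = min_mac)
  if (length(flt$report$kept_snp_ids) == 0L) {
    message("no SNPs survive the inclusion filters in this region")
    out <- list()
    attr(out, "filter_report") <- flt$report
    return(out)
  }
  part <- partition_by_maf(flt$dosages, split = maf_split)
  n_r <- ncol(part$rare$dosage); n_c <- ncol(part$common$dosage)
  P_half <- null_model$P_half; R <- null_model$R

  kernel_test <- function(d, method) {
    W <- snp_weights(minor_allele_frequencies(d), scheme = weights,
                     maf_split = maf_split)
    K <- if (kernel == "linear") linear_kernel(d, W) else
      rbf_kernel(d, W, rbf_scale(d, W))
    M <- test_matrix(P_half, K)
    Q <- score_statistic(R, M)
    dv <- davies_pvalue(Q, M$eigenvalues)
    list(result = test_result(method, Q, dv$p, dv$status,
                              n_rare = n_r, n_common = n_c),
         M = M)
  }

  out <- list()
  rare_fit <- if (n_r > 0L) kernel_test(part$rare, "rare")
  common_fit <- if (n_c > 0L) kernel_test(part$common, "common")
  if ("rare" %in% methods && n_r > 0L) out$rare <- rare_fit$result
  if ("common" %in% methods && n_c > 0L) out$common <- common_fit$result
  if ("K_all" %in% methods)
    out$K_all <- kernel_test(flt$dosages, "K_all")$result
  if (n_r > 0L && n_c > 0L) {
    if ("WS" %in% methods) {
      ws <- ws_test(rare_fit$M, common_fit$M, R)
      ws$n_snps_rare <- n_r; ws$n_snps_common <- n_c
      out$WS <- ws
    }
    if ("Fisher" %in% methods) {
      fi <- fisher_test(rare_fit$result$p_value, common_fit$result$p_value,
                        rare_fit$M, common_fit$M)
      fi$n_snps_rare <- n_r; fi$n_snps_common <- n_c
      out$Fisher <- fi
    }
  } else if (any(c("WS", "Fisher") %in% methods)) {
    message("one MAF partition is empty: WS/Fisher skipped ",
            "(use the single-kernel test)")
  }
  attr(out, "filter_report") <- flt$report
  out
}

#' Write region test results as delimited text
#'
#' One row per region x method with Q, p, SNP counts, phi, r and the Davies
#' status flag.
#'
#' @param results Named list: region label -> list of `TestResult`.
#' @param path Output path.
#' @return The result data frame, invisibly.
#' @export
write_results <- function(results, path) {
  rows <- list()
  for (lab in names(results)) {
    for (res in results[[lab]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = lab, method = res$method, Q = res$Q, p_value = res$p_value,
        n_snps_rare = res$n_snps_rare, n_snps_common = res$n_snps_common,
        phi = res$phi, r = res$r_cov, davies_status = res$davies_status)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(df)
}
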