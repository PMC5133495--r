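#' Minor allele frequencies from dosages
#'
#' `nu_m = mean(dosage column m) / 2`, folded to the minor allele:
#' `nu_m <- min(nu_m, 1 - nu_m)`.
#'
#' @param dos A `DosageMatrix` or plain dosage matrix (samples x SNPs).
#' @return Numeric vector of MAFs in `[0, 0.5]`.
#' @export
minor_allele_frequencies <- function(dos) {
  G <- if (inherits(dos, "DosageMatrix")) dos$dosage else as.matrix(dos)
  nu <- colMeans(G) / 2
  pmin(nu, 1 - nu)
}

#' MAF-based SNP weights
#'
#' Normalized diagonal dosage weights `W_mm = f(nu_m) / sum_m f(nu_m)` over
#' the tested SNP set, for three weighting rules:
#' \describe{
#'   \item{`equal`}{`f(nu) = 1` — all SNPs alike.}
#'   \item{`inverse_maf`}{`f(nu) = 1/nu` — sharply upweights rare alleles.}
#'   \item{`beta`}{`f(nu) = Beta(nu; 1, 25)` density for `nu <= maf_split`
#'     and `Beta(nu; 0.5, 0.5)` for `nu > maf_split` — distinguishes MAFs
#'     more moderately than `1/nu`.}
#' }
#' Weights are always renormalized within the SNP set passed in, so rare-only
#' and common-only kernels each carry weights summing to one.
#'
#' @param maf Numeric MAF vector (all > 0 for `inverse_maf` and `beta`).
#' @param scheme One of `"equal"`, `"inverse_maf"`, `"beta"`.
#' @param beta_rare,beta_common Shape pairs of the two Beta densities.
#' @param maf_split MAF threshold separating the two Beta regimes
#'   (default 0.05).
#' @return A list of class `WeightMatrix` with elements `w` (normalized
#'   diagonal, sums to 1), `raw`, `maf`, `scheme`.
#' @export
snp_weights <- function(maf, scheme = c("equal", "inverse_maf", "beta"),
                        beta_rare = c(1, 25), beta_common = c(0.5, 0.5),
                        maf_split = 0.05) {
  scheme <- match.arg(scheme)
  stopifnot(length(maf) >= 1L, all(maf >= 0), all(maf <= 0.5))
  raw <- switch(scheme,
    equal = rep(1, length(maf)),
    inverse_maf = {
      if (any(maf == 0)) stop("inverse_maf weight undefined at MAF = 0")
      1 / maf
    },
    beta = {
      if (any(maf == 0)) stop("beta weight undefined at MAF = 0")
      ifelse(maf <= maf_split,
             stats::dbeta(maf, beta_rare[1L], beta_rare[2L]),
             stats::dbeta(maf, beta_common[1L], beta_common[2L]))
    })
  structure(list(w = raw / sum(raw), raw = raw, maf = maf, scheme = scheme),
            class = "WeightMatrix")
}

#' Write per-SNP weights as delimited text
#'
#' One row per SNP with its MAF, raw weight and normalized weight.
#'
#' @param W A `WeightMatrix` from [snp_weights()].
#' @param snp_ids Character vector of SNP ids (same order as the MAFs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(W, snp_ids, path) {
  stopifnot(length(snp_ids) == length(W$w))
  df <- data.frame(snp_id = snp_ids, maf = W$maf, scheme = W$scheme,
                   raw = W$raw, weight = W$w)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

weight_diag <- function(W) {
  if (inherits(W, "WeightMatrix")) W$w else as.numeric(W)
}

#' Linear kernel on weighted dosages
#'
#' `K = G W G^T` with diagonal weight matrix `W`; models additive SNP
#' effects without SNP-SNP interactions.
#'
#' @param G Dosage matrix (samples x SNPs) or `DosageMatrix`.
#' @param W A `WeightMatrix` (or bare weight vector).
#' @return A list of class `KernelMatrix` with elements `K`, `kernel`
#'   (`"linear"`), `weights`.
#' @export
linear_kernel <- function(G, W) {
  Gm <- if (inherits(G, "DosageMatrix")) G$dosage else as.matrix(G)
  w <- weight_diag(W)
  stopifnot(ncol(Gm) == length(w))
  K <- tcrossprod(Gm %*% diag(sqrt(w), nrow = length(w)))
  structure(list(K = (K + t(K)) / 2, kernel = "linear", weights = w),
            class = "KernelMatrix")
}

#' Effective number of independent SNPs
#'
#' Li–Ji-style estimate from the eigenvalues `lambda` of the SNP x SNP
#' Pearson correlation matrix:
#' \deqn{M_{eff} = \sum_i \left[ 1(\lambda_i \ge 1) +
#'       (\lambda_i - \lfloor \lambda_i \rfloor) \right].}
#' Perfectly duplicated SNPs collapse to 1; mutually independent SNPs give
#' `M_eff = N`.
#'
#' @param G Dosage matrix (samples x SNPs) or `DosageMatrix`; each SNP
#'   column must be non-constant.
#' @return Scalar in `[1, N]`.
#' @export
effective_snp_number <- function(G) {
  Gm <- if (inherits(G, "DosageMatrix")) G$dosage else as.matrix(G)
  if (any(apply(Gm, 2L, stats::sd) == 0))
    stop("constant SNP column: correlation undefined")
  if (ncol(Gm) == 1L) return(1)
  lam <- eigen(stats::cor(Gm), symmetric = TRUE, only.values = TRUE)$values
  # the floor-based rule is discontinuous at integers; snap eigenvalues that
  # sit within rounding error of an integer (perfect-LD blocks)
  lam <- round(pmax(lam, 0), 8L)
  sum(as.numeric(lam >= 1) + (lam - floor(lam)))
}

# Weighted squared-distance matrix D_ij = (g_i - g_j)^T W (g_i - g_j),
# clipped at 0 and symmetrized.
weighted_sqdist <- function(Gm, w) {
  A <- Gm %*% diag(sqrt(w), nrow = length(w))
  sq <- rowSums(A^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(A)
  D <- pmax((D + t(D)) / 2, 0)
  diag(D) <- 0
  D
}

#' RBF kernel scale parameter
#'
#' The scale is the average weighted squared genetic difference between
#' subjects, over all ordered pairs including i = j,
#' \deqn{\mu = \frac{1}{n^2} \sum_{i,j} (g_i-g_j)^T W (g_i-g_j)
#'       \cdot M_{eff},}
#' multiplied by the effective number of independent SNPs in the set.
#'
#' @inheritParams linear_kernel
#' @param m_eff Effective SNP number; computed by `m_eff_fun` when `NULL`.
#' @param m_eff_fun Function used to estimate the effective SNP number
#'   (default [effective_snp_number()]); pluggable because the estimator is
#'   a convention, not part of the kernel definition.
#' @return Positive scalar `mu`.
#' @export
rbf_scale <- function(G, W, m_eff = NULL,
                      m_eff_fun = effective_snp_number) {
  Gm <- if (inherits(G, "DosageMatrix")) G$dosage else as.matrix(G)
  w <- weight_diag(W)
  if (is.null(m_eff)) m_eff <- m_eff_fun(Gm)
  D <- weighted_sqdist(Gm, w)
  mu <- mean(D) * m_eff
  if (mu <= 0) stop("all subjects genetically identical: RBF scale is 0")
  mu
}

#' RBF kernel on weighted dosages
#'
#' `K_ij = exp(-(g_i - g_j)^T W (g_i - g_j) / mu)`; entries in (0, 1],
#' diagonal exactly 1. Captures SNP-SNP interactions of all orders.
#'
#' @inheritParams linear_kernel
#' @param mu Positive scale parameter, typically from [rbf_scale()].
#' @return A `KernelMatrix` with elements `K`, `kernel` (`"rbf"`), `mu`,
#'   `weights`.
#' @export
rbf_kernel <- function(G, W, mu) {
  stopifnot(mu > 0)
  Gm <- if (inherits(G, "DosageMatrix")) G$dosage else as.matrix(G)
  w <- weight_diag(W)
  K <- exp(-weighted_sqdist(Gm, w) / mu)
  diag(K) <- 1
  structure(list(K = K, kernel = "rbf", mu = mu, weights = w),
            class = "KernelMatrix")
}

#' Test matrix of the kernel score statistic
#'
#' `M = (P_half %*% K %*% P_half) / 2`; its eigenvalues define the null
#' distribution of `Q = R^T M R` as a mixture of 1-df chi-squares, so they
#' are computed once and cached (descending order).
#'
#' @param P_half Symmetric square root of the null projection matrix (from
#'   [fit_null_reml()]).
#' @param K A `KernelMatrix` or bare kernel matrix.
#' @return A list of class `TestMatrix` with elements `M`, `eigenvalues`.
#' @export
test_matrix <- function(P_half, K) {
  Km <- if (inherits(K, "KernelMatrix")) K$K else as.matrix(K)
  stopifnot(nrow(P_half) == nrow(Km))
  M <- P_half %*% Km %*% P_half / 2
  M <- (M + t(M)) / 2
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  structure(list(M = M, eigenvalues = ev), class = "TestMatrix")
}
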