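#' Blom rank-inverse-normal transformation
#'
#' Maps a quantitative trait to approximate standard-normal scores via
#' \deqn{y_i = \Phi^{-1}\!\left(\frac{r_i - 3/8}{n + 1/4}\right)}
#' where `r_i` is the rank of value i (ties receive average ranks). Used to
#' normalize right-skewed traits such as systolic blood pressure before the
#' mixed-model fit.
#'
#' @param values Numeric vector, length >= 3, not all equal.
#' @return Numeric vector of Blom scores, monotone in `values`.
#' @export
blom_transform <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values for the Blom transformation")
  if (anyNA(values)) stop("missing values not allowed")
  if (diff(range(values)) == 0)
    stop("all values identical: ranks are degenerate")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Build the fixed-effect design matrix
#'
#' Columns are (intercept, age, sex, age x sex) with sex coded 0 = male,
#' 1 = female. Any full-rank sex coding yields the identical null projection
#' matrix; the 0/1 convention is just the reported parameterization.
#'
#' @param phe A `PhenotypeTable` (or data frame with `age`, `sex` columns;
#'   sex coded 1 = male, 2 = female).
#' @return An `n x 4` numeric matrix with columns
#'   `intercept`, `age`, `sex`, `age_sex`.
#' @export
build_design <- function(phe) {
  if (anyNA(phe$age) || anyNA(phe$sex))
    stop("age/sex must be complete for the design matrix")
  sex01 <- as.numeric(phe$sex == 2L)
  X <- cbind(intercept = 1, age = as.numeric(phe$age), sex = sex01,
             age_sex = as.numeric(phe$age) * sex01)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient (collinear column(s): ",
         paste(bad, collapse = ", "), ")")
  }
  X
}

#' Symmetric PSD matrix square root
#'
#' Eigendecomposition-based square root: `B = U diag(sqrt(lambda)) U^T` with
#' eigenvalues below a clipping threshold set to zero. Intended for the
#' rank-deficient null projection matrix, whose square root defines the
#' residual vector of the score test.
#'
#' @param A Symmetric matrix with eigenvalues >= -1e-6 (smaller negative
#'   values raise an error; values in (-1e-6, 0] are clipped to 0).
#' @return Symmetric PSD matrix `B` with `B %*% B = A` up to clipping.
#' @export
matrix_sqrt_psd <- function(A) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < -1e-6)
    stop("matrix is not positive semidefinite (min eigenvalue ",
         format(min(lam)), ")")
  thresh <- 1e-10 * max(abs(lam), 0)
  lam[lam < thresh] <- 0
  B <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
  (B + t(B)) / 2
}

#' Fit the polygenic null model by REML
#'
#' Fits the genetic null model `Y = X b + c + e` with
#' `cov(Y) = V = s2_fam * Phi + s2_o * I`, where `Phi` is the pedigree
#' kinship matrix, by restricted maximum likelihood. The variance components
#' are reparameterized as total variance times the familial ratio
#' `h = s2_fam / (s2_fam + s2_o)`; the total variance is profiled out and `h`
#' is optimized on `[0, 1 - 1e-6]` by bounded scalar search on the profile
#' REML log-likelihood, using a one-time eigendecomposition of `Phi` for
#' cheap likelihood evaluations.
#'
#' From the fit, the function also returns the null projection matrix
#' \deqn{P_0 = V^{-1} - V^{-1} X (X^T V^{-1} X)^{-1} X^T V^{-1},}
#' its symmetric PSD square root `P_half`, and the residual vector
#' `R = P_half %*% Y` used by the kernel score statistic.
#'
#' @param Y Numeric response (typically Blom-transformed trait).
#' @param X Design matrix from [build_design()].
#' @param kin Kinship matrix aligned to `Y`.
#' @param tol Scalar-search tolerance on `h` (default 1e-8).
#' @return A list of class `NullModel` with elements `b_o`, `s2_o`, `s2_fam`,
#'   `V_o`, `P_o`, `P_half`, `R`, `reml_loglik`, `h`.
#' @export
fit_null_reml <- function(Y, X, kin, tol = 1e-8) {
  Y <- as.numeric(Y)
  n <- length(Y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(kin) == n, ncol(kin) == n)
  eg <- eigen((unclass(kin) + t(unclass(kin))) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6)
    stop("kinship matrix is not positive semidefinite")
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  Yt <- drop(crossprod(U, Y))
  Xt <- crossprod(U, X)

  profile <- reml_profile_fun(Yt, Xt, lam, n, p)
  opt <- stats::optimize(profile, interval = c(0, 1 - 1e-6),
                         maximum = TRUE, tol = tol)
  h <- opt$maximum
  # bounded search never lands exactly on 0; snap when the boundary is as good
  if (profile(0) >= opt$objective - 1e-10) h <- 0
  pr <- reml_profile_fun(Yt, Xt, lam, n, p, details = TRUE)(h)
  s2_tot <- pr$s2_tot
  s2_fam <- h * s2_tot
  s2_o <- (1 - h) * s2_tot
  if (s2_o <= 0) {
    warning("residual variance estimated at the zero bound")
    s2_o <- max(s2_o, 1e-12)
  }

  d <- s2_tot * (h * lam + (1 - h))        # eigenvalues of V
  V_o <- U %*% (d * t(U))
  Vinv <- U %*% ((1 / d) * t(U))
  XtVinv <- crossprod(X, Vinv)             # p x n
  XtVinvX <- XtVinv %*% X
  b_o <- drop(solve(XtVinvX, XtVinv %*% Y))
  P_o <- Vinv - t(XtVinv) %*% solve(XtVinvX, XtVinv)
  P_o <- (P_o + t(P_o)) / 2
  P_half <- matrix_sqrt_psd(P_o)
  R <- drop(P_half %*% Y)

  structure(list(b_o = stats::setNames(b_o, colnames(X)),
                 s2_o = s2_o, s2_fam = s2_fam, h = h,
                 V_o = V_o, P_o = P_o, P_half = P_half, R = R,
                 reml_loglik = pr$loglik),
            class = "NullModel")
}

# Profile REML log-likelihood in the familial ratio h, with the total
# variance profiled out analytically. Operates on the kinship eigenbasis.
reml_profile_fun <- function(Yt, Xt, lam, n, p, details = FALSE) {
  force(Yt); force(Xt); force(lam)
  function(h) {
    d <- h * lam + (1 - h)                  # unit-scale eigenvalues of V
    w <- 1 / d
    XtWX <- crossprod(Xt, w * Xt)
    beta <- solve(XtWX, crossprod(Xt, w * Yt))
    res <- Yt - drop(Xt %*% beta)
    rss <- sum(w * res^2)
    s2_tot <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2_tot) + sum(log(d)) +
                    determinant(XtWX, logarithm = TRUE)$modulus[1L] +
                    (n - p))
    if (details) list(loglik = ll, s2_tot = s2_tot, beta = drop(beta)) else ll
  }
}

#' Profile REML log-likelihood of the familial ratio
#'
#' Evaluates the profile restricted log-likelihood (total variance profiled
#' out) at given values of `h = s2_fam / (s2_fam + s2_o)`. Mainly for
#' diagnostics and for verifying the optimum against a grid.
#'
#' @inheritParams fit_null_reml
#' @param h Numeric vector of ratios in `[0, 1)`.
#' @return Numeric vector of profile log-likelihood values.
#' @export
reml_profile_loglik <- function(Y, X, kin, h) {
  Y <- as.numeric(Y)
  n <- length(Y); p <- ncol(X)
  eg <- eigen((unclass(kin) + t(unclass(kin))) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Yt <- drop(crossprod(eg$vectors, Y))
  Xt <- crossprod(eg$vectors, X)
  f <- reml_profile_fun(Yt, Xt, lam, n, p)
  vapply(h, f, numeric(1L))
}

#' @export
print.NullModel <- function(x, ...) {
  cat("Polygenic null model (REML)\n")
  cat("  s2_fam =", format(x$s2_fam, digits = 4),
      " s2_o =", format(x$s2_o, digits = 4),
      " h =", format(x$h, digits = 4), "\n")
  cat("  fixed effects:", paste(names(x$b_o), format(x$b_o, digits = 3),
                                sep = "=", collapse = ", "), "\n")
  cat("  REML loglik:", format(x$reml_loglik, digits = 6), "\n")
  invisible(x)
}

#' Write a null-model summary as delimited text
#'
#' @param nm A `NullModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_model <- function(nm, path) {
  df <- data.frame(
    parameter = c(names(nm$b_o), "s2_fam", "s2_o", "h", "reml_loglik"),
    estimate = c(nm$b_o, nm$s2_fam, nm$s2_o, nm$h, nm$reml_loglik)
  )
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
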