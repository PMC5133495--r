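test_that("minor allele frequencies are column means / 2, folded at 0.5", {
  dos <- make_dos(cbind(c(0, 0, 0), c(0, 1, 2), c(2, 2, 1.4)))
  expect_equal(unname(minor_allele_frequencies(dos)), c(0, 0.5, 0.1))
})

test_that("weight schemes normalize to one and match hand values", {
  w_eq <- snp_weights(c(0.1, 0.4), "equal")
  expect_equal(w_eq$w, c(0.5, 0.5))

  w_inv <- snp_weights(c(0.1, 0.4), "inverse_maf")
  expect_equal(w_inv$w, c(0.8, 0.2))  # raw (10, 2.5)

  # beta density at 0.01 under Beta(1, 25): 25 * 0.99^24
  w_b <- snp_weights(c(0.01, 0.2), "beta")
  expect_equal(w_b$raw[1L], 25 * 0.99^24)
  expect_equal(w_b$raw[1L], dbeta(0.01, 1, 25))
  expect_equal(w_b$raw[2L], dbeta(0.2, 0.5, 0.5))  # common side

  # split boundary: nu = 0.05 belongs to the rare regime
  w_split <- snp_weights(c(0.05, 0.0500001), "beta")
  expect_equal(w_split$raw[1L], dbeta(0.05, 1, 25))
  expect_equal(w_split$raw[2L], dbeta(0.0500001, 0.5, 0.5))

  for (sch in c("equal", "inverse_maf", "beta")) {
    set.seed(4)
    for (i in 1:10) {
      maf <- runif(sample(1:20, 1L), 0.001, 0.5)
      expect_equal(sum(snp_weights(maf, sch)$w), 1, tolerance = 1e-12)
    }
  }
  expect_error(snp_weights(c(0, 0.1), "inverse_maf"), "MAF = 0")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w_inv, c("rs1", "rs2"), f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$weight, c(0.8, 0.2))
})

test_that("beta weights separate well-separated rare MAFs more moderately than 1/nu", {
  # the claim is about distinguishing genuinely different MAFs; for nearly
  # equal values above 0.04 the Beta(1, 25) density is locally steeper than
  # 1/nu, so the comparison is made for at least twofold MAF differences
  set.seed(8)
  for (i in 1:25) {
    nu1 <- runif(1, 0.001, 0.025)
    nu2 <- runif(1, 2 * nu1, 0.05)
    ratio_beta <- dbeta(nu1, 1, 25) / dbeta(nu2, 1, 25)
    ratio_inv <- nu2 / nu1
    expect_lte(ratio_beta, ratio_inv + 1e-12)
  }
})

test_that("linear kernel equals the explicit weighted sum", {
  set.seed(12)
  G <- matrix(sample(0:2, 20, replace = TRUE), 4, 5)
  rownames(G) <- paste0("s", 1:4)
  W <- snp_weights(pmax(minor_allele_frequencies(G), 0.01), "equal")
  K <- linear_kernel(G, W)$K
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    brute[i, j] <- sum(W$w * G[i, ] * G[j, ])
  expect_equal(unname(K), brute, tolerance = 1e-12)

  # zero dosage vector -> zero row/column
  G[2L, ] <- 0
  K0 <- linear_kernel(G, W)$K
  expect_equal(unname(K0[2L, ]), rep(0, 4))

  # hand value: g_i = g_j = (1,1), W = diag(0.5, 0.5)
  K2 <- linear_kernel(rbind(a = c(1, 1), b = c(1, 1)), c(0.5, 0.5))$K
  expect_equal(K2[1L, 2L], 1)

  # single SNP: rank-1 outer product
  g <- matrix(c(0, 1, 2), dimnames = list(paste0("s", 1:3), "v"))
  K1 <- linear_kernel(g, 1)$K
  expect_equal(unname(K1), outer(c(0, 1, 2), c(0, 1, 2)))
})

test_that("effective SNP number follows the eigenvalue rule", {
  set.seed(3)
  base <- rnorm(50)
  dup <- cbind(base, base, base)
  expect_equal(effective_snp_number(dup), 1)

  # orthogonalized columns: correlation exactly I -> M_eff = N
  Q <- qr.Q(qr(matrix(rnorm(50 * 4), 50)))
  expect_equal(effective_snp_number(Q), 4, tolerance = 1e-8)

  # two SNPs with known correlation: eigenvalues (1 + r, 1 - r)
  x <- rnorm(200); y <- rnorm(200)
  r <- cor(x, y)
  m_eff <- effective_snp_number(cbind(x, y))
  lam <- c(1 + abs(r), 1 - abs(r))
  expect_equal(m_eff, sum((lam >= 1) + (lam - floor(lam))), tolerance = 1e-10)

  expect_error(effective_snp_number(cbind(base, rep(1, 50))), "constant")
})

test_that("RBF scale is the pair-averaged weighted squared difference times M_eff", {
  G <- matrix(c(0, 2), ncol = 1, dimnames = list(c("a", "b"), "v"))
  expect_equal(rbf_scale(G, 1, m_eff = 1), 2)  # (0+4+4+0)/4
  expect_equal(rbf_scale(G, 1, m_eff = 2), 4)  # linear in M_eff
  expect_error(rbf_scale(matrix(1, 3, 1, dimnames = list(1:3, "v")), 1,
                         m_eff = 1), "identical")
})

test_that("RBF kernel has unit diagonal and the defining tail behavior", {
  set.seed(21)
  G <- matrix(sample(0:2, 30, replace = TRUE), 6, 5)
  rownames(G) <- paste0("s", 1:6)
  W <- snp_weights(rep(0.2, 5), "equal")
  mu <- rbf_scale(G, W)
  K <- rbf_kernel(G, W, mu)$K
  expect_equal(unname(diag(K)), rep(1, 6))
  expect_true(all(K > 0 & K <= 1))
  # identical subjects -> kernel entry 1
  G2 <- G; G2[2L, ] <- G2[1L, ]
  expect_equal(rbf_kernel(G2, W, mu)$K[1L, 2L], 1)
  # distance equal to the scale -> e^{-1}
  g <- matrix(c(0, 1), ncol = 1, dimnames = list(c("a", "b"), "v"))
  expect_equal(rbf_kernel(g, 1, mu = 1)$K[1L, 2L], exp(-1))
  # mu -> infinity: all entries -> 1
  expect_equal(unname(rbf_kernel(G, W, mu = 1e12)$K),
               matrix(1, 6, 6), tolerance = 1e-9)
})

test_that("kernels are PSD for random dosage matrices", {
  set.seed(33)
  for (i in 1:10) {
    G <- matrix(sample(0:2, 8 * 6, replace = TRUE, prob = c(6, 3, 1)), 8, 6)
    rownames(G) <- paste0("s", 1:8)
    maf <- pmax(minor_allele_frequencies(G), 0.01)
    W <- snp_weights(maf, sample(c("equal", "inverse_maf", "beta"), 1L))
    Kl <- linear_kernel(G, W)$K
    expect_gte(min(eigen(Kl, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    mu <- tryCatch(rbf_scale(G, W), error = function(e) NULL)
    if (!is.null(mu)) {
      Kr <- rbf_kernel(G, W, mu)$K
      expect_gte(min(eigen(Kr, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
    }
  }
})

test_that("test matrix is the half-projected kernel with cached eigenvalues", {
  n <- 5L
  M0 <- test_matrix(diag(n), matrix(0, n, n))
  expect_equal(unname(M0$M), matrix(0, n, n))
  expect_equal(M0$eigenvalues, rep(0, n))

  Mi <- test_matrix(diag(n), diag(n))
  expect_equal(unname(Mi$M), diag(n) / 2)
  expect_equal(Mi$eigenvalues, rep(0.5, n))

  set.seed(44)
  P <- matrix_sqrt_psd(crossprod(matrix(rnorm(n * n), n)))
  K <- crossprod(matrix(rnorm(n * n), n))
  M <- test_matrix(P, K)
  expect_equal(sum(diag(M$M)), sum(diag(P %*% P %*% K)) / 2,
               tolerance = 1e-10)  # tr(M) = tr(P0 K)/2
  expect_equal(M$eigenvalues, sort(eigen(M$M, symmetric = TRUE,
                                         only.values = TRUE)$values,
                                   decreasing = TRUE))
})
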