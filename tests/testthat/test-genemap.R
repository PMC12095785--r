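test_that("zscore centers and scales with the population-SD convention", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 8))
  z <- zscore(m)
  expect_equal(z[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(z^2)), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(cbind(1:3, rep(2, 3))), "zero-variance")
  expect_warning(z2 <- zscore(cbind(1:3, rep(2, 3)), on_constant = "drop"),
                 "dropped")
  expect_equal(ncol(z2), 1)
})

test_that("pca_denoise removes the first component and matches the SVD oracle", {
  set.seed(51)
  # exact rank-1 matrix: residuals vanish
  u <- rnorm(20); v <- rnorm(15)
  R <- pca_denoise(outer(u, v))
  expect_lt(max(abs(R)), 1e-8)
  X <- matrix(rnorm(20 * 50), 20)
  D <- pca_denoise(X)
  expect_equal(D, oracle_pca_denoise(X), tolerance = 1e-10)
  # residual columns orthogonal to the PC1 scores
  Xc <- sweep(X, 2, colMeans(X))
  pc1 <- svd(Xc)$u[, 1]
  expect_lt(max(abs(crossprod(D, pc1))), 1e-8)
  expect_error(pca_denoise(matrix(0, 5, 3)), "rank-0")
})

test_that("pls_fit recovers a noiseless shared latent factor", {
  set.seed(52)
  # one latent score generates both blocks (plus a whisper of noise in X so
  # the fit is well-posed); a single component must explain Y almost fully
  t_lat <- rnorm(40)
  X <- zscore(outer(t_lat, rnorm(30)) + 1e-3 * matrix(rnorm(40 * 30), 40))
  Y <- zscore(outer(t_lat, rnorm(4)))
  f <- pls_fit(X, Y, 1)
  expect_gte(f$var_explained[1], 0.999)
})

test_that("pls_fit satisfies its algebraic contracts", {
  set.seed(53)
  X <- zscore(matrix(rnorm(30 * 50), 30))
  Y <- zscore(matrix(rnorm(30 * 6), 30))
  f <- pls_fit(X, Y, 4)
  # successive X-scores mutually orthogonal
  G <- crossprod(f$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # the two block decompositions hold as identities of the fit
  expect_lt(max(abs(f$T %*% t(f$P) + f$E - X)), 1e-8)
  expect_lt(max(abs(f$U %*% t(f$Q) + f$F - Y)), 1e-8)
  expect_true(all(f$var_explained >= 0 & f$var_explained <= 1))
  expect_error(pls_fit(X, Y[1:10, ], 2), "same number")
  expect_error(pls_fit(X, Y, 40), "rank")
})

test_that("pls_fit matches an independently coded NIPALS oracle", {
  set.seed(54)
  X <- zscore(matrix(rnorm(30 * 50), 30))
  Y <- zscore(matrix(rnorm(30 * 6), 30))
  Y[, 1] <- Y[, 1] + X %*% rnorm(50, sd = 0.2)
  f <- pls_fit(X, Y, 3)
  o <- oracle_pls(X, Y, 3)
  expect_equal(f$var_explained, o$var_explained, tolerance = 1e-6)
  for (a in 1:3) {
    # agreement up to component sign
    s <- sign(sum(f$W[, a] * o$W[, a]))
    expect_equal(f$W[, a], s * o$W[, a], tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(f$T[, a], s * o$T[, a], tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(f$P[, a], s * o$P[, a], tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("pls permutation p-values are seeded with the add-one lower bound", {
  set.seed(55)
  X <- zscore(matrix(rnorm(30 * 20), 30))
  w <- rnorm(20)
  Y <- zscore((X %*% w) %*% t(rnorm(3)) + matrix(rnorm(30 * 3), 30) * 0.05)
  p1 <- pls_perm_test(X, Y, 1, n_perm = 99, seed = 2)
  expect_equal(p1$p[1], 1 / 100)
  p2 <- pls_perm_test(X, Y, 1, n_perm = 99, seed = 2)
  expect_identical(p1, p2)
  expect_error(pls_perm_test(X, Y, 1, n_perm = 10), "99")
})

test_that("surrogate-based permutation accepts matching ensembles only", {
  set.seed(56)
  coords <- cbind(runif(40, 0, 10), runif(40, 0, 10), 0)
  X <- zscore(matrix(rnorm(40 * 15), 40))
  Y <- zscore(matrix(rnorm(40 * 2), 40))
  surr <- lapply(1:2, function(j)
    make_surrogates(Y[, j], coords, n = 99, seed = j))
  p <- pls_perm_test(X, Y, 1, n_perm = 99, seed = 1, surrogates = surr)
  expect_true(p$p[1] > 0 && p$p[1] <= 1)
  expect_error(pls_perm_test(X, Y, 1, 99, 1, surrogates = surr[1]),
               "one surrogate ensemble per response column")
})

test_that("bootstrap z separates planted drivers from noise genes", {
  set.seed(57)
  n <- 60; m <- 150
  ph <- rnorm(n)
  X <- matrix(rnorm(n * m), n)
  X[, 1:10] <- X[, 1:10] + 1.5 * ph
  colnames(X) <- sprintf("g%03d", 1:m)
  Y <- sapply(1:4, function(j) ph * c(1, 0.8, 0.5, 0.3)[j] + rnorm(n) * 0.3)
  z <- pls_bootstrap_z(zscore(X), zscore(Y), 2, n_boot = 150, seed = 3)
  top <- rownames(z)[rank(-abs(z[, 1])) <= 10]
  expect_gte(sum(sprintf("g%03d", 1:10) %in% top), 9)
  # noise genes center near zero
  expect_lt(abs(mean(z[-(1:10), 1])), 0.5)
  expect_identical(z, pls_bootstrap_z(zscore(X), zscore(Y), 2, 150, seed = 3))
  expect_error(pls_bootstrap_z(zscore(X), zscore(Y), 2, n_boot = 10), "100")
})

test_that("fiqt adjustment matches the BH back-transform oracle and shrinks", {
  z <- c(3.0, 2.0, 1.0, 0.5, 0.1)
  expect_equal(fiqt_adjust(z), oracle_fiqt(z), tolerance = 1e-8)
  expect_equal(fiqt_adjust(0.7), 0.7)     # m = 1: BH is the identity
  expect_equal(fiqt_adjust(c(0, 1.4))[1], 0)
  set.seed(58)
  zz <- rnorm(50, sd = 2)
  expect_true(all(abs(fiqt_adjust(zz)) <= abs(zz) + 1e-12))
  expect_equal(sign(fiqt_adjust(zz)), sign(zz))
  expect_error(fiqt_adjust(c(1, NA)), "finite")
})

test_that("significant_genes filters on the absolute threshold", {
  za <- cbind(PLS1 = c(a = 2.5, b = -3.1, c = 0.4, d = 1.96),
              PLS2 = c(a = 0.1, b = 0.2, c = -2.0, d = 0))
  s <- significant_genes(za, 1.96)
  expect_setequal(s$PLS1, c("a", "b"))
  expect_setequal(s$PLS2, "c")
  expect_length(significant_genes(za * 0.1, 1.96)$PLS1, 0)
  expect_length(significant_genes(za, 0)$PLS1, 4)
})

test_that("surrogates preserve the value multiset and basic geometry errors", {
  set.seed(59)
  coords <- cbind(runif(50, 0, 10), runif(50, 0, 10), 0)
  map <- sin(coords[, 1] / 2) + 0.2 * rnorm(50)
  s <- make_surrogates(map, coords, n = 15, seed = 4)
  expect_equal(dim(s$surrogates), c(15, 50))
  for (i in 1:15) {
    expect_identical(sort(s$surrogates[i, ]), sort(map))
  }
  expect_identical(make_surrogates(map, coords, 5, seed = 4)$surrogates[1, ],
                   s$surrogates[1, ])
  expect_error(make_surrogates(map, coords * 0, 5, seed = 1), "coincident")
})
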