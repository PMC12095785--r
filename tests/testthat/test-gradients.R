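test_that("affinity kernel reproduces hand-computable angles", {
  # block fixture with sparsity low enough that no entry is thresholded:
  # identical rows give zero angle (affinity 1), orthogonal rows give
  # theta = pi/2, so 1 - theta/pi = 0.5
  f <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  a <- build_affinity(f, sparsity = 0.01)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0.5)
  expect_equal(a[2, 4], 0.5)
})

test_that("affinity rows keep exactly the top fraction of entries", {
  set.seed(21)
  x <- matrix(runif(30 * 30, 0.1, 1), 30)
  x <- (x + t(x)) / 2
  A <- build_affinity(x, sparsity = 0.9)
  # reconstruct the thresholded matrix to count kept entries per row
  keep <- ceiling(0.1 * 30)
  expect_equal(keep, 3)
  expect_true(isSymmetric(A))
  expect_true(all(A >= 0))
  expect_error(build_affinity(x, sparsity = 1.2), "sparsity")
  expect_error(build_affinity(x[, 1:10]), "square")
})

test_that("diffusion embedding matches a dense eigensolver oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(12, 20, 30)[seed]
    base <- matrix(runif(n * n, 0.05, 1), n)
    aff <- (base + t(base)) / 2
    diag(aff) <- 1
    g <- diffusion_embed(aff, k = 4)
    o <- oracle_embed(aff, k = 4)
    for (j in 1:4) {
      expect_gt(abs(cor(g$components[, j], o$components[, j])), 0.999)
    }
    expect_equal(g$eigenvalues, o$eigenvalues, tolerance = 1e-8)
  }
})

test_that("G1 separates a planted two-block structure", {
  aff <- two_block_affinity(6)
  g <- diffusion_embed(aff, k = 3)
  s <- sign(g$components[, 1])
  expect_true(all(s[1:6] == s[1]) && all(s[7:12] == -s[1]))
})

test_that("embedding is equivariant under node permutation", {
  set.seed(30)
  base <- matrix(runif(15 * 15, 0.1, 1), 15)
  aff <- (base + t(base)) / 2; diag(aff) <- 1
  g <- diffusion_embed(aff, k = 3)
  perm <- sample(15)
  gp <- diffusion_embed(aff[perm, perm], k = 3)
  # up to component sign, permuted rows match
  for (j in 1:3) {
    expect_equal(abs(gp$components[, j]), abs(g$components[perm, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("eigenvalues are nonincreasing in [0, 1]; bad input errors", {
  set.seed(31)
  base <- matrix(runif(100, 0.1, 1), 10)
  aff <- (base + t(base)) / 2; diag(aff) <- 1
  g <- diffusion_embed(aff, k = 5)
  expect_true(all(diff(g$eigenvalues) <= 1e-12))
  expect_true(all(g$eigenvalues >= 0 & g$eigenvalues <= 1))
  expect_error(diffusion_embed(aff, k = 10), "smaller")
  disc <- matrix(0, 6, 6)
  disc[1:3, 1:3] <- 1; disc[4:6, 4:6] <- 1
  expect_error(diffusion_embed(disc, k = 2), "disconnected")
})

test_that("procrustes alignment recovers orthogonal transforms", {
  set.seed(32)
  ref <- matrix(rnorm(20 * 4), 20)
  expect_equal(procrustes_align(ref, ref), ref, tolerance = 1e-12)
  Q <- random_orthogonal(4, seed = 1)
  expect_equal(procrustes_align(ref %*% Q, ref), ref, tolerance = 1e-8)
  # alignment never increases the Frobenius distance
  src <- matrix(rnorm(20 * 4), 20)
  d_before <- sqrt(sum((src - ref)^2))
  d_after <- sqrt(sum((procrustes_align(src, ref) - ref)^2))
  expect_lte(d_after, d_before + 1e-12)
  expect_error(procrustes_align(src[, 1:3], ref), "dimensions")
})

test_that("dispersion statistics reproduce hand computations exactly", {
  G <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(within_dispersion(G, 1:3), 4 / 3)
  same <- matrix(1, 4, 3)
  expect_equal(within_dispersion(same, 1:4), 0)
  G2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 4, 0), c(3, 4, 0))
  expect_equal(between_dispersion(G2, 1:2, 3:4), 5)
  expect_equal(between_dispersion(G2, 1:2, 1:2), 0)
  expect_equal(between_dispersion(G2, 1:2, 3:4),
               between_dispersion(G2, 3:4, 1:2))
  expect_error(within_dispersion(G, 1), "2 member")
  expect_error(between_dispersion(G, integer(0), 2:3), "nonempty")
})

test_that("dispersion is invariant to joint orthogonal transforms and shifts", {
  set.seed(33)
  G <- matrix(rnorm(30 * 3), 30)
  Q <- random_orthogonal(3, seed = 2)
  GQ <- G %*% Q
  expect_equal(within_dispersion(G, 1:10), within_dispersion(GQ, 1:10),
               tolerance = 1e-10)
  expect_equal(between_dispersion(G, 1:10, 11:30),
               between_dispersion(GQ, 1:10, 11:30), tolerance = 1e-10)
  shift <- sweep(G, 2, c(5, -2, 1), "+")
  expect_equal(within_dispersion(G, 1:10), within_dispersion(shift, 1:10),
               tolerance = 1e-10)
})

test_that("dispersion pipeline yields zero changes for identical sessions", {
  cfg <- tiny_config(seed = 14, n_subjects = 3, n_sessions = 2)
  geom <- gen_geometry(cfg)
  ts <- gen_timeseries(cfg, geom, rep(0, 3))
  fc_pre <- lapply(ts$pre, build_fc)
  feats <- list(FC = list(pre = fc_pre, post = fc_pre))
  tab <- dispersion_pipeline(feats, as.character(geom$network_labels))
  ch <- tab[tab$session == "change", ]
  expect_equal(ch$value, rep(0, nrow(ch)), tolerance = 1e-10)
  # row count: subjects x sessions(+change) x modalities x 3 measures
  expect_equal(nrow(tab), 3 * 3 * 1 * 3)
  expect_true(all(tab$value[tab$measure != "VN-FPN-between" &
                              tab$session != "change"] >= 0))
})

test_that("session changes shrink with the noise level", {
  cfg_hi <- tiny_config(seed = 15, n_subjects = 3, n_sessions = 2, noise_sd = 1)
  cfg_lo <- tiny_config(seed = 15, n_subjects = 3, n_sessions = 2,
                        noise_sd = 0.05)
  geom <- gen_geometry(cfg_hi)
  mean_abs_change <- function(cfg) {
    prof <- gen_profiles(cfg, geom, rep(0, 3))
    feats <- list(MPC = lapply(prof[c("pre", "post")], function(arr) {
      lapply(seq_len(dim(arr)[1]), function(s) {
        m <- arr[s, , ]; rownames(m) <- dimnames(arr)[[2]]; build_mpc(m)
      })
    }))
    tab <- dispersion_pipeline(feats, as.character(geom$network_labels))
    mean(abs(tab$value[tab$session == "change"]))
  }
  expect_lt(mean_abs_change(cfg_lo), mean_abs_change(cfg_hi))
})

test_that("normalize_to_control subtracts the control mean", {
  expect_equal(normalize_to_control(c(2, 4), c(1, 3)), c(0, 2))
  x <- rnorm(5)
  expect_equal(normalize_to_control(x, c(-1, 1)), x)
  ctrl <- rnorm(8)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 0)
  expect_error(normalize_to_control(1:3, numeric(0)), "empty")
})
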