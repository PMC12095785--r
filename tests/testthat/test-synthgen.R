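test_that("geometry is deterministic, complete, and seed-sensitive", {
  cfg <- tiny_config(seed = 5, n_nodes = 200)
  g1 <- gen_geometry(cfg)
  g2 <- gen_geometry(cfg)
  expect_identical(g1, g2)
  expect_equal(length(g1$network_labels), 200)
  expect_equal(nlevels(g1$network_labels), 7)
  expect_setequal(as.character(unique(g1$network_labels)),
                  c("VN", "SMN", "DAN", "SAL", "LIM", "FPN", "DMN"))
  expect_gte(sum(g1$network_labels == "VN"), 3)
  expect_gte(sum(g1$network_labels == "FPN"), 3)
  # different seeds: different coordinates, comparable label allocation
  counts <- sapply(1:10, function(s) {
    g <- gen_geometry(tiny_config(seed = s, n_nodes = 200))
    sort(as.integer(table(g$network_labels)))
  })
  g3 <- gen_geometry(tiny_config(seed = 6, n_nodes = 200))
  expect_false(isTRUE(all.equal(g1$coordinates, g3$coordinates)))
  # every allocation spreads 200 nodes over 7 patches without tiny/huge ones
  expect_true(all(counts >= 3))
  expect_true(all(counts <= 120))
  expect_error(gen_geometry(tiny_config(n_nodes = 12)), "7 networks")
})

test_that("expression fields are deterministic with planted associations", {
  cfg <- tiny_config(seed = 2, planted_genes = 1:8, planted_effect_size = 2,
                     noise_sd = 0.1)
  geom <- gen_geometry(cfg)
  ph <- as.numeric(scale(geom$coordinates[, 1]))
  e1 <- gen_expression(cfg, geom, ph)
  expect_identical(e1, gen_expression(cfg, geom, ph))
  expect_equal(dim(e1), c(40, 60))
  cors <- abs(cor(e1, ph))
  expect_gt(mean(cors[1:8]), quantile(cors[-(1:8)], 0.95))
  # null case: planted correlations look like non-planted ones
  cfg0 <- tiny_config(seed = 2, planted_genes = 1:8, planted_effect_size = 0)
  e0 <- gen_expression(cfg0, geom, ph)
  c0 <- abs(cor(e0, ph))
  expect_lt(abs(mean(c0[1:8]) - mean(c0[-(1:8)])), 2 * sd(c0))
  bad <- tiny_config(seed = 2)
  bad$planted_genes <- 1000L
  expect_error(gen_expression(bad, geom, ph), "planted")
  expect_error(gen_expression(cfg, geom, ph[-1]), "length")
})

test_that("profiles have the right shape and a noise-only null", {
  cfg <- tiny_config(seed = 3, noise_sd = 1e-4)
  geom <- gen_geometry(cfg)
  prof <- gen_profiles(cfg, geom, rep(0, 4))
  expect_named(prof, c("baseline", "pre", "post"))
  expect_equal(dim(prof$pre), c(4, 40, 8))
  # zero effects: pre and post differ only by (vanishing) noise
  expect_lt(mean(abs(prof$post - prof$pre)), 1e-3)
  cfg2 <- tiny_config(seed = 3, noise_sd = 1)
  prof2 <- gen_profiles(cfg2, geom, rep(0, 4))
  expect_gt(mean(abs(prof2$post - prof2$pre)), mean(abs(prof$post - prof$pre)))
  expect_error(gen_profiles(tiny_config(n_sessions = 1), geom, rep(0, 4)),
               "n_sessions")
})

test_that("planted microstructural change drives VN MPC dispersion", {
  cfg <- tiny_config(seed = 9, n_nodes = 100, n_subjects = 10, n_sessions = 2,
                     n_depths = 12)
  geom <- gen_geometry(cfg)
  eff <- seq(0.2, 2, length.out = 10)
  prof <- gen_profiles(cfg, geom, eff)
  feats <- list(MPC = lapply(prof, function(arr) {
    out <- lapply(seq_len(dim(arr)[1]), function(s) {
      m <- arr[s, , ]; rownames(m) <- dimnames(arr)[[2]]; build_mpc(m)
    })
    names(out) <- dimnames(arr)[[1]]
    out
  }))
  disp <- dispersion_pipeline(feats, as.character(geom$network_labels))
  ch <- disp[disp$session == "change" & disp$measure == "VN-within", ]
  fit <- lm(ch$value ~ eff)
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.3)
})

test_that("time series respect the block-covariance construction", {
  cfg <- tiny_config(seed = 4, n_sessions = 2, n_timepoints = 200)
  geom <- gen_geometry(cfg)
  ts <- gen_timeseries(cfg, geom, rep(1, 4))
  expect_equal(dim(ts$pre[[1]]), c(40, 200))
  fc <- build_fc(ts$pre[[1]])
  labels <- as.character(geom$network_labels)
  same <- outer(labels, labels, "==") & upper.tri(fc)
  diff <- !outer(labels, labels, "==") & upper.tri(fc)
  expect_gt(mean(fc[same]), mean(fc[diff]))
  # zero coupling: FPN dispersion change centered near 0
  cfg0 <- tiny_config(seed = 4, n_sessions = 2, n_subjects = 8,
                      fc_change_scale = 0)
  ts0 <- gen_timeseries(cfg0, geom, rep(1, 8))
  feats <- list(FC = lapply(ts0, function(sl) lapply(sl, build_fc)))
  disp <- dispersion_pipeline(feats, labels)
  ch <- disp$value[disp$session == "change" & disp$measure == "FPN-within"]
  expect_lt(abs(mean(ch)) / (sd(ch) / sqrt(length(ch)) + 1e-12), 3)
  expect_error(gen_timeseries(tiny_config(n_timepoints = 9), geom, rep(0, 4)),
               "n_timepoints")
})

test_that("behavior follows the logarithmic curve and clips to [0, 100]", {
  cfg <- tiny_config(seed = 6, noise_sd = 0)
  beh <- gen_behavior(cfg, rep(0, 4), a_base = 50, b_base = 10)
  one <- beh[beh$subject == "sub1", ]
  expect_equal(one$accuracy, 50 + 10 * log(1:3), tolerance = 1e-12)
  expect_equal(round(one$accuracy, 2), c(50, 56.93, 60.99))
  # coupling zero: fitted rates unrelated to effects
  cfg2 <- tiny_config(seed = 6, n_subjects = 30, noise_sd = 1,
                      dispersion_behavior_coupling = 0)
  eff <- rnorm(30)
  beh2 <- gen_behavior(cfg2, eff)
  bhat <- sapply(paste0("sub", 1:30), function(s) {
    d <- beh2[beh2$subject == s, ]
    fit_learning_rate(d$accuracy, d$t)[["b"]]
  })
  expect_lt(abs(cor(bhat, eff)), 0.45)
  # recovery: fitted rates track true rates at unit noise
  cfg3 <- tiny_config(seed = 7, n_subjects = 30, noise_sd = 1,
                      dispersion_behavior_coupling = 5)
  beh3 <- gen_behavior(cfg3, rnorm(30, 1, 0.5))
  btrue <- attr(beh3, "b")
  bhat3 <- sapply(paste0("sub", 1:30), function(s) {
    d <- beh3[beh3$subject == s, ]
    fit_learning_rate(d$accuracy, d$t)[["b"]]
  })
  expect_gt(cor(bhat3, btrue), 0.7)
  expect_true(all(beh3$accuracy >= 0 & beh3$accuracy <= 100))
})

test_that("gene-map variogram range grows with the spatial length scale", {
  ranges <- sapply(c(0.5, 1.5, 4), function(ell) {
    cfg <- tiny_config(seed = 8, n_nodes = 120, n_genes = 5,
                       spatial_corr_length = ell)
    geom <- gen_geometry(cfg)
    e <- gen_expression(cfg, geom, rep(0, 120))
    vg <- variogram(e[, 1], geom$coordinates)
    # distance at which the variogram first reaches 75% of its sill
    sill <- mean(tail(vg$gamma, 3))
    vg$h[which(vg$gamma >= 0.75 * sill)[1]]
  })
  expect_true(all(diff(ranges) > 0))
})

test_that("synthetic inputs round-trip through TSV", {
  cfg <- tiny_config(seed = 10, n_subjects = 2)
  geom <- gen_geometry(cfg)
  ph <- rep(0, 40)
  expr <- gen_expression(cfg, geom, ph)
  prof <- gen_profiles(cfg, geom, rep(0, 2))
  ts <- gen_timeseries(cfg, geom, rep(0, 2))
  beh <- gen_behavior(cfg, rep(0, 2))
  dir <- withr::local_tempdir()
  write_synth_inputs(cfg, geom, expr, prof, ts, beh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  expect_equal(back, expr, tolerance = 1e-12)
})
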