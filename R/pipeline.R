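#' Default configuration for the multisession synthetic run
#'
#' The synthetic study conditions: 200 left-hemisphere nodes, 2,000 genes
#' (50 planted drivers), 20 subjects, three imaging sessions
#' (baseline/pre/post), three training sessions, 500 permutations and 200
#' bootstrap samples. Effect sizes plant a visual-network microstructural
#' dispersion increase, a fronto-parietal functional dispersion increase, a
#' gene-expression association with the changed regions, and a
#' dispersion-behavior coupling.
#'
#' @param seed master integer seed
#' @return named list understood by [run_multisession()] and
#'   [run_intervention()]
#' @export
default_run_config <- function(seed = 1) {
  list(
    synth = synth_config(n_subjects = 20, n_sessions = 3, n_nodes = 200,
                         n_genes = 2000, n_depths = 12, n_timepoints = 150,
                         n_training_sessions = 3, spatial_corr_length = 1.5,
                         planted_genes = 1:50, planted_effect_size = 1,
                         dispersion_behavior_coupling = 5, noise_sd = 1,
                         seed = derive_seed(seed, 100)),
    sparsity = 0.9, k = 5, alpha = 0.5, t = 0,
    n_perm = 500, n_boot = 200, n_iter_specificity = 500,
    z_threshold = 1.96, alpha_level = 0.05,
    use_surrogates = TRUE, denoise = TRUE,
    seed = as.integer(seed))
}

# per-subject effect magnitudes: positive, unit-mean, moderately variable
draw_subject_effects <- function(n, seed) {
  set.seed(derive_seed(seed, 6))
  pmax(stats::rnorm(n, mean = 1, sd = 0.4), 0.05)
}

build_feature_lists <- function(profiles, timeseries) {
  sessions <- names(profiles)
  subj <- dimnames(profiles[[1]])[[1]]
  mpc <- lapply(sessions, function(ses) {
    out <- lapply(seq_along(subj), function(s) {
      m <- profiles[[ses]][s, , ]
      rownames(m) <- dimnames(profiles[[ses]])[[2]]
      build_mpc(m)
    })
    names(out) <- subj
    out
  })
  names(mpc) <- sessions
  fc <- lapply(timeseries, function(sl) lapply(sl, build_fc))
  list(MPC = mpc, FC = fc)
}

# subjects x 3 matrix of dispersion values for one modality/session
dispersion_matrix <- function(tab, modality, session) {
  sub <- tab[tab$modality == modality & tab$session == session, ]
  m <- stats::reshape(sub[, c("subject", "measure", "value")],
                      idvar = "subject", timevar = "measure",
                      direction = "wide")
  rn <- m$subject
  m <- as.matrix(m[, -1])
  colnames(m) <- sub("^value\\.", "", colnames(m))
  rownames(m) <- rn
  m[, c("VN-within", "FPN-within", "VN-FPN-between"), drop = FALSE]
}

# group-mean post-minus-pre change of aligned gradient components (G1-G3)
group_change_maps <- function(grads) {
  cols <- list()
  for (mod in names(grads)) {
    pre <- grads[[mod]][["pre"]]
    post <- grads[[mod]][["post"]]
    ch <- Reduce(`+`, lapply(names(pre), function(s)
      change_map(post[[s]][, 1:3], pre[[s]][, 1:3]))) / length(pre)
    colnames(ch) <- paste0(mod, "_G", 1:3)
    cols[[mod]] <- ch
  }
  do.call(cbind, cols)
}

# synthetic gene-set collection: one set enriched for planted drivers plus
# random sets of comparable size
synthetic_gene_sets <- function(gene_ids, planted_idx, seed, n_random = 19,
                                set_size = 80) {
  set.seed(derive_seed(seed, 7))
  planted <- gene_ids[planted_idx]
  extras <- sample(setdiff(gene_ids, planted), set_size - length(planted))
  sets <- list(planted_set = c(planted, extras))
  for (i in seq_len(n_random)) {
    sets[[paste0("random_set", sprintf("%02d", i))]] <-
      sample(gene_ids, set_size)
  }
  sets
}

behavior_analysis <- function(outcome, tab, modality, cfg) {
  ch <- dispersion_matrix(tab, modality, "change")
  res <- regress(outcome, ch)
  perm_p <- permutation_regression_p(outcome, ch, cfg$n_perm,
                                     derive_seed(cfg$seed, 50 + nchar(modality)))
  cv <- loocv(outcome, ch)
  spec <- if ("baseline" %in% tab$session) {
    specificity_permutation(dispersion_matrix(tab, modality, "baseline"),
                            dispersion_matrix(tab, modality, "pre"),
                            outcome, cfg$n_iter_specificity,
                            derive_seed(cfg$seed, 60 + nchar(modality)),
                            cfg$alpha_level)
  } else NULL
  list(regression = res, perm_p = perm_p, loocv = cv, specificity = spec)
}

#' Run the multisession training analysis end-to-end on synthetic data
#'
#' Generates the full synthetic study (geometry, expression, profiles, time
#' series, behavior), builds MPC and FC matrices, embeds and aligns
#' gradients, computes dispersion changes, fits the dispersion-behavior
#' regressions (with permutation, LOOCV and baseline/pre specificity
#' checks), runs the PLS gene-map association (raw and PCA-denoised
#' predictors; row-permutation and spatial-surrogate nulls; bootstrap
#' z-weights with FIQT adjustment) and the gene-set enrichment, and reports
#' which planted effects were flagged.
#'
#' @param cfg configuration list from [default_run_config()]
#' @param out_dir optional directory for TSV/JSON outputs and the manifest
#' @param verbose print stage progress
#' @return a results bundle (named list); see the `flags` element for the
#'   planted-effect report
#' @export
run_multisession <- function(cfg = default_run_config(), out_dir = NULL,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  sc <- cfg$synth
  say("synthgen: geometry, expression, profiles, time series, behavior")
  geom <- gen_geometry(sc)
  effects <- draw_subject_effects(sc$n_subjects, sc$seed)
  phenotype <- planted_change_pattern(sc, geom)
  expression <- gen_expression(sc, geom, phenotype)
  profiles <- gen_profiles(sc, geom, effects)
  timeseries <- gen_timeseries(sc, geom, effects)
  behavior <- gen_behavior(sc, effects)

  say("features + gradients + dispersion")
  feats <- build_feature_lists(profiles, timeseries)
  disp <- dispersion_pipeline(feats, as.character(geom$network_labels),
                              sparsity = cfg$sparsity, k = cfg$k,
                              alpha = cfg$alpha, t = cfg$t,
                              keep_gradients = TRUE)

  say("behavior regressions")
  subj <- paste0("sub", seq_len(sc$n_subjects))
  rates <- vapply(subj, function(s) {
    d <- behavior[behavior$subject == s, ]
    fit_learning_rate(d$accuracy, d$t)[["b"]]
  }, 0)
  beh <- list(MPC = behavior_analysis(rates, disp, "MPC", cfg),
              FC = behavior_analysis(rates, disp, "FC", cfg))

  say("genemap: PLS + permutation + bootstrap + FIQT")
  Y <- group_change_maps(attr(disp, "gradients"))
  Xz <- zscore(expression)
  Yz <- zscore(Y)
  l <- 3
  fit <- pls_fit(Xz, Yz, l)
  perm <- pls_perm_test(Xz, Yz, l, cfg$n_perm, derive_seed(cfg$seed, 70))
  surr_perm <- NULL
  if (isTRUE(cfg$use_surrogates)) {
    surr <- lapply(seq_len(ncol(Y)), function(j)
      make_surrogates(Yz[, j], geom$coordinates, cfg$n_perm,
                      derive_seed(cfg$seed, 71 + j)))
    surr_perm <- pls_perm_test(Xz, Yz, l, cfg$n_perm,
                               derive_seed(cfg$seed, 78), surrogates = surr)
  }
  denoised <- NULL
  if (isTRUE(cfg$denoise)) {
    Xd <- zscore(pca_denoise(expression))
    denoised <- list(fit = pls_fit(Xd, Yz, l),
                     perm = pls_perm_test(Xd, Yz, l, cfg$n_perm,
                                          derive_seed(cfg$seed, 79)))
  }
  z <- pls_bootstrap_z(Xz, Yz, l, cfg$n_boot, derive_seed(cfg$seed, 80))
  z_adj <- apply(z, 2, fiqt_adjust)
  dimnames(z_adj) <- dimnames(z)
  sig <- significant_genes(z_adj, cfg$z_threshold)

  say("enrichment")
  sets <- synthetic_gene_sets(colnames(expression), sc$planted_genes, cfg$seed)
  enr <- if (length(sig[[1]]) > 0)
    enrich(sig[[1]], sets, colnames(expression)) else NULL

  say("report")
  # flag rule (fixed upfront): a PLS component is flagged at a
  # Bonferroni-corrected permutation threshold; a dispersion measure is
  # flagged when its modality's model is permutation-significant AND its own
  # correlation with the outcome passes a Bonferroni-corrected test.
  # Per-measure correlations are used rather than multiple-regression
  # coefficients because the change measures are strongly collinear.
  pls_flags <- perm$p < cfg$alpha_level / l
  measure_flag <- function(b, modality) {
    ch <- dispersion_matrix(disp, modality, "change")
    ct <- apply(ch, 2, function(v) {
      h <- stats::cor.test(v, rates)
      c(r = unname(h$estimate), p = h$p.value)
    })
    model_sig <- b$perm_p < cfg$alpha_level
    list(flag = model_sig & (ct["p", ] < cfg$alpha_level / 3),
         r = ct["r", ], p = ct["p", ])
  }
  mpc_f <- measure_flag(beh$MPC, "MPC")
  fc_f <- measure_flag(beh$FC, "FC")
  flags <- list(
    pls_component = stats::setNames(pls_flags, paste0("PLS", seq_len(l))),
    mpc_measure = mpc_f$flag, mpc_r = mpc_f$r,
    fc_measure = fc_f$flag, fc_r = fc_f$r)

  results <- list(config = cfg, geometry = geom, subject_effects = effects,
                  behavior = behavior, learning_rates = rates,
                  dispersion = disp, behavior_models = beh,
                  pls = list(fit = fit, perm = perm, surrogate_perm = surr_perm,
                             denoised = denoised, z = z, z_adj = z_adj,
                             significant = sig),
                  enrichment = enr, flags = flags)
  if (!is.null(out_dir)) write_multisession_outputs(results, out_dir)
  results
}

write_multisession_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(results$dispersion, file.path(out_dir, "dispersion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  beh_json <- lapply(results$behavior_models, function(b)
    list(beta = as.list(b$regression$beta), t = as.list(b$regression$t),
         F = b$regression$F, df1 = b$regression$df1, df2 = b$regression$df2,
         r_squared = b$regression$r_squared,
         adj_r_squared = b$regression$adj_r_squared,
         perm_p = b$perm_p, loocv_cor = b$loocv$cor_pred_obs,
         specificity = b$specificity[c("n_significant", "p")]))
  write_manifest(beh_json, file.path(out_dir, "behavior_models.json"))
  gene_tab <- data.frame(gene = rep(rownames(results$pls$z), ncol(results$pls$z)),
                         component = rep(colnames(results$pls$z) %||%
                                           paste0("PLS", seq_len(ncol(results$pls$z))),
                                         each = nrow(results$pls$z)),
                         weight = as.vector(results$pls$fit$W),
                         z = as.vector(results$pls$z),
                         z_adj = as.vector(results$pls$z_adj))
  gene_tab$significant <- abs(gene_tab$z_adj) > results$config$z_threshold
  utils::write.table(gene_tab, file.path(out_dir, "pls_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$enrichment))
    utils::write.table(results$enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(list(config = results$config[setdiff(names(results$config), "synth")],
                      synth = unclass(results$config$synth),
                      pls_perm_p = results$pls$perm$p,
                      flags = results$flags),
                 file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Run the stimulation-intervention analysis on synthetic data
#'
#' Two groups (active and sham control) with pre/post sessions in one visit;
#' the functional-dispersion plant is applied to the active group only.
#' Dispersion changes of the active group are normalized to the control
#' group and summarized descriptively per modality and measure.
#'
#' @param cfg configuration list from [default_run_config()] (the synth block
#'   is re-used with `n_sessions = 2` per group)
#' @param out_dir optional output directory
#' @return list with the dispersion table, normalized per-subject changes,
#'   and a group summary table
#' @export
run_intervention <- function(cfg = default_run_config(), out_dir = NULL) {
  sc <- cfg$synth
  mk <- function(seed_off, coupling_on) {
    synth_config(n_subjects = sc$n_subjects, n_sessions = 2,
                 n_nodes = sc$n_nodes, n_genes = 10,
                 n_depths = sc$n_depths, n_timepoints = sc$n_timepoints,
                 spatial_corr_length = sc$spatial_corr_length,
                 mpc_change_scale = 0,
                 fc_change_scale = if (coupling_on) sc$fc_change_scale else 0,
                 noise_sd = sc$noise_sd, seed = derive_seed(sc$seed, seed_off))
  }
  cfg_anodal <- mk(8, TRUE)
  cfg_sham <- mk(9, FALSE)
  geom <- gen_geometry(cfg_anodal)
  eff_anodal <- draw_subject_effects(sc$n_subjects, cfg_anodal$seed)
  eff_sham <- draw_subject_effects(sc$n_subjects, cfg_sham$seed)
  feats <- list()
  for (grp in c("anodal", "sham")) {
    gcfg <- if (grp == "anodal") cfg_anodal else cfg_sham
    geff <- if (grp == "anodal") eff_anodal else eff_sham
    prof <- gen_profiles(gcfg, geom, geff)
    ts <- gen_timeseries(gcfg, geom, geff)
    f <- build_feature_lists(prof, ts)
    for (mod in names(f)) for (ses in names(f[[mod]])) {
      named <- f[[mod]][[ses]]
      names(named) <- paste0(grp, "_", names(named))
      feats[[mod]][[ses]] <- c(feats[[mod]][[ses]], named)
    }
  }
  disp <- dispersion_pipeline(feats, as.character(geom$network_labels),
                              sparsity = cfg$sparsity, k = cfg$k,
                              alpha = cfg$alpha, t = cfg$t)
  ch <- disp[disp$session == "change", ]
  ch$group <- ifelse(grepl("^anodal", ch$subject), "anodal", "sham")
  norm_rows <- list()
  for (mod in unique(ch$modality)) for (ms in unique(ch$measure)) {
    a <- ch[ch$group == "anodal" & ch$modality == mod & ch$measure == ms, ]
    s <- ch[ch$group == "sham" & ch$modality == mod & ch$measure == ms, ]
    a$normalized <- normalize_to_control(a$value, s$value)
    norm_rows[[paste(mod, ms)]] <- a
  }
  normalized <- do.call(rbind, norm_rows)
  rownames(normalized) <- NULL
  summary_tab <- do.call(rbind, lapply(split(
    normalized, paste(normalized$modality, normalized$measure)), function(d)
      data.frame(modality = d$modality[1], measure = d$measure[1],
                 mean_normalized_change = mean(d$normalized),
                 median_normalized_change = stats::median(d$normalized),
                 sd_normalized_change = stats::sd(d$normalized),
                 n = nrow(d))))
  rownames(summary_tab) <- NULL
  out <- list(dispersion = disp, normalized = normalized,
              summary = summary_tab)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary_tab, file.path(out_dir, "intervention_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(normalized, file.path(out_dir, "intervention_normalized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
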