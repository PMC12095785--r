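#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator that emulates the inputs of the
#' gradient-plasticity analysis: a node-parcellated gene-expression matrix,
#' per-subject per-session depth-wise microstructure (MT) profiles, resting
#' time series, behavioral training accuracies, and node geometry with a
#' seven-network partition. The seed fully determines every output.
#'
#' @param n_subjects number of subjects
#' @param n_sessions number of imaging sessions (>= 2; labeled
#'   baseline/pre/post)
#' @param n_nodes number of cortical nodes (parcels)
#' @param n_genes number of genes in the expression matrix
#' @param n_depths number of intracortical sampling depths per node (>= 3)
#' @param n_timepoints resting time-series length
#' @param n_training_sessions number of behavioral training sessions (>= 3)
#' @param spatial_corr_length length scale of the squared-exponential spatial
#'   kernel for gene maps, in the same (arbitrary) units as node coordinates
#'   (the node sheet spans roughly 10 units)
#' @param planted_genes integer indices of genes that carry the planted
#'   phenotype association
#' @param planted_effect_size standardized slope of the planted gene-phenotype
#'   term
#' @param dispersion_behavior_coupling standardized slope linking per-subject
#'   brain-change magnitude to the learning rate
#' @param mpc_change_scale per-unit-effect multiplicative depth-tilt applied
#'   to visual-network profiles after training (the planted microstructural
#'   change)
#' @param fc_change_scale per-unit-effect widening of the fronto-parietal
#'   within-network covariance spread after training (the planted functional
#'   change)
#' @param noise_sd observation-noise scale (behavioral accuracy SD in percent;
#'   scales background expression variability and profile noise)
#' @param seed integer master seed
#' @return a `synth_config` list
#' @export
synth_config <- function(n_subjects = 20, n_sessions = 3, n_nodes = 200,
                         n_genes = 16651, n_depths = 12, n_timepoints = 150,
                         n_training_sessions = 3,
                         spatial_corr_length = 1.5,
                         planted_genes = integer(0),
                         planted_effect_size = 0,
                         dispersion_behavior_coupling = 0,
                         mpc_change_scale = 0.25,
                         fc_change_scale = 0.2,
                         noise_sd = 1, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_sessions = as.integer(n_sessions),
              n_nodes = as.integer(n_nodes),
              n_genes = as.integer(n_genes),
              n_depths = as.integer(n_depths),
              n_timepoints = as.integer(n_timepoints),
              n_training_sessions = as.integer(n_training_sessions),
              spatial_corr_length = spatial_corr_length,
              planted_genes = as.integer(planted_genes),
              planted_effect_size = planted_effect_size,
              dispersion_behavior_coupling = dispersion_behavior_coupling,
              mpc_change_scale = mpc_change_scale,
              fc_change_scale = fc_change_scale,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_nodes < 10) stop("invalid config: n_nodes must be >= 10")
  if (cfg$n_sessions < 2) stop("invalid config: n_sessions must be >= 2")
  if (cfg$n_subjects < 1) stop("invalid config: n_subjects must be >= 1")
  if (cfg$n_depths < 3) stop("invalid config: n_depths must be >= 3")
  if (cfg$n_training_sessions < 3)
    stop("invalid config: n_training_sessions must be >= 3")
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (cfg$spatial_corr_length <= 0)
    stop("invalid config: spatial_corr_length must be > 0")
  if (length(cfg$planted_genes) > cfg$n_genes)
    stop("invalid config: more planted genes than genes")
  if (length(cfg$planted_genes) && any(cfg$planted_genes > cfg$n_genes))
    stop("planted gene index exceeds n_genes")
  invisible(cfg)
}

yeo7_names <- function() c("VN", "SMN", "DAN", "SAL", "LIM", "FPN", "DMN")

session_labels <- function(cfg) {
  base <- c("baseline", "pre", "post")
  n <- cfg$n_sessions
  if (n <= 3) utils::tail(base, n) else c(base, paste0("post", seq_len(n - 3) + 1))
}

#' Generate node geometry with a seven-network partition
#'
#' Nodes are sampled on a smooth 2-D sheet embedded in 3-D; network labels
#' form spatially contiguous patches (k-means on the sheet coordinates).
#' The visual (VN) and fronto-parietal (FPN) networks are placed at opposite
#' ends of the sheet's first axis, echoing the occipital-prefrontal layout.
#'
#' @param cfg a [synth_config()]
#' @return list with `coordinates` (nodes x 3) and `network_labels`
#'   (factor of length n_nodes over the seven network names)
#' @export
gen_geometry <- function(cfg) {
  validate_synth_config(cfg)
  n <- cfg$n_nodes
  if (n < 21)
    stop("invalid config: n_nodes too small to allocate 7 networks (need >= 21)")
  set.seed(derive_seed(cfg$seed, 1))
  for (attempt in 1:10) {
    u <- stats::runif(n, 0, 10)
    v <- stats::runif(n, 0, 10)
    z <- sin(u / 2) * cos(v / 2)
    coords <- cbind(x = u, y = v, z = z)
    km <- stats::kmeans(coords[, 1:2], centers = 7, nstart = 5, iter.max = 50)
    # order patches along the sheet's first axis: VN at one end, FPN near the
    # other, matching the occipital-to-prefrontal naming
    ord <- order(km$centers[, 1])
    lab_idx <- match(km$cluster, ord)
    labels <- factor(yeo7_names()[lab_idx], levels = yeo7_names())
    counts <- table(labels)
    if (all(counts >= 1) && counts[["VN"]] >= 3 && counts[["FPN"]] >= 3) {
      rownames(coords) <- paste0("node", seq_len(n))
      names(labels) <- rownames(coords)
      return(list(coordinates = coords, network_labels = labels))
    }
  }
  stop("invalid config: could not allocate 7 spatially contiguous networks")
}

# squared-exponential covariance over node coordinates, with a small white
# nugget so the Cholesky factor exists for coincident-ish nodes
se_kernel <- function(coords, length_scale, nugget = 0.05) {
  d2 <- as.matrix(stats::dist(coords))^2
  (1 - nugget) * exp(-d2 / (2 * length_scale^2)) + nugget * diag(nrow(coords))
}

#' Generate a nodes x genes expression matrix with planted associations
#'
#' Each gene is a spatially autocorrelated Gaussian field over the node sheet
#' (squared-exponential kernel, length scale `cfg$spatial_corr_length`),
#' scaled by `cfg$noise_sd`. Planted genes additionally carry
#' `planted_effect_size` times the standardized phenotype map.
#'
#' @param cfg a [synth_config()]
#' @param geom output of [gen_geometry()]
#' @param phenotype_map numeric vector of length n_nodes (the spatial pattern
#'   planted genes track)
#' @return numeric matrix (n_nodes x n_genes) with node/gene dimnames
#' @export
gen_expression <- function(cfg, geom, phenotype_map) {
  validate_synth_config(cfg)
  if (length(phenotype_map) != cfg$n_nodes)
    stop("phenotype_map length must equal n_nodes")
  if (length(cfg$planted_genes) && any(cfg$planted_genes > cfg$n_genes))
    stop("planted gene index exceeds n_genes")
  set.seed(derive_seed(cfg$seed, 2))
  K <- se_kernel(geom$coordinates, cfg$spatial_corr_length)
  U <- chol(K + 1e-8 * diag(cfg$n_nodes))
  Z <- matrix(stats::rnorm(cfg$n_nodes * cfg$n_genes), cfg$n_nodes, cfg$n_genes)
  expr <- cfg$noise_sd * crossprod(U, Z)
  if (length(cfg$planted_genes) && cfg$planted_effect_size != 0) {
    ph <- (phenotype_map - mean(phenotype_map)) / stats::sd(phenotype_map)
    expr[, cfg$planted_genes] <- expr[, cfg$planted_genes] +
      cfg$planted_effect_size * ph
  }
  dimnames(expr) <- list(rownames(geom$coordinates),
                         sprintf("gene%05d", seq_len(cfg$n_genes)))
  expr
}

# per-network smooth depth templates plus stable two-dimensional node
# deviations; returned once so every session shares the same baseline
# microstructure. Two depth basis functions give the node residual profiles
# a continuous angular spread, so planted shifts produce graded covariance
# changes instead of sign flips.
profile_templates <- function(cfg, geom) {
  set.seed(derive_seed(cfg$seed, 3))
  nets <- yeo7_names()
  d <- seq(0, 1, length.out = cfg$n_depths)
  slope <- stats::runif(7, -0.8, 0.8)
  curve <- stats::runif(7, -0.4, 0.4)
  tmpl <- sapply(seq_along(nets),
                 function(k) 1.5 + slope[k] * d + curve[k] * sin(pi * d))
  colnames(tmpl) <- nets
  b1 <- d - mean(d)
  b2 <- cos(pi * d) - mean(cos(pi * d))
  tau1 <- stats::rnorm(cfg$n_nodes, 0, 0.12)
  tau2 <- stats::rnorm(cfg$n_nodes, 0, 0.12)
  # fixed per-node direction of the post-training depth tilt; splits VN
  # profiles apart so the planted change raises within-network dispersion
  het_sign <- sample(c(-1, 1), cfg$n_nodes, replace = TRUE)
  list(depth = d, templates = tmpl, b1 = b1, b2 = b2,
       tau1 = tau1, tau2 = tau2, het_sign = het_sign)
}

# node profiles given the per-node deviation coefficients
node_profiles <- function(tp, labels, tau1) {
  t(tp$templates[, labels]) *
    (1 + outer(tau1, tp$b1) + outer(tp$tau2, tp$b2))
}

# the fixed +/- subcluster assignment of the functional plant
fpn_sign_pattern <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 4))
  sample(c(-1, 1), cfg$n_nodes, replace = TRUE)
}

#' Deterministic spatial pattern of the planted brain changes
#'
#' The per-node direction in which the planted training effects move each
#' node: the fixed depth-tilt direction for visual-network nodes
#' (microstructural plant) and the fixed covariance-subcluster sign for
#' fronto-parietal nodes (functional plant), zero elsewhere. This is the
#' spatial phenotype that planted genes track, standardized.
#'
#' @param cfg a [synth_config()]
#' @param geom output of [gen_geometry()]
#' @return standardized numeric vector of length n_nodes
#' @export
planted_change_pattern <- function(cfg, geom) {
  tp <- profile_templates(cfg, geom)
  s <- fpn_sign_pattern(cfg)
  lab <- as.character(geom$network_labels)
  ph <- tp$het_sign * (lab == "VN") + s * (lab == "FPN")
  as.numeric((ph - mean(ph)) / stats::sd(ph))
}

#' Generate depth-wise microstructure profiles per subject and session
#'
#' Node profiles are a network-specific smooth depth template modulated by a
#' stable node tilt, plus measurement noise. In post-training sessions the
#' visual-network (and, attenuated, fronto-parietal) profiles receive a
#' multiplicative depth-dependent perturbation proportional to each subject's
#' effect — the planted microstructural change. Multiplicative shape changes
#' (not additive noise) are used so the plant survives covariance
#' normalization.
#'
#' @param cfg a [synth_config()]
#' @param geom output of [gen_geometry()]
#' @param subject_effects numeric vector (one per subject) scaling the
#'   planted change
#' @return named list over sessions; each element an array
#'   `[subjects, nodes, depths]`
#' @export
gen_profiles <- function(cfg, geom, subject_effects) {
  validate_synth_config(cfg)
  if (cfg$n_sessions < 2) stop("n_sessions must be >= 2")
  stopifnot(length(subject_effects) == cfg$n_subjects)
  tp <- profile_templates(cfg, geom)
  labels <- as.character(geom$network_labels)
  base_profiles <- node_profiles(tp, labels, tp$tau1)
  sessions <- session_labels(cfg)
  is_vn <- labels == "VN"
  out <- list()
  for (si in seq_along(sessions)) {
    arr <- array(NA_real_, dim = c(cfg$n_subjects, cfg$n_nodes, cfg$n_depths),
                 dimnames = list(paste0("sub", seq_len(cfg$n_subjects)),
                                 rownames(geom$coordinates), NULL))
    post_session <- grepl("^post", sessions[si])
    for (s in seq_len(cfg$n_subjects)) {
      set.seed(derive_seed(cfg$seed, 100 + si * 1000 + s))
      prof <- base_profiles
      if (post_session) {
        # planted microstructural change: shift each VN node's first
        # deviation coefficient in its fixed direction, widening the
        # network's covariance spread in proportion to the subject effect
        tau1 <- tp$tau1
        tau1[is_vn] <- tau1[is_vn] +
          cfg$mpc_change_scale * subject_effects[s] * tp$het_sign[is_vn]
        prof <- node_profiles(tp, labels, tau1)
      }
      noise <- matrix(stats::rnorm(cfg$n_nodes * cfg$n_depths,
                                   sd = 0.02 * cfg$noise_sd),
                      cfg$n_nodes, cfg$n_depths)
      arr[s, , ] <- prof * (1 + noise)
    }
    out[[sessions[si]]] <- arr
  }
  out
}

# block correlation matrix with an optional fronto-parietal spread term
# (rank-one +/- split) and a common within-FPN coupling drop (coherent
# network-level loosening); jittered toward the identity until positive
# definite
block_sigma <- function(labels, fpn_sign, spread, common_drop = 0,
                        rho_within = 0.35, rho_between = 0.10) {
  n <- length(labels)
  R <- matrix(rho_between, n, n)
  for (net in unique(labels)) {
    idx <- which(labels == net)
    R[idx, idx] <- rho_within
  }
  if (spread != 0 || common_drop != 0) {
    fpn <- which(labels == "FPN")
    s <- fpn_sign[fpn]
    R[fpn, fpn] <- R[fpn, fpn] + spread * tcrossprod(s) - common_drop
  }
  diag(R) <- 1
  R <- pmin(pmax(R, -0.95), 0.95)
  diag(R) <- 1
  for (jit in c(0, 1e-6, 1e-4, 1e-2, 1e-1)) {
    Rj <- (R + jit * diag(n)) / (1 + jit)
    ch <- tryCatch(chol(Rj), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("internal error: could not make block covariance positive definite")
}

#' Generate resting time series per subject and session
#'
#' Draws multivariate-Gaussian node time series from a block covariance with
#' stronger within- than between-network correlation. In post-training
#' sessions the fronto-parietal within-network covariance acquires a
#' rank-one spread term proportional to the subject effect, splitting the
#' network into subclusters — the planted functional-dispersion increase.
#'
#' @inheritParams gen_profiles
#' @return named list over sessions; each element a list (one per subject) of
#'   nodes x timepoints matrices
#' @export
gen_timeseries <- function(cfg, geom, subject_effects) {
  validate_synth_config(cfg)
  stopifnot(length(subject_effects) == cfg$n_subjects)
  if (cfg$n_timepoints <= cfg$n_nodes / 4)
    stop("n_timepoints must exceed n_nodes / 4 for stable correlations")
  labels <- as.character(geom$network_labels)
  fpn_sign <- fpn_sign_pattern(cfg)
  sessions <- session_labels(cfg)
  out <- list()
  for (si in seq_along(sessions)) {
    post_session <- grepl("^post", sessions[si])
    subj_list <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      spread <- if (post_session)
        min(max(cfg$fc_change_scale * subject_effects[s], 0), 0.3) else 0
      ch <- block_sigma(labels, fpn_sign, spread)
      set.seed(derive_seed(cfg$seed, 200 + si * 1000 + s))
      Z <- matrix(stats::rnorm(cfg$n_nodes * cfg$n_timepoints),
                  cfg$n_nodes, cfg$n_timepoints)
      ts <- crossprod(ch, Z)
      rownames(ts) <- rownames(geom$coordinates)
      subj_list[[s]] <- ts
    }
    names(subj_list) <- paste0("sub", seq_len(cfg$n_subjects))
    out[[sessions[si]]] <- subj_list
  }
  out
}

#' Generate behavioral training accuracies
#'
#' Accuracy follows a logarithmic learning curve,
#' `accuracy(t) = a_s + b_s * ln(t) + noise`, with the per-subject learning
#' rate `b_s = b_base + dispersion_behavior_coupling * subject_effect`.
#' Accuracies are clipped to `[0, 100]` after noise (percent-correct
#' semantics).
#'
#' @inheritParams gen_profiles
#' @param a_base baseline accuracy intercept (percent)
#' @param b_base baseline learning rate (percent per log-session)
#' @return data.frame with columns subject, t, accuracy; the true per-subject
#'   intercepts and learning rates are attached as attributes `a` and `b`
#' @export
gen_behavior <- function(cfg, subject_effects, a_base = 50, b_base = 10) {
  validate_synth_config(cfg)
  stopifnot(length(subject_effects) == cfg$n_subjects)
  set.seed(derive_seed(cfg$seed, 5))
  a_s <- a_base + cfg$noise_sd * stats::rnorm(cfg$n_subjects)
  b_s <- b_base + cfg$dispersion_behavior_coupling * subject_effects
  tt <- seq_len(cfg$n_training_sessions)
  df <- expand.grid(subject = paste0("sub", seq_len(cfg$n_subjects)), t = tt,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(df$subject, paste0("sub", seq_len(cfg$n_subjects)))
  acc <- a_s[idx] + b_s[idx] * log(df$t) +
    cfg$noise_sd * stats::rnorm(nrow(df))
  df$accuracy <- pmin(pmax(acc, 0), 100)
  df <- df[order(idx, df$t), ]
  rownames(df) <- NULL
  attr(df, "a") <- a_s
  attr(df, "b") <- b_s
  df
}

#' Write synthetic inputs to disk as labeled TSV plus a JSON manifest
#'
#' @param cfg a [synth_config()]
#' @param geom,expression,profiles,timeseries,behavior generator outputs
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synth_inputs <- function(cfg, geom, expression, profiles, timeseries,
                               behavior, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geo <- data.frame(id = rownames(geom$coordinates), geom$coordinates,
                    network = as.character(geom$network_labels))
  utils::write.table(geo, file.path(dir, "geometry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(expression, file.path(dir, "expression.tsv"))
  for (ses in names(profiles)) {
    for (s in seq_len(dim(profiles[[ses]])[1])) {
      m <- profiles[[ses]][s, , ]
      rownames(m) <- dimnames(profiles[[ses]])[[2]]
      colnames(m) <- paste0("depth", seq_len(ncol(m)))
      write_matrix_tsv(m, file.path(dir, sprintf("profiles_%s_sub%02d.tsv", ses, s)))
    }
  }
  for (ses in names(timeseries)) {
    for (s in seq_along(timeseries[[ses]])) {
      m <- timeseries[[ses]][[s]]
      colnames(m) <- paste0("t", seq_len(ncol(m)))
      write_matrix_tsv(m, file.path(dir, sprintf("timeseries_%s_sub%02d.tsv", ses, s)))
    }
  }
  utils::write.table(behavior, file.path(dir, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(c(unclass(cfg), list(sessions = session_labels(cfg))),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}
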