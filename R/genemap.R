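#' Regress out the first principal component of gene expression
#'
#' Computes the first principal-component score vector across nodes of the
#' (column-centered) expression matrix and residualizes every gene column on
#' it (with intercept). Used to denoise expression dominated by a single
#' regional over-expression axis before the PLS fit.
#'
#' @param X nodes x genes expression matrix
#' @return residual matrix, same shape and dimnames
#' @export
pca_denoise <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 nodes")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 1, nv = 0)
  if (sv$d[1] < 1e-12) stop("rank-0 input: no principal component to remove")
  scores <- sv$u[, 1] * sv$d[1]
  D <- cbind(1, scores)
  R <- X - D %*% qr.solve(D, X)
  dimnames(R) <- dimnames(X)
  R
}

# one PLS component on the current (deflated) blocks: the
# covariance-maximizing weight pair, i.e. the dominant singular pair of
# X'Y. Computed exactly from the small p x p cross-product eigenproblem
# (p = number of response maps), which shares the NIPALS fixed point but is
# deterministic and fast when p << m.
pls_component <- function(X, Y) {
  M <- crossprod(X, Y)                       # m x p
  if (ncol(M) == 1) {
    w <- M[, 1]
  } else {
    ee <- eigen(crossprod(M), symmetric = TRUE)
    w <- as.numeric(M %*% ee$vectors[, 1])
  }
  w_norm <- sqrt(sum(w^2))
  w <- w / w_norm
  t_ <- as.numeric(X %*% w)
  cc <- as.numeric(crossprod(Y, t_))
  cc <- cc / sqrt(sum(cc^2))
  u <- as.numeric(Y %*% cc)
  # deterministic sign: largest-|w| element positive
  s <- sign(w[which.max(abs(w))])
  if (s < 0) { w <- -w; t_ <- -t_; cc <- -cc; u <- -u }
  list(w = w, t = t_, c = cc, u = u, w_norm = w_norm)
}

#' Partial least squares regression
#'
#' Extracts `l` covariance-maximizing latent components (the NIPALS fixed
#' point, computed exactly per component) relating a predictor block X
#' (nodes x genes) to a response block Y (nodes x maps), deflating both
#' blocks after each component. Populates
#' X-scores T, Y-scores U, X-loadings P, Y-loadings Q, residual blocks E and
#' F (so that `X = T P' + E` and `Y = U Q' + F` hold as identities of the
#' fit), normalized X-weights W, and the fraction of total Y variance
#' explained by each component's rank-one reconstruction.
#'
#' @param X predictor matrix (z-scored), nodes x genes
#' @param Y response matrix (z-scored), nodes x maps
#' @param l number of components (>= 1, bounded by rank)
#' @return object of class `pls_model`
#' @export
pls_fit <- function(X, Y, l) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of nodes")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite input")
  n <- nrow(X); m <- ncol(X); p <- ncol(Y)
  if (l < 1 || l > min(n - 1, m)) stop("l exceeds the rank bound min(n - 1, m)")
  ssY0 <- sum(Y^2)
  Xc <- X; Yc <- Y
  Tm <- matrix(0, n, l); Um <- matrix(0, n, l)
  Wm <- matrix(0, m, l); Pm <- matrix(0, m, l); Qm <- matrix(0, p, l)
  varY <- numeric(l); w_norm <- numeric(l)
  for (a in seq_len(l)) {
    cmp <- pls_component(Xc, Yc)
    tt <- sum(cmp$t^2)
    if (tt < 1e-24) stop("l exceeds the rank of the data (component ", a, ")")
    p_a <- crossprod(Xc, cmp$t) / tt
    q_reg <- crossprod(Yc, cmp$t) / tt
    uu <- sum(cmp$u^2)
    q_u <- if (uu > 1e-24) crossprod(Yc, cmp$u) / uu else q_reg
    Tm[, a] <- cmp$t; Um[, a] <- cmp$u
    Wm[, a] <- cmp$w; Pm[, a] <- p_a; Qm[, a] <- q_u
    w_norm[a] <- cmp$w_norm
    varY[a] <- tt * sum(q_reg^2) / ssY0
    Xc <- Xc - tcrossprod(cmp$t, p_a)
    Yc <- Yc - tcrossprod(cmp$t, q_reg)
  }
  rownames(Wm) <- rownames(Pm) <- colnames(X)
  rownames(Qm) <- colnames(Y)
  structure(list(T = Tm, U = Um, W = Wm, P = Pm, Q = Qm,
                 E = X - tcrossprod(Tm, Pm), F = Y - tcrossprod(Um, Qm),
                 var_explained = varY, w_norm = w_norm, n = n, l = l),
            class = "pls_model")
}

#' Permutation test for PLS component significance
#'
#' Builds a null distribution of per-component Y-variance-explained by
#' refitting the PLS on row-permuted responses (all response columns permuted
#' jointly, preserving inter-map correlation), or on surrogate responses when
#' a spatially constrained surrogate ensemble is supplied. Add-one p-values.
#'
#' @inheritParams pls_fit
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed
#' @param surrogates optional list with one surrogate matrix
#'   (n_surrogates x nodes) per response column, from [make_surrogates()];
#'   when given, iteration i uses surrogate i of every column
#' @return list with per-component `p`, `observed` variance explained, and
#'   the `null` matrix (n_perm x l)
#' @export
pls_perm_test <- function(X, Y, l, n_perm = 1000, seed = 1, surrogates = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- pls_fit(X, Y, l)$var_explained
  n <- nrow(Y)
  if (!is.null(surrogates)) {
    surrogates <- lapply(surrogates, function(s)
      if (inherits(s, "surrogate_ensemble")) s$surrogates else s)
    if (length(surrogates) != ncol(Y))
      stop("need one surrogate ensemble per response column")
    for (s in surrogates) {
      if (ncol(s) != n) stop("surrogate node count does not match Y")
      if (nrow(s) < n_perm) stop("fewer surrogates than permutations")
    }
  }
  set.seed(derive_seed(seed, 21))
  null <- matrix(NA_real_, n_perm, l)
  for (i in seq_len(n_perm)) {
    Yp <- if (is.null(surrogates)) {
      Y[sample(n), , drop = FALSE]
    } else {
      zscore(sapply(surrogates, function(s) s[i, ]))
    }
    null[i, ] <- pls_fit(X, Yp, l)$var_explained
  }
  p <- vapply(seq_len(l), function(a) perm_pvalue(null[, a], obs[a]), 0)
  list(p = p, observed = obs, null = null)
}

#' Bootstrap z-weights for PLS gene loadings
#'
#' Resamples nodes with replacement, refits the PLS, Procrustes-rotates each
#' bootstrap's gene-loading matrix onto the observed one (correcting axis
#' rotation and reflection across bootstrap samples), and normalizes the
#' observed weights by the bootstrap standard deviation, giving z-score-like
#' weights per gene per component. Weights enter on the covariance-loading
#' scale (unit response-weight, no unit-norm constraint on the gene vector):
#' a unit-norm constraint would couple every gene's bootstrap value to the
#' resampling-inflated norm of the whole vector and systematically deflate
#' the bootstrap SDs; on the covariance scale the z-scores are calibrated.
#'
#' @inheritParams pls_fit
#' @param n_boot number of bootstrap samples (>= 100)
#' @param seed integer seed
#' @param procrustes apply the rotation correction (default TRUE; disabling
#'   it exposes the sign-flip inflation the correction removes)
#' @return genes x components matrix of z values, with attribute `"sd"`
#'   (bootstrap SDs) and `"n_retries"`
#' @export
pls_bootstrap_z <- function(X, Y, l, n_boot = 1000, seed = 1,
                            procrustes = TRUE) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fit0 <- pls_fit(X, Y, l)
  W_obs <- fit0$W %*% diag(fit0$w_norm, l)
  acc <- matrix(0, nrow(W_obs), l)
  acc2 <- matrix(0, nrow(W_obs), l)
  set.seed(derive_seed(seed, 22))
  retries <- 0L
  for (b in seq_len(n_boot)) {
    Wb <- NULL
    for (try in 1:50) {
      idx <- sample(n, replace = TRUE)
      Wb <- tryCatch({
        fb <- pls_fit(X[idx, , drop = FALSE], Y[idx, , drop = FALSE], l)
        fb$W %*% diag(fb$w_norm, l)
      }, error = function(e) NULL)
      if (!is.null(Wb)) break
      retries <- retries + 1L
    }
    if (is.null(Wb)) stop("bootstrap sample rank-deficient after 50 retries")
    if (procrustes) {
      sv <- svd(crossprod(Wb, W_obs))
      Wb <- Wb %*% (sv$u %*% t(sv$v))
    }
    acc <- acc + Wb
    acc2 <- acc2 + Wb^2
  }
  sd_boot <- sqrt(pmax(acc2 / n_boot - (acc / n_boot)^2, 0))
  z <- W_obs / pmax(sd_boot, 1e-300)
  dimnames(z) <- dimnames(fit0$W)
  attr(z, "sd") <- sd_boot
  attr(z, "n_retries") <- retries
  z
}

#' FDR inverse quantile transformation of z-scores
#'
#' Shrinks a vector of z-scores for winner's-curse bias: two-sided p-values
#' are Benjamini-Hochberg adjusted and mapped back to the z scale, so
#' `|adjusted z| <= |z|` always.
#'
#' @param z numeric vector of z-scores
#' @return adjusted z vector, same sign pattern
#' @export
fiqt_adjust <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  q <- stats::p.adjust(pmax(p, 1e-300), method = "BH")
  z_adj <- sign(z) * stats::qnorm(q / 2, lower.tail = FALSE)
  sign(z) * pmin(abs(z_adj), abs(z))
}

#' Select significant genes from adjusted z-scores
#'
#' @param z_adj genes x components matrix (or vector) of adjusted z-scores
#' @param threshold absolute-z cutoff (1.96, i.e. two-sided p < 0.05)
#' @return list (per component) of significant gene names/indices
#' @export
significant_genes <- function(z_adj, threshold = 1.96) {
  z_adj <- as.matrix(z_adj)
  out <- lapply(seq_len(ncol(z_adj)), function(a) {
    idx <- which(abs(z_adj[, a]) > threshold)
    if (!is.null(rownames(z_adj))) rownames(z_adj)[idx] else idx
  })
  names(out) <- colnames(z_adj) %||% paste0("PLS", seq_along(out))
  out
}

#' Empirical variogram of a node map
#'
#' Bins node pairs by Euclidean distance and averages half squared
#' differences per bin.
#'
#' @param map numeric node vector
#' @param coords nodes x d coordinate matrix
#' @param n_bins number of distance bins (equal-count)
#' @return data.frame with bin center `h` and semivariance `gamma`
#' @export
variogram <- function(map, coords, n_bins = 10) {
  D <- as.matrix(stats::dist(coords))
  iu <- which(upper.tri(D))
  d <- D[iu]
  dif2 <- 0.5 * (outer(map, map, "-")^2)[iu]
  br <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(d, br, include.lowest = TRUE)
  data.frame(h = tapply(d, bin, mean), gamma = tapply(dif2, bin, mean),
             row.names = NULL)
}

#' Spatially constrained surrogate maps by variogram matching
#'
#' Generates null maps that preserve the value multiset of the source map
#' exactly (rank remapping) while approximately preserving its spatial
#' autocorrelation: a random permutation of the map is smoothed with a
#' Gaussian distance kernel plus a white-noise blend, the kernel width and
#' blend weight being calibrated once against the source variogram, and the
#' smoothed field's ranks then receive the original sorted values.
#'
#' @param map numeric node vector
#' @param coords nodes x d coordinate matrix
#' @param n number of surrogates (>= 1)
#' @param seed integer seed
#' @param n_bins variogram bins used for calibration
#' @param n_calib trial surrogates per candidate parameter pair
#'   (their pooled variogram drives the choice)
#' @return object of class `surrogate_ensemble`: list with `surrogates`
#'   (n x nodes matrix), `width`, `beta`, `calib_rel_err`
#' @export
make_surrogates <- function(map, coords, n, seed = 1, n_bins = 10,
                            n_calib = 15) {
  coords <- as.matrix(coords)
  if (n < 1) stop("n must be >= 1")
  D <- as.matrix(stats::dist(coords))
  if (max(D) < 1e-12) stop("degenerate geometry: all nodes coincident")
  n_nodes <- length(map)
  vg0 <- variogram(map, coords, n_bins)
  map <- unname(map)
  sorted_vals <- sort(map)
  smooth_mats <- function(width) {
    K <- exp(-D^2 / (2 * width^2))
    K / rowSums(K)
  }
  one_surrogate <- function(S, beta) {
    perm <- map[sample(n_nodes)]
    field <- as.numeric(S %*% perm) + beta * stats::sd(perm) *
      stats::rnorm(n_nodes)
    sorted_vals[rank(field, ties.method = "first")]
  }
  rel_err <- function(vg) mean(abs(vg$gamma - vg0$gamma) / pmax(vg0$gamma, 1e-12))
  widths <- stats::quantile(D[D > 0], c(0.03, 0.05, 0.08, 0.12, 0.2, 0.35))
  betas <- c(0, 0.1, 0.25, 0.5, 1, 2)
  set.seed(derive_seed(seed, 31))
  best <- list(err = Inf)
  for (w in widths) {
    S <- smooth_mats(w)
    for (b in betas) {
      g <- Reduce(`+`, lapply(seq_len(n_calib), function(i)
        variogram(one_surrogate(S, b), coords, n_bins)$gamma)) / n_calib
      err <- rel_err(data.frame(gamma = g))
      if (err < best$err) best <- list(err = err, width = w, beta = b, S = S)
    }
  }
  set.seed(derive_seed(seed, 32))
  surr <- t(replicate(n, one_surrogate(best$S, best$beta)))
  if (n == 1) surr <- matrix(surr, nrow = 1)
  structure(list(surrogates = surr, width = unname(best$width),
                 beta = best$beta, calib_rel_err = best$err),
            class = "surrogate_ensemble")
}
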