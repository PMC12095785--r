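# Independent brute-force oracles used to pin the package's numerics.
# Each is written from the definition, without reusing package internals.

# partial correlation of depth profiles controlling the cortex-wide mean
# profile, Fisher z, negatives clipped, zero diagonal
oracle_mpc <- function(profiles) {
  n <- nrow(profiles)
  mp <- colMeans(profiles)
  res <- matrix(NA_real_, ncol(profiles), n)
  for (i in seq_len(n)) {
    fit <- stats::lm(profiles[i, ] ~ mp)
    res[, i] <- stats::residuals(fit)
  }
  z <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- stats::cor(res[, i], res[, j])
    r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
    z[i, j] <- max(atanh(r), 0)
  }
  z
}

# textbook Pearson correlation matrix of node time series
oracle_fc <- function(ts) {
  n <- nrow(ts)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- ts[i, ] - mean(ts[i, ]); xj <- ts[j, ] - mean(ts[j, ])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# normal-equations OLS on z-scored data with explicit F/t formulas
oracle_regress <- function(y, X) {
  zy <- (y - mean(y)) / stats::sd(y)
  zX <- apply(X, 2, function(v) (v - mean(v)) / stats::sd(v))
  n <- length(y); p <- ncol(X)
  D <- cbind(1, zX)
  beta <- solve(t(D) %*% D, t(D) %*% zy)
  fitted <- D %*% beta
  rss <- sum((zy - fitted)^2)
  tss <- sum((zy - mean(zy))^2)
  r2 <- 1 - rss / tss
  sigma2 <- rss / (n - p - 1)
  se <- sqrt(diag(solve(t(D) %*% D)) * sigma2)
  list(beta = beta[-1], t = (beta / se)[-1],
       F = (r2 / p) / ((1 - r2) / (n - p - 1)),
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# leverage-based closed-form LOO predictions for OLS
oracle_loo_predictions <- function(y, X) {
  D <- cbind(1, X)
  H <- D %*% solve(t(D) %*% D) %*% t(D)
  fitted <- as.numeric(H %*% y)
  y - (y - fitted) / (1 - diag(H))
}

# independently coded NIPALS oracle: classic alternating power iteration
# per component with deflation
oracle_pls <- function(X, Y, l, tol = 1e-13, max_iter = 5000) {
  n <- nrow(X)
  ssY0 <- sum(Y^2)
  Tm <- matrix(0, n, l); Wm <- matrix(0, ncol(X), l)
  Pm <- matrix(0, ncol(X), l); varY <- numeric(l)
  for (a in seq_len(l)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_ <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- as.numeric(crossprod(X, u)); w <- w / sqrt(sum(w^2))
      t_new <- as.numeric(X %*% w)
      cc <- as.numeric(crossprod(Y, t_new)); cc <- cc / sqrt(sum(cc^2))
      u <- as.numeric(Y %*% cc)
      if (sqrt(sum((t_new - t_)^2)) < tol * sqrt(sum(t_new^2))) { t_ <- t_new; break }
      t_ <- t_new
    }
    if (sign(w[which.max(abs(w))]) < 0) { w <- -w; t_ <- -t_ }
    p_ <- as.numeric(crossprod(X, t_)) / sum(t_^2)
    q_ <- as.numeric(crossprod(Y, t_)) / sum(t_^2)
    varY[a] <- sum(t_^2) * sum(q_^2) / ssY0
    X <- X - outer(t_, p_)
    Y <- Y - outer(t_, q_)
    Tm[, a] <- t_; Wm[, a] <- w; Pm[, a] <- p_
  }
  list(T = Tm, W = Wm, P = Pm, var_explained = varY)
}

# SVD-projection oracle for removing the first principal component
oracle_pca_denoise <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  pc1 <- sv$u[, 1]
  D <- cbind(1, pc1)
  X - D %*% solve(t(D) %*% D) %*% t(D) %*% X
}

# step-by-step BH + quantile back-transform for FIQT
oracle_fiqt <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  sign(z) * stats::qnorm(1 - q / 2)
}

# exact hypergeometric tail by enumeration over the overlap support
oracle_hyper_tail <- function(k, set_size, bg, n_hits) {
  kk <- k:min(set_size, n_hits)
  sum(choose(set_size, kk) * choose(bg - set_size, n_hits - kk)) /
    choose(bg, n_hits)
}

# dense eigensolver oracle for the diffusion embedding: eigenvectors of the
# row-stochastic transition matrix after alpha-normalization
oracle_embed <- function(aff, k, alpha = 0.5) {
  d <- rowSums(aff)
  W <- aff / outer(d^alpha, d^alpha)
  P <- W / rowSums(W)
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  vecs <- Re(e$vectors[, ord])
  vals <- Re(e$values[ord])
  list(components = vecs[, 2:(k + 1), drop = FALSE],
       eigenvalues = vals[2:(k + 1)] / vals[1])
}

# small random orthogonal matrix via QR
random_orthogonal <- function(k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(k * k), k)))
}

# two-block affinity fixture: strong within-block, weak between
two_block_affinity <- function(n_per_block = 6, strong = 1, weak = 0.05) {
  n <- 2 * n_per_block
  A <- matrix(weak, n, n)
  A[1:n_per_block, 1:n_per_block] <- strong
  A[(n_per_block + 1):n, (n_per_block + 1):n] <- strong
  diag(A) <- 1
  A
}

# small fully-valid synthetic config for fast tests
tiny_config <- function(seed = 1, ...) {
  args <- list(n_subjects = 4, n_sessions = 3, n_nodes = 40, n_genes = 60,
               n_depths = 8, n_timepoints = 60, spatial_corr_length = 1.5,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}
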