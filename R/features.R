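#' Microstructure profile covariance (MPC) matrix
#'
#' For every node pair, the partial correlation between depth-wise intensity
#' profiles controlling for the cortex-wide mean profile, Fisher r-to-z
#' transformed. Negative edges are clipped to zero by default (required for
#' the non-negative affinity step) and the diagonal is set to zero.
#'
#' @param profiles nodes x depths matrix of intensities (>= 3 depths)
#' @param clip_negative clip negative z edges to 0 (default TRUE)
#' @return symmetric nodes x nodes matrix, zero diagonal
#' @export
build_mpc <- function(profiles, clip_negative = TRUE) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles) || any(!is.finite(profiles)))
    stop("profiles contain missing or non-finite values")
  if (ncol(profiles) < 3) stop("need at least 3 depths")
  depth_var <- apply(profiles, 1, stats::var)
  if (any(depth_var < 1e-14)) {
    bad <- which(depth_var < 1e-14)
    stop("degenerate node(s) with constant profile: ",
         paste(rownames(profiles)[bad] %||% bad, collapse = ", "))
  }
  mean_profile <- colMeans(profiles)
  D <- cbind(1, mean_profile)                 # depths x 2
  P <- t(profiles)                            # depths x nodes
  resid <- P - D %*% qr.solve(D, P)
  rvar <- apply(resid, 2, stats::var)
  if (any(rvar < 1e-14)) {
    bad <- which(rvar < 1e-14)
    stop("degenerate node(s): profile collinear with mean profile: ",
         paste(rownames(profiles)[bad] %||% bad, collapse = ", "))
  }
  r <- stats::cor(resid)
  cap <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -cap), cap))
  if (clip_negative) z[z < 0] <- 0
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(rownames(profiles), rownames(profiles))
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Functional connectivity matrix
#'
#' Pairwise Pearson correlation of node time series.
#'
#' @param timeseries nodes x timepoints matrix (>= 3 timepoints)
#' @return symmetric correlation matrix with unit diagonal
#' @export
build_fc <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (ncol(timeseries) < 3) stop("need at least 3 timepoints")
  v <- apply(timeseries, 1, stats::var)
  if (any(v < 1e-14)) {
    bad <- which(v < 1e-14)
    stop("degenerate node(s) with zero-variance time series: ",
         paste(rownames(timeseries)[bad] %||% bad, collapse = ", "))
  }
  fc <- stats::cor(t(timeseries))
  diag(fc) <- 1
  dimnames(fc) <- list(rownames(timeseries), rownames(timeseries))
  fc
}

#' Post-minus-pre change map
#'
#' @param post,pre matrices or vectors of identical shape
#' @return elementwise `post - pre`
#' @export
change_map <- function(post, pre) {
  if (!identical(dim(post), dim(pre)) || length(post) != length(pre))
    stop("shape mismatch between post and pre")
  post - pre
}
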