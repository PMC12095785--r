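#' Fit a logarithmic learning curve
#'
#' Least-squares fit of `accuracy = a + b * ln(t)`; the slope `b` is the
#' learning rate.
#'
#' @param accuracy numeric vector of accuracies (percent)
#' @param t session indices (>= 3 distinct values, t >= 1)
#' @return named vector `c(a = intercept, b = learning rate)`
#' @export
fit_learning_rate <- function(accuracy, t) {
  if (length(unique(t)) < 3) stop("need at least 3 distinct training sessions")
  fit <- stats::lm.fit(cbind(1, log(t)), accuracy)
  stats::setNames(fit$coefficients, c("a", "b"))
}

#' Multiple regression with standardized coefficients
#'
#' OLS on z-scored outcome and predictors. Returns standardized betas,
#' per-coefficient t statistics and p-values, the overall F with degrees of
#' freedom, R-squared and adjusted R-squared.
#'
#' @param outcome numeric vector (one value per subject)
#' @param predictors numeric matrix or data.frame (subjects x predictors)
#' @return object of class `regression_result`
#' @export
regress <- function(outcome, predictors) {
  X <- as.matrix(predictors)
  n <- length(outcome)
  p <- ncol(X)
  if (n <= p + 1) stop("need more subjects than predictors + 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12) || qr(cbind(1, X))$rank < p + 1) {
    stop("singular design; collinear or constant predictor(s): ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "))
  }
  zy <- as.numeric(scale(outcome))
  zX <- scale(X)
  df <- data.frame(y = zy, zX)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  structure(list(
    beta = stats::setNames(co[, 1], colnames(X)),
    t = stats::setNames(co[, 3], colnames(X)),
    p_coef = stats::setNames(co[, 4], colnames(X)),
    F = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]),
    df2 = unname(sm$fstatistic[3]),
    p_model = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                        lower.tail = FALSE),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = n), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4f, R2 = %.3f (adj %.3f), n = %d\n",
              x$df1, x$df2, x$F, x$p_model, x$r_squared, x$adj_r_squared, x$n))
  print(round(cbind(beta = x$beta, t = x$t, p = x$p_coef), 4))
  invisible(x)
}

# fast overall-F for a fixed design across many outcome vectors
model_F <- function(Qm, y, p) {
  n <- length(y)
  proj <- crossprod(Qm, y)
  rss <- max(sum(y^2) - sum(proj^2), 0)   # guard tiny negative round-off
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  (r2 / p) / ((1 - r2) / (n - p - 1))
}

#' Permutation p-value for a multiple regression
#'
#' Permutes the outcome across subjects and compares the observed overall F
#' to its permutation null. Uses the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @inheritParams regress
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed
#' @return scalar p-value
#' @export
permutation_regression_p <- function(outcome, predictors, n_perm = 1000,
                                     seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  X <- as.matrix(predictors)
  p <- ncol(X)
  Qm <- qr.Q(qr(cbind(1, X)))
  f_obs <- model_F(Qm, outcome, p)
  set.seed(derive_seed(seed, 11))
  f_null <- replicate(n_perm, model_F(Qm, sample(outcome), p))
  perm_pvalue(f_null, f_obs)
}

#' Specificity permutation over random baseline/pre pairings
#'
#' Tests whether dispersion-behavior coupling could arise from session
#' differences unrelated to training: in each iteration the baseline and
#' pre-training measurements of every subject are randomly ordered, a
#' pseudo-change predictor set is formed from their difference, and the
#' regression on the outcome is refit. Returns the fraction of iterations
#' with a significant model and its complement (the convention under which a
#' large `p` supports specificity).
#'
#' @param baseline,pre subjects x predictors matrices of the same shape and
#'   subject order
#' @param outcome numeric vector (one value per subject)
#' @param n_iter number of random pairings
#' @param seed integer seed
#' @param alpha significance level for counting a model as significant
#' @return list with `n_significant`, `fraction_significant`, `p`
#' @export
specificity_permutation <- function(baseline, pre, outcome, n_iter = 1000,
                                    seed = 1, alpha = 0.05) {
  baseline <- as.matrix(baseline)
  pre <- as.matrix(pre)
  if (!all(dim(baseline) == dim(pre)))
    stop("baseline and pre tables must cover the same subjects and measures")
  n <- nrow(baseline)
  set.seed(derive_seed(seed, 12))
  n_sig <- 0L
  for (i in seq_len(n_iter)) {
    flip <- stats::runif(n) < 0.5
    pseudo <- pre - baseline
    pseudo[flip, ] <- -pseudo[flip, , drop = FALSE]
    res <- tryCatch(regress(outcome, pseudo), error = function(e) NULL)
    if (!is.null(res) && res$p_model < alpha) n_sig <- n_sig + 1L
  }
  list(n_significant = n_sig, fraction_significant = n_sig / n_iter,
       p = 1 - n_sig / n_iter)
}

#' Leave-one-out cross-validation of a multiple regression
#'
#' Refits the model with each subject left out and predicts the held-out
#' outcome; summarizes with the predicted-vs-observed correlation.
#'
#' @inheritParams regress
#' @return list with `predicted` (length n), `cor_pred_obs`, `n_skipped`
#' @export
loocv <- function(outcome, predictors) {
  X <- as.matrix(predictors)
  n <- length(outcome)
  if (n < ncol(X) + 2) stop("need at least predictors + 2 subjects")
  pred <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(
      stats::lm.fit(cbind(1, X[-i, , drop = FALSE]), outcome[-i]),
      error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      skipped <- skipped + 1L
      warning("singular design in fold ", i, "; fold skipped")
      next
    }
    pred[i] <- sum(c(1, X[i, ]) * fit$coefficients)
  }
  ok <- !is.na(pred)
  list(predicted = pred,
       cor_pred_obs = if (sum(ok) > 2) stats::cor(pred[ok], outcome[ok]) else NA_real_,
       n_skipped = skipped)
}
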