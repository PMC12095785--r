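#' Row-sparsified normalized-angle affinity matrix
#'
#' Each row of the feature matrix keeps only its strongest entries (the top
#' `1 - sparsity` fraction, 10% by default); similarity between thresholded
#' rows is the normalized-angle kernel `1 - acos(cos_sim) / pi`, symmetrized
#' by averaging. This is the de-facto standard precursor for connectome
#' gradient embeddings.
#'
#' @param feature square symmetric feature matrix (MPC or FC)
#' @param sparsity fraction of entries zeroed per row (default 0.9)
#' @return symmetric nonnegative affinity matrix
#' @export
build_affinity <- function(feature, sparsity = 0.9) {
  feature <- as.matrix(feature)
  n <- nrow(feature)
  if (n != ncol(feature)) stop("feature matrix must be square")
  if (max(abs(feature - t(feature))) > 1e-8) stop("feature matrix must be symmetric")
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0, 1)")
  keep <- ceiling((1 - sparsity) * n)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(feature[i, ], decreasing = TRUE)
    top <- ord[seq_len(keep)]
    A[i, top] <- feature[i, top]
  }
  norms <- sqrt(rowSums(A^2))
  if (any(norms < 1e-12)) {
    bad <- which(norms < 1e-12)
    stop("degenerate row(s) with undefined angle: ", paste(bad, collapse = ", "))
  }
  cosim <- tcrossprod(A) / tcrossprod(norms)
  cosim <- pmin(pmax(cosim, -1), 1)
  aff <- 1 - acos(cosim) / pi
  aff <- (aff + t(aff)) / 2
  dimnames(aff) <- dimnames(feature)
  aff
}

# connected components of the nonzero pattern (simple BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Standard diffusion maps: density normalization with exponent `alpha`
#' (0.5 by default), spectral decomposition of the normalized transition
#' operator, trivial constant component dropped, components ordered by
#' eigenvalue. With `t = 0` components are scaled by their eigenvalues;
#' with `t > 0` by `eigenvalue^t`.
#'
#' @param affinity symmetric nonnegative matrix from [build_affinity()]
#' @param k number of components to retain (k < n)
#' @param alpha density-normalization exponent
#' @param t diffusion time
#' @return object of class `gradient_set`: list with `components` (n x k),
#'   `eigenvalues` (length k, nonincreasing), `aligned_to` (NULL)
#' @export
diffusion_embed <- function(affinity, k = 5, alpha = 0.5, t = 0) {
  W <- as.matrix(affinity)
  n <- nrow(W)
  if (k >= n) stop("k must be smaller than the number of nodes")
  if (any(W < -1e-12)) stop("affinity must be nonnegative")
  comp <- graph_components(W)
  if (max(comp) > 1)
    stop("affinity graph is disconnected (", max(comp), " components: sizes ",
         paste(tabulate(comp), collapse = ", "), ")")
  d <- rowSums(W)
  Wa <- W / outer(d^alpha, d^alpha)
  d2 <- rowSums(Wa)
  M <- Wa / sqrt(outer(d2, d2))
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  lambda <- eig$values / eig$values[1]
  psi <- eig$vectors / sqrt(d2)
  # drop trivial constant component, keep the next k
  idx <- 2:(k + 1)
  lam_k <- pmax(pmin(lambda[idx], 1), 0)
  comps <- psi[, idx, drop = FALSE]
  comps <- sweep(comps, 2, sqrt(colSums(comps^2)), "/")
  scale_fac <- if (t == 0) lam_k else lam_k^t
  comps <- sweep(comps, 2, scale_fac, "*")
  dimnames(comps) <- list(rownames(W), paste0("G", seq_len(k)))
  structure(list(components = comps, eigenvalues = lam_k, aligned_to = NULL),
            class = "gradient_set")
}

grad_components <- function(x) {
  if (inherits(x, "gradient_set")) x$components else as.matrix(x)
}

#' Procrustes alignment of one gradient set to a reference
#'
#' Finds the orthogonal transform (rotation plus reflection, no scaling)
#' minimizing the Frobenius distance between source and reference components
#' and applies it to the source.
#'
#' @param source,reference gradient sets (or plain n x k matrices) with equal
#'   dimensions
#' @return the aligned source, same class as the input
#' @export
procrustes_align <- function(source, reference) {
  S <- grad_components(source)
  R <- grad_components(reference)
  if (!all(dim(S) == dim(R))) stop("source and reference dimensions differ")
  sv <- svd(crossprod(S, R))
  Q <- sv$u %*% t(sv$v)
  aligned <- S %*% Q
  dimnames(aligned) <- dimnames(S)
  if (inherits(source, "gradient_set")) {
    source$components <- aligned
    source$aligned_to <- attr(reference, "id") %||% "reference"
    source
  } else aligned
}

dispersion_space <- function(grads) {
  G <- grad_components(grads)
  if (ncol(G) < 3) stop("need at least 3 gradient components for dispersion")
  G[, 1:3, drop = FALSE]
}

#' Within-network dispersion
#'
#' Sum of squared Euclidean distances of a network's nodes to the network
#' centroid in the space of the first three gradients. The sum (not the
#' mean) is used, so the value scales with network size.
#'
#' @param grads a `gradient_set` or n x k matrix (k >= 3)
#' @param members indices (or names) of the network's nodes (>= 2)
#' @return nonnegative scalar
#' @export
within_dispersion <- function(grads, members) {
  G <- dispersion_space(grads)
  sub <- G[members, , drop = FALSE]
  if (nrow(sub) < 2) stop("need at least 2 member nodes")
  centroid <- colMeans(sub)
  sum(sweep(sub, 2, centroid)^2)
}

#' Between-network dispersion
#'
#' Euclidean distance between two network centroids in the space of the
#' first three gradients.
#'
#' @param grads a `gradient_set` or n x k matrix (k >= 3)
#' @param nodes_a,nodes_b nonempty index sets
#' @return nonnegative scalar
#' @export
between_dispersion <- function(grads, nodes_a, nodes_b) {
  G <- dispersion_space(grads)
  a <- G[nodes_a, , drop = FALSE]
  b <- G[nodes_b, , drop = FALSE]
  if (nrow(a) < 1 || nrow(b) < 1) stop("node sets must be nonempty")
  sqrt(sum((colMeans(a) - colMeans(b))^2))
}

#' Dispersion pipeline over subjects and sessions
#'
#' For each subject/session feature matrix: affinity, diffusion embedding,
#' Procrustes alignment to a group reference template (embedded from the
#' grand-average feature matrix of that modality), then VN-within,
#' FPN-within and VN-FPN-between dispersion. Post-minus-pre change rows are
#' appended with session label `"change"`.
#'
#' @param features nested list: `features[[modality]][[session]][[subject]]`
#'   is a nodes x nodes feature matrix
#' @param partition character vector of network labels per node (must contain
#'   `"VN"` and `"FPN"`)
#' @param sparsity,k,alpha,t embedding parameters (see [build_affinity()],
#'   [diffusion_embed()])
#' @param keep_gradients also return per-subject aligned gradients
#' @return data.frame (subject, session, modality, measure, value); when
#'   `keep_gradients` is TRUE, aligned gradient matrices are attached as
#'   attribute `"gradients"` and reference templates as `"reference"`
#' @export
dispersion_pipeline <- function(features, partition, sparsity = 0.9, k = 5,
                                alpha = 0.5, t = 0, keep_gradients = FALSE) {
  partition <- as.character(partition)
  vn <- which(partition == "VN")
  fpn <- which(partition == "FPN")
  if (length(vn) < 2 || length(fpn) < 2)
    stop("partition must contain at least 2 VN and 2 FPN nodes")
  measures <- c("VN-within", "FPN-within", "VN-FPN-between")
  rows <- list()
  grads_out <- list()
  refs <- list()
  for (mod in names(features)) {
    sess <- features[[mod]]
    all_mats <- unlist(sess, recursive = FALSE)
    gavg <- Reduce(`+`, all_mats) / length(all_mats)
    ref <- diffusion_embed(build_affinity(gavg, sparsity), k, alpha, t)
    refs[[mod]] <- ref
    for (ses in names(sess)) {
      for (s in seq_along(sess[[ses]])) {
        subj <- names(sess[[ses]])[s] %||% paste0("sub", s)
        g <- tryCatch(
          diffusion_embed(build_affinity(sess[[ses]][[s]], sparsity), k, alpha, t),
          error = function(e) stop("subject ", subj, " session ", ses,
                                   " modality ", mod, ": ", conditionMessage(e)))
        g <- procrustes_align(g, ref)
        G <- g$components
        vals <- c(within_dispersion(G, vn), within_dispersion(G, fpn),
                  between_dispersion(G, vn, fpn))
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj, session = ses, modality = mod,
          measure = measures, value = vals, stringsAsFactors = FALSE)
        if (keep_gradients) grads_out[[mod]][[ses]][[subj]] <- G
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (all(c("pre", "post") %in% unique(tab$session))) {
    pre <- tab[tab$session == "pre", ]
    post <- tab[tab$session == "post", ]
    key <- function(d) paste(d$subject, d$modality, d$measure)
    post <- post[match(key(pre), key(post)), ]
    chg <- pre
    chg$session <- "change"
    chg$value <- post$value - pre$value
    tab <- rbind(tab, chg)
  }
  rownames(tab) <- NULL
  if (keep_gradients) {
    attr(tab, "gradients") <- grads_out
    attr(tab, "reference") <- refs
  }
  tab
}

#' Normalize a group's values to a control group
#'
#' Subtracts the control-group mean from every value (the intervention-arm
#' normalization used when comparing an active to a sham group).
#'
#' @param values numeric vector (active group)
#' @param control_values numeric vector (control group, nonempty)
#' @return `values - mean(control_values)`
#' @export
normalize_to_control <- function(values, control_values) {
  if (!length(control_values)) stop("control group is empty")
  values - mean(control_values)
}
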