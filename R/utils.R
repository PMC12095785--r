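#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages draw their seed from the run seed through this
#' function so that stages can be re-run independently and deterministically.
#' The result always fits in a 32-bit signed integer.
#'
#' @param seed master integer seed
#' @param offset integer stage offset (one per named stage)
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 69069 + 12345 * offset) %% 2147483587L)
}

#' Column z-scoring with the population-SD convention
#'
#' Centers each column to mean 0 and scales to SD 1, where the SD divides by
#' n (population convention) rather than n - 1. Zero-variance columns are an
#' error by default, or dropped with a warning.
#'
#' @param x numeric matrix
#' @param on_constant `"error"` (default) or `"drop"` for zero-variance columns
#' @return matrix with column means 0 and population SD 1
#' @export
zscore <- function(x, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sd_pop <- sqrt(colMeans(xc^2))
  bad <- sd_pop < 1e-12
  if (any(bad)) {
    if (on_constant == "error") {
      stop("zero-variance column(s): ", paste(which(bad), collapse = ", "))
    }
    warning(sum(bad), " zero-variance column(s) dropped")
    xc <- xc[, !bad, drop = FALSE]
    sd_pop <- sd_pop[!bad]
  }
  sweep(xc, 2, sd_pop, "/")
}

#' Write a labeled numeric matrix as TSV
#'
#' Row names go in a leading `id` column; column names form the header.
#'
#' @param m numeric matrix with dimnames
#' @param path output file path
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' @param path file written by [write_matrix_tsv()]
#' @return numeric matrix with dimnames
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a run manifest as JSON
#'
#' @param manifest named list (config, seeds, stage parameters)
#' @param path output file path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# add-one Monte-Carlo p-value (never exactly 0)
perm_pvalue <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}
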