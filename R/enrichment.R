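#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path
#' @return named list of character gene-id vectors; descriptions in
#'   attribute `"description"`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character gene-id vectors
#' @param path output path
#' @param description per-set descriptions (recycled)
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, ds, genes) paste(c(nm, ds, genes), collapse = "\t"),
                  names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided hypergeometric tail probability `P(overlap >= observed)` per
#' set, with fold enrichment `(overlap / hits) / (set / background)` and
#' multiple-testing correction across sets. An optional EASE-style
#' conservative variant subtracts one from the observed overlap.
#'
#' @param hits character vector of significant gene ids (must lie in the
#'   background)
#' @param collection named list of gene sets (each a subset of the
#'   background)
#' @param background character vector: the gene universe
#' @param correction `"BH"` (default), `"bonferroni"` or `"none"`
#' @param ease use the EASE overlap-minus-one score (default FALSE)
#' @return data.frame: set, overlap, set_size, n_hits, background_size,
#'   fold, p, q
#' @export
enrich <- function(hits, collection, background,
                   correction = c("BH", "bonferroni", "none"), ease = FALSE) {
  correction <- match.arg(correction)
  hits <- unique(hits)
  offenders <- setdiff(hits, background)
  if (length(offenders))
    stop("hit gene(s) outside background: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) " ..." else "")
  N <- length(unique(background))
  nh <- length(hits)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), background)
    if (!length(set)) stop("gene set '", nm, "' is empty within the background")
    K <- length(set)
    k <- length(intersect(hits, set))
    k_eff <- if (ease) max(k - 1, 0) else k
    p <- if (k_eff == 0) 1 else
      stats::phyper(k_eff - 1, K, N - K, nh, lower.tail = FALSE)
    fold <- if (nh == 0) 0 else (k / nh) / (K / N)
    data.frame(set = nm, overlap = k, set_size = K, n_hits = nh,
               background_size = N, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- switch(correction,
                  BH = stats::p.adjust(out$p, "BH"),
                  bonferroni = stats::p.adjust(out$p, "bonferroni"),
                  none = out$p)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector in \[0, 1\]
#' @return step-up adjusted q-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
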