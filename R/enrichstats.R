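# Enrichment of resistance mutations inside the observed portion of SNV
# space: the probability that at least k of n mutations would fall among the
# alignment-observed SNVs if all possible missense SNVs were equally likely.

#' Upper binomial tail probability
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, p)` by exact summation of the
#' probability mass, accumulated in log space so large `n` stays accurate.
#'
#' @param k Number of successes (0 to `n`).
#' @param n Number of trials.
#' @param p Success probability in `[0, 1]`.
#' @return The tail probability in `[0, 1]`.
#' @examples
#' binomial_tail(2, 2, 0.5)  # 0.25
#' binomial_tail(0, 10, 0.3) # 1
#' @export
binomial_tail <- function(k, n, p) {
  if (length(k) != 1L || length(n) != 1L || length(p) != 1L ||
      is.na(k) || is.na(n) || is.na(p)) {
    stop("k, n and p must be single non-missing values", call. = FALSE)
  }
  k <- as.integer(k); n <- as.integer(n)
  if (n < 0L || k < 0L || k > n) {
    stop("require 0 <= k <= n, got k = ", k, ", n = ", n, call. = FALSE)
  }
  if (p < 0 || p > 1) stop("p must lie in [0, 1], got ", p, call. = FALSE)
  if (k == 0L) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  j <- k:n
  terms <- lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
  m <- max(terms)
  min(1, exp(m) * sum(exp(terms - m)))
}

#' Enrichment of classified mutations in observed SNV space
#'
#' Pools one or more SNV spectra into a background probability
#' `p = observed / possible` (the fraction of all possible missense SNVs that
#' occur in the alignments), pools the occurred/total counts of the selected
#' mutation classes into `k` and `n`, and returns the exact upper binomial
#' tail `P(X >= k)`: the probability that at least as many of the `n`
#' mutations would be alignment-observed by chance alone, assuming all
#' possible missense SNVs equally probable. A small tail indicates that the
#' mutations are confined to the evolutionarily observed part of SNV space.
#'
#' @param spectra A single `snv_spectrum` or a list of them (one per gene).
#' @param table A `mutation_class_table` from [classify_mutations()].
#' @param classes Which classes of the table to pool (default all).
#' @param stratified If `TRUE`, also computes per-gene tails using each
#'   gene's own background and reports their product as
#'   `stratified_probability`.
#' @return An `enrichment_result`: list with `n`, `k`, `possible`,
#'   `observed`, `p_background`, `tail_probability` and (optionally)
#'   `stratified_probability`.
#' @export
occurrence_enrichment <- function(spectra, table, classes = NULL,
                                  stratified = FALSE) {
  if (inherits(spectra, "snv_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("no SNV spectra supplied", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "snv_spectrum")))
  if (!nrow(table)) stop("mutation class table is empty", call. = FALSE)
  rows <- if (is.null(classes)) table else table[table$class %in% classes, ,
                                                drop = FALSE]
  if (!nrow(rows)) {
    stop("no rows of the class table match classes: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  spec_genes <- vapply(spectra, function(s) s$gene_id, character(1))
  missing <- setdiff(unique(rows$gene), spec_genes)
  if (length(missing) && !identical(unique(rows$gene), "all")) {
    stop("no SNV spectrum supplied for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  possible <- sum(vapply(spectra, function(s) s$possible, numeric(1)))
  observed <- sum(vapply(spectra, function(s) s$observed, numeric(1)))
  if (possible <= 0) stop("pooled possible-SNV count is 0", call. = FALSE)
  p <- observed / possible
  k <- sum(rows$occurred)
  n <- sum(rows$total)
  out <- list(n = as.integer(n), k = as.integer(k),
              possible = as.integer(possible), observed = as.integer(observed),
              p_background = p, tail_probability = binomial_tail(k, n, p))
  if (stratified) {
    strat <- vapply(unique(rows$gene), function(g) {
      s <- spectra[[match(g, spec_genes)]]
      r <- rows[rows$gene == g, , drop = FALSE]
      binomial_tail(sum(r$occurred), sum(r$total), s$observed / s$possible)
    }, numeric(1))
    out$stratified_probability <- prod(strat)
  }
  structure(out, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Occurrence enrichment: ", x$k, " of ", x$n, " mutations observed in ",
      "the alignment;\n  background p = ", x$observed, "/", x$possible,
      " = ", signif(x$p_background, 4), "; P(X >= k) = ",
      format(x$tail_probability, scientific = TRUE, digits = 3), "\n",
      sep = "")
  if (!is.null(x$stratified_probability)) {
    cat("  stratified per-gene product: ",
        format(x$stratified_probability, scientific = TRUE, digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}
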