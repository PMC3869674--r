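# Ordered conditional co-occurrence of mutation pairs across alignment rows:
# the compound-mutation analysis. The conditional frequency P(second | first)
# is directional, so the resulting matrix is generally asymmetric.

#' Conditional co-occurrence of two mutations across alignment rows
#'
#' Among the rows that carry the first mutation's mutant residue at its
#' mapped column, counts how many also carry the second mutation's mutant
#' residue at its column. Rows with gaps or ambiguity codes at the second
#' column count in the denominator (if they carry the first mutant) but never
#' in the joint count.
#'
#' @param profile An `alignment_profile`.
#' @param first,second `point_mutation`s or tokens; positions must differ.
#' @return A `conditional_cooccurrence`: list with `first`, `second`,
#'   `denominator` (rows carrying the first mutant), `joint`, `conditional`
#'   (`NA` when the denominator is 0) and `n_rows`.
#' @export
conditional_cooccurrence <- function(profile, first, second) {
  stopifnot(inherits(profile, "alignment_profile"))
  if (!inherits(first, "point_mutation")) first <- as_point_mutations(first)[[1L]]
  if (!inherits(second, "point_mutation")) second <- as_point_mutations(second)[[1L]]
  if (first$position == second$position) {
    stop("conditional co-occurrence requires distinct positions; both ",
         "mutations are at ", first$position, call. = FALSE)
  }
  col1 <- validate_mutation_position(profile, first)
  col2 <- validate_mutation_position(profile, second)
  has_first <- profile$mat[, col1] == first$mut
  joint <- sum(has_first & profile$mat[, col2] == second$mut)
  denom <- sum(has_first)
  structure(
    list(first = first, second = second,
         denominator = as.integer(denom), joint = as.integer(joint),
         conditional = if (denom > 0L) joint / denom else NA_real_,
         n_rows = profile$n_rows),
    class = "conditional_cooccurrence"
  )
}

#' @export
print.conditional_cooccurrence <- function(x, ...) {
  cat("P(", format(x$second), " | ", format(x$first), ") = ",
      if (is.na(x$conditional)) "undefined (condition never observed)"
      else paste0(x$joint, "/", x$denominator, " = ",
                  report_percent(x$joint, max(x$denominator, 1L))),
      "\n", sep = "")
  invisible(x)
}

# Colour bin for a conditional frequency, on the percentage scale:
# < 10 white, [10, 19) yellow, [19, 50] orange, > 50 red. The published bins
# "10-19%" and "19-50%" share the value 19; the overlap is resolved in favour
# of the higher bin.
cooccurrence_bin <- function(conditional) {
  vapply(conditional, function(p) {
    if (is.na(p)) return(NA_character_)
    pct <- 100 * p
    if (pct < 10) "white" else if (pct < 19) "yellow"
    else if (pct <= 50) "orange" else "red"
  }, character(1))
}

#' All-ordered-pairs conditional co-occurrence matrix
#'
#' Computes `conditional_cooccurrence()` for every ordered pair of the given
#' mutations. Pairs at identical protein positions (e.g. Y253F vs Y253H)
#' cannot be conditioned on each other; their cells are `NA` and the skipped
#' pairs are summarised in a warning at the end.
#'
#' @param profile An `alignment_profile`.
#' @param mutations At least two mutations (tokens or `point_mutation`s).
#' @return A `compound_matrix`: list with `mutations` (tokens), `marginal`
#'   (per-mutation row counts), `joint`, `denominator`, `conditional` and
#'   `bin` matrices (first mutation on rows, second on columns), `n_rows` and
#'   `skipped` (character vector describing same-position pairs).
#' @export
compound_matrix <- function(profile, mutations) {
  muts <- as_point_mutations(mutations)
  if (length(muts) < 2L) {
    stop("compound analysis needs at least two mutations", call. = FALSE)
  }
  tokens <- names(muts)
  cols <- vapply(muts, function(m) validate_mutation_position(profile, m),
                 integer(1))
  has <- vapply(seq_along(muts),
                function(i) profile$mat[, cols[i]] == muts[[i]]$mut,
                logical(profile$n_rows))
  marginal <- as.integer(colSums(has))
  names(marginal) <- tokens
  k <- length(muts)
  joint <- matrix(NA_integer_, k, k, dimnames = list(tokens, tokens))
  skipped <- character(0)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && muts[[i]]$position == muts[[j]]$position) {
        skipped <- c(skipped, paste0(tokens[i], " vs ", tokens[j],
                                     " (same position ", muts[[i]]$position, ")"))
        next
      }
      joint[i, j] <- sum(has[, i] & has[, j])
    }
  }
  denominator <- matrix(rep(marginal, times = k), k, k,
                        dimnames = list(tokens, tokens))
  conditional <- ifelse(denominator > 0L, joint / denominator, NA_real_)
  bin <- matrix(cooccurrence_bin(conditional), k, k,
                dimnames = list(tokens, tokens))
  if (length(skipped)) {
    warning("skipped ", length(skipped) / 2L,
            " same-position pair(s): ",
            paste(unique(skipped), collapse = "; "), call. = FALSE)
  }
  structure(
    list(mutations = tokens, marginal = marginal, joint = joint,
         denominator = denominator, conditional = conditional, bin = bin,
         n_rows = profile$n_rows, skipped = unique(skipped)),
    class = "compound_matrix"
  )
}

#' @export
print.compound_matrix <- function(x, ...) {
  cat("Compound-mutation conditional matrix over ", length(x$mutations),
      " mutations (", x$n_rows, " alignment rows)\n", sep = "")
  pct <- matrix(ifelse(is.na(x$conditional), "NA",
                       sprintf("%.0f%%", 100 * x$conditional)),
                nrow = nrow(x$conditional), dimnames = dimnames(x$conditional))
  print(pct, quote = FALSE)
  invisible(x)
}

#' Export a compound matrix as a tidy row-major table
#'
#' One row per ordered pair, in row-major order over the input mutation
#' order — the streaming layout used for full all-pairs scans.
#'
#' @param x A `compound_matrix`.
#' @param path Optional path; when given the table is also written as TSV.
#' @return Data frame with columns first, second, joint, denominator,
#'   conditional, percent, bin.
#' @export
compound_matrix_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "compound_matrix"))
  k <- length(x$mutations)
  idx <- expand.grid(j = seq_len(k), i = seq_len(k))[, c("i", "j")]
  out <- data.frame(
    first = x$mutations[idx$i],
    second = x$mutations[idx$j],
    joint = x$joint[cbind(idx$i, idx$j)],
    denominator = x$denominator[cbind(idx$i, idx$j)],
    conditional = x$conditional[cbind(idx$i, idx$j)],
    stringsAsFactors = FALSE
  )
  out$percent <- ifelse(is.na(out$conditional) | out$denominator == 0L, NA,
                        report_percent(ifelse(is.na(out$joint), 0L, out$joint),
                                       pmax(out$denominator, 1L)))
  out$bin <- x$bin[cbind(idx$i, idx$j)]
  if (!is.null(path)) write_tsv(out, path)
  out
}

# Unordered pairs of a compound matrix, excluding same-position pairs.
unordered_pairs <- function(x, candidates = NULL) {
  tokens <- x$mutations
  if (is.null(candidates)) {
    if (length(tokens) < 2L) {
      return(data.frame(first = character(0), second = character(0)))
    }
    cmb <- utils::combn(tokens, 2L)
    candidates <- data.frame(first = cmb[1L, ], second = cmb[2L, ],
                             stringsAsFactors = FALSE)
  }
  if (!is.data.frame(candidates)) {
    candidates <- do.call(rbind, lapply(candidates, function(p) {
      data.frame(first = p[[1L]], second = p[[2L]], stringsAsFactors = FALSE)
    }))
  }
  bad <- !(candidates$first %in% tokens) | !(candidates$second %in% tokens)
  if (any(bad)) {
    stop("candidate pair(s) outside the matrix mutation list: ",
         paste(candidates$first[bad], candidates$second[bad], sep = "/",
               collapse = ", "), call. = FALSE)
  }
  candidates
}

#' Completely novel compound mutations
#'
#' Pairs whose joint count is zero in both orders while each single mutation
#' is itself observed in at least one row: double variations never seen
#' together in any homologue although both components occur separately.
#'
#' @param x A `compound_matrix`.
#' @param candidates Optional candidate pairs (data frame with columns
#'   `first`, `second`, or a list of 2-vectors); defaults to all unordered
#'   pairs in the matrix.
#' @return Data frame of novel pairs (columns first, second).
#' @export
find_novel_compounds <- function(x, candidates = NULL) {
  stopifnot(inherits(x, "compound_matrix"))
  cand <- unordered_pairs(x, candidates)
  if (!nrow(cand)) return(cand)
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand$first[r]; j <- cand$second[r]
    jij <- x$joint[i, j]; jji <- x$joint[j, i]
    !is.na(jij) && !is.na(jji) && jij == 0L && jji == 0L &&
      x$marginal[i] >= 1L && x$marginal[j] >= 1L
  }, logical(1))
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Obligate mutation pairs
#'
#' Pairs that are always observed together: the conditional frequency is 1 in
#' both directions (every row carrying one mutant also carries the other) and
#' the joint count is at least 1. Set `bidirectional = FALSE` to accept pairs
#' where only one direction is obligate.
#'
#' @param x A `compound_matrix`.
#' @param bidirectional Require conditional 1 in both orders (default TRUE).
#' @return Data frame of obligate pairs (columns first, second, joint).
#' @export
find_obligate_pairs <- function(x, bidirectional = TRUE) {
  stopifnot(inherits(x, "compound_matrix"))
  cand <- unordered_pairs(x)
  if (!nrow(cand)) return(cbind(cand, joint = integer(0)))
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand$first[r]; j <- cand$second[r]
    cij <- x$conditional[i, j]; cji <- x$conditional[j, i]
    jnt <- x$joint[i, j]
    if (is.na(jnt) || jnt < 1L) return(FALSE)
    if (bidirectional) {
      !is.na(cij) && !is.na(cji) && cij == 1 && cji == 1
    } else {
      (!is.na(cij) && cij == 1) || (!is.na(cji) && cji == 1)
    }
  }, logical(1))
  out <- cand[keep, , drop = FALSE]
  out$joint <- x$joint[cbind(out$first, out$second)]
  rownames(out) <- NULL
  out
}
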