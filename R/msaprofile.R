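# Alignment profiles: mapping full-protein mutation coordinates onto MSA
# columns and deciding, per mutation, whether the variant residue occurs
# among homologues ("occurred") or is novel.

GAP_CHARS <- "-"
AMBIGUITY_CHARS <- c("X", "B", "Z", "J", "U", "O")

#' Build an alignment profile around a reference row
#'
#' Maps every non-gap residue of the reference row to its alignment column
#' (full-protein numbering via `reference_offset`) and tabulates per-column
#' residue counts over all rows, reference included. Gap and ambiguity
#' symbols are tabulated too, so every column's counts sum to the number of
#' rows.
#'
#' @param rows Named character vector of equal-length aligned sequences, or a
#'   path to an aligned FASTA file.
#' @param reference_id Id of the reference row.
#' @param reference_offset 1-based full-protein position of the reference
#'   row's first (non-gap) residue.
#' @param column_confidence Optional numeric vector in `[0, 1]`, one value per
#'   alignment column (GUIDANCE-style confidence).
#' @return An object of class `alignment_profile` with fields `mat` (residue
#'   matrix, rows x columns), `ids`, `reference_id`, `reference_offset`,
#'   `column_map` (named integer vector: protein position -> column),
#'   `column_counts` (list of per-column residue count tables), `n_rows` and
#'   `column_confidence`.
#' @export
build_profile <- function(rows, reference_id, reference_offset = 1L,
                          column_confidence = NULL) {
  if (is.character(rows) && length(rows) == 1L && is.null(names(rows)) &&
      file.exists(rows)) {
    rows <- read_alignment(rows)
  }
  if (!length(rows)) stop("alignment has no rows", call. = FALSE)
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named by sequence id", call. = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ",
         paste(sort(unique(widths)), collapse = ", "), call. = FALSE)
  }
  ref_idx <- match(reference_id, names(rows))
  if (is.na(ref_idx)) {
    stop("reference id '", reference_id, "' not found among the ",
         length(rows), " alignment rows", call. = FALSE)
  }
  rows <- toupper(chartr(".", "-", rows))
  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                nrow = length(rows), byrow = TRUE,
                dimnames = list(names(rows), NULL))
  ref_chars <- mat[ref_idx, ]
  ref_cols <- which(ref_chars != GAP_CHARS)
  if (!length(ref_cols)) {
    stop("reference row '", reference_id, "' contains no residues",
         call. = FALSE)
  }
  column_map <- ref_cols
  names(column_map) <- as.character(
    seq(from = as.integer(reference_offset), length.out = length(ref_cols)))
  column_counts <- lapply(seq_len(ncol(mat)), function(j) table(mat[, j]))
  if (!is.null(column_confidence)) {
    if (length(column_confidence) != ncol(mat)) {
      stop("column_confidence must have one value per alignment column (",
           ncol(mat), "), got ", length(column_confidence), call. = FALSE)
    }
    if (any(column_confidence < 0 | column_confidence > 1, na.rm = TRUE)) {
      stop("column_confidence values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(mat = mat, ids = names(rows), reference_id = reference_id,
         reference_offset = as.integer(reference_offset),
         column_map = column_map, column_counts = column_counts,
         n_rows = length(rows), column_confidence = column_confidence),
    class = "alignment_profile"
  )
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat("Alignment profile: ", x$n_rows, " rows x ", ncol(x$mat), " columns; ",
      "reference '", x$reference_id, "' spans protein positions ",
      names(x$column_map)[1L], "-", names(x$column_map)[length(x$column_map)],
      "\n", sep = "")
  invisible(x)
}

# Map a protein position to its column, or fail with a coordinate error.
profile_column <- function(profile, position) {
  col <- profile$column_map[as.character(position)]
  if (is.na(col)) {
    rng <- range(as.integer(names(profile$column_map)))
    stop("protein position ", position, " is not mapped in the profile ",
         "(reference covers ", rng[1L], "-", rng[2L], ")", call. = FALSE)
  }
  unname(col)
}

# Check that the reference residue at a mutation's column matches its stated
# wild type; returns the column index.
validate_mutation_position <- function(profile, mutation) {
  col <- profile_column(profile, mutation$position)
  ref_res <- profile$mat[match(profile$reference_id, profile$ids), col]
  if (ref_res != mutation$wt) {
    stop("reference mismatch for ", format(mutation), ": expected wild-type '",
         mutation$wt, "' but reference '", profile$reference_id,
         "' has '", ref_res, "' at position ", mutation$position,
         call. = FALSE)
  }
  col
}

#' Report a count as the printed percentage convention
#'
#' Percentages at or above 1% are truncated toward zero to a whole percent
#' (87/276 prints as "31%", not "32%"); percentages below 1% are truncated to
#' one decimal place.
#'
#' @param count,total Non-negative counts with `total >= 1`.
#' @return Character, e.g. `"31%"` or `"0.3%"`.
#' @examples
#' report_percent(146, 276)  # "52%"
#' report_percent(1, 276)    # "0.3%"
#' @export
report_percent <- function(count, total) {
  if (any(total < 1)) stop("total must be >= 1", call. = FALSE)
  if (any(count < 0 | count > total)) {
    stop("count must lie in [0, total]", call. = FALSE)
  }
  pct <- 100 * count / total
  out <- ifelse(pct >= 1,
                sprintf("%d%%", as.integer(floor(pct + 1e-9))),
                sprintf("%.1f%%", floor(pct * 10 + 1e-9) / 10))
  out
}

#' Occurrence of a point mutation among aligned homologues
#'
#' Counts the rows carrying the mutant residue at the alignment column mapped
#' from the mutation's full-protein position. The denominator is always the
#' total number of rows (reference included); rows with gaps or ambiguity
#' codes stay in the denominator and never match the mutant.
#'
#' @param profile An `alignment_profile`.
#' @param mutation A `point_mutation` or token such as `"T790M"`.
#' @return An `occurrence_record`: list with `mutation`, `observed`, `count`,
#'   `n_rows`, `frequency` and `reported_percent`.
#' @export
mutation_occurrence <- function(profile, mutation) {
  stopifnot(inherits(profile, "alignment_profile"))
  if (!inherits(mutation, "point_mutation")) {
    mutation <- as_point_mutations(mutation)[[1L]]
  }
  col <- validate_mutation_position(profile, mutation)
  count <- sum(profile$mat[, col] == mutation$mut)
  structure(
    list(mutation = mutation, observed = count >= 1L,
         count = as.integer(count), n_rows = profile$n_rows,
         frequency = count / profile$n_rows,
         reported_percent = report_percent(count, profile$n_rows)),
    class = "occurrence_record"
  )
}

#' @export
print.occurrence_record <- function(x, ...) {
  cat(format(x$mutation), ": ",
      if (x$observed) "occurred" else "novel", " (", x$count, "/", x$n_rows,
      " rows, ", x$reported_percent, ")\n", sep = "")
  invisible(x)
}

#' Tabulate occurrence records for a mutation list
#'
#' @param profile An `alignment_profile`.
#' @param mutations Tokens or `point_mutation`s.
#' @return Data frame with columns mutation, observed, count, n_rows,
#'   frequency, reported_percent — the TSV export layout.
#' @export
occurrence_table <- function(profile, mutations) {
  muts <- as_point_mutations(mutations)
  recs <- lapply(muts, function(m) mutation_occurrence(profile, m))
  data.frame(
    mutation = vapply(recs, function(r) format(r$mutation), character(1)),
    observed = vapply(recs, function(r) r$observed, logical(1)),
    count = vapply(recs, function(r) r$count, integer(1)),
    n_rows = vapply(recs, function(r) r$n_rows, integer(1)),
    frequency = vapply(recs, function(r) r$frequency, numeric(1)),
    reported_percent = vapply(recs, function(r) r$reported_percent,
                              character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Possible versus observed missense-SNV spectrum of a domain
#'
#' For every domain position, takes the amino acids reachable from the
#' reference codon by a single nucleotide substitution and intersects them
#' with the residues present in at least one alignment row at the mapped
#' column. Totals give the "possible" and "observed" SNV counts.
#'
#' @param profile An `alignment_profile` covering the domain.
#' @param domain A `coding_domain`; its translation must match the reference
#'   residues at the mapped columns.
#' @param min_confidence Optional confidence threshold: columns whose
#'   confidence is below it are excluded from the spectrum entirely. Default
#'   `NULL` (no masking).
#' @return An `snv_spectrum`: list with `gene_id`, `possible`, `observed` and
#'   `detail` (data frame: position, codon, wt, reachable, observed_subset,
#'   n_reachable, n_observed).
#' @export
observed_spectrum <- function(profile, domain, min_confidence = NULL) {
  stopifnot(inherits(profile, "alignment_profile"),
            inherits(domain, "coding_domain"))
  positions <- seq(domain$protein_start, domain$protein_end)
  unmapped <- positions[!as.character(positions) %in% names(profile$column_map)]
  if (length(unmapped)) {
    stop("domain positions not mapped in the profile: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, length(positions))
  if (!is.null(min_confidence) && !is.null(profile$column_confidence)) {
    cols <- profile$column_map[as.character(positions)]
    keep <- profile$column_confidence[cols] >= min_confidence
  }
  detail <- lapply(seq_along(positions), function(k) {
    if (!keep[k]) return(NULL)
    pos <- positions[k]
    codon <- domain$codons[k]
    nb <- missense_neighbors(codon)
    col <- profile_column(profile, pos)
    present <- names(profile$column_counts[[col]])
    obs <- intersect(nb$reachable, present)
    data.frame(position = pos, codon = codon, wt = nb$wt_aa,
               reachable = paste(nb$reachable, collapse = ","),
               observed_subset = paste(obs, collapse = ","),
               n_reachable = length(nb$reachable),
               n_observed = length(obs),
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, detail)
  if (is.null(detail)) {
    detail <- data.frame(position = integer(0), codon = character(0),
                         wt = character(0), reachable = character(0),
                         observed_subset = character(0),
                         n_reachable = integer(0), n_observed = integer(0))
  }
  structure(
    list(gene_id = domain$gene_id,
         possible = sum(detail$n_reachable),
         observed = sum(detail$n_observed),
         detail = detail),
    class = "snv_spectrum"
  )
}

#' @export
print.snv_spectrum <- function(x, ...) {
  cat("SNV spectrum for '", x$gene_id, "': ", x$observed, " of ", x$possible,
      " possible missense SNVs observed in the alignment (",
      report_percent(x$observed, max(x$possible, 1L)), ")\n", sep = "")
  invisible(x)
}

#' Classify mutations as occurred or novel, grouped by gene and class
#'
#' @param profile An `alignment_profile` (or a named list of profiles, one per
#'   gene, when mutations from several genes are classified together).
#' @param mutations Tokens or `point_mutation`s.
#' @param labels Data frame with columns `mutation`, `gene`, `class` labelling
#'   each token (e.g. class "resistant" or "activating"). If omitted, all
#'   mutations form one group.
#' @return A `mutation_class_table`: data frame with columns gene, class,
#'   occurred, novel, total; per-mutation records in attribute `"records"`.
#' @export
classify_mutations <- function(profile, mutations, labels = NULL) {
  muts <- as_point_mutations(mutations)
  tokens <- names(muts)
  if (is.null(labels)) {
    labels <- data.frame(mutation = as.character(tokens),
                         gene = rep("all", length(muts)),
                         class = rep("all", length(muts)),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("mutation", "gene", "class") %in% names(labels))) {
    stop("labels must have columns mutation, gene, class", call. = FALSE)
  }
  if (!length(muts)) {
    out <- data.frame(gene = character(0), class = character(0),
                      occurred = integer(0), novel = integer(0),
                      total = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("mutation_class_table", "data.frame")
    return(out)
  }
  missing_lab <- setdiff(tokens, labels$mutation)
  if (length(missing_lab)) {
    stop("no (gene, class) label for mutation(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  get_profile <- function(gene) {
    if (inherits(profile, "alignment_profile")) return(profile)
    pr <- profile[[gene]]
    if (is.null(pr)) stop("no profile supplied for gene '", gene, "'",
                          call. = FALSE)
    pr
  }
  observed <- vapply(seq_along(muts), function(i) {
    gene <- labels$gene[match(tokens[i], labels$mutation)]
    rec <- tryCatch(mutation_occurrence(get_profile(gene), muts[[i]]),
                    error = function(e) {
                      stop("mutation ", tokens[i], ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    rec$observed
  }, logical(1))
  idx <- match(tokens, labels$mutation)
  groups <- data.frame(gene = labels$gene[idx], class = labels$class[idx],
                       observed = observed, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(groups, list(groups$gene, groups$class),
                                     drop = TRUE), function(g) {
    data.frame(gene = g$gene[1L], class = g$class[1L],
               occurred = sum(g$observed), novel = sum(!g$observed),
               total = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$gene, agg$class), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "records") <- data.frame(mutation = tokens, gene = groups$gene,
                                     class = groups$class, observed = observed,
                                     stringsAsFactors = FALSE)
  class(agg) <- c("mutation_class_table", "data.frame")
  agg
}
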