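# Synthetic alignments and coding sequences with known ground truth. The
# generator emulates the statistical structure the analysis assumes: rows are
# exchangeable and columns independent, except for explicitly planted
# single-site variant supports and pairwise couplings. Ground truth records
# the exact realised counts, so tests never re-derive it from the generator's
# internals.

#' Specification of a synthetic homolog family
#'
#' @param reference Reference protein string (canonical residues); the
#'   reference row is emitted unmutated and gapless.
#' @param n_sequences Total number of alignment rows, reference included.
#' @param reference_id Id of the reference row.
#' @param offset 1-based full-protein position of the reference's first
#'   residue.
#' @param epsilon Background substitution rate: each non-reference cell
#'   carries the reference residue with probability `1 - epsilon`, otherwise
#'   a draw from the alternative set.
#' @param alt_set Alternative residues for background substitution; default
#'   all residues other than the column's reference residue. Planted residues
#'   are excluded from the background draw at their columns so that planted
#'   counts stay exact.
#' @param supports Planted single-site variants: data frame with columns
#'   `position`, `residue`, `freq` (target frequency among non-reference
#'   rows). Several residues may be planted at one position if their
#'   frequencies sum to at most 1.
#' @param couplings Planted pairwise couplings: data frame with columns
#'   `first_pos`, `first_res`, `second_pos`, `second_res`, `fraction`. The
#'   fraction is the share of non-reference rows assigned the coupled
#'   haplotype (both residues together); it must not exceed either residue's
#'   support frequency, and both residues must have entries in `supports`.
#' @param gap_rate Per-cell gap injection rate for non-planted cells
#'   (default 0).
#' @param seed Random seed; the same spec yields byte-identical output.
#' @return A `synthetic_msa_spec`.
#' @export
synthetic_msa_spec <- function(reference, n_sequences, reference_id = "REF",
                               offset = 1L, epsilon = 0, alt_set = NULL,
                               supports = NULL, couplings = NULL,
                               gap_rate = 0, seed = 1L) {
  reference <- toupper(reference)
  res <- strsplit(reference, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, AA20)
  if (length(bad)) {
    stop("reference contains non-canonical residue '", bad[1L], "'",
         call. = FALSE)
  }
  if (n_sequences < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (epsilon < 0 || epsilon > 1 || gap_rate < 0 || gap_rate > 1) {
    stop("epsilon and gap_rate must lie in [0, 1]", call. = FALSE)
  }
  offset <- as.integer(offset)
  last <- offset + length(res) - 1L
  in_range <- function(p) all(p >= offset & p <= last)
  ref_at <- function(p) res[p - offset + 1L]
  if (!is.null(supports)) {
    stopifnot(all(c("position", "residue", "freq") %in% names(supports)))
    supports$position <- as.integer(supports$position)
    supports$residue <- check_residue(supports$residue)
    if (!in_range(supports$position)) {
      stop("support position outside the reference range ", offset, "-", last,
           call. = FALSE)
    }
    if (any(supports$freq < 0 | supports$freq > 1)) {
      stop("support frequencies must lie in [0, 1]", call. = FALSE)
    }
    if (any(supports$residue == ref_at(supports$position))) {
      stop("a planted residue equals the reference residue at its position",
           call. = FALSE)
    }
    if (anyDuplicated(supports[c("position", "residue")])) {
      stop("duplicate (position, residue) support entries", call. = FALSE)
    }
    persum <- tapply(supports$freq, supports$position, sum)
    if (any(persum > 1 + 1e-12)) {
      stop("support frequencies at position ",
           names(persum)[which(persum > 1)[1L]], " sum to more than 1",
           call. = FALSE)
    }
  }
  if (!is.null(couplings)) {
    stopifnot(all(c("first_pos", "first_res", "second_pos", "second_res",
                    "fraction") %in% names(couplings)))
    couplings$first_pos <- as.integer(couplings$first_pos)
    couplings$second_pos <- as.integer(couplings$second_pos)
    couplings$first_res <- check_residue(couplings$first_res)
    couplings$second_res <- check_residue(couplings$second_res)
    if (is.null(supports)) {
      stop("couplings require matching support entries", call. = FALSE)
    }
    for (r in seq_len(nrow(couplings))) {
      cp <- couplings[r, ]
      if (cp$first_pos == cp$second_pos) {
        stop("coupling positions must differ", call. = FALSE)
      }
      fkey <- supports$position == cp$first_pos &
        supports$residue == cp$first_res
      skey <- supports$position == cp$second_pos &
        supports$residue == cp$second_res
      if (!any(fkey) || !any(skey)) {
        stop("coupling (", cp$first_res, cp$first_pos, ", ", cp$second_res,
             cp$second_pos, ") has no matching support entries", call. = FALSE)
      }
      if (cp$fraction > min(supports$freq[fkey], supports$freq[skey]) + 1e-12) {
        stop("infeasible coupling: fraction ", cp$fraction,
             " exceeds a marginal support frequency", call. = FALSE)
      }
      if (cp$fraction < 0) stop("coupling fraction must be >= 0", call. = FALSE)
    }
    pos_used <- c(couplings$first_pos, couplings$second_pos)
    if (anyDuplicated(pos_used)) {
      stop("each position may take part in at most one coupling",
           call. = FALSE)
    }
  }
  structure(
    list(reference = reference, residues = res, n_sequences = as.integer(n_sequences),
         reference_id = reference_id, offset = offset, epsilon = epsilon,
         alt_set = if (is.null(alt_set)) NULL else check_residue(alt_set),
         supports = supports, couplings = couplings, gap_rate = gap_rate,
         seed = as.integer(seed)),
    class = "synthetic_msa_spec"
  )
}

#' Simulate a homolog family with planted ground truth
#'
#' Draws `n_sequences - 1` non-reference rows column-independently around the
#' reference, then injects the planted single-site supports and coupled
#' haplotypes and records the exact realised counts.
#'
#' @param spec A `synthetic_msa_spec`.
#' @return A list with `rows` (named character vector, reference row first)
#'   and `truth` (data frame: type, position, residue, position2, residue2,
#'   target, count, n_rows). Counts are realised counts over all rows; the
#'   reference row never carries a planted residue, so they equal the counts
#'   [mutation_occurrence()] reports.
#' @export
simulate_msa <- function(spec) {
  stopifnot(inherits(spec, "synthetic_msa_spec"))
  set.seed(spec$seed)
  res <- spec$residues
  L <- length(res)
  n_eff <- spec$n_sequences - 1L
  mat <- matrix(rep(res, each = n_eff), nrow = n_eff)
  planted <- matrix(FALSE, n_eff, L)

  col_of <- function(pos) pos - spec$offset + 1L
  planted_residues <- list()  # per column: residues background must avoid
  add_avoid <- function(pos, r) {
    j <- as.character(col_of(pos))
    planted_residues[[j]] <<- c(planted_residues[[j]], r)
  }
  if (!is.null(spec$supports)) {
    for (r in seq_len(nrow(spec$supports))) {
      add_avoid(spec$supports$position[r], spec$supports$residue[r])
    }
  }

  # background substitutions
  if (spec$epsilon > 0) {
    for (j in seq_len(L)) {
      hit <- which(stats::runif(n_eff) < spec$epsilon)
      if (!length(hit)) next
      alt <- if (is.null(spec$alt_set)) setdiff(AA20, res[j]) else
        setdiff(spec$alt_set, res[j])
      alt <- setdiff(alt, planted_residues[[as.character(j)]])
      if (!length(alt)) next
      mat[hit, j] <- sample(alt, length(hit), replace = TRUE)
    }
  }

  truth <- list()
  supports <- spec$supports
  support_count <- function(pos, residue) {
    # realised count at this point of the assignment
    sum(mat[, col_of(pos)] == residue & planted[, col_of(pos)])
  }

  # coupled haplotypes first; their supports are consumed here
  if (!is.null(spec$couplings)) {
    for (r in seq_len(nrow(spec$couplings))) {
      cp <- spec$couplings[r, ]
      fkey <- supports$position == cp$first_pos &
        supports$residue == cp$first_res
      skey <- supports$position == cp$second_pos &
        supports$residue == cp$second_res
      f_a <- supports$freq[fkey]; f_b <- supports$freq[skey]
      cls <- sample(c("both", "a", "b", "none"), n_eff, replace = TRUE,
                    prob = c(cp$fraction, f_a - cp$fraction,
                             f_b - cp$fraction,
                             1 - f_a - f_b + cp$fraction))
      ja <- col_of(cp$first_pos); jb <- col_of(cp$second_pos)
      sel_a <- cls %in% c("both", "a"); sel_b <- cls %in% c("both", "b")
      mat[sel_a, ja] <- cp$first_res;  planted[sel_a, ja] <- TRUE
      mat[sel_b, jb] <- cp$second_res; planted[sel_b, jb] <- TRUE
      truth[[length(truth) + 1L]] <- data.frame(
        type = "coupling", position = cp$first_pos, residue = cp$first_res,
        position2 = cp$second_pos, residue2 = cp$second_res,
        target = cp$fraction, count = sum(cls == "both"),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "support", position = cp$first_pos, residue = cp$first_res,
        position2 = NA_integer_, residue2 = NA_character_,
        target = f_a, count = sum(sel_a), stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "support", position = cp$second_pos, residue = cp$second_res,
        position2 = NA_integer_, residue2 = NA_character_,
        target = f_b, count = sum(sel_b), stringsAsFactors = FALSE)
      supports <- supports[!(fkey | skey), , drop = FALSE]
    }
  }

  # remaining independent supports, grouped by position
  if (!is.null(supports) && nrow(supports)) {
    for (pos in unique(supports$position)) {
      sub <- supports[supports$position == pos, , drop = FALSE]
      cls <- sample(c(sub$residue, "."), n_eff, replace = TRUE,
                    prob = c(sub$freq, 1 - sum(sub$freq)))
      j <- col_of(pos)
      sel <- cls != "."
      mat[sel, j] <- cls[sel]
      planted[sel, j] <- TRUE
      for (r in seq_len(nrow(sub))) {
        truth[[length(truth) + 1L]] <- data.frame(
          type = "support", position = pos, residue = sub$residue[r],
          position2 = NA_integer_, residue2 = NA_character_,
          target = sub$freq[r], count = sum(cls == sub$residue[r]),
          stringsAsFactors = FALSE)
      }
    }
  }

  # gap injection on non-planted cells only
  if (spec$gap_rate > 0) {
    gap <- matrix(stats::runif(n_eff * L) < spec$gap_rate, n_eff, L) & !planted
    mat[gap] <- "-"
  }

  rows <- c(spec$reference,
            apply(mat, 1L, paste, collapse = ""))
  names(rows) <- c(spec$reference_id,
                   sprintf("seq%04d", seq_len(n_eff)))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), position = integer(0),
               residue = character(0), position2 = integer(0),
               residue2 = character(0), target = numeric(0),
               count = integer(0), stringsAsFactors = FALSE)
  truth$n_rows <- rep(spec$n_sequences, nrow(truth))
  list(rows = rows, truth = truth)
}

#' Simulate a family and write it to disk
#'
#' Writes `<prefix>.fasta` (aligned FASTA) and `<prefix>.truth.tsv`
#' (the ground-truth table). Output is byte-identical for identical specs.
#'
#' @param spec A `synthetic_msa_spec`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
simulate_msa_files <- function(spec, prefix) {
  sim <- simulate_msa(spec)
  fasta <- paste0(prefix, ".fasta")
  con <- file(fasta, open = "wb")
  writeLines(paste0(">", names(sim$rows), "\n", unname(sim$rows)), con,
             sep = "\n")
  close(con)
  truth <- paste0(prefix, ".truth.tsv")
  write_tsv(sim$truth, truth)
  invisible(c(fasta = fasta, truth = truth))
}

# codons per amino acid under the standard code (stop excluded)
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[AA20]
})

#' Simulate a coding sequence for a protein
#'
#' Picks one codon per residue, uniformly over its synonymous codons under
#' the standard genetic code, so the translation round-trips exactly.
#'
#' @param protein Protein string over the 20 canonical residues.
#' @param gene_id Identifier for the resulting domain.
#' @param protein_start 1-based full-protein position of the first residue.
#' @param seed Optional random seed.
#' @return A `coding_domain`.
#' @examples
#' simulate_cds("MW")$codons  # "ATG" "TGG" (single-codon residues)
#' @export
simulate_cds <- function(protein, gene_id = "synthetic_cds",
                         protein_start = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, AA20)
  if (length(bad)) {
    stop("invalid residue '", bad[1L], "' in protein string", call. = FALSE)
  }
  codons <- vapply(res, function(a) {
    opts <- .codons_by_aa[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  coding_domain(codons, gene_id = gene_id, protein_start = protein_start)
}
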