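# Genetic-code algebra: which amino acids are reachable from a codon by a
# single nucleotide substitution, and how large the missense-SNV space of a
# whole coding domain is.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_MARKER <- "*"

#' Canonicalise a codon string
#'
#' Uppercases, maps RNA `U` to `T` and validates that the result is exactly
#' three bases over `{A,C,G,T}`.
#'
#' @param codon A length-3 nucleotide string (DNA or RNA, any case).
#' @return The canonical uppercase DNA codon.
#' @keywords internal
normalize_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    stop("codon must be a single character string", call. = FALSE)
  }
  codon <- chartr("u", "T", chartr("U", "T", toupper(codon)))
  if (nchar(codon) != 3L) {
    stop("codon must have exactly 3 bases, got '", codon, "'", call. = FALSE)
  }
  bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
  bad <- setdiff(bases, c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("invalid base '", bad[1L], "' in codon '", codon,
         "' (alphabet is A, C, G, T; U is accepted for T)", call. = FALSE)
  }
  codon
}

#' Translate a codon under the standard genetic code
#'
#' @param codon A codon string; lowercase and RNA `U` are accepted.
#' @return A single amino-acid letter, or `"*"` for a stop codon.
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(codon) {
  codon <- normalize_codon(codon)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Amino acids reachable from a codon by one nucleotide substitution
#'
#' Enumerates the nine single-base substitutions of a sense codon and collects
#' the distinct amino acids they encode, excluding synonymous outcomes and
#' substitutions that create a stop codon. Distinctness is at the protein
#' level: several nucleotide events encoding the same residue count once.
#'
#' @param codon A sense codon (must not translate to stop).
#' @return An object of class `missense_neighborhood` with fields `source`
#'   (canonical codon), `wt_aa` (its translation) and `reachable` (sorted
#'   character vector of reachable amino acids, length at most 9).
#' @examples
#' missense_neighbors("AGC")$reachable  # Ser: 6 residues
#' @export
missense_neighbors <- function(codon) {
  codon <- normalize_codon(codon)
  wt <- translate_codon(codon)
  if (wt == STOP_MARKER) {
    stop("codon '", codon, "' is a stop codon; missense neighbourhoods are ",
         "defined for sense codons only", call. = FALSE)
  }
  bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
  reachable <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[pos])) {
      mutated <- bases
      mutated[pos] <- alt
      aa <- unname(Biostrings::GENETIC_CODE[[paste(mutated, collapse = "")]])
      if (aa != STOP_MARKER && aa != wt) reachable <- c(reachable, aa)
    }
  }
  structure(
    list(source = codon, wt_aa = wt, reachable = sort(unique(reachable))),
    class = "missense_neighborhood"
  )
}

#' @export
print.missense_neighborhood <- function(x, ...) {
  cat("Missense neighbourhood of ", x$source, " (", x$wt_aa, "): {",
      paste(x$reachable, collapse = ", "), "} [", length(x$reachable),
      " residues]\n", sep = "")
  invisible(x)
}

#' Is a mutant residue reachable from a codon by a single nucleotide change?
#'
#' @param codon The wild-type codon.
#' @param mutant A canonical amino-acid letter different from the codon's
#'   translation.
#' @return `TRUE` if the mutant is among the codon's missense neighbours.
#' @examples
#' snv_accessible("ACG", "M")  # TRUE:  Thr790 -> Met is a single SNV
#' snv_accessible("ACA", "M")  # FALSE: this Thr codon cannot reach Met
#' @export
snv_accessible <- function(codon, mutant) {
  nb <- missense_neighbors(codon)
  mutant <- toupper(mutant)
  if (!mutant %in% AA20) {
    stop("mutant must be one of the 20 canonical amino-acid letters, got '",
         mutant, "'", call. = FALSE)
  }
  if (mutant == nb$wt_aa) {
    stop("mutant residue equals the wild-type translation (", nb$wt_aa,
         "): not a mutation", call. = FALSE)
  }
  mutant %in% nb$reachable
}

#' Construct a coding domain
#'
#' A coding domain is an ordered list of codons together with the 1-based
#' full-protein coordinates it spans, so that codon `k` encodes protein
#' position `protein_start + k - 1`.
#'
#' @param codons Character vector of codons (or a single in-frame nucleotide
#'   string whose length is a multiple of 3).
#' @param gene_id Identifier for the domain.
#' @param protein_start 1-based full-protein position of the first codon.
#' @return An object of class `coding_domain` with fields `gene_id`, `codons`,
#'   `protein_start`, `protein_end` and `aa` (the translated residues).
#' @export
coding_domain <- function(codons, gene_id = "domain", protein_start = 1L) {
  if (length(codons) == 1L && nchar(codons) > 3L) {
    if (nchar(codons) %% 3L != 0L) {
      stop("coding sequence length (", nchar(codons),
           ") is not a multiple of 3", call. = FALSE)
    }
    starts <- seq(1L, nchar(codons), by = 3L)
    codons <- substring(codons, starts, starts + 2L)
  }
  if (!length(codons)) {
    return(structure(list(gene_id = gene_id, codons = character(0),
                          protein_start = as.integer(protein_start),
                          protein_end = as.integer(protein_start) - 1L,
                          aa = character(0)),
                     class = "coding_domain"))
  }
  codons <- vapply(codons, normalize_codon, character(1), USE.NAMES = FALSE)
  aa <- vapply(codons, translate_codon, character(1), USE.NAMES = FALSE)
  internal_stop <- which(aa == STOP_MARKER)
  if (length(internal_stop)) {
    stop("coding domain '", gene_id, "' contains a stop codon at domain ",
         "position ", internal_stop[1L], call. = FALSE)
  }
  protein_start <- as.integer(protein_start)
  structure(
    list(gene_id = gene_id, codons = codons, protein_start = protein_start,
         protein_end = protein_start + length(codons) - 1L, aa = aa),
    class = "coding_domain"
  )
}

#' @export
print.coding_domain <- function(x, ...) {
  cat("Coding domain '", x$gene_id, "': ", length(x$codons), " codons, ",
      "protein positions ", x$protein_start, "-", x$protein_end, "\n", sep = "")
  invisible(x)
}

#' Look up the codon for a full-protein position
#'
#' @param domain A `coding_domain`.
#' @param position 1-based full-protein position.
#' @return The codon string.
#' @export
domain_codon <- function(domain, position) {
  stopifnot(inherits(domain, "coding_domain"))
  idx <- as.integer(position) - domain$protein_start + 1L
  if (any(idx < 1L | idx > length(domain$codons))) {
    stop("position ", position[which(idx < 1L | idx > length(domain$codons))[1L]],
         " is outside domain '", domain$gene_id, "' (",
         domain$protein_start, "-", domain$protein_end, ")", call. = FALSE)
  }
  domain$codons[idx]
}

#' Total number of possible missense SNVs in a coding domain
#'
#' Sums the missense neighbourhood sizes over every codon in the domain: the
#' number of distinct (position, replacement residue) pairs reachable by a
#' single nucleotide substitution, excluding nonsense changes.
#'
#' @param domain A `coding_domain`.
#' @return Integer count; 0 (with a warning) for an empty domain.
#' @export
count_possible_missense <- function(domain) {
  stopifnot(inherits(domain, "coding_domain"))
  if (!length(domain$codons)) {
    warning("empty coding domain '", domain$gene_id,
            "': possible missense-SNV count is 0", call. = FALSE)
    return(0L)
  }
  sum(vapply(domain$codons,
             function(cd) length(missense_neighbors(cd)$reachable),
             integer(1)))
}
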