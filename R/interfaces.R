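# Mutation-token grammar, FASTA ingestion and TSV output.

#' Parse a mutation token
#'
#' Tokens follow the usual protein-notation grammar `<wt><position><mut>`,
#' e.g. `"T315I"`. Compound (double) mutations are two tokens joined by `"/"`,
#' e.g. `"E255K/T315I"`; their order is preserved because conditional
#' co-occurrence is directional.
#'
#' @param token A single non-empty token.
#' @return A `point_mutation` (fields `wt`, `position`, `mut`) or a
#'   `compound_mutation` (ordered list of two `point_mutation`s).
#' @examples
#' parse_mutation("T315I")
#' parse_mutation("E255K/T315I")
#' @export
parse_mutation <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token) ||
      !nzchar(token)) {
    stop("mutation token must be a single non-empty string", call. = FALSE)
  }
  parts <- strsplit(token, "/", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) {
    pair <- lapply(parts, parse_mutation)
    return(structure(list(first = pair[[1L]], second = pair[[2L]],
                          token = toupper(token)),
                     class = "compound_mutation"))
  }
  if (length(parts) != 1L) {
    stop("malformed compound token '", token,
         "': expected exactly one '/'", call. = FALSE)
  }
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1L]]
  if (length(m) != 4L) {
    stop("malformed mutation token '", token,
         "': expected <AA><position><AA>, e.g. T315I", call. = FALSE)
  }
  wt <- toupper(m[2L]); mut <- toupper(m[4L])
  pos <- as.integer(m[3L])
  for (r in c(wt, mut)) {
    if (!r %in% AA20) {
      stop("'", r, "' in token '", token,
           "' is not a canonical amino-acid letter", call. = FALSE)
    }
  }
  if (wt == mut) {
    stop("token '", token, "' is not a mutation: wild-type and mutant ",
         "residues are identical", call. = FALSE)
  }
  if (pos < 1L) stop("position in '", token, "' must be >= 1", call. = FALSE)
  point_mutation(wt, pos, mut)
}

#' @rdname parse_mutation
#' @param wt,position,mut Components of a point mutation.
#' @export
point_mutation <- function(wt, position, mut) {
  wt <- toupper(wt); mut <- toupper(mut)
  stopifnot(wt %in% AA20, mut %in% AA20, wt != mut, position >= 1)
  structure(list(wt = wt, position = as.integer(position), mut = mut),
            class = "point_mutation")
}

#' @export
format.point_mutation <- function(x, ...) paste0(x$wt, x$position, x$mut)

#' @export
print.point_mutation <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' @export
format.compound_mutation <- function(x, ...) {
  paste0(format(x$first), "/", format(x$second))
}

#' @export
print.compound_mutation <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Coerce tokens or mutation objects to a list of point mutations
#'
#' @param x A character vector of tokens, a single `point_mutation`, or a list
#'   of tokens/`point_mutation`s.
#' @return A list of `point_mutation` objects, named by their tokens.
#' @export
as_point_mutations <- function(x) {
  if (inherits(x, "point_mutation")) x <- list(x)
  if (is.character(x)) x <- as.list(x)
  out <- lapply(x, function(el) {
    if (inherits(el, "point_mutation")) return(el)
    if (inherits(el, "compound_mutation")) {
      stop("expected a point mutation, got compound '", format(el), "'",
           call. = FALSE)
    }
    parse_mutation(el)
  })
  names(out) <- vapply(out, format, character(1))
  out
}

#' Read a mutation list file
#'
#' Accepts whitespace- or comma-separated tokens, one or several per line.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to a text file of mutation tokens.
#' @return Character vector of tokens (compound tokens kept intact).
#' @export
read_mutations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tokens <- unlist(strsplit(lines, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("no mutation tokens found in '", path, "'",
                            call. = FALSE)
  tokens
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned amino-acid FASTA file (gap character `-`;
#'   `.` is accepted and normalised to `-`). CRLF line endings are accepted.
#' @return A named character vector of aligned rows (names are record ids,
#'   i.e. the first whitespace-delimited word of each header).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("alignment file '", path, "' is empty", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id '", dup[1L], "' in '", path, "'",
         call. = FALSE)
  }
  rows <- as.character(set)
  names(rows) <- ids
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment in '", path, "': row lengths ",
         paste(sort(unique(widths)), collapse = ", "), call. = FALSE)
  }
  toupper(chartr(".", "-", rows))
}

#' Read a nucleotide FASTA record
#'
#' @param path Path to a nucleotide FASTA file.
#' @param id Optional record id; defaults to the first record.
#' @return The sequence as a single uppercase DNA string (U mapped to T).
#' @export
read_fasta_nt <- function(path, id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("FASTA file '", path, "' is empty", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(id)) {
    i <- 1L
  } else {
    i <- match(id, ids)
    if (is.na(i)) stop("record '", id, "' not found in '", path, "'",
                       call. = FALSE)
  }
  chartr("U", "T", toupper(as.character(set[[i]])))
}

#' Extract a coding domain from a CDS FASTA file
#'
#' The reading frame starts at codon 1 of the record, i.e. the record's first
#' codon encodes protein position `cds_start` (default 1, a full-protein CDS).
#' The domain is selected by 1-based inclusive full-protein coordinates.
#'
#' @param path CDS FASTA file.
#' @param start,end 1-based inclusive protein coordinates of the domain.
#' @param gene_id Identifier for the resulting domain (defaults to record id).
#' @param id Optional FASTA record id.
#' @param cds_start Protein position encoded by the record's first codon.
#' @return A `coding_domain` spanning `start`..`end`.
#' @export
read_coding_domain <- function(path, start, end, gene_id = NULL, id = NULL,
                               cds_start = 1L) {
  seqstr <- read_fasta_nt(path, id = id)
  if (is.null(gene_id)) {
    gene_id <- sub("\\s.*$", "", names(Biostrings::readBStringSet(path))[1L])
  }
  start <- as.integer(start); end <- as.integer(end)
  if (start < cds_start || end < start) {
    stop("invalid domain coordinates ", start, "-", end, call. = FALSE)
  }
  first_base <- 3L * (start - as.integer(cds_start)) + 1L
  last_base <- 3L * (end - as.integer(cds_start)) + 3L
  if (last_base > nchar(seqstr)) {
    stop("domain ", start, "-", end, " extends beyond the CDS (",
         nchar(seqstr), " nt)", call. = FALSE)
  }
  coding_domain(substr(seqstr, first_base, last_base),
                gene_id = gene_id, protein_start = start)
}

#' Write a data frame as headered TSV
#'
#' UTF-8, tab-delimited, `.` decimal separator, no quoting, no row names.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a headered TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}
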