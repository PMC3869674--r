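# Shared fixtures and independent oracles.

AAs <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")

# All 61 sense codons of the standard genetic code.
sense_codons <- local({
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

# Independent brute-force enumeration of single-substitution missense
# neighbours, translated with seqinr (a different code path than the
# package's Biostrings lookup).
oracle_neighbors <- function(codon) {
  v0 <- strsplit(toupper(codon), "", fixed = TRUE)[[1]]
  wt <- seqinr::translate(tolower(v0))
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(BASES, v0[i])) {
      v <- v0
      v[i] <- b
      aa <- seqinr::translate(tolower(v))
      if (aa != "*" && aa != wt) out <- c(out, aa)
    }
  }
  sort(unique(out))
}

# Small hand-built alignment: reference ACDEF at offset 100, with known
# variant counts at each column.
toy_rows <- c(
  REF = "ACDEF",
  s1  = "AGDEF",   # C101G
  s2  = "AGDEF",   # C101G
  s3  = "ACDKF",   # E103K
  s4  = "AC-EF",   # gap at column 3
  s5  = "ACDEX",   # ambiguity at column 5
  s6  = "AGDKF",   # C101G + E103K
  s7  = "ACDEF"
)
toy_profile <- function() build_profile(toy_rows, "REF", 100)

# Random rectangular profile whose reference is the first row; mutations are
# sampled so they always satisfy the wild-type precondition.
random_profile <- function(seed, n_rows = 40, L = 10) {
  set.seed(seed)
  ref <- sample(AAs, L, replace = TRUE)
  mat <- vapply(seq_len(L), function(j) {
    c(ref[j], sample(c(ref[j], sample(AAs, 3)), n_rows - 1, replace = TRUE))
  }, character(n_rows))
  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- c("REF", sprintf("r%03d", seq_len(n_rows - 1)))
  build_profile(rows, "REF", 1)
}

# A mutation at `pos` of a profile whose mutant residue actually occurs
# somewhere in that column (so marginals are non-trivial when possible).
profile_mutation <- function(profile, pos) {
  col <- unname(profile$column_map[as.character(pos)])
  ref_idx <- match(profile$reference_id, profile$ids)
  wt <- profile$mat[ref_idx, col]
  seen <- setdiff(unique(profile$mat[, col]), c(wt, "-", "X"))
  mut <- if (length(seen)) seen[1] else setdiff(AAs, wt)[1]
  point_mutation(wt, pos, mut)
}
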