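test_that("Grantham distances reproduce the published worked values", {
  expect_equal(grantham_distance("I", "L"), 5)    # conservative
  expect_equal(grantham_distance("C", "F"), 205)  # radical
  expect_equal(grantham_distance("F", "H"), 100)  # the mean-distance pair
  expect_equal(grantham_distance("A", "A"), 0)
  expect_error(grantham_distance("B", "A"), "not a canonical")
})

test_that("the distance table is symmetric with zero diagonal and mean 100", {
  M <- grantham_matrix()
  expect_identical(M, t(M))
  expect_equal(unname(diag(M)), rep(0L, 20))
  expect_equal(max(M), 215)  # Cys-Trp, the most radical pair
  expect_equal(mean(M[upper.tri(M)]), 100, tolerance = 0.01)
})

test_that("the property formula cross-validates the integer table", {
  M <- grantham_matrix()
  aa <- rownames(M)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  form <- grantham_from_properties(aa[pairs[, 1]], aa[pairs[, 2]])
  dev <- abs(form - M[pairs])
  is_wd <- (aa[pairs[, 1]] == "W" & aa[pairs[, 2]] == "D") |
    (aa[pairs[, 1]] == "D" & aa[pairs[, 2]] == "W")
  # every pair agrees within about one unit of rounding drift (the largest,
  # Asn-Glu, is 1.09: table 42 vs formula 40.9) ...
  expect_lte(max(dev[!is_wd]), 1.1)
  # ... except Trp-Asp, where the published table prints 181 but the
  # composition/polarity/volume formula yields about 191
  expect_equal(M["W", "D"], 181)
  expect_equal(dev[is_wd], 10, tolerance = 0.05)
  expect_equal(grantham_from_properties("F", "H"), 100, tolerance = 0.005)
  expect_equal(grantham_from_properties("A", "A"), 0)
})

test_that("median Grantham follows the stated conventions", {
  expect_equal(median_grantham("T315I"), 89)
  expect_equal(median_grantham(c("I315L", "C315F")), 105)  # midpoint of 5, 205
  muts <- c("T315I", "I2L", "C3F", "F4H", "W5D")
  expect_equal(median_grantham(muts), median_grantham(rev(muts)))
  # per-residue collapse: two substitutions of one residue count once
  expect_equal(median_grantham(c("T315I", "T315A"), per_residue = TRUE),
               median(c(median(c(89, 58)))))
  expect_error(median_grantham(character(0)), "empty")
})

write_demo_pssm <- function(freq = TRUE) {
  aa_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  scores <- list(
    `747` = c(L = 4, M = 2, I = 1, V = 0),
    `768` = c(S = 3, I = -2, R = 1, T = 2),
    `790` = c(T = 1, M = 3, A = 1, K = -3),
    `387` = c(L = 3, F = 3, M = 3, W = -1)
  )
  freqs <- list(
    `747` = c(L = 60, M = 20, I = 10, V = 10, S = 5),
    `768` = c(S = 55, I = 0, R = 5, T = 30, A = 10),
    `790` = c(T = 30, M = 50, A = 15, K = 0),
    `387` = c(L = 40, F = 30, M = 30, W = 0)
  )
  wt <- c(`747` = "L", `768` = "S", `790` = "T", `387` = "L")
  path <- tempfile(fileext = ".pssm")
  lines <- c("Last position-specific scoring matrix computed", "",
             paste0("          ",
                    paste(rep(sprintf("%3s", aa_order), if (freq) 2 else 1),
                          collapse = " ")))
  for (p in names(scores)) {
    srow <- setNames(rep(-4, 20), aa_order)
    srow[names(scores[[p]])] <- scores[[p]]
    frow <- setNames(rep(0, 20), aa_order)
    frow[names(freqs[[p]])] <- freqs[[p]]
    vals <- sprintf("%3d", srow)
    if (freq) vals <- c(vals, sprintf("%3d", frow))
    lines <- c(lines, paste0(sprintf("%5s %s  ", p, wt[p]),
                             paste(vals, collapse = " "),
                             if (freq) "  0.35 0.12"))
  }
  writeLines(lines, path)
  path
}

test_that("ASCII PSSM tables parse into per-position score maps", {
  pssm <- read_pssm(write_demo_pssm())
  expect_setequal(pssm$positions, c(747, 768, 790, 387))
  expect_equal(unname(pssm$wt["768"]), "S")
  expect_equal(pssm$scores["790", "M"], 3)
  expect_equal(pssm$freq["768", "I"], 0)
  expect_equal(ncol(pssm$scores), 20)
  # score-only dialect (no frequency block)
  bare <- read_pssm(write_demo_pssm(freq = FALSE))
  expect_null(bare$freq)
  # full-protein offsets shift positions
  shifted <- read_pssm(write_demo_pssm(), offset = 1000)
  expect_true(1790 %in% shifted$positions)
})

test_that("PSSM deltas classify mutations by relative conservation", {
  pssm <- read_pssm(write_demo_pssm())
  # equal scores -> similar (the L387F / L387M pattern)
  expect_equal(pssm_delta(pssm, "L387F")$classification, "similar")
  expect_equal(pssm_delta(pssm, "L387M")$classification, "similar")
  # mutant scoring higher -> more conserved (the T790M pattern)
  d <- pssm_delta(pssm, "T790M")
  expect_equal(d$classification, "mutant_more_conserved")
  expect_equal(d$wt_score, 1)
  expect_equal(d$mut_score, 3)
  # mutant scoring lower -> less conserved
  expect_equal(pssm_delta(pssm, "L747S")$classification,
               "mutant_less_conserved")
  # frequency 0 overrides the score comparison
  expect_equal(pssm_delta(pssm, "S768I")$classification, "not_present")
  expect_equal(pssm_delta(pssm, "T790K")$classification, "not_present")
  # tolerance widens "similar"
  expect_equal(pssm_delta(pssm, "T790A", similar_tol = 1)$classification,
               "similar")
  expect_error(pssm_delta(pssm, "T999A"), "absent from the PSSM")
})

test_that("conservation medians are computed per residue, not per mutation", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("position\tscore\tgrade",
               "315\t-1.2\t9", "316\t0\t5", "317\t2\t1", "318\t-1\t8"),
             path)
  cons <- read_conservation(path)
  expect_s3_class(cons, "conservation_profile")
  expect_equal(median_conservation(cons, "A315G"), -1.2)
  # several SNVs of one residue count its score once
  expect_equal(median_conservation(cons, c("T315I", "T315A", "T316G")),
               median(c(-1.2, 0)))
  expect_equal(median_conservation(cons, c("A318G", "A316C", "A317S")), 0)
  expect_error(median_conservation(cons, "A999G"), "999")
})

test_that("biochem_table assembles the per-mutation export layout", {
  pssm <- read_pssm(write_demo_pssm())
  cons <- data.frame(position = c(747, 790), score = c(-0.8, -1.5))
  class(cons) <- c("conservation_profile", "data.frame")
  tab <- biochem_table(c("L747S", "T790M"), pssm = pssm, conservation = cons)
  expect_equal(tab$grantham, c(grantham_distance("L", "S"),
                               grantham_distance("T", "M")))
  expect_equal(tab$classification,
               c("mutant_less_conserved", "mutant_more_conserved"))
  expect_equal(tab$consurf_score, c(-0.8, -1.5))
})
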