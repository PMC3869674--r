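test_that("profiles map reference positions to columns and count all rows", {
  rows <- c(a = "ACD", b = "ACD", REF = "ACD")
  pr <- build_profile(rows, "REF", 10)
  expect_equal(unname(pr$column_map), 1:3)
  expect_equal(names(pr$column_map), c("10", "11", "12"))
  expect_equal(pr$n_rows, 3)

  # reference gaps are unmappable; other rows' gaps are counted per column
  rows2 <- c(REF = "A-CD", s = "AWCD", t = "A-C-")
  pr2 <- build_profile(rows2, "REF", 5)
  expect_equal(unname(pr2$column_map), c(1, 3, 4))
  expect_equal(names(pr2$column_map), c("5", "6", "7"))
  # denominator conservation: every column's counts sum to n_rows
  expect_true(all(vapply(pr2$column_counts, sum, numeric(1)) == 3))

  expect_error(build_profile(rows, "nope", 1), "not found")
  expect_error(build_profile(c(REF = "AC", s = "ACD"), "REF", 1), "ragged")
  expect_error(build_profile(character(0), "REF", 1), "no rows")
  expect_error(build_profile(c(REF = "---"), "REF", 1), "no residues")
})

test_that("mutation occurrence counts rows carrying the mutant residue", {
  pr <- toy_profile()
  rec <- mutation_occurrence(pr, "C101G")  # 3 of 8 rows
  expect_true(rec$observed)
  expect_equal(rec$count, 3)
  expect_equal(rec$n_rows, 8)
  expect_equal(rec$frequency, 3 / 8)

  absent <- mutation_occurrence(pr, "A100V")
  expect_false(absent$observed)
  expect_equal(absent$count, 0)

  # gaps and ambiguity codes stay in the denominator, never the numerator
  recD <- mutation_occurrence(pr, "D102E")
  expect_equal(recD$n_rows, 8)
  expect_equal(recD$count, 0)
  recF <- mutation_occurrence(pr, "F104W")
  expect_equal(recF$count, 0)  # the ambiguity row never matches a mutant
  expect_equal(recF$n_rows, 8)
})

test_that("occurrence validation errors name the offending coordinate", {
  pr <- toy_profile()
  expect_error(mutation_occurrence(pr, "C200G"), "not mapped")
  err <- tryCatch(mutation_occurrence(pr, "W101G"), error = identity)
  expect_match(conditionMessage(err), "expected wild-type 'W'")
  expect_match(conditionMessage(err), "has 'C'")
})

test_that("reported percentages follow the truncation convention", {
  expect_equal(report_percent(87, 276), "31%")   # 31.52 truncates, not rounds
  expect_equal(report_percent(146, 276), "52%")  # 52.90 truncates
  expect_equal(report_percent(51, 276), "18%")
  expect_equal(report_percent(1, 276), "0.3%")   # one decimal below 1%
  expect_equal(report_percent(0, 10), "0.0%")
  expect_equal(report_percent(276, 276), "100%")
  expect_equal(report_percent(69, 276), "25%")   # exact quarter stays exact
  expect_error(report_percent(1, 0), "total")
  expect_error(report_percent(5, 4), "count")
})

test_that("observed spectra intersect reachable sets with column residues", {
  ref <- "ASTCT"
  dom <- simulate_cds(ref, gene_id = "toy", protein_start = 20, seed = 2)

  # monomorphic family: nothing beyond the reference is observed
  mono <- build_profile(setNames(rep(ref, 5), c("REF", paste0("s", 1:4))),
                        "REF", 20)
  sp0 <- observed_spectrum(mono, dom)
  expect_equal(sp0$observed, 0)
  expect_gt(sp0$possible, 0)

  # saturated columns: every reachable residue is somewhere in the column
  sat_rows <- c(REF = ref,
                setNames(vapply(1:20, function(i)
                  paste(rep(AAs[i], 5), collapse = ""), character(1)),
                  paste0("x", 1:20)))
  spsat <- observed_spectrum(build_profile(sat_rows, "REF", 20), dom)
  expect_equal(spsat$observed, spsat$possible)

  # per-position bookkeeping is internally consistent
  expect_equal(sp0$possible, sum(sp0$detail$n_reachable))
  expect_equal(spsat$observed, sum(spsat$detail$n_observed))

  expect_error(observed_spectrum(mono, simulate_cds("AC", protein_start = 90)),
               "not mapped.*90")
})

test_that("occurrence and spectrum agree on what counts as observed", {
  spec <- synthetic_msa_spec(
    "ASTCTMERW", 120, offset = 311, epsilon = 0.05,
    supports = data.frame(position = 315, residue = "I", freq = 0.3),
    seed = 9)
  sim <- simulate_msa(spec)
  pr <- build_profile(sim$rows, "REF", 311)
  dom <- simulate_cds("ASTCTMERW", gene_id = "syn", protein_start = 311,
                      seed = 9)
  sp <- observed_spectrum(pr, dom)
  for (pos in 311:319) {
    row <- sp$detail[sp$detail$position == pos, ]
    reach <- strsplit(row$reachable, ",")[[1]]
    obs <- strsplit(row$observed_subset, ",")[[1]]
    for (aa in reach) {
      rec <- mutation_occurrence(pr, point_mutation(row$wt, pos, aa))
      expect_equal(rec$observed, aa %in% obs,
                   label = paste0(row$wt, pos, aa))
    }
  }
})

test_that("profiles are invariant to row order", {
  spec <- synthetic_msa_spec("ASTCTMERW", 60, offset = 1, epsilon = 0.1,
                             seed = 4)
  sim <- simulate_msa(spec)
  pr1 <- build_profile(sim$rows, "REF", 1)
  set.seed(1)
  pr2 <- build_profile(sample(sim$rows), "REF", 1)
  expect_equal(pr1$column_map, pr2$column_map)
  for (j in seq_along(pr1$column_counts)) {
    expect_equal(as.list(pr1$column_counts[[j]]),
                 as.list(pr2$column_counts[[j]]))
  }
})

test_that("classification splits mutations into occurred and novel by group", {
  pr <- toy_profile()
  empty <- classify_mutations(pr, character(0))
  expect_s3_class(empty, "mutation_class_table")
  expect_equal(nrow(empty), 0)

  labels <- data.frame(mutation = c("C101G", "E103K", "A100V"),
                       gene = "toy", class = "resistant")
  tab <- classify_mutations(pr, labels$mutation, labels)
  expect_equal(tab$occurred, 2)
  expect_equal(tab$novel, 1)
  expect_equal(tab$total, 3)
  expect_equal(tab$occurred + tab$novel, tab$total)

  # two classes are reported as separate rows
  labels2 <- data.frame(mutation = c("C101G", "E103K", "A100V"),
                        gene = "toy",
                        class = c("resistant", "resistant", "activating"))
  tab2 <- classify_mutations(pr, labels2$mutation, labels2)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$total[tab2$class == "resistant"], 2)

  # validation failures carry the mutation token
  expect_error(classify_mutations(pr, "W101G",
                                  data.frame(mutation = "W101G", gene = "toy",
                                             class = "resistant")),
               "W101G")
})
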