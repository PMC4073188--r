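test_that("well-formed tables parse in both layouts and dialects", {
  tab <- write_lines_tmp(c(
    "r1\tTGAGGTAGTAGGTTGTATAGTT",
    "r2\tAACTATACAACCTACTACCTCA",
    "r3\tACGTACGTACGTACGTACGTA",
    "r4\tTTTTAAAACCCCGGGGTTTTA"
  ))
  out <- parse_reagent_table(tab, layout = "active_only")
  expect_equal(nrow(out$records), 4L)
  expect_true(all(out$records$activity == "active"))
  expect_equal(out$report$n_malformed, 0L)
  expect_equal(out$report$n_total, 4L)

  csv <- write_lines_tmp(c(
    "id,sequence,phenotype",              # header: sequence column not a DNA string
    "r1,TGAGGTAGTAGGTTGTATAGTT,active",
    "r2,AACTATACAACCTACTACCTCA,With Phenotype",
    "r3,ACGTACGTACGTACGTACGTA,0",
    "r4,TTTTAAAACCCCGGGGTTTTA,no"
  ), ext = ".csv")
  out <- parse_reagent_table(csv, layout = "active_and_inactive")
  expect_equal(out$records$activity, c("active", "active", "inactive", "inactive"))
  expect_equal(out$records$line_number, 2:5)
  expect_equal(out$report$n_total, 4L)
})

test_that("malformed rows are excluded, classified and reported with examples", {
  f <- write_lines_tmp(c(
    "r1\tTGAGGTAGTAGGTTGTATAGTT\tactive",
    "r2\t\tactive",                          # missing_sequence
    "r3\tTGAGGXAGTAGGTTGTATAGTT\tactive",    # illegal_character
    "r4\tTGAGGTA\tactive",                   # too_short_for_seed
    "r5\tTGAGGTAGTAGGTTGTATAGTT",            # missing_activity
    "r6\tTGAGGTAGTAGGTTGTATAGTT\tmaybe",     # bad_activity_value
    "r7\tugagguaguagguuguauaguu\tinactive"   # RNA lower case is fine
  ))
  out <- parse_reagent_table(f, layout = "active_and_inactive")
  expect_equal(out$records$reagent_id, c("r1", "r7"))
  expect_equal(out$report$n_total, 7L)
  expect_equal(out$report$n_malformed, 5L)
  expect_setequal(out$report$error_kinds,
                  c("missing_sequence", "illegal_character",
                    "too_short_for_seed", "missing_activity",
                    "bad_activity_value"))
  expect_lte(nrow(out$report$error_examples), 5L)
  expect_equal(out$report$malformed_lines, 2:6)
})

test_that("degenerate reagent tables raise input errors", {
  expect_error(parse_reagent_table(tempfile()), "not readable")
  empty <- write_lines_tmp(character(0))
  expect_error(parse_reagent_table(empty), "no data rows")
})

test_that("duplicate reagent ids and empty ids get deterministic names", {
  f <- write_lines_tmp(c(
    "r1\tTGAGGTAGTAGGTTGTATAGTT",
    "r1\tAACTATACAACCTACTACCTCA",
    "\tACGTACGTACGTACGTACGTA"
  ))
  out <- parse_reagent_table(f, layout = "active_only")
  expect_equal(out$records$reagent_id, c("r1", "r1__2", "reagent_3"))
})

test_that("preprocessing gate aborts strictly above 25% malformed", {
  expect_equal(enforce_preprocess_gate(fake_report(100, 30)), "abort")
  expect_equal(enforce_preprocess_gate(fake_report(100, 25)), "proceed")
  expect_equal(enforce_preprocess_gate(fake_report(100, 10)), "proceed")
  # monotone in n_malformed at fixed n_total
  verdicts <- vapply(0:40, function(k) enforce_preprocess_gate(fake_report(40, k)),
                     character(1))
  aborted <- verdicts == "abort"
  expect_false(any(diff(aborted) < 0))  # never flips back to proceed
})

test_that("reference FASTA is normalized, de-duplicated and filtered", {
  f <- write_lines_tmp(c(">NM_1 some description", "acgu", "ACGT",
                         ">t1", "ACGT",
                         ">t1", "GGGG",
                         ">bad", "ACNT"), ext = ".fasta")
  tx <- read_reference_fasta(f)
  expect_equal(tx$accession, c("NM_1", "t1", "t1__2"))
  expect_equal(tx$sequence[1], "ACGTACGT")
  expect_equal(tx$description[1], "some description")
  expect_equal(attr(tx, "n_skipped"), 1L)
  empty <- write_lines_tmp(character(0), ext = ".fasta")
  expect_error(read_reference_fasta(empty), "no FASTA records")
})

test_that("FASTA write/read round-trips with 80-column wrapping", {
  set.seed(7)
  tx <- data.frame(
    accession = sprintf("s%d", 1:5),
    description = c("alpha", "", "gamma delta", "", "epsilon"),
    sequence = vapply(c(30, 80, 81, 200, 1000), random_dna_string, ""),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".fasta")
  write_fasta(tx, f, width = 80)
  back <- read_reference_fasta(f)
  expect_equal(back$accession, tx$accession)
  expect_equal(back$sequence, tx$sequence)
  expect_equal(back$description, tx$description)
})

test_that("enrichment table round-trips numbers at printed precision", {
  res <- run_synthetic_screen(plant_spec(n_transcripts = 30L, rng_seed = 5L))
  f <- tempfile(fileext = ".tsv")
  write_enrichment_table(res$run$results, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 30L)
  for (col in c("smf_active", "smf_inactive", "p_fisher", "p_yates",
                "p_selected", "p_bonferroni", "p_holm", "p_bh")) {
    expect_equal(back[[col]], signif(res$run$results[[col]], 6),
                 tolerance = 1e-5, label = col)
  }
  expect_equal(back$rank, res$run$results$rank)
  expect_equal(back$sig_bh, res$run$results$sig_bh)
  expect_equal(back$selected_test, res$run$results$selected_test)
})

test_that("only_significant restricts the enrichment table by selected p", {
  res <- run_synthetic_screen(plant_spec(n_transcripts = 30L, rng_seed = 5L))
  f <- tempfile(fileext = ".tsv")
  write_enrichment_table(res$run$results, f, only_significant = TRUE,
                         alpha = 0.05)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), sum(res$run$results$p_selected <= 0.05))

  # empty result set still writes a header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_enrichment_table(res$run$results[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
})

test_that("match detail lists only transcripts at or below alpha", {
  res <- run_synthetic_screen(plant_spec(rng_seed = 3L))
  f <- tempfile(fileext = ".tsv")
  write_match_detail(res$run$results, res$run$match_detail, f, alpha = 0.05)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  keep <- res$run$results[res$run$results$p_selected <= 0.05, ]
  expect_equal(back$accession, keep$accession)
  expect_true(res$off_target %in% back$accession)
  ids <- strsplit(back$matched_active_ids[back$accession == res$off_target],
                  ",")[[1]]
  expect_gte(length(ids), 12L)  # all planted sharers match
  expect_true(all(sprintf("ACT_%03d", 1:12) %in% ids))

  # no transcript passes -> header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_match_detail(res$run$results, res$run$match_detail, f2, alpha = 1e-300)
  expect_equal(length(readLines(f2)), 1L)
})
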