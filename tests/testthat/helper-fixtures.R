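# Shared fixtures and independent oracles, all built in code at test time.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Position-by-position scanning oracle for overlapping exact occurrences.
naive_count_occurrences <- function(site, seq) {
  w <- nchar(site)
  L <- nchar(seq)
  if (w > L) return(0L)
  sum(substring(seq, 1:(L - w + 1L), w:L) == site)
}

# Generate, parse and analyse one synthetic screen.
run_synthetic_screen <- function(spec, ...) {
  tx <- generate_transcriptome(spec)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  generate_screen(spec, path)
  parsed <- parse_reagent_table(path, layout = "active_and_inactive")
  run <- run_enrichment(parsed$records, tx$transcripts, ...)
  list(run = run, off_target = tx$off_target, transcripts = tx$transcripts)
}

# Minimal parse report for gate tests.
fake_report <- function(n_total, n_malformed) {
  structure(list(n_total = n_total, n_malformed = n_malformed,
                 malformed_fraction = n_malformed / n_total,
                 error_kinds = character(0),
                 error_examples = data.frame(),
                 malformed_lines = integer(0)),
            class = "parse_report")
}
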