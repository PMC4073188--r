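#' Parse a reagent table
#'
#' Reads a delimited text table of RNAi reagents. Two layouts are supported:
#' `"active_and_inactive"` expects three columns (id, sequence, activity) and
#' `"active_only"` expects two (id, sequence), with every reagent treated as
#' active. A header row is optional and is detected when the sequence column
#' of the first row is not a valid nucleotide string.
#'
#' Malformed rows are excluded from the returned records but counted in the
#' parse report, which drives the pre-processing gate
#' ([enforce_preprocess_gate()]). Error kinds: `missing_sequence`,
#' `illegal_character` (outside A/C/G/T/U in either case),
#' `too_short_for_seed` (shorter than `1 + seed_length` after `trim`),
#' `missing_activity`, `bad_activity_value`. Accepted activity tokens
#' (case-insensitive): active = \{active, 1, yes, with phenotype\};
#' inactive = \{inactive, 0, no, without phenotype\}.
#'
#' @param path Path to the reagent table.
#' @param layout `"active_and_inactive"` or `"active_only"`.
#' @param dialect Field delimiter: `"tab"`, `"comma"`, or `"auto"` (tab if the
#'   first non-blank line contains a tab, else comma).
#' @param seed_length,trim Seed length and 3'-trim used to flag sequences too
#'   short to yield a seed; defaults match [seed_config()].
#' @return A list with `records` (data frame: `reagent_id`, `sequence`,
#'   `activity`, `line_number`) and `report` (a `"parse_report"`: `n_total`,
#'   `n_malformed`, `malformed_fraction`, `error_kinds`, `error_examples` (up
#'   to 5 rows), `malformed_lines`).
#' @export
parse_reagent_table <- function(path,
                                layout = c("active_and_inactive", "active_only"),
                                dialect = c("auto", "tab", "comma"),
                                seed_length = 7L, trim = 0L) {
  layout <- match.arg(layout)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("reagent table not readable: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_numbers <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("reagent table contains no data rows", call. = FALSE)
  }
  sep <- switch(dialect,
                tab = "\t", comma = ",",
                auto = if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ",")
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, trimws)

  seq_of <- function(f) if (length(f) >= 2L) f[[2L]] else ""
  is_nt <- function(x) nzchar(x) && grepl("^[ACGTUacgtu]+$", x)
  if (!is_nt(seq_of(fields[[1L]]))) {  # header row
    fields <- fields[-1L]
    line_numbers <- line_numbers[-1L]
  }
  if (length(fields) == 0L) {
    stop("reagent table contains no data rows", call. = FALSE)
  }

  active_tokens <- c("active", "1", "yes", "with phenotype")
  inactive_tokens <- c("inactive", "0", "no", "without phenotype")
  min_len <- 1L + as.integer(seed_length) + as.integer(trim)

  n <- length(fields)
  reagent_id <- character(n); sequence <- character(n); activity <- character(n)
  error_kind <- character(n)  # "" = well-formed
  for (i in seq_len(n)) {
    f <- fields[[i]]
    id <- if (length(f) >= 1L) f[[1L]] else ""
    sq <- seq_of(f)
    act <- if (length(f) >= 3L) f[[3L]] else ""
    kind <-
      if (!nzchar(sq)) "missing_sequence"
      else if (!is_nt(sq)) "illegal_character"
      else if (nchar(sq) < min_len) "too_short_for_seed"
      else if (layout == "active_and_inactive" && !nzchar(act)) "missing_activity"
      else if (layout == "active_and_inactive" &&
               !(tolower(act) %in% c(active_tokens, inactive_tokens))) "bad_activity_value"
      else ""
    error_kind[i] <- kind
    if (!nzchar(kind)) {
      reagent_id[i] <- if (nzchar(id)) id else sprintf("reagent_%d", line_numbers[i])
      sequence[i] <- sq
      activity[i] <- if (layout == "active_only") "active"
                     else if (tolower(act) %in% active_tokens) "active" else "inactive"
    }
  }

  bad <- nzchar(error_kind)
  ex_idx <- which(bad)[seq_len(min(5L, sum(bad)))]
  report <- structure(list(
    n_total = n,
    n_malformed = sum(bad),
    malformed_fraction = sum(bad) / n,
    error_kinds = unique(error_kind[bad]),
    error_examples = data.frame(
      line_number = line_numbers[ex_idx],
      error_kind = error_kind[ex_idx],
      raw = lines[ex_idx],
      stringsAsFactors = FALSE
    ),
    malformed_lines = line_numbers[bad]
  ), class = "parse_report")

  records <- data.frame(
    reagent_id = make_unique_ids(reagent_id[!bad]),
    sequence = sequence[!bad],
    activity = activity[!bad],
    line_number = line_numbers[!bad],
    stringsAsFactors = FALSE
  )
  list(records = records, report = report)
}

# Deterministic de-duplication: second and later occurrences get "__k".
make_unique_ids <- function(ids) {
  if (anyDuplicated(ids)) {
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    dup <- occ > 1L
    ids[dup] <- sprintf("%s__%d", ids[dup], occ[dup])
  }
  ids
}

#' Pre-processing gate on the parse report
#'
#' The analysis aborts when more than 25% of the data rows are malformed
#' (strictly greater; exactly 25% proceeds). On `"proceed"` the malformed rows
#' are simply ignored and their line numbers surface in the run summary.
#'
#' @param report A `"parse_report"` from [parse_reagent_table()].
#' @param max_fraction Abort threshold (default 0.25).
#' @return `"abort"` or `"proceed"`.
#' @export
enforce_preprocess_gate <- function(report, max_fraction = 0.25) {
  if (report$malformed_fraction > max_fraction) "abort" else "proceed"
}

#' Read a reference transcript set from FASTA
#'
#' Each record's first whitespace-delimited header token becomes the
#' accession; the remainder is kept as the description. Sequences are
#' uppercased and U is mapped to T; records containing any other character
#' (e.g. N) are skipped and counted. Duplicate accessions are suffixed
#' `"__k"` (k = occurrence index, from 2) so accessions stay unique.
#'
#' @param path Path to a FASTA file (multi-line records allowed).
#' @return Data frame with columns `accession`, `description`, `sequence`,
#'   with attribute `n_skipped` giving the number of records dropped for
#'   non-ACGT characters.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records found in %s", path), call. = FALSE)
  }
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- chartr("U", "T", toupper(as.character(set)))
  ok <- !grepl("[^ACGT]", sequence) & nzchar(sequence)
  out <- data.frame(
    accession = make_unique_ids(accession[ok]),
    description = description[ok],
    sequence = sequence[ok],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Write transcripts to FASTA
#'
#' @param transcripts Transcript data frame (`accession`, `description`,
#'   `sequence`).
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 80L) {
  set <- Biostrings::DNAStringSet(transcripts$sequence)
  desc <- transcripts$description
  names(set) <- ifelse(nzchar(desc),
                       paste(transcripts$accession, desc),
                       transcripts$accession)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Fixed-decimal formatting at 6 significant digits; values below `sci_below`
# switch to scientific notation (used for small p-values).
format_number <- function(x, sci_below = NA_real_) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == 0) return("0.000000")
    if (!is.na(sci_below) && abs(v) < sci_below) return(sprintf("%.5e", v))
    dec <- max(0L, 6L - 1L - as.integer(floor(log10(abs(v)))))
    sprintf("%.*f", dec, v)
  }, character(1))
}

#' Write the per-transcript enrichment table
#'
#' Tab-delimited with a header row; one row per tested transcript in rank
#' order. Numeric columns use 6 significant digits; p-values below 1e-4 are
#' printed in scientific notation. With `only_significant`, rows are
#' restricted to `p_selected <= alpha`.
#'
#' @param results Ranked enrichment results from [run_enrichment()].
#' @param path Output path.
#' @param only_significant Restrict to transcripts with
#'   `p_selected <= alpha`.
#' @param alpha Significance threshold (default 0.05).
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(results, path, only_significant = FALSE,
                                   alpha = 0.05) {
  if (only_significant && nrow(results) > 0L) {
    results <- results[results$p_selected <= alpha, , drop = FALSE]
  }
  pcols <- c("p_fisher", "p_yates", "p_selected",
             "p_bonferroni", "p_holm", "p_bh")
  out <- data.frame(
    accession = results$accession,
    description = results$description,
    n_active_matched = results$n_active_matched,
    smf_active = format_number(results$smf_active),
    n_inactive_matched = results$n_inactive_matched,
    smf_inactive = format_number(results$smf_inactive),
    stringsAsFactors = FALSE
  )
  for (col in c("p_fisher", "p_yates", "p_selected")) {
    out[[col]] <- format_number(results[[col]], sci_below = 1e-4)
  }
  out$selected_test <- results$selected_test
  out$rank <- results$rank
  for (col in c("p_bonferroni", "p_holm", "p_bh")) {
    out[[col]] <- format_number(results[[col]], sci_below = 1e-4)
  }
  out$sig_bonferroni <- results$sig_bonferroni
  out$sig_holm <- results$sig_holm
  out$sig_bh <- results$sig_bh
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the match-detail file
#'
#' Lists, for each transcript with `p_selected <= alpha`, the active reagents
#' whose seeds match it (comma-separated, in reagent input order).
#'
#' @param results Ranked enrichment results from [run_enrichment()].
#' @param matches Named list, accession to character vector of matching active
#'   reagent ids (the `match_detail` element of [run_enrichment()]).
#' @param path Output path.
#' @param alpha Inclusion threshold on the selected p-value (default 0.05).
#' @return `path`, invisibly.
#' @export
write_match_detail <- function(results, matches, path, alpha = 0.05) {
  keep <- results[results$p_selected <= alpha, , drop = FALSE]
  out <- data.frame(
    accession = keep$accession,
    matched_active_ids = vapply(
      keep$accession,
      function(acc) paste(matches[[acc]], collapse = ","),
      character(1)
    ),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
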