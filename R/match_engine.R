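#' Matching configuration
#'
#' @param min_matches Minimum number of seed-complement sites a transcript
#'   must carry for a reagent to count as matched (default 1). Occurrences
#'   are counted allowing overlap.
#' @return A list of class `"match_config"`.
#' @export
match_config <- function(min_matches = 1L) {
  min_matches <- as.integer(min_matches)
  if (length(min_matches) != 1L || is.na(min_matches) || min_matches < 1L) {
    stop("min_matches must be a single integer >= 1", call. = FALSE)
  }
  structure(list(min_matches = min_matches, overlap_counting = TRUE),
            class = "match_config")
}

#' Transcript-side target site of a seed
#'
#' The site searched on the transcript's sense sequence (read 5' to 3') is
#' the reverse complement of the guide-strand seed.
#'
#' @param seed Character vector of seed sequences (guide 5' to 3').
#' @return Character vector of target-site strings.
#' @export
target_site <- function(seed) {
  reverse_complement(seed)
}

#' Count perfect site occurrences in transcript sequences
#'
#' Counts every start position at which `site` occurs exactly, allowing
#' overlapping occurrences. A site longer than the transcript yields 0.
#'
#' @param site A single target-site DNA string.
#' @param transcript_seq Character vector of transcript sequences.
#' @return Integer vector of occurrence counts, one per transcript.
#' @export
count_occurrences <- function(site, transcript_seq) {
  stopifnot(length(site) == 1L, nzchar(site))
  Biostrings::vcountPattern(site, Biostrings::DNAStringSet(transcript_seq))
}

#' Build per-transcript match profiles
#'
#' Scans every transcript for the target sites of every reagent seed (all
#' sites of one analysis share the seed length, so the search uses a
#' preprocessed constant-width dictionary). A reagent's site count on a
#' transcript is the sum of occurrence counts over all of its seeds (one for
#' guide-only analyses, two when passenger seeds are included), and the
#' reagent is matched when that count reaches `cfg$min_matches`.
#'
#' @param seeds Seed data frame from [extract_reagent_seeds()] (possibly with
#'   theoretical inactives appended).
#' @param activities Named character vector mapping reagent_id to
#'   `"active"`/`"inactive"`, in reagent input order.
#' @param transcripts Transcript data frame from [read_reference_fasta()].
#' @param cfg A [match_config()].
#' @return List of match profiles, one per transcript, each a list with
#'   `accession`, `matched_active_ids`, `matched_inactive_ids`, and
#'   `site_counts` (named integer vector over all reagents).
#' @export
build_match_profiles <- function(seeds, activities, transcripts,
                                 cfg = match_config()) {
  if (nrow(transcripts) == 0L) {
    stop("no transcripts to scan", call. = FALSE)
  }
  if (!all(seeds$reagent_id %in% names(activities))) {
    stop("every seed must belong to a reagent with a known activity",
         call. = FALSE)
  }
  sites <- target_site(seeds$seed)
  site_unique <- unique(sites)
  subject <- Biostrings::DNAStringSet(transcripts$sequence)
  counts <- Biostrings::vcountPDict(
    Biostrings::PDict(Biostrings::DNAStringSet(site_unique)), subject
  )  # sites x transcripts
  per_seed <- counts[match(sites, site_unique), , drop = FALSE]
  per_reagent <- rowsum(per_seed, group = seeds$reagent_id, reorder = FALSE)
  # order rows by reagent input order
  per_reagent <- per_reagent[match(names(activities), rownames(per_reagent)), ,
                             drop = FALSE]
  rownames(per_reagent) <- names(activities)

  active_ids <- names(activities)[activities == "active"]
  inactive_ids <- names(activities)[activities == "inactive"]
  lapply(seq_len(nrow(transcripts)), function(j) {
    sc <- per_reagent[, j]
    matched <- names(sc)[sc >= cfg$min_matches]
    list(
      accession = transcripts$accession[j],
      matched_active_ids = matched[matched %in% active_ids],
      matched_inactive_ids = matched[matched %in% inactive_ids],
      site_counts = sc
    )
  })
}
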