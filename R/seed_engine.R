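#' Seed analysis configuration
#'
#' Bundles the parameters that control how guide strands and seed regions are
#' derived from reagent sequences. Defaults mirror the standard settings for
#' miRNA-like off-target analysis: a 7-nt seed taken from nucleotides 2-8 of
#' the guide (antisense) strand, with no trimming.
#'
#' @param seed_length Seed length in nucleotides; the seed occupies positions
#'   2..(1 + seed_length) from the 5' end of the guide strand. Integer in 4..12.
#' @param input_strand Which strand the input sequences represent:
#'   `"antisense"` (guide) or `"sense"` (passenger).
#' @param reagent_type `"sirna"` or `"shrna"`. Only shRNA sequences may be
#'   trimmed, because hairpin library sequences can carry extra nucleotides
#'   relative to the mature Dicer product.
#' @param trim Number of nucleotides (0-3) removed from the 3' end of each
#'   provided sequence before strand resolution. Requires
#'   `reagent_type = "shrna"` when positive.
#' @param seed_strands `"guide_only"` (default) scans with the guide-strand
#'   seed; `"both"` additionally scans with the passenger-strand seed, and a
#'   reagent matches a transcript if either seed matches.
#' @return A list of class `"seed_config"`.
#' @export
seed_config <- function(seed_length = 7L,
                        input_strand = c("antisense", "sense"),
                        reagent_type = c("sirna", "shrna"),
                        trim = 0L,
                        seed_strands = c("guide_only", "both")) {
  input_strand <- match.arg(input_strand)
  reagent_type <- match.arg(reagent_type)
  seed_length <- as.integer(seed_length)
  trim <- as.integer(trim)
  if (length(seed_length) != 1L || is.na(seed_length) ||
      seed_length < 4L || seed_length > 12L) {
    stop("seed_length must be a single integer in 4..12", call. = FALSE)
  }
  if (length(trim) != 1L || is.na(trim) || trim < 0L || trim > 3L) {
    stop("trim must be a single integer in 0..3", call. = FALSE)
  }
  if (trim > 0L && reagent_type != "shrna") {
    stop("trim > 0 is only meaningful for shRNA reagents", call. = FALSE)
  }
  structure(
    list(seed_length = seed_length, input_strand = input_strand,
         reagent_type = reagent_type, trim = trim,
         seed_strands = match.arg(seed_strands)),
    class = "seed_config"
  )
}

#' Normalize a nucleotide sequence
#'
#' Uppercases the input and maps U to T. Any residual character outside
#' A/C/G/T raises a validation error (condition class
#' `"seedscreen_validation_error"`), which the reagent parser records as
#' `illegal_character`.
#'
#' @param raw Character vector of nucleotide sequences (DNA or RNA, any case).
#' @return Character vector of uppercase DNA sequences.
#' @export
normalize_sequence <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw)) || any(!nzchar(raw))) {
    stop_validation("empty sequence")
  }
  s <- chartr("U", "T", toupper(raw))
  bad <- grepl("[^ACGT]", s)
  if (any(bad)) {
    stop_validation(sprintf("illegal character in sequence '%s'",
                            raw[which(bad)[1L]]))
  }
  s
}

stop_validation <- function(msg) {
  stop(structure(
    class = c("seedscreen_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of DNA strings (vectorized).
#'
#' @param s Character vector over the alphabet A/C/G/T.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  if (length(s) == 0L) return(character(0))
  if (any(grepl("[^ACGT]", s))) {
    stop_validation("reverse_complement requires sequences over {A,C,G,T}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Derive guide strands from reagent sequences
#'
#' Normalizes each sequence, removes `cfg$trim` nucleotides from its 3' end
#' (shRNA only), and resolves strand: antisense input is the guide as given;
#' sense input is reverse-complemented into the guide.
#'
#' @param sequence Character vector of reagent sequences as provided.
#' @param cfg A [seed_config()].
#' @return Character vector of guide-strand DNA sequences (5' to 3').
#' @export
derive_guide <- function(sequence, cfg = seed_config()) {
  s <- normalize_sequence(sequence)
  if (cfg$trim > 0L) {
    s <- substr(s, 1L, pmax(0L, nchar(s) - cfg$trim))
  }
  if (any(nchar(s) < 1L + cfg$seed_length)) {
    stop_validation("sequence too short to contain a seed after trimming")
  }
  if (cfg$input_strand == "sense") s <- reverse_complement(s)
  s
}

#' Extract the seed region from a guide strand
#'
#' The seed is the substring at positions 2..(1 + seed_length), 1-based from
#' the 5' end of the guide.
#'
#' @param guide Character vector of guide-strand DNA sequences.
#' @param seed_length Seed length in nucleotides.
#' @return Character vector of seed sequences (guide 5' to 3').
#' @export
extract_seed <- function(guide, seed_length = 7L) {
  if (any(nchar(guide) < 1L + seed_length)) {
    stop_validation(sprintf("guide shorter than %d nt; cannot extract seed",
                            1L + seed_length))
  }
  substr(guide, 2L, 1L + seed_length)
}

#' Build the seed table for a set of reagents
#'
#' One guide-strand seed per reagent; with `seed_strands = "both"` an
#' additional passenger-strand seed (positions 2..(1+L) of the reverse
#' complement of the guide) is added, and downstream matching treats the
#' reagent as matched if either seed matches.
#'
#' @param records Reagent data frame with columns `reagent_id` and `sequence`
#'   (see [parse_reagent_table()]).
#' @param cfg A [seed_config()].
#' @return Data frame with columns `reagent_id`, `seed`, `origin_strand`.
#' @export
extract_reagent_seeds <- function(records, cfg = seed_config()) {
  guide <- derive_guide(records$sequence, cfg)
  seeds <- data.frame(
    reagent_id = records$reagent_id,
    seed = extract_seed(guide, cfg$seed_length),
    origin_strand = "guide",
    stringsAsFactors = FALSE
  )
  if (cfg$seed_strands == "both") {
    passenger <- reverse_complement(guide)
    seeds <- rbind(seeds, data.frame(
      reagent_id = records$reagent_id,
      seed = extract_seed(passenger, cfg$seed_length),
      origin_strand = "passenger",
      stringsAsFactors = FALSE
    ))
  }
  seeds
}

#' Construct the theoretical inactive seed set
#'
#' When a screen provides only active reagents, a surrogate inactive set is
#' built by replacing the first nucleotide of each active seed with its
#' Watson-Crick complement (A<->T, C<->G); all other positions are unchanged.
#' Surrogate reagent ids carry the suffix `"_thinact"`.
#'
#' @param seeds Seed data frame from [extract_reagent_seeds()].
#' @return Seed data frame of the same shape with complemented first bases.
#' @export
make_theoretical_inactive <- function(seeds) {
  first <- chartr("ACGT", "TGCA", substr(seeds$seed, 1L, 1L))
  data.frame(
    reagent_id = paste0(seeds$reagent_id, "_thinact"),
    seed = paste0(first, substr(seeds$seed, 2L, nchar(seeds$seed))),
    origin_strand = seeds$origin_strand,
    stringsAsFactors = FALSE
  )
}

#' Scramble seeds for the randomized control analysis
#'
#' Replaces every seed by a uniformly random permutation of its own
#' nucleotides (Fisher-Yates, via [sample()]), preserving base composition.
#' The caller is responsible for seeding the RNG; [run_enrichment()] does this
#' from its `rng_seed` argument so that control runs are reproducible.
#'
#' @param seeds Seed data frame from [extract_reagent_seeds()].
#' @return Seed data frame with permuted seed strings.
#' @export
scramble_seeds <- function(seeds) {
  seeds$seed <- vapply(
    strsplit(seeds$seed, "", fixed = TRUE),
    function(ch) paste(sample(ch), collapse = ""),
    character(1)
  )
  seeds
}
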