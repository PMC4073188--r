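#' Specification for a synthetic screen with planted off-target structure
#'
#' Describes a synthetic transcriptome and reagent screen in which a chosen
#' number of active reagents share seed-complement sites planted into one
#' designated off-target transcript — the enrichment signature the analysis
#' is designed to detect. Defaults describe a mid-sized screen: 200
#' transcripts of about 1 kb, 30 actives and 90 inactives, 12 of the actives
#' carrying one planted site each.
#'
#' Reagents are random 21-nt guides; seeds follow the default convention
#' (7 nt, positions 2-8 of the guide).
#'
#' @param n_transcripts Number of background transcripts.
#' @param transcript_length Mean transcript length (nt).
#' @param length_sd Standard deviation of transcript lengths.
#' @param n_active,n_inactive Reagents per activity class.
#' @param n_sharing Number of active reagents whose seed complements are
#'   planted into the off-target transcript (`<= n_active`).
#' @param sites_per_sharer Planted sites per sharing reagent (>= 1);
#'   planted sites never overlap one another.
#' @param gc_content Background GC fraction.
#' @param rng_seed Integer seed; every byte of the generated FASTA and
#'   reagent table is a deterministic function of the spec.
#' @return A list of class `"plant_spec"`.
#' @export
plant_spec <- function(n_transcripts = 200L,
                       transcript_length = 1000L,
                       length_sd = 150L,
                       n_active = 30L,
                       n_inactive = 90L,
                       n_sharing = 12L,
                       sites_per_sharer = 1L,
                       gc_content = 0.45,
                       rng_seed = 1L) {
  spec <- list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    length_sd = as.numeric(length_sd),
    n_active = as.integer(n_active),
    n_inactive = as.integer(n_inactive),
    n_sharing = as.integer(n_sharing),
    sites_per_sharer = as.integer(sites_per_sharer),
    gc_content = as.numeric(gc_content),
    rng_seed = as.integer(rng_seed),
    guide_length = 21L,
    seed_length = 7L
  )
  stopifnot(spec$n_transcripts >= 1L, spec$n_active >= 1L,
            spec$n_inactive >= 0L, spec$n_sharing >= 0L,
            spec$n_sharing <= spec$n_active, spec$sites_per_sharer >= 1L,
            spec$gc_content > 0, spec$gc_content < 1)
  structure(spec, class = "plant_spec")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Deterministic reagent guides for a spec: actives first (sharers are the
# first n_sharing), then inactives whose seed-complement sites are resampled
# until they collide with none of the planted sites. Seeds the RNG itself.
synth_guides <- function(spec) {
  set.seed(spec$rng_seed)
  uniform_guide <- function() {
    paste(sample(c("A", "C", "G", "T"), spec$guide_length, replace = TRUE),
          collapse = "")
  }
  active <- vapply(seq_len(spec$n_active), function(i) uniform_guide(),
                   character(1))
  planted_sites <- target_site(
    extract_seed(active[seq_len(spec$n_sharing)], spec$seed_length))
  inactive <- character(spec$n_inactive)
  for (i in seq_len(spec$n_inactive)) {
    repeat {
      g <- uniform_guide()
      if (!(target_site(extract_seed(g, spec$seed_length)) %in% planted_sites))
        break
    }
    inactive[i] <- g
  }
  list(active = active, inactive = inactive, planted_sites = planted_sites)
}

#' Generate a synthetic transcriptome with planted off-target sites
#'
#' Background transcripts are i.i.d. bases at the spec's GC content. The
#' first transcript is the designated off-target: for each sharing active
#' reagent, `sites_per_sharer` copies of that reagent's seed-complement site
#' are embedded at non-overlapping random positions.
#'
#' @param spec A [plant_spec()].
#' @return List with `transcripts` (data frame as from
#'   [read_reference_fasta()]) and `off_target` (the designated accession).
#' @export
generate_transcriptome <- function(spec) {
  guides <- synth_guides(spec)
  set.seed((spec$rng_seed + 1L) %% .Machine$integer.max)
  len <- pmax(300L, as.integer(round(stats::rnorm(
    spec$n_transcripts, spec$transcript_length, spec$length_sd))))
  seqs <- vapply(len, random_dna, character(1), gc = spec$gc_content)

  sites <- rep(guides$planted_sites, each = spec$sites_per_sharer)
  if (length(sites) > 0L) {
    w <- nchar(sites[[1L]])
    L <- len[[1L]]
    starts <- sample(seq_len(L - w + 1L))
    chosen <- integer(0)
    for (s in starts) {
      if (all(abs(s - chosen) >= w)) chosen <- c(chosen, s)
      if (length(chosen) == length(sites)) break
    }
    if (length(chosen) < length(sites)) {
      stop("off-target transcript too short to host all planted sites",
           call. = FALSE)
    }
    target <- seqs[[1L]]
    for (i in seq_along(sites)) {
      substr(target, chosen[i], chosen[i] + w - 1L) <- sites[i]
    }
    seqs[[1L]] <- target
  }
  acc <- sprintf("TX%04d", seq_len(spec$n_transcripts))
  transcripts <- data.frame(
    accession = acc,
    description = c("synthetic off-target transcript",
                    rep("synthetic background transcript",
                        spec$n_transcripts - 1L)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  list(transcripts = transcripts, off_target = acc[[1L]])
}

#' Generate a synthetic reagent screen table
#'
#' Writes a tab-delimited reagent table in the active-and-inactive layout
#' (columns id, sequence, activity; guide/antisense 21-mers) matching the
#' transcriptome generated from the same spec: the first `n_sharing` actives
#' are the reagents whose seed complements are planted into the off-target
#' transcript.
#'
#' @param spec A [plant_spec()].
#' @param path Output path for the reagent table.
#' @return `path`, invisibly; the written table parses cleanly with
#'   [parse_reagent_table()].
#' @export
generate_screen <- function(spec, path) {
  guides <- synth_guides(spec)
  df <- data.frame(
    reagent_id = c(sprintf("ACT_%03d", seq_len(spec$n_active)),
                   sprintf("INACT_%03d", seq_len(spec$n_inactive))),
    sequence = c(guides$active, guides$inactive),
    activity = c(rep("active", spec$n_active),
                 rep("inactive", spec$n_inactive)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
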