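#' Run the seed-match enrichment analysis
#'
#' End-to-end pipeline: guide derivation, seed extraction, optional
#' theoretical-inactive construction (actives-only layout) and seed
#' scrambling (control run), transcript scanning, per-transcript 2x2
#' contingency tests with the Fisher/Yates selection rule, and ranking with
#' Bonferroni/Holm/BH correction.
#'
#' @param records Reagent data frame (`reagent_id`, `sequence`, `activity`)
#'   from [parse_reagent_table()], malformed rows already removed.
#' @param transcripts Transcript data frame from [read_reference_fasta()].
#' @param seed_cfg A [seed_config()].
#' @param match_cfg A [match_config()].
#' @param alpha Significance level (default 0.05); also the inclusion
#'   threshold of the match-detail output.
#' @param layout `"active_and_inactive"` uses the provided activity labels;
#'   `"active_only"` requires all records active and pairs them with a
#'   theoretical inactive set built by [make_theoretical_inactive()].
#' @param scramble If `TRUE`, every seed (active and inactive alike) is
#'   replaced by a random permutation of itself before matching — the
#'   randomized control analysis. Requires `rng_seed`.
#' @param rng_seed Integer seed for the scramble RNG; recorded in the run
#'   summary so control runs are reproducible.
#' @return List with `results` (ranked per-transcript data frame, see
#'   [write_enrichment_table()] for columns), `match_detail` (named list:
#'   accession to matching active reagent ids, only for transcripts with
#'   `p_selected <= alpha`), and `summary` (parameters and counts).
#' @export
run_enrichment <- function(records, transcripts,
                           seed_cfg = seed_config(),
                           match_cfg = match_config(),
                           alpha = 0.05,
                           layout = c("active_and_inactive", "active_only"),
                           scramble = FALSE,
                           rng_seed = NULL) {
  layout <- match.arg(layout)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (nrow(records) == 0L || !any(records$activity == "active")) {
    stop("no usable active reagents", call. = FALSE)
  }
  if (layout == "active_only" && any(records$activity != "active")) {
    stop("active_only layout but inactive records present", call. = FALSE)
  }
  if (layout == "active_and_inactive" && !any(records$activity == "inactive")) {
    stop("active_and_inactive layout requires at least one inactive reagent",
         call. = FALSE)
  }
  if (scramble && is.null(rng_seed)) {
    stop("scramble = TRUE requires an explicit rng_seed", call. = FALSE)
  }

  seeds <- extract_reagent_seeds(records, seed_cfg)
  activities <- stats::setNames(records$activity, records$reagent_id)
  if (layout == "active_only") {
    thinact <- make_theoretical_inactive(seeds)
    seeds <- rbind(seeds, thinact)
    activities <- c(activities,
                    stats::setNames(rep("inactive", nrow(records)),
                                    paste0(records$reagent_id, "_thinact")))
  }
  if (scramble) {
    set.seed(as.integer(rng_seed))
    seeds <- scramble_seeds(seeds)
  }

  profiles <- build_match_profiles(seeds, activities, transcripts, match_cfg)
  n_active <- sum(activities == "active")
  n_inactive <- sum(activities == "inactive")

  fisher_cache <- new.env(parent = emptyenv())
  rows <- lapply(profiles, function(pr) {
    tab <- build_contingency(pr, n_active, n_inactive)
    key <- paste(tab$a, tab$c, sep = ":")
    p <- get0(key, envir = fisher_cache)
    if (is.null(p)) {
      p <- c(fisher_exact_two_sided(tab), yates_chi_square(tab))
      assign(key, p, envir = fisher_cache)
    }
    sel <- select_pvalue(tab, p[[1L]], p[[2L]])
    data.frame(
      accession = pr$accession,
      n_active_matched = tab$a,
      smf_active = tab$a / n_active,
      n_inactive_matched = tab$c,
      smf_inactive = tab$c / n_inactive,
      p_fisher = p[[1L]],
      p_yates = p[[2L]],
      p_selected = sel$p_selected,
      selected_test = sel$selected_test,
      stringsAsFactors = FALSE
    )
  })
  results <- do.call(rbind, rows)
  results$description <- transcripts$description[
    match(results$accession, transcripts$accession)]
  results <- rank_and_adjust(results, alpha)
  results <- results[, c(
    "accession", "description", "n_active_matched", "smf_active",
    "n_inactive_matched", "smf_inactive", "p_fisher", "p_yates",
    "p_selected", "selected_test", "rank", "p_bonferroni", "p_holm",
    "p_bh", "sig_bonferroni", "sig_holm", "sig_bh")]

  sig_acc <- results$accession[results$p_selected <= alpha]
  detail <- stats::setNames(lapply(profiles, `[[`, "matched_active_ids"),
                            vapply(profiles, `[[`, "", "accession"))
  match_detail <- detail[names(detail) %in% sig_acc]

  summary <- list(
    layout = layout,
    n_active = n_active,
    n_inactive = n_inactive,
    n_theoretical_inactive = if (layout == "active_only") nrow(records) else 0L,
    n_transcripts = nrow(transcripts),
    parameters = list(
      seed_length = seed_cfg$seed_length,
      input_strand = seed_cfg$input_strand,
      reagent_type = seed_cfg$reagent_type,
      trim = seed_cfg$trim,
      seed_strands = seed_cfg$seed_strands,
      min_matches = match_cfg$min_matches,
      alpha = alpha
    ),
    scramble = scramble,
    rng_seed = if (is.null(rng_seed)) NA_integer_ else as.integer(rng_seed),
    version = as.character(utils::packageVersion("seedscreen"))
  )
  list(results = results, match_detail = match_detail, summary = summary)
}
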