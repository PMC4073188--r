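#' Build the 2x2 contingency table for one transcript
#'
#' Rows are reagent activity (active / inactive), columns are matched /
#' unmatched: `a` actives matched, `b` actives unmatched, `c` inactives
#' matched, `d` inactives unmatched.
#'
#' @param profile A match profile from [build_match_profiles()].
#' @param n_active,n_inactive Total reagents per class (each >= 1).
#' @return Named list `(a, b, c, d)` of class `"contingency_table"`.
#' @export
build_contingency <- function(profile, n_active, n_inactive) {
  a <- length(profile$matched_active_ids)
  c_ <- length(profile$matched_inactive_ids)
  if (a > n_active || c_ > n_inactive) {
    stop("matched counts exceed class totals; inconsistent profile",
         call. = FALSE)
  }
  structure(list(a = a, b = n_active - a, c = c_, d = n_inactive - c_),
            class = "contingency_table")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass method: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table (comparison with relative tolerance 1e-7 to
#' absorb floating-point noise). A table with any zero margin has a single
#' compatible configuration and returns 1.
#'
#' @param t A `"contingency_table"` or a list with elements `a`, `b`, `c`, `d`.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(t) {
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0L || n == 0L || k == 0L || b + d == 0L) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Yates continuity-corrected chi-square test for a 2x2 table
#'
#' Statistic `N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' `N = a+b+c+d`, referred to the upper tail of the chi-square distribution
#' with 1 degree of freedom. Any zero margin returns p = 1.
#'
#' @param t A `"contingency_table"` or a list with elements `a`, `b`, `c`, `d`.
#' @return The p-value.
#' @export
yates_chi_square <- function(t) {
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  N <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0L)) return(1)
  stat <- N * max(0, abs(a * d - b * c_) - N / 2)^2 / prod(margins)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Select between the Fisher and Yates p-values
#'
#' The Fisher exact p-value is used when the sample is small in the usual
#' chi-square-validity sense: any expected cell count below 5, or total
#' N below 40. Otherwise the Yates chi-square p-value is used.
#'
#' @param t A `"contingency_table"`.
#' @param p_fisher,p_yates The two candidate p-values.
#' @return List with `p_selected` and `selected_test` (`"fisher"`/`"yates"`).
#' @export
select_pvalue <- function(t, p_fisher, p_yates) {
  N <- t$a + t$b + t$c + t$d
  expected <- outer(c(t$a + t$b, t$c + t$d), c(t$a + t$c, t$b + t$d)) / N
  small <- N < 40 || any(expected < 5)
  if (small) list(p_selected = p_fisher, selected_test = "fisher")
  else list(p_selected = p_yates, selected_test = "yates")
}

#' Rank transcripts and adjust for multiple testing
#'
#' Sorts ascending by selected p-value (accession breaks ties
#' deterministically), assigns ranks 1..m, and computes Bonferroni, Holm
#' (Bonferroni step-down) and Benjamini-Hochberg adjusted p-values via
#' [stats::p.adjust()]. Significance flags compare each adjusted p-value to
#' `alpha`.
#'
#' @param results Data frame of per-transcript results carrying at least
#'   `accession` and `p_selected`.
#' @param alpha Significance level for the `sig_*` flags (default 0.05).
#' @return The data frame in rank order with `rank`, `p_bonferroni`,
#'   `p_holm`, `p_bh`, `sig_bonferroni`, `sig_holm`, `sig_bh` added.
#' @export
rank_and_adjust <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 1L)
  ord <- order(results$p_selected, results$accession)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  results$rank <- seq_len(nrow(results))
  results$p_bonferroni <- stats::p.adjust(results$p_selected, "bonferroni")
  results$p_holm <- stats::p.adjust(results$p_selected, "holm")
  results$p_bh <- stats::p.adjust(results$p_selected, "BH")
  results$sig_bonferroni <- results$p_bonferroni <= alpha
  results$sig_holm <- results$p_holm <= alpha
  results$sig_bh <- results$p_bh <= alpha
  results
}
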