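---
title: "Seed-match enrichment analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-match enrichment analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

## The model

RNAi reagents can act like microRNAs: the guide strand's seed region —
nucleotides 2 to 8 from its 5' end, by default — pairs with complementary
sites in transcripts (canonically 3'UTRs) and silences them. When one
transcript carries seed-complement sites for many of the reagents that
scored in a screen, the parsimonious explanation is that those reagents are
hits *because* they silence that transcript, not their intended targets.

`seedscreen` formalizes this as a per-transcript association test. Each
reagent is either *active* (scored) or *inactive*, and either *matched*
(its seed's reverse complement occurs at least `min_matches` times in the
transcript) or unmatched. The resulting 2×2 table

|            | matched | unmatched |
|------------|---------|-----------|
| active     | a       | b         |
| inactive   | c       | d         |

is tested for independence two ways: the two-sided Fisher exact test
(probability-mass convention: the p-value sums the hypergeometric
probabilities of all tables with the observed margins that are at most as
probable as the observed one) and the Yates continuity-corrected chi-square
test with statistic

$$X^2 = \frac{N\,\big(\max(0,\ |ad-bc| - N/2)\big)^2}{(a+b)(c+d)(a+c)(b+d)},
\qquad N = a+b+c+d,$$

referred to $\chi^2_1$. The *selected* p-value is Fisher's when the sample
is small in the textbook chi-square-validity sense — any expected cell
count below 5, or $N < 40$ — and Yates' otherwise; the choice is recorded
per transcript in the `selected_test` column. Transcripts are ranked by the
selected p-value (ties broken by accession so runs are reproducible) and
adjusted with Bonferroni, Holm (the step-down Bonferroni) and
Benjamini–Hochberg, via `stats::p.adjust`. The seed match frequencies
`smf_active = a/(a+b)` and `smf_inactive = c/(c+d)` are reported as
fractions in [0, 1].

Matching is exact string matching of the full-length seed complement on the
transcript's sense strand, with overlapping occurrences counted — there is
no wobble pairing, no mismatch tolerance, and no site-type hierarchy. With
the default `min_matches = 1` overlap counting is consequence-free; for
larger thresholds it means tandem overlapping sites each count.

## Assumptions and what the method does not do

- Region selection is the user's job: the reference FASTA is searched along
  its full length, so supply 3'UTRs if 3'UTRs are what you mean.
- Every reagent contributes one seed (or two, with
  `seed_strands = "both"`); strand selection thermodynamics, expression
  levels and site context are all out of scope.
- Results are per transcript. Collapsing transcripts of a gene is left to
  post-processing.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `seed_length` | 7 nt | seed occupies guide positions 2..(1+L); 4–12 allowed |
| `input_strand` | `antisense` | whether input sequences are guide or passenger strands |
| `reagent_type` | `sirna` | `shrna` enables trimming |
| `trim` | 0 | 0–3 nt removed from the 3' end of each provided sequence (shRNA libraries may include overhangs relative to the mature Dicer product) |
| `seed_strands` | `guide_only` | `both` also scans the passenger-strand seed; a reagent matches if either seed matches |
| `min_matches` | 1 site | sites per transcript needed to call a reagent matched |
| `alpha` | 0.05 | threshold for the significance flags and the match-detail file |

Trimming removes nucleotides from the 3' end of the sequence *as provided*,
before strand resolution. Which end hairpin libraries pad is
library-specific; the 3' end was chosen because Dicer cleavage defines the
mature duplex ends there, and the option is explicit so users who know
their library can set `trim = 0` and pre-trim themselves.

## Input handling

Reagent tables are tab- or comma-delimited, two columns (id, sequence) for
actives-only screens or three (id, sequence, activity) otherwise. Activity
tokens accepted case-insensitively: `active`/`1`/`yes`/`with phenotype`
versus `inactive`/`0`/`no`/`without phenotype`. A header row is detected by
the convention that the sequence field of the first row is not a valid
nucleotide string — which means a *malformed* first data row is silently
absorbed as a header; keep headers on your files and this ambiguity never
arises. Malformed rows (missing sequence, illegal characters, too short to
yield a seed, missing or unrecognized activity) are excluded and counted;
if more than 25% of rows are malformed (strictly — exactly 25% proceeds)
the run aborts with the error kinds and up to five example lines, otherwise
the ignored line numbers are listed in the run summary. U is mapped to T
and case is normalized everywhere; reference FASTA records containing any
other character (e.g. N) are skipped and counted, and duplicate accessions
are deterministically suffixed `__2`, `__3`, ….

## Actives-only screens and the scrambled control

Without inactive reagents there is no comparison class, so a *theoretical
inactive* set is built: each active seed is copied with its first
nucleotide replaced by the Watson–Crick complement (a substitution at seed
position 1 only — the seed is not reversed or shifted), one surrogate per
active seed, ids suffixed `_thinact`. This preserves the size and, roughly,
the composition of the active set while destroying position-1-anchored
matching.

The scrambled control replaces every seed (actives and inactives alike) by
a uniformly random permutation of its own bases — `sample()`'s Fisher–Yates
shuffle — preserving base composition. Permutations equal to the original
seed are kept; rejecting them would bias the permutation distribution. A
control run is a separate invocation with `--scramble --rng-seed <int>`;
the RNG is seeded once from `rng_seed` at the start of the run, so control
results are exactly reproducible and two runs with the same inputs and seed
produce byte-identical files (the run summary deliberately contains no
timestamp).

## Numerical choices

- Fisher's two-sided sum uses a relative tolerance of 1e-7 when comparing
  table probabilities to the observed one, absorbing floating-point noise
  in `dhyper`; the implementation agrees with an exact enumeration oracle
  to < 1e-10 over every table with N ≤ 40.
- Any zero-margin table returns p = 1 for both tests (a degenerate table
  carries no evidence), and the Yates statistic clamps to zero when
  |ad − bc| ≤ N/2 rather than going negative.
- The per-run Fisher/Yates pair is memoized on (a, c): within one analysis
  all transcripts share the same margins, so only distinct matched-count
  pairs are computed.
- Output tables print numbers at 6 significant digits, fixed notation, with
  p-values below 1e-4 switching to scientific notation; re-reading a
  written table reproduces every numeric column at that precision.
- Site search uses a constant-width Aho–Corasick dictionary
  (`Biostrings::PDict`) over the unique target sites; its counts are
  contract-tested against a naive per-position scan.

## The synthetic screen generator

`plant_spec()` describes a screen whose off-target signature is known by
construction: background transcripts are i.i.d. bases at a set GC content,
and one designated transcript additionally carries, for each of
`n_sharing` active reagents, `sites_per_sharer` non-overlapping copies of
that reagent's seed complement. Inactive guides are resampled until their
seed complements collide with none of the planted sites — but they are
*not* screened against chance background occurrences, which are part of
the tested regime.

Defaults — 200 transcripts of mean length 1000 nt (sd 150, floor 300 nt),
GC 0.45, 30 actives, 90 inactives, 12 sharers with one site each, 21-nt
guides — describe a mid-sized cell-based screen with a moderately strong
off-target cluster: a 3:1 inactive:active ratio is typical of annotated
hit lists, ~1 kb is a realistic mammalian 3'UTR length, and 12/30 actives
sharing one off-target matches the situation the method is designed to
flag. Under these conditions the planted transcript is ranked first and
BH-significant at α = 0.05 in ≥ 95% of seeded replicates, and with no
planted structure (`n_sharing = 0`) it is BH-significant in ≤ 5% — both
properties are exercised by the test suite over 20 and 40 seeds
respectively, and recomputed by `scripts/acceptance.R`.

What the generator does not emulate: real screens have non-uniform base
composition, 3'UTR length distributions far from Gaussian, correlated
reagent designs (several reagents per gene), and quantitative activity
scores thresholded into classes. Passing the recovery property therefore
shows the pipeline detects the enrichment signature it defines, not that
any particular biological screen will yield significant calls.

## Validation problem sizes

The test suite runs the Fisher implementation against exhaustive
enumeration over all 2×2 tables with N ≤ 40, the matcher against a naive
scan on 500 random transcript/seed instances (transcripts up to 2 kb), the
correction procedures against step-by-step oracles on 1000 random
p-vectors, and the end-to-end recovery/null properties on 20 + 40 seeded
synthetic screens at the default spec. These sizes make the whole suite
run in a few minutes on a single core while leaving each property's
evidence exhaustive (Fisher) or comfortably replicated (everything else).

## Known limitations

- Transcript-level only; no gene-level aggregation or annotation joining —
  the FASTA description line is carried through instead of gene symbols.
- A single fixed-length perfect-match site model; no 6mer/8mer hierarchy,
  conservation or context scores, so it is a triage tool, not a target
  predictor.
- The discrete tests are conservative at small counts; with few reagents
  the scrambled control is the better yardstick than the nominal α.
- `.xlsx` input is not read; export spreadsheets to tab- or comma-delimited
  text first.
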