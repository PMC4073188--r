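# seedscreen

Seed-match enrichment analysis for triaging RNAi screen hit lists.

## The problem

siRNA and shRNA reagents silence unintended transcripts through miRNA-like
off-target effects: the guide strand's *seed region* (nucleotides 2–8 from
its 5' end) pairs with complementary sites, typically in 3'UTRs, and
down-regulates those transcripts. In a large screen, many "active" reagents
can owe their phenotype to the same off-targeted transcript rather than
their intended genes, producing clusters of false-positive hits.
`seedscreen` is for screeners who want to flag such candidate off-targeted
transcripts before investing in follow-up validation.

## The method

Reagents are split into **active** (scored in the screen) and **inactive**
classes. For each reagent the guide-strand seed is extracted and its reverse
complement is searched, as an exact string, in every transcript of a
user-supplied reference FASTA (3'UTRs recommended). For a transcript *t*
with *a* of *n*₊ active and *c* of *n*₋ inactive reagents matched (at least
`min_matches` sites each), the seed match frequencies are

SMF₊ = a / n₊  and  SMF₋ = c / n₋

and enrichment of matches among actives is tested on the 2×2 table
(a, n₊−a; c, n₋−c) with the two-sided Fisher exact test and the Yates
continuity-corrected chi-square test. The Fisher p-value is selected when
the sample is small (any expected cell count < 5, or N < 40), otherwise the
Yates p-value. Transcripts are ranked by the selected p-value and adjusted
with the Bonferroni, Holm (Bonferroni step-down) and Benjamini–Hochberg
procedures.

If only active reagents are available, a *theoretical inactive* set is
constructed by replacing the first nucleotide of each active seed with its
complement. A scrambled-seed control run (every seed replaced by a random
permutation of itself) gives a sense of how strong purely coincidental
outliers are.

## Worked example

The built-in generator creates a synthetic screen in which 12 of 30 active
reagents carry seed-complement sites planted into one designated transcript
(`TX0001`) among 200 decoys — the signature the analysis is meant to find:

```r
library(seedscreen)

spec <- plant_spec(rng_seed = 1)                      # 200 transcripts, 30+90 reagents
tx <- generate_transcriptome(spec)
generate_screen(spec, "reagents.tsv")

parsed <- parse_reagent_table("reagents.tsv", layout = "active_and_inactive")
run <- run_enrichment(parsed$records, tx$transcripts)
head(run$results[, c("accession", "n_active_matched", "smf_active",
  "n_inactive_matched", "smf_inactive", "p_selected", "selected_test",
  "rank", "p_bh", "sig_bh")], 3)
```

```
  accession n_active_matched smf_active n_inactive_matched smf_inactive
1    TX0001               12      0.400                  6       0.0667
2    TX0190                7      0.233                  5       0.0556
3    TX0110                4      0.133                  1       0.0111
  p_selected selected_test rank  p_bh sig_bh
1   5.48e-05        fisher    1 0.011   TRUE
2   1.01e-02        fisher    2 0.913  FALSE
3   1.37e-02        fisher    3 0.913  FALSE
```

The planted transcript is ranked first: 12/30 actives match it (SMF₊ = 0.40)
against 6/90 inactives (SMF₋ = 0.067), and it is the only transcript that
stays significant after Benjamini–Hochberg correction
(`run$match_detail[["TX0001"]]` lists the twelve matching active reagents,
`ACT_001`…`ACT_012`). The decoys behind it are chance seed matches and do
not survive correction.

The same analysis from a shell:

```sh
Rscript exec/seedscreen --input reagents.tsv --reference transcripts.fasta \
    --layout both --strand antisense --out-prefix myrun
```

writes `myrun.enrichment.tsv` (all transcripts, ranked),
`myrun.matches.tsv` (matching active reagents for transcripts with selected
p ≤ 0.05) and `myrun.summary.json` (every effective parameter and the
counts of used/ignored reagents). Add `--scramble --rng-seed <int>` for the
control run.

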