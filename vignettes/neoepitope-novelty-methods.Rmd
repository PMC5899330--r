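---
title: "Neoepitope novelty metrics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoepitope novelty metrics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoprior)
```

## The problem

MHC class I neoepitope callers emit every mutated peptide window that is
predicted to bind a patient's HLA alleles — typically far more
candidates than can be validated or vaccinated against. The working
hypothesis behind this package is that a neoepitope's immunogenicity
tracks its *novelty*: how different it looks from what the immune system
has already tolerized against. Novelty is quantified along four axes —
against the paired normal epitope (binding and sequence), against the
whole human proteome, and against bacterial and viral peptides — and
those axes feed population-level accounting and a simple linear model of
peptide-specific immune response.

Everything operates at the protein level on missense variants. Upstream
steps (variant calling, annotation, HLA typing, MHC binding prediction)
are consumed as files, never run.

## The four metrics and their assumptions

### 1. Paired binding-affinity difference

`affinity_difference(normal, tumor)` is `normal − tumor` in nM, positive
when the mutation *improves* binding. The *putatively novel binding
change* classifier (`is_novel_binding`) requires three conditions at
once:

* tumor affinity strictly below the strong-binder threshold (500 nM);
* normal affinity at or above that threshold;
* normal/tumor ratio at least the fold-change threshold (5).

Boundary inclusivity is a literal reading of the rule's wording
("below", "minimum", "at least"): tumor `< 500`, normal `>= 500`, ratio
`>= 5`. The exhaustive boundary grid `tumor ∈ {499, 500, 501} ×
normal ∈ {2494, 2495, 2500, 2505}` is asserted in the acceptance suite.
Both thresholds live in `novelty_config()` because the bare `< 500 nM`
strong-binder convention is reused alone by the HLA-overlap analysis.
Ratios are evaluated on the raw input affinities; no rounding is
applied. Missing (peptide, allele) affinities are errors, never imputed
— silent imputation would bias every population statistic built on the
flags.

### 2. Anchor-masked self-normalized similarity

`blosum_score(a, b, mask)` sums BLOSUM62 entries over unmasked
positions; `percent_similarity(q, s, mask)` is
`100 · S(q, s) / S(q, q)`. The mask defaults to
`anchor_positions(k) = {2, k}`: the residues anchored in the MHC groove,
least accessible to T-cell receptors. Two deliberate choices:

* **Mask generalization.** Anchors are classically defined for 9mers;
  this package applies the same `{2, last}` rule to 8/10/11mers. That is
  a direct generalization, not an established convention — which is why
  every scoring function accepts an arbitrary mask and
  `pipeline_config(anchor_masks = ...)` can override it per length.
* **Denominator masking.** The self-score in the denominator uses the
  *same* mask as the numerator. Each percent scale is then internally
  consistent and bounded by 100 through the diagonal dominance of
  BLOSUM62 (`m[a,a] ≥ m[a,b]`, verified over all 400 standard residue
  pairs at load time and in the tests).

The bundled matrix is the standard NCBI half-bit integer BLOSUM62 over
the 20 standard letters plus the ambiguity codes B, Z, X (scored with
their standard rows; any other letter is rejected — matching the blastp
alphabet and avoiding silent miscoding). Percent similarities can be
negative; only the upper bound of 100 is structural. Mismatch counts are
plain Hamming distances over *all* positions — anchor masking never
applies to them.

### 3–4. Closest human / microbial peptide

`search_closest()` is an exact replacement for a blastp "protein-protein,
local, ungapped" search at fixed alignment length k = 9: every length-k
window of the database is scored with the all-residue BLOSUM62 sum and
all windows attaining the maximum are returned. The equivalence rests on
a monotonicity argument: at fixed query length, alignment length, and
database size, the blastp E-value is a strictly decreasing function of
the raw score, so "lowest E-value" and "highest raw score" select the
same hits. The historical E-value cap (200,000) only kept weak hits
visible in BLAST output and cannot affect the top hit; it is carried in
`pipeline_config()` for provenance and never used.

Numerical/determinism choices:

* **Ranking scale.** Ranking uses all k residues (as blastp does);
  *both* percent-similarity variants (non-anchor and all-residue) are
  reported per hit, and the "microbial closer than both human
  comparators" flags are computed on each scale separately, because
  either scale is a defensible reading of the published comparison.
* **Ties.** Identical tied subject sequences are collapsed into one row
  carrying all origins; rows are sorted by subject sequence, making
  results invariant under database record permutation (tested).
* **Match status.** `gene_match_status()` returns "matching" if *any*
  tied top hit originates from the query's gene. With ties the published
  rule ("a top match") is ambiguous; the any-tie rule is the documented
  choice here.
* **No-hits.** An exhaustive search over a non-empty database always has
  a top hit, so no-hits can only arise from an empty database. In batch
  profiling an absent/empty database yields explicit `NA` no-hit markers
  rather than an error.
* When tied human subjects exist and an affinity comparison against the
  matched human peptide is requested, the first tied subject (sorted
  order) present in the affinity table is used.

The search is exhaustive by design — correctness first; desk-scale
databases make it cheap, and every result is checked against a naive
double-loop oracle in the tests.

## Epitope-pair enumeration

For a missense variant at protein position p and length k,
`enumerate_epitope_pairs()` emits every length-k window containing p
that lies fully inside the protein (window starts
`max(1, p − k + 1) … min(p, L − k + 1)`), ordered by (length, start).
Interior mutations give exactly k windows per length — the classical
"9mers from a 17-mer" construction. Positions are 1-based, windows are
closed intervals, matching protein-coordinate conventions of VEP-style
annotation. Truncation at protein ends is handled by the start-range
formula; reference-mismatch and synonymous inputs are hard errors (or
skipped with a log line under `--skip-bad` in the CLI).

## Population metrics

`recurrence_counts()` deduplicates within patient first, then counts
*distinct patients* per sequence (overall and within disease) — not
occurrence rows, which is the documented resolution of an ambiguity in
how repetition rates are usually quoted. `sample_allele_sets()` draws
2 + 2 + 2 alleles without replacement per gene, independently across
genes; each set uses a substream seed derived from (seed, set index), so
set i is stable regardless of how many sets are requested.
`overlap_spectrum()` calls an epitope a binder of an allele iff its
affinity is strictly `< 500 nM` (consistent with the strong-binder
convention; configurable) and reports exact-k counts that provably
partition the total — an identity asserted on every fixture.

## The immunogenicity model

Responses are binarized per source study (`binarize_response`):
a strict `> 10%` threshold on neoantigen-specific T-cell percentages
where continuous data exist, pass-through booleans where only binary
data exist, clonal-expansion-only for the study that also reported
ELISpot reactivity (reactivity without expansion is a non-responder),
and co-culture T-cell reactivity for the remaining two. Incomplete
records are dropped with a logged count.

The model is ordinary least squares on the 0/1 response — a linear
probability model, kept deliberately because that is how the published
analysis was specified; `logistic = TRUE` offers the standard
alternative. Three shapes:

* single predictor (per-metric significance screens);
* the full nine-term additive model (neoepitope affinity, novel-binding
  flag, paired and closest-human affinity differences, paired mismatch
  count, and the four percent similarities);
* the reduced "multiplicative" model: the four retained predictors
  (`neo_affinity`, `sim_viral`, `human_match_diff`,
  `mismatches_paired`) under R's full factorial `*` expansion (16
  coefficients). The exact term set of the published reduced model lives
  in supplementary material not shipped with the paper's text; the full
  factorial expansion is the most literal reading of "multiplicative" in
  an `lm` context and the term set is overridable via `terms =`.

Per-term two-sided t p-values, adjusted R², and the overall F-test
p-value are reported. No train/test split is imposed (in-sample AUROC
mirrors the published evaluation); records evaluated against several
alleles stay one record per (peptide, allele). `auroc()` is the
rank-based Mann-Whitney statistic with ties counted ½ — exactly the
probability a random responder outranks a random non-responder — and is
verified against brute-force pair counting to 1e-12.

## What the synthetic generators emulate — and what they do not

`generate_proteome()` draws i.i.d. uniform residues (weights
configurable): it reproduces the *geometry* of a proteome (record
structure, window counts, gene annotations), not its composition,
homology structure, or repeat content. `simulate_neoepitopes()`
implements the null model: windows uniform over all length-k windows (not
over proteins), substitution position uniform over 1..k, substituted
letter uniform over the 19 non-original letters. A "substitution" that
repeats the original residue would be protein-level synonymous, so it is
excluded — a documented decision where the published description is
silent.

`pseudo_affinity()` is a pure positional hash, not a learned predictor:
each (allele, position, residue) combination hashes to a unit score,
anchor positions carry 3× weight (so anchor mutations swing affinity, and
novel-binding cases arise at realistic rarity), and the weighted mean is
mapped log-uniformly onto [1, 50000] nM. It exists so pipelines are
executable and deterministic without external tools; it encodes no
biology.

`generate_cohort()` draws affinities log-uniform on [1, 50000] nM and
percent similarities from normals with the field-typical means/sds
(paired 83.5 (6.3), human 84.3 (10.7), bacterial 91.4 (6.6), viral
76.7 (9.1), truncated at 100), forms a latent linear score from known
coefficients, adds Gaussian noise, and thresholds at the quantile giving
a 30% responder prevalence. The generating truth is returned so
coefficient recovery (within 3 reported SEs at n = 5000 over 20 seeded
replicates) is a testable contract.

Hence a green suite establishes *algorithmic correctness against
independent oracles and stated invariants* — it does not establish any
biological effect size, and none of the published cohort-scale numbers
(novel-binding rates, match-rate percentages, AUROC on the real
419-peptide cohort) are claimed or reproduced here; they require
external data at scales this package's fixtures deliberately do not
emulate.

## Numerical and interface choices

* All randomness flows through explicit integer seeds; generators use
  isolated RNG state (`withr::with_seed`) and never disturb the caller's
  stream. Substream seeds stay below 2^31.
* Integer scoring throughout (BLOSUM sums are exact); percent
  similarities are the only derived floats, and test tolerances are
  dominated by the 1e-12 AUROC agreement bound.
* TSV (tab-separated, header, UTF-8, `.` for missing) is the interchange
  format; FASTA for sequence databases (gene ids via a `gene=` token in
  the description line, defaulting to the protein id). Config files are
  JSON — the YAML option was dropped because no YAML parser is a
  declared dependency — with unknown keys rejected.
* Every CLI output gets a `.manifest.json` with the package version,
  config hash and input/output MD5s; logging goes to standard error and
  never alters outputs.
* Degenerate inputs fail loudly and early: empty databases, single-class
  cohorts, rank-deficient or underdetermined designs, non-positive
  affinities, unknown letters, masks outside the window.

## Known limitations

* Protein-level only: no nucleotide reconstruction, no frameshift,
  indel, or fusion epitopes.
* The ungapped fixed-length search is exact but O(#windows) per query;
  it targets desk-scale databases, not nr-scale ones.
* The anchor-mask generalization beyond 9mers and the any-tie matching
  rule are documented choices where the published method is silent.
* Expression levels and variant allele frequencies are not modeled.
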