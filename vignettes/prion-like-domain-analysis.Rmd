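---
title: "Detecting and characterizing prion-like domains in bacterial proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing prion-like domains in bacterial proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prdscan)
```

## The problem

Prion-like domains (PrDs) are low-complexity protein regions, biased toward
asparagine, glutamine, serine and glycine, that can nucleate self-templating
conformational conversion. In bacterial proteomes they are rare — on the
order of 0.3% of proteins — and disproportionately found in proteins
involved in cell-surface remodelling, secretion, macromolecular assembly and
host interaction. `prdscan` implements the full analysis chain for asking
where such regions occur and what their host proteins do: compositional
detection, annotation joining, enrichment statistics, and a domain census,
plus synthetic-data generators that make every stage testable against
planted ground truth.

## The detection model

The scanner treats PrD detection as a composition problem. Each window of
`window_length` residues is scored as a position-independent log2 likelihood
ratio between a *prion* composition model \(P\) and a *background* model
\(B\):

\[ S = \sum_{i=1}^{w} \log_2 \frac{P(a_i)}{B(a_i)} \quad \text{bits.} \]

This form was chosen deliberately: it reproduces the documented behaviour of
compositional PrD predictors — a bit-scale score, a fixed call threshold,
sensitivity to N/Q/S/G-rich low-complexity stretches — in a transparent,
unit-testable way (the score is additive over concatenation, permutation
invariant, and exactly zero when both models coincide). The model slot is
pluggable, so a positional window-HMM could replace it without touching the
rest of the pipeline.

Parameters that matter:

* `window_length` (residues, default **60**): yeast-derived prion domains
  are tens of residues long; at 60 residues the 50-bit cutoff requires an
  average of > 0.83 bits per residue, which background composition
  essentially never sustains.
* `cutoff_bits` (default **50**): the call threshold. The cutoff rule is
  `>=` after rounding scores to 6 decimal places; a strictly-greater variant
  is available (`strict_greater = TRUE`) because real-valued ties at the
  boundary, while vanishingly rare, must have a defined outcome.
* `step` (default 1) and `merge_gap` (default 0): qualifying windows that
  overlap or abut (within `merge_gap` residues) the maximal window are
  merged into one called region; each protein yields at most one call, with
  other qualifying clusters kept in a diagnostics channel rather than
  counted. Proteins shorter than the window are scanned as a single window
  of their own length.
* Default prion model: N 0.30, Q 0.21, S 0.11, G 0.11, the remaining 0.27
  uniform over the other 16 residues. Default background: average bacterial
  residue frequencies, shipped as an editable TSV fixture. A pseudocount of
  `1e-4` is added to every probability before normalization so log-ratios
  stay finite. Ambiguity codes (B, Z, X, U, O) contribute 0 bits and are
  excluded from composition summaries: no information, no penalty.

Coordinates are 1-based inclusive throughout.

## Enrichment statistics

For each term the enrichment factor is
\( EF = (n_l/p_l) / (n_b/p_b) \),
the term's frequency among annotated PrD-list proteins relative to its
background frequency. Significance is a one-sided hypergeometric
(over-representation) test — exact and oracle-verifiable, which is why no
chi-square approximation is offered — followed by Benjamini–Hochberg
adjustment; a term is flagged when `log2(EF) > 0.5` **and** `q < 0.1`, both
comparisons strict. Terms absent from the background (`n_b = 0`) are skipped
with a warning rather than failing the run. GO terms are counted as given,
with no ancestor propagation up the ontology graph.

**The background universe.** `p_l` counts only annotated PrD proteins
(unannotated calls cannot contribute hits). Two choices of `p_b` are
supported. With `background = "all"`, `p_b` is every protein in the
annotation table — the literal reading of the EF definition ("the total
number of proteins"). With `background = "annotated"`, both universes are
conditioned on carrying at least one term. The distinction matters: when
annotation is sparse, conditioning only the list side inflates EF under the
null (a protein observed to be annotated is more likely to carry any given
term), and we measured mean null EF near 1.3 in synthetic tables with ~50
sparse terms. The calibrated `"annotated"` mode restores a null EF of 1 and
is what the recovery tests and the pipeline's default analyses use; the
`"all"` mode remains available and tested. A related subtlety feeds the
end-to-end tests: a term planted at fold \(f\) among PrD proteins has a
*realized* enrichment below \(f\) when baselines are sparse, again because
of annotation conditioning, so recovery tests use a baseline (0.1) dense
enough that realized and nominal folds agree.

Subset comparisons (`compare_subsets()`, e.g. pathogens versus the full
call set) require both result sets to share a background; per-term log2 EF
ratios are reported with equal EFs mapping to exactly 0, including the
0/0 case.

## Census and architecture rules

The Pfam census counts domain *instances* across PrD-containing proteins —
a domain occurring twice in one protein counts twice — and keeps domains
seen strictly more than five times (`min_count = 5`; the boundary is a
tested contract: exactly 5 is excluded, 6 included). "Multi-domain"
likewise means at least two domain instances, not two distinct families.
Functional grouping of terms and domains is supplied as an editable YAML
fixture mapping IDs to named clusters (cell wall dynamics, nucleotide
binding, invasion and virulence, ...), because such groupings are curation,
not computation; `cluster_rollup()` conserves totals, with unmapped IDs
pooled as "unclustered".

A call's position relative to its protein's domain architecture is labelled
N-terminal, C-terminal, inter-domain, overlapping (more than 10% of the
call's length inside a domain) or undomained. When a small (\(\le\) 10%)
overlap leaves the call straddling a domain edge, the label is decided by
the call's midpoint relative to the first and last domain — the
classification must be total, and the midpoint rule is the least surprising
tie-break.

## Reporting rules

Report-level percentages are computed by `report_fraction()`: half-away-
from-zero rounding at an explicit, per-field number of decimals (1 decimal
for the PrD fraction, 2 where two are conventionally printed, 0 otherwise).
Every percentage in a `SummaryReport` is therefore a pure function of its
integer numerator and denominator, and the tests recompute each one from
the emitted counts.

## What the synthetic generators emulate — and what they do not

`generate_proteome()` draws proteins residue-wise from the background model
(lengths uniform on 150–600 residues), plants one prion-composition segment
(uniform 60–150 residues, replacing background residues so lengths stay
distribution-exact) in a Bernoulli(0.003) subset, and records the truth.
`generate_annotations()` assigns baseline terms independently, plants terms
among PrD-truth proteins at `fold × baseline` (capped at 1 with a warning),
draws Pfam architectures from a domain-count distribution whose defaults
(0.31, 0.414, 0.173, 0.103) reproduce the headline structure ratios (69%
of PrD proteins with a domain; 40% of those multi-domain), and annotates
only 11% of PrD proteins by default, mirroring the sparse annotation of
prion-like candidates. Determinism is strict: every record is generated
from a per-index substream seed, so outputs are pure functions of
(parameters, seed) and record order never perturbs other records.

These generators emulate compositional contrast and controlled
over-representation — the properties the method detects. They do **not**
emulate real sequence redundancy across databases, homology between
proteins, operon or phylogenetic structure, correlated GO terms, ontology
structure, or length-biased annotation. Passing recovery tests therefore
demonstrates that the implementation detects what it models, at the planted
contrast; it does not certify sensitivity on real proteomes, where prion
domains shade into weaker composition bias and annotation is far from
independent.

## Numerical and design choices

* Scores are rounded to 6 decimals before the cutoff comparison, making the
  call boundary reproducible across platforms.
* Ties for the maximal window resolve to the leftmost; merged calls carry
  the maximum window score, not a region-level rescoring.
* Deduplication of input sequences is by accession only; identical
  sequences under different accessions are scanned independently.
* The hypergeometric tail is computed as `phyper(n_l - 1, ...,
  lower.tail = FALSE)`; the tests verify it against exhaustive enumeration
  for every contingency with a background of up to 60 proteins, at 1e-12.
* BH adjustment delegates to `p.adjust(method = "BH")` and is
  property-tested against an independent step-up construction, including
  rejection-set equivalence.
* Pipeline configuration is a validated in-R object
  (`pipeline_config()`) rather than a free-form YAML file: every option is
  checked at construction time (paths exist, thresholds in range), the
  command-line flags map one-to-one onto its arguments, and an R object
  composes naturally with the generators in scripted and test use. The
  cluster map — which is genuinely curated data — stays in YAML.
* Degenerate inputs have defined outcomes: empty proteomes, empty call
  sets and empty universes raise informative errors; an all-domainless
  call set reports a multidomain percentage of 0 with a warning; a
  no-pathogen run skips the subset comparison with a warning and leaves
  the full analysis untouched.

## Problem sizes used in the tests

The study-condition checks run at desk scale, chosen to keep the suite
fast while leaving the statistics meaningful: scanner recovery uses ten
seeded proteomes of 10,000 proteins at the default 0.3% planted fraction
(sensitivity ≥ 0.9, false-positive rate ≤ 1e-3 per protein, pooled);
enrichment recovery uses twenty seeded runs of 10,000 proteins with a 5%
PrD fraction and planted folds 2–10 (≥ 90% of qualifying planted terms
flagged, ≤ 10% of flags unplanted); the composition contract pools ≥ 50,000
planted residues. The acceptance script reproduces the composition contract
end-to-end from a user-supplied seed.

## Known limitations

* The scorer is a pure composition model; it cannot distinguish two
  regions with identical residue counts but different ordering, and it
  will score any N/Q/S/G-rich low-complexity region, prion-forming or not.
* One call per protein matches per-protein counting in downstream
  statistics, but proteins with two genuinely distinct PrDs surface only
  through the diagnostics channel.
* Enrichment treats terms as independent and flat; correlated or nested GO
  terms share counts and the FDR is controlled only in the flat sense.
* The default background composition is a single bacterial average;
  organisms with unusual proteome composition (e.g. AT-rich genomes with
  elevated N content) warrant a custom background model via
  `read_composition_model()`.
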