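---
title: "Screening for CENP-C-like domain architectures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for CENP-C-like domain architectures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenpcscan)
```

## The problem

CENP-C is the inner-kinetochore protein that links CENP-A-containing
centromeric nucleosomes to the outer kinetochore. Two short degenerate
blocks mediate nucleosome binding — the CENP-C motif (core `RxxxxPxxYW`)
and the central-region block (consensus `RxSxxPSxWW`, core `RxxxxPxxWW`) —
and a C-terminal cupin β-barrel domain mediates dimerization. Because
CENP-C evolves rapidly, distant orthologs often retain only these
landmarks. In ray-finned fish no annotated CENP-C is known; candidate
orthologs carry a well-conserved cupin domain plus degraded copies of the
core block upstream, while M18BP1 of most non-mammalian vertebrates
carries a near-complete CENP-C motif and no cupin at all. `cenpcscan`
operationalizes exactly this style of evidence: degenerate motif
detection, cupin localization by local alignment, and a rule-based
per-protein architecture call.

## Degenerate motifs and matching semantics

A motif is an ordered list of residue sets over the 20 amino acids. In
pattern strings, `x`/`X` is the full set, `B` = {D,N}, `Z` = {E,Q},
`J` = {I,L}, and a plain letter is a singleton. Sequences may themselves
contain `B`, `Z`, `J` and `X` (the bundled 23-residue vertebrate motif
consensus does), so matching is defined symmetrically: a motif position
matches a sequence residue iff the two residue sets intersect. Only
*constrained* positions (set smaller than 20) can be violated and only
they count toward mismatches; wildcards are recorded as `.` in the
per-position string, satisfied constraints as `|`, violations as `x`, and
the mismatch count of a hit always equals its number of `x` marks.

The default mismatch tolerance is 0. The classifier uses a tolerance of 2
for degraded-motif detection, because the candidate shark protein lacks
both tryptophans of the `RxxxxPxxWW` core — exactly two violated
positions.

**Specificity is limited at that tolerance.** For a pattern with
constrained positions of set sizes $s_i$, the probability that a uniform
random window matches exactly is $\prod_i s_i/20$ — for `RxxxxPxxYW` that
is $(1/20)^4 = 6.25\times10^{-6}$. But allowing $k \le 2$ violations on
the 4 constrained positions of `RxxxxPxxWW` raises the per-window
probability to $\sum_{j\ge 2}\binom{4}{j}(1/20)^j(19/20)^{4-j} \approx
1.4\times10^{-2}$: several hundred residues of sequence almost surely
contain a chance degraded match. Two consequences are designed in:

- Degraded hits establish *class membership* (a cupin-bearing protein with
  degraded core matches upstream is a fish-type candidate) but distance
  measurements anchor on exact hits whenever any exist; otherwise the
  chance match closest to the cupin would dominate the measured spacing.
- A `CUPIN_ONLY` call is a fallback label, reliable only for proteins with
  short upstream regions or when the tolerance is lowered; it is not a
  recoverable planted condition on realistic protein lengths. The
  `estimate_false_positive_rate()` helper quantifies this for any motif
  and background.

## Consensus derivation

`derive_consensus()` works per alignment column. A column is dropped when
its gap fraction exceeds `max_gap_fraction` (default 0: any gap drops the
column — the bundled 23-residue motif is contiguous). Otherwise residues
are counted (ambiguity letters as their own symbols, then expanded), and a
residue is *admissible* when its frequency is at least `min_fraction`
times the column's modal frequency. This relative-to-mode convention makes
the strict default (`min_fraction = 1`) keep exactly the residues tied for
the mode: two rows `RDPW`/`RNPW` yield {D,N} at position 2 and hence `B`,
while `RAPW`/`RRPW` yield a mixed set and hence a wildcard. The admissible
set collapses to a single residue, to `B`/`Z`/`J` when it lies within one
ambiguity class (unless `allow_ambiguity_codes = FALSE`), else to a
wildcard. Whether a consensus over diverged sequences should be strict
(modal) or permissive is genuinely open; both are supported through
`min_fraction`, and the strict rule is the default. Note that a *strict*
consensus need not match every source row at variable columns; choosing a
small `min_fraction` admits every observed residue and restores that
property.

## Local alignment and cupin localization

`smith_waterman()` is a standard affine-gap (Gotoh) local alignment with
the protein-BLAST default scheme: BLOSUM62, gap open 11, gap extend 1, a
gap of length $L$ costing $11 + L$. The matrix is shipped in NCBI text
format; scores involving `B`, `Z`, `J` or `X` are recomputed from the
20×20 core as the mean of member-pair scores rounded toward zero, so
alignment scoring and motif matching agree on one set semantics (the
file's own ambiguity rows, computed differently by NCBI, are ignored).
Ties are broken deterministically — diagonal over vertical over horizontal
during the DP, first maximal cell in row-major order for the traceback
start — so outputs are byte-stable. A best score of zero returns an empty
alignment. The implementation is validated against an exhaustive
substring-pair oracle on tiny inputs and against an independent aligner
(`Biostrings::pairwiseAlignment`) on random pairs.

No E-value model is used: database-size-dependent statistics are out of
scope. Instead a cupin hit must cover at least `min_domain_length` aligned
columns (default 40) and score at least `min_score_per_column` (default 2)
per column — roughly one bit per column in BLOSUM62 half-bit units. Both
thresholds are exposed and have a monotone effect. Among passing
references the best score wins, ties broken by higher identity then
lexicographic reference id. The package ships two *synthetic* reference
sequences (random, fixed seed, labelled as such) so the machinery runs out
of the box; real cupin-domain FASTA should be substituted for production
screens.

## Classification rules

Rules apply in order; "upstream" means the motif interval ends at or
before the cupin start, per the N-terminal placement of both motif blocks
relative to the cupin domain.

1. Cupin present **and** an exact `RxxRxxxxPLxYWxGERxxY` hit with
   $0 \le \text{gap} \le$ `canonical_gap_max` (default 100, encoding the
   "within about 100 amino acids" placement) → `CANONICAL_CENPC`.
2. Cupin present **and** ≥ 1 `RxxxxPxxWW` hit (≤ `degraded_max_mismatches`
   violations) upstream → `PUTATIVE_FISH_CENPC`;
   `conserved_region_count` counts non-overlapping such hits greedily left
   to right (the candidate fish architecture has two), and violated
   positions of degraded hits are recorded.
3. No cupin **and** a canonical-pattern hit within the same tolerance →
   `MOTIF_ONLY`. This is reported as M18BP1-like *evidence*; ortholog
   assignment is beyond motif evidence.
4. Otherwise `CUPIN_ONLY` or `NONE`.

Whether a degraded region with both tryptophans lost should count toward
the conserved-region tally is left to interpretation downstream: the hits
and their violated positions are all on the record, and
`validate_call()` checks every call's internal consistency.

`spacing_ratio()` compares the motif-to-cupin distances of two calls using
each call's cupin-proximal hit, preferring exact hits as above; the
candidate teleost architecture shows a ratio of about 2 relative to
canonical vertebrate CENP-C.

## The synthetic-data generator

`generate_proteome()` emulates the three observed architectures plus
background: canonical proteins plant a realized identity-pattern instance
40–80 residues upstream of a cupin copy (so gaps fall inside the 100
residue rule with margin); fish-type proteins plant a cupin copy plus two
`RxxxxPxxWW` instances, cupin-proximal at gap 80–160 — about twice the
canonical spacing, per the reported ratio — and distal at 220–320;
motif-only proteins place an identity-pattern instance at a random
position; `NONE` proteins are pure background. Default lengths are
500–800 residues, the scale of vertebrate CENP-C itself (human CENP-C is
943 residues) and the smallest range accommodating the distal plant.
Motif instances sample constrained positions uniformly within their sets
and wildcards from the background table; substitutions (a per-residue
rate for cupin copies; a fixed count, optionally confined to given motif
positions such as the two tryptophans, for fish-core instances) always
change the residue, so the truth table's substitution counts are exact.
Cupin-only plants are not in the default mixture: as shown above, a
degraded-tolerance screen cannot recover that label on long proteins, and
the three planted classes plus background are the observed conditions
being emulated.

The default background is uniform over the 20 residues — unrealistic, but
it makes the closed-form hit probabilities exact; a Swiss-Prot-like
composition is available via `aa_frequencies("swissprot")`. The generator
does **not** emulate indels, evolutionary correlation along a tree,
compositional bias along the sequence, or homologous non-orthologous
domains. Passing recovery tests on these proteomes therefore demonstrates
the pipeline's correctness, determinism and sensitivity under controlled
substitution, not its specificity on real proteomes, where paralogous
cupin domains and compositionally biased regions will produce candidates
that need downstream scrutiny.

All randomness flows from one seed; the generator saves and restores the
caller's RNG state.

## Numerical and interface conventions

- Coordinates are 0-based half-open everywhere internally; conversion to
  1-based inclusive happens only at report serialization (TSV/JSON), and
  the two conversions are exact inverses.
- Sequences are uppercased on load; the extended alphabet is the 20
  residues plus `B`, `Z`, `J`, `X`; a stop `*` is allowed terminally and
  stripped; anything else is rejected with the record id and offset.
- Truncation toward zero (not flooring) defines ambiguity scores, so
  `mean(6, 1) = 3.5` gives 3 and negative means shrink toward zero.
- All drivers are deterministic: repeated runs on the same inputs are
  byte-identical, which the tests assert.

## Problem sizes used in the checks

The standing test suite and the acceptance script use: 1000 random
scanner-vs-oracle cases (sequences ≤ 200, patterns ≤ 12 positions);
exhaustive alignment oracles on sequences of length ≤ 8 plus 200 random
pairs ≤ 60 against the independent aligner; 200-protein proteomes for
recovery (once at substitution rate 0, once with both core tryptophans
substituted); a 25-row sampled alignment for consensus recovery; and
20,000 Monte-Carlo trials of length-200 sequences for the false-positive
rate, compared to the closed form within three standard errors. These
sizes give stable, well-separated expectations for every assertion.

## Known limitations

- Identity-pattern evidence only: no position-specific scoring matrices or
  profile HMMs, by design — the screen reproduces identity-based
  reasoning.
- No alignment significance model beyond the length and per-column score
  thresholds; candidate lists from large databases need an external
  statistical filter.
- The bundled cupin references are synthetic stand-ins; biological
  conclusions require real reference domains.
- Gap handling in consensus derivation drops gapped columns by default;
  motifs spanning indel-rich regions need a permissive
  `max_gap_fraction` and careful reading of the retained-column mapping.
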