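---
title: "Screening chloroplast proteomes for vesicle-transport cargo signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chloroplast proteomes for vesicle-transport cargo signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorocargo)
```

## The biological model

In cytosolic COPII transport, cargo is selected at the donor (ER) membrane by
short linear motifs exposed to the cytosol: diacidic and dihydrophobic
signals in the C-terminal tails of transmembrane cargo, di/mono-basic signals
near the first TM helix, an ILV signal on soluble cargo recognized by
p24-family receptors, and a dilysine motif by which those receptors contact
the coat. If chloroplasts run an analogous system from the inner envelope to
the thylakoids, the stroma plays the role of the cytosol: nuclear-encoded
thylakoid proteins should carry the same signal grammar on their
stroma-facing tails, downstream of the cleavable N-terminal transit peptide
that got them into the organelle in the first place.

`chlorocargo` implements that transfer of the COPII signal grammar as an
explicit, testable screen. It deliberately separates three concerns:

1. **Pattern matching** (`compile_pattern()`, `scan_pattern()`) — a small
   Prosite-subset engine with exact, enumerable semantics.
2. **Topology** (`build_region_map()` and the `motif_in_*` filters) — where a
   match sits and which membrane side that region faces.
3. **Evidence** (`decide_localization()`, `nterm_overhang()`) — whether the
   protein is plausibly chloroplast-localized at all.

Structural annotations (TM spans, terminus orientations, domains,
coiled-coils, transit-peptide ends) are *inputs*, read from TSV tables in the
same shape as the published evidence; the package predicts none of them.

## The pattern engine

Patterns are ordered elements: residue classes (`[DE]`), negated classes
(`{P}`), and wildcards `x`, each with a repeat qualifier `(n)` or `(n,m)`;
`<` and `>` anchor a match to the first or last residue. Coordinates are
1-based and inclusive at both ends everywhere in the package, matching the
Prosite convention and the way positions are written in the biological
literature. The scanner reports *every* distinct match — overlapping matches
and every feasible span of a variable wildcard — because deduplication is a
screening decision, not a matching decision.

Two semantic choices are worth calling out:

* **Ambiguity letters.** Sequences may contain `X`, `B`, `Z`, `U`. These are
  matched only by wildcards, never by residue classes or negated classes: a
  class asserts a chemical identity that an ambiguous letter does not
  support.
* **The dibasic pattern.** The catalog compiles the basic signal as
  `[RK]-x(0,1)-[RK]` even though the strict dibasic form has a mandatory
  one-residue spacer. The printed evidence for this class consists of
  adjacent `KK` pairs, which the strict form cannot match; including the
  zero-length spacer makes the catalog consistent with its own evidence. The
  strict form remains one `compile_pattern("[RK]-x-[RK]")` away. The
  monobasic fallback (a single K/R suffices "in some cases") is off by
  default because no rule says when it applies; when enabled, monobasic
  matches are flagged so downstream analysis can tell them apart.

The scanner's correctness is not argued but tested: a brute-force oracle in
the test suite enumerates every repeat-count assignment of every pattern as a
fixed regular expression and tests every substring, on random sequences up to
60 residues, including ambiguity letters.

## Topology and the placement rules

`build_region_map()` tiles each protein exactly into `transit`, `n_tail`,
`tm`, `loop` and `c_tail` regions. Sides are derived by alternation: the
N-tail takes the annotated N-terminus orientation, each TM span flips the
side, and the result must land on the annotated C-terminus orientation.
A mismatch is an error by default; `strict = FALSE` trusts the annotated
C-tail side and records the inconsistency, which is needed for printed
topologies that list alternative orientations (those proteins are screened
under both alternatives and flagged `orientation_ambiguous`).

The three placement filters are pure predicates on (match, region map):

* `motif_in_stromal_c_tail()` — wholly inside the C-tail, C-tail side `"in"`,
  and within `c_tail_max_dist` of the C-terminus. The default distance is
  unlimited because the source rule ("C-terminal side after the
  transmembrane helix") imposes none; the knob exists for stricter screens.
* `motif_in_nterm_window()` — wholly inside the N-tail (hence downstream of
  any transit peptide) and starting within `nterm_window` residues of the
  first TM span. "Proximal to the TM helix" is not quantified in the source
  description, so the default of 25 residues is a recorded package choice;
  every test that depends on it uses synthetic truth generated against the
  same window, not published counts.
* `motif_outside_transit()` — no overlap with the transit peptide; exact
  boundary semantics (a match starting at `transit_end` fails, at
  `transit_end + 1` passes).

## Receptor architecture

A receptor call requires three architecture features: a GOLD domain wholly in
the C-terminal half of the mature sequence (after the transit peptide), a
dilysine match wholly inside that GOLD span, and a CRAL_TRIO domain. The
"half" boundary operationalizes the qualitative "in their C-terminal" /
"towards the N-terminal side" descriptions; the fraction (default 0.5) is
configurable. An N-terminal coiled-coil and the absence of TM spans are
reported as supporting evidence rather than required, because they are
described descriptively, not as selection criteria.

## The localization decision tree

Acceptance is two-staged: a consensus score of at least 10 (inclusive — the
threshold is written "≥10") accepts outright; below that, at least
`min_tools` individual chloroplast tool calls accept via the fallback route,
with the supporting tools recorded on the verdict. `min_tools` defaults to 2:
the published fallback acceptances cite between 2 and 8 tools and never state
a minimum, so the package records the weakest rule consistent with that
evidence and keeps every verdict re-filterable (a stricter re-analysis is a
filter over `supporting_tools`, not a recomputation). Experimental flags
(proteomics MS/MS, chloroplast-project membership) are appended as notes and
never decide acceptance — mirroring their corroborative use. Proteins with no
transit peptide at all can still be accepted via the fallback route, which is
how the screen treats the receptor candidates whose chloroplast support is
largely experimental; their verdicts make that visible rather than deciding
the biology.

`aggregate_scores()` is a deliberately simple stand-in used only to fabricate
coherent synthetic evidence (a rescaled weighted mean with a unanimity
ceiling); real consensus scores are inputs, and no attempt is made to
re-derive the external Bayesian consensus algorithm.

## Transit-peptide extensions by alignment

The published procedure inspected multiple alignments by eye for an "extra
N-terminal stretch". That criterion is pairwise-decidable, so the package
replaces it with affine-gap Needleman-Wunsch global alignment
(`global_align()`) plus a minimum-over-homologues rule (`nterm_overhang()`):
for each homologue, count the query residues placed before the first column
in which both sequences carry a residue; the conservative overhang is the
minimum. An extension is called at `min_length = 20` residues (inclusive), a
typical lower bound for plant chloroplast transit peptides; both the
threshold and the scoring scheme (default BLOSUM62, gap open 10, gap extend
1, a gap of length L costing `open + L * extend`) are configurable and
recorded on every alignment object.

Numerical choices: the dynamic program breaks ties deterministically
(diagonal, then vertical, then horizontal during traceback), so identical
inputs give byte-identical alignments. Scores are validated in the test suite
against an independent memoized recursion on all pairs up to 15 residues and
against an independent alignment library on longer random pairs.

## The synthetic proteome generator

`sim_config()` fixes the study conditions the tests run under: 500 proteins,
half of them chloroplast-localized, Ser/Thr-enriched transit peptides of
30-80 aa, hydrophobic-enriched TM spans of 18-24 aa with tails and loops of
30-90 and 10-40 aa, uniform background composition (an average published
composition is available as an option — the screens are composition-agnostic,
but tests should not be), and a planted-motif plan of 10 correct placements
plus 5 of each applicable control type per signal class. Controls violate
exactly one rule each (wrong region, wrong orientation, or inside the transit
peptide) so that a failing filter is attributable to that rule. Localization
noise defaults to 0.2 with a 0.5 fallback-success probability and a consensus
ceiling of 20.

Recovery is scored at the coordinate level (`evaluate_recovery()`): a planted
motif counts as recovered only when a passing match of its class has exactly
its coordinates. This is deliberate — background sequence can and does
contain incidental signal-like 3-mers (a diacidic match arises in roughly 1%
of positions under uniform composition), and the screen is supposed to find
those too; coordinate-level scoring measures the placement rules, not the
background rate. Consequently the generator emulates what the screens
*assume* (signal placement, topology, evidence structure), not what real
proteomes *are*: no homology structure, no realistic domain content, no
correlated tool errors. Passing tests demonstrate that the rules are
implemented exactly, not that the screen's biological yield on a real
proteome is correct.

## Packaged fixtures and known discrepancies

The package ships the printed motif tables, the localization-evidence table
for the initiation/receptor candidates, and the functional categories of the
32 categorized cargo candidates as TSV fixtures (`fixture_path()`). Scanning
the printed motif strings with the compiled catalog reproduces the
section-level counts (12 ILV proteins, 3 basic, 1 dihydrophobic, 17 diacidic
table rows) and the category summary (14 photosynthesis proteins, 5 LHC).
Two published counts are deliberately not asserted anywhere: the prose counts
of 16 diacidic and 32 total cargo proteins disagree with the printed tables
(17 diacidic rows; 33 distinct table accessions, one of which — a photosystem
I subunit — carries no functional category in the prose listing and is
reported as `unknown` with a warning).

## Problem sizes and limitations

The test suite runs the oracle comparisons on dozens of random sequences up
to 60 residues, the alignment oracle on pairs up to 15 residues, the
planted-motif recovery on a 500-protein proteome under a fixed seed, and the
noise-model calibration on 2000 synthetic evidence records; the whole suite
completes in well under a minute on one core. Known limitations: the screen
consumes annotations rather than predicting topology or domains, so
annotation errors propagate; the pattern engine implements only the Prosite
subset the catalog needs (no profile/weight-matrix scanning); pairwise
overhang measurement can under-report extensions against homologues that are
themselves N-terminally truncated, which the minimum rule makes conservative
by construction.
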