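# chlorocargo

Chloroplasts are hypothesized to run a COPII-like vesicle transport system
that moves material from the inner envelope membrane to the thylakoids. If
that system carries proteins as well as lipids, thylakoid proteins should
carry the same kind of short sorting signals that cytosolic COPII cargo uses,
in the topologically correct place. `chlorocargo` is an R package for running
that screen: it identifies putative transmembrane cargo, soluble cargo and
Sec14-family cargo receptors in an annotated plant proteome, decides putative
chloroplast localization from multi-tool prediction evidence, and measures
N-terminal transit-peptide extensions by global alignment. It is aimed at
plant cell biologists and bioinformaticians who want the screen's rules as
tested, reusable code rather than a one-off manual analysis.

## The screen

Five hand-defined Prosite-style sorting-signal patterns drive the screen:

| id | pattern | role | placement rule |
|----|---------|------|----------------|
| `diacidic` | `[DE]-x-[DE]` | TM cargo | stromal C-terminal tail, after the last TM helix |
| `dihydrophobic` | `[FY](2)` | TM cargo | stromal C-terminal tail |
| `basic` | `[RK]-x(0,1)-[RK]` (optional monobasic fallback) | TM cargo | N-tail, within 25 residues of the first TM helix, downstream of the transit peptide |
| `ilv` | `I-x(2)-L-x(9)-V` | soluble cargo | anywhere except the transit peptide |
| `dilysine` | `K-x(0,1)-K-x(2)` | cargo receptor | inside a C-terminal GOLD domain |

Positional rules are evaluated on a region map that partitions each protein
into transit peptide, N-tail, TM spans, inter-TM loops and C-tail, with
membrane-side labels ("in" = stromal) derived from the annotated terminus
orientations by alternation across TM spans. A cargo receptor call requires a
GOLD domain in the C-terminal half of the mature sequence containing a
dilysine motif, plus a CRAL_TRIO domain; an N-terminal coiled-coil and the
absence of TM spans are reported as supporting evidence.

Chloroplast localization is decided by a two-stage tree: accept when the
multi-tool consensus score is >= 10 (inclusive), otherwise accept when at
least two individual prediction tools call chloroplast; experimental evidence
is recorded but never decisive. Transit-peptide evidence for borderline
proteins comes from affine-gap Needleman-Wunsch global alignment against
non-plastid homologues: the minimum number of query residues left unpaired
before the first aligned column, called an extension when >= 20 residues.

A synthetic-proteome generator emulates the statistical structure the screen
assumes (Ser/Thr-enriched transit peptides of 30-80 aa, hydrophobic TM spans
of 18-24 aa, planted signals at correct positions and as controls violating
exactly one rule each, noisy localization evidence) so every stage is
testable without database downloads.

## Worked example

A 200-residue membrane protein with a transit peptide at 1-50, one TM span at
100-120, a stromal C-terminus, and a diacidic `DID` signal at 180:

```r
library(chlorocargo)

seqv <- rep("G", 200); seqv[1:50] <- "S"; seqv[100:120] <- "L"
seqv[180:182] <- c("D", "I", "D")
prot <- annotated_protein("DEMO1", paste(seqv, collapse = ""),
                          transit_end = 50, tm_spans = cbind(100, 120),
                          n_orientation = "out", c_orientation = "in")
calls <- screen_tm_cargo(prot)
calls[[1]]
#> <cargo_call> DEMO1 [tm_diacidic]: PASS (1 candidate match(es))
calls[[1]]$matches
#>   pattern_id start end matched_text outside_transit stromal_c_tail passed
#> 1   diacidic   180 182          DID            TRUE           TRUE   TRUE
```

The call passes because the match sits wholly in the C-tail (121-200), that
tail faces the stroma, and it is outside the transit peptide. Moving the same
`DID` into the N-tail, or flipping the C-terminus orientation to "out", turns
the verdict to fail with the responsible filter named in the output.

The localization decision tree on the packaged evidence fixture:

```r
ev <- read_evidence(fixture_path("localization_evidence.tsv"))
decide_localization(ev[["At3g52190"]])
#> <localization_verdict> At3g52190: accepted (route tool_fallback, chloroplast score 7.6)
#>   supporting tools: MultiLoc, PCLR, SLPFA, TargetP
#>   notes: experimental: chloroplast2010
```

The consensus score 7.6 is below the threshold of 10, but four individual
tools call chloroplast, so the protein is accepted via the fallback route.

A thin command-line front end (`exec/chlorocargo`) exposes the same pipeline
as subcommands `scan`, `screen-cargo`, `screen-receptors`, `consensus`,
`extension`, `simulate` and `report`.

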