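---
title: "Methods: diagnostic nucleotide combinations and morphological keys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic nucleotide combinations and morphological keys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coidiag)
```

## The problem

Integrative species descriptions of morphologically conservative taxa —
here modelled on the Northeast Atlantic trichobranchid genus
*Terebellides* — increasingly publish, alongside morphology, a
*character-based DNA diagnosis*: for each species, a list of alignment
coordinate ranges and motifs in the COI barcode, e.g.
`78–99: TCAACCCGGTGCTTACCTCGGT, …, 306: C`, in which some positions are
strictly diagnostic (autapomorphic: fixed within the species and absent
from every other sequenced congener) and the rest are invariant context.
`coidiag` turns that practice into a tested pipeline: it extracts such
combinations from a labeled alignment, verifies and minimizes them,
parses and re-emits the printed dialect, identifies unaligned queries
against the profiles, and re-implements the paper-style morphological
identification system (uncini, branchiae and Methyl-Green typologies, a
taxon-by-character matrix, and an 18-couplet dichotomous key).

## The diagnostic model

Let an alignment have columns $1..L$ (1-based, inclusive — the convention
of the printed diagnoses) and a species map over its sequences. For a
focal species $s$:

* a column $j$ is **focal-invariant** if every sequence of $s$ carries the
  same plain base at $j$ (a gap or IUPAC ambiguity code anywhere in the
  focal sample disqualifies the column — printed motifs are pure ACGT);
* a focal-invariant column is **strictly diagnostic** if no background
  sequence *can* match the focal base. A background ambiguity code whose
  set contains the focal base counts as a potential match and disqualifies
  the column (the conservative reading of "unequivocal"); a background gap
  never matches and never disqualifies;
* a **region** is a maximal run of consecutive focal-invariant columns
  containing at least one strictly diagnostic column; its motif is the
  shared focal states over the run. This is the only reading consistent
  with printed motifs that mix underlined diagnostic sites with invariant
  context. Single-column regions are legal (`306: C`).

`verify_combination()` checks the two published claims separately: every
focal sequence matches every motif exactly, and every background sequence
is excluded at one or more diagnostic columns (evidence recorded per
sequence). `minimal_combination()` is a greedy set cover over the
regions' exclusion sets (largest number of not-yet-excluded background
sequences first, ties to the smaller start coordinate), so output is
deterministic; greedy cover is not guaranteed minimum-cardinality, but is
reproducible and verified sufficient.

Diagnoses of single-sequence species are permitted (invariance is then
vacuous) but flagged with a low-support warning.

### The printed dialect and its typos

`parse_diagnosis_block()` accepts `start–end: MOTIF` and `pos: MOTIF`
entries, en dash or hyphen, arbitrary whitespace (including `288– 292`),
and the stray cedilla that appears as a separator in one printed block.
Printed underlining (which motif sites are diagnostic) does not survive
into machine-readable text, so parsed regions carry the whole span as
candidate-diagnostic; the package never guesses per-column status for
printed blocks. Entries whose motif length contradicts their span (e.g.
`558–591: CCGT`, or a single position followed by a 31-nt motif) are
flagged `span_length_mismatch` and excluded from the strict region list
but retained verbatim in the parse report — the validator flags, it never
repairs. The six published blocks ship verbatim under
`inst/extdata/diagnosis_blocks/` and four of them carry such flags.

## Query identification

A query is placed into reference coordinates by global dynamic
programming against the majority-rule consensus of the reference
alignment (gap-majority columns kept as `-`; ties broken
`A < C < G < T < '-'`), with deterministic traceback (diagonal, then
consume-query, then consume-reference). A region is matched only if every
one of its columns maps from the query with a compatible state (query
ambiguity codes match their base sets; an unmapped column is a mismatch,
flagged distinctly as `absent`). The verdict is `assigned` iff exactly
one species matches all of its regions.

**Gap penalty.** The scoring is match $+1$, mismatch $-1$, linear gap
penalty, default $-8$ rather than the conventional $-2$. With a cheap gap
and realistic interspecific background divergence (~10%), a one-column
shift across a chance self-similar window outscores the correct ungapped
placement by a point precisely where the query's species diverges from
the consensus — its own diagnostic motif — and entire species then fail
identification (5–25% of queries in our simulations). COI is
protein-coding and effectively indel-free within a genus, so gaps should
be expensive; with $-8$, placement was correct for all 648 simulated
queries across all seeds tested, while genuine deletions still map
(an unbroken mismatch run costs more than the gap run). All scores remain
user-settable.

No reverse-complement or reading-frame search is attempted: queries are
assumed forward-strand barcodes, as in the curated data this emulates.
Queries under 50 nt are rejected as fragments.

`p_distance_matrix()` (uncorrected, pairwise deletion of non-ACGT sites)
and `cluster_by_threshold()` (single-linkage components below a strict
threshold, default 0.04 — a conventional COI cutoff) support synthetic
validation only; they are not a species-delimitation method.

## The morphological system

The verbal typologies are made decidable with explicit numeric cut
points, calibrated once so that the published nominal values classify
correctly, and all configurable:

| classifier | types | thresholds |
|---|---|---|
| thoracic uncini | 1 / 3 / 4 / unknown | type 1 requires rostrum:capitium ≥ 1.5 with 2–3 *large* first-row teeth; types 3 (4–5 *mid*) and 4 (5–7 *small*, ≥ 2 rows) are decided by the tooth profile |
| abdominal uncini | 1A / 2 / unknown | capitium/rostrum ≤ 0.8 (nominal 1/0.7) with 3–5 large teeth → 1A; > 0.8 (nominal 1/0.9) with 4–5 teeth → 2 |
| branchiae | 1–4 | reduced lobes & fusion < 0.15 → 4; fusion ≥ 0.8 → 1; ≥ 0.3 → 2; else 3 |
| Methyl Green | 1 / 2 / 9 / other | segment-class templates over SG 1–14; a J-shaped glandular region is required for 9 and forbidden for 1 and 2; SG 15–18 ignored |

A shared tooth count (5) between thoracic types 3 and 4 is resolved by
the size class, following the published definitions. The published group
descriptions print a ~2:1 rostrum:capitium ratio even for species whose
uncini are typed 3/4 (nominally 1:1); the classifiers therefore privilege
the tooth profile and treat the ratio as secondary for those types — a
source-document inconsistency, not resolved here.

The character matrix (JSON resource) carries the tabulated
discriminating characters of the six focal species plus one augmentation:
the extent of white ventral colouration (TC 1–4 vs TC 4 only), taken from
the species remarks, because the tabulated characters alone leave the two
colouration-bearing species separated only by distribution trends.
`matrix_identify()` returns every taxon consistent with the specimen's
derived states; unknowns on either side match anything.

The key (JSON resource) mirrors the published 18 couplets one for one and
names 21 species; two terminal leads legitimately hold two species each
(separable only genetically, or by geography/bathymetry — couplet 18 is
encoded on depth and evaluated only when the specimen carries a depth,
degrading otherwise to the multi-taxon union). Traversal follows a lead
only when it alone is satisfied; at any undecidable or contradictory
couplet it stops and returns the union of taxa reachable from that point,
so partial specimens get a superset, never a wrong answer. The key graph
is validated at load (existing targets, acyclicity, reachability).

One specimen field (`glandular_tc3_mg_stain`) extends the published
character list because couplet 14 separates two taxa by the staining
reaction of the TC 3 glandular region; it defaults to unknown.

## The synthetic world

`generate_alignment()` emulates the statistical structure the diagnoses
presuppose — within-species invariance at diagnostic columns,
between-species exclusivity, variable background — with fully
seed-reproducible output and an explicit truth set:

* ~660-column alignments over six species with the published per-specimen
  counts (30/17/15/6/20/20) by default; 3 planted regions per species of
  8–25 columns, about a quarter of each region's columns diagnostic;
* each species receives a distinct base at each of its diagnostic
  columns, guaranteed absent elsewhere (conflicting user-supplied plants
  are a configuration error);
* the columns flanking each region carry one within-species substituted
  base, so the maximal invariant run equals the planted span and the
  truth is exactly recoverable at zero noise (a gap is deliberately not
  used here: a gap adjacent to a region makes that sequence's own query
  placement ambiguous at the region boundary);
* interspecific background divergence (default 0.1 = expected pairwise
  background p-distance; columns drawn at twice that rate because a
  random species split makes a given pair differ at about half of them)
  never creates spurious diagnostics: a state carried by exactly one
  species is knocked out with a gap in one of its sequences, which breaks
  invariance without inflating within-species p-distance;
* intraspecific noise (default 0.005/column/sequence, roughly the <1%
  variability of conspecific COI) never touches any species' diagnostic
  columns — the published premise that diagnostic sites "do not show
  variation" — unless the adversarial mode is switched on to exercise
  verification failure paths.

What a green test therefore establishes: the extraction, verification and
identification machinery is exact on data satisfying the diagnoses'
premises. What it does not establish: robustness to features real data
may have — rate heterogeneity, codon structure, pseudogenes,
reverse-strand or frame-shifted queries, heavily ambiguous sequences, or
diagnostic-column polymorphism that would invalidate a published
diagnosis itself.

`generate_specimens()` samples continuous and count characters uniformly
within each species' published ranges (no distribution is published —
uniformity is an explicit assumption), fixes categorical characters to
the published states, couples body length and abdominal chaetiger count
through a Gaussian copula (default 0.7), and samples depths within the
published bathymetric ranges. Two published inconsistencies are resolved
in the resource and logged: the species-16 tooth count (printed 3–4 vs
4–5 in the type definition; the generator uses 4) and the J-region
conflicts between colour-pattern paragraphs, remarks and the key (the
TC 3 glandular field and the MG stain J segments are kept independent).

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; no half-open interfaces.
* `U` → `T` and lowercase are normalized at ingestion; `.` is rejected;
  ambiguity codes are retained, not expanded, with their semantics decided
  at diagnosis time.
* An empty strict diagnostic set yields an empty diagnosis plus a
  warning, not an error; verification of an empty diagnosis fails.
* p-distance with zero comparable sites is `NA` with a warning;
  clustering refuses incomplete matrices, listing the missing pairs.
* "Above/below 200 m" is computed on the numeric depth with both
  orientations reported, sidestepping ambiguous verbal usage; specimen
  listings whose stated counts contradict the enumerated codes (the
  published 17-codes-under-"16 specimens" case) are reported, never
  reconciled.

## Known limitations

* Greedy minimization can exceed the true minimum cover on adversarial
  exclusion structures.
* Placement against a consensus is an artifact decision (the source
  publications do not say how a future user should match a query against
  printed diagnoses); profile matching is only as good as that placement.
* The registry parser targets the specific listing dialect (ZMBN / GNM /
  NTNU–VM prefixes, region-labelled parentheticals, bare numbers
  inheriting the preceding prefix); it is not a general specimen-citation
  parser.
* Published depth percentages for two species require supplementary
  material not shipped here; they are modelled, not asserted.
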