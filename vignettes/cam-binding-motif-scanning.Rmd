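---
title: "Scanning for calmodulin-binding motifs: model, curation and design choices"
author: "CaMScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for calmodulin-binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaMScan)
```

## The motif model

Calcium-dependent calmodulin (CaM) binding is mediated by an ~18–22
residue basic amphipathic segment whose signature is the spacing of bulky
hydrophobic *anchor* residues rather than a conserved sequence. CaMScan
models this as a set of anchor-spacing classes. A class named
`1-x(-y)` places anchors at relative positions 1, x (and y), counted
inclusively from the first anchor; internally these are the 0-based
offsets `positions - 1`:

```{r}
vapply(motifClasses(), function(cl) paste(cl@anchorOffsets, collapse = ","), "")
```

This inclusive convention is fixed by the curated assignments it must
reproduce: the CaMKIIα CaMBD `296RRKLKGAILTTMLATR311` carries a single
1-5-10 motif anchored at Leu299/Ile303/Leu308 — offsets 0, 4, 9 from the
first anchor — with fingerprint `LIL`:

```{r}
scanMotifs(proteinSequence("CaMKIIA", "RRKLKGAILTTMLATR", offset = 296))
```

Two anchor sets are built in. The **core** set {F, I, L, V, W} is the
canonical anchor-hydrophobic list and is the default. The **extended**
set adds M and Y because some curated motif assignments are unreachable
without them (a reported 1-12 in the calcineurin CaMBD requires Met406 as
its terminal anchor; reported `VY` fingerprints require Tyr). Extended
mode is opt-in so that default scans stay on the conservative alphabet;
matches under core are always a subset of matches under extended. `X`
(unknown residue) is accepted in input but never matches any anchor set
or any bracketed class of the IQ pattern.

Calcium-independent binding is handled separately by the IQ motif regex
`[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]` (`x` = any residue), scanned with
overlap, i.e. every matching 14-residue window is reported.

## Raw enumeration and the subsumption rule

`enumerateMatches()` is deliberately exhaustive: every (class, start)
pair whose anchors all land on anchor-set residues yields a match, and
overlapping matches across classes are all kept (curated lists do contain
a 1-16 and a 1-12 sharing a terminal anchor, as in the transglutaminase-2
CaMBD1). Exhaustive scans, however, systematically report one artifact
that visually curated lists do not: whenever a three-anchor motif is
present, its two terminal anchors also constitute a valid two-anchor
motif of the parent class. `applySubsumption()` removes exactly this —
a two-anchor match whose terminal anchor pair coincides with the first
and last anchors of an emitted three-anchor match of its refining class
(1-10 under a 1-5-10, 1-14 under a 1-8-14) — and nothing else. Curated
mode is the reporting default because it reproduces the curated counts on
the peptides where those counts are internally consistent; raw mode is a
flag.

The sort order of match tables is (span start, span length, class name),
a fixed tie-break so serialized output is stable.

## Fixtures and what "clean" means

Twelve curated CaMBD peptides from the Tau network (Tau R2, CaMKIIα,
GSK3β ×3, Cdk5 ×2, ROCK1 ×2, calcineurin, TGM2 ×2) are packaged with
their reported motif annotations. Each fixture carries a status computed,
not asserted: **clean** iff the curated core-anchor scan reproduces the
reported count and class multiset exactly ({Tau-R2, CaMKIIA,
ROCK1-CaMBD1, TGM2-CaMBD1}); **label-inconsistent** where the printed
string contradicts its own position labels (the Cdk5 CaMBD1 string has 25
letters for an 18-residue span, an apparent duplication typo);
**curation-ambiguous** where the reported list is not reproducible by
exhaustive scanning (e.g. counts that disagree with their own class
lists, or classes requiring extended anchors). Ambiguous fixtures are
retained verbatim with explanatory notes — we do not guess the original
curators' intent — and only clean fixtures feed count-based tests.

Two offset conventions deserve note. Coordinates are 1-based inclusive
throughout, matching residue labels like Leu299; only BED export converts
to 0-based half-open. Where a peptide's printed end label disagrees with
its string length, the string and the start label are taken as
authoritative and the end is recomputed (ROCK1 CaMBD1: label 86–105, 19
residues, end 104). The Tau R2 peptide is the one exception on the start
side: its printed start label (286) is inconsistent with both its length
and the stated serine positions, while placing it at 287–304 in canonical
2N4R numbering reconciles Ser289/Ser293 with the serines in the string;
the fixture therefore uses offset 287 and keeps 286 as sidecar metadata.
All motif-count results are offset-independent.

## The CaMBD propensity predictor

The literature's CaMBD proposals rely on an external database whose
scoring algorithm is unpublished. CaMScan's predictor is therefore a
documented stand-in heuristic, and is deliberately *not* validated
against curated CaMBD coordinates — the packaged peptides feed the motif
engine instead. Its purpose is to propose basic amphipathic 18–22 residue
windows for downstream motif scanning.

For each residue, over a centered window (default 21, odd; truncated at
sequence ends), three components are computed and combined as a weighted
sum rescaled to [0, 9]:

* mean **Kyte–Doolittle hydropathy**, min–max normalized over the
  theoretical scale range [−4.5, 4.5];
* **net positive charge fraction** `(count(R,K) − count(D,E)) / window
  length`, clipped to [0, 1]; His counts 0 by default (a flag counts it
  +0.5); the denominator is the actual, possibly truncated, window
  length so edge scores stay on the same scale;
* mean **Chou–Fasman α-helix propensity**, min–max normalized over its
  range [0.57, 1.51].

Residues absent from a table (`X`) score the table minimum. Default
weights are 0.4/0.4/0.2: hydrophobicity and basicity — the two properties
that jointly define a basic amphipathic CaM-binding helix — weighted
equally, with helix propensity as a lighter tiebreak.

**Threshold.** The default calling threshold is 3.5, not the scale
midpoint 4.5. Under this normalization a genuine basic amphipathic
segment plateaus near 4–4.5, because the *mean* hydropathy of a segment
alternating hydrophobic and charged residues sits near the middle of the
hydropathy scale by construction, while uniform background scores around
2 and, in anchor-free synthetic background, never exceeds 3. A midpoint
threshold would therefore sit above the signal plateau; 3.5 separates the
two regimes with margin on both sides. One related caveat: on the
Kyte–Doolittle index Trp is mildly hydrophilic (−0.9, below Gly's −0.4),
so substituting W into a glycine background *lowers* the hydropathy
component even though W is an anchor residue; monotonicity of the
component holds for genuinely index-hydrophobic substitutions (I, L, V,
F, C, M, A).

**Candidate shaping.** Maximal runs of positions scoring ≥ threshold are
shaped into candidates within the length bounds [18, 22]: a run already
inside the bounds is kept as its own span; a longer run is trimmed to its
maximum-sum 22-residue sub-window; a shorter run is extended to the
maximum-sum 18-residue window containing it (ties leftmost throughout).
Length is only altered when a run violates the bounds — maximizing the
score sum over variable lengths would always pick 22, since scores are
non-negative, and would inflate clean runs of intermediate length.
Overlapping candidates are resolved greedily, keeping the higher-scoring
window (leftmost on ties); survivors are ranked by descending mean score.
Sequences shorter than the window are rejected with advice to scan them
for motifs directly, which is the appropriate analysis for an isolated
peptide.

## The synthetic-data generator

`synthProtein()` emulates the null background the predictor and scanner
are tested against. In the default mode the background alphabet excludes
the core anchors (F, I, L, V, W) *and* the basic residues R and K, so any
motif match or charge signal must come from the embedded segment — a
zero false-positive floor by construction. A `realistic` mode draws
uniformly from all 20 residues for stress tests. Generation is
deterministic for a fixed seed and restores the caller's RNG state. The
embedded test segment used throughout, `KLWKKLLKLFSKLWKQIKKV`
(20 residues, 9 Lys, alternating hydrophobics), is a prototypical basic
amphipathic CaM-binding helix.

What passing these tests shows — and does not. Recovery of the embedded
segment in ≥ 90 of 100 seeded runs (the suite observes 100/100;
background length 400, one embedded 20-mer) demonstrates that the score
separates a basic amphipathic segment from uniform background. It does
not demonstrate sensitivity or specificity on real proteomes, where
hydrophobic and basic stretches abound (transmembrane helices,
nuclear-localization signals), nor agreement with any external CaMBD
database. Predictor output should be read as a shortlist for motif-level
inspection, not as a binding call.

## Numerical and degenerate-input choices

* Scoring weights must sum to 1 within 1e-9; all scores are provably in
  [0, 9], asserted by class validity.
* Empty scans are valid results everywhere: header-only TSV, empty JSON
  match arrays, exit code 0.
* Sequences shorter than a motif class's span simply yield no matches of
  that class; sequences shorter than the predictor window are an error.
* Sorting and overlap resolution use fixed, documented tie-breaks
  (leftmost wins) so all outputs are deterministic.
* Problem sizes in the test suite — 200–300 random short sequences for
  oracle equivalence, 1,000 random 200-mers for IQ agreement, 100 seeded
  400-mers for recovery — were chosen as comfortably large for the
  properties tested while keeping the suite quick to run routinely.

## Phosphosite tables

The Tau phosphosite table is a static transcription, in 2N4R (441
residue) numbering with no isoform lifting: CaMKII and Cdk5 target
lists, GSK3β hyperphosphorylation sites, the MARK4 site, calcineurin
dephosphorylation effect sizes (percent decrease in phosphorylation:
Ser262 63%, Ser396 78%, Ser199 38%, Thr217 32%, Ser422 32%), the two
AD-phosphorylated serines inside the Tau CaMBD (enzyme recorded as
`unassigned` — the source names none), and per-kinase potential-site
counts (85 potential sites: 45 Ser, 35 Thr, 5 Tyr). The
pre-/hyper-phosphorylation/dephosphorylation staging is stored as a
`stage` column on site rows rather than as an executable signaling
model. Transcription quirks are preserved, not corrected: a site listed
twice for CaMKII (Thr212/Ser214) is stored once with a note; a likely
`S369`-for-`Ser396` typo is transcribed as printed and flagged. Row
counts per enzyme are checked against a packaged provenance file at test
time.

## Known limitations

* The predictor's constants (scales, weights, threshold) are design
  choices of this package; no published scoring exists to validate them
  against, and no binding-affinity or calcium-dependence modeling is
  attempted beyond IQ-motif flagging.
* Curation-ambiguous fixtures document, but cannot resolve,
  inconsistencies in their source annotations.
* The MARK4 CaMBD sequence is recorded as metadata only (its sequence is
  available only as a figure image).
* No nucleotide support, no alignment, no remote accession fetching:
  UniProt identifiers in fixture descriptions are inert metadata.
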