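---
title: "Element graphs, helix axes and pseudoknot topology: methods"
author: "rnasse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Element graphs, helix axes and pseudoknot topology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasse)
```

This vignette records the models, conventions and numerical choices
behind `rnasse`, at the level of detail a user needs to interpret its
output or compare it against other tools.

## The element graph

The canonical secondary-structure form is the *pair table*: an
involutive 1-based vector `p` with `p[i] = j` for a pair and 0 for
unpaired, plus the positions of backbone breaks between chains. From it
the *bulge graph* partitions residues into named elements: stems
(maximal runs of consecutive stacked pairs), hairpin loops, interior
loops (both strands of an internal loop are **one** `i` element, so a
one-sided bulge is simply an `i` with an empty strand), multiloop
segments, and unpaired 5'/3' ends. Four conventions matter in practice:

* **A single isolated pair is a valid 1-bp stem.** Whether such helices
  count is exposed as `min_stem_bp` (default 1); raising it treats pairs
  in shorter helices as unpaired. Varying this threshold changes what
  counts as a junction, which is why it is a parameter rather than a
  constant.
* **Zero-length multiloop segments are kept** as empty `m` elements.
  Two stems can sit directly adjacent on the backbone and stack across
  that empty segment; the stacking analysis needs the connecting
  element to express this, so dropping it would silently remove exactly
  the most interesting records. Empty hairpin loops (`"()"`) are kept
  for the same reason; empty 5'/3' ends are not created at all — an
  `f`/`t` element exists only when unpaired overhang residues exist.
* **Crossing pairs are ordinary stems.** Their surrounding
  single-stranded stretches become `m` elements flagged as
  pseudoknotted, and junction detection skips multiloops pierced by a
  crossing helix (decompose with `remove_pk = TRUE` to analyse those).
* **The exterior loop is not a junction.** Junctions are closed cycles
  of `m` segments around a multiloop, so every junction has at least
  three bounding stems; stem pairs connected only across the open
  exterior strand produce no record.

Pseudoknot removal (`remove_pseudoknots()`) maximizes the number of
retained *pairs* (not helices) by interval dynamic programming; ties are
broken toward the 5'-most pair. This objective is exactly reproducible
by brute-force subset enumeration, which the tests exploit as an oracle.

## Coarse-grained helix axes

Each stem is reduced to a cylinder axis fitted from C1' atoms: the
per-pair center is the midpoint of the two C1' atoms, the axis is the
total-least-squares line through the pair centers (first principal
direction), and the axis endpoints are the orthogonal projections of
the terminal pair centers onto that line, with *start* at the pair
containing the 5'-most residue. Degenerate cases: a 2-bp stem uses the
line through its two centers; a 1-bp stem uses the least-squares
base-plane normal of its single pair, given a half-rise of extent so a
direction exists. Pairs lacking C1' coordinates are dropped from the
fit; a stem with no complete pair is an error rather than a guess.

The *twist vector* at each end is the unit component, orthogonal to the
axis, of the vector from the axis endpoint to the terminal pair's
strand-1 C1' atom. It is a deterministic, rigid-motion-equivariant
proxy for the orientation of the terminal pair (and thus the groove
direction). Note that the residual of the pair *center* itself cannot
serve here: the axis endpoint is that center's projection, so the
orthogonal residual is identically zero for any straight helix.

Loop elements inherit endpoints from their stems: an `m` or `i` element
spans the facing axis ends of its two stems; `h`/`f`/`t` run from the
adjacent stem's loop-side end to the C1' of their farthest residue.

## Junction geometry and the stacking call

For two stems adjacent across a multiloop segment, the stem vectors
point *away* from the segment along the axes, so 180° between them is
the coaxial-stack geometry. The offset is the minimum distance between
the two rays anchored at the segment-side ends and directed along the
stem vectors, computed with the exact closed form (the constrained
quadratic's optimum is either interior or on a `λ = 0` boundary, giving
the line–line, point–line and point–point cases). Because both rays
point away from the segment, two stacked stems have diverging rays and
their offset equals the anchor separation — a few Å for a true stack —
rather than zero; collinear *converging* rays give exactly zero.

The stacking call is deliberately relaxed: stems count as stacking when
any nucleotide of one stem's segment-side closing pair shares a
continuous stack (from a DSSR-style JSON annotation) with any
nucleotide of the other stem's segment-side pair. Intermediate stacked
nucleotides are allowed and need not be backbone-connected, and
bulged-out nucleotides missing from the stack do not break the call.
The package never invokes the annotation tool itself; it consumes its
JSON artifact, which keeps analyses reproducible from archived files.

## Pseudoknot topology and angles

The *shadow* keeps only crossing pairs and collapses each crossing
helix to one chord; a helix interrupted by internal loops still
collapses when no other chord endpoint intervenes. Genus is computed by
the boundary walk on the fatgraph: faces are the cycles of
`σ ∘ α` (α swaps chord endpoints, σ advances along the backbone), and
`g = (1 + n − r)/2` per connected component. For multi-chain diagrams
the backbones are concatenated into a single circle by default: the
per-backbone-vertex formula would assign genus 0 to an intermolecular
kissing dimer (two disks joined by three ribbons form a sphere), while
the kissing class is defined by its crossing pattern; concatenation
makes class and genus agree for inter- and intramolecular cases alike.
Exhaustive enumeration of irreducible diagrams with up to four chords
finds exactly four genus-1 classes — `ABAB` (H), `ABACBC` (K, kissing),
`ABCABC` (L) and `ABCADBCD` (M) — and the classifier matches those
patterns up to backbone reversal.

Angle conventions (the one genuinely open design area, documented here
so results can be cross-checked): for H-type, the interface is the
mutually nearest pair of axis ends and both vectors point away from it
(backbone-based rules are unusable here because crossing stems each
enclose a strand of the other). For kissing hairpins, each regular
stem's vector points away from the helix side whose loop holds the
kissing strand; the kissing-stem vector runs from its end nearer
stem 1's interface to the far end, stem 1 being the 5'-most regular
stem (assigned arbitrarily but deterministically for two-chain dimers).
Under these conventions a stack between stem 1 and the kissing stem
gives α near 180°, and a stack at the kissing stem's *other* end gives
β near 0° — the all-coaxial dimer geometry reports (α, β) ≈ (180°, 0°).
Kissing families are thresholded explicitly because they are otherwise
qualitative: family 1 at `γ < 32°` and `min(α, β) > 130°`; family 2 at
`γ ∈ [60°, 120°]`; family 3 when one of α/β exceeds 160° and the other
is below 20°; everything else is unclassified. All thresholds are
arguments of `kissing_family()`.

## Structure files and the sequence model

PDB and mmCIF files are read through `bio3d` (first model only; the
handling of duplicate residue identifiers across models is out of
scope). A chain is RNA when more than half of its residues normalize to
A/C/G/U and carry a C1' atom. Modified residues are normalized via a
bundled table of common chemical-component codes mapping to their
parent letter, with the original code kept as an annotation; unknown
codes are an error by default because silent coercion hides data
problems (`permissive = TRUE` maps them to N with a warning). The table
is an offline snapshot — reproducibility beats completeness — and
`inst/scripts/refresh_modifications.R` rebuilds it from the public
dictionary when desired. Residues declared in the header but lacking
coordinates (REMARK 465 / `pdbx_unobs_or_zero_occ_residues`) become
`present = FALSE` sequence entries, giving every sequence two views:
present-only (addressed by strict 1-based integers) and with-missing
(addressed by residue ids `chain:number[icode]`, which also carry
negative and offset reference numbering).

The built-in base-pair heuristic is a geometric fallback with explicit,
overridable thresholds: every canonical donor–acceptor contact of the
pair type (A-U: N1–N3, N6–O4; G-C: N1–N3, N2–O2, O6–N4; G-U: O6–N3,
N1–O2) must lie in 2.4–3.5 Å with at least two contacts, base-plane
normals within 30°, and mean inter-plane distance at most 2.5 Å (this
last test is what rejects stacked neighbours, whose planes are parallel
but ~2.8 Å apart). Conflicts are resolved greedily by the smallest mean
deviation from 2.9 Å, so each residue pairs at most once,
deterministically. The 6 Å protein/ligand interaction search uses all
RNA atoms against non-RNA C and N atoms (the atom set on the RNA side
is not pinned down by convention; using all atoms is the inclusive
choice and is stated here so it can be matched elsewhere).

## What the fixtures do and do not show

The generator builds duplexes with per-pair C1' midpoints exactly on
the local axis, spaced by the fiber-model rise of 2.81 Å and twisted
32.7° per step, with planar minimal-atom bases whose Watson-Crick-edge
contacts land inside the detection window by construction. Junction
fixtures place helices at exact angles and offsets (the anchor
separation is chosen perpendicular to both stem vectors, so the true
ray offset equals the requested value); kissing fixtures solve the
spherical-triangle relation `cos γ = cos α cos β + sin α sin β cos φ`
for a consistent placement and fail loudly on unrealizable triples.
Toy files add modified, missing and insertion-coded residues and a
decoy protein chain.

Passing on these fixtures shows that the pipeline — file parsing, pair
detection, decomposition, axis fitting, and the angle/offset/genus
computations — is internally correct and numerically exact on ideal
geometry. It does not show robustness to the messiness of experimental
structures: non-ideal helices bend, real base pairs deviate from
planarity, annotation tools disagree near modified residues, and the
axis fit on a strongly curved stem is a straight-line compromise.
Recovery tolerances on real data should be expected in the few-degree /
1 Å range that the end-to-end checks enforce, not at the numerical
precision the fixtures themselves achieve.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on generated
data: the geometry grid uses 15 fixtures (5 angles x 3 offsets) of
10-bp helices; the genus oracle enumerates all 124 chord diagrams with
up to 4 chords; the removal oracle covers all 11,464 perfect matchings
up to 12 positions in the tests (1,069 up to 10 positions in the
acceptance script); format round trips use 200 random structures up to
length 60. These sizes were chosen to make each exhaustive claim
literally exhaustive at desk scale while keeping a full run in minutes.
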