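---
title: "Kinase conformational geometry, conservation mapping, and binding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase conformational geometry, conservation mapping, and binding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconform)
```

## What this package computes

Selective kinase inhibitors are characterized along three complementary
axes: *which* kinases a compound inhibits (kinome selectivity panels),
*why* those kinases and not others (residue conservation shared by the
inhibited group), and *how* the compound holds its target (the
conformational state of the bound kinase domain, and the equilibrium
binding and dose-response behaviour). `kinconform` implements this whole
desk-side analysis chain for serine/threonine kinase domains, with the
AMPK alpha2 catalytic domain as the packaged default anchor set, plus a
seeded synthetic-data module so every stage can be exercised against known
planted truths.

## Panel selectivity groups

A kinome panel reports percent remaining activity per kinase for one
compound. `classify_groups()` partitions the panel with two inclusive
thresholds: *inhibited* at or below 50% remaining activity, and
*non-inhibited* at or above 99%. Kinases in between form an explicit
`unclassified` band rather than being discarded, so reports can state how
much of the panel the two cutoffs leave undecided. Duplicate measurements
per kinase/compound are averaged at load time and their SEM retained,
matching how panels reporting means of duplicate assays are consumed.
Identifiers are compared case-insensitively after whitespace stripping;
we deliberately do not resolve kinase name aliases, because silent alias
mapping is a classic source of irreproducible panel analyses.

## Conservation profiles

The conservation stage grades each alignment column on the familiar 1-9
scale (9 = most conserved). The scorer is deliberately tree-free and fully
deterministic:

1. **Henikoff position-based weights** down-weight redundant sequences.
2. Each column's weighted residue distribution is compared to a
   Robinson-Robinson background by **Jensen-Shannon divergence** (log base
   2), scaled by the weighted non-gap fraction. Gaps are never a 21st
   symbol; the scaling stops gappy columns from outranking fully occupied
   columns of the same composition.
3. **Grades** are equal-count rank bins: the top ninth of columns by score
   is grade 9, the bottom ninth grade 1. Ties share the grade of their
   first-occurrence bin, and a degenerate all-equal profile collapses to
   the neutral midpoint grade 5.

This is a different estimator from the phylogenetic Bayesian rate scorers
used by conservation web servers: those fit a tree and a substitution
model, and their grade values are not reproducible without the exact
alignment, tree, and model. Output therefore carries
`method_tag = "jsd-henikoff-v1"`, and grade *differences* from
phylogenetic scorers should be treated as qualitative when compared with
this package's grades.

Confidence flagging follows the same two-part rule conservation servers
print: a column is low-confidence when fewer than 6 sequences cover it, or
when its grade is unstable under resampling - here defined as the central
95% interval of the grade across bootstrap resamples of the sequences
(default 200 replicates, explicit seed required) being wider than 3 grade
points. The bootstrap is this package's own definition of the confidence
interval; it is deterministic under the seed.

`pairwise_identity()` counts matches over mutually non-gap columns, and
`map_to_reference()` projects column indices onto the author numbering of
a chosen reference row, so downstream tables speak in residue numbers.

## Differential conservation screen

`grade_delta()` subtracts non-inhibited-group grades from inhibited-group
grades per residue. The delta is signed so that "conserved in the
inhibited group but variable elsewhere" is positive; retention filters on
`|delta| >= 3` by default, and residues flagged low-confidence in either
profile are omitted unless requested otherwise. Residues covered by only
one profile are reported in an attribute, never silently dropped.
`assign_regions()` places retained residues into four editable spans of
AMPKalpha2 numbering: N-lobe (6-93), ATP-pocket ring (hinge 94-100 plus
catalytic loop 140-150), activation loop (157-182), and C-lobe helices
(the remainder to 280). The literature names these four clusters without
printing boundaries; the shipped spans are our choice, trimmed so they are
disjoint (the hinge is counted with the ATP pocket, not the N-lobe,
because assignment requires non-overlapping intervals).

## Structure geometry

Structures are parsed with bio3d (PDB and mmCIF) into a flat atom table;
hydrogens are dropped, alternate locations resolve to the
highest-occupancy conformer (ties prefer altloc A), and heteroatoms are
kept but excluded from protein residue indexing. Author residue numbering
is used throughout, because the community's anchor residues (Lys45, Glu64,
Leu68, the DFG triad 157-159, gatekeeper Met93, His137, Cys106/Cys174)
are author numbers.

The measured quantities:

* **D1** - D1-anchor (alphaC-Glu+4, Leu68) CA to DFG-Phe CZ; **D2** -
  beta3-Lys CA to DFG-Phe CZ; **Lys-Glu** - the salt-bridge CB-CB
  distance. Computation keeps full precision; tables conventionally print
  one decimal in Angstrom.
* **Phi/Psi** over the x-DFG-x window, IUPAC convention
  (`Phi(i) = C(i-1)-N(i)-CA(i)-C(i)`), range (-180, 180]. A peptide C-N
  distance above 2.5 Angstrom is a chain break: dihedrals across it are
  reported missing with a warning rather than computed across the gap.
* **Disulfides**: unordered CYS SG-SG pairs at or below 2.3 Angstrom
  (a typical S-S bond is about 2.05), matched greedily nearest-first so
  each cysteine joins at most one bridge.
* **Regulatory spine**: minimum side-chain heavy-atom distance between
  consecutive spine residues; any link above 4.5 Angstrom breaks the
  spine. The default spine set is the lower spine actually used when
  describing broken-spine inactive states - DFG-Phe158, HRD-His137 and
  alphaF-Asp196 - because a full four-residue spine numbering for
  AMPKalpha2 is not standardized; the set is an ordinary argument.
* **Superposition**: Kabsch least squares, proper rotation only
  (determinant +1), RMSD over the paired atoms; degenerate (fewer than 3
  or collinear) inputs are an error.

## Conformational calls

`spatial_label()` maps (D1, D2) to DFG-in / DFG-out / DFG-inter with the
default rule: DFG-out when `D2 <= 11`; DFG-in when `D2 >= 11` and
`D2 - D1 >= 2`; otherwise inter. Published classification schemes do not
print universal boundaries, so these defaults are chosen to label the
canonical DFG-in range (D1 around 11-13, D2 around 16-19 Angstrom) as
DFG-in; every call echoes `thresholds_used`, and the label is a pure
function of measurements plus thresholds. `alphaC_label()` calls the helix
*out* when the Lys-Glu distance strictly exceeds 10 Angstrom - the
boundary itself is *in*.

`dihedral_cluster()` assigns the ten x-DFG-x angles to the nearest
centroid by mean circular distance (wraparound respected: -179 and 179
degrees are 2 apart), with missing terminal angles dropped under weight
renormalization. A best distance above the 45-degree cutoff yields
`"unassigned"` - deliberately representable, since real structures do
fall outside every established cluster. The shipped centroid library is
illustrative data, clearly labelled as such; users wanting assignments
against a published taxonomy should load that taxonomy's centroids into
the same structure.

## Binding models

Two curve models are implemented exactly as practitioners specify them:

* one-site total binding,
  `Y = Bmax*X/(Kd + X) + NS*X + Background`, and
* the variable-slope inhibitor-versus-response logistic on log10
  concentration,
  `Y = Bottom + (Top - Bottom) / (1 + 10^((log10(IC50) - log10(X))*Hill))`.

Fitting is unweighted Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`), replicates fitted jointly; no weighting scheme is
assumed because the assay software producing such fits defaults to
unweighted least squares too. Initialization comes from the data
(background/bottom from the response minimum, Kd at the half-rise
concentration, IC50 at the half-response quartile, Hill sign from the
trend); bounds keep `Kd` and `IC50` positive and `Bmax` non-negative.
Standard errors come from the Jacobian at the optimum. A flat response
vector returns `converged = FALSE` rather than a silent answer, and the
4PL fit is canonicalized to `Top >= Bottom` (swapping plateaus and
negating the Hill slope is the identical curve). Zero-concentration
points cannot sit on a log axis and are dropped from the logistic fit
with a warning.

`dilution_series()` reproduces the 1:1 serial-dilution design used for
spectral-shift binding assays: from 250 concentration units, 16 two-fold
steps floor at `250/2^15` (about 0.0076), while 15 points floor at
`250/2^14` (about 0.0153). Protocols quoting "16 steps ... down to 0.015"
are internally consistent with the 15-point reading; both are available
through `n_points`, and the package takes no position beyond exposing the
closed form.

## The synthetic-data module

Every generator is a pure function of its seed, and each emits its planted
truth alongside the data so downstream tests are self-contained.

* `make_panel()` draws activities inside the planted bands (defaults: 7
  inhibited, 10 non-inhibited, 123 between - a 140-kinase panel shape).
* `make_msa()` plants three column classes: conserved (one residue),
  variable (balanced multiset over a 10-residue pool), and intermediate
  (a dominant residue at a per-column fraction of 0.6-0.8, remainder from
  the pool). Compositions are balanced multisets rather than i.i.d.
  draws: with i.i.d. sampling the realized dominant fraction of an
  intermediate column can drift far enough to cross the conserved score
  floor, which would make the planted classes overlap by construction
  noise rather than by anything the scorer did. Intermediate columns
  exist to fill the middle of the rank distribution so equal-count
  grading can place conserved columns in grades 8-9 and variable columns
  in grades 1-2.
* `make_structure()` builds an N/CA/C backbone by sequential
  internal-coordinate (NeRF) placement with ideal bond lengths and angles
  (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; 111/117/121 degrees;
  omega fixed at 180), so measured Phi/Psi equal the planted targets to
  numerical precision. Optional plants: a CYS pair whose SG-SG distance
  is exact, and an anchor set realizing stated D1/D2/Lys-Glu distances.
  The anchor residues are free-standing islands placed by sphere
  intersection (the inter-CA separation is set to `max(D1, D2)`, which
  always admits a solution for positive distances); the result is a
  measurement fixture, not a physical fold, and makes no claim to
  side-chain realism.
* `make_curve()` composes the dilution design with either curve model and
  seeded Gaussian noise (the assays' error model is not published;
  Gaussian is the neutral choice), two technical replicates per
  concentration by default.

What passing the planted-truth tests shows: the measurement and
classification code inverts its own constructions exactly, and the
fitters recover generating parameters under the stated noise. What it
does not show: agreement with phylogenetic conservation graders on real
alignments, robustness to crystallographic pathologies (disorder, low
occupancy, alternate chains) beyond the altloc rule, or the biological
validity of the default thresholds - the real-structure checks in the
test suite fetch two public PDB kinase-domain entries and verify the
printed distance and dihedral tables directly when a network is present.

## Problem sizes and runtime choices

The packaged analyses run at desk scale by design: 140-kinase panels,
50-sequence by 90-column alignments with 200 bootstrap replicates, planted
structures of tens of residues, 16-point curves with two replicates, and
100-repeat Monte-Carlo recovery studies at 2% noise. These sizes keep the
whole suite and the acceptance script in the seconds-to-minutes range
while leaving every statistical property testable.

## Known limitations

* Grades are estimator-specific; only grade *differences* of 3 or more
  between groups are treated as screen-worthy signal, mirroring the
  conservative use of such scales.
* The dihedral cluster library ships illustrative centroids, not a
  published taxonomy.
* The DFG spatial boundaries are configurable stand-ins; they are echoed
  in every output precisely so that downstream readers never have to
  guess which rule produced a label.
* No de novo alignment, no phylogenetic tree inference, no
  crystallographic data processing, and no molecular graphics - alignments
  and coordinates are inputs, and the outputs are tables a viewer can
  consume.
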