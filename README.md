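# kinconform

Desk-side analysis of kinase inhibitor selectivity and structure:
kinome-panel selectivity grouping, group-differential residue-conservation
screening, geometric classification of kinase-domain conformational states,
and equilibrium binding / dose-response curve fitting — with seeded
synthetic-data generators so every stage is testable against planted
truths. The packaged residue anchors default to the AMPK alpha2 kinase
domain, the system for which this analysis chain is most often run, but
every anchor, threshold, and span is an ordinary argument.

It is written for structural bioinformaticians and chemical biologists who
have: a kinome panel table (percent remaining activity per kinase), kinase
domain alignments for an inhibited and a non-inhibited kinase group,
coordinates of inhibitor-bound kinase domains (PDB or mmCIF), and raw
concentration–response measurements.

## The core quantities

**Selectivity groups.** A kinase is *inhibited* when remaining activity
≤ 50 %, *non-inhibited* when ≥ 99 % (both boundaries inclusive), and
*unclassified* in between; `overlap_groups()` gives the Venn partition
of two compounds' inhibited sets.

**Conservation.** Per-column scores are Henikoff-weighted Jensen–Shannon
divergences from a Robinson–Robinson background, rank-binned onto the 1–9
grade scale (9 = conserved), with bootstrap low-confidence flags
(coverage < 6 sequences, or a 95 % bootstrap grade interval wider than 3).
The differential screen keeps residues with |Δgrade| ≥ 3 between groups
and maps them to four structural regions in reference numbering.

**Conformational state.** For an anchor set
(β3-Lys45, αC-Glu64, Leu68, DFG 157–159, x-DFG-x 156–160):

```
D1 = |Leu68 CA − Phe158 CZ|      DFG-out  iff D2 ≤ 11 Å
D2 = |Lys45 CA − Phe158 CZ|      DFG-in   iff D2 ≥ 11 Å and D2 − D1 ≥ 2 Å
Lys–Glu = |Lys45 CB − Glu64 CB|  αC-out   iff Lys–Glu > 10 Å
```

plus IUPAC Φ/Ψ over the x-DFG-x window with nearest-centroid dihedral
clustering (mean circular distance, `"unassigned"` beyond 45°), disulfide
detection (SG–SG ≤ 2.3 Å, greedy nearest-first), regulatory-spine contact
status (side-chain minimum distance ≤ 4.5 Å per adjacent pair), and
Kabsch superposition.

**Binding models.**

```
Y = Bmax·X/(Kd + X) + NS·X + Background                (one-site total)
Y = Bottom + (Top − Bottom)/(1 + 10^((log10 IC50 − log10 X)·Hill))   (4PL)
```

fitted by unweighted Levenberg–Marquardt least squares with
Jacobian-based standard errors and honest convergence flags.

## Worked example

```r
library(kinconform)

# a 140-kinase panel with a planted partition, recovered by the classifier
syn <- make_panel(n_inhibited = 7, n_noninhibited = 10, n_between = 123,
                  seed = 42)
classify_groups(syn$table, "CMPD-1")
#> Selectivity groups for CMPD-1 (<=50% inhibited, >=99% non-inhibited)
#>   inhibited:    7
#>   noninhibited: 10
#>   unclassified: 123

# a fixture with planted D1/D2/Lys-Glu distances, classified
s <- make_structure(n_res = 10, resno_start = 153,
                    anchor_distances = list(
                      d1 = 12.4, d2 = 18.4, lys_glu = 11.7,
                      resno = c(lys = 45, glu = 64, d1_anchor = 68,
                                phe = 158)),
                    seed = 7)
classify_conformation(s$model)
#> synthetic: DFG-in, alphaC-out, dihedral cluster: unassigned
#>   D1 12.4 A, D2 18.4 A, Lys-Glu 11.7 A

# a noisy 16-point dose-response curve, fitted back
cv <- make_curve("dose-response",
                 params = list(top = 100, bottom = 0, ic50 = 0.5,
                               hill = -1),
                 sigma = 2, seed = 11)
fit_dose_response(cv$curve)
#> dose-response-4pl fit (converged)
#>   top             98.2863  (SE 0.7957)
#>   bottom        -0.451455  (SE 0.5181)
#>   ic50           0.513653  (SE 0.01641)
#>   hill           -1.03402  (SE 0.03133)
#>   RSS 61.0364
```

The classifier recovers the planted 7/10/123 partition exactly; the
planted distances come back at full precision and label DFG-in with an
out αC helix; and the fitted IC50 (0.514 µM) sits within the noise of the
generating 0.5 µM.

A full multi-stage run (panel → conservation → differential; structure →
geometry → classification; curves → fits) is driven from one YAML file by
`validate_config()` / `run_pipeline()`, which write per-stage TSVs and a
consolidated `report.json` embedding every threshold and seed used.

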