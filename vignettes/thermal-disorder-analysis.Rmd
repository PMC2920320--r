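---
title: "Structural disorder across prokaryotic thermal classes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural disorder across prokaryotic thermal classes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Intrinsically disordered proteins and regions (IDPs/IDRs) lack a fixed
native structure, are enriched in regulatory and signalling functions, and
are unusually resistant to temperature extremes in vitro. A natural
hypothesis is that organisms adapted to very low or very high optimal
growth temperature (OGT) exploit disorder more than mesophiles do. The
comparative analysis implemented here tests that hypothesis on proteome
scale: it quantifies predicted disorder per proteome, groups species into
four thermal classes — psychrophiles (OGT 5–17 °C), mesophiles (20–42 °C),
thermophiles (45–75 °C) and hyperthermophiles (75–105 °C) — and compares
the classes with nonparametric statistics, alongside a charge–hydropathy
control analysis, a transcription-factor profile and a GO
biological-process profile of proteins with long disordered regions.

`thermidp` implements that pipeline end to end and couples it to a seeded
synthetic proteome generator, so every stage is testable on a desk machine
with no database downloads.

## Disorder scores and proteome measures

Disorder is consumed as a per-residue *score track* in [0, 1], one value
per residue. Tracks come from either of two sources:

* **External predictors.** An adapter reads IUPred-style three-column
  output (position, residue, score; `#` comment lines delimit proteins).
  Tracks must cover every protein of the panel and match sequence lengths
  exactly; any gap or mismatch aborts the analysis before statistics are
  computed.
* **The bundled composition-window scorer.** Each residue is assigned a
  propensity — 1 for the disorder-promoting set {Ala, Arg, Gly, Gln, Ser,
  Pro, Glu, Lys}, 0 for the order-promoting set {Trp, Cys, Phe, Ile, Tyr,
  Val, Leu}, 0.5 for everything else including the ambiguity codes X, B,
  Z, U — and smoothed with a centred running mean of width 21 residues
  (odd, configurable). At the termini the window shrinks rather than pads,
  so no boundary residues are invented. This scorer is a transparent
  composition-based stand-in, not a reimplementation of IUPred's pairwise
  energy estimation or VSL2's trained models; it exists so that the
  pipeline and its tests are self-contained. Conclusions asserted on its
  output in the test-suite concern synthetic panels only and do not claim
  numeric agreement with the published predictors.

A residue is called disordered when its score is **strictly above 0.5**
("above the threshold" is read as strict). From the binary mask the
package derives, per protein: the mean score, the number of disordered
residues, the *mostly disordered* flag (strictly more than half of the
residues disordered — a protein with exactly half is not mostly
disordered), and *long IDRs*, maximal runs of at least 30 consecutive
disordered residues, reported as 1-based inclusive intervals. A run of 29
is never a long IDR; the boundary is covered explicitly by tests against a
brute-force run scan.

Per proteome, five percentage measures are reported. Two of them answer
the same question with different weights, and both are emitted because
summaries of "average disorder" are ambiguous between them:

* `avg_protein_mean_score` — the per-protein mean score, averaged over
  proteins (each protein counts equally). This is the default headline
  measure for grouping, binning and the size correlation.
* `pct_disordered_residues` — pooled fraction of residues above the
  threshold (each residue counts equally).

plus the percentage of proteins with mean score above the threshold, the
percentage of mostly disordered proteins, and the percentage of residues
inside long IDRs. Raising the threshold can only lower every measure; this
monotonicity is a tested property.

## Charge–hydropathy (Uversky) control

Predictor-independent classification uses mean net charge
`R = |n(Arg) + n(Lys) − n(Asp) − n(Glu)| / n` and mean hydropathy `H` on
the min–max normalised Kyte–Doolittle scale (`(kd + 4.5)/9`, Ile 1, Arg
0), both computed over all non-ambiguous residues. The separating line is

&nbsp;&nbsp;&nbsp;&nbsp;`H = (R + 1.151) / 2.785`

with proteins strictly below the line called disordered. Points exactly on
the line are called ordered: the line is the separator, and the
conventional reading places boundary points with the ordered side; the
choice is documented here and covered by a test. `R` and `H` are plain
means over the full sequence — the original charge–hydropathy method's
short windowed variant is not applied, because plain means are the
simplest reading of a "normalized Kyte-Doolittle scale" and the windowed
variant changes nothing about composition-level conclusions. Both
quantities depend only on composition, so the classification is invariant
under sequence permutation (a tested property). Panels larger than 2000
proteins are reduced to a seeded uniform sample of 2000 without
replacement, mirroring the published sampling depth per thermal category.

His is treated as uncharged. Ambiguity codes are excluded from both the
charge and hydropathy sums; a sequence consisting only of ambiguity codes
has no defined CH point and is rejected.

## Thermal classes, group statistics, taxonomy and size

OGT handling follows three rules: an exact value passes through; a range
is replaced by its arithmetic midpoint (20–30 °C becomes 25 °C); a species
with neither keeps an unknown OGT and must carry a class label. The four
printed class ranges share the 75 °C boundary; 75 °C is assigned to the
hyperthermophiles, since the hyperthermophile discussion concerns OGT ≥
75. Values in the gaps (17, 20) and (42, 45), or outside 5–105 °C, occur
in synthetic or user data even though the published dataset had none; they
are assigned to the class with the nearest range boundary (ties to the
colder class) and flagged for audit rather than rejected, keeping
classification total.

Per class, the package reports n, mean, median, SEM (0 for singleton
classes) and the min–max range of the chosen measure, and compares each
non-mesophilic class to the mesophiles with the Mann–Whitney test.
Genus-level averages are binned for taxonomic display as white [0, 16),
yellow [16, 20), ochre [20, 24), orange [24, 28) and red [28, ∞) percent —
half-open bins so that every value falls in exactly one bin. The
proteome-size/disorder relation is summarised by the Spearman rank
correlation between the number of proteins and the headline measure: the
underlying claim is ordinal (smaller genomes, less disorder), so a rank
statistic is the right level of commitment and is labelled as such in the
output.

## Statistics

The Mann–Whitney U statistic is computed from rank sums with midranks for
ties. For small tie-free comparisons (combined n ≤ 12) the two-sided
p-value is exact; otherwise the normal approximation with tie correction
and continuity correction is used. The switch point is a cost/benefit
choice — enumeration grows combinatorially, and the group sizes of any
realistic panel force the approximation anyway. The exact branch is
verified in the tests against full enumeration of label assignments, and
the approximate branch holds its type-I error (rejection rate at α = 0.05
within [0.03, 0.07] over 2000 seeded null simulations). The 2×2 chi-square
uses the Pearson statistic without continuity correction against a 1-df
chi-square distribution. Significance is annotated as `*` (p < 0.05) and
`***` (p < 0.0001), both strict; p-values are two-sided and reported raw —
the handful of planned comparisons is not multiplicity-corrected, and the
report metadata says so.

## Transcription factors and GO profiling

A transcription factor (TF) is any protein *directly* annotated
GO:0003700; no ontology-graph propagation is attempted, which keeps the
definition reproducible without an ontology snapshot. Per thermal class
the package reports TF count, mean length ± SEM, mean predicted disorder
(per-protein mean score, %) ± SEM, and the TF ratio among annotated
proteins, with Mann–Whitney comparisons against the mesophiles.

Two mesophile control groups are built to separate genome-size effects
from thermal adaptation: *meso-thermo* and *meso-hyper*, matched on mean
proteome size of thermophiles and hyperthermophiles respectively. The
construction is a deterministic, seedless greedy rule: sort mesophiles by
distance of their proteome size from the target mean (ties by species
id), then add species while each addition moves the subset mean no
farther from the target. When no mesophile is small enough — which is the
expected situation when hyperthermophile proteomes are half the mesophile
mean — the achieved mean can miss the target by more than 10%, and the
function warns rather than fails.

For the functional profile, proteins with at least one long IDR are
grouped — hyperthermophiles (H) against mesophiles with low (MLD, 1–4%)
and medium (MMD, 8–11%) average disorder, closed bands on the headline
measure — and tabulated by GO biological-process term. The denominator is
all long-IDR proteins of the group (not only those with a process
annotation; the alternative is a configuration switch away since the
published convention is not stated). A protein with several process terms
counts once per term, so a column may sum above 100%. Percentages below
1% are displayed with the floor marker `"<1%"` while the numeric value is
retained in the machine-readable output.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not real genomes. Each protein is a concatenation of segments; a segment
is disordered with probability `p = 2t/(1 + t)`, where `t` is the class
disorder target, so that with geometric segment lengths of mean 40
(disordered) and 80 (ordered) the expected residue fraction in disordered
segments equals `t`. The length means straddle the 30-residue
segmentation boundary on purpose: sub-threshold disordered segments must
occur for the long-IDR rule to be exercised. Disordered segments draw
residues from the disorder-promoting set with probability 0.8 (remaining
mass uniform over the other canonical residues); ordered segments mirror
this with the order-promoting set. This enrichment separates the bundled
scorer's output on the two segment types by well over 0.2 score units, a
tested property. Protein lengths are jittered ±50% around the mean with a
floor of 30 residues; proteome sizes ±20% around the class mean.

Default study conditions, chosen once: six species per class; class mean
proteome sizes 400 (psychrophile), 600 (mesophile), 500 (thermophile) and
300 (hyperthermophile) proteins — hyperthermophiles at half the mesophile
mean; disorder targets 4%, 12%, 10% and 3% respectively; mean protein
length 300; TF fraction 3% of proteins; hyperthermophile TFs shorter
(length factor 0.7) and less disordered (disorder factor 0.5) than
mesophilic ones, psychrophile TFs shorter (0.7) as well. These sizes are
desk-scale — the default panel holds roughly 11,000 proteins and 3 M
residues — and the recovered per-class medians of
`pct_disordered_residues` land within ±2 percentage points of the
configured targets across seeds, a property the test-suite and the
acceptance script both recompute.

Randomness is split into a per-species stream derived from the master
seed and a stable per-species index, so adding species to one class never
perturbs the proteomes of existing species — a property the tests assert
byte for byte. OGT values are drawn uniformly within the class range and
reported as an exact value (60% of species), as a ±2 °C range (30%), or
withheld with only the class label (10%), exercising all three metadata
conventions.

What the generator does **not** emulate: phylogenetic correlation between
genera (genus labels are arbitrary groupings), codon-level or
secondary-structure realism, halophile-style charge biases that are known
to confound CH-based predictions, and the residue-level statistics of any
real predictor. Passing tests on synthetic panels therefore demonstrate
that the pipeline's arithmetic, rules and statistics behave as specified —
not that the bundled scorer reproduces published disorder levels for real
proteomes.

## Packaged reference tables

Two small tables ship under `inst/extdata/`, both *synthetic stand-ins*
(and named so): a species table with 332 rows of which 195 carry an exact
OGT, 124 an OGT range and 13 only a class label, and a TF table with 18 /
1581 / 62 / 101 transcription factors in psychrophiles / mesophiles /
thermophiles / hyperthermophiles. The marginal counts match the published
dataset description; row-level content (ids, taxa, temperatures) is
generated, because the original per-species tables are not
redistributable in plain text. They exist to exercise the parsing and
counting paths at the real dataset's shape.

## Numerical and degenerate-input choices

* Threshold comparisons (`> 0.5`, `> 50%`, star thresholds, band edges)
  are strict or closed exactly as stated above; each rule carries a test.
* SEM of a single observation is defined as 0 (a singleton class displays
  a zero-width error bar rather than NA).
* Empty inputs fail loudly: an empty proteome summary, a species with no
  OGT and no class, a score outside [0, 1], non-consecutive track
  positions, and a zero-margin chi-square table are all errors, not
  warnings.
* The orchestrated run writes every intermediate table, a JSON report
  mirroring them with provenance (scorer label, window, threshold, seed),
  a plain-text summary and a MANIFEST; reruns with identical
  configuration are byte-identical, which the tests compare file by file.

## Known limitations

The bundled scorer is intentionally simple; its absolute score levels
have a composition-driven floor (≈0.16 on fully ordered segments), so
`avg_protein_mean_score` on synthetic panels sits well above the
residue-fraction target, while `pct_disordered_residues` recovers the
target closely. Comparisons across classes are unaffected, but absolute
levels from the bundled scorer should never be compared with published
predictor output. The matched-mesophile rule cannot conjure small
mesophiles where none exist; it warns instead. GO profiling ignores
ontology structure entirely.
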