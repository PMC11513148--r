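---
title: "Profiling membrane-protein quality control: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling membrane-protein quality control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcprof)
```

## What the package computes

Golgi-resident quality control in yeast is thought to recognize *orphaned*
membrane proteins — subunits that mislocalized or failed to assemble — by a
physical feature of their transmembrane domains (TMDs): hydrophobic length.
A rhomboid-pseudoprotease-containing ubiquitin-ligase complex locally thins
the bilayer, engages proteins whose TMDs are too short for the surrounding
membrane, and routes them to degradation. Loss of this pathway leaves a
measurable fingerprint in three kinds of data, and `qcprof` implements the
corresponding analyses:

1. **SILAC differential membrane proteomics** (`run_silac_contrast()` and
   friends): which proteins accumulate in a deletion mutant relative to
   wild type, from heavy/light peptide ratio tables across biological
   replicates, with an overlap classification between two mutant contrasts
   and a GO-component frequency table.
2. **TMD signature profiling** (`parse_topology()`, `extract_tmds()`,
   `signature_stats()`): the hydrophobic-length distribution of the
   accumulating proteins' TMDs, oriented cytosolic-to-luminal, with the
   headline fractions (TMDs at or below 16/18 residues, per-protein
   shortest TMD, per-protein TMD counts).
3. **Lipidome acyl-asymmetry analysis** (`normalize_per_class()`,
   `classify_asymmetry()`, `compare_groups()`): per-class mol%
   normalization, total-acyl-carbon aggregation, classification of
   short/long asymmetric glycerophospholipid species, and per-species group
   statistics under a two-stage adaptive FDR.
4. **Bilayer thinning maps** (`assign_leaflets()`, `thickness_map()`,
   `thinning_summary()`, `difference_map()`): time-averaged inter-leaflet
   distance on an x–y grid from membrane trajectory frames, the bulk-vs-
   minimum thinning summary, and condition differences.

Each analysis has a seeded generator (`generate_proteome()`,
`generate_silac_table()`, `generate_lipidome()`,
`generate_bilayer_trajectory()`) that produces inputs with the statistical
structure the stage assumes, so every claim the test suite makes is checked
against a known ground truth without downloading anything.

## SILAC differential abundance

Peptide-level log2(H/L) records are reduced to one value per protein and
replicate. The default reduction is the **median** — robust to a single
aberrant peptide — with the mean available (`aggregate = "mean"`). A protein
enters the analysis only with **two or more distinct peptides** quantified
in **at least two of the three replicates**; both thresholds are arguments.

Each retained protein is tested against the *background* formed by all
retained proteins' replicate-level values. In a genome-scale label-swap
experiment the overwhelming majority of proteins are unregulated, so the
background mean estimates the no-change expectation, and deviation from it
is the quantity of interest. The statistic is a one-sample t of the
protein's replicate values against the background mean with
`df = n_replicates − 1`. Two scale policies are provided:

* `"pooled"` (default): the scale is the **larger** of the target SD and the
  background SD. This guards against understated per-protein variance (a
  protein quantified by few peptides can have an accidentally tiny spread)
  and is deliberately conservative: under a global null its realized type-I
  error is at or below the nominal level.
* `"target_only"`: the plain one-sample t. This is the calibrated choice —
  under a simulated global null the fraction of p ≤ 0.05 is 0.05 within
  Monte-Carlo error — and what the test suite uses to check calibration of
  the whole filter→test→call chain.

Significance uses the printed rule: mean −log2(H/L) ≥ 0.3 **and** raw
p ≤ 0.05, both boundaries inclusive. Benjamini–Hochberg adjusted values are
reported alongside, but the flag follows the raw p, as the rule states.
The overlap of two contrasts is classified on the shared quantified
(membrane) proteins into `both` / `a_only` / `b_only` / `neither`; the
`−log2 > −1` floor trims only the scatter display table, never the
classification.

## TMD topology and signatures

Two topology dialects are parsed: a GFF3-like table (`id label start end`,
1-based inclusive, with `# id Length:` headers) and a three-line per-residue
format (`>id | TM=k` / sequence / label string over `I O M S`). Parsing
validates that segments tile `[1, length]` exactly; corrupt inputs are
rejected with the protein and position named, because a silent off-by-one in
TMD coordinates would bias every downstream length statistic.

Orientation follows the flanking labels: a helix preceded by a cytosolic
(`inside`) segment runs in→out, one preceded by a luminal (`outside`) or
signal segment runs out→in, and `oriented_seq` is reversed for out→in
helices so that all TMDs read cytosolic-side first. "Cytosolic" is equated
with the predictor's `inside` label — correct for ordinary single-membrane
topologies, a documented approximation for exotic multi-pass cases. An
N-terminal helix with no preceding segment is oriented from the following
flank; a helix with no flank at all is an error.

`signature_stats()` reports the raw predicted segment length
(`end − start + 1`) with no trimming. Length thresholds are inclusive
(≤ 16, ≤ 18 residues) and the count threshold splits at ≤ 10 / > 10;
all are arguments. Quartiles use R's default linear interpolation
(`quantile(type = 7)`); this affects only the dotted-quartile reproduction,
not any headline fraction. Proteins with zero predicted TMDs are tallied
separately (`n_proteins_no_tmd`) and excluded from length statistics, never
silently dropped. `compare_signatures()` adds per-statistic deltas and a
Wilcoxon rank-sum p on the raw lengths — the rank-sum test is an extension
for synthetic benchmarking, not a statistic the source analysis defines.

A deliberately simple hydropathy fallback (`hydropathy_fallback_tmds()`,
19-residue Kyte–Doolittle window, cutoff 1.6) exists so the pipeline can run
on bare sequences; it is labeled non-authoritative, makes no orientation
call, and its only tested guarantee is ≥ 90% recall of planted TMD
midpoints on the synthetic proteome.

`helix_extension_rise()` encodes the ideal α-helical rise of 1.5 Å per
residue: extending a TMD by 3 or 6 residues adds 4.5 Å or 9 Å of spanning
length.

## Lipidome asymmetry and the two-stage FDR

Abundances are expressed as **mol% of class**: within each (sample, class)
the values are rescaled to sum to 100. The operation is idempotent and
conservation is tested to 1e-9. Total-acyl labels (`C-26`, `C-28`, …) sum
the two chains' carbons. A species is called **asymmetric** when its chains
differ by ≥ 6 carbons — a cut that covers 10:0/16:0 and 10:0/18:x pairings
while excluding the common 16/18 combinations — and the saturation profile
separates two-saturated-chain species from those whose long chain is
mono-unsaturated. Species known only by sum composition stay in total-acyl
panels and are excluded (as `unknown`) from asymmetry panels.

Group comparison is a per-species unpaired t with **pooled variance**
(equal variances assumed, i.e. Student rather than Welch), means ± SD
reported per group. Discovery flags come from the **two-stage
Benjamini–Krieger–Yekutieli** adaptive step-up at Q = 1%: stage one runs a
BH step-up at q′ = Q/(1+Q) to estimate the number of true nulls
m₀ = m − r₁, stage two reruns the step-up at q′·m/m₀. When stage one
rejects nothing the procedure stops with no discoveries; when it rejects
everything, everything is flagged. The statistical family is one lipid
class's species set by default, mirroring per-class figure panels
(`family = "global"` corrects across all species instead); the choice is
exposed because the source analysis does not state its family.

One property worth stating explicitly: mol%/class is compositional, so a
planted enrichment of one species necessarily depresses its class siblings.
Discoveries among siblings of a planted species are therefore *true*
differences, and the planted-truth tests assert "planted species found,
untouched classes clean" rather than "nothing but the planted species".

## Bilayer thinning maps

Trajectory frames are point clouds of one reference point per lipid with a
leaflet tag. For PDB input every atom is taken as a reference point (the
expectation is a pre-reduced trajectory, e.g. phosphorus atoms); leaflet
tags ride in the chain identifier, and untagged points are assigned by the
per-frame median z (`assign_leaflets()`), which recovers generator truth
perfectly whenever thermal noise is small against the leaflet separation.

`thickness_map()` bins the x–y plane (2 Å default) and, per bin and frame,
takes mean upper-leaflet z minus mean lower-leaflet z; the map value is the
average over frames in which both leaflets are present in the bin. Bins
never populated are reported `NA` — empty, never zero, and never
interpolated — because a protein-occupied footprint is information, not
missing data. The averaging window defaults to the **final 40% of frames**,
mirroring analysis of the converged tail of a production run, and is an
argument. `thinning_summary()` takes the map minimum as the thinning site,
the mean over bins farther than 25 Å from it as bulk, and reports
`bulk − min`. `difference_map()` subtracts per bin (nearest-bin resampling
when grids differ) and differences the two thinning summaries.

## Synthetic generators: what they emulate, and what they do not

All generators draw through an isolated RNG (`with_seed()`): the same spec
and seed give byte-identical output and the caller's RNG state is never
touched.

* `generate_silac_table()` plants per-protein −log2(H/L) shifts, Gaussian
  peptide noise in log2 space (the standard error model for isotope-ratio
  quantification), and uniform-at-random missingness. It does *not* emulate
  intensity-dependent missingness, shared peptides, or protein-inference
  ambiguity.
* `generate_proteome()` builds polar linkers alternating with
  hydrophobic-alphabet TMD stretches of sampled lengths (support
  constrained to 10–30 residues), alternating membrane sidedness. It does
  not emulate real amino-acid composition beyond the hydropathy contrast,
  signal peptides, or re-entrant loops.
* `generate_lipidome()` applies multiplicative group effects to a species
  catalog, log-normal replicate noise at a chosen CV, then renormalizes per
  class. Defaults: 4 replicates per group; 5–10% CV spans typical shotgun
  replicate scatter for abundant glycerophospholipid species.
* `generate_bilayer_trajectory()` is a geometry-only stand-in for a
  membrane patch: two sheets of per-lipid reference points, a Gaussian
  dimple of depth d and width σ split symmetrically across leaflets, and
  thermal z-noise. Defaults (64×64 Å box, 250 points per leaflet, 40 Å
  separation, σ = 8 Å, 1 Å noise, 100 frames) were chosen once so that a
  4 Å-binned, 100-frame map accumulates ≳100 samples per bin, putting the
  Monte-Carlo error of the map minimum near 0.1 Å (3·sd/√n ≈ 0.3 Å
  tolerance in the tests). Lateral positions are redrawn each frame — an
  idealized fluid — so there is no lateral diffusion correlation, no
  molecular detail, and no physics.

Passing tests on these inputs demonstrate that the *analysis* recovers what
the generators plant under the stated noise; they cannot certify behavior
on real search-engine output, real lipid annotation quirks, or real
force-field trajectories.

## Numerical choices and degenerate inputs

* Threshold boundaries are inclusive exactly as printed (≥ 0.3, ≤ 0.05,
  ≤ 16/18, > 10).
* `adjust_bh()` and the step-up core call `stats::p.adjust`; the brute-force
  step-up definition lives in the test suite as an independent oracle, and
  the two-stage composition is checked against a hand-run of both stages
  exhaustively for families up to 12 hypotheses.
* Zero-variance backgrounds are an error (a degenerate experiment, not a
  p-value); zero-variance targets under `"target_only"` collapse to the
  smallest representable p when shifted and to 1 when not.
* Species constant in both groups get p = 1 with a warning rather than NaN.
* A point exactly at the median z is assigned to the lower leaflet with a
  warning; a frame whose points all land on one side is an error.
* Maps too small to contain a bulk region (no bin farther than the bulk
  radius from the minimum) are an error rather than a silent bulk-equals-
  minimum summary.

## Problem sizes used by the tests and the acceptance script

Simulation-backed checks run at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: 2000 proteins for type-I calibration
(SE ≈ 0.005 on a 0.05 rate), 1000 repetitions of a 100-hypothesis null
family for the FDR bound, 100-frame trajectories with 300 points per
leaflet for the 0.3 Å dimple tolerance, and 120 frames with 400 points per
leaflet for the 10% width-recovery check.

## Known limitations

* The background-test formula of the original acquisition software is not
  public; the implementation here is the package's own, documented above,
  with the conservative/calibrated switch exposed.
* Multi-pass proteins with non-standard topologies (re-entrant loops,
  interrupted helices) are oriented purely by flanking labels.
* The thinning analysis assumes a single dominant thinning site; multiple
  comparable minima would make the bulk-region definition ambiguous.
* Periodic-boundary wrapping is not applied to x–y coordinates; frames are
  expected pre-wrapped into the box.
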