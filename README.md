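# qcprof — membrane-protein quality-control profiling

`qcprof` is an R package for scientists studying how Golgi quality control
recognizes and degrades *orphaned* membrane proteins — proteins that
mislocalized or failed to find their binding partners. The working model is
physical: a Golgi ubiquitin-ligase complex carrying a rhomboid
pseudo-protease subunit locally thins the bilayer and engages proteins whose
α-helical transmembrane domains (TMDs) are too short for the surrounding
membrane, so that a short hydrophobic length acts as a degron. Testing that
model computationally takes four different analyses, and the package
implements all of them behind one consistent, seeded, file-based pipeline:

| Analysis | Core quantity | Entry points |
|---|---|---|
| SILAC differential proteomics | per-protein mean −log₂(H/L), background-based t-test, BH adjustment; significant iff −log₂ ≥ 0.3 and p ≤ 0.05 | `run_silac_contrast()`, `overlap_contrasts()`, `go_component_frequency()` |
| TMD signature profiling | oriented TMD lengths; frac(length ≤ L), per-protein shortest TMD, TMD counts | `parse_topology()`, `extract_tmds()`, `signature_stats()` |
| Lipidome acyl asymmetry | mol%/class; Δ-carbons ≥ 6 asymmetry calls; pooled-variance t with two-stage Benjamini–Krieger–Yekutieli FDR at Q = 1% | `normalize_per_class()`, `classify_asymmetry()`, `compare_groups()` |
| Bilayer thinning maps | time-averaged inter-leaflet distance d(x,y); max thinning = bulk − min | `thickness_map()`, `thinning_summary()`, `difference_map()` |

Every analysis has a matching seeded generator (`generate_silac_table()`,
`generate_proteome()`, `generate_lipidome()`,
`generate_bilayer_trajectory()`) so the full pipeline runs and is tested
without any external data. `run_pipeline()` orchestrates
simulate → analyze → report from a single validated YAML/list config.

The statistical core, briefly: peptide log₂(H/L) ratios are reduced to
protein × replicate medians, filtered (≥ 2 peptides in ≥ 2 of 3 replicates),
and each protein's replicate values are tested against the background of all
quantified proteins with a one-sample t (df = n−1; scale either
max(SD_target, SD_background) — conservative, the default — or SD_target —
calibrated). TMD length is the raw predicted helix span, written
cytosolic→luminal. Lipid group comparisons use Student's pooled-variance t
per species with the adaptive two-stage step-up: stage 1 at q′ = Q/(1+Q)
estimates the true-null count m₀, stage 2 reruns the step-up at q′·m/m₀.
Thickness maps average (mean z_upper − mean z_lower) per x–y bin over the
converged tail (final 40%) of the frames.

## Worked example

Parse a topology prediction, extract the oriented TMD, and check the degron
arithmetic — a single C-terminal TMD spanning residues 293–310 is 18
residues long, and extending it by 3 or 6 residues adds 4.5 Å / 9 Å of
helical rise:

```r
library(qcprof)
ann <- parse_topology(paste("HMX1\tinside\t1\t292",
                            "HMX1\tTMhelix\t293\t310",
                            "HMX1\toutside\t311\t317", sep = "\n"))
extract_tmds(ann)
#> # A tibble: 1 × 7
#>   protein_id index start   end length orientation oriented_seq
#>   <chr>      <int> <int> <int>  <int> <chr>       <chr>
#> 1 HMX1           1   293   310     18 in_out      <NA>
helix_extension_rise(c(3, 6))
#> [1] 4.5 9.0
```

Profile a synthetic short-TMD proteome and recover planted SILAC effects:

```r
prot <- generate_proteome(proteome_spec(100, tmd_count_sampler = 1:3,
                                        tmd_length_sampler = 14:18, seed = 42))
signature_stats(prot$tmds)
#> TMD signature: 199 TMDs across 100 proteins (0 proteins without TMDs)
#>   length median [Q1, Q3]: 16.0 [15.0, 17.0] residues
#>   TMDs with length <= 16: 58%; proteins with shortest TMD <= 16: 76%
#>   TMDs with length <= 18: 100%; proteins with shortest TMD <= 18: 100%
#>   proteins with > 10 TMDs: 0%

tab <- generate_silac_table(silac_spec(60, effect_map = c(P0003 = 1.2, P0010 = 1.0),
                                       peptide_noise_sd = 0.1,
                                       peptides_per_protein_sampler = 5, seed = 42))
res <- run_silac_contrast(tab, membrane_ids = sprintf("P%04d", 1:60))
res[res$significant, c("protein_id", "neg_log2", "p_value")]
#> # A tibble: 2 × 3
#>   protein_id neg_log2 p_value
#> 1 P0003          1.22  0.0103
#> 2 P0010          1.03  0.0146
```

The two flagged proteins are exactly the planted ones: a 1.2 and 1.0 log₂
upregulation recovered at 0.1 log₂ units of peptide noise, each passing both
the −log₂ ≥ 0.3 effect threshold and the p ≤ 0.05 background test.

See `vignettes/qcprof-methods.Rmd` for the models, parameter defaults, and
the design decisions behind each stage.

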