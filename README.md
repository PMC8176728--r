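# snoscape

Tools for characterizing the human snoRNome from a tissue panel of TPM
abundance values. Small nucleolar RNAs (snoRNAs) are mid-size non-coding
RNAs, mostly encoded in the introns of host genes, that guide chemical
modification of rRNA and snRNA. Across healthy human tissues their
abundance splits into two regimes: a majority that behaves like
housekeeping RNA and a minority strongly enriched in brain or reproductive
tissues. `snoscape` is for transcriptomics researchers who want to
reproduce or reuse that classification and the downstream host-gene
analysis on their own abundance matrices.

The package implements:

* **Abundance classes.** Per gene, the coefficient of variation across
  tissue means, `CV = 100 * sd / mean`. A Gaussian KDE of the CV
  distribution is computed and the class boundary is the x-axis crossing
  of the tangent traced at the steepest descending flank right of the
  global mode, `x0 - f(x0)/f'(x0)`. For an exact Gaussian N(µ, σ²) this is
  µ + 2σ — with the dominant CV mode near 65 and spread near 30 it gives
  the canonical CV = 125 cut. Genes above the threshold are
  tissue-enriched (TE), the rest uniformly expressed (UE); each TE gene's
  enrichment tissue is the abundance argmax, with a joint breast/ovary
  call when those two lead within 2-fold.
* **Host-gene correlation.** Pearson's r (two-sided p) for every
  intron-embedded snoRNA against its host, one Benjamini–Hochberg FDR
  family per run, classes anticorrelated (r < −0.25), non-correlated
  (−0.25 ≤ r ≤ 0.25) and positive (r > 0.25), plus per-tissue
  log2((sno+1)/(host+1)) ratios.
* **Association battery.** Fisher's exact tests (2×2 and 2×k) and
  Mann–Whitney U tests linking the classes to box type, target class,
  host biotype and function, NMD susceptibility, promoter architecture
  (dual- vs simple-initiation) and phastCons conservation.
* **Synthetic cohorts.** A seeded generator with planted classes,
  correlations and annotation odds ratios emulating the 7-tissue ×
  3-replicate design (390 UE / 85 TE by default), used to validate every
  stage end to end.

## Worked example

```r
library(snoscape)

sim <- simulate_cohort(sim_params(seed = 1))     # synthetic 7-tissue cohort
rep <- run_pipeline(matrix = sim$matrix, annotation = sim$annotation)
print(rep)
#> <snoscape_report> 915 genes loaded, 915 expressed; 475 snoRNAs analyzed
#>   CV threshold 111.71 -> 393 UE / 82 TE
#>   440 host pairs, 293 significant correlations
```

The report's threshold (111.7 on this cohort) is the tangent crossing on
this cohort's own CV density; 393 of the 475 snoRNAs fall below it (UE)
and 82 above (TE). Each TE gene carries its enrichment tissue:

```r
head(rep$assignments[rep$assignments$abundance_class == "TE", ], 3)
#>   gene_id       cv n_tissues abundance_class enriched_tissues
#> 1 SNOSIM0006  138.         7 TE              brain
#> 2 SNOSIM0020  131.         7 TE              breast
#> 3 SNOSIM0038  115.         7 TE              testis

rep$correlation_class_counts
#>   correlation_class     n percent
#> 1 anticorrelated       79    18.0
#> 2 non-correlated       80    18.2
#> 3 positive            281    63.9
```

About 64% of snoRNA/host pairs are positively correlated here (the
generator plants 60% at ρ = 0.7), and the association battery recovers the
planted annotation structure:

```r
head(rep$battery[, c("test_id", "statistic", "p_value", "stars")], 5)
#>   test_id                   statistic  p_value stars
#> 1 box_type_x_class               2.17 3.59e- 3 **
#> 2 target_x_class                NA    3.38e-10 ***
#> 3 host_biotype_x_class          NA    5.80e-13 ***
#> 4 conservation_vert_x_class  24116    1.46e-12 ***
#> 5 conservation_prim_x_class  24476    1.40e-13 ***
```

Real data enter through `read_abundance_table()` (TSV matrix + sample
sheet) and `read_gene_annotation()`, or a wide supplementary-style export
through `reproduce_from_supplementary()` with a column map. A thin CLI
wrapper lives at `inst/scripts/snoscape` (`simulate`, `run-all`,
`reproduce` subcommands).

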