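# hpglyco

Site-specific haptoglobin (Hp) glycopeptide biomarker analysis for liver
disease cohorts.

Hp is an abundant plasma acute-phase glycoprotein whose β-chain carries four
N-glycosylation sites (N184, N207, N211, N241). In hepatocellular carcinoma
(HCC), Hp glycans shift toward higher fucosylation, branching, sialylation
and high-mannose content, making site-specific glycopeptides candidate
biomarkers for distinguishing early-stage HCC from chronic liver disease.
`hpglyco` implements the full quantitative analysis such a study needs,
downstream of the spectrum-to-peptide search:

- **Glycan composition algebra** — parsing/formatting of the
  `HexNAc(x)Hex(x)Fuc(x)NeuAc(x)` notation, monoisotopic mass arithmetic,
  oxonium diagnostic-ion m/z (e.g. the core-fucose Hex+HexNAc+Fuc ion at
  m/z 512.20), classification into families and feature classes
  (fucosylation/sialylation degree, bi/tri/tetra-antennary, high-mannose),
  and enumeration of isobaric composition ambiguities such as
  2×Fuc ↔ 1×NeuAc (Δ1.02 Da, absorbed by a one-isotope
  monoisotopic-peak misassignment).
- **In-silico digestion** — trypsin + Glu-C proteolysis with missed
  cleavages and the K/R-not-before-P rule, N-X-S/T sequon discovery, and
  theoretical glycopeptide m/z with fixed cysteine carbamidomethylation.
- **Quantification** — normalization of XIC peak areas to the summed top-3
  peptides of a spiked heavy-Hp internal standard, per-glycopeptide
  minimum-value imputation of left-censored missingness, QC coefficients of
  variation, and glycan-feature aggregation.
- **Statistics** — two-sided Wilcoxon rank-sum tests, Benjamini–Hochberg
  control at FDR 20%, ROC/AUC by tie-corrected pair counting
  (`U/(n₁n₂) = AUC`), sensitivity at 90% specificity and specificity at 90%
  sensitivity on empirical thresholds, AUC performance tiers, and stratified
  evaluation by Hp phenotype (1-1/2-1/2-2), etiology and cirrhosis status
  with a minimum of 10 patients per group.
- **Synthetic cohorts** — a generator that emulates the study design
  (57 controls / 50 early / 32 late; 36/42/31/50 glycoforms across the four
  sites; ~10⁵ dynamic range; ~10% technical CV shared with the heavy
  standard; left-censored missingness) with a ground-truth ledger of
  designed effects expressed as binormal AUCs, enabling parameter-recovery
  testing.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on evaluation results, and `autoplot()` /
`plot_feature_abundance()` for figures.

## Worked example

```r
library(hpglyco)

# the core-fucose diagnostic oxonium ion
round(oxonium_mz("Hex(1)HexNAc(1)Fuc(1)"), 2)
#> [1] 512.2

# a study-shaped synthetic cohort with known designed effects
co <- generate_cohort(cohort_config(), seed = 42)
co
#> Synthetic glycopeptide cohort
#>   samples:   139 (57 control, 50 early, 32 late)
#>   compounds: 159 across 4 glycosites
#>   missing:   5.0% of XIC areas (left-censored)
#>   markers:   102 with designed non-null effects

run <- run_glyco_pipeline(co$quant, co$heavy, co$meta)
head(subset(run$markers, contrast == "control vs early" &
                         !grepl("^feature:", marker)), 3)
#>   marker                                    p        q significant auc_oriented
#> 1 N241:HexNAc(6)Hex(7)Fuc(2)NeuAc(4) 2.55e-09 7.26e-08        TRUE        0.823
#> 2 N241:HexNAc(4)Hex(5)Fuc(3)         1.09e-08 2.66e-07        TRUE        0.821
#> 3 N207:HexNAc(6)Hex(7)Fuc(3)NeuAc(4) 2.25e-08 4.81e-07        TRUE        0.814

glance(run$markers_by_contrast[["control_vs_early"]])
#>   contrast         n_markers n_significant fdr band_gt90 band_80_90 ...
#> 1 control vs early       171            89 0.2         1         12 ...
```

The marker table reports, per glyco-compound (site + composition) and per
aggregate glycan feature: the Wilcoxon p-value, the BH q-value and its flag
at FDR 20%, the fixed-orientation AUC (cases positive, so down-regulated
markers fall below 0.5), the auto-oriented AUC, and both 90% operating
points. Highly fucosylated, highly branched compounds at N207/N241 top the
ranking here because the generator designed them up-regulated; the simulated
AFP benchmark recovers its designed AUC (`run$afp`, oriented AUC ≈ 0.80 in
this cohort). A thin command-line wrapper over the same functions is
installed at `inst/cli/hpglyco.R` (subcommands `simulate`, `analyze`,
`digest`).

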