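---
title: "Methods: site-specific glycopeptide biomarker analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-specific glycopeptide biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpglyco)
```

# The problem

Haptoglobin (Hp) carries four N-glycosylation sites on its β-chain. In
hepatocellular carcinoma the glycans at these sites shift toward higher
fucosylation, branching, sialylation and high-mannose content, and individual
site-specific glycopeptides can discriminate early-stage disease from chronic
liver conditions. `hpglyco` implements the quantitative analysis downstream of
glycopeptide identification: composition-level mass arithmetic and
classification, internal-standard normalization, imputation, feature
aggregation, differential testing with FDR control, and ROC-based panel
evaluation — together with a synthetic cohort generator that makes the whole
pipeline testable against known ground truth.

# Glycan model

Compositions are count vectors over a four-monomer alphabet (HexNAc, Hex,
Fuc, NeuAc) written `HexNAc(x)Hex(x)Fuc(x)NeuAc(x)`. Monoisotopic residue
masses (Da): HexNAc 203.07937, Hex 162.05282, Fuc 146.05791, NeuAc
291.09542; proton 1.007276, water 18.010565, C13 spacing 1.003355. Residue
masses are dehydrated, so glycan mass is linear in the counts and the empty
composition weighs exactly zero. A B-type oxonium ion is
`mass − losses·water + proton`; the core-fucose trisaccharide gives the
familiar m/z 512.20 check value, and the NeuAc−H₂O ion computes to 274.0921
(conventionally printed 274.0919 — comparisons are made at 3 decimals).

**Classification.** Families are assigned from counts alone: high-mannose
requires HexNAc 2, Hex 5–9 and no Fuc/NeuAc (the Man5–Man9 series; HexNAc 2
with fewer hexoses falls into paucimannose/other); complex requires
HexNAc ≥ 4; hybrid is HexNAc 3 with Hex ≥ 5. Antennarity for complex glycans
uses `min(HexNAc − 2, Hex − 3)` capped at 4, and the bisecting flag fires
when `HexNAc − 2 > Hex − 3` — i.e. a HexNAc that no galactose accounts for.
This heuristic reproduces the canonical labelled examples (biantennary
disialylated HexNAc(4)Hex(5)NeuAc(2), bisected HexNAc(5)Hex(5)NeuAc(1),
tetra-antennary HexNAc(6)Hex(7)Fuc(1)NeuAc(4)) but deliberately mislabels
agalactosylated antennae, which count-only data cannot distinguish from
bisecting GlcNAc; it is documented as a heuristic, not a structure call.
Whether bisected tri-antennary species should count as tetra-antennary is
genuinely open at the composition level; we resolve it by the same rule
(they do not), and report the bisecting flag separately so either tally can
be reconstructed.

**Isobaric ambiguity.** Two compositions are reported as alternatives when
their mass difference matches `k × 1.003355 Da` (k the monoisotopic-peak
error, default −1…+1) within a ppm tolerance evaluated at the glycopeptide's
mass (default 20 ppm, the usual MS2 tolerance). Candidates come from count
perturbations bounded per-monomer (±2) and in total L1 change (4), which
covers the classical 2×Fuc ↔ 1×NeuAc swap: Δ = 1.0204 Da, matched by one
isotope spacing with a 17 mDa residual — inside a 20 ppm window at 4000 Da,
but far outside any window at k = 0. The enumeration is symmetric by
construction.

# Digestion

Trypsin (after K/R, not before P) and Glu-C cuts are pooled into one
boundary set; every peptide with at most the configured missed cleavages
(default 2) is emitted, so the zero-missed peptides concatenate back to the
protein and the count law `#peptides = Σ_{m=0..M} (c + 1 − m)` holds for `c`
internal sites. Glu-C specificity defaults to E-only — in ammonium
bicarbonate Glu-C can also cut after D, so `DE` is selectable — and the
choice is visible in the rule object. Sequons follow N-X-S/T with X ≠ P.
Coordinates are 0-based half-open internally and 1-based in labels; a
configurable numbering offset lets a mature-chain FASTA carry
precursor-numbered labels such as N184. Methionine oxidation is outside the
default mass enumeration (quantification consumes search-engine output, not
our enumeration) but can be added as an extra modification mass.

# Quantification

The pipeline order is fixed: **normalize → impute → aggregate**.

*Normalization* divides each sample's XIC areas by that sample's summed
top-3 heavy-standard peptide abundances T(s) and rescales by the cohort mean
of T(s) so output stays on the input intensity scale. The top-3 are chosen
by global mean abundance with a lexicographic tie-break (the selection
criterion is otherwise underdetermined), and the selection is attached to
the result. Because of the mean-T(s) rescale, jointly scaling one sample's
areas and heavy abundances leaves the normalized profile unchanged up to a
single cohort-wide constant; pure ratios would be exactly invariant but
would change the units, and we prefer interpretable intensities.

*Imputation* replaces each glyco-compound's missing values with that
compound's minimum observed area across the whole dataset — "that
glycopeptide['s]" minimum scopes to the row, not the group. Observed cells
are never altered and the operation is idempotent. Rows observed nowhere are
dropped with a warning rather than zero-filled: zeros would fabricate rank
signal in downstream Wilcoxon/ROC statistics.

*Aggregation* sums intensities over feature classes — fucosylation and
sialylation degree 1–4 (degree ≥ 5 pools into 4), antennae 2/3/4 (complex
only) and high-mannose — globally or per site. Degrees partition the
classified rows, so summing a degree family from 0 upward conserves total
intensity; this is the conservation property the tests assert. A compound
contributes to every class it belongs to (a tetra-antennary difucosylated
glycan appears in both `fucosylation_2` and `antennae_4`), matching how
summed "glycans presenting k fucoses" style features are built.

*QC CV* is `100·sd/mean` over replicate control measurements, at protein
level (column sums over all rows — the protein-level abundance definition
here, since a search-engine protein roll-up is not available to this stage)
or per designated peptide set.

# Statistics

Group comparisons use the two-sided Wilcoxon rank-sum test: exact when
`min(n₁, n₂) ≤ 8` with no ties, otherwise the normal approximation with tie
and continuity corrections (delegated to `stats::wilcox.test`; the exact
path is verified against full permutation enumeration, and the approximate
path agrees with the exact one to well under the decisions it feeds —
differences at n = 8 stay below 0.02). U is computed from midranks so that
`U/(n₁n₂)` equals the tie-corrected AUC, an identity asserted for every
marker evaluated. Multiple testing uses Benjamini–Hochberg at FDR 20% —
a deliberately permissive screening level — applied per contrast jointly
across glyco-compounds and aggregate features (the family definition is
recorded in the run manifest; AFP benchmarking sits outside the family).

ROC curves are empirical (`score ≥ threshold` calls a case), AUC is
tie-corrected pair counting, and operating points take the best
complementary metric over empirical thresholds subject to
specificity ≥ 90% (or sensitivity ≥ 90%) without interpolation —
reproducible and conservative at small n. AUC orientation is fixed with the
disease group positive, so down-regulated markers (e.g. the abundant
biantennary disialylated form) report AUC < 0.5; the auto-oriented
`max(AUC, 1 − AUC)` is carried alongside, and tier counts (>0.90,
0.80–0.90, 0.75–0.80, 0.70–0.75, plus nested >0.90/>0.80/>0.75/>0.70) are
emitted in both conventions because published tallies are ambiguous between
them. Operating points for down-regulated markers are read off the flipped
score.

Stratified evaluation re-runs the marker evaluation within Hp phenotype,
etiology-flag or cirrhosis strata, skipping any stratum with fewer than 10
patients in either contrast group (the per-group reading of the minimum-10
rule), and emits a per-stratum vs whole-cohort AUC comparison. The default
contrasts are control vs early, control vs late, early vs late, and control
vs pooled HCC.

# Synthetic cohorts

No clinical data ship with the package; the generator produces cohorts with
the structure the analysis assumes, at the study's stated scale by default:
57/50/32 samples (control/early/late), 36/42/31/50 glycoforms at
N184/N207/N211/N241 drawn without replacement from an 89-composition master
catalog (Man5–9, hybrids, bi/tri/tetra-antennary complex species with 0–4
fucoses and up to antenna-many sialic acids, plus bisected forms), baselines
log10-uniform over 5 decades starting at 10³ (log-uniform is the simplest
shape consistent with a stated 10⁵ dynamic range), and ~5% of intensities
hard left-censored to missing at a global quantile threshold — low-abundance
glycoforms simply fall below the observable floor, which is the mechanism
attributed to non-identified glycoforms in real data.

Effects are parameterized as *designed AUCs* per feature class and group and
converted to log10 shifts via the binormal identity
`AUC = Φ(δ/(σ√2))` with `σ² = bio_sd² + tech_sd²`. The biological SD
defaults to 0.5 log10 (inter-subject CVs above 100% are typical for
glycoform abundances); the technical CV defaults to 0.10, consistent with
the ~10% replicate CVs such workflows report. A compound matching several
effect classes takes its strongest class shift per group — summing shifts
would silently overshoot the designed AUCs the truth ledger promises. The
default effect map encodes the qualitative disease progression (tri-/tetra-
fucosylation, tetra-antennary, tetra-sialylation and high-mannose up in
early disease and further up in late); its magnitudes are illustrative and
labelled as such. A per-sample technical factor multiplies all rows *and*
the heavy standard, so normalization can remove it — the designed AUCs
describe the post-normalization data, and the shared factor is excluded
from σ. Phenotypes are assigned per group by the clinical cohort's
proportions (giving counts 4/16/26 + 4 unknown in an n = 50 early group);
etiology flags approximate the cohort's marginals but are illustrative,
since the published patient table reports combination categories rather
than flags. A simulated AFP column with designed AUC 0.79 (≈5% missing,
excluded pairwise) exercises the benchmarking path.

What the generator does **not** emulate: correlated glycoform co-regulation
within pathways, charge-state splitting of compounds, retention-time or
identification errors, batch drift beyond the per-sample factor, and
informative (disease-dependent) missingness beyond abundance censoring.
Passing recovery tests therefore demonstrate that the pipeline's arithmetic
and statistics are correct under the assumed model — not that the model
captures every property of clinical LC-MS data.

# Numerical choices and problem sizes

Tolerances: ppm matching defaults to 20 ppm (MS2-scale); masses are
reported to 4 decimals. Ties: top-3 heavy selection breaks ties
lexicographically; AUC ties earn 0.5 per pair; operating points never
interpolate. Degenerate inputs: all-missing rows are dropped with a
warning, zero heavy totals and empty contrast groups are hard errors, a CV
with zero mean reports NA, and classification is total over all
compositions. The test suite sizes its simulations to run comfortably on a
single CPU: parameter recovery uses one cohort at n = 200/group (where the
mean estimated AUC over ~50 designed markers must land within ±0.02 of the
designed 0.90), and null-calibration uses 200 small cohorts (40 compounds,
20 + 20 samples). The full-size deterministic run uses the default
139-sample, 159-glycoform configuration.

# Known limitations

Antennarity/bisecting inference from counts is heuristic (above). The
Wilcoxon/BH/ROC stack treats samples as exchangeable within groups — no
covariate adjustment (age, sex, etiology) beyond stratification. Minimum
imputation compresses low-abundance variance and can slightly deflate AUCs
of markers whose control values are censored; it is kept because it is the
standard practice this pipeline mirrors, and its effect is visible in the
recovery tests. DeLong confidence intervals and multivariable marker
combinations are out of scope.
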