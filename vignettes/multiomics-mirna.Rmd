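---
title: "Methods: candidate-based multi-omics association of miRNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-based multi-omics association of miRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miromics)
```

`miromics` tests whether microRNAs are linked to cardiometabolic traits in
three layers of population omics data — regulatory-region genetics, CpG
methylation, and plasma expression — and intersects the layers per miRNA.
This vignette is the package's account of the statistical procedure, its
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## The candidate-based design

The pipeline is deliberately not a genome-wide scan. The SNP layer tests
only variants annotated to miRNA-related regions; the CpG and expression
layers test only miRNAs already implicated by the SNP layer, at a nominal
0.05 level. This candidate-based structure is what justifies nominal
thresholds downstream: the heavy multiple-testing correction is paid once,
in the SNP layer, and later layers are confirmatory. The cost is that the
procedure cannot discover a miRNA with methylation or expression evidence
but no genetic signal.

## Coordinates and regions

All input formats (GFF3, Illumina-style manifests, TSV catalogs) are read
as 1-based inclusive and converted exactly once to 0-based half-open
intervals internally; writers convert back. A single conversion boundary is
the only reliable defence against off-by-one drift in interval code.

Each precursor miRNA contributes three region classes: the precursor
hairpin, its mature arms, and a flank window extending `flank_bp`
(default 2000 bp) on both sides, clipped at position zero. The flank is
symmetric and strand-agnostic — the regulatory window is defined as "within
±2 kb", not "upstream" — and strand is carried only to sign the
site-to-precursor distance (negative = upstream of the precursor on its own
strand). A site in several classes of one miRNA gets the most specific
class (mature > precursor > flank); a site on the flank's outer end
boundary is excluded by half-open semantics, one on its start boundary
included. miR-eQTL catalog SNPs are annotated to their target miRNA by the
catalog itself (class `eqtl`), not by proximity: most reported cis-miR-eQTLs
are distal regulators, hundreds of kb from the miRNA.

The region-scan and eQTL catalogs are merged as a union keyed on rsID; a
SNP present in both is counted once and carries both source tags. This is
forced by the arithmetic of the published catalog sizes
(18,545 + 5,528 − 83 = 23,990).

## SNP layer: LD pruning and Bonferroni thresholds

The number of independent tests is estimated by LD pruning at r² > 0.7.
The published analyses name only the tool and the r² cut, so the pruning
policy here is fixed as: SNPs ordered by position; sliding windows of
`window_bp` (default 250 kb, advancing by half a window); within each
window, while any surviving pair exceeds the cut, the worst pair (largest
r², ties broken lexicographically on indices) loses its larger-index
member; window passes repeat until stable. The policy is deterministic,
idempotent, and close to the documented behaviour of standard pruning
tools. Missing pairwise r² values are treated as independence (r² = 0) and
logged.

Thresholds are per imputation panel — the pruned count is computed on the
SNPs actually present in each panel's GWAS, not on the full catalog — and
equal α/m. With α = 0.05 the published counts m = 2,358 (HapMap) and
m = 8,652 (1000 Genomes) give 2.12×10⁻⁵ and 5.78×10⁻⁶, which the test
suite reproduces exactly.

Summary statistics are harmonized against the SNP catalog when the catalog
records alleles: swapped effect/other alleles flip the sign of beta;
strand-ambiguous (A/T, C/G) rows that match neither orientation are dropped
with a log line. Zero p-values are floored at 10⁻³⁰⁰ for plotting only;
significance always uses the raw comparison.

## CpG layer: mixed-model EWAS

Methylation beta-values are the dependent variable:

    methylation ~ trait + covariates + (1 | batch)

fitted by REML. The orientation is a design decision — the technical random
effects (array/plate, collapsed to one batch label) act on the methylation
measurement, so methylation belongs on the left-hand side; the expression
layer uses the opposite orientation because there the disease-prevalence
models require the trait as outcome. Beta-values are used untransformed, so
coefficients are on the methylated-fraction scale (an M-value logit switch
would change only the scale, not the architecture, and is not enabled).

The covariate ledger: every fit adjusts for age, sex, current smoking and
blood cell count fractions (monocytes, granulocytes, lymphocytes).
Group-specific additions are: anthropometric — BMI for WC and WHR only (a
trait never adjusts for itself); glycemic — BMI and diabetic medication;
lipid — BMI and lipid-lowering medication; cardiovascular — BMI,
blood-pressure-lowering and lipid-lowering medication. Fits are
complete-case per (probe, trait).

When the batch variance estimate is singular the fit falls back to ordinary
least squares with batch as a fixed factor, and the fallback is recorded in
the result. Wald tests use a t reference on the residual degrees of
freedom; a normal reference is visibly anticonservative at cohort sizes of
a few hundred and would bias the type-I calibration the test suite checks
(significant fraction at 0.05 within the binomial 99% CI over ≥2,000 null
fits). Degenerate inputs (constant probe or trait, < 30 complete cases,
collinear design) are errors, reported per fit and skipped by the scan
driver with a log entry.

## Expression layer: CPM, LLOQ, association models

Counts are normalized to counts per million and transformed as
log2(CPM + 1). The pseudocount of 1 maps zero counts to 0 on the log2-CPM
scale, which keeps the "not expressed below 1.0 log2 CPM" floor meaningful;
per-sample CPM columns sum to 10⁶ before the pseudocount, and scaling a
sample's counts by any constant leaves its log2-CPM column unchanged.

Low-abundance miRNAs have noisy measurements, visible as a mean–SD profile
that decreases with the mean. The lower limit of quantification is derived
from that profile: per-miRNA SD is regressed on mean by antitonic
(monotone-non-increasing isotonic) regression, lightly smoothed by a
5-point running mean with monotonicity re-imposed, and the LLOQ is the
smallest mean whose fitted SD falls to the cut `c`. The cut is the midpoint
of the fitted curve's range by default — a scale-free rule, exposed as
`lloq_cut` and flagged in QC output, since the published method states the
curve but not the cut. A flat SD profile triggers a logged degenerate
branch returning the minimum mean; fewer than 10 points is an error.

Two sequential filters select analysable miRNAs: the expression floor
(mean log2 CPM ≥ 1.0; the summary statistic is a package choice, as the
published floor does not name one) and the well-expression rule (strictly
more than 50% of samples strictly above the LLOQ — a miRNA at exactly 50%
is excluded). Housekeeping probes pass through normalization but are
excluded from the LLOQ fit and from association testing.

Association models put the trait on the left: linear for continuous
traits, binomial for disease prevalence (T2D, CHD), with the
expression-layer base covariates (age, sex, current smoking) plus the same
group-specific additions as the EWAS. Disease coefficients are log-odds per
log2-CPM unit. Complete separation in a logistic fit yields a flagged
result with a missing p-value rather than a crash. Validated target genes
of implicated miRNAs can be screened by reusing the annotation + GWAS
stages on gene intervals, with a per-miRNA Bonferroni threshold of α
divided by the SNPs tested in that miRNA's target genes.

## Cross-referencing and integration

me-QTL pairs are cis when SNP and CpG share a chromosome and lie at most
250,000 bp apart — the boundary counts as cis ("no further than") — and
trans otherwise. External me-QTL and miR-eQTM catalogs are trusted as
given (their FDR values are not recomputed); eQTM pairs are pre-filtered at
FDR < 0.01.

The evidence matrix has one row per SNP-layer miRNA. MiRNA ids from
different layers (precursor names, mature arms) are matched on a
precursor-level family key that strips the -3p/-5p suffix. For each
downstream layer a miRNA is `supported`, `null` (tested, nothing
significant) or `unavailable` (no probes, not well-expressed, phenotype
missing) — the distinction keeps "tested 64 of 67" style accounting honest
instead of conflating missingness with negative results.

Selection applies the trait-compatibility rule: SNP trait set nonempty,
some CpG trait inside it, and some expression trait inside it — the CpG-
and expression-matched traits need not coincide with each other. This is
the weakest rule reproducing the published multi-omics overlap table, where
a miRNA's CpG evidence matches LDL and its expression evidence TC while the
SNP layer carries both; requiring a single common trait across all three
layers would be strictly stronger and is not what that table shows.
Prioritization requires the miR-eQTL evidence flag — the flag, like the
tissue-expression and structure-change flags, is an input annotation
(their derivation from expression atlases or RNA folding is outside the
pipeline's scope). Reports are deterministic: identical inputs give
byte-identical TSV/JSON output, including per-stage counts and run
metadata.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study's data-generating conditions at
desk scale, with planted truth for validation:

- **Genotypes**: hard-call dosages {0,1,2} from two thresholded latent
  Gaussian haplotypes with AR(1) correlation (`ld_rho`, default 0.8)
  inside blocks of 25 consecutive SNPs; minor allele frequencies uniform
  on [0.05, 0.5]. Default 5,000 SNPs, most inside miRNA flanks plus a
  distal miR-eQTL catalog.
- **GWAS**: trait scores are linear combinations of planted SNP dosages
  (per-allele effect `snp_beta` = 0.4) plus unit noise, n = 5,000; summary
  statistics are computed from those genotypes by single-variant OLS, so
  an independent `lm()` re-derivation matches the stored betas to 10⁻⁸.
  HapMap-panel GWAS cover a 60% subset of the catalog (1000G covers all);
  planted SNPs are always covered, because a planted truth must be
  observable by the layer that is supposed to recover it.
- **Methylation**: beta-values = baseline + 0.01·(trait z-score) for
  planted CpGs + batch intercepts (8 batches, SD 0.01) + N(0, 0.02) noise,
  clipped to (0, 1); n = 700.
- **Counts**: per-miRNA mean log2-CPM on [−2, 10] (planted miRNAs in the
  upper range), per-miRNA SD following 2·exp(−mean/3) + 0.2 — the
  decreasing mean–SD relation the LLOQ stage assumes — realized as Poisson
  counts of a log-normal rate against library sizes of 2–4 million;
  n = 1,000, plus 13 housekeeping probes.
- **Planted miRNAs** (default 10) each receive a SNP, a CpG and an
  expression effect on one shared trait, so three-layer selection has a
  known answer; disease prevalences use a logistic link.

Determinism is part of the contract: identical config + seed reproduce the
cohort byte-for-byte.

What the generator does *not* emulate: real allele-frequency spectra or
fine-scale LD, 450K probe chemistry and cross-reactive probes, miRNA
sequence content, population structure, or confounding between layers
(each cohort's covariates are independent of the planted effects). Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under the stated model — not that the pipeline is robust to
artefacts these data types show in the wild.

## Problem sizes and numerical choices

Module tests run on reduced cohorts (roughly n = 250–800 samples, 40–60
miRNAs, 400–600 SNPs, 200–300 CpGs), chosen so the full suite exercises
every path in about a minute while keeping planted effects comfortably
detectable. The statistical property suite runs at the sizes its
guarantees are stated for: ≥2,000 null mixed-model fits and 2,000 null
linear fits for type-I calibration (binomial 99% CI around 0.05), 500
mean–SD points for LLOQ recovery within 0.25 log2-CPM of the analytic
crossing, and parameter recovery within 3 standard errors for mixed,
linear and logistic models. The acceptance script uses an intermediate
cohort (n = 3,000 GWAS / 700 methylation / 1,000 expression; 150 miRNAs)
for the end-to-end planted-recovery run.

Other numerical details: p-values from 0 are floored at 10⁻³⁰⁰ only for
−log10 displays; the LD-pruning tie-break is lexicographic and documented
above; `fit_lloq` re-imposes monotonicity after smoothing with a reversed
cumulative maximum; evidence-matrix trait sets are stored as list-columns
and compared as sets, so trait order never matters.

## Known limitations

- The EWAS model orientation (methylation as outcome) and the LLOQ cut
  rule (midpoint of the fitted SD range) are package decisions where the
  published description is silent; both are parameterized and logged.
- Whether the two methylation sub-cohorts should be fitted jointly or
  meta-analyzed is unstated in the source design; the package fits jointly
  (an optional sub-cohort fixed covariate can be added by the caller via
  the phenotype table).
- Prioritization flags are inputs, not computations; the pipeline cannot
  itself establish that a variant changes miRNA expression in a relevant
  tissue.
- No liftover: all inputs must share one genome build. No causal or
  mediation analysis: the output is associative evidence, intersected.
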