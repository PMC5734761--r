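---
title: "Methods: family-based association and directed eQTL enrichment for nasal polyposis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based association and directed eQTL enrichment for nasal polyposis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fampoly)
```

# Scope and model

`fampoly` re-implements, as tested and reusable components, the
computational chain of a family-based genome-wide association study of
chronic rhinosinusitis with nasal polyps (CRSwNP): cohort quality
control, two family-aware association scans, LD-interval gene-set
enrichment, two-group differential expression, and a directed eQTL
enrichment test calibrated with a matched-gene empirical null. Because
the original cohort genotypes and the external reference resources
(population reference panels, expression series, eQTL catalogues) are
not redistributable, a synthetic-data module generates every input with
the statistical structure the analysis assumes. This vignette documents
the models, the parameters that matter, the numerical choices, and what
the synthetic tests do and do not establish about behaviour on real
data.

# The synthetic cohort generator

`simulate_cohort()` draws nuclear families (two parents, a configurable
number of children) plus unrelated singleton cases and controls.

* **Haplotypes.** Per-marker allele-1 frequencies are uniform on
  `maf_range` (default 0.05–0.5, common variants on a genotyping
  array). Within an LD block of `ld_block_length` markers (default 10),
  each marker's latent uniform is copied from its left neighbour with
  probability `within_block_r` (default 0.8), otherwise redrawn. This
  first-order copying model produces tunable pairwise r² without a
  coalescent dependency; blocks are independent of each other.
* **Transmission.** Children inherit one parental haplotype per LD
  block, chosen fairly and independently per block. Transmission is
  therefore exactly Mendelian marker by marker (the basis for the
  exhaustive Mendel-consistency tests) while preserving within-block LD
  in offspring.
* **Disease model.** Penetrance is multiplicative:
  `P(affected) = prevalence × RR^x` capped at 1, with `x` the model
  coding (additive dosage, dominant indicator, recessive indicator) at
  each planted risk locus. The default baseline prevalence is 0.1,
  matching the elevated polyp prevalence observed among first-degree
  relatives of patients rather than the 2–4% population figure, since
  the simulated families stand in for a cohort recruited through
  affected probands.
* **Ascertainment.** Families are accepted only if at least one child
  is affected, mirroring recruitment of index patients with relatives;
  singletons are sampled conditional on their case/control label.
  Without this, a null-prevalence cohort would carry almost no affected
  children and the family strata would be empty.

The generator is bit-reproducible given its seed, and every artifact
injected for QC testing (`inject_qc_artifacts()`) is logged with sample
IDs and marker names so tests can assert exact recovery. Missing calls
are a dedicated `NA` code, never a zero dosage. Sex is simulated but no
X-chromosome logic exists; all markers are autosomal.

What the generator does **not** emulate: genotyping-chip cluster
artifacts, batch effects, population-scale haplotype structure
(coalescent genealogies, recombination hotspots), or realistic
chromosome counts and gene densities. Tests passing on this generator
validate the algorithms' statistical behaviour under their stated
assumptions, not performance on any particular chip or population.

# Quality control

Filter order is pinned because counts depend on it: sample filters
first (missingness > 2%, heterozygosity beyond 3 SD of the cohort mean,
more than 100 Mendelian errors), then marker filters (missingness > 2%,
more than 3 Mendelian errors, monomorphic), then LD pruning
(r² < 0.2, windowed greedy, window 50 / step 5 markers — the window
parameters are conventional defaults, configurable), then PCA
ancestry-outlier removal. All thresholds are strict inequalities;
boundary cases (exactly 2% missing, exactly 3 Mendel errors) are
retained, and the tests pin this bit-exactly.

A Mendelian error is a child call impossible under the transmissible
alleles of the available parents (trio rules; duo rules when one parent
is genotyped; fully ungenotyped parents contribute nothing). Each error
increments the child, each genotyped parent, and the marker. The
counter is verified against exhaustive enumeration of all trio and duo
genotype combinations. This attribution is deliberately simple and
testable; it is close to, but not numerically identical with, PLINK's
shared-attribution scheme.

Ancestry outliers are found by joint PCA of study plus reference
samples on the pruned markers: the genomic relationship matrix of
standardized dosages ((g − 2f)/√(2f(1−f)), mean-imputed missing calls)
is eigendecomposed, per-sample scores are the top three eigenvectors
scaled by the root eigenvalues, and the ancestry distance E is the
Euclidean distance to the reference centroid. Samples with
E > 5·SD(E) are removed, with SD(E) computed over all study samples in
a single pass (whether the original filter iterated is unknown; single
pass is pinned). The heterozygosity filter is likewise single-pass. On
small synthetic marker panels the top noise eigenvectors can localize
on a few samples, so rare false positives at 5 SD are expected; the
tests therefore assert exact recovery of planted admixed samples and a
low, not zero, false-positive count.

# Family-aware association scans

## Stratified CMH ("DFAM-style")

Per marker, observed and expected allele-1 counts in affected
individuals accumulate over independent strata:

* **TDT stratum** — affected genotyped children with both parents
  genotyped. Transmissions from heterozygous parents are Bernoulli(1/2)
  under the null; the het parents' joint contribution is the child
  dosage minus the transmissions forced by homozygous parents, so the
  double-heterozygous ambiguity never arises at the count level. E adds
  n_het/2 and V adds n_het/4 per informative transmission. With one
  genotyped parent, a heterozygous parent's transmission is resolvable
  only for homozygous children, and only then counted.
* **Sibship strata** — families without two genotyped parents but with
  at least one affected and one unaffected genotyped sibling. The
  affected siblings' allele count is compared with the hypergeometric
  draw of the affected allele slots from the sibship's pooled alleles.
  Alleles, not siblings, are the exchangeable units; the exhaustive
  permutation oracle in the test suite enumerates allele subsets.
* **Unrelated stratum** — singletons form a single case/control × allele
  2×2 with hypergeometric moments.

The statistic is `T = (Σ(O−E))² / ΣV` against χ²(1). Markers with zero
total variance are uninformative (p = 1, flagged). Stratum membership
is decided at the pedigree level; per-marker missing calls only remove
the affected trio/sib/singleton from that marker's stratum. The PLINK
DFAM stratification is under-documented, so this construction is pinned
as this package's definition; numerical identity with PLINK is not
claimed. Type-I error is verified to be nominal ([0.04, 0.06] at
α = 0.05 over 2000 null markers) and a planted RR 2.0 locus at MAF 0.3
ranks in the top 10 of 1000 markers in ≥ 90% of seeds.

## Mixed model ("EMMAX-style")

The binary phenotype is treated as quantitative (the standard EMMAX
convention). Variance components of `Var(y) = σg²K + σe²I` are fitted
once by REML on the null model, profiling the restricted likelihood
over `δ = σe²/σg²` on the eigenbasis of the GRM (one-dimensional
`optimize` over log δ in [−15, 15]; eigenvalues are floored at zero
with a 1e-8 jitter so weights stay finite). Each marker is then tested
by generalized least squares on the rotated data under three codings of
the allele-1 dosage — additive (0,1,2), dominant (0,1,1), recessive
(0,0,1) — and the smallest Wald p is reported with its coding label.
This min-p convention is deliberately unadjusted for the three-way
multiplicity, exactly as in the original analysis; the test suite
documents its anti-conservativeness under the null. Missing genotypes
are mean-imputed per coding; constant codings are skipped. At identity
kinship the GLS t-test reduces exactly to OLS (`summary(lm)`), which is
asserted to 1e-9. Heritability recovery at h² = 0.5 is within ±0.15 on
pedigree cohorts of ~500 samples.

# LD-interval gene-set enrichment

The top 1000 markers by p (ties broken in genome order) are merged into
intervals by connected components of the pairwise r² > 0.25 graph
(chains, not cliques: "pairwise" is ambiguous in prose, and the chain
rule is order-independent). Cross-chromosome edges are never formed;
singletons become 1-bp intervals. Coordinates are pinned: BED gene
inputs are 0-based half-open, intervals are reported 1-based inclusive,
and overlap arithmetic converts the interval end to half-open [start,
end+1) and compares directly against the BED coordinates, so a gene
starting exactly at the interval end still overlaps.

The enrichment statistic of a set is the number of intervals
overlapping at least one member gene. The null replicates place one
random region per observed interval, matched in length and SNP density
within ±10% (relative; configurable), uniformly among feasible
placements across chromosomes; when no placement is found within a
bounded number of proposals the tolerance is relaxed stepwise (×1.5)
with a warning. Proposals mix uniform starts with marker-anchored
starts so that short, marker-dense templates (a 1-bp singleton has
density 1) remain placeable; acceptance always enforces the density
match. The empirical p is `(1 + #{replicate ≥ observed})/(R + 1)`,
never zero; the replicate tie counts are returned so tie-aware rank
conventions are recoverable. The second-stage multiple-testing
bootstrap of the INRICH tool is intentionally not reproduced; raw
empirical p ranks the sets, the top 20 per run are taken, and the union
of their interval-overlapping genes across runs is the target gene
list.

**Calibration at desk scale.** The overlap count is a small discrete
statistic, so the tie-inclusive empirical p is conservative by
construction, with an atom at 1. In addition, when the toy genome has
few chromosomes and few genes, the observed intervals' fixed chromosome
assignment interacts with per-chromosome gene-count fluctuations that
the chromosome-redrawing null averages away, inflating the variance of
the observed statistic relative to the null — an effect that shrinks
with genome size and is negligible at real scale (thousands of genes,
22 autosomes). The calibration test therefore runs on a
single-chromosome genome model, which isolates the placement machinery
from this finite-genome artifact, and checks both validity of the
reported p and uniformity of the tie-randomized rank.

# Differential expression and target overlap

Per probe, a Welch two-sample t-test on log2 intensities and
`log2FC = mean(case) − mean(control)`; `bh_adjust()` applies
Benjamini–Hochberg step-up (delegating to `p.adjust`, verified against
a brute-force implementation of the definition). Welch's test is used
in place of the moderated empirical-Bayes t of the original web
pipeline, whose exact settings are unrecorded; the moderated variant
would be a natural extension. Degenerate probes (zero variance in both
groups) get p = 1 at equal means and p = 0, flagged, otherwise. A
target gene is reported when any of its probes is significant at
BH-adjusted p < 0.05, via its minimum-adjusted-p probe, with fold
change 2^log2FC. Planted probes at |log2FC| = 1, noise SD 0.3 and group
sizes 20 vs 17 are recovered at sensitivity ≥ 0.95 with observed FDR
≤ 0.1.

# Directed eQTL enrichment

The headline procedure. Catalogue filters: the multi-tissue dialect
keeps, per SNP–gene pair, the tissue (LCL or skin) with the smaller p
(ties go to LCL), then drops records with p > 0.05 or |β| < 0.01, both
strict; the blood dialect keeps records with FDR < 0.5 and imposes no
effect-size limit. Each surviving record is binned by regulatory
direction (up iff β > 0 for the effect allele; β = 0 excluded with a
warning) and by the effect allele's frequency in cases versus controls
computed by plain allele counting over all affected and all unaffected
individuals, relatives included. Equality (within 1e-12, absorbing
floating error on rational frequencies) counts as "−", per the
published footnote's "similar or decreased". The 2×2 is tested with a
two-sided Fisher exact test under the minimum-likelihood convention
with a (1 + 1e-7) relative tie tolerance — the convention of standard
statistical software, and the one that reproduces the published
p-values from the published cells. Degenerate margins give p = 1. The
tail terms are summed in sorted order so that equivalent tables (the
same multiset of margins) produce bit-identical p-values; without this,
ulp-level float differences between mathematically equal p-values made
the empirical-null rank misread ties as strict inequalities, a bias the
calibration tests caught. The rank comparisons additionally use a
symmetric 1e-9 relative tie tolerance.

The empirical null follows the published escalation rule exactly: genes
with the target's SNP count n form the pool (differentially expressed
genes and the target removed); if fewer than 500 qualify, genes with
n+1, n+2, … SNPs are added and subsampled to n SNPs uniformly without
replacement, one draw per null gene. The empirical p is
`(1 + #{null Fisher p ≤ target p})/(N + 1)` — the +1 form avoids zero
and is standard for resampling nulls; `n_less`, `n_leq` and the
achieved N are reported so the alternative r/N convention and
tie-randomized ranks are recoverable.

**Why the reported empirical p is not exactly uniform.** Fisher's p on
a 10–30-SNP table is discrete with a large probability of equalling 1
(0.14–0.5 in simulation, shrinking with n). The tie-inclusive rank is
therefore valid but conservative, with a matching atom at 1; no valid
implementation of this formula can produce an exactly uniform p at
realistic SNP counts. The test suite asserts validity at every level
and exact uniformity of the tie-randomized rank, and the calibration
scenario uses a marker pool large enough (3000 markers) that the 200
sampled target genes share few markers, since heavy marker sharing
makes their p-values dependent and defeats the i.i.d. assumption of the
KS test.

# Problem sizes used by the tests and the acceptance script

Simulated scenarios are sized for a laptop-scale run while preserving
the statistical structure each check needs: null calibration on 2000
independent markers with 300 families plus 400 unrelateds; power and
recovery over 20–50 seeds at 400–1000 markers; the REML recovery on
~500 samples; the exhaustive Fisher oracle over all 135,751 tables with
total ≤ 40; enrichment calibration at 200 repetitions of R = 199
replicates. The published contingency tables are reproduced from the
shipped summary TSVs in under a second.

# Known limitations

* No X/Y/mitochondrial logic, no imputation, no chip-cluster artifacts.
* The DFAM-style stratification and the mixed-model scan are pinned
  reimplementations, not numerical clones of PLINK or the commercial
  EMMAX implementation.
* eQTLs are consumed from catalogues, never computed from raw
  expression + genotype data.
* Fisher's test ignores LD among a gene's eQTL SNPs; the matched-gene
  empirical null is the (published) mitigation, and it calibrates rank,
  not LD structure.
* The GWAS-scale results of the original study (top-SNP tables, the
  138-gene target list, the 36-gene expression overlap) depend on the
  real cohort and external resources and are exercised structurally,
  not numerically.
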