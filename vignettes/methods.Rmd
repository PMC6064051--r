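---
title: "Inferring multi-omics druggability: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring multi-omics druggability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druggable)
```

## The problem

Precision oncology asks, for each tumor, whether any of its molecular
alterations is a biomarker of response to an available drug. `druggable`
implements that inference over three data levels — somatic mutations, mRNA
expression, and (phospho)protein expression — driven by a curated
variant/drug knowledgebase in which each entry links one variant to one
drug, in one tumor type, with an effect (sensitive or resistant) and an
ordinal evidence level (preclinical < case report < clinical trial < FDA
approved). The package also nominates *putative* drug-response mutations
from 3D co-location with known ones, integrates calls across levels into
per-tumor multi-omics profiles, quantifies demographic enrichment, and
validates biomarkers against a cell-line drug screen.

## Knowledgebase matching and call resolution

A mutation is matched through three routes, mirroring how curated
knowledgebases encode variants:

1. **Exact**: the (gene, protein change) pair equals an unambiguous entry
   (e.g. BRAF V600E).
2. **Ambiguous single residue**: the entry names only a reference amino
   acid and position (e.g. BRAF V600); any substitution at that residue
   matches, but the reference amino acid must agree — V600 matches V600K,
   not A600K. The notation implies this constraint without stating it; we
   enforce it because a mismatched reference amino acid indicates a
   different annotation frame.
3. **Codon range**: entries such as an exon-19-equivalent in-frame deletion
   range (EGFR 729–761) match mutations of the required class whose *first
   affected codon* falls inside the range. Partial overlaps whose start lies
   outside the range do not match; the start codon is the only coordinate
   reliably present in short-form protein annotation.

Loose frameshift/nonsense categories match by (gene, class, position), with
`*` as a wildcard position.

Resolution per (sample, mutation): if any sensitive interaction exists the
call is sensitive (sensitive-over-resistant rule); among effect-consistent
matches, the drug with the globally maximal evidence level — across all
tumor types — is chosen, taking the alphabetically first drug on an
equal-evidence tie (a documented, deterministic choice; all tied entries
remain on the call). The call is *cancer-type specific* when the sample's
cancer type itself attains that maximal level; otherwise the drug is
borrowed off-label (*non-specific*, the repurposing setting). Entries with
an `UNSPECIFIED` tumor type never confer specificity: specificity asserts
that evidence exists *in this cancer type*, which an unspecified annotation
cannot support.

Cumulative evidence-tier summaries count each sample once at its best tier,
so the fraction at "at least clinical trial" always contains the fraction
at "FDA approved". Only sensitive calls count toward druggability
fractions; resistant calls flow to the co-occurrence reports.

## Cohort QC

Three filters precede matching:

* **Large/complex indels**: indels longer than 100 bp (strict: 100 bp is
  kept) and rows whose variant type is a configured "complex" token.
* **Near-duplicate samples**: a pair with variant concordance above 60% is
  collapsed unless both samples have at most five variants. Concordance is
  shared variants divided by the *smaller* sample's variant count — the
  conservative denominator, which flags a sample fully contained in
  another. Of a flagged pair we drop the sample with fewer variants
  (lexicographically later barcode on a tie). Both choices are deterministic
  and logged; other conventions exist, and users comparing against other
  pipelines should check this knob first.
* **Common variants**: population allele frequency above 0.05% *and* not
  flagged pathogenic. A missing frequency is treated as rare and kept — a
  variant cannot fail a threshold it lacks.

The filters only remove records and commute up to the duplicate tie-break,
so full-QC output is invariant to input row order.

## Expression outliers

For each knowledgebase gene whose expression direction is linked to drug
response, the cohort-wide first and third quartiles (Q1, Q3) define the
outlier score

$$\mathrm{score} = (x - Q_3)/\mathrm{IQR} \quad\text{or}\quad (Q_1 - x)/\mathrm{IQR},$$

with a score strictly greater than 1.5 calling the sample an outlier — the
classical Tukey fence. Quartiles use linear interpolation between order
statistics (`quantile` type 7, the default of mainstream numeric stacks);
the convention is fixed and shared by tests and oracles. Features need at
least 10 non-missing samples; configured cancer types (e.g. acute myeloid
leukemia, whose expression program distorts pan-cancer quartiles) are
removed before quartiles are computed; zero-IQR features are degenerate and
skipped with a warning. Scores are location–scale free: any affine
transform of a feature leaves every score unchanged. Under normality
Q3 + 1.5·IQR sits at about 2.70 standard deviations, so null data yields
roughly 0.35% calls per tail (≈0.7% over both tails) — the background rate
against which planted-outlier recovery is judged. Outliers are ranked
within each sample (dense ranks, ties shared) to surface the most promising
target per tumor. Quartiles are computed across the whole pan-cancer
cohort, not per cancer type; a consequence, and a known limitation, is that
outliers in cancer types with low baseline expression can be missed.
Phosphosite rows (`GENE:pSNNN`) inherit the parent gene's entry by default
(`inherit_phosphosites = FALSE` requires explicit entries).

## Spatial proximity clustering

On each protein structure, every residue pair's distance (minimum
inter-atomic distance when parsing PDB input; a precomputed distance table
is the primary channel) contributes to a background distribution. A mutated
pair's p-value is the proportion of *all* pairwise distances less than or
equal to its own; clustering uses only significant proximal pairs with
p < 0.05 and distance < 5 Å (both strict). Single-link agglomeration — the
connected components of the significant-pair graph — forms initial
clusters. The centroid is the member with the highest cohort recurrence;
ties fall to the member minimizing the recurrence-weighted sum of
shortest-path distances to all members (closest to the recurrent mass — our
operationalization of "near highly recurrent mutations", for which no
formula is published), then to the lowest residue number. Each cluster is
focused to a 5 Å graph radius around its centroid; members left outside
re-enter clustering among themselves, incrementing a generation counter,
until no significant pair remains. This recursion recovers secondary
functional regions that a single radius cut would discard. P-values are
computed once per structure: the background is structure-wide and does not
change across recursion rounds. No sequence-separation filter is applied,
so adjacent residues are eligible pairs. When a gene has several
structures, each is clustered independently and putative calls are unioned.

Uncatalogued members of a cluster containing a known sensitive mutation
become `putative_sensitive`; clusters with known resistant mutations yield
`putative_resistant` members only when they share no residue with any
sensitive-containing cluster, preventing contradictory annotation. Putative
calls enter downstream summaries at a dedicated `hotspot3d` tier placed
strictly below preclinical: they carry no direct experimental evidence.

## Cell-line screen validation

Two orthogonal checks. First, LN(IC50) values of lines carrying
knowledgebase mutations, joined to their mapped drugs, are compared to the
background of *every* drug–cell-line measurement with a two-sided
Mann-Whitney U test (exact for small untied samples, tie-corrected normal
approximation with continuity correction otherwise); per (mutation, drug)
combinations require at least five carrier lines and use that drug's own
background. The background deliberately includes the carriers (the literal
reading of "all measurements, carrier or not"), which makes the test
slightly conservative — measured type-I error ≈0.03–0.05 at nominal 0.05.
Second, for each expression-sensitivity gene, every probe is regressed
(OLS, `y = Bx + a`) against LN(IC50), with the probe's outlier score on the
cell-line panel itself as `x`; combinations need five lines and a
non-degenerate predictor, significance is p < 0.05 *and* B < 0, and a gene
is validated when at least one of its probes is significant. No
multiple-testing correction is applied across the probe–drug family — a
deliberate mirror of the validation design this implements; treat the
per-combination p-values as descriptive, not confirmatory.

## Demographic enrichment

For each eligible cancer type and commonly druggable gene, the matrix cell
is $\log_2\!\big((d_A/n_A)\,/\,(d_B/n_B)\big)$ for demographic categories A
and B, with ±∞ clamped to ±3 for display. Eligibility: ≥20 tumors per
category per cancer type; genes druggable in ≥150 (sex) or ≥40 (race)
tumors cohort-wide; ≥10 carriers of the gene in the cancer type per cell.
The sex analysis excludes sex-specific cancer types (BRCA, CESC, PRAD, OV,
UCEC, UCS). Significance is a two-sided Fisher exact test per cell with
Benjamini–Hochberg FDR across all cells of the matrix at q < 0.05 (BH is
the specific FDR method chosen; the family is all computed cells per trait
analysis). With more than two categories the two largest are contrasted,
ties broken by first appearance in the traits table; pass `categories` to
fix the contrast explicitly. This is descriptive enrichment — no ancestry
adjustment or causal claim.

## The synthetic-data generator

Every input dialect is generated with ground truth so each stage is
testable without downloads. The defaults are the study conditions, chosen
once:

* an exact missense driver at **40%** of synthetic melanoma (the canonical
  BRAF V600E scenario) plus drivers at 3–25% elsewhere, including a
  codon-range in-frame deletion at 10% of lung adenocarcinoma and a
  resistant RAC1 P29S at 5% of melanoma;
* passenger mutations at Poisson mean 6 per sample in non-druggable genes,
  5% of them flagged common and non-pathogenic (QC bait);
* two planted near-duplicate samples at 70% concordance, one small
  identical pair (3 variants each), three 150 bp indels and two 100 bp
  boundary indels;
* expression baselines Normal(µ ∈ [6, 10], σ = 1) per feature, five
  planted outliers per druggable feature shifted to Q3 + 3·IQR — comfortably
  past the 1.5 fence so recovery is deterministic — with 10% missingness on
  the protein panel;
* a structure whose hotspot residues (the V600 neighborhood: 596, 600, 601,
  604, 613) sit pairwise within a 4 Å ball while decoys are ≥15 Å apart, so
  the significant-pair graph contains exactly the hotspot clique;
* a screen of 120 lines with background LN(IC50) ~ Normal(2.5, 1.2²), a
  −2 shift for carrier lines on the paired drug, and a linear
  outlier-score response with slope −0.8 and noise σ = 0.1 for
  expression-paired drugs (planted effects are kept disjoint per drug).

All draws are fixed by the config seed (R's default Mersenne-Twister);
identical seeds give byte-identical files. What the generator does *not*
emulate: mutational signatures, copy number, batch effects, correlated
expression programs, or heavy-tailed expression (an optional t-distributed
mode would stress the IQR fence). Passing tests therefore demonstrate
algorithmic correctness on data satisfying the model's assumptions, not
robustness to real-data pathologies.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere.
* Strict inequalities at every published threshold (score > 1.5, p < 0.05,
  distance < 5, concordance > 0.60, AF > 0.05%, indel > 100 bp).
* Zero-IQR features, empty backgrounds, empty cohorts and zero
  denominators raise warnings or errors rather than propagating NaN.
* Equal-evidence drug ties: alphabetical; duplicate-entry ties: file
  order; centroid ties: weighted-distance then lowest residue. All
  deterministic, so knowledgebase row permutations cannot change results.

## Problem sizes used by the test suite

The suite cross-checks matching on 100 random cohorts (≤200 mutations, ≤30
entries) and clustering on 100 random structures (≤15 mutated residues)
against exhaustive references; Monte-Carlo checks use 1000 replicates for
the screen test's type-I error, 500 for slope-CI coverage, 200 for
demographic detection power, and n = 10,000 for the null fence rate; the
end-to-end cohort is ~700 tumors. These sizes give stable Monte-Carlo
estimates while keeping a full run around two minutes.
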