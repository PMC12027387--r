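---
title: "Methods: differential phosphoproteomics and priming-site inference"
author: "phosphoprimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential phosphoproteomics and priming-site inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoprimer)
```

# Scope and scientific background

Gsk-3 family kinases — Mck1 in *Saccharomyces cerevisiae* — phosphorylate
substrates bearing the consensus (S/T)XXX(S/T), and typically require the
C-terminal (+4) serine/threonine to be phosphorylated first by a separate
"priming" kinase. Deleting the kinase therefore produces a paired signature
in site-level quantitative phosphoproteomics: phosphorylation at first
sites collapses (and, because the primed +4 site sits on the same peptide,
that signal lives mostly on multiplicity ≥ 2 phosphopeptides), while the
monophosphorylated primed species at the +4 position accumulates.

This package implements the quantitative chain that extracts that signature
from intensity tables and places it in its regulatory context: differential
statistics with permutation FDR, occupancy normalization to the proteome,
consensus scanning with priming classification, transcript–protein
integration, and a synthetic-data generator carrying planted ground truth.
Upstream spectral processing (search engines, TMT reporter quantification)
and de-novo motif discovery are out of scope: the site-level table is the
entry point, and the consensus is scanned as a fixed pattern.

# Data model and conventions

* All residue coordinates are **1-based** indices into the protein
  sequence; `S113` means serine at position 113. No 0-based interface
  exists anywhere.
* Intensities are handled on the **log2 scale**. Absent values are encoded
  as empty fields in TSV and `NA` in memory; they are distinct from
  measured zeros and are the only values imputation touches.
* A phosphopeptide record is one (protein, position, multiplicity) class,
  mirroring MaxQuant site-table semantics: the same site can appear as a
  multiplicity 1, 2 and 3 record with separate quantifications.
* Sample identifiers follow `genotype_phase_replicate` (`WT_PDS_2`), from
  which the design metadata is parsed.
* Records with phosphogroup localization probability below 0.75 are
  removed on ingestion (`read_site_table()`, `filter_sites()`); the
  threshold is exposed.

# Normalization and imputation

**Median normalization.** Each sample is shifted so that its median over
present log2 values equals the median of the per-sample medians. Defining
the common target as the median of medians (rather than, say, the grand
median of all values) makes the operation exactly idempotent and removes a
constant shift of any one sample without residue. The known limitation is
compositional: when a large, direction-asymmetric fraction of features is
truly regulated (in the generator's reference conditions, 25% of genes
down and 10% up), the mutant-sample medians absorb part of the regulation
and all fold changes shift by a common small offset. This is inherent to
median normalization, not to this implementation; analyses that plant very
dense regulation should interpret absolute fold changes accordingly.

**Imputation.** Missing values are assumed left-censored (below detection)
and are drawn per sample from
$\mathcal{N}(\hat\mu_s - 1.8\,\hat\sigma_s,\ (0.3\,\hat\sigma_s)^2)$,
where $\hat\mu_s, \hat\sigma_s$ are computed over the present values of
sample $s$. The defaults 1.8 / 0.3 are the de-facto convention for
label-based proteomics and are exposed (`downshift`, `width_factor`).
Imputation is refused for samples with fewer than 3 present values, and is
deterministic under a seed.

# The moderated differential test

For every feature the two-group comparison (mutant minus wild type, within
one growth phase) is summarized by

$$\tilde t_g = \frac{\bar x_{g,1} - \bar x_{g,2}}
{\sqrt{\tilde s_g^2\,(1/n_1 + 1/n_2)}},\qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

with $s_g^2$ the pooled sample variance on $d = n_1+n_2-2$ degrees of
freedom. The prior $(d_0, s_0^2)$ is estimated from the whole variance
ensemble by the method of moments on log variances: with
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$ (the digamma term corrects the
downward bias of $\log s^2$),

$$\operatorname{Var}(e) - \psi'(d/2) = \psi'(d_0/2)\cdot\tfrac{2}{2} \;\Rightarrow\;
d_0 = 2\,\psi'^{-1}\!\big(\operatorname{Var}(e) - \psi'(d/2)\big),\qquad
s_0^2 = \exp\!\big(\bar e + \psi(d_0/2) - \log(d_0/2)\big).$$

When the observed spread of log variances does not exceed its sampling
component, $d_0 = \infty$ and $s_0^2 = \exp(\bar e)$ — the bias-corrected
ensemble variance. P-values are two-sided from a t distribution on
$d_0 + d$ degrees of freedom. Two limits matter and are tested: with
`prior_df = 0` the statistic is exactly the ordinary equal-variance t, and
the full estimator agrees with the reference empirical-Bayes
implementation (limma) to numerical precision on shared inputs. Note that
the degenerate case of identical sample variances yields the
bias-corrected common variance, not the raw sample variance: using the raw
value would inflate all statistics by $\sqrt{\exp(\log(d/2)-\psi(d/2))}$
(≈ 14% at $d=4$) and make null p-values anticonservative.

# Permutation-based FDR

Labels are reshuffled **within the tested phase** (the contrast actually
tested is genotype within phase), enumerating the distinct non-identity
reassignments; for balanced designs complementary swaps, which leave
$|\tilde t|$ unchanged, are counted once — a 3 vs 3 design thus has 9
usable permutations. Permuted statistics are pooled across features and
the estimate for the threshold at each observed $|\tilde t|$ is

$$\hat q(t) \;=\; \frac{\bigl(1 + \textstyle\sum_b V_b(t)\bigr)/(B+1)}
{\max\{1,\ R(t)\}},$$

monotonized to be non-increasing in $|\tilde t|$ and clipped to $[0,1]$,
where $V_b(t)$ counts permuted statistics at least as extreme in
permutation $b$ and $R(t)$ counts observed ones.

The add-one pooled form is a deliberate numerical choice. A
median-over-permutations ratio estimator degenerates at the extreme ranks
when only a handful of distinct balanced splits exist: the ten split maxima
of a null 3 vs 3 dataset are exchangeable, so the observed maximum exceeds
the median of the permuted maxima about half the time, handing the
top-ranked feature $\hat q = 0$ on completely null data. The add-one
estimator bounds $\hat q$ at the top rank below by $1/(B+1)$ and, in the
package's calibration tests (2,000 null features, 3 vs 3, 200 seeds), no
null dataset yields any feature with $q < 0.05$, while the uniformity of
the p-values passes a 1%-level Kolmogorov–Smirnov screen in ≈98% of runs.

**Calling.** A feature is `reduced` when $\mathrm{log2FC} \le -\log_2 f$
and $q <$ the FDR threshold, `enhanced` symmetrically. The fold threshold
$f$ is layer-specific by convention: 2.0 for phosphopeptide records, 1.5
for transcripts and proteins; the FDR threshold defaults to 0.05. All
three are arguments, not constants.

# Occupancy normalization

"Occupancy-level" regulation is the phosphopeptide change after
normalization to the parent protein: on the log2 scale,
$\mathrm{lfc}_{\text{occ}} = \mathrm{lfc}_{\text{phospho}} -
\mathrm{lfc}_{\text{protein}}$, a ratio of ratios. The identity is exact
record by record (both sides are differences of group means) and is
asserted pipeline-wide at $10^{-9}$. Occupancy significance is recomputed
by default: per sample, the parent protein's log2 intensity is subtracted
from the site's, and the moderated test plus permutation FDR is rerun on
the normalized matrix (`recompute_fdr = FALSE` instead thresholds the
normalized fold changes with the phospho-level q). Records whose parent
protein is unquantified are flagged and kept with absent occupancy values.
Peptides mapping to several proteins are attributed to the first listed
(razor-style). True stoichiometry estimation — which would require the
unmodified counterpart peptides — is explicitly not attempted.

# Consensus scanning and priming classification

`scan_consensus()` reports **every** index pair $(i, i+4)$ with S or T at
both positions: overlapping matches are all kept (in cascades of 4-spaced
serines one residue is the +4 site of one match and the first site of the
next), tyrosine never matches, and positions within four residues of the
C-terminus cannot open a match (no padding). The scanner is tested for
exact set equality against a brute-force double-loop enumeration.

A match is classified from the differential evidence at its two positions:
`primed_pair` (reduced first site *and* enhanced +4), `first_reduced_only`,
`plus4_only`, or `none`. Evidence defaults to **directional per-record
significance**: a record at the position with moderated $p < 0.05$ and the
signed fold change in the right direction. The rationale is that the
consensus scan pre-specifies the position pair, so the classification is a
conjunction of two directional tests at fixed positions — its false-pair
rate scales with $\alpha^2$ — whereas the table-wide FDR q remains the
appropriate control for the headline discovery sets. Both alternatives are
available (`evidence = "q"` and `evidence = "call"`, the latter reusing the
fold+FDR call flags). Under the generator's reference conditions the
default rule recovers planted primed pairs with sensitivity above 0.8 while
no non-substrate protein receives a primed-pair call.

`multiplicity_statistics()` summarizes the signature: the fraction of
distinct reduced first sites observed **only** at multiplicity ≥ 2, and the
fraction of enhanced +4 evidence that is monophosphorylated. Empty
denominators yield flagged `NA`s, never silent `NaN`s.

`consensus_enrichment()` compares the fraction of proteins whose consensus
first positions carry phospho evidence between a substrate set and a
disjoint background, against a null of within-protein residue shuffles
(composition preserved, phospho positions fixed), with the add-one
empirical p-value.

# Transcript–protein integration

`correlate_layers()` computes the Pearson correlation of log2 fold changes
over the genes significant in **either** layer and quantified in **both** —
the union-minus-missing construction used for published transcript/protein
comparisons. `classify_quadrants()` assigns each gene quantified in both
layers to `both_up` / `both_down`, a single-layer class, or `neither`; the
rare both-significant-discordant combination gets an explicit `discordant`
class so that counts always sum to the analyzed universe.
`gene_set_overlap()` gives the exact hypergeometric upper-tail p (verified
against exhaustive enumeration for universes ≤ 20) and the Jaccard index;
the universe defaults in practice to all genes quantified in the relevant
layer and is always an explicit argument.

# The synthetic-data generator

`simulate_study()` emulates the structure of a 2-genotype
(WT, *mck1Δ*) × 2-phase (exponential, post-diauxic shift) TMT-style study:

* **Design.** 3 replicates per group (12 samples). The real design this
  mirrors is an 11-plex with no published per-group replicate count; a
  balanced 3-per-group layout is the closest well-posed choice and keeps
  every contrast testable.
* **Sequences.** Residues are drawn i.i.d. from a fixed table with S and T
  up-weighted to 8% each (remaining 18 residues uniform). The up-weighting
  guarantees background, non-planted consensus matches, so specificity is
  genuinely exercised. Each of the `n_substrates` proteins receives one
  planted S/T pair spaced exactly 4 apart at a random interior position.
* **Phospho table.** Log2 intensities are Gaussian around a per-record
  baseline $\mathcal{N}(20, 2^2)$ with noise
  $\sigma_{\log_2} = \mathrm{cv}/\ln 2$ (cv default 0.2). In mutant
  samples of the shifted phase, planted first-site records are reduced by
  2.0 log2 units and appear, with probability 0.75, only as
  multiplicity-2 records (otherwise multiplicity 1); each planted +4 site
  gains a multiplicity-1 record increased by 1.0 log2 units. Background
  sites fall on observed S/T (and ~5% Y) with multiplicities drawn
  0.6/0.3/0.1. Planted records carry localization probability in
  U(0.75, 1) — they represent the confidently localized class — while
  background records draw from Beta(8, 1), so about 10% exercise the 0.75
  ingestion filter.
* **Missingness.** Absence is a soft detection limit: a sharp logistic in
  intensity (width 0.25 sd) whose midpoint is root-found so the expected
  overall rate matches `missingness_rate` (default 0.05). Missing values
  are therefore genuinely low, matching the downshifted-imputation
  assumption; an earlier, softer curve that also deleted mid-intensity
  values contradicted that assumption and was replaced.
* **Expression layers.** A planted Mck1-activated regulon (25% of genes)
  is reduced and a smaller set (10%) enhanced in the shifted-phase mutant,
  with per-gene transcript/protein effects drawn from a bivariate normal
  (mean ±1.5, sd 0.8 log2, correlation 0.4 by default). A Gcn5-activated
  regulon (20%) overlaps the Mck1 set (12.5% of genes) for the gene-set
  overlap analyses. A fraction (0.25) of substrate parents also changes at
  the protein level so occupancy- and phosphorylation-level calls can
  disagree. All genotype effects act in the shifted phase only; a
  gene-specific phase response shared by both genotypes provides
  between-phase structure.
* **Determinism.** Each generator runs on its own RNG stream derived from
  the master seed, so adding phosphosites never perturbs the sequences;
  identical seed and configuration give byte-identical outputs.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: peptide digestion and shared/razor peptides, TMT
reporter-ion interference and ratio compression, batch structure, count
noise in RNA-seq (the transcript layer is a normalized-abundance matrix),
non-Gaussian intensity tails, and correlated missingness across samples.
Recovery results certify the inference chain's correctness on data
matching its model assumptions; they do not quantify robustness to these
real-data pathologies.

# Numerical choices and problem sizes

* Permutations default to *all* distinct non-identity label reassignments
  (9 for a 3 vs 3 design); requests beyond the available count fall back
  with a warning, and designs too large to enumerate are sampled.
* k-means uses Euclidean distance on row-z-scored profiles, $k = 4$ by
  default with 50 random restarts, best fit by total within-cluster sum of
  squares; clusters are renumbered in decreasing size order, so results
  are deterministic under a seed.
* Ties and degenerate inputs: zero-variance features are rejected by the
  z-scoring step; empty evidence sets yield flagged undefined fractions;
  all-absent samples are an error, as are samples with fewer than 3
  present values at imputation.
* The test-suite runs its statistical checks at fixed sizes chosen to keep
  the whole suite under a minute: null calibration at 2,000 features ×
  200 seeds (uniformity screened on 100), the full recovery experiment at
  the 400-protein reference scale plus one 200-substrate run for the
  multiplicity fraction, correlation recovery at 500 genes, and the motif
  enrichment power check at reduced scale (8 seeds × 199 shuffles over 60
  proteins) with the same pass rule as the full-scale description.

# Known limitations

* Occupancy is a relative ratio-of-ratios, not absolute stoichiometry.
* Median normalization carries the usual compositional bias under dense,
  asymmetric regulation (see above).
* The permutation count for small balanced designs bounds the attainable
  q resolution at $1/(B+1)$; with 2 replicates per group the scheme
  degenerates (1 usable permutation) and the moderated p-values are then
  the only usable evidence.
* Multi-protein peptide mappings are resolved razor-style to the first
  listed protein and flagged, which can misattribute sites shared between
  paralogs.
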