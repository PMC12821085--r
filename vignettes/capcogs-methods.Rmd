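---
title: "Methods: enhancer-gene scoring and GWAS gene prioritisation from Promoter Capture Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer-gene scoring and GWAS gene prioritisation from Promoter Capture Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capcogs)
library(dplyr)
```

capcogs links distal regulatory elements to the genes they control using
Promoter Capture Hi-C (PCHi-C) and uses those links to prioritise effector
genes for GWAS traits. This vignette is the package's account of its models,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate.

## The data model

All fragment-grain coordinates (restriction-fragment maps, peaks, LD blocks)
are 0-based half-open, the BED convention. GWAS variant positions are 1-based,
the summary-statistic convention; a 1-based position $p$ lies in half-open
$[s, e)$ iff $s < p \le e$. The fragment map — an ordered, contiguous tiling of
each chromosome by restriction fragments (e.g. DpnII fragments, median length
around 1.5 kb) — is the backbone: baits, promoter-proximal windows,
promoter-interacting regions (PIRs) and candidate enhancers are all sets of
fragment IDs. Interaction tables carry CHiCAGO-normalised counts
($N_{obs}$), raw read counts and CHiCAGO scores at either single-fragment or
~5 kb-binned resolution (baited fragments left unbinned); `merge_consensus()`
takes the non-redundant union of the two resolutions at fragment grain, so
downstream feature assembly is uniform.

## ABCC: Activity-by-Captured-Contact

For an element $E$ and gene $G$, the ABC score is

$$\mathrm{ABC}_{E,G} = \frac{A_E \times C_{E,G}}
  {\sum_{e\,\text{within 5 Mb of } G} A_e \times C_{e,G}}$$

where $A_E$ is the geometric mean of the ATAC and H3K27ac read counts over
the element and $C_{E,G}$ the contact frequency. The capture-Hi-C adaptation
imputes $C$ in CHiCAGO-normalised count space. For a baited promoter,

$$C = \max(N_{obs},\; N_{exp}), \qquad N_{exp} = B_{mean} / (s_i\, s_j),$$

the rationale being that contact frequency cannot fall below the Brownian
collision background ($B_{mean}$ is CHiCAGO's Brownian noise level; $s_i$,
$s_j$ the bait- and other-end scaling factors). The printed form of this
expression is ambiguous between $B_{mean}/(s_i s_j)$ and
$(B_{mean}/s_i)\,s_j$; we divide by both factors — that is the reading
consistent with transporting a background level into normalised-count space —
and expose `divide_both = FALSE` to flip it. For promoters that could not be
baited (or failed QC), $C = f(d)$, CHiCAGO's fitted distance function
evaluated at the bait-element midpoint distance. Because $f$ rises steeply
below ~1.5 kb, elements whose nearest fragment is the bait itself or an
adjacent fragment are capped at $f(\text{median fragment length})$, i.e.
$f(1.5\,\mathrm{kb})$ at the default fragment size, so sub-fragment distances
do not dominate.

Numerical choices:

* **$f(d)$ representation.** Piecewise-linear interpolation in
  log-distance/log-count space over the tabulated knots, extrapolating the
  end slopes beyond the first/last knot. CHiCAGO's fit is near-linear in
  log-log space, and for an exact power law this interpolation is exact.
* **Distance** is midpoint-to-midpoint, the same convention under which the
  distance function is indexed.
* **Activity pseudocount** defaults to 0 — a plain geometric mean, so a zero
  in either assay zeroes the element — and is configurable.
* **Candidate elements** are the union of ATAC and H3K27ac peaks, merged
  when overlapping, excluding any element touching the gene's own baited
  promoter fragment (mirroring the original ABC's exclusion of a gene's
  promoter from its own enhancer list). Element-level contact over a
  multi-fragment element is the per-fragment maximum.
* **Window membership**: element midpoint within 2.5 Mb of the TSS (a 5 Mb
  window). One anchor promoter per gene is used for ABCC: the first baited
  promoter in annotation order, falling back to the first promoter (and the
  $f(d)$ route) when none is baited.
* **Degenerate genes** whose window sum of numerators is zero receive
  all-zero scores and a `zero_denominator` flag rather than NaN.

The score cutoff for calling enhancer-gene pairs is selected by maximising
the Pearson correlation between the per-gene sum of above-cutoff numerators
and gene expression over a cutoff grid (ties resolved to the smallest
cutoff); the deployed default downstream is 0.023, with 0.04 as the
threshold at which called enhancers feed gene prioritisation.

## Fine-mapped signals

GWAS summary statistics are partitioned into approximately independent LD
blocks (half-open intervals; variants outside every block are dropped with a
logged count). Missing z-scores are imputed by the conditional-mean Gaussian
rule $\hat z_m = R_{mo} (R_{oo} + \lambda I)^{-1} z_o$ with ridge
$\lambda = 0.1$ by default (the reference method's standard regularisation;
configurable), reporting per-variant imputation quality
$r^2 = \mathrm{diag}(R_{mo}(R_{oo}+\lambda I)^{-1}R_{om})$. Observed
variants always keep their input values. Imputed variants get $p$ as the
plain two-sided normal tail of $z$ — triage only needs order-of-magnitude
p-values, so no $r^2$ rescaling is applied by default.

Blocks whose minimum $p < 10^{-6}$ (strict) are routed to multivariate
fine-mapping; the package consumes externally computed credible sets (e.g. a
SuSiE export) as per-signal PIP tables and does not re-implement the
multivariate algorithm. All remaining blocks take the single-causal-variant
fallback with Wakefield approximate Bayes factors,

$$\mathrm{ABF} = \sqrt{\tfrac{V}{V+W}}\;
  \exp\!\Big(\tfrac{z^2 W}{2(V+W)}\Big), \quad V = se^2,$$

normalised to posterior probabilities of association over the block
(computed on the log scale). The effect-size prior $W = 0.04$ (prior sd 0.2
on the log-odds scale) is the conventional value in this method family; it
is configuration with a documented default, not a claim about any particular
study, and is recorded in run metadata.

## multiCOGS

A gene's feature set unions four categories over all of its annotated
promoters: coding variant positions (an input annotation table, not a VEP
call), the TSS fragment ±5 fragments (promoters included whether or not they
were baited in the capture design), other-end fragments of consensus
interactions with CHiCAGO score ≥ 5 anchored at the gene's baited promoters,
and fragments of ABCC elements paired to the gene at score ≥ 0.04. One
fine-mapped signal's score for the gene is the PIP mass over the *unique*
variants falling in any feature — a variant in both a PIR and the proximal
window counts once, the only reading that keeps scores probabilistic — and
is clipped at 1 (clipping is logged; credible-set masses can marginally
exceed 1 through rounding). Signals combine as

$$\mathrm{multiCOGS}_{gene} = 1 - \prod_{\text{block, credset}}
  (1 - \mathrm{Score}_{gene,\,\text{block},\,\text{credset}}),$$

the probability that at least one signal is linked to the gene. Standard
(single-causal) COGS is the same machinery restricted to one credible set
per block. Per-category decomposition reruns the scoring with features
restricted to one category at a time; category scores are not bounded by the
full score because each category run re-combines across signals separately.

Variants in the MHC (GRCh38 6:28510120–33480577, extreme LD) are removed
before scoring. The interval is interpreted as printed, 1-based closed on
variant positions, so a variant at 6:28,510,119 is retained. Prioritisation
uses a strict `multicogs > 0.5` by default (the `>= 0.5` variant is a flag),
with deterministic ranking (score descending, then gene ID).

## cPIR enrichment by transplantation

Per gene, cis PIR fragments are collapsed into contiguous blocks (cPIRs):
overlapping or book-ended fragments merge; trans-chromosomal PIRs are
removed first. Each cPIR records its bp offset from the gene's baited
fragment midpoint. The permutation null "transplants" each gene's *entire*
cPIR set to a randomly selected gene's bait — targets drawn uniformly
without replacement within a permutation (a gene may draw itself), sizes and
bait-relative offsets preserved exactly — so the null preserves both the
distance-from-bait distribution and the spatial arrangement of a gene's
PIRs, which a per-PIR shuffle would not. Transplants exceeding chromosome
bounds are re-drawn (counted, logged). Overlap is ≥ 1 bp intersection, and
the statistic is the per-cPIR (not bp-weighted) overlap proportion, over 100
permutations by default.

Fold enrichment is observed/null-mean; the 95% CI propagates both error
sources on the log-fold scale by the delta method:
$\exp\big(\log F \pm 1.96\sqrt{\mathrm{Var}(p_{obs})/p_{obs}^2 +
\mathrm{Var}(\bar p_{null})/\bar p_{null}^2}\big)$ with binomial variance
for the observed proportion and the standard error of the null mean across
permutations. This delta-method construction is our interpretation of
"error propagation" for a ratio of proportions.

## Alternative-promoter PIR sharing

For genes with more than one baited promoter, each with at least one
significant interaction (score ≥ 5, ≥ 5 reads), each significant PIR is
labelled *fully shared* (contacts all qualifying promoters), *partially
shared* (a strict subset of more than one; only possible with > 2
promoters), or *distinct*. A candidate-distinct PIR is rescued to shared if
it — or either fragment adjacent to it — contacts another promoter at the
lenient score ≥ 3. With exactly two promoters the classifier can by
construction only emit fully-shared or distinct.

## The synthetic-data generator

All inputs the toolkit consumes are generated from one integer seed, with
planted ground truth, at sizes chosen for fast, deterministic recovery
tests: 3 chromosomes × 2,000 fragments (log-normal lengths, median 1.5 kb),
200 genes with 1–3 alternative TSSs and ~90% of promoters baited, 20 planted
enhancer contacts, 20 LD blocks × 100 variants. Background interaction
counts follow a tabulated power-law decay $f(d) = c\,d^{-1}$ anchored at
$f(1.5\,\text{kb}) = 2B_{mean}$ with gamma noise and a 1% nominal
significant-score rate; planted contacts get a 30-fold boost over their
expected level and scores above 5. Planted elements carry strong peaks in
both assays; planted GWAS causals sit inside planted enhancer fragments and
are emitted as single-variant SuSiE-like credible sets of PIP mass 0.95;
z-scores follow $MVN(R\lambda, R)$ with AR(1) LD ($\rho = 0.9$) and
non-centrality 7 on causals; expression is the per-gene sum of ABCC
numerators above 0.02 plus optional Gaussian noise.

What these tests show — and do not. Recovery of planted pairs and genes
demonstrates that the scoring machinery propagates a strong, well-localised
signal end to end; it does not demonstrate performance on real data, where
activity and contact are noisier, LD does not follow AR(1), credible sets
spread mass over many variants, and chromosomes dwarf the 5 Mb ABC window.
Two desk-scale artefacts are worth naming explicitly:

* a synthetic chromosome (~3 Mb) fits entirely inside the 5 Mb ABC window,
  so a strong planted enhancer is assigned to most genes on its chromosome
  and a planted credible set can prioritise many genes through the shared
  ABCC feature — gene-level specificity at this scale comes from the
  CHiCAGO-PIR route;
* single-causal identification under AR(1) LD is limited by the LD itself:
  with $\rho = 0.9$ a near-perfect proxy overtakes the true causal in
  roughly one replicate in ten regardless of method, so the
  planted-causal-recovery check is run at moderate LD ($\rho = 0.5$), where
  ranking by posterior is expected to identify the causal in ≥ 95% of
  replicates; the z-imputation quality check keeps $\rho = 0.9$, where
  conditional-mean imputation is strong.

## Known limitations

The package consumes CHiCAGO outputs and model parameters; it does not
re-fit them from raw counts, and it does not implement multivariate
fine-mapping, Hi-C matrix normalisation, VEP annotation or liftover. LD
arrives as matrices, not haplotype panels. The alternative-promoter
classifier and the 5 kb-binned inputs assume the bin bookkeeping of the
upstream caller; bins are accepted as provided and expanded to fragments
internally.
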