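---
title: "Methods: discovering immune-checkpoint lncRNA regulatory circuitry triplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering immune-checkpoint lncRNA regulatory circuitry triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icplnc)
```

# The problem

Immune checkpoints (ICPs) such as PD-1, PD-L1 and CTLA-4 are the targets of
checkpoint-inhibitor immunotherapy, and long non-coding RNAs (lncRNAs) are
increasingly implicated in their regulation. `icplnc` implements a
four-step computational framework for nominating **ICP-related
lncRNA-mediated core regulatory circuitry triplets** — units of one
lncRNA, one or more mediating immune genes, and one ICP gene — from bulk
tumor expression cohorts, and for assigning each triplet its most likely
regulatory wiring.

The four steps are:

1. **Differential expression with permutation calibration.** A moderated
   two-group t-test (empirical-Bayes variance shrinkage, the limma
   approach) compares tumor with normal samples. Because cohort sizes vary
   enormously across cancer types, raw p-values are re-calibrated against
   `B = 1000` random relabelings of the samples: each gene's calibrated
   p-value is the fraction of relabelings whose p-value beats the observed
   one, with a `+1` pseudocount so it is never zero. Genes at
   Benjamini-Hochberg FDR < 0.01 continue.
2. **Co-expression network and propagation.** Pearson correlations among
   the differentially expressed lncRNAs, immune genes and ICP genes define
   a weighted network (edge significance again by label permutation with
   BH correction; mutual information on equal-frequency bins provides a
   nonparametric cross-check of the same pairs). Personalized PageRank
   with restart mass on the ICP genes ranks every other gene by network
   proximity to the checkpoints; the top `k = 200` lncRNAs and immune
   genes per role continue.
3. **Triplet scoring.** All statistics in this step use first-order
   partial correlation with tumor purity as the covariate,
   \[ \mathrm{PCC}(i,j) =
      \frac{R_{LC} - R_{LP} R_{CP}}{\sqrt{1 - R_{LP}^2}\sqrt{1 - R_{CP}^2}}, \]
   because bulk-tumor immune-gene expression is strongly driven by the
   fraction of non-tumor cells in the sample. A (lncRNA, ICP) pair is a
   candidate only if its own purity-adjusted correlation is significant
   (BH FDR < 0.01 over the candidate universe). For each candidate pair,
   immune genes are ranked by their combined signed evidence
   \(\mathrm{sign}(r)\,(-\log_{10} p)\) against the lncRNA plus the same
   quantity against the ICP, and preranked GSEA against the immune
   pathway collection retains the leading-edge genes of pathways enriched
   at permutation p < 0.05. The pair's score is
   \[ S = \sum_i w_i\left[(-\log_{10}P_{1i})\,\mathrm{sign}(cor_{1i}) +
      (-\log_{10}P_{2i})\,\mathrm{sign}(cor_{2i})\right], \]
   where \(w_i\) is the enrichment score of the pathway (of largest |ES|)
   containing immune gene *i*, and the 1/2 subscripts denote the
   lncRNA-immune and ICP-immune partial correlations. Pair significance
   comes from 1000 joint sample-label shuffles of the lncRNA and ICP
   profiles with BH correction; pairs at FDR < 0.01 become triplets.
4. **Regulatory pattern selection.** Each (L = lncRNA, C = ICP, M =
   immune gene) triple is fit under four linear-Gaussian DAGs:
   INDEP \(P(L)P(C|L)P(M|L)\); COO \(P(L)P(M)P(C|L,M)\);
   LGI \(P(L)P(M|L)P(C|M)\); LIG \(P(L)P(C|L)P(M|C)\).
   Maximum likelihood gives \(\mathrm{AIC}_j = -2\log L_j + 2K_j\) and
   Akaike weights \(w_j = e^{-\Delta_j/2} / \sum_j e^{-\Delta_j/2}\); the
   minimum-AIC (maximum-weight) pattern is selected.

Downstream utilities relate discovered lncRNAs to antitumor immune
activity (marker-mean MHC/CYT signature scores, per-sample ssGSEA,
Spearman and Kruskal-Wallis screens) and to outcome (a dual univariate
Cox + log-rank screen, and a multivariate-Cox risk score
\(\mathrm{Risk} = \sum_j \beta_j \cdot \exp_j\) with a median split and
log-rank comparison).

# Design choices in the open corners

Several components are specified only loosely in the literature this
framework follows; the package makes these choices explicitly.

**GSEA ranking metric (per pair, not per lncRNA).** Ranking immune genes
only by their association with the lncRNA cannot detect the COO pattern:
under \(C = aL + bM + \varepsilon\) with independent \(L\) and \(M\), the
immune gene is marginally independent of the lncRNA, so no
lncRNA-anchored ranking will ever enrich its pathway. The immune genes
are therefore ranked by the *combined* signed evidence from the lncRNA
and the ICP sides, consistent with the S score summing those same two
terms. The cost is that enrichment is computed per candidate pair rather
than per lncRNA; the pair-candidacy screen keeps that set small.

**Pair candidacy via PCC(ij).** The lncRNA-ICP partial correlation is
computed first and acts as a gate (BH FDR < 0.01 over the candidate
universe). Without this gate, a pair whose S score is carried entirely by
the ICP side — for example a decoy lncRNA correlated with the immune
compartment only through tumor purity, paired with a genuinely
immune-embedded ICP — is statistically indistinguishable from a true
pair under the label-permutation null. All four regulatory patterns imply
a direct or mediated lncRNA-ICP dependence, so the gate costs no
sensitivity at the modeled effect sizes.

**Permutation null for S (`fixed_weights` default).** Under a shuffle,
re-running pathway selection ("full" mode) conditions the null on chance
re-enrichment; with co-expressed immune modules, a permuted profile that
happens to graze a module produces coherent evidence across its members
and a large conditional null S. That null is insensitive to pairs whose
evidence is one-sided (COO again). The default therefore holds the
observed pathway weights and retained genes fixed and re-computes only
the partial-correlation evidence, testing "is this much weighted evidence
surprising for these genes under no lncRNA/ICP-immune association".
`perm_mode = "full"` remains available; inside it, pathway enrichment is
judged against the observed run's gene-label |ES| critical values, since
a nested gene-label permutation per sample shuffle would be quadratic in
B and the gene-label null does not depend on the sample relabeling.

**p-value floors.** Every permutation p-value uses the
\((1 + \#\{\cdot\})/(B+1)\) pseudocount, and analytic p-values entering
\(-\log_{10}\) terms are floored at \(1/(B+1)\), keeping the S score
finite and its evidence scale commensurate with what B permutations can
resolve.

**Other fixed conventions.** "Not expressed" means a raw value of exactly
zero (configurable epsilon); the 70% filter is strict (`> 0.70`
removed); the log2 pseudocount is 1; network propagation uses |r| as edge
weight (PageRank needs non-negative weights), damping 0.85 and L1
tolerance 1e-8 with dangling mass returned to the restart distribution;
the top-200 cut is applied per role; exact AIC ties are broken by the
fixed order INDEP > COO > LGI > LIG with the ambiguity flag forced; calls
with top Akaike weight below 0.5 are flagged ambiguous but not removed;
variables are z-scored before pattern fitting so log-likelihoods are
comparable across triplets (all four patterns have K = 8 free parameters
under the linear-Gaussian parameterization, so AIC ordering equals
likelihood ordering — asserted in the tests); the median split sends
exact-median samples to the low-risk group; within a pathway collection a
gene retained by several enriched pathways takes the weight of the
largest-|ES| one.

# The synthetic cohort generator

Real multi-cancer compendia (TCGA/GTEx-scale) are far beyond a desk-scale
test budget, so validation rests on `simulate_cohort()`, which emits a
raw-scale expression table, metadata, gene catalog, pathway collection
and ground truth. Its defaults define the study conditions used by the
test suite and `scripts/acceptance.R`:

* 60 tumor and 20 normal samples; 50 lncRNAs, 200 immune genes, 10 ICP
  genes, 500 background genes — sizes chosen so every stage (including
  1000-permutation calibration) runs in seconds while leaving enough
  genes for FDR machinery to behave non-trivially.
* One planted triplet per regulatory pattern with structural coefficients
  `a = b = 0.8` and noise `sigma = 0.5`; each planted immune gene carries
  a module of 8 co-members at correlation 0.7, inserted with it into two
  host pathways of the 18-pathway collection. Modules are what make
  pathway enrichment a meaningful filter; a single isolated immune gene
  cannot dominate a 25-gene set's running sum.
* Tumor purity is Beta(5,2) per tumor sample; its z-score is added (loading
  1) to the members of three randomly chosen "infiltration" pathways, to
  all ICP genes, and to five decoy lncRNAs whose only association with
  the immune system runs through purity. The decoys are the generator's
  core test: purity-adjusted runs must reject them, plain-correlation
  runs (`use_purity = FALSE`) largely accept them.
* DE structure: a 2 log2-unit shift (random sign) on all planted genes,
  decoys and ICPs, on half of the remaining immune genes and lncRNAs and
  10% of background genes. With 1000 permutations the calibrated p-value
  floor is 1/1001, so BH selection at FDR < 0.01 requires a non-trivial
  fraction of genes to be truly shifted — a property of real pan-cancer
  comparisons as well.
* Survival: exponential proportional hazards on the z-scored expression
  of the first planted triplet (betas 0.8 each, baseline hazard 0.1,
  independent exponential censoring at rate 0.03, giving roughly 20-30%
  censoring); normals carry no survival or purity.
* Expression is exponentiated to the raw scale (`2^x - 1`), with sporadic
  5% dropout on background genes plus a 25-gene block at ~80% zeros that
  the 70% filter must remove.

`simulate_null_cohort()` keeps the purity loading (part of the null for
purity-adjusted statistics) but removes all planted structure, ties
survival to nothing, and is used for calibration checks: uniform
calibrated DE p-values, and triplet discoveries bounded by the nominal
FDR.

What the generator does **not** emulate: negative-binomial count noise,
batch structure, sample-specific library sizes, miRNA/ceRNA layers, or
any non-linear regulation. Passing tests therefore demonstrate that the
machinery is correct and calibrated under its own modeling assumptions
(log-scale Gaussian signal, linear regulation, purity as a single linear
confounder) — not that the biological discoveries from any particular
cohort are correct.

# Numerical notes and degenerate inputs

* Constant genes are dropped with a warning wherever a correlation is
  required; a constant purity vector falls back to plain Pearson with a
  flag. Zero pooled variance in the t-test is floored with a warning.
* Partial correlations are clamped to [-1, 1]; degenerate denominators
  (|correlation with purity| = 1) are errors in the scalar API and NA
  (gene excluded) in the vectorized pipeline.
* The GSEA running sum takes the first position attaining the maximum
  |deviation| within 1e-12, making exact rational ties deterministic; a
  set whose in-set ranking scores are all zero falls back to equal step
  weights.
* The equal-frequency MI binning uses first-occurrence rank ties, with
  constant vectors mapped to a single bin (MI = 0).
* Stage seeds are derived from the master seed by a fixed integer scheme,
  so a pipeline run is a pure function of (inputs, parameters, seed);
  the test suite asserts byte-identical reruns.

# Problem sizes used by the tests

Unit tests run on toy objects (tens of genes) and a reduced cohort (40
tumor / 15 normal, 255 genes, 2 planted triplets). The acceptance-style
tests use the full default generator: two cohorts for end-to-end
recovery (with purity-adjusted and plain modes for the decoy contrast),
three null cohorts for calibration, 100 replicates per pattern at
n = 500 (and 50, 200 for the monotonicity check), and 50 cohorts for
survival power. The complete suite runs in a few minutes on one CPU.

# Known limitations

* Pattern selection compares four fixed three-node DAGs; it is model
  selection, not causal discovery, and inherits all linear-Gaussian
  assumptions. Purity components left in the expression of immune and
  ICP genes can tilt likelihoods; the scoring stage adjusts for purity
  but the pattern stage fits observed expression as-is.
* Gene-label GSEA permutations ignore inter-gene correlation, so pathway
  p-values are anti-conservative for tightly co-expressed sets; this is
  mitigated (not removed) by the pair-level permutation FDR downstream.
* With `B = 1000`, no permutation p-value can fall below 1/1001; BH
  selection at FDR < 0.01 therefore needs either many true signals or a
  larger B.
* The default MHC/CYT marker lists are reconstructions shipped as
  editable data, not curated truth.
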