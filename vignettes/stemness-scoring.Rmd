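---
title: "Stemness scoring with a one-class logistic regression signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stemness scoring with a one-class logistic regression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemscore)
```

## The model

Cancer cells with stem-like properties (self-renewal, rapid proliferation)
are associated with treatment resistance and recurrence, and annotating
them from single-cell or spatial data by manual marker curation is slow and
reference-biased. `stemscore` instead quantifies stemness with a signature
learned from pluripotent reference profiles alone.

The signature is a **one-class logistic regression (OCLR)**: given $n$
reference profiles $x_1, \dots, x_n \in \mathbb{R}^G$ of the positive
(stem) class only — typically log-scale bulk or pseudobulk expression of
iPSC/ESC samples — the per-gene weight vector $w$ minimizes

$$
L(w) \;=\; \frac{1}{n} \sum_{i=1}^{n} \log\!\left(1 + e^{-\langle w,\, x_i \rangle}\right)
\;+\; \frac{\lambda}{2}\, \lVert w \rVert_2^2,
$$

with no intercept, initialized at $w = 0$. Because there is no negative
class, the loss simply rewards positive margins on the reference profiles;
the ridge term makes the problem strongly convex, so the solution is unique
and deterministic. Genes highly expressed across the stem references
receive large positive weights.

A cell (or spatial spot) $p$ is then scored by the **Spearman correlation**
$\rho = \mathrm{cor}(\mathrm{rank}(w), \mathrm{rank}(p))$ over the genes
shared between the model and the measured features, and the per-cohort
correlations are min-max scaled to the **stemness index**
$\mathrm{SI}_i = (\rho_i - \min\rho) / (\max\rho - \min\rho) \in [0,1]$.
Rank correlation is what makes the score portable across platforms: it is
invariant to any per-cell strictly monotone transform, so raw counts,
log-normalized counts and antibody intensities all give the same $\rho$ as
long as within-cell orderings agree.

## Why the training matrix is not centered within itself

A natural preprocessing impulse is to mean-center each gene across the
training samples before the fit. For a one-class model this is
self-defeating: if every gene has mean zero over the $n$ training samples
then $\sum_i \langle w, x_i \rangle = 0$ for *every* $w$, and by Jensen's
inequality on the strictly convex logistic loss
$\frac1n \sum_i \log(1+e^{-s_i}) \ge \log 2$ with equality only when all
margins are zero. Adding the ridge, the unique global minimizer of $L$ is
exactly $w = 0$ — the solver converges at its starting point and the model
carries no information. `fit_oclr()` therefore takes the training profiles
as they are (log scale, uncentered), which is also what makes the weights
interpretable as a shrunken stem expression profile. `center_genes()` is
still exported for two legitimate uses: centering against an *external*
baseline (a reference cohort that is not the training set), and
constructing the degenerate identical-sample input whose fit must collapse
to zero — a useful solver check.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `lambda` | `fit_oclr()` | 1.0 | Ridge strength. The fitted weights scale roughly as $1/\lambda$; since scoring is rank-based, the index is insensitive to `lambda` over orders of magnitude. It is recorded in the model file header so any score is reproducible from the file. |
| `tol` | `fit_oclr()` | 1e-8 | Sup-norm of the gradient at convergence. |
| `min_overlap` | `match_genes()`, `refit_on_panel()` | 10 | Smallest model/matrix gene intersection worth scoring; a rank correlation over fewer features is dominated by noise. |
| QC thresholds | `qc_thresholds()` | 200 < features < 5000, mito < 10%, counts > 200 | The standard human single-cell bounds. All four inequalities are strict, so boundary cells are removed. |
| `scale_factor` | `log_normalize()` | 10,000 | Per-cell library-size target of `ln(1 + v * sf / T)`. |
| `fc_floor`, `alpha` | `wilcoxon_deg()` | 0.5, 0.05 | Absolute log2 fold-change floor and Bonferroni-adjusted p cutoff for calling a differential gene. |

Mitochondrial genes are identified by symbol prefix (`MT-` for human);
configurable because the convention differs across organisms. Gene matching
is case-insensitive everywhere, since antibody panels print mixed-case
marker names (`PanCK`) while RNA references use uppercase symbols.

## Restricted panels

Targeted in-situ or antibody platforms measure tens to hundreds of
features, not the transcriptome. `refit_on_panel()` restricts the training
matrix to the panel ∩ training-gene intersection and refits, so the
weights are optimized for exactly the features the platform measures;
refitting was chosen over simply subsetting the full weight vector because
the two are not equivalent under the ridge penalty, and refitting is the
defensible choice when the panel is small. The panel model is then scored
with the same engine (`score_cells()` on the matched features).

## Downstream procedures

* **Stratification.** The `k = round\_half\_up(0.25N)` highest- and
  lowest-index cells form equal-sized top/bottom strata (half-up rounding,
  not banker's rounding, reproduces cohort counts such as 45,079 from
  180,315). Boundary ties are broken lexicographically by cell id so the
  strata are reproducible under permutation.
* **Differential expression.** Per gene, a two-sided Wilcoxon rank-sum
  test between the strata: exact enumeration of all
  $\binom{n_1+n_2}{n_1}$ rank-sum values when both groups have ≤ 7 cells
  (this handles ties correctly, which the textbook exact distribution does
  not), otherwise a normal approximation with tie correction and
  continuity correction; the two paths agree within 0.01 in p at group
  sizes 8–12. Bonferroni correction multiplies by the number of genes
  actually tested. Effect sizes use the single-cell marker-test
  convention: `log2_fc = log2((mean(expm1(top))+1)/(mean(expm1(bottom))+1))`
  and the difference in percent of cells expressing the gene, so the usual
  cutoffs transfer.
* **Cluster annotation.** Each cluster × candidate label score is the mean,
  over the label's markers present in the matrix, of the z-score of the
  cluster's mean expression across clusters; the argmax labels the
  cluster, ties broken alphabetically with a warning.
* **Bootstrap stability.** Subsets of growing size are drawn without
  replacement (the growing-subset design makes the full-cohort endpoint an
  exact reference: at size $N$ every draw is the whole cohort and the
  median matches exactly); a `replace = TRUE` flag covers the classical
  bootstrap reading.

## The synthetic cohort generator

Real cohorts need downloads and trained reference weights, so validation
runs on synthetic data with known ground truth. `gen_signatures()` draws a
shared positive baseline per gene and marks a disjoint 20% of genes as
4-fold up in the stem signature and 20% as 4-fold up in the differentiated
signature. Each cell of `gen_cohort()` has a stem fraction
$\alpha_i \in [0,1]$ (uniform by default), an expected profile
proportional to $\alpha_i \cdot \text{stem} + (1-\alpha_i) \cdot
\text{diff}$ normalized to sum 1, and Poisson counts at an expected
library size of 5,000. Training profiles are `log1p(stem signature)` plus
Gaussian noise (sd 0.2), mimicking replicate bulk references. The spatial
variant places cells on a uniform grid over the unit square with a
stem-rich disc, so disc membership is deterministic. Defaults (500 genes,
1,000 cells, 30 training profiles) are large enough for stable rank
correlations yet keep the full validation pipeline to seconds.

Poisson noise (no overdispersion), a single 4-fold effect size and
library sizes without dropout are deliberate simplifications: they are
sufficient for testing a rank-based score, but passing on this generator
does not demonstrate robustness to the overdispersion, batch structure,
ambient contamination or segmentation artifacts of real data. With these
defaults the pipeline recovers the planted fraction with
$\mathrm{Spearman}(\alpha, \mathrm{SI}) > 0.99$, and about 0.89 when
scoring is restricted to a 28-gene panel refit.

```{r recovery}
p <- sim_params(G = 200, n_cells = 300, seed = 1)
cohort <- gen_cohort(p)
model <- fit_oclr(gen_training_matrix(p))
idx <- minmax_scale(score_cells(cohort$matrix, model))$stemness_index
cor(cohort$alpha, idx, method = "spearman")
```

## Numerical choices and degenerate inputs

* The fit uses a damped Newton iteration with backtracking line search;
  when genes far outnumber samples the Newton system is solved in the
  $n$-dimensional sample space via the Woodbury identity, so a
  transcriptome-wide fit costs no more than its sample count dictates.
  Convergence is declared at gradient sup-norm ≤ `tol`; non-convergence is
  an error, never a silent partial result.
* Spearman ties receive average ranks. A cell with zero rank variance over
  the matched genes (e.g. expressing none of them) scores $\rho = 0$ with
  a warning rather than NaN, so cohort-level stratification never crashes.
* A cohort whose correlations are all equal min-max scales to 0.5
  everywhere, with a warning.
* Cells with zero total counts survive `log_normalize()` as all-zero
  profiles; QC normally removes them first.
* Min-max scaling is cohort-wide in a single run. Scaling is a cohort-level
  operation by construction: indices from different runs are comparable
  only through the underlying $\rho$, not the index.

## Known limitations

* The index is relative within a scored cohort (min-max over the run), so
  a "0.7" in one dataset is not a "0.7" in another; cross-dataset
  statements should compare distributions of $\rho$ or score the pooled
  cohort.
* Weights trained on RNA references applied to antibody intensity panels
  assume the protein panel's rank structure tracks transcript ranks; the
  panel refit mitigates but does not remove this.
* No batch correction is attempted; the score is computed per cell and is
  rank-invariant to per-cell monotone effects, but not to gene-specific
  batch effects.
* The DEG universe is all genes in the supplied matrix; expression-fraction
  pre-filters common in single-cell toolkits are not applied by default.

## Problem sizes used in the test suite

Unit and property tests run on cohorts of 80–500 genes and 50–1,000 cells;
the end-to-end recovery checks use the generator defaults (500 genes,
1,000 cells, 30 training profiles, five seeds) and complete in seconds.
The two published cohort sizes (80,682 and 180,315 cells) are exercised at
full size in the stratification checks, which are O(N log N).
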