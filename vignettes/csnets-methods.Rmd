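---
title: "Methods: cell-line-specific regulatory networks via a pairwise MRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-line-specific regulatory networks via a pairwise MRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csnets)
```

## The problem and the model

Chromatin-accessibility footprinting (e.g. PIQ on DNase-seq) yields, per
cell line, predicted transcription-factor binding sites with a binding
probability. Mapping those sites into promoter windows (TSS ± 2 kb) gives a
*preliminary* TF→gene network per cell line: per (TF, gene, cell line) we
keep the maximum probability over the sites falling in any of the gene's
promoter windows. These networks are noisy and treat each cell line in
isolation, although similar cell lines share most of their regulatory
program.

`csnets` therefore refines each regulatory relationship jointly across cell
lines. For one TF *A* and one gene *B*, let \(x_i \in \{0,1\}\) indicate
whether *A* regulates *B* in cell line *i*. The field over
\(X = (x_1,\dots,x_n)\) has

* a **node potential**
  \(\phi_i(x_i) = P_{1,i}/P_{0,i}\) if \(P_{1,i} > P_{0,i}\) and \(x_i=1\);
  \(P_{0,i}/P_{1,i}\) if \(P_{0,i} > P_{1,i}\) and \(x_i=0\); and 1
  otherwise, where \(P_{1,i}\) is the observed binding probability and
  \(P_{0,i} = 1 - P_{1,i}\);
* an **edge potential** \(\psi_{ij}(x_i,x_j) = e^{w_{ij}}\) when
  \(x_i = x_j\) and 1 otherwise, on the pairs \((i,j)\) with coupling
  weight \(w_{ij} = (\mathrm{CSI}_{ij} + \mathrm{TNI}_{ij})/2 > c\).

The joint distribution is \(\Pr(X) \propto \prod_i \phi_i \prod_{(i,j)}
\psi_{ij}\); its negative log is the pseudo-energy
\(E(X) = -\gamma - \sum_i \ln\phi_i(x_i) - \sum_{(i,j)} \ln\psi_{ij}(x_i,x_j)\).
We fix \(\gamma = 0\): a constant offset cannot change the minimiser or the
marginals. The partition function is never formed outside the enumeration
oracle; belief propagation works with normalised messages.

### Coupling weights

**CSI** (cell-line similarity index): genes × cell-lines expression is
restricted to a differentially expressed gene list (supplied by the user;
without one, the 592 most variable genes, preserving the customary list
length), each gene row is z-scored with the population standard deviation,
and the matrix is decomposed as \(USV^T\). Cell line *j* is represented by
its coordinates \((s_1 v_{1j}, \dots, s_k v_{kj})\) in the leading
\(k = 16\) singular dimensions and CSI is the Pearson correlation of two
such coordinate vectors. Two choices deserve comment:

* Only \(V\) carries per-cell-line coordinates (the left singular vectors
  live in gene space), so "leading dimensions" are taken as singular-value-
  scaled rows of \(V\); scaling weights dimensions by explained variance.
  An unscaled variant is available (`scale_dims = FALSE`).
* Singular vectors are defined only up to sign, and the Pearson correlation
  of coordinate vectors is *not* invariant to per-dimension sign flips. We
  canonicalise each column of \(V\) so its largest-magnitude entry is
  positive, which makes the CSI deterministic and invariant to gene order
  and to orthogonal rotations of gene space (verified in the test suite).

A correlation over \(k = 16\) points is a high-variance estimate; `n_dims`
is exposed and capped at the matrix rank (a z-scored matrix over \(n\) cell
lines has rank at most \(n-1\), which is why small simulated designs use
fewer dimensions).

**TNI** (TF non-specificity index): the proportion of common targets of
the TF between two cell lines' preliminary networks, read as the Jaccard
index \(|T_i \cap T_j| / |T_i \cup T_j|\) (two empty sets give 0). The
wording "proportion of common targets" admits other denominators; a
min-denominator variant sits behind `denominator = "min"`.

Cell lines *i, j* are coupled iff \(w_{ij} > c\) with default \(c = 0.5\).
Any \(c \ge 0\) keeps every pairwise log-potential submodular
(\(\beta(1,1) + \beta(0,0) = 2w_{ij} \ge 0 = \beta(1,0) + \beta(0,1)\)),
which is what makes exact MAP inference by min-cut applicable.

## Inference

Three routines operate on the same instance:

* `map_by_mincut()` — exact global MAP. The pairwise term
  \(-w_{ij}[x_i = x_j]\) equals the Ising cut cost
  \(w_{ij}[x_i \ne x_j]\) up to a constant, so the energy minimiser is the
  minimum s–t cut of a graph with terminal capacities
  \(\max(0, \mp(\ln\phi_i(1) - \ln\phi_i(0)))\) and pairwise capacities
  \(w_{ij}\). We implement the textbook reduction and verify it against an
  exhaustive-enumeration oracle on hundreds of seeded random instances
  rather than reverse-engineering any particular prose description of the
  construction.
* `icm_refine()` — iterated conditional modes, a greedy single-site
  descent; useful as a cheap local refiner and kept because the field's
  description of the optimisation mixes ICM with the max-flow reduction.
  We expose both and do not guess which variant produced any published
  network.
* `lbp_marginals()` — synchronous (flooding) sum-product loopy belief
  propagation with linear damping 0.5, message normalisation at every
  update, and convergence declared when the largest message change drops
  below `tol` (default 1e-6; the acceptance checks run it tighter). On
  trees the fixed point is exact; on loopy graphs beliefs are approximate
  but stay in [0, 1] and non-convergence is reported, not hidden.

Binding probabilities are clamped to \([\varepsilon, 1-\varepsilon]\),
\(\varepsilon = 10^{-6}\), before any ratio, so all potentials are finite.
A TF–gene pair absent from a cell line's preliminary network enters the
field with \(P_{1,i} = \varepsilon\): "not observed" rather than
"impossible", which lets strong evidence in coupled cell lines resurrect an
edge. The alternative — restricting the field to cell lines where the pair
was observed — is available via `observed_only = TRUE`.

`refine_networks()` runs one field per TF–gene pair over all cell lines
(all pairs of one TF share a coupling graph, so the LBP pass is vectorised
across genes). Refined probability is the belief \(\Pr(x_i = 1)\) under
LBP, or the 0/1 MAP label under `mincut`/`icm`; a final edge is called when
the refined probability exceeds `call_threshold = 0.5` (how marginals
become edge calls is a package decision; nothing in the model fixes it).
Degenerate tie cases (\(P_{1,i} = 0.5\)) leave \(\phi_i \equiv 1\) and the
node is decided by its couplings; message argmax ties resolve toward
\(x = 0\), and ICM keeps the current label on exact ties.

## Evaluation protocol

For a TF and cell line with a ChIP experiment: peaks are mapped into the
same promoter windows; candidate genes score the maximum overlapping peak
score. *M* is the median of three sizes — candidates, refined-network
targets, preliminary-network targets — and the gold standard is the top-M
candidates by score, ties at the boundary broken by gene id. AUC uses the
Wilcoxon midrank statistic with the gold standard as positives and all
remaining promoter-bearing genes as negatives (unscored genes get 0).
Overlap counts shared genes after truncating the network's targets to its
top M. Improvements are summarised as relative changes
\((\text{new}-\text{old})/\text{old}\) (undefined at old = 0; such records
are flagged and excluded), optionally aggregated to TF level by averaging
over cell lines, and tested with the one-sided exact binomial tail
\(\Pr(X \ge k)\) at \(p_0 = 0.5\).

Downstream utilities follow field defaults where the procedure was left
open: "FDR ≤ 0.2" uses Benjamini–Hochberg; "positive" enrichment restricts
terms to those annotated to the TF in a user-supplied map; tissue
clustering uses distance \(1 - \text{Jaccard}\) and expression clustering
\(1 - \text{CSI}\), both with average linkage (UPGMA); the rank-set
enrichment statistic is a weighted Kolmogorov–Smirnov running sum (weight =
|score|) whose p-value comes from seeded membership permutations with the
add-one correction. Tied scores are processed as blocks, so the statistic
does not depend on arbitrary order within ties and a constant score vector
gives exactly 0.

## The synthetic generator

`simulate_truth()` / `emit_observations()` produce every pipeline input
with known ground truth: cell lines split contiguously into tissues; true
networks = a shared core (10% of genes per TF) ∪ tissue-specific targets
(10%) ∪ small private sets (2%); expression = per-tissue gene programs
N(0,1) plus N(0, 0.3) noise, so within-tissue CSI exceeds between-tissue
CSI in expectation; binding probabilities Beta(0.8a, 0.2a) on true edges
and Beta(0.2a, 0.8a) on sampled false candidates. The default
concentration a = 2 is deliberately *moderate* noise: the two distributions
overlap substantially, preliminary AUC stays clearly below 1, and
refinement has headroom — a large concentration collapses both
distributions onto 0.8/0.2 and every method saturates. Peaks are placed in
the promoters of true targets with Beta-distributed scores.

`null_binding = TRUE` removes the binding signal entirely: sites are placed
on uniformly random candidate sets of the same size with probabilities from
one Beta(0.5a, 0.5a). Randomising only the probabilities would not be a
null — *which* sites exist is itself informative, and refinement still
improves markedly under such a partial null.

`recovery_experiment()` runs the full pipeline per replicate and evaluates
both networks against peak-derived gold standards. The test suite and the
acceptance script use 10 cell lines in 2 tissues, 5 TFs, 300 genes and 20
replicates — sizes at which every stage, including the exhaustive oracles,
runs comfortably on a laptop. Under the signal condition the fraction of
(TF, cell line) evaluations where the refined AUC beats the preliminary
AUC is close to 1; under pure-noise binding the mean AUC change is ~0 and the
*fraction* improved fluctuates around 0.5 (roughly 0.48–0.60 across
seeds), often landing slightly above it: refinement produces many tiny
positive tie-breaking gains and fewer, larger losses, so the median change
can be marginally positive even when the mean is zero. This mild skew is a
property of the rank-based evaluation, not evidence of signal recovery.

What the generator does **not** emulate: realistic genome geography (genes
sit 10 kb apart on one chromosome, one site per candidate pair), motif
content, read-level noise, correlated false positives between similar cell
lines, or expression–network coupling (expression blocks and network
blocks share the tissue partition but are otherwise independent). Passing
the recovery checks therefore demonstrates that the machinery behaves as
designed under its own assumptions, not that those assumptions hold in any
particular dataset.

## Numerical and design notes

* Coordinates are 0-based half-open everywhere inside the package; GTF
  (1-based inclusive) is converted on read. Overlap requires ≥ 1 bp.
* No missing-value imputation anywhere; malformed cells are errors with
  coordinates.
* Multiple binding sites per promoter take the maximum probability
  (probability of at least one binding event is dominated by the strongest
  site and stays in [0, 1]); multiple transcript TSSs contribute the union
  of their windows.
* Enumeration MAP ties break toward the lexicographically smallest
  labeling; min-cut may return any energy-equivalent labeling, so
  equivalence is asserted on energies.
* All randomised components (generators, permutation tests) take explicit
  seeds and restore the RNG state; inference itself is deterministic, and
  identical seeds give byte-identical outputs end-to-end.

## Limitations

* LBP on densely coupled cell-line sets (near-cliques) is approximate;
  beliefs can deviate a few percent from exact marginals. The min-cut MAP
  is exact but returns hard labels.
* The CSI treats similarity as global per cell-line pair; the model
  formulation would also admit a regulation-specific similarity, which is
  out of scope here.
* With very few cell lines the coupling graph is small and refinement
  approaches per-cell-line thresholding.
* The binomial summary assumes independent evaluations; ChIP experiments
  sharing a TF are correlated, which the TF-level aggregation mitigates
  but does not remove.
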