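---
title: "Codon models and selection tests in codonsel: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon models and selection tests in codonsel: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Repeated evolutionary loss of a costly trait — here, flight in insects — sets
up a natural experiment: if flight maintains strong purifying selection on
particular genes (locomotory machinery, energy metabolism), lineages that
abandoned flight should show a measurable shift in the molecular selection
regime of those genes. `codonsel` implements the two codon-model hypothesis
tests used to look for such shifts, the cross-lineage inference logic that
turns per-gene test results into candidate gene lists, and the
over-representation statistics used to summarise candidate lists
functionally. A seeded simulation module generates codon alignments,
flight-loss study designs and annotation tables with known ground truth, so
every stage of the pipeline can be exercised and calibrated without any
external data.

## The codon substitution model

All likelihoods are computed under a Goldman–Yang (GY94) codon model over the
sense codons of the active genetic code (61 for the standard nuclear code, 62
for the invertebrate mitochondrial code; both are supported because nuclear
and mitochondrial gene sets are analysed with different codes). The
instantaneous rate from codon $i$ to codon $j$ is

$$
q_{ij} \propto \pi_j \cdot \kappa^{\mathbb{1}[\text{transition}]} \cdot
\omega^{\mathbb{1}[\text{nonsynonymous}]}
$$

for single-nucleotide changes and $0$ otherwise, where $\pi$ are stationary
codon frequencies, $\kappa$ the transition/transversion rate ratio and
$\omega = dN/dS$ the nonsynonymous/synonymous rate ratio. The matrix is
normalised to one expected substitution per codon per unit branch length.
Frequencies come from the data under `F3x4` (position-specific nucleotide
frequencies, the default and the customary codeml-style choice), `F1x4`, or
`equal`; unobserved codons receive a small floor (`1e-8` before
renormalisation) so the reversible decomposition stays well-defined.

Transition probabilities are obtained by eigendecomposition of the
symmetrised generator $D_\pi^{1/2} Q D_\pi^{-1/2}$. Because that matrix is
exactly symmetric for every admissible parameter value, the decomposition is
unconditionally stable and no scaling-and-squaring fallback is needed; tiny
negative round-off entries are clamped and rows renormalised.

## The two selection tests

**Branch-site test of episodic positive selection.** The alternative (model
A) has four site classes: conserved everywhere ($\omega_0 \le 1$), neutral
everywhere ($\omega = 1$), and two classes that switch to $\omega_2 \ge 1$ on
designated foreground branches while being conserved or neutral elsewhere.
The class proportions factor as an outer product of two Bernoulli
proportions, which the fitter exploits: the mixture weights are profiled out
by a closed-form EM inner loop, leaving only $(\kappa, \omega_0, \omega_2)$
to the quasi-Newton outer optimiser. The null (A1) fixes $\omega_2 = 1$. The
test statistic $2\Delta\ell$ is referred to $\chi^2_1$ by default — the
conservative convention at the $\omega_2 = 1$ boundary — with the 50:50
point-mass/$\chi^2_1$ mixture available behind a flag; practice varies in
the field, and the package defaults to $\chi^2_1$ precisely because it is
conservative. A gene is *called*
positively selected only when the test is significant **and** the fitted
$\omega_2$ exceeds 1 with a nonzero selected-site fraction.

**Rate normalisation across site classes.** In a mixture model the relative
evolutionary *rate* of the site classes matters, not just their substitution
composition. All four class generators share the normalisation of the
conserved-class ($\omega_0$) process, so neutral and selected sites evolve
proportionally faster than conserved ones — a selected site accumulates more
substitutions on the foreground branch, which is the signal the test is
built to see. Normalising each class separately would leave only a
compositional signal and drains essentially all power at realistic branch
lengths (we verified this directly during development). Branch lengths are
therefore measured in expected substitutions per codon *for a conserved
site*; since the same convention is used for simulation and for both nested
models, likelihood-ratio tests and parameter recovery are unaffected by the
choice of reference.

**Pooled-branch rate test of relaxed selection.** Branches carry small
integer classes (0 background, 1 flightless, 2 flying). The 3-rate model
fits one $\omega$ per class; the nested 2-rate model shares one $\omega$
across the two focal classes. Their likelihood-ratio statistic is referred
to $\chi^2_1$ (no boundary issue here, as the pooled parameter is interior).
The *relaxed selection* reading — significantly higher $\omega$ in the
flightless class with both focal estimates inside $(0,1)$ — is recorded as a
classification field on the result, not as a different statistic: weakened
purifying selection raises $\omega$ toward 1 across the whole gene, in
contrast to episodic positive selection which pushes a few sites beyond it.

Across genes, raw p-values are adjusted by the Benjamini–Hochberg step-up
procedure with a family-wise level of 0.05, one family per gene set and
test.

## Fitting: parameterisation, bounds, restarts

Optimisation is bounded `L-BFGS-B` on log-transformed parameters:
$\omega \in [10^{-4}, 999]$, $\kappa \in [0.01, 100]$, $\omega_0 \in
(10^{-4}, 1]$, $\omega_2 \in [1, 999]$, and the branch-length scale in
$[0.01, 100]$. Default starting values are $\kappa = 2$, $\omega = 0.2$,
$\omega_2 = 2.5$; `n_restarts` adds log-normal jitter (sd 0.75) around them,
deterministically given `seed`. Alternative models are additionally
warm-started from their null's optimum, which enforces the nesting
inequality $\ell_1 \ge \ell_0$ up to optimiser slack; likelihood-ratio
statistics are clamped at zero.

**Branch lengths** are either taken as given (`"fixed"`) or rescaled by a
single free factor (`"scale"`). The selection tests estimate that factor
once under the one-ratio M0 model and then hold the lengths fixed for both
nested fits, so the compared models always share one branch-length
treatment. Full per-branch re-estimation is deliberately not offered: at
desk scale it destabilises the nested comparisons without changing the test
statistics appreciably, and a single proportional factor captures the
rate-calibration error that matters. Simulation studies whose trees carry
the generating lengths can skip the scale step (`estimate_scale = FALSE`).

**Missing data.** Any codon containing a gap or ambiguity letter is treated
as fully missing (a partial-likelihood vector of ones) — standard practice
that avoids enumerating ambiguity expansions. How the original analyses
configured gap handling is unknown, so this is a documented choice, not a
reproduction. Unambiguous stop codons anywhere in a sequence are an error at
construction time, naming the taxon and codon site.

## Comparative design logic

Three small, exactly-testable operations turn per-gene results into
candidate sets:

* `unique_focal_candidates()`: genes significant on a focal stem branch but
  on neither the upstream nor downstream control branch (set subtraction).
* `tally_candidates()`: per gene, the count of flightless panels in which it
  was significant minus its count over related flying panels (floored at
  zero), keeping genes with net count at or above a threshold (default 3
  lineages). Genes absent from a panel's universe simply contribute no
  count; a `panels_tested` denominator can be attached for transparency.
* `direction_sign_test()`: a two-sided exact binomial test at $p = 1/2$ on
  direction-of-effect calls, with the two-sided p-value computed by doubling
  the smaller (inclusive) tail and capping at 1. This convention gives the
  canonical 12-of-14 $\rightarrow$ 0.013 exactly; note that for 11-of-13
  every standard two-sided convention (doubling, minimum-likelihood,
  central) agrees at 0.0225, so reports of 0.023 for such a split reflect a
  rounding or convention difference we could not reconstruct.

## Over-representation statistics

For a category with $K$ members among $N$ background genes and $O$ observed
among $n$ candidates: expected count $E = Kn/N$, fold enrichment $FE = O/E$
with $E$ *unrounded* (using the displayed one-decimal $E$ would distort
small categories: $3/0.36 = 8.4$-fold, not $3/0.4 = 7.5$), one-tailed
Fisher tests as inclusive hypergeometric tails, a binomial analogue
$P(X \ge O)$, $X \sim \mathrm{Bin}(n, K/N)$, and an EASE-style conservative
score that removes one observed candidate ($P(X \ge O - 1)$; a singleton hit
scores 1 by construction). Display columns round half-away-from-zero to one
decimal, falling back to one significant digit below 0.1. Raw p-values only:
candidate lists already come out of an FDR-controlled testing stage, so no
second correction is layered on. Published DAVID p-values are treated as
approximate cross-checks only, since DAVID's exact margin adjustment for the
decremented cell is not fully specified; the documented convention here
keeps the margins of the original table. Grouped "terms of interest" (wing
development; mitochondrion/ATP/respiratory chain) are ordinary Fisher tests
on user-defined category unions — no separate statistic.

## The simulators and what they do (and do not) emulate

`simulate_codon_alignment()` draws root codons from $\pi$ and propagates
them along the tree with the *same* transition matrices the likelihood uses
(site-wise transition sampling, not event simulation), which closes the
generative/inferential loop exactly. Branch-site site classes are drawn once
per site and keep their identity across the tree, matching the mixture's
semantics. `make_flight_scenario()` builds coalescent-shaped panels (default
14 taxa, the smallest panel of the emulated design; 11 flightless and 9
flying panels) with exactly one focal branch each.
`simulate_flight_study()` writes a complete study to disk — pooled
comparison tree with 11 flightless, 9 flying and 6 background terminal
branches, 50 genes of 500 codons, 5 of them "relaxed" — through the same
file formats the readers consume. Default rates are $\kappa = 2$, background
$\omega = 0.05$, flying $\omega = 0.02$ and relaxed-flightless
$\omega = 0.1$ — the order of magnitude typical of purifying selection on
insect protein-coding genes, where flying-lineage ratios around 0.02 rise
modestly (toward 0.03–0.1) after flight loss without approaching
neutrality. Branch lengths are drawn uniformly on $[0.02, 0.3]$ expected
substitutions per codon, typical of within-order codon divergences.

What the simulators deliberately do **not** model: insertions/deletions,
alignment error, codon-usage heterogeneity across genes, among-site rate
variation beyond the branch-site classes, and non-monophyletic trait
mapping. Passing tests therefore demonstrate correctness and calibration of
the *inference machinery* under the model's own assumptions — not robustness
to the many ways real transcriptome data violate them.

## Numerical choices

* Pattern compression: identical site columns are collapsed with weights
  before pruning; per-node rescaling guards against underflow.
* The EM inner loop for branch-site mixture weights runs to a $10^{-9}$
  log-likelihood increment (max 200 iterations) and is exact because the
  four class weights factor over two independent binary latents.
* Optimiser tolerance `factr = 1e8` (about $10^{-8}$ relative), chosen so
  likelihood-ratio statistics are stable to well below the 0.01 scale that
  matters for p-values.
* Ties in enrichment ranking break by larger fold enrichment, then category
  name, for reproducible output ordering.
* Degenerate inputs: zero-length branches, single-class trees, empty
  candidate sets and header-only tables are all defined rather than errors.

## Problem sizes used by the test suite

The replicated-simulation checks run at sizes chosen to make their
statistical targets sharp while staying desk-scale: ordering recovery uses
100 seeded 1000-codon genes on the 26-taxon pooled tree; null calibration
uses 200 replicates of 300-codon genes on an 8-taxon comparison tree (rate
test) and 200 replicates of 150-codon genes on a 6-taxon panel (branch-site
test); the end-to-end study runs the full 50-gene default scenario under
three independent seeds. The brute-force oracle is exercised on 100 random
instances with at most 4 leaves and 3 sites, where exhaustive enumeration
over $61^{3}$ internal-state assignments is exact and fast.

## Known limitations

* Per-branch branch-length optimisation is not implemented (single scale
  factor only), so absolute branch-length estimates inherit the input
  tree's relative proportions.
* Bayes empirical Bayes identification of *which* sites are selected is out
  of scope; detection is gene-level.
* The EASE convention here fixes the original margins; DAVID's published
  values may differ slightly.
* Codon frequency model misspecification (e.g. strong codon-usage bias) is
  untested territory for the calibration results above.
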