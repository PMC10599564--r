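---
title: "Sparse maximum-entropy models of 5' splice-site ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse maximum-entropy models of 5' splice-site ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A donor (5' splice) site is represented as a 9-mer over {A,C,G,T}: the last
three exonic positions (labelled -3, -2, -1) followed by the first six
intronic positions (+1..+6), the region that base-pairs with the U1 snRNA
during early spliceosome assembly.  Given an ensemble of donor sequences
from one species, `splicepotts` fits the least-structured probability
distribution consistent with the observed one-site frequencies $f_i(s)$ and
two-site frequencies $f_{ij}(s,t)$: a Potts model

$$\hat P(S) = \frac{1}{Z}\, e^{-E(S)}, \qquad
  E(S) = -\sum_{i} h_i(s_i) - \sum_{i<j} J_{ij}(s_i, s_j),$$

with 36 field parameters $h_i(s)$ (9 sites $\times$ 4 letters) and 576
couplings $J_{ij}(s,t)$ (36 site pairs $\times$ 16 letter pairs).  $E$ acts
as a data-driven energy: low-energy sequences are the frequent donors,
high-energy ones the rare or un-donor-like 9-mers.  The state space has
$4^9 = 262\,144$ sequences, small enough that $Z$, all model marginals
$P_i, P_{ij}$, gradients, and exact i.i.d. samples are computed by **full
enumeration** (in compiled code); no MCMC or mean-field approximation is
used anywhere.

## Estimation

`estimate_marginals()` counts letters and letter pairs.  A pseudocount
$\alpha$ (default 1 for fitting inputs, 0 for reporting) is applied as
$\alpha$ per one-site cell and $\alpha/4$ per two-site cell, so both tables
share the denominator $N + 4\alpha$ and the pair tables marginalize exactly
to the one-site table at any $\alpha$.  The pseudocounted moments are a
convex mixture of the empirical distribution with the uniform one, hence
always an interior point of the moment polytope: the maximum-likelihood fit
exists and matches them exactly at $\gamma = 0$.

`fit_maxent()` minimizes the per-sequence negative log-likelihood plus an
L1 penalty on the couplings only,

$$\mathrm{NLL}(h, J) + \gamma \sum_{ij,st} |J_{ij}(s,t)|,$$

by monotone accelerated proximal gradient (FISTA with backtracking line
search; whenever the accelerated candidate would raise the objective the
step falls back to plain ISTA and the momentum restarts, so the objective
is non-increasing across accepted steps).  Gradients are exact,
$\partial \mathrm{NLL}/\partial h = P_i - f_i$ and
$\partial \mathrm{NLL}/\partial J = P_{ij} - f_{ij}$, and soft-thresholding
leaves shrunk couplings at exactly zero — the sparse support *is* the
result of interest.  Convergence requires a relative objective change below
`tol` ($10^{-9}$), a KKT violation on J below `kkt_tol` ($10^{-5}$), and
$\max |P_i - f_i| <$ `kkt_tol`; non-convergence returns the model with a
warning and `fit_metadata$converged = FALSE` rather than an error.

**Gauge.** The Potts parametrization is redundant; after convergence the
fields are shifted to the zero-sum gauge ($\sum_s h_i(s) = 0$ per
position), which changes every energy by the same constant and no
probability.  Absolute energies are therefore comparable only within one
model; energy *differences* and orderings are the meaningful quantities.

**Choosing $\gamma$.**  $\gamma$ is the per-parameter penalty on the
per-sequence log-likelihood scale.  A planted coupling $J$ between letters
of frequency $p$ and $q$ perturbs its pair marginal by roughly
$J\,p(1-p)\,q(1-q)$, so it survives shrinkage only when that footprint
clearly exceeds $\gamma$.  Consensus-letter couplings of magnitude 0.5–0.8
survive $\gamma = 0.025$; couplings between rare letters (frequencies near
0.08) need $\gamma \lesssim 0.002$.  This is why the parameter-recovery
checks fit at $\gamma = 0.002$ while the species-panel analyses use the
sparser $\gamma = 0.025$ regime, and it is the quantitative reason sparse
models keep only the strongest interaction patterns.

## Energetics and null ensembles

`score_ensemble()` evaluates $E$ over an ensemble; `sample_random_sequences()`
draws the fully disordered uniform null; `sample_decoys()` samples genomic
GT dinucleotide loci (both strands, with replacement), keeps the 9-mer with
3 nt upstream and 4 nt downstream of the GT, reduces to unique sequences,
and splits them into decoy-A (sequence never occurs among annotated donors)
and decoy-B (sequence matches at least one annotated donor) — a sequence-
identity classification, not a locus classification.  `rank_sum_compare()`
is the two-sided Mann–Whitney test (normal approximation with tie
correction, via `stats::wilcox.test`).  `minimum_energy_sequence()` is an
exhaustive argmin with lexicographic tie-breaking; on consensus-dominated
ensembles it returns the U1-complementary `CAGGTAAGT`.

## Coupling patterns

`classify_site_bases()` labels each of the 36 site-base combinations as
exonic/intronic $\times$ consensus/non-consensus (consensus = per-position
argmax of $f_i$, ties resolved alphabetically with a warning).
`group_mean_couplings()` averages $J$ over all cells of each category pair
(10 pairs: EC-EC, EC-EN, ..., IN-IN).  Structural zeros are included in the
mean by default — the sparse model's zeros are statements, not missing
data — with a `nonzero_only` flag for the alternative convention.  Cell
counts are fixed by combinatorics (e.g. EC-EC has $\binom{3}{2} = 3$ cells)
and asserted in the tests.

## Phylogenetic signal

`sankoff_parsimony()` is the tips-to-root dynamic program for a binary
character under an arbitrary 2x2 cost matrix (unit costs by default),
handling polytomies.  `maddison_slatkin()` permutes the tip states
uniformly while preserving the present/absent counts, recomputes the
parsimony score each time, and reports

$$p = \frac{1 + \#\{\text{null} \le \text{observed}\}}{1 + n_{\mathrm{perm}}}.$$

Two deliberate choices here.  First, the *direction*: few observed steps
relative to the null means the trait is phylogenetically clustered, so the
lower tail is counted.  Second, ties at the observed score are counted and
one pseudo-permutation is added (the standard Monte-Carlo validity
correction), which makes the p-value conservative.  Because parsimony
scores on a 30-leaf tree take only a handful of integer values, this
conservativeness is substantial: under random traits the empirical
$P(p \le 0.05)$ is near 0.02 rather than 0.05.  The test is valid
($P(p \le \alpha) \le \alpha + 1/(n_{\mathrm{perm}}+1)$, property-tested)
but not tightly calibrated — an inherent feature of permutation tests on
heavily tied discrete statistics, worth remembering when reading its
p-values.  `bonferroni_adjust()` multiplies by the number of couplings
tested, capped at 1.

## Dendrogram comparison

Species are embedded as the 576-vector of model two-site probabilities
$P_{ij}$ (model-derived by default, empirical $f_{ij}$ by option), compared
by Euclidean distance, and clustered by complete linkage
(`stats::hclust`).  Comparisons with a reference tree use:

- **cophenetic correlation** — Pearson on the full cophenetic matrices
  (merge heights vs patristic distances; Pearson is insensitive to the
  scale mismatch up to linearity);
- **Fowlkes–Mallows $B_k$** — both trees cut into $k$ clusters,
  $B_k = T_k/\sqrt{P_k Q_k}$, significance by relabelling one side
  (`n_perm` permutations, upper-tail count with the same +1 smoothing);
  shuffling one side is the same exchangeable null as shuffling both;
- **entanglement** — after an alternating two-sided untangling pass (each
  side's nodes rotated so its leaves sort by the other side's current
  ranks, via `stats::reorder.dendrogram`), the normalized
  $\sum |r_a - r_b|^{L}$ with $L = 1.5$, the common tanglegram convention;
  0 is perfectly aligned.

Non-ultrametric reference phylogenies cannot be cut as dendrograms
directly; they are rendered as complete-linkage trees of their patristic
distances (exact for ultrametric input).

## The synthetic generator

`make_random_potts()` plants sparse ground truth (fields
$\mathcal N(0, 0.5^2)$, couplings $\pm 0.5$ by default);
`make_planted_genome()` builds two-exon genes whose exon-intron junctions
spell prescribed 9-mers, about half on the minus strand, introns closed
with AG, no ambiguous bases; `make_species_panel()` emulates a panel of
related species in three lineages: a shared consensus-favoring field
template (strength 1.2, with A/G co-dominant at +3, echoing the weak
conservation of that position), shared backbone couplings (stabilizing
-2A:-1G and +5G:+6T at +0.6, destabilizing cross-boundary -2A:+5G at
-0.5), one group-specific coupling per lineage (-1G:+6T, -1G:+5G, +3G:+5G
at $|J| = 0.8$, mirroring the animal/plant/metazoan-style signatures), and
species-level field jitter (sd 0.05) so within-group models differ;
ensembles are exact samples (default 50,000 sequences per species).
`make_trait_on_tree()` produces clustered (single clade) or random
binary traits.

What the generator does *not* emulate: genome-scale base composition,
splice-site context beyond the 9-mer, U12-type donors, annotation errors,
and unequal ensemble sizes across species.  Passing tests therefore
demonstrate the correctness of the machinery on data whose generative
process is known, not the biological conclusions one would draw from real
genomes.

## Numerical choices and degenerate inputs

- Letters are ordered A,C,G,T and positions -3..-1,+1..+6 everywhere; pair
  blocks are lexicographic in the position indices.  State indices order
  sequences lexicographically, which is what makes `which.min` the
  lexicographic tie-break.
- log-sum-exp stabilization for $Z$; probabilities normalize to 1 within
  $10^{-9}$, block sums of $P_{ij}$ to 1 within $10^{-10}$.
- Empty ensembles, constant traits, label mismatches, out-of-bounds exons,
  malformed 9-mer lines, and zero-frequency fitting targets are rejected
  with specific errors (or, for constant traits, returned flagged with
  $p = 1$).
- Donor deduplication is by genomic site (sequence, position, strand), not
  per transcript isoform, switchable via `dedupe = FALSE`.
- All randomness is seeded through function arguments; the generators are
  pure functions of their seeds.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at sizes chosen to
exercise every claim on one CPU in minutes: moment matching on a
200,000-sequence ensemble; recovery from the exact marginals of a
10-coupling planted model; 50 replicates of the 12-species, 3-group panel
(50,000 sequences per species, $\gamma = 0.025$, Maddison-Slatkin with
9,999 permutations, $B_3$ with 999); 2,000 replicates of the calibration
study on a fixed 30-leaf tree with 999 permutations; 200 random trees for
the Sankoff-vs-exhaustive check; 500-donor planted genomes for extraction.
The acceptance script reports the same quantities at 10 panel replicates.

## Known limitations

- Absolute energies are gauge-dependent; only differences are comparable
  across reports.
- The L1 regularization scale is a package convention; other sparse
  penalties (e.g. group-lasso over letter pairs) would select slightly
  different supports at the same nominal level.
- The Maddison-Slatkin p-value is conservative on small trees (see above).
- Extraction trusts the annotation's exon coordinates; it does not attempt
  transcript assembly or repair of inconsistent isoforms, and introns
  shorter than 6 nt yield windows that read into the downstream exon, as
  the definition dictates.
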