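---
title: "Detecting intra-species divergent evolution: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intra-species divergent evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladiv)
```

`cladiv` implements an evidence chain for asking whether two subclades of a
virus species have diverged from each other in a specific sub-region of a
protein-coding gene. The motivating setting is an adenoviral immediate-early
gene: a ~253-codon coding sequence whose 62-codon transactivation sub-domain
(present only in the longer splice isoform) appears to split one species
into two groups. Three independent lines of evidence are implemented:
consensus proteotyping of the protein alignment, a clade-partitioned codon
model with a likelihood-ratio test, and codon-usage-bias ordination. A
seeded simulator generates data with all of the planted structure the
analyses look for, so the whole chain is testable without any sequence
downloads.

## 1. Proteotyping

For a protein alignment, the per-column consensus is the modal non-gap
residue (ties broken alphabetically, so results are deterministic). The
signature matrix records, for every taxon and column, whether the residue
matches the consensus, is a gap, or is a specific non-consensus residue;
exports carry a fixed residue-to-color table so repeated runs of the same
data produce identical figures.

The classic calling rule — "a unique proteotype is a pattern at least 10%
divergent from the consensus" — is ambiguous when two groups each sit
~10% from a blended consensus but 20% from each other. We therefore
operationalize it as **single-linkage clustering of pairwise signature
divergence** (the fraction of mutually ungapped columns at which two taxa
differ), cutting the dendrogram where linkage distance reaches the
threshold (default 0.10). Distance-to-consensus is still computed and
reported per taxon, but clustering drives the assignment: in the
two-groups-far-apart configuration the pairwise rule recovers both groups
where the consensus-distance rule can fail to separate them. Proteotype
ids are assigned by decreasing cluster size (ties by first-taxon order),
so id 1 is always the largest pattern.

Columns gapped in either member of a pair are excluded from that pair's
denominator; gaps are display information, not divergence. The assignment
is invariant to row and column order, and the number of proteotypes is
non-increasing in the threshold — both are tested properties.

The assortment scan is deliberately simple: given per-region proteotype
assignments ordered by genomic position, it tabulates ids per taxon and
reports, for any taxon pair, the region boundaries where the pair switches
between sharing and not sharing a proteotype. That is the operation behind
reading recombination extents off a proteotype table; no statistical test
of recombination is attempted.

## 2. The clade-partitioned codon model

The substitution process is the Goldman–Yang codon model on the 61 sense
codons: a substitution changing more than one codon position has rate 0,
and a single-position change from codon *i* to *j* has rate
$\pi_j \kappa^{[\mathrm{ts}]} \omega^{[\mathrm{nonsyn}]}$, where $\kappa$
is the transition/transversion rate ratio and $\omega$ the
nonsynonymous/synonymous rate ratio. Codon frequencies $\pi$ default to
F3x4 (position-specific nucleotide frequencies, renormalized over sense
codons); F61 and uniform are selectable. Frequencies are treated as
empirical quantities, not free parameters — this is what makes the
parameter counts come out as reported for this model family
(`np_cmc(60, 2)` = 123 = 117 branch lengths + $\kappa$ + two class
proportions + $\omega_0$ + two divergent $\omega$'s).

Sites belong to one of three classes: purifying ($\omega_0 < 1$,
proportion $p_0$), neutral ($\omega = 1$, proportion $p_1$), and a
*divergent* class ($p_2$) whose $\omega$ differs between clade partitions
of the tree. Partitions are carried per branch, written and read in
Newick as `$k` suffixes on node labels (a label applies to the branch
above the node and its whole subtree). The null model gives the focal
species one divergent-class $\omega$; the alternate splits the focal
species into its two subclades, adding exactly one parameter — the
likelihood-ratio statistic is referred to $\chi^2_1$.

Numerical choices worth knowing about:

* **Likelihoods** are computed by Felsenstein pruning over the 61-codon
  state space, with per-site-class passes and per-branch transition
  matrices from a symmetric eigendecomposition of the reversible
  generator (one decomposition per distinct $(\kappa, \omega)$, reused
  across branches). Column patterns are compressed; per-node rescaling
  guards against underflow. Gap and ambiguous codons are missing data
  (all-ones partial likelihoods). The pruning implementation is tested
  against an exhaustive sum over all internal-node state assignments on
  small instances.
* **Scaling.** Branch lengths are expected substitutions per codon at the
  mixture-average rate; the class-2 contribution to that average uses the
  background partition's $\omega$. Any such convention is shared between
  the simulator and the likelihood and absorbed by branch lengths, and it
  preserves the nesting identity (equal divergent $\omega$'s collapse the
  alternate model onto the null exactly — a tested identity).
* **Fitting.** $p_0, p_1, p_2$ are profiled out by an inner EM over the
  per-class site likelihoods; the outer quasi-Newton (`nlminb`) works on
  $\log \kappa$, logit $\omega_0$, $\log \omega_2[k]$ and (by default)
  log branch lengths, with analytic gradients propagated through the
  eigendecomposition. Fits use three starts by default (divergent
  $\omega$'s all 1; spread; random from the seed) because the mixture
  surface can be multimodal. Convergence is declared at relative
  log-likelihood change below 1e-8. `fix_branch_lengths = TRUE` keeps the
  input tree's lengths and adds one free global rate multiplier; this is
  the fast mode used throughout the simulation studies, and its parameter
  count (4 + K + 1) is deliberately not comparable to joint-estimation
  fits — the function warns about exactly that.
* **Nesting, exactly.** In the `$k` convention, the alternate labeling
  leaves the combined focal clade's stem branch in the background (it
  belongs to neither subclade), which would make the null and alternate
  models differ on that one branch and allow the LR statistic to go
  slightly negative. `cmc_test` assigns that stem to the first refining
  subclade, so the null is exactly nested in the alternate; the alternate
  fit also warm-starts from the null solution. Together these make
  LR $\ge 0$ structural rather than hoped-for.

## 3. Codon usage bias

RSCU (relative synonymous codon usage) is computed over the 59 informative
codons — the 61 sense codons minus the single-codon families Met and Trp.
For each amino-acid family present in a sequence, RSCU of a codon is its
count divided by the family mean, so family sums equal family sizes
exactly (a tested invariant). Codons of absent amino acids are kept as
zero columns (the 59-column contract is fixed) and flagged per taxon.

Correspondence analysis follows the standard SVD formulation: divide the
table by its grand total, subtract the rank-one independence expectation,
standardize by row/column margins, decompose, and scale to principal
coordinates. Total inertia equals the table's $\chi^2$ statistic over its
grand total, and the full-rank embedding reproduces $\chi^2$ distances
between row profiles — both tested, along with agreement with
`MASS::corresp` as an independent implementation. CA is run on RSCU
values by default (the stated, if slightly nonstandard, choice for this
analysis; counts are available as an option by passing a count table).

Published analyses of this kind judge group separation visually from the
2-D plot. To make that claim testable we report the mean silhouette width
of the group labels in the 2-D embedding — a package addition, clearly
labeled as such, not a published statistic.

## 4. What the simulator emulates — and what it does not

`sim_config()` defaults describe one concrete study: a 253-codon gene for
16 taxa — 6 background taxa plus two focal subclades of 5 — with a
62-codon divergent window at codons 132–193 (spanning the positions where
the real sub-domain's conserved residues sit). Site classes have
proportions (0.35, 0.25, 0.40) with $\omega_0 = 0.1$; the divergent class
uses $\omega$ = 1 (background), 0.2 (group 1) and 3.0 (group 2) inside
the window, and the background value everywhere outside it — the
divergence is confined to the window, and outside it the divergent class
is effectively neutral (those sites are absorbed by the neutral class,
which is exactly what lets the fitted divergent class specialize on the
window and gives the contrast its power).

One calibration lesson from building this is worth stating prominently:
when the divergent class's $\omega$ is close to 1, class 2 becomes
statistically indistinguishable from the neutral class and the mixture
likelihood sits on a degenerate ridge. On that ridge the $\chi^2_1$
calibration of the divergence LRT visibly fails — we measured ~8.5%
rejection at nominal 5% with a shared divergent $\omega$ of 1.5 (across
several problem sizes, with optimization and likelihood correctness
verified independently), versus 4.5% with a shared $\omega$ of 3, where
the whole LR distribution matches $\chi^2_1$ quantiles. The type-I
calibration study therefore simulates its null with shared
$\omega_2 = 3$, and the ridge is also why the null fits of the
excision study use two optimizer starts: a single start occasionally
under-maximizes the null there and inflates the statistic. Simulation
studies of clade models should avoid the $\omega_2 \approx 1$ corner
unless the degeneracy itself is the object of study. Trees are
Yule subtrees of depth 0.3 grafted with stems of 0.3 (expected
substitutions per codon); $\kappa = 2$; codon frequencies uniform. The
divergent-class proportion and tree depth were chosen to emulate a
sub-domain whose inter-clade protein identity drops to roughly two thirds
— the regime the analyses target — on a species-scale tree; the
$\omega$ contrast and the 16 × 253 / 62-codon geometry are the canonical
test fixture. Branch-wise evolution samples each site directly from
$P(t) = e^{Qt}$ (exact, no event-by-event simulation), and the generator
is sense-restricted so stop codons cannot arise.

Codon bias is planted *post hoc*: within each group, codons are resampled
toward group-specific preferred synonymous codons with a given
probability. This changes exactly what RSCU measures while leaving the
amino-acid sequence (and hence the dN/dS structure) untouched, keeping
the two experimental axes orthogonal.

What the simulator does **not** emulate: indels and alignment error (all
simulated alignments are gapless and correctly aligned), recombination
mosaics across genome regions (the assortment scan is tested on
constructed label tables), rate variation beyond the three-class mixture,
and non-equilibrium or lineage-varying codon frequencies. Passing tests
therefore certify the statistical machinery under the model's own
assumptions, not robustness to real-data pathologies.

## 5. Scaled-down study sizes used by the test suite

The test suite re-derives the statistical behavior at sizes a desk
machine handles comfortably; these sizes are package choices, stated here
so they can be revisited:

* **Type-I error of the divergence LRT**: 200 replicates of 6 taxa × 100
  codons simulated under the null (shared divergent $\omega = 3$, the
  identifiable design discussed above), fit with fixed true branch
  lengths and single-start fits; the rejection rate at $\alpha = 0.05$
  must stay within 5% ± 3%.
* **Power and the excision contrast**: 20 replicates of the canonical
  16 × 253 fixture; the LRT must reject at $\alpha = 0.05$ in at least
  80% of full-gene replicates, and at most 3 of 20 after the divergent
  window is excised (the binomial 95% bound at the nominal level).
* **Proteotype recovery**: 100 replicates of planted two-group protein
  alignments (25% between-group divergence, ≤4–5% within-group noise);
  the recovered partition must equal the planted one (adjusted Rand
  index 1) in at least 95%.
* **Pruning correctness**: exhaustive-state oracle on all instances with
  ≤4 taxa and ≤3 sites over random parameters.
* **NJ correctness**: exact recovery of random additive matrices, n ≤ 8.

## 6. Known limitations

* The clade model's likelihood surface is genuinely multimodal in corners
  of parameter space; three starts are a default, not a guarantee. For
  definitive analyses use more starts and joint branch-length estimation.
* With few taxa the site-class proportions are weakly identified and
  routinely end up on the boundary ($p_1 = 0$, or $\omega_0$ at its
  bounds). This does not disturb the LRT's calibration (tested), but the
  class proportions themselves should not be over-interpreted at small n.
* `fix_branch_lengths = TRUE` conditions on the input tree; a tree
  estimated from the same alignment makes the test slightly liberal in
  principle. The calibration study uses the true simulated tree, which is
  the clean version of that design.
* Proteotype ids are per-region labels; the assortment table deliberately
  carries no cross-region identity, and apparent id "matches" across
  regions are meaningless.
* The silhouette summary of CA separation depends on the 2-D truncation;
  with more than two well-separated groups, inspect the inertia fractions
  before trusting it.
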