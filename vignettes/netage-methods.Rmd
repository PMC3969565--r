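---
title: "Methods: gene ages, parsimony and age-coupling nulls in netage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene ages, parsimony and age-coupling nulls in netage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netage)
```

This vignette documents the models behind `netage`, the choices made where
the design was genuinely open, and what the bundled tests do and do not
demonstrate about real data.

## The age scale and species tree

Gene ages are expressed on an ordered scale of clade strata
("age groups"), by default eleven of them from Prokaryota (rank 1) to
Mammalia (rank 11). Rank order is the only structure used: all age
distances are differences of integer ranks on the full scale, so the
rarely-populated Radiata stratum (rank 7) still counts as a step when a
pair spans it. This keeps distances stable whatever subset of groups a
particular data set happens to use; collapsing sparse strata would make
"jump" sizes depend on the data set rather than on the scale.

Short labels follow the convention `Pr, E, V, U, O, M, R, B, Ch, Vr, Ma`;
labels are matched as exact case-insensitive tokens, so `V`
(Viridiplantae) and `Vr` (Vertebrata) never collide.

The species tree is any rooted Newick tree — binary or multifurcating;
branch lengths are ignored — with each leaf assigned to exactly one age
group. The bundled `fixture_tree()` has twelve species in a ladder
topology, one per group plus a second early eukaryote, so that every age
group is monophyletic. On such a tree the oldest-hit age and the Dollo
age provably coincide, which the tests exploit; on real trees with
non-monophyletic strata the two can differ, and no such guarantee is
claimed.

## Profiles and their annotations

A profile cell is 1 when the gene has at least one bidirectional hit with
score at or above `min_score` in that species (default 0.05, the
customary floor for scored reciprocal-hit output; the upstream search's
own thresholds travel as metadata and are not recomputed). The seed
organism's column is always 1 for its own genes. Transitive extension
through secondary seed organisms only ever adds presences, with
provenance recorded per cell, so it is monotone and idempotent.

Isolated-hit flags mark presences supported by at most
`max_group_support` species in their age group (default 1) and separated
by at least `min_gap` ranks from the gene's nearest other presence
(default 2). These defaults flag the classic single-bacterial-hit pattern
suggestive of horizontal transfer or contamination while leaving
ordinary patchy presence unflagged. Flags never change the matrix; they
matter only when the oldest-hit rule is asked to discount them, in which
case the assignment skips to the oldest non-isolated presence and says
so.

Losses in model organisms are called operationally: an absence in
species *s* counts as a (candidate) loss when the gene is present in at
least one species of a strictly older stratum. Absence in a draft genome
is treated like any other absence in the matrix, but the genome
completeness flag is carried into the loss record so downstream reports
can caveat claims appropriately.

Gene clustering is UPGMA on Euclidean distances between 0/1 rows.
Because 0/1 vectors produce many exact distance ties, the merge order is
made deterministic and input-order-invariant by always merging the tied
pair with the lexicographically smallest gene label, and by expanding
dendrogram children smaller-label-first. The implementation is a plain
O(n³) loop — entirely adequate at the hundred-gene scale this package
targets — and is checked against `hclust(method = "average")` on
tie-free data.

## Gene-age inference

**Oldest hit.** `age(g) = min rank` over present cells. Simple, but
sensitive to isolated hits; the `discount_isolated` policy is therefore
exposed and off by default (the undiscounted value is what the rule
literally says).

**Dollo parsimony** assumes one gain per gene family: the gain is the
MRCA of present leaves, internal nodes of that clade are present iff a
carrier lies below them, and each maximal carrier-free subtree costs one
loss. The reported cost is the number of losses.

**Wagner parsimony** allows repeated gains and losses and minimises
`c_gain·gains + c_loss·losses` by the Sankoff recursion (sum over
children of the per-state minimum plus transition cost), with
multifurcations handled natively. Defaults are symmetric costs
`c_gain = c_loss = 1`, the conventional Wagner choice when no external
calibration exists. Two tie-breaks fix a unique reconstruction: the root
prefers absence on equal cost (genes are born, not primordial by
default), and an equal-cost backtrace keeps the child absent (a loss is
preferred over a gain). A present root is charged one gain on a virtual
stem branch, so a gene present in every species still records exactly
one gain; this convention is what makes expensive-gain Wagner
(`c_gain ≥ n_leaves · c_loss`) collapse onto the Dollo reconstruction,
a property the tests verify against exhaustive enumeration.

The age implied by a reconstruction is the oldest rank among leaves of
the gain clade; when Wagner infers several gains, the gain whose subtree
contains the reference organism (human by default) dates the copy that
organism inherited.

Probabilistic (branch-length-aware) ancestral reconstruction is out of
scope by design: the intended inputs include draft genomes whose absence
calls are too unreliable to support rate estimation.

**Emergence curves** report, per stratum, the cumulative fraction of the
stratum's genes with rank ≤ r. Normalisation is within-stratum (every
curve ends at 1). The alternative reading — dividing by the number of
species per age group — answers a different question and is not applied;
with multi-tier genes counted once per stratum, within-stratum
normalisation is the only choice that makes curves comparable across
strata of different sizes.

## Enrichment statistics

Per age group, a 2×2 Fisher exact test (input in/not in group vs
background in/not in group), two-sided by the standard minimum-likelihood
rule — the p-value sums hypergeometric point probabilities not exceeding
the observed one within relative tolerance 1e-7 — with the convention
p = 1 for any zero margin. Bonferroni correction multiplies by the
number of groups with non-zero background. Input genes are removed from
the background before testing (double-counting the input inside its own
reference inflates the background toward the input and masks
enrichment). The global test is Mann–Whitney U on the two rank lists:
midrank ties, exact enumeration when n₁+n₂ ≤ 12, otherwise the normal
approximation with tie-corrected variance and no continuity correction.
Means and medians are reported in rank units unless a group→MYA map is
supplied.

Published enrichment tables for the DDR network depend on external
protein-family databases; this package reproduces the statistical
machinery and the report schema, not those numbers.

## The modification-network analysis

The packaged pair table (`ptm_fixture_path()`) lists 99 curated human
DDR target–modifier pairs with modification type (P/U/S/A/deA) and both
genes' age labels. Five pairs are self-modifications and are excluded
from all statistics.

**Harmonization.** A curated table can list one gene with different ages
in different rows. Each gene is mapped to its modal rank over all
appearances, ties broken toward the older rank (the direction in which
an oldest-hit age errs only by missing data, not by inventing it), and
every rewritten cell is logged. On the packaged table exactly one gene
(CHEK2) is discordant, and harmonizing it is what reconciles the
pairwise counts with the published 29/33/32 same/younger/older split.

**Free null.** Replicates permute the modifier column against fixed
targets; a permutation creating any self-pair is rejected and redrawn
whole, keeping the sample space clean. This preserves both marginal age
distributions and the pair count — the minimal null consistent with
"shuffle the interacting pairs". Empirical p-values use (r+1)/(n+1)
smoothing, two-sided by doubling the smaller tail and capping at 1.

**Stratified null.** The second question is about age distances given
the category counts: are the jumps longer or shorter than chance allows?
Holding each pair inside its own category would fix the modifier-rank
multiset per category and make mean distances permutation-invariant —
nothing would be testable. The null therefore conditions on the category
*counts*: modifier assignments are randomized over all non-self pairs
subject to the same/younger/older triple staying exactly at its observed
value. Sampling uses a transposition Markov chain, the standard edge-swap
sampler for constrained network nulls: starting from the observed (valid)
assignment, a proposed swap of two pairs' modifiers is accepted when
neither pair becomes a self-pair and the two category changes cancel.
Twenty proposals per pair separate consecutive replicates (and precede
the first), which on the 94-pair fixture mixes well — replicate summaries
are stable across seeds — while keeping 1,000 replicates around two
seconds. Per replicate the small/large jump counts (threshold 3 ranks)
and the large-jump count among pairs with an older modifier are
recorded.

**Jumps.** A pair's jump is `|rank(target) − rank(modifier)|`; jumps of
1–2 are "small", ≥ 3 "large", matching the published "< 3 groups"
boundary.

## Synthetic data

`simulate_gene_history()` implements the Dollo generative story: one
gain on a chosen branch, then independent Bernoulli loss per descendant
branch (no regain). Emitted truth (gain node, loss branches) replays to
the exact leaf vector, which tests use as an oracle.
`simulate_profile_set()` draws gain branches so true ages follow a
configurable distribution; the default concentrates 10% of mass at rank
1 and 60% at rank 2, the shape typical of an anciently-rooted cellular
network, with the remainder uniform. `simulate_ptm_network()` draws
pairs whose probability of being forced same-age is the `assortativity`
parameter, with modification types at the packaged table's proportions
(P 0.77, U 0.14, S 0.06, A 0.02, deA 0.01).

What the generators emulate is the *statistical* structure the analysis
assumes — single-gain histories, independent losses, age-assortative
pairing. They do not emulate sequence-level realities: correlated loss
across related species, annotation artifacts in draft genomes,
orthology misassignment between paralogs, or horizontal transfer. A
passing recovery test therefore validates the inference machinery, not
the upstream orthology calls.

## Problem sizes and numerical choices

The test suite runs at deliberately modest sizes — parsimony oracles on
≥ 500 random trees of ≤ 8 leaves (exhaustive enumeration beyond that is
pointless, 2⁷ labelings already cover every structural case on these
trees), 118-gene simulated profiles matching the packaged network's
scale, 1,000-replicate nulls, and a full Fisher sweep over all 2×2
tables with margins ≤ 30. Distance ties in clustering are compared with
an absolute tolerance of 1e-12; Fisher point-probability comparisons use
the standard 1 + 1e-7 relative slack. All randomized procedures are
bit-reproducible given (parameters, seed).

## Known limitations

- Ages are ordinal ranks; no attempt is made to calibrate strata in
  time units unless the user supplies a map.
- The loss caller reports operational absences; it cannot distinguish
  true loss from annotation failure (the completeness flag is the only
  mitigation).
- The stratified null samples by MCMC, so replicates are exchangeable
  but not independent draws from the admissible set; summary means and
  sds are stable at the default chain length, but extreme tail
  quantiles should not be over-interpreted.
- Harmonization by majority rule is a heuristic; with deeply discordant
  curation (no modal age) it falls back to the older rank, which may
  not be the curator's intent.
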