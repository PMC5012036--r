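---
title: "Inferring explicit hybridization networks from distance data"
author: "lexinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring explicit hybridization networks from distance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexinet)
```

## The problem

Trees are the default model for the evolution of species and of natural
languages alike, but both domains feature events a tree cannot express:
hybridization and horizontal transfer in biology, lexical hybridization and
word borrowing in linguistics. `lexinet` implements a distance-based method
that produces an *explicit* network: alongside a tree skeleton it names each
recipient of transferred material, its two donors, and the proportion of
material attributed to each donor (the hybridization or reticulation
degree). This contrasts with implicit representations such as split graphs,
which display conflict but identify neither direction nor degree.

The package works from any symmetric distance matrix. For lexical data it
also provides the upstream encodings: a cognate database (one record per
word form, grouped into cognate sets per meaning) is turned into a binary
presence-absence matrix over cognate sets, and pairwise Hamming distances
between the taxon profiles form the input matrix.

## The model and the detection rule

The backbone is neighbor joining (NJ). At each agglomeration step the pair
$(i, j)$ minimizing the least-squares total tree length over all
one-cherry configurations is selected; this is equivalent to minimizing the
canonical criterion $Q(i,j) = (n-2)\,d(i,j) - R_i - R_j$ with $R_i$ the row
sum, and the equivalence is verified against an exhaustive
ordinary-least-squares configuration scan in the test suite. After a join,
the new node $X$ replaces $i$ and $j$ with
$d(X,k) = \tfrac12\big(d(i,k) + d(j,k)\big)$.

Before each join, the pending pair is screened for a hybrid. Three
statistics drive the decision, all computed on the current matrix of $n$
active nodes:

**Hybridization degree** (`estimateAlpha`). Assume $h$ is a hybrid of
donors $i$ and $j$ in proportions $\alpha$ and $1-\alpha$. With
$S_l = \sum_{k \ne i,j,h} d(k,l)/(n-3)$, $Y_k = d(k,h) - d(k,j)$ and
$X_k = S_j - S_i + d(k,i) - d(k,j)$, the least-squares degree is

$$\hat\alpha_{i,j}^{\,h} =
  \frac{\sum_{k \ne i,j,h} X_k\,(Y_k - S_h + S_j)}
       {\sum_{k \ne i,j,h} X_k^2},$$

the closed-form minimizer of the misfit
$LS_{i,j}^{\,h} = \sum_{k \ne i,j,h} (Y_k - S_h + S_j - \alpha X_k)^2$
(`leastSquaresFit`). On a matrix satisfying
$d(k,h) = \alpha\,d(k,i) + (1-\alpha)\,d(k,j)$ for every other node $k$ the
estimator is exact, because then $Y_k - S_h + S_j = \alpha X_k$ identically.
When every $X_k$ vanishes the donors are directionally indistinguishable
and the candidate is rejected (this happens, for example, when the donors
are sister leaves — see *Identifiability* below).

**Reticulation score** (`hybridizationScore`). For a candidate triplet,

$$Sc_{i,j}^{\,h} = \min_{k \ne i,j,h}\big\{\,
  d(i,j)+d(k,h)-d(i,h)-d(k,j);\;
  d(i,j)+d(k,h)-d(j,h)-d(k,i)\,\big\}$$

measures deviation from the four-point condition: it is 0 on any
tree-realizable matrix and grows as $h$ is pulled off a tree position.

**Neighbor deviation** (`neighborDeviation`). For the pending pair,

$$\Delta_{i,j}^{\,h} = \sum_{k \ne i,j}
  \big(d(j,h)+d(i,k)-d(j,k)-d(i,h)\big)$$

is 0 for every $h$ when $i$ and $j$ are true neighbors in an additive tree.
The node $h_0$ maximizing $|\Delta|$ is the hybrid suspect at this step.

**The decision** (`detectAtStep`). Among triplets $(h_0, i_0, k)$ with
$i_0 \in \{i, j\}$ and $k$ any other active node, those with
$Sc \ge MIN_{Sc}$ and $\alpha_{MIN} \le \hat\alpha \le \alpha_{MAX}$ are
admissible; the admissible triplet with minimal $LS$ is accepted iff
$LS < \Delta^2$ (strictly; a tie rejects). On acceptance the recipient
$h_0$ is removed from the matrix — the pending join is *not* performed, and
pair selection restarts on the reduced matrix; otherwise the join proceeds
as in plain NJ. The loop is $O(n^3)$ like NJ. Donors are whatever nodes are
active at the detection step, so an inferred donor may be an original taxon
or an agglomerated cluster standing for an ancestral branch; reticulation
records always carry the donor's member list. The degree reported is the
one estimated at detection time; it is not re-estimated later.

Hybrids often sit next to one of their donors in a tree and can distort
their neighborhood; `iterateRemoval` reruns inference on matrices from
which already-detected recipients have been pruned, accumulating
reticulations round by round until nothing new is found.

## Tunable parameters

* `minScore` ($MIN_{Sc}$, unitless, on the scale of the distances):
  minimum reticulation score of an admissible triplet. Default 0 for
  matrices of up to 20 nodes.
* `alphaMin`, `alphaMax` (unitless, in $(0,1)$): admissible degree range.
  Defaults 0.1 and 0.9 for small matrices.
* For larger matrices (over 20 nodes) the defaults switch to the
  restrictive regime $(0.1, 0.25, 0.75)$, trading sensitivity for fewer
  false positives; both regimes are exposed via `DetectionParameters()`
  and `defaultDetectionParameters(n)`.
* `minTaxa` (word trees): characters attested in fewer taxa get no tree,
  since trees with under four leaves carry no topological signal.

Detection needs at least five active nodes (a candidate triplet plus two
reference nodes); smaller inputs fall back to plain NJ with a warning.

## Distance encodings for lexical data

* `hammingDistance(pam, "missing_as_zero")` counts cognate sets containing
  a form of exactly one of the two taxa, with missing slots encoded as 0.
  This is the default encoding and the one used throughout the examples.
* `hammingDistance(pam, "normalized")` restricts the count to characters
  attested in both taxa and divides by the number of such characters; a
  pair sharing no attested character is an error.
* `normalizedLevenshtein` is the unit-cost edit distance divided by the
  longer word's length; strings are compared by code point, with no
  transliteration or sound-class mapping (orthographic forms are compared
  as given).
* `meaningDistance` combines both levels for one meaning $m$: each cognate
  set contributes 0 (neither taxon present), 1 (exactly one present — any
  two non-cognate forms count as maximally distant), or the minimum
  normalized Levenshtein distance across cross-taxon form pairs; the sum is
  divided by the number of sets containing either taxon. Sets containing
  neither taxon contribute 0 to the numerator while being excluded from the
  denominator, exactly as the formula is stated. `buildWordTrees` turns
  these matrices into per-meaning NJ trees for downstream consensus
  methods.

## Numerical choices

* **Reduction formula and branch lengths.** The plain-average reduction
  $d(X,k) = \tfrac12(d(i,k)+d(j,k))$ adds $d(i,j)/2$ to every distance out
  of $X$ relative to the reduced tree (for a cherry $(i,j)$ below $X$,
  $\tfrac12(d(i,k)+d(j,k)) = d(X,k) + \tfrac12 d(i,j)$). Each agglomerated
  node therefore carries an offset $h_X = d_{\mathrm{cur}}(i,j)/2$, and
  writing $d_{\mathrm{cur}}(u,v) = d_T(u,v) + h_u + h_v$ one can check that
  the standard NJ pendant estimate returns the true length plus $h_u$. The
  engine subtracts the offset, so on additive input the leaf-to-leaf path
  lengths of the output tree reproduce the input distances exactly (a
  tested property). Negative pendant estimates are reported as-is.
* **Tie-breaking.** All ties — pair selection, the $\Delta$ maximizer,
  equal-misfit triplets — break lexicographically on labels (bytewise,
  locale-independent), making every run deterministic. Agglomerated nodes
  are labeled by the sorted `+`-joined list of their members.
* **Noise guard.** On exactly additive input $\Delta$ is zero only up to
  rounding, and $LS < \Delta^2$ could fire on noise squared; a step whose
  maximal $|\Delta|$ is below $10^{-9}(1 + \max d)$ is treated as additive
  and no candidate is returned.
* **Degenerate inputs.** Zero distances (identical taxa) are legal; the
  pair is joined with zero-length pendants. $\sum X_k^2 = 0$ rejects the
  candidate rather than erroring.

## The synthetic-data generator

Real cognate databases of the kind this method targets (tens of languages,
a couple of hundred basic meanings, around four to seven cognate sets per
meaning, roughly a fifth of slots missing) are not shipped; the generator
produces structurally matched stand-ins at desk scale:

* `randomAdditiveMatrix(n)` draws a random unrooted binary topology with
  branch lengths uniform on $[0.1, 1]$ — the neutral choice when no
  particular depth profile is assumed — and returns its path-length
  matrix.
* `injectHybrid` adds a row following the convex rule underlying the
  degree estimator; this is the noise-free, distance-level idealization of
  a hybrid.
* `simulateCognateDatabase` works at the cognate level: a fixed random
  tree defines lineages; per character, taxa are partitioned into cogsets
  by cutting a branch-length-resampled copy of the tree, and a hybrid
  taxon takes a fraction $\alpha$ of its per-character memberships from
  one donor's cogset and the rest from the other's (deterministic split by
  default, Bernoulli draws optionally). Encoding such a database and
  computing Hamming distances yields a matrix carrying approximately the
  same convex signal, plus the integer-valued distortion of real encodings.
* `exampleHybridDatabase` is a fully deterministic 8-language instance (4
  meanings, 16 cognate sets, one even-degree hybrid, one outgroup) whose
  inference run is reproduced step by step in the README.

**Identifiability of donor pairs.** A hybrid of two sister leaves is
invisible to any distance method: if $d(k,i) - d(k,j)$ is constant over
$k$, the convex mixture is itself realizable as a leaf of the same tree.
The same holds when the donors' attachment points are joined by a single
internal edge — the mixture then attaches along that edge (writing
$d(k,h) = d(k,u) + \alpha b_i + (1-\alpha)(\ell_{uv} + b_j)$ on one side
and symmetrically on the other shows it is additive for all $k$ outside
the donors). `simulateHybridMatrix` therefore samples donors at
topological leaf distance of at least 4 edges, the smallest separation at
which the mixture is genuinely non-additive; this emulates reticulation
between distinct clades, which is also where the real-data events of
interest lie.

What passing these simulations does *not* show: the generator has no
sound change, semantic shift, borrowing chains, or correlated missingness,
and its noise-free convex rows are the method's best case. Real datasets
will sit between the clean distance-level study and the integer-distorted
cognate-level study, and judgments about any single reported reticulation
on real data still need external (here: historical) corroboration.

## Simulation studies and their scale

`hybridRecoveryStudy` (100 replicates, 20 taxa, one injected hybrid,
$\alpha \sim U[0.25, 0.75]$, noise-free) measures how often the recipient
and both donors are identified; `cognateAlphaStudy` (100 replicates, 8
taxa, 50 meanings, 4 cogsets each) measures the degree error through the
full cognate pipeline. These sizes mirror the language-group analyses the
method is meant for and keep the default test run fast. Both studies pass
the group-scale parameters $(0, 0.1, 0.9)$ explicitly, because the
size-based default would switch regimes at 21 nodes and clip the simulated
degree range at its own boundary.

The studies also expose the method's characteristic failure mode: when
$\alpha$ is near the edge of its range the hybrid's profile approximates
its majority donor, NJ selects the (hybrid, donor) pair for joining, and
the detection rule — which only ever tests nodes *outside* the pending
pair — can no longer remove it. In the distance-level study roughly one
replicate in ten fails this way (the recovery study computes the exact
rate on each run); degree estimates in recovered replicates are exact to
machine precision at the distance level and within a few hundredths
through the cognate pipeline. Choosing a recipient that later turns out to
be a cluster containing the true hybrid is the visible trace of the same
phenomenon.

## Design choices where the design was open

* **After accepting a hybrid the pending join is dropped** and selection
  restarts on the reduced matrix; joining is strictly the else-branch of
  the decision.
* **$\Delta$ in the acceptance test** is that of the suspect $h_0$ for the
  pending pair — the statistic whose magnitude nominated $h_0$ in the
  first place.
* **The $(n-3)$ in the degree estimator** uses the current active-node
  count, which equals the number of summands; using the original taxon
  count would make the two diverge after the first join.
* **Donor-2 candidates** range over active nodes outside the pending pair
  and the suspect, matching the one-cherry configuration in which the test
  is derived.
* **Input format**: a clean 4-column TSV (`taxon`, `character`, `cogset`,
  `form`) rather than any legacy lexicostatistical format; multiple forms
  per (taxon, character) are allowed and may sit in different cogsets.
  Taxa and cogsets are ordered lexicographically so that all output is
  reproducible.
* **PHYLIP square matrices** are read and written without the classic
  10-character label truncation (a relaxed, documented dialect).

## Known limitations

* Recipients absorbed into a cluster before detection are only ever
  reported at cluster resolution, and a hybrid joined to its majority
  donor may be missed entirely (see above).
* Reticulations carry no statistical significance measure; the score
  orders candidates but has no null distribution here.
* Timing or dating of reticulation events is out of scope, as is mapping
  them onto an externally supplied reference tree.
* The Levenshtein-based word distances treat regular sound change as
  noise; languages with systematic orthographic divergence will look more
  distant than a historical linguist would judge.

## A worked run

```{r example}
db <- exampleHybridDatabase()
D <- hammingDistance(buildPresenceAbsence(db))
net <- inferNetwork(D, DetectionParameters(0, 0.1, 0.9))
net
networkTrace(net)
cat(enewick(net))
```
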