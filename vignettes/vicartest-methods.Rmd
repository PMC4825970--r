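---
title: "Methods: event-based biogeography and temporal congruence with vicartest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-based biogeography and temporal congruence with vicartest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicartest)
```

vicartest implements the downstream inferential chain that leads from a set
of fossil-calibrated, dated phylogenies to biogeographic conclusions: which
nodes of the tree represent vicariant splits of an ancestral range, and
which dated geological or climatic events could have caused them. The
worked system throughout is the Neotropical Triatominae (kissing bugs),
whose ranges are coded over twelve biogeographic units (A–L, Mexican
Transition Zone through North America), but every stage is generic.

The pipeline has four stages, each usable on its own:

1. **Trees** — reading rooted ultrametric dated trees (Newick or NEXUS),
   deriving node ages in Ma, and comparing topologies.
2. **Ancestral ranges** — event-based parsimony (DIVA, with S-DIVA
   averaging over tree samples) and Bayesian binary MCMC (BBM)
   reconstruction of per-area presence.
3. **Event inference** — consensus vicariance calls over a grid of
   reconstructions, highest-posterior-density (HPD) intervals for node
   ages, temporal-congruence tests of event windows, and a
   calibration-sensitivity regression.
4. **Synthetic data** — seeded generators for every input, so each stage
   can be validated against a known truth.

## Tree model

A `dated_tree` is an ape `phylo` with branch durations in Myr, validated to
be rooted, strictly bifurcating and ultrametric; node ages in Ma are the
tree height minus the root-to-node path length, so all tips sit at the
present. Ultrametricity is accepted within a relative tolerance of `1e-6`
of tree height, because dating software prints rounded branch lengths.
Polytomies are rejected rather than auto-resolved: the DIVA dynamic
programme below assumes two daughter lineages per split, and silently
resolving a polytomy would manufacture vicariance events the data do not
contain.

Clades are identified across topologies by their *clade key* — the sorted
set of subtended tip labels — which is what makes "the same clade in every
topology" a well-defined criterion when topologies disagree elsewhere.

Topology disagreement is summarised by `discordant_taxa()`: a greedy search
that repeatedly removes the single taxon whose removal most reduces the
symmetric difference of the two trees' clade sets (ties broken
alphabetically) until the sets coincide. This is an approximation to the
minimal discordant taxon set — the exact problem is a set-cover-type search —
but the tests verify it is exact on single and double tip moves, and the
returned set always reconciles the trees.

Posterior tree samples are read with a burn-in fraction (default 0.25,
applied by count after rounding down), the standard treatment of Bayesian
dating output.

## The DIVA cost model and its exact solution

DIVA is event-based parsimony over geographic ranges. A range is a
non-empty subset of the area alphabet. At a cladogenetic node the ancestral
range either splits into two disjoint non-empty subsets (vicariance, free)
or — for a single-area ancestor — is duplicated into both daughters (free).
Along a branch, each area gained costs 1 (dispersal) and each area lost
costs 1 (local extinction), so the branch cost between the inherited subset
`S` and the child's range `C` is the symmetric difference `|C \ S| + |S \ C|`.

`diva_optimize()` solves this exactly by dynamic programming: a bottom-up
table `cost(node, R)` over all candidate ranges, enumerating at each
internal node every ordered bipartition of `R` (the `3^k` growth of
subset pairs is why exact mode is capped at 8 areas; beyond that the
candidate set is restricted to the union-closure of observed tip ranges,
with a warning). A top-down traceback then marks every range that occurs at
each node in at least one globally minimal reconstruction. All co-optimal
ranges are kept with uniform weights — parsimony ties are data, not
nuisance, and collapsing them to one arbitrary answer would bias the
downstream vicariance counts. `max_areas` (default 12) caps ancestral range
sizes inside the recursion without touching observed tip ranges.

The implementation is validated against an independent oracle that
enumerates *every* assignment of ranges to internal nodes on small
instances (up to 6 tips and 3 areas): minimal cost and the optimal range
sets agree on hundreds of random instances per test run.

`sdiva()` averages the per-clade tie weights over a tree sample: for each
clade the frequency of a candidate range is the mean of its weights over
the trees that contain the clade, with the clade's *occupancy* (fraction of
trees containing it) reported alongside. Frequencies therefore sum to one
within every clade.

## Bayesian binary MCMC

BBM models each area independently as a two-state (absent/present)
continuous-time Markov chain along the dated tree. Under the empirical
model the stationary presence frequency of area `a` is the observed
fraction of tips occupying it, clamped to `[0.05, 0.95]`; all-absent or
all-present areas trigger the clamp with a warning, since a frequency of
exactly 0 or 1 makes the chain degenerate.

The chain rate needs one scaling decision. We set the rate to `1 / tree
height` per area — one expected transition opportunity per root-to-tip
path. The tempting alternative, scaling so the stationary *flux* equals
one change per path, inflates the rate without bound as the empirical
frequency approaches the clamp boundaries; every branch then relaxes to
stationarity, the tips lose all influence on the ancestral states, and a
unanimously occupied area can no longer be reconstructed with confidence at
the root. Unit chain rate keeps branch memory comparable across areas
regardless of how skewed their frequencies are. When the range process is
known — as on simulated data — `pi` and `rate` can be supplied directly
(for a gain/loss process with rates `g` and `l`, the matching chain has
`rate = g + l`, `pi = g / (g + l)`).

Ancestral presence bits are sampled by single-site Gibbs updates in random
node order; one generation is one full sweep. Three root priors are
available: `null` (root drawn from the stationary distribution), `wide`
(root fixed to the full alphabet) and `custom` (user-supplied range — the
package cannot guess a custom prior, so it must be explicit). Two
independent runs of 50,000 generations are the default; each discards its
first 25% as burn-in, the runs are pooled, and the maximum between-run
difference in any per-node marginal is reported as a convergence
diagnostic (at default settings it sits well under 0.05 on the synthetic
suite).

Per-node *range* weights combine the per-area marginals under independence,
renormalised over non-empty ranges; the root additionally gets the joint
sampled posterior over presence patterns (`root_posterior`), which is the
quantity to use when asking "what single range does the root most likely
occupy" — the independence product can misrepresent strongly coupled areas.

## Event annotation and route strings

For reporting, each internal node is classified from its modal range
(ties to the smallest bitmask, for determinism) and its children's modal
ranges: a *vicariance* when the children partition the parent range, a
*dispersal* when a child gains areas, an *extinction* when areas are only
lost, and a *duplication* otherwise. The textual route grammar is

```
<parent-range> ( "|" <left> "^" <right> | "->" <gained> | "^" <gained> )*
```

with ranges as concatenated area letters (`AB|A^B`, `A->B`);
`parse_route()` and `serialize_route()` are exact inverses, which the tests
check on random token sequences.

## Consensus vicariance and the replication grid

Reconstruction methods disagree, and so do topologies from different
dating analyses. The package therefore runs a *grid* — every method crossed
with every topology; with S-DIVA plus three BBM prior modes on four
topologies that is 16 reconstructions — and calls a clade vicariant only if

1. it is annotated vicariant in at least 50% of the grid (inclusive), and
2. its clade key occurs in **every** supplied topology.

The 50% criterion is computed over the whole grid by default; whether it
should instead be required within each topology separately is a genuinely
open reading, so a `scope = "per-topology"` mode exists and the choice is
recorded in the output.

## HPD intervals and temporal congruence

`hpd_interval()` returns the shortest window over the sorted age samples
containing `ceiling(mass * n)` of them, ties resolved toward the smaller
lower bound; it matches brute-force enumeration of all windows exactly and
attains nominal coverage on simulated posteriors.

A cladogenetic event is tested against a dated event window by interval
overlap. The default rule, `all-runs-overlap`, rejects the hypothesis that
the event drove the divergence iff the window is disjoint from the node's
95% interval in **at least one** dating analysis. This is deliberately the
strictest of the symmetric overlap rules: requiring overlap in a single
analysis (`any-run-overlap`) lets the least-calibrated, widest intervals
rescue any hypothesis, while a midpoint rule (`mean-in-window`) ignores
the interval widths entirely; both remain selectable and the rule used is
always recorded. Intervals are closed — a shared endpoint counts as
overlap — which is conservative toward non-rejection. Windows may be
entered older-bound-first or younger-bound-first; they are normalised
internally. No multiple-testing correction is applied across rows of a
hypothesis table; each window is a separate, pre-specified hypothesis, and
the reports say so.

The packaged fixtures (`load_fixture()`) carry a worked Triatominae
hypothesis set — 14 hypothesis rows covering 11 cladogenetic events, 13
geological windows plus one biotic (host-hitchhiking) window, with 95%
intervals from three dating analyses B1/B2/B3 using one, six and seven
fossil calibrations — and the corresponding seven fossil calibration
priors. In the calibration table, one Emesinae fossil prior switches
parameterisation with the configuration: normal(45, 7) when a second
Emesinae fossil is included (B3), exponential(mean 10.5) with a hard
25 Ma minimum when it is not (B2). Decimal commas in the transcribed
source were normalised to decimal points, and the readers normalise them
on input as well. Running the congruence stage on this fixture reproduces
all 14 recorded decisions (12 not rejected, 2 rejected) with the default
rule.

## The calibration-sensitivity regression

`precision_regression()` fits, per dating analysis, ordinary least squares
of the 95% interval width `w` on the mean node age `m`. The slope is the
rate at which dating uncertainty grows with age; comparing slopes across
analyses with increasing calibration counts shows whether added fossils
tighten the estimates. Analyses are compared on their shared node set only
(others are dropped with a warning), and at least three shared nodes are
required. `tidy()`, `glance()` and `autoplot()` expose coefficients, fit
statistics and the standard width-versus-age panel.

## The synthetic-data generator

The generator exists to give every stage a ground truth; it emulates the
statistical structure of real inputs, not their full complexity.

* **Trees**: forward birth–death simulation, frozen one event-free waiting
  time after the extant count first reaches `n_tips` (so terminal branches
  are positive), resampled up to 1,000 times on total extinction. Defaults:
  birth 0.15/Myr, death 0.05/Myr, 20 tips — tree heights of a few tens of
  Myr, the scale of the empirical system.
* **Ranges**: independent per-area gain/loss (default 0.02/Myr each) along
  branches from a root range, with forced disjoint splits at designated
  *implanted vicariance* nodes. A loss that would empty a lineage's range
  is suppressed and counted, rather than resampling the subtree: observed
  ranges must be non-empty for DIVA, and suppression keeps the recorded
  truth consistent with the history that actually generated the tips.
  Implanting at a node whose range has drifted to a single area is an
  error (a singleton cannot split), so implantation scenarios favour
  cherries — nodes whose two children are tips — whose subtrees are
  disjoint (`cherry_nodes()`).
* **Pseudo-posteriors**: for each node of true age `a` and analysis label,
  lognormal samples with mean exactly `a` and coefficient of variation
  equal to the label's noise scale (defaults 0.4, 0.25, 0.15 for B1, B2,
  B3). Interval widths therefore grow proportionally with node age and
  shrink as calibrations are added — the qualitative structure seen when
  one, six and seven fossil calibrations are compared — without simulating
  any MCMC. Lognormality keeps ages positive.
* `perturb_node_ages()` produces pseudo-replicate datings of one topology
  (lognormal noise on the root age, logit-normal noise on each child/parent
  age ratio), preserving ultrametricity and node ordering — the cheap
  stand-in for topologies that agree on clades but differ in ages.

All randomness flows through the supplied seed; identical configurations
reproduce byte-identical outputs.

### Validation regimes and problem sizes

The recovery suites run in regimes chosen for identifiability, and it is
worth being explicit about why. Ancestral-state recovery is only a
well-posed check when the expected number of range changes per root-to-tip
path is well below one: at the generator's general-purpose default
(0.02/Myr, roughly one change per path) the root pattern is genuinely not
identifiable from 20 tips, and the posterior honestly spreads over
neighbouring patterns — no correct sampler could concentrate 0.8 of its
mass on the truth. The BBM and consensus recovery suites therefore use
gain = loss = 0.005/Myr (about 0.15 expected changes per path) with the
known generating rates supplied to the sampler. Under those conditions the
true root pattern receives at least 0.8 posterior mass in well over 80% of
seeded replicates, and the consensus filter recovers on average more than
2 of 3 implanted vicariance nodes through a full 16-member grid.

Validation problem sizes were chosen as the smallest that make the checks
statistically meaningful: DIVA–oracle equivalence on 200 random instances
(≤ 6 tips, ≤ 3 areas, where exhaustive enumeration is feasible); HPD
coverage on 500 replicates of 2,000 draws; BBM recovery on 20 replicates
of 20 tips × 3 areas at the default 50,000 generations; consensus recovery
on 20 replicates of a 16-member grid at 5,000 generations per BBM run
(the chains at this size mix long before that, as the run-agreement
diagnostic shows).

## Known limitations

* BBM treats areas independently; jointly constrained ranges (e.g. a
  fixed maximum range size during sampling) are not modelled, and the
  independence product can overstate the probability of unobserved area
  combinations — hence the joint root posterior for root-level questions.
* DIVA has no time stratification and no founder-event speciation; DEC-type
  likelihood models are out of scope.
* `discordant_taxa()` is a greedy approximation to a minimal discordant
  set; it is exact on small perturbations but not guaranteed minimal in
  general.
* The pseudo-posterior generator reproduces width-versus-age structure but
  not between-node correlations of real dating posteriors, so tests built
  on it validate interval arithmetic, not MCMC behaviour.
* The congruence decision is a pure overlap rule on pre-computed intervals;
  it does not model the joint uncertainty of event ages and node ages.
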