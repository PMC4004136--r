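---
title: "Measuring dissemination potential and message diffusion on follower networks"
author: "disseminet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dissemination potential and message diffusion on follower networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disseminet)
```

## The problem

Health organizations use broadcast platforms such as Twitter to push
information to the public, and a recurring question in infodemiology is how
far a message *could* travel through an organization's follower network
versus how far it *actually* travels. `disseminet` implements the standard
social-network-analysis toolkit for that question on a directed follower
graph: audience-size metrics, follower overlap and cohesion, activity-based
pruning, per-tweet propagation measurement, and diffusion simulation under
the independent cascade model. Because platform snapshots of this kind are
not redistributable, the package also ships generators that produce
reference topologies and realistic multi-organization fixtures, so the
whole pipeline is testable offline.

## The graph convention

A `follow_graph` stores edges in the direction information flows: an edge
$u \to v$ means $v$ follows $u$ and therefore receives $u$'s messages.
Diffusion is then a breadth-first process over out-edges. Each account
carries two distinct audience numbers that are never conflated:

* `declared_follower_count` — the platform-reported global follower count,
  which may exceed anything visible in the graph at hand (harvested graphs
  are samples);
* `structural_follower_count` — the out-degree actually present in the
  graph.

All potential metrics default to declared counts, because second-hop
audiences of a sampled graph live mostly outside the sample; every such
function accepts `mode = "structural"` for the in-graph variant.

## Dissemination metrics

For an organization with follower set $F$, the **Level-2 follower sum** is
$\sum_{f \in F} c(f)$ where $c(f)$ is $f$'s follower count, and the
**dissemination potential** is

$$ P = |F| + \sum_{f \in F} c(f), $$

the theoretical audience if every follower retweeted once and no two
followers shared a listener. The no-overlap assumption is part of the
metric's definition, so no deduplication is applied; `unique_reach()`
provides the exact deduplicated two-hop set size for graphs where the
second hop is materialized. The organization's own account is never counted
in its follower set or potential.

**Overlap** between two follower sets is
$|A \cap B| / \min(|A|, |B|) \times 100$, undefined (an error) when either
set is empty. **Group cohesion** is the number of neighbors common to every
member of a group divided by the group's total distinct neighbors,
computed on the undirected projection. Two choices here were genuinely
open. First, the common-over-total phrase could also be read as an average
of pairwise Jaccard indices; we implement intersection-over-union of the
whole group and expose `pairwise_jaccard()` separately, without claiming
one reading is canonical. Second, members are excluded from each other's
neighbor sets, so mutual follows inside the group cannot inflate cohesion;
with no exclusion a clique would be maximally cohesive regardless of its
surroundings. Clustering coefficients are likewise computed on the
undirected projection (triangles are direction-agnostic), with nodes of
degree below 2 assigned 0 rather than NaN.

**Actual dissemination** of one tweet is the summed declared follower
counts of the accounts that retweeted it — again no deduplication, and
neither the organization's first-hop audience nor the retweeter count
itself is added, which keeps the number directly comparable to $P$ through
`fraction_of_potential()`. Published tables of such fractions mix
precisions; `format_fraction()` renders 3 significant figures, dropping to
2 below $10^{-4}$, and percentage comparisons round half-to-even at the
printed number of decimals.

**Pruning** removes every follower with tweet count $\le t$ together with
its Level-2 contribution; the threshold is inclusive ("only $t$ or fewer
tweets"), so $t = 0$ removes exactly the never-tweeted followers, and
`max_tweets = NULL` prunes nothing. Percent reduction is monotone
non-decreasing in $t$, and the pruned potential provably equals the
potential recomputed on the graph with those followers deleted — both
facts are property-tested.

## Diffusion simulation

`flood_diffusion()` is deterministic BFS: everyone who receives forwards.
Hop numbering starts at 1 for direct followers. Redundant receptions count
every delivery beyond a node's first, and `messages_sent` totals the
out-degrees of all forwarding nodes — on a star fired from the center this
is exactly $n-1$ messages with zero redundancy, the efficiency benchmark.

`independent_cascade()` implements the classic node-centric model: each
newly reached node forwards once with fixed independent probability $p$
(one coin per node, not per edge — the model describes a *person* deciding
whether a message is worth resending). Two implementation choices matter:

* **Coupled coins.** All node coins are drawn from the seed alone, before
  $p$ is consulted; a node fires iff its uniform is below $p$. Runs at the
  same seed are therefore monotone in $p$ by construction
  ($\mathrm{reached}(p_1) \subseteq \mathrm{reached}(p_2)$ for
  $p_1 \le p_2$), and $p = 1$ coincides *exactly* with flood diffusion,
  coin for coin. Both properties are asserted in the test suite rather
  than merely expected in distribution.
* **Explicit seeds everywhere.** Every stochastic entry point takes a seed
  and restores the caller's RNG state on exit. `cascade_experiment()`
  derives replicate $r$'s seed as `seed + r - 1` and reuses one coin set
  across the whole $p$ grid within a replicate.

Monte-Carlo checks compare mean reach against exhaustive enumeration over
all $2^k$ coin outcomes on graphs small enough to enumerate ($k \le 12$
potential firers), with a 3-standard-error acceptance band at 10,000
replicates. Multi-hop audience estimates beyond the second hop are
available only through this simulator; no closed-form third-hop metric is
offered, since the potential metric itself is defined at two hops.

## What the generators emulate

`make_star()`, `make_random()` and `make_power_law()` produce the three
reference topologies used to reason about diffusion efficiency: the star
(instant one-hop broadcast from the center, zero cohesion, nothing from the
periphery), the Erdős–Rényi random graph (binomial degrees, no hubs,
redundant messaging), and the power-law graph (hubs plus low diameter —
the small-world shape that follower graphs empirically resemble). The
power-law generator draws out-degrees from a discrete power law via the
continuous inverse-transform approximation and wires targets uniformly
(configuration-model style), capping degrees at $n - 1$. A
maximum-likelihood fit (`igraph::fit_power_law`) recovers a configured
exponent of 2.3 within ±0.3 at $n = 5000$; the floor discretization biases
the fitted exponent slightly upward at small minimum degree, which the
tolerance absorbs.

`make_twitter_fixture()` emulates the data shape of a multi-organization
follower study: $K$ organization accounts, follower sets of requested
sizes, exact pairwise overlaps (shared followers drawn from a common pool
before group-specific remainders are filled, then verified to within 2
percentage points), heavy-tailed declared follower counts with
per-organization target medians, and zero-inflated discrete-lognormal
tweet activity. The defaults are the conditions of the motivating study's
three mid-sized physician associations: follower-set sizes 7546 / 5955 /
11,768, audience-size medians 120 / 165 / 81, zero-activity masses 6.92% /
7.22% / 8.17%, and 25% pairwise overlap — the midpoint of the 13–55% band
such communities exhibit. Organization tweet volumes default to 2788 /
2979 / 1184. The activity law's positive part (median 200 tweets,
log-sd 1.5) is our own choice of a realistic heavy-tailed account-activity
profile; only zero masses and audience medians were reported quantities.

Known departures from real data, hence limits on what passing tests show:

* Fixture graphs are two-level (organization → follower edges only);
  followers' own audiences exist as declared counts, not materialized
  edges. Cascade simulations beyond hop 1 are therefore exercised on the
  topology generators, not on fixtures.
* Overlap is realized pairwise; no higher-order (three- or four-way)
  intersections are generated unless configured implicitly through shared
  pairs. The all-groups intersection metric is tested on hand-built
  profiles instead.
* A follower belonging to several groups draws its attributes from its
  first group's law, so realized per-group medians under overlap are
  mixtures and only approximate the targets.
* Audience size and activity are sampled independently, so fixtures do not
  reproduce the empirical pattern that silent followers tend to have small
  audiences; tests of that pattern construct the correlation explicitly.

## Numerical and interface choices

Account ids are opaque strings (handles like `@AAFP` pass through
verbatim). CSV I/O is RFC-4180 with UTF-8; thousands separators are
accepted on read and never written. All writers sort output, so identical
invocations yield identical bytes. Reading a network strictly rejects edge
endpoints absent from the account table; lenient mode registers them with
zeroed attributes and says how many. Rows flagged disabled, private, or
unrecognizable are excluded and tallied so the cleaning step is auditable.
Degenerate inputs are flagged, not silently dropped: diameter of a graph
with unreachable pairs is `Inf` in strict mode, cohesion of an all-isolated
group is `NA` with `defined = FALSE`, and percent reduction is undefined
when the unpruned potential is zero.

Problem sizes in the test suite were chosen to make every stochastic check
decisive at desk scale: goodness-of-fit at $n = 2000$, exponent recovery
and reach monotonicity at $n = 5000$, enumeration oracles at $\le 9$
nodes with 10,000 Monte-Carlo replicates.

## A worked pass

```{r example, eval = FALSE}
fx <- make_twitter_fixture(fixture_config(seed = 2026))
characterize_orgs(fx$graph, fx$profiles)
prune_sweep(fx$graph, fx$profiles[[1]], thresholds = c(NA, 0, 10))

g <- make_power_law(2000, exponent = 2.3, min_degree = 1, seed = 1)
cascade_experiment(g, sources = "0", p_values = c(0, 0.1, 0.5, 1),
                   reps = 20, seed = 99)
```

## Limitations

The package measures structure, not content: nothing here models why a
message is retweeted, tie formation or decay over time, reciprocal-follow
probability, or followers who miss messages by checking sporadically.
Potentials are theoretical upper bounds under the no-overlap assumption
and should be read as such — the gap between `dissemination_potential()`
and `actual_dissemination()` is typically orders of magnitude, and that
gap is the finding, not an error.
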