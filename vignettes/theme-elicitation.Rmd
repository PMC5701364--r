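---
title: "Eliciting themes from multi-sorter card sorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting themes from multi-sorter card sorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themesort)
```

## The method

`themesort` turns the pile sorts of several lay co-researchers into one
set of thematic groups. The input is deliberately minimal: a long-format
table with one row per (participant, excerpt, pile) assignment, the shape
in which a sorting session is naturally recorded in a spreadsheet. Pile
labels carry no meaning across participants — `Gp2` from one sorter and
`Gp2` from another are unrelated — and the package never compares them
across sorters.

The combination step is a network construction. For each of the
$n(n-1)/2$ unordered excerpt pairs, the **similarity score** $s(a,b)$
counts the sorters who placed $a$ and $b$ in the same pile. Any pair with
$s \ge 1$ is joined by a tie carrying the **conceptual distance**
$d = 1/s$: a pair everyone co-sorted sits at distance $1/m$, a pair
co-sorted once sits at distance 1, and a pair nobody co-sorted has no tie
at all. Score-0 pairs are represented by the *absence* of an edge rather
than an infinite-distance sentinel; shortest-path routines treat the
resulting unreachability directly, which keeps the arithmetic honest for
disconnected networks.

Groups are found by Girvan–Newman edge removal: compute the weighted
**edge betweenness** of every tie (the fractional count of shortest
paths, by conceptual distance, crossing it, once per unordered node
pair), delete the single highest tie, recompute, and repeat until no ties
remain. Every deletion that splits a component records a new level of a
nested dendrogram, from the connected components of the full network down
to singletons.

Two weight conventions coexist deliberately. Path computations use
*distances* ($1/s$): betweenness should be high on ties joining
conceptually distant regions. Partition assessment uses the raw *scores*
as affinities, via weighted modularity
$$Q = \sum_c \left[ \frac{W_{in}(c)}{W} - \left(\frac{S_c}{2W}\right)^2 \right],$$
where $W$ is the total score mass, $W_{in}(c)$ the score inside community
$c$ and $S_c$ its summed node strengths. Using distances in $Q$ would
reward cutting exactly the strong ties the themes are built from.

## Choosing the cut

The dendrogram does not choose its own level, so `select_partition()`
defaults to the level with maximal weighted modularity, taking the
earliest level on ties. This default matters — it decides how many themes
come out — and it is therefore overridable: `k = 4` returns the first
level with exactly four communities. On the package's four-item worked
example the maximum sits at level 0 ($Q = 0$ for the single community,
negative for every split), so the sort resolves to one theme, which is
the expected behaviour for a network with no internal cleavage.

After the cut, communities of size $\ge 2$ become groups, numbered in
decreasing size (ties by smallest member label). Singleton communities
and isolated nodes are reported as **unassigned**: excerpts sorted so
inconsistently that they belong to no theme, which in practice marks them
as cross-cutting and worth individual reading.

Determinism is enforced throughout. When several ties share the maximal
betweenness (within a relative tolerance of $10^{-12}$, the same
tolerance used to declare alternative path lengths equal), the
lexicographically smallest (min label, max label) tie is removed. Equal-
length shortest paths share betweenness fractionally, the standard
dependency-accumulation convention. Identical input therefore yields an
identical dendrogram, clustering and report on every run.

## Key quotes

Within each group, the excerpt with the lowest mean weighted distance to
its group-mates is the **key quote by closeness** — the theme's most
representative voice. Closeness is computed on the subgraph induced by
the group: the quote competes only against the other quotes of its own
cluster, and ties wholly outside the group cannot shift the ranking
(`scope = "global"` switches to full-network paths, since the framing is
genuinely ambiguous). The **key quote by betweenness** maximizes
unnormalized weighted node betweenness on the full network, because
bridging is a property of the whole sort, not of one cluster
(`scope = "cluster"` restricts it). Arg-min/arg-max ties are reported in
full, never broken silently — equivalently central quotes are a real
outcome, not an error. Unassigned excerpts appear in the report with no
flags and no mean distance.

A group supplied by hand whose induced subgraph is disconnected has no
defined within-group distances; this raises an error naming the group.
Dendrogram-derived groups are always internally connected, so the guard
only fires for external clusterings.

## Preservation

A sorter's pile is *preserved* when all of its excerpts land in a single
final group; a pile containing an unassigned excerpt is never preserved.
Per sorter, the package reports total piles, multi-excerpt piles and
preserved piles; preserved $\le$ multi $\le$ total holds by construction.
Singleton piles are excluded from the preserved count by default — they
are trivially coherent and would inflate the diagnostic — but
`count_singletons = TRUE` implements the alternative reading, and
`low_preservation_flags()` can use either denominator. Sorters with low
preservation ratios sorted a genuinely different structure; the intended
use is qualitative follow-up, not exclusion.

## The simulator and what it does (not) show

Real multi-sorter pile data are rarely shareable, so the package carries
its own generative model for validation. A `planted_design()` fixes $n$
excerpts grouped into $K$ latent themes; each of $m$ sorters starts from
that partition and independently distorts it:

- with probability `p_merge`, merges one random pair of piles (a lumper's
  reading) — skipped if fewer than three piles remain, so every sorter
  keeps the minimum of two;
- with probability `p_split`, splits one random pile of $\ge 4$ excerpts
  into two parts of $\ge 2$ (a splitter's reading);
- each excerpt then moves to a uniformly chosen *other* pile with
  probability `epsilon` (idiosyncratic noise), so `epsilon` is exactly
  the expected fraction of displaced excerpts — a property the tests
  verify by Monte Carlo.

Defaults are one realistic sorting session: $n = 40$, $m = 8$, $K = 4$
with a near-even theme-size split, `p_merge = p_split = 0.2`,
`epsilon = 0.1` — sorters mostly reproduce the latent structure, about
one in five lumps or splits a theme, one in ten excerpts lands somewhere
surprising. Randomness derives from one root seed with fixed per-sorter
offsets, so enlarging the panel never perturbs earlier sorters' draws,
and the generator restores the caller's RNG state.

The validation suite runs this model at sizes chosen for sharp inference
at desk scale: 200 random graphs of $\le 8$ nodes against an exhaustive
path-enumeration betweenness oracle, 100 exact-recovery trials with
identical sorters (where the network is a disjoint union of cliques and
the planted partition must return with adjusted Rand index 1), and 200
replicates per noise level $\varepsilon \in \{0, 0.1, 0.3\}$ checking
that mean recovery never increases with noise (two-Monte-Carlo-SE
tolerance).

What passing these tests does **not** show: the generator plants
equally-coherent, non-overlapping themes and independent sorters. Real
sorters share reading order, fatigue and conversation; real themes
overlap, and excerpts can be genuinely multi-thematic — the unassigned
category absorbs some of this, but the simulation cannot certify how
much. Results on real data should always be read alongside the
preservation table, which is the package's only window onto systematic
sorter disagreement.

## Numerical and degenerate cases

- Path-length and betweenness ties: relative tolerance $10^{-12}$;
  key-quote ties: relative tolerance $10^{-9}$ on the mean distances.
- An edgeless network yields a one-level dendrogram of isolated
  singletons and $Q = 0$ for every partition, by convention.
- Incomplete sorts (a participant missing excerpts) are a hard error by
  default; `allow_incomplete = TRUE` scores only observed co-assignments,
  leaving $n$ unchanged.
- The "at least two piles" instruction binds sorters, not data:
  `validate_protocol()` warns, never errors.
- `K = 1` designs are rejected: a single planted theme cannot honour the
  two-pile minimum.

## Limitations

Only one community-detection algorithm is implemented; the dendrogram
and modularity machinery would support alternatives (Louvain, label
propagation), but comparing algorithms is out of scope here. Theme
*naming* and interpretation are human steps: the package surfaces
groups, key quotes and diagnostics, not meaning. And modularity
maximization over dendrogram levels, while the natural default, is a
package choice the analyst should know about — report `k` explicitly
whenever the cut was forced.
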