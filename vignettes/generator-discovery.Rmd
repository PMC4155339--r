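---
title: "Discovering network growth rules by symbolic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering network growth rules by symbolic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgp)
library(igraph)
```

## The problem

Many networks — neural wiring, protein interactions, social ties — are the
outcome of a decentralised growth process. Given only an observed network,
netgp searches for a *generator*: a small symbolic rule that, driving a
stochastic arc-by-arc growth process, reproduces the network's structure.
Because generators are ordinary mathematical expressions, a successful
search yields an interpretable model rather than a black-box fit.

## Generators and the growth process

A generator is an expression tree over arithmetic operators
(`+ - * / pow exp log abs min max`), branching comparisons
(`gt lt eq eq0`), an affinity function `psi`, numeric constants, and
per-arc variables. Evaluated on a candidate arc $(i, j)$ it returns a
weight $w_{ij}$.

Growth starts from $n$ isolated nodes with sequential identifiers
$1..n$ and adds one arc per step until $m$ arcs exist. At each step a
random sample $S$ of non-existing, non-self arcs is drawn
($|S| = \max(\text{min\_sample}, \lfloor s_r n^2 \rceil)$) and one member is
selected with probability

$$P_{ij} = \frac{\pi(w_{ij})\, w_{ij}}{\sum_{(u,v) \in S} \pi(w_{uv})\, w_{uv}},
\qquad \pi(w) = \begin{cases}1 & w > 0\\ 0 & \text{otherwise,}\end{cases}$$

with all weights replaced by 1 when none is strictly positive (so a rule
like "the target's degree" can bootstrap itself on an empty network).
Self-links and duplicate arcs are never created; nodes do not arrive over
time.

The variables available to a program are the endpoints' degree
descriptors ($k$: origin out-degree, $k'$: target in-degree; plain degrees
in undirected mode, where only $k$ is legal), the identifiers $i$ and $j$,
and heuristic hop distances $d$ (undirected view), $d_D$ (along arcs) and
$d_R$ (against arcs). Two one-node programs express classical models:
a positive constant is uniform random attachment (the Erdős–Rényi growth
limit) and `k'` is preferential attachment. Identifier-based rules encode
a-priori node heterogeneity — `(/ 1 i)` gives hyperbolically distributed
propensities, and `(psi g a b)` returns `a` when $i \equiv j \pmod g$ and
`b` otherwise, encoding `g` affinity groups.

```{r quick-example}
set.seed(1)
pa <- parse_program("k'")
g <- generate_network(pa, n = 100, m = 1000)
max(degree(g, mode = "in"))   # a hub, unlike the ER value of ~20
```

### Heuristic distances

Distances are estimated by bounded random walks rather than BFS: linking is
modelled as hop-by-hop navigation, and exact all-pairs distances inside the
innermost loop would be prohibitively expensive anyway. Each query runs
`walks` (default 5) independent walks of at most `walk_length` (default 7)
hops and reports the earliest hop at which any walk hits the target, or the
cap `walk_length + 1`. Estimates therefore never undershoot the true
distance and sharpen as the budget grows. The defaults keep per-candidate
cost constant and resolve the short distances that dominate dense growth
experiments; both are exposed in `growth_config()`.

### Protected evaluation

Evolution must never crash on a pathological expression, so operators are
protected: division by zero and `log` of a non-positive value return 0,
`pow` uses the absolute value of its base, and every node's result has NaN
collapsed to 0 and magnitude clamped to $10^{300}$. Evaluation is total and
pure. Comparisons are branching forms — `(gt a b t f)` returns `t` or `f` —
keeping the language numerically closed without booleans; whether the
original formulation returned indicator values instead is not documented,
and the branch form was chosen because it subsumes the indicator as
`(gt a b 1 0)`.

## Scoring a candidate network

A candidate is compared to the target on feature distributions: in- and
out-degree, direct and reverse PageRank (damping 0.85), directed and
undirected shortest-path distance distributions (with an explicit
unreachable bucket; exhaustive BFS up to 1000 nodes, 1000 sampled sources
beyond), and the triadic profile (13 connected directed triad classes, or
open-triple/triangle frequencies undirected). Undirected networks use the
four applicable features.

Degree and PageRank distributions are compared with the 1-D Earth mover's
distance (degree on the shared integer support; PageRank on 50 equal-width
bins spanning both value ranges — the binning is a package choice).
Distance distributions and triadic profiles use a cheaper ratio-based
dissimilarity: with add-one smoothing of raw counts,
$\text{mean}_i\,[\max(x_i{+}1, y_i{+}1)/\min(x_i{+}1, y_i{+}1) - 1]$.
The formula is isolated in `ratio_dissimilarity()` so an alternative is a
one-line change.

Each raw dissimilarity $D_m$ is divided by $b_m$, the mean dissimilarity
between the target and 30 size-matched $G(n,m)$ networks, putting all
metrics on a scale where 1 means "no better than random". The fitness of a
candidate is $\max_m D_m / b_m$, and the search minimises it. An ER
baseline rather than, say, the configuration model is deliberate: a null
model that already copies the degree distribution could never be improved
upon along that axis.

A property worth knowing: because fitness is the *maximum* of several
noisy ratios, its expectation for an ER candidate against an ER target is
not 1 but roughly 1.4–1.8 (each ratio is centred on 1, and the max of
several such ratios with 15–80% relative noise sits well above 1; the
sparse tails of distance and triad counts are Poisson-noisy). The
normalization is still sound for its purpose — all candidates are ranked
under the same statistic — but the minimax fitness should not be read as
an unbiased "times better than random" figure.

## The evolutionary search

The search keeps just two individuals: `w_o`, the best-fitness program so
far, and `w_s`, the shortest evaluated program whose fitness is within the
anti-bloat tolerance (10%) of `w_o`'s. Each generation clones a parent
picked uniformly from $\{w_o, w_s\}$, mutates it by replacing a uniformly
chosen sub-tree with a sub-tree extracted from a fresh random tree, grows
*one* synthetic network at the target's size, and scores it. `w_o` is
replaced only on strict improvement (ties keep the incumbent, so stalls
are honest); `w_s` is re-derived from the archive of every evaluated
program whenever the state changes, which lets previously seen short
programs re-qualify when `w_o` improves. The run stops after `stall_limit`
(default 1000) generations without change and returns `w_s` — program
length is the model-complexity measure, and the tolerance trades a little
precision for interpretability.

Random trees use grow-style generation with maximum depth 5, terminal
probability 0.4, constant probability 0.3 and constants uniform on
$[-5, 5]$ — conventional genetic-programming settings, exposed as
arguments; the original experiment's exact values are not published and
search outcomes are robust to them.

```{r search, eval = FALSE}
target <- make_fixture("PA", n = 100, m = 1000, seed = 42)$network
res <- evolve(target, stall_limit = 200, seed = 7)
format_program(res$w_s)
```

## Comparing generators behaviourally

Two syntactically different programs may encode the same behaviour
(`k'` and `(* 2 k')` assign identical selection probabilities). The
behavioural distance grows a network with $w$ while $w'$ shadows it: at
every step both programs assign probabilities to the same candidate
sample, and the absolute probability differences are averaged over all
candidates and steps, giving $d_{ww'}$; the converse run gives $d_{w'w}$
and $d = (d_{ww'} + d_{w'w})/2$. The per-candidate distance
($|P - P'|$) and the replicate count (3 per direction) are package
choices; the measure is zero for behaviourally identical programs and
scale-invariant by construction.

Recovery experiments classify a found program as *correct* when its $d$ to
the canonical generator is below a threshold. A natural-looking
calibration — the dissimilarity of the canonical generator with itself —
is degenerate (it is exactly zero on shared samples), so the threshold is
instead set to half the measured separation between the two canonical
rules (ER vs PA) at the experiment's size: the midpoint of the only
behavioural contrast the experiment defines. *Exact* recovery additionally
requires the canonical syntax, with any positive constant accepted as the
constant generator.

## What the built-in fixtures do and do not cover

`make_fixture()` produces ER, PA, hyperbolic-identifier and affinity-group
networks at the five preset sizes (100/1000 up to 500/5000 nodes/arcs,
linear steps). These span homogeneous, degree-driven and
identifier-heterogeneous growth, which is what the recovery experiments
need. They do not emulate real-world features such as spatial constraints,
assortative mixing by attributes, or node arrival over time; passing
recovery tests on fixtures shows the machinery can re-identify known rules,
not that every real network has a concise generator.

Desk-scale settings used in the automated checks: 10 searches per
canonical generator at $n=100$, $m=1000$ with the stall limit reduced to
200 generations. At that scale correct-recovery rates reach the expected
near-total level, while exact (bloat-free) rates sit well below full-scale
runs — shorter runs leave less time for the anti-bloat rule to find the
minimal program after the behaviour has converged.

## Numerical and degenerate-input choices

* Sampling uses rejection with a duplicate filter; when fewer legal arcs
  remain than the nominal sample size, the sample is the full remainder,
  and a complete network raises an error before any work.
* A zero ER baseline for a metric yields ratio 0 when the candidate's
  dissimilarity is also 0, else infinity — surfacing, rather than hiding,
  a degenerate normalization.
* All stochastic draws (R and C++ alike) flow from R's RNG, so
  `set.seed()` reproduces networks, searches and dissimilarities exactly.
* Networks read from files must be simple: self-loops and duplicate arcs
  are rejected with the offending location, since the growth model cannot
  produce them.

## Known limitations

* Mutation-only, two-individual search can stall in local minima; the
  archive and anti-bloat rule mitigate bloat but not multimodality.
  Population-based or recombining searches are deliberately out of scope.
* The triadic profile uses raw class frequencies, not z-scores against a
  randomized ensemble — a deliberate cost choice inside the innermost
  loop.
* The minimax fitness is upward-biased for near-random candidates (see
  above); comparisons across different targets should use the per-metric
  ratios, not the single fitness number.
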