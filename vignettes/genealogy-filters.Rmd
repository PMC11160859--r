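---
title: "Genealogy processes and filter-equation likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogy processes and filter-equation likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genfilter)
```

# The model class

`genfilter` computes exact likelihoods of time-calibrated genealogies under
discretely structured Markovian population models. A model is a jump process
on an integer lattice of population states, together with:

* a set of **demes** indexed $i \in \mathbb{D}$ — subpopulations within
  which lineages are exchangeable (in an SEIRS model, the incubating hosts
  $E$ and the infectious hosts $I$);
* a **deme occupancy** $n_i(x)$: how many lineages live in deme $i$ when the
  population is in state $x$;
* a set of **jump marks** $u$, each with hazard $\alpha_u(t,x)$, a
  deterministic state update, and a *participant descriptor* saying how many
  lineages act as birth parent, offspring, migrants, samples, or deaths.

From the descriptor the package derives each mark's **production** $r^u$:
the per-deme number of lineages that *emerge* from (descend from a node
inserted at) one event of that mark. All offspring count, migrants count in
their destination deme, a surviving parent counts, surviving sampled
lineages count; dying lineages never count. The production is a fixed
integer vector per mark — this is what makes the likelihood theory work,
and `validate_model()` checks that each mark's state update moves occupancy
exactly as its descriptor claims.

Seven example families ship with the package (`builtin_model()`): SIRS,
SEIRS, two-strain competition, complex infection progression,
superspreading, the Moran model, and the linear birth-death-sampling
process. The last two anchor the classical phylodynamic likelihoods and
serve as oracles for everything else.

# The genealogy process, pruning, and obscuring

`simulate_genealogy()` runs the Gillespie algorithm and grows the genealogy
alongside the population: births insert a branch node above a uniformly
chosen parent tip of the parent deme; migrations insert an inline
(single-child) node and recolor the lineage below it; sampling inserts
sample nodes; deaths delete tips and recursively remove childless
non-sample nodes; neutral events do nothing. Lineage selections are uniform
within deme and independent across events — the exchangeability assumption
that the likelihood formulas rest on.

Real data never show the full genealogy. `prune()` reduces it to the
sample-spanning colored subtree: tips are dropped and childless non-sample
nodes removed recursively, while inline nodes *on surviving paths are
kept*. These inline nodes matter: each records a real population event (a
migration, or a birth whose other descendants left no samples), and the
colored filter treats each one as a genuine event with its own update.
`obscure()` then erases demes and splices out non-sample inline nodes,
leaving only branch points and samples with their times — the information
content of a dated phylogeny.

All interval conventions are right-continuous: an edge lives on
`[parent_time, child_time)`, the lineage count `lineage_count(p, t)` is the
post-event value at an event time, and `saturation(p, t)` counts the
lineages emerging from nodes at exactly `t`.

# Likelihoods

## Given the history

Conditional on the complete population history, the probability of a
colored pruned genealogy is a product of per-event weights
(`loglik_given_history()`): for an event of mark $u$ at post-jump state $x$,

$$\phi_u = \frac{\prod_i \binom{n_i(x)-\ell_i}{r_i^u-s_i}}
                {\prod_i \binom{n_i(x)}{r_i^u}} \, Q_u,$$

where $\ell$ is the lineage count, $s$ the saturation, and $Q_u$ the
0/1 compatibility of the mark with the local tree structure (a branch
point needs a birth-type mark with matching parent deme and enough
production; a sample node needs the right sampling mark; an event with a
sampling component can never leave the pruned tree unchanged). The
binomial ratio is the exchangeability probability that the event's
emergent lineages intersect the observed genealogy exactly as recorded; by
the Chu–Vandermonde identity its normalization over saturations is exact,
and the test suite verifies this in integer arithmetic.

## Filter equations

Unconditionally, the likelihood solves a linear *filter equation*: between
genealogical events a weight vector over population states obeys a linear
ODE (gain terms for jumps that leave the tree unchanged, loss at the total
event rate), and at each event it is hit by a sparse multiplicative update
built from the $\alpha_u \phi_u$ factors. `filter_forward()` integrates
from the initial distribution and sums at the horizon;
`filter_adjoint()` integrates the adjoint system backward from the
terminal condition 1 and contracts against the initial distribution. The
two agree to integration tolerance on every valid input — a strong
internal consistency check, since they share only the generator assembly.

Two modes exist, dispatched on the tree class:

* **colored** (`pruned_genealogy`): the deme history and every inline node
  are part of the data. Off-event gains use saturation 0 only — a birth
  off a tree lineage *would have left an inline node*, so its absence is
  informative.
* **obscured** (`obscured_genealogy`): the weight gains a hidden
  coordinate, the deme assignment of each current lineage, and the regular
  part also carries *hidden-inline* transitions: births whose parent is a
  tree lineage (continuing as parent or as one of the offspring) and
  migrations of a tree lineage. For the Moran model this marginalization
  reproduces the textbook coalescent coefficient
  $\mu\,(1 - \binom{\ell}{2}/\binom{n}{2})$ between events and
  $\mu/\binom{n}{2}$ at branch points, which the tests check exactly for
  $n \le 6$.

Because a colored tree *asserts* a complete inline-node record while an
obscured tree marginalizes hidden inlines, the two modes answer different
questions even for single-deme models, and their values differ. The
closed forms below correspond to the obscured reading.

Scheduled sampling at the horizon is supported in two flavors: binomial
(each lineage of a deme sampled independently with probability $\rho$,
the linear birth-death convention, singular factor
$\binom{n_i}{m}\rho^m(1-\rho)^{n_i-m}$) and fixed-count (the classical
"take $m$ of $n$ now" Kingman setting, conditioned on, factor 1).
Likelihoods follow the ordered-samples convention: $m$ simultaneous
samples carry a $1/m!$ relative to an unordered convention. This drops
out of inference but matters when comparing against other software.

## Closed forms

`kingman_loglik()` and `moran_serial_loglik()` evaluate the Moran-model
likelihoods: branch points contribute $\mu/\binom{n}{2}$, terminal
serial samples $\psi(1-\ell(t)/n)$ (with the *post-event* lineage count —
the convention is fixed by requiring exact agreement with the filter),
inline samples $\psi/n$, and the regular part contributes the
coalescent-interval decay **plus a $-\psi T$ survival term** for observing
no further samples. The survival term is forced by the filter equation
(sampling marks contribute loss but no off-event gain) and by the exact
agreement, to $10^{-8}$, between `moran_serial_loglik()` and
`filter_obscured()` on simulated trees.

`lbd_loglik()` evaluates the linear birth-death-sampling likelihood via
two auxiliary functions $G$ and $H$ solving a final-value problem
($G(T)=1-\rho$, $H(T)=1$; $G$ is the probability a lineage leaves no
sampled descendants). The package integrates the ODEs numerically
(adaptive Dormand–Prince, default relative tolerance $10^{-10}$) rather
than using the textbook closed form, so that time-varying extensions stay
within reach; the tests verify the ODE residual by finite differences and
the boundary conditions directly.

## Sequential Monte Carlo

`smc_loglik()` estimates the obscured-genealogy likelihood without
enumerating the hidden space: particles carry a population state and a
deme assignment of the current lineages; population jumps are proposed
from the model; hidden involvement options (none, hidden birth off lineage
$k$ continuing in deme $d$, hidden migration of lineage $k$) are drawn
from the uniform kernel and reweighted by $\phi \times \#\text{options}$;
at each observed node the event is forced, with the summed density
$\sum_u \alpha_u \phi_u$ as weight and the outcome drawn proportionally.
Uniform kernels are the sanctioned default; the enumeration of locally
compatible options is the algorithm's core data structure. Systematic
resampling triggers below an effective-sample-size fraction (default 0.5).
Particles are split into independent groups (default 10) so the reported
standard error comes from genuinely independent replicate estimates; the
estimate is the log of the mean of the group likelihoods, each unbiased on
the natural scale.

Two practical notes. First, a proposal jump of a sampling mark between
observation times kills the particle (such a history is genuinely
incompatible with the data), so high sampling rates raise estimator
variance — the price of the plug-and-play bootstrap proposal. Second,
hidden marginalization of marks that migrate several lineages at once is
not implemented (no builtin model needs it); the filter and SMC refuse
such models rather than silently mis-marginalizing.

# Numerical choices

* **Propagation.** The regular parts are linear ODEs with a sub-generator
  matrix (non-negative off-diagonal, column sums $\le 0$). They are
  propagated by *uniformization* — the action of the matrix exponential
  computed as a Poisson-weighted series of sparse matrix–vector products,
  chunked so the weights stay representable and truncated at relative
  tail mass $10^{-14}$. For time-homogeneous rates this is exact up to
  truncation, which is why the filters meet $10^{-8}$ agreement with the
  closed forms. (No ODE solver package is available in the target
  environment; uniformization is also simply the right tool for this
  matrix class.)
* **Underflow.** The weight vector is renormalized after every event with
  the log-scale accumulated separately; likelihoods shrink geometrically
  in the number of events, so this is load-bearing.
* **Support masking.** Initial weights are restricted to states whose
  occupancy covers the initial lineage count (and the adjoint contracts
  against the same mask); the per-event binomial ratios enforce the
  constraint everywhere else automatically.
* **Truncation.** State spaces are finite lattices fixed at construction
  (`xmax` for the linear birth-death model). Filters refuse states outside
  the bounds rather than renormalizing; a mark whose target leaves the
  lattice keeps its hazard (loss) but transfers no mass, so over-tight
  truncation biases the likelihood down and the tests verify invariance
  once the bound exceeds reachable occupancy.
* **Exact combinatorics.** Binomial ratios use exact integer arithmetic
  for occupancies up to 20 and log-space otherwise, keeping the
  Chu–Vandermonde test exact.
* **Ties and degenerate input.** Continuous-time clocks make ties
  measure-zero; simultaneous scheduled events process in declared order.
  Structurally impossible data returns `-Inf`, never an error.

# The synthetic-data generator

All test inputs come from the built-in simulator; there are no external
datasets. The generator emulates: epidemic transmission trees under
compartmental dynamics (SEIRS and friends) with serial sampling; neutral
constant-size genealogies (Moran) with bulk and/or serial sampling; and
supercritical birth-death trees with present-day and serial sampling.
Fixture parameters are desk-scale on purpose (populations 10–30,
horizons 2–5, a handful of samples), chosen so that the deterministic
filter, the closed forms, the history-averaging Monte Carlo, and the SMC
estimator can all be run against each other within seconds.

What the generator does *not* emulate: sequence evolution (inputs are
genealogies, not alignments), time-varying rates, diffusion components,
multi-parent birth events, and simultaneous multi-deme migration or
sampling in one mark (the mark constructor accepts per-deme sample
vectors for the production rule, but the simulator and filters restrict
to one deme per sampling mark). A green test therefore establishes the
internal consistency and the classical-limit correctness of the
likelihood machinery on small structured models — not calibration against
any empirical data.

# Design decisions on genuinely open points

* **Inline-node semantics.** Whether the colored filter's event set
  includes inline nodes without a color change is settled here as *yes*:
  they are retained by pruning, each gets its own singular update, and
  the obscured mode's hidden-inline marginalization is exactly what
  restores the textbook Moran coefficients. The two modes are kept as
  distinct semantics dispatched on the tree class.
* **Serial-sample lineage-count convention.** The $\psi(1-\ell(t)/n)$
  factor uses the post-event (right-continuous) count; fixed by exact
  filter agreement.
* **Survival term.** The serial Moran closed form carries the $-\psi T$
  survival factor (see above); the linear birth-death loss term
  $-(\lambda+\mu+\psi)x$ makes the same accounting explicit.
* **Parameter recovery check.** Recovery of the birth rate from 50
  simulated birth-death trees is asserted on the estimate maximizing the
  *pooled* log-likelihood (1.47 for truth 1.5 in the shipped test). The
  mean of per-tree maximizers is noticeably low (about 1.26) at these
  tree sizes: single-tree rate MLEs are skewed and occasionally pinned at
  the search boundary. That is a property of the per-tree estimator, not
  of the likelihood — the pooled curve is centered at the truth, and the
  closed form agrees with the independent filter route to $10^{-6}$.
* **Monte-Carlo oracle construction.** Averaging
  `exp(loglik_given_history)` over unconditioned histories cannot work:
  histories containing the exact genealogical event times have measure
  zero. The oracle (`mc_loglik()`) therefore forces a jump at each event
  time, weighting by the event density $\sum_u \alpha_u \phi_u$ — an
  importance-sampling identity that uses only simulation and the
  per-event weights, never the filter solution.

# Known limitations

Time-homogeneous rates only (time-varying rates would need a
user-declared thinning envelope for simulation and a time-stepping
propagator for the filters); scheduled events at the horizon only;
hidden-space size grows as $|\mathbb{D}|^{\ell}$, guarded by an explicit
size check with SMC as the fallback; population sizes beyond ~$10^6$ are
out of scope (no composition-rejection scheduler); no likelihood
gradients.
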