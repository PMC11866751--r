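---
title: "DNA melting in crowded media: model, sampler, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA melting in crowded media: model, sampler, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crowdmelt` simulates the melting (strand-separation) transition of a lattice
DNA in a medium crowded by inert macromolecules, and extracts the melting
temperature, its finite-size scaling, and the statistics of denaturation
bubbles. This vignette explains the model, the algorithms, and every choice a
maintainer might want to revisit. All empirical numbers quoted here are the
ones the package's own test suite and `scripts/acceptance.R` compute.

## The model

The DNA is two self- and mutually avoiding walks $\mathbf r^A$, $\mathbf r^B$
on the simple cubic lattice, grown monomer by monomer from a common pinned
origin at the centre of a hard box. The single exception to mutual avoidance
is *equal-index* co-occupation, $\mathbf r^A_i = \mathbf r^B_i$, which
represents a base pair and contributes energy $-\epsilon$; the Hamiltonian is
$H = -\epsilon \sum_i \delta_{\mathbf r^A_i, \mathbf r^B_i}$ and each contact
carries Boltzmann weight $e^{\beta\epsilon}$. We set
$\epsilon = k_B = 1$, so temperature is measured in units of the pairing
energy. A chain of $N$ steps carries $N+1$ monomers per strand, including the
always-bound origin pair, so the contact number satisfies
$1 \le n_c \le N+1$. Configurations decompose into double-stranded (bound)
segments, *bubbles* — maximal runs of broken pairs enclosed by bound pairs,
with size $\ell_b$ equal to the index difference of the enclosing bound
indices, hence $\ell_b \ge 2$ — and an open Y-fork at the free end, which is
never counted as a bubble.

Crowders are modelled as quenched site dilution: each lattice site is
retained with probability $p$ and diluted (made permanently unavailable to
the chains) otherwise, so $1-p$ is the crowder density. Dilution is
spatially uncorrelated and frozen — appropriate for crowders whose
rearrangement is much slower than the DNA's conformational sampling. The
model deliberately omits sequence heterogeneity, differential bending
rigidity, helicity, and polydisperse or attractive crowders.

## Disorder generation

The diluted medium is grown with the Leath algorithm: starting from the
occupied centre, neighbouring sites are visited and retained with
probability $p$; each site's fate is decided exactly once, at first visit.
Growth halts at the box faces. The growth front can be consumed LIFO
(depth-first) or FIFO (breadth-first); the two produce differently shaped
clusters with statistically identical ensembles, which the test suite
verifies with a two-sample test on cluster masses. The recursion of a
textbook depth-first search is replaced by an explicit container so boxes of
$L = 599$ cannot overflow the call stack. Neighbours are visited in the
fixed order $+x, -x, +y, -y, +z, -z$; since no direction is special, any
fixed order is valid and a fixed one makes runs exactly reproducible.

A realization is kept only if its cluster *spans* — touches all six faces of
the box (`spanning_lattice()` retries with derived sub-seeds and reports the
attempt count). At the site-percolation threshold of the cubic lattice,
$p_c = 0.3116$, the spanning cluster is a fractal with mass dimension
$d_f = 2.52$; the package reproduces both numbers, the first from the
crossing of spanning-probability curves at increasing $L$ (located by linear
interpolation of the curve differences for each pair of sizes, averaged over
pairs), the second from the mass–radius scaling $M \sim r^{d_f}$.

Two numerical choices deserve emphasis. First, mass–radius profiles are
*cumulative* site counts in unit-width concentric shells about the cluster's
centre of mass, and profiles are averaged over an ensemble of clusters
*before* the log–log fit: a single cluster's centre of mass frequently sits
in a sparse region, so per-cluster fits are dominated by the depleted core.
Second, the fit window defaults to $[L/8,\ L/2]$ — below $\sim L/8$ the
centre-of-mass depletion corrupts the cumulative mass, above $\sim L/2$ the
box truncates it. The window is exposed as a parameter of
`fractal_dimension()` / `fractal_dimension_ensemble()`.

## The sampler

Both strands grow simultaneously by one monomer per step. The candidate set
for a step is the Cartesian product of the free nearest neighbours of the
two growing ends; an element with equal sites is a contact (weight
$e^{\beta}$), all others have weight 1. The one-step local partition sum
$w_n$ is the total weight of the set, a step is drawn by roulette selection,
and the running Rosenbluth weight is $W_n = \prod_{i\le n} w_i$. Averaging
$W_n$ over *started tours* estimates the partition sum, $Z_n = \langle W_n
\rangle$, and weighted sums of $n_c$, $n_c^2$, the constrained sums binned
by $n_c$, and the bubble histogram give all thermal observables as ratios
$\langle Q \rangle = \sum W Q / \sum W$.

Pruning and enrichment control the population through the ratio
$r = W_n / Z_n$ against the *running* estimate of $Z_n$:

* $r < 0.9$: the branch is killed with probability $1-r$; a survivor
  continues with its weight reset to $Z_n$. With kill probability $1-r$ the
  expected post-decision weight is exactly $r \cdot Z_n = W_n$, so the reset
  is unbiased — this is why that particular kill probability is used.
* $r > 1.1$: the branch is split into $k = \min(\lfloor r \rfloor,
  |\mathcal S_n|)$ copies, each continuing with weight $W_n / k$ from the
  same configuration; child weights sum exactly to the parent's.
* Early in a run ($<10$ started tours, or $Z_n$ still zero) the branch just
  continues — plain Rosenbluth growth — because $r$ is undefined or noisy
  before the estimate stabilizes; any fixed bootstrap rule is unbiased.

A tour is therefore a rooted tree of branches; the engine traverses it
depth-first, undoing lattice occupancy on backtrack, so the lattice is
bit-identical across tours (asserted in tests). Weights are carried in log
space with per-length offsets: at $N = 500$ and low temperature $W_N \sim
e^{N/T}$ overflows any linear-space accumulator, while the offsets make the
accumulation exact up to a common multiplicative constant that cancels in
every ratio. Random numbers come from the Mersenne–Twister generator; each
(temperature, tour) pair gets an independent substream derived from the
master seed by integer hashing, so results are reproducible bit for bit and
independent of scheduling.

The sampler is validated against `enumerate_dual_walks()`, an exhaustive
enumeration of the identical state space (ordered step-pair sequences, so
partition sums match constant for constant) feasible up to $n = 6$. The
acceptance suite checks $Z_n$, $\langle n_c \rangle$, the contact
distribution and the bubble histogram at $n = 5$, at $\beta \in \{0, 1,
1.5\}$, on the full lattice and two diluted fixtures, in all four
(bias × population-control) modes, using pooled ratio estimates with
leave-one-subrun-out jackknife errors. Pooling before dividing matters:
per-run ratio estimates are skewed when weight distributions are heavy, and
the biased modes receive larger budgets for the same reason.

## The look-ahead bias

In strongly diluted media most growth attempts die in dead ends. The
optional directional bias scans, for each candidate direction of each
strand, a pyramid of depth $h$ (layer $k$ is a $(2k+1)^2$ square at distance
$k$ along the axis, clipped at the box; the apex is excluded) and computes
$f_{\text{bias}} = n_{as} / (1 + n_{os})$, where $n_{as}$ counts available
sites and $n_{os}$ occupied sites in the scanned volume — the $+1$ prevents
divergence when nothing is occupied. A direction whose pyramid contains no
available site gets a floor value $10^{-6}$, effectively excluding it while
keeping all weights positive. The sampling weight of a step pair is
multiplied by the product of the two strands' directional factors, and the
chosen pair's contribution to $W_n$ is divided by the same factor, which
restores unbiasedness exactly (importance sampling). The default depth in
production configurations is $h = 3$. Odd layer widths were chosen so the
pyramid is symmetric about its axis. The tests verify both neutrality (all
estimates unchanged within error on diluted fixtures) and usefulness: at
$p = 0.5$ near melting, the number of walks reaching $N = 100$ at a matched
tour budget increases, asserted as strictly greater aggregated over
disorder realizations — the gain fluctuates strongly between realizations,
and on the *undiluted* lattice the bias only adds cost, so it is off by
default.

## Observables and disorder averaging

Per temperature the package reports $\log Z_n$, $\langle n_c \rangle$, the
contact fluctuation $C_c = \langle n_c^2 \rangle - \langle n_c \rangle^2$
(the configuration variance of the contact number), the normalized contact
distribution $P(n_c)$, the weighted bubble-size histogram $P(\ell_b)$ (each
bubble contributes its configuration's weight), the mean bubble count
$\langle n_b \rangle$, and optionally the per-tour $\ln W$ samples for the
sampling diagnostic: comparing $P(\ln W)$ with $W P(\ln W)$ and reporting
the fraction of $W P$ mass lying where $P$ is appreciable (at least 1% of
its maximum bin, by default). Overlap near 1 means the estimate is supported
by typical tours; overlap near 0 means a few rare tours dominate and the run
cannot be trusted.

Disorder averages come in two forms. The annealed average pools
realizations with weight $Z$, $[\langle Q\rangle] = \sum_r Z_r \langle
Q\rangle_r / \sum_r Z_r$, with free energy $f_a = -T \ln [Z_n]$; the
quenched average gives each realization that produced at least one chain of
length $n$ equal weight, with $f_q = -T[\ln Z_n]$, excluding and counting
zero-weight realizations. Both reduce to the single-lattice thermal average
at $p = 1$ and coincide when realizations are identical; whether the pinned
origin makes the physical problem quenched is an argument, not a
computation, so the package simply reports both side by side.

## Scaling analysis

Near the transition the order parameter obeys $n_c / N^{\phi} = h\!\left((T
- T_m) N^{\phi}\right)$ and the fluctuation $C_c / N^{2\phi}$ collapses
against the same abscissa; $\phi = 1$ signals first-order-like melting,
$\phi = 1/2$ continuous. `fit_collapse()` minimizes a standard
collapse-quality objective — the mean squared deviation of each scaled point
from the linear interpolation of the *other* curves at the same scaled
abscissa, normalized by the overall variance so the objective is invariant
under curve relabeling and common rescaling — by Nelder–Mead from the best
point of a coarse $(T_m, \phi)$ grid. Curves whose scaled windows do not
overlap are refused. Parameter uncertainties quoted by `tidy()` come from
the curvature of the objective at the optimum and should be read as rough
scales; for production data, bootstrap over tours or realizations instead.

The bubble exponent $c$ in $P(\ell_b) \sim \ell_b^{-c}$ ($c \ge 2$
first-order, $1 < c < 2$ continuous) is minus the least-squares slope of
$\log P$ vs $\log \ell_b$ over an intermediate window, by default sizes
20–100, below finite-chain corrections and above the discreteness scale.
Fluctuation-peak positions are located by a quadratic through the three
samples around the grid maximum; monotone curves get a no-peak flag. The
phase line $T_m(p)$ is fitted as $T_m = 1/\ln(c_1 p + c_2)$ — implemented
as an ordinary linear fit of $e^{1/T_m}$ against $p$, which is exactly
equivalent and conditions better — plus a power law $T_m \sim p^{-\alpha}$
on the weak-disorder window $p \in [0.6, 1]$; the growth of the power-law
residuals below $p \approx 0.6$ is the package's diagnostic for the
crossover into the strong-disorder regime. For media disordered enough that
fluctuation cumulants converge too slowly, `estimate_tm_inflection()` falls
back to the steepest descent of a smoothing spline through $\langle n_c
\rangle(T)$, with correspondingly lower accuracy.

## Problem sizes, defaults, and what the tests do and do not show

The shipped analyses use desk-scale problem sizes chosen so the full suite
runs on one CPU in minutes: threshold curves at $L \in \{17, 25, 33\}$ with
2000 realizations per point; fractal dimension from 120 spanning clusters at
$L = 99$; the undiluted melt from a single $N = 200$ scan at $10^5$ tours
per temperature, harvesting the $n = 50$ and $100$ curves from the same runs
(partition-sum estimates exist at every intermediate length, a standard
chain-growth dividend); bubble statistics pooled over $N \in \{300, 500\}$
with a few million tours. At these sizes the recovered values carry visible
finite-size effects — the crossover exponent comes out near 0.9 rather than
1, and the bubble exponent carries a standard error near 0.15 — which is
the expected behaviour, not a defect; the production-scale configurations in
`long_run_configs()` ($L = 599$, $N$ up to 500, $10^3$–$10^4$ disorder
realizations, bias depth 3) are what full-accuracy reproduction requires,
and are far beyond a test suite.

The synthetic generators used in tests emulate specific, known-truth
aspects: exactly collapsible curve families, exact discrete power laws,
and hand-built dilution patterns and contact masks. Passing those tests
demonstrates the estimators and fitters are correct on their stated state
space; it does not demonstrate anything about real DNA — the model is
homogeneous, unstructured, and athermal in everything except base pairing.

Default box sizes follow the hard-box convention: `melt_curve()` uses
$L = \min(2N + 3,\ 599)$, so small chains can never touch the wall and
production chains would need some 300 net steps in one direction to do so.
The temperature grid, tour counts, number of realizations, bias depth, and
every seed are explicit arguments everywhere and are recorded in the
experiment manifest, so any run can be reproduced bit for bit.

## Known limitations

* Single chain pair, homogeneous pairing energy; no sequence effects.
* Site dilution only — no bond dilution, periodic boundaries, or
  correlated/attractive disorder.
* The quenched average is computed from the same per-realization ledgers as
  the annealed one; no replica-level quantities beyond means are kept.
* The collapse objective interpolates linearly between grid points; very
  coarse temperature grids bias the quality surface (use grids of at most
  $\sim 0.005$ spacing near the transition).
* `enumerate_dual_walks()` is exponential by design and refuses $n > 6$.
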