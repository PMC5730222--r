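---
title: "Partial-propensity stochastic simulation: models, engines and validation"
author: "ppsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-propensity stochastic simulation: models, engines and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppsim)
```

## The model class

`ppsim` simulates networks of irreversible mass-action channels over
discrete molecular populations. A channel has at most two *distinct*
reactant species, of which at most one may carry a stoichiometry above
one (the `A + N B` form, `N = 1, 2, 3, ...`); reversible reactions must
be split into two channels. The propensity of channel $\mu$ is

$$a_\mu = c_\mu \prod_i \binom{n_i}{s_i},$$

the specific probability rate $c_\mu$ times the reaction degeneracy
(number of distinct reactant combinations). Macroscopic rate constants
$k$ convert to specific rates once, at network build:
$c = k\,\Omega^{1-o} \prod_i s_i!$ with $o = \sum_i s_i$ the total
reactant order and $\Omega = N_A V$ (Avogadro scaling, used by the
endosome model, where rates are printed in m$^6$ mol$^{-2}$ min$^{-1}$)
or $\Omega = V$. In the dilute limit this reproduces deterministic mass
action, which the test suite checks numerically. Initial concentrations
convert to copy numbers as $\mathrm{round}(C \cdot \Omega)$, rounding
half-up, once at build.

Two validation models state their constants as *lumped* values ($k_1/V$,
$k_2V$); model factories accept these directly as specific rates. For the
homodimerization `A + A -> 0` we adopt the convention
$a = (k_1/V)\,n(n-1)$, i.e. $c = 2k_1/V$ under the $\binom{n}{2}$
degeneracy. This convention is not a free choice: it is the one under
which the closed-form stationary distribution below agrees with the
brute-force master-equation solution, which we treat as authoritative
throughout.

## Partial-propensity factorization

Partial-propensity methods factor each propensity over a designated
*pivot* reactant, $a_\mu = n_{\mathrm{pivot}} \pi_\mu$, and sample in two
stages — "which molecule?" (a species group, proportional to
$\Sigma_i = n_i \Lambda_i$), then "which partner?" (a column within the
group's row, proportional to $\pi$). The structure stores one row per
species plus a row for source channels; $\Lambda_i$ are row sums and
$a_0 = \sum_i \Sigma_i$. Conventions fixed here:

* source channel: pivot "source", $\pi = c$;
* single reactant of stoichiometry $s$: $\pi = c\binom{n-1}{s-1}/s$
  (so $\pi = c$ for unimolecular, $c(n-1)/2$ for a homodimer), clamped
  to 0 below $n = 1$ for $s > 1$;
* two distinct reactants: the pivot is the stoichiometry-one species if
  the other has stoichiometry above one, otherwise the reactant with the
  *smaller species index* (a fixed tie-break that keeps lookup tables
  deterministic); $\pi = c\binom{n_{\mathrm{other}}}{s_{\mathrm{other}}}$.

After a firing, only the entries registered in per-species update tables
are recomputed, and $\Lambda$, $\Sigma$, $a_0$ are adjusted
incrementally. The R-level structure (`buildPPState()`,
`ppApplyUpdate()`) is the readable reference; the compiled engines
maintain the same structure and the tests verify (i) that incremental
updates equal a full rebuild entrywise on random networks and (ii) that
the engines' $a_0$ stays within $10^{-9}$ (relative) of a directly
recomputed propensity sum after thousands of events with periodic
rebuilds disabled. In production runs the engines rebuild the structure
from scratch every $2^{20}$ events, or whenever $a_0$ falls below
$10^{-12}$ of its running maximum, to bound floating-point drift.

## Engines

All engines draw the waiting time from $\mathrm{Exp}(a_0)$ and pick
channel $\mu$ with probability $a_\mu/a_0$; they differ only in how the
pick is organized, so their sampled distributions are identical (this
*exactness equivalence* is asserted by chi-square tests at $10^4$ final
states per engine pair).

* **DM** — reference direct method, linear scan over all channel
  propensities.
* **PDM** — two-level scan over $\Sigma_i$ then over the row. One
  uniform drives both levels (remainder reuse), so an event consumes two
  uniforms: time and selection.
* **SPDM** — PDM plus one-step promotion: the selected group and column
  are swapped one position toward the front of their scan orders, an
  online adaptation to skewed propensity distributions. Reordering only
  changes scan order, never probabilities.
* **PSSA-CR** — group selection by composition-rejection: groups with
  $\Sigma_i \in [2^j, 2^{j+1})$ share bin $j$; a bin is chosen
  proportionally to its sum (linear scan over occupied bins, whose number
  is logarithmic in the dynamic range), a member is proposed uniformly
  and accepted with probability $\Sigma_i/2^{j+1} \ge 1/2$. Partner
  selection as in PDM. Whether the original formulation also applies
  composition-rejection at the partner level is not settled here;
  group-level CR with a linear partner scan preserves exactness, which is
  what the tests pin down.
* **dPDM** — PDM plus a time-ordered queue of pending completions (ties
  FIFO by insertion). A *consuming* delayed channel removes its reactants
  at initiation and applies its products at $t + \tau$; a *non-consuming*
  channel applies its whole update at completion. A completion that would
  drive a count negative (possible for non-consuming delays, e.g. a
  single molecule that keeps re-initiating) is a model-semantics error
  and is reported with the reaction index and time — never clamped.
  With no delayed channels dPDM degenerates to PDM exactly.

The linear scans pick the first index whose cumulative sum strictly
exceeds $r\cdot\mathrm{total}$ and fall back to the last positive entry,
so floating-point drift can never select a zero-propensity channel.

**Reproducibility.** Each trajectory runs on its own
`mt19937_64` stream seeded by a `splitmix64` mix of (master seed,
trajectory index); uniforms use the generator's top 53 bits. Identical
(model, method, seed, index) therefore give bit-identical event
sequences on any platform, and Monte-Carlo samples are independent of
execution order.

## Reaction–diffusion on Cartesian grids

The spatial engine implements the next-subvolume method: the domain is a
uniform grid of well-mixed subvolumes; within a subvolume reactions run
on the per-subvolume partial-propensity structure (a DM fallback exists
for cross-validation), and diffusion of species $s$ is a first-order
jump at rate $D_s/h^2$ per neighbor direction to a uniformly chosen
neighbor. Specific rates of order-$o$ channels are rescaled by
$n_{\mathrm{sub}}^{\,o-1}$ because the per-subvolume volume is
$\Omega/n_{\mathrm{sub}}$; the edge length $h$ is supplied independently
as geometry. Boundaries default to reflective (zero flux), matching a
membrane section between two poles; periodic is available. The
subvolume with the earliest absolute next-event time fires; after any
event the affected subvolumes redraw their times (exponential waiting
times make the redraw exact).

Limiting behavior anchors the implementation: a single-subvolume grid
reproduces the well-mixed engine distribution; diffusion-only species
conserve their totals exactly; a single walker occupies a reflective
1-D grid uniformly; and on a two-cell grid the per-cell marginal
approaches the binomial split of the total as coupling grows — for that
last check the test uses a dimerizing network, because a pure
birth–death model satisfies the binomial split identically at *any*
coupling (Poisson marginals) and has no discriminating power.

The endosome demonstration below can be placed on a 20-subvolume 1-D
grid with diffusive Rab coupling. One unit caveat is documented rather
than resolved: with the printed diffusion constants
($10^{-21}$ m$^2$ min$^{-1}$) and total volume ($4\times10^{-21}$ m$^3$),
any physically plausible $h$ gives jump rates far below one event per
100 min, which cannot produce propagating activation fronts on that
horizon. `buildGrid()` therefore leaves $D$ (per species) and $h$ as
free configuration, and front propagation is a qualitative demonstration
at user-chosen coupling, not a quantitative reproduction.

## Validation mathematics

**Closed forms.** The homoreaction `A+A -> 0`, `0 -> A` (lumped rates
$k_1/V = 0.016\,$s$^{-1}$, $k_2V = 10\,$s$^{-1}$, $n_0 = 25$) has
stationary distribution
$\phi(n) \propto (\sqrt{2K})^{n}/n!\; I_{n-1}(2\sqrt{2K})$ with
$K = (k_2V)/(2k_1/V) = 312.5$ and $I$ the modified Bessel function
($I_{-1} = I_1$ for the $n=0$ term). We renormalize numerically on
$0..n_{\max}$ with the tail below $10^{-12}$, which makes the typeset
normalization constant irrelevant. The heteroreaction `A+B -> B`,
`0 -> A` ($k_1/V = 0.04$, $k_2V = 1$, $n_a(0)=25$, $n_b \equiv 1$) is a
linear birth–death process whose stationary law is Poisson with mean
$K/n_b$, $K = (k_2V)/(k_1/V) = 25$. The source text's typeset $K$ for
this model ($k_2V^2/2k_1$, which would give 12.5) disagrees with the
birth–death balance; we bind to the master-equation oracle, which
confirms the Poisson mean 25 to $10^{-10}$ sup-norm.

**The oracle.** `cmeSteadyState()` enumerates the states reachable from
the initial condition inside a truncation box, assembles the sparse
master-equation generator (outflow across the truncation dropped) and
solves for the normalized null vector, doubling the box until the
boundary mass drops below $10^{-10}$ (conserved species are excluded
from the boundary criterion — they can never reach their bound).
Reachability restriction keeps the stationary vector unique when
conservation laws disconnect the lattice. Systems without a stationary
distribution (pure birth) keep growing until the state cap and error
out, which is the correct diagnosis.

**Convergence diagnostics.** `klConvergenceStudy()` draws $S$ final
states at $t_{\mathrm{end}} = 100$ s (at least 20 relaxation times for
both validation models at the printed rates; the final state is the only
sample, so no burn-in issues), forms the empirical distribution and
computes $D(\hat p \,\|\, \phi) = \sum \hat p \ln(\hat p/\phi)$ against
the strictly positive analytic reference — this direction has no
zero-bin pathologies. For a Monte-Carlo method with strong order $-1/2$
the divergence decays as $S^{-1}$; the least-squares slope of mean
$\log\mathrm{KL}$ vs $\log S$ over $S \in \{10^2, 10^3, 10^4\}$ with 10
repetitions per size recovers $-1$ within $\pm 0.25$ for every engine.
The size grid is a deliberate desk-scale choice; the plug-in KL bias
$\approx |\mathrm{support}|/(2S)$ stays well below the signal at these
sizes.

## The endosome cut-out switch

The built-in seven-channel network couples membrane-bound active Rab5
(`R5`), active Rab7 (`R7`) and the active/inactive effector forms
`S0`/`S1` (with the Rab7 effectors identified with `S0`/`S1`, whose
total — the parameter $S_{01}$ — is conserved). Rates and the volume
$4\times10^{-21}$ m$^3$ are the printed operating point; 1 mol m$^{-3}$
converts to 2409 molecules. Increasing $S_{01}$ mimics endosome
progression; the positive feedback of `R7` on its own activation through
the trimolecular channels makes the high-`R7`/low-`R5` state take over
abruptly — the cut-out switch.

`bifurcationScan()` runs 100 trajectories of 100 simulated minutes per
$S_{01}$ value (the published sampling design) and classifies a final
state as *switched* when R5 falls below $\theta = 0.5$ of its fixed
early-endosome initial count ($\theta$ is configurable; no printed
classification rule exists). The default grid
`seq(0.6, 2.0, by = 0.2)` mol m$^{-3}$ is a design choice documented
here: the upper end lies past the deterministic saddle-node of the R7
subsystem at $S_{01} \approx k_3/(2\sqrt{k_{21}k_{22}}) \approx 1.6$
mol m$^{-3}$, and the lower end stays above $\approx 0.5$ mol m$^{-3}$
because below that the *unswitched* R5 steady level
($\approx k_{01}S_{01}/k_1$) itself falls under the fixed threshold and
the classification degenerates. On this grid the switched fraction rises
from 0 to 1 within roughly one grid step near $S_{01} \approx 1.45$; the
published figure does not print its axis values, so the location is a
property of this parameterization, not a reproduced number.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: $10^4$ samples for
exactness chi-squares ($\alpha = 0.01$, adjacent outcome bins pooled to
a minimum of 20 observations), $\{10^2, 10^3, 10^4\}\times 10$
repetitions for convergence slopes, 100 samples per scan value, and
brute-force graph enumeration for $N \le 12$ — sizes chosen so the whole
validation runs on a laptop-class single core in minutes while leaving
every statistical test with conventional power. One structural fact the
enumeration exposes: the colloidal-aggregation dependency graph follows
the $3N-7$ maximum out-degree law from $N = 5$ upward, but at $N = 4$
the true maximum is 6 (e.g. `S1+S2 -> S3` changes `S1`, `S2`, `S3`,
which between them are reactants of six of the eight channels); the
tests bind to the enumeration.

## Known limitations

* Mass-action kinetics only; no Hill or Michaelis–Menten rate laws, no
  SBML Events/Rules/FunctionDefinitions.
* The `A + N B` reactant restriction is structural (the factorization
  requires a product-form propensity), not a parser limitation.
* Delayed channels are not available in the spatial engine.
* The SBML annotation schema (rate/delay/diffusion elements in the
  package's namespace) is this package's own; compatibility with other
  simulators' annotation conventions is not claimed.
* Synthetic validation covers well-mixed dilute mass-action kinetics;
  passing tests say nothing about crowding, anomalous diffusion or
  non-elementary kinetics in real systems.
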