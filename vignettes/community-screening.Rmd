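---
title: "Dynamic flux-balance screening of microbial systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flux-balance screening of microbial systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commscreen)
```

# The question the package answers

Given a set of organisms with genome-scale metabolic models, a target
product and an environment (medium composition, oxygen regime, carbon
source), should a bioprocess use a monoculture or a two-member
community — and which one?  `commscreen` simulates every candidate system
under identical conditions and compares them on productivity, yield,
interaction type and viability.  The community is always benchmarked
against the *best* of its constituent monocultures, not their average:
a community is only recommended when it beats the best thing you could
do with one organism.

# The simulation model

## Static-optimisation dynamic FBA

Each species is a constraint-based metabolic model: stoichiometric matrix
$A \in \mathbb{R}^{m\times n}$, flux vector $v$, bounds
$v_l \le v \le v_u$ and a biomass objective $c$.  The batch of length $T$
is discretised into steps $\Delta t$; at each step every species solves

$$\max_v c^\top v \quad \text{s.t.} \quad A v = 0, \; v_l \le v \le v_u,$$

a quasi-steady-state assumption: intracellular metabolism equilibrates
fast relative to the batch dynamics.  There is *no* joint community
objective — each species greedily maximises its own growth against the
current pool, and all interaction emerges from the shared extracellular
compartment.

## Uptake bounds

The uptake bound of species $i$ for pool metabolite $j$ at concentration
$S_j$ is

$$v_s = \min\!\left(\frac{S_j}{X_i\,\Delta t},\;
  \frac{V_{\max} S_j}{K_m + S_j}\right),$$

the lesser of what is physically present per gram biomass per step and
what Michaelis–Menten transport kinetics admit.  Both terms vanish with
$S_j$, so depleted metabolites close smoothly.  A species with zero
biomass gets a zero bound.

## Parsimonious growth solutions

FBA optima are usually degenerate: many flux vectors achieve the same
growth rate but differ in secretion, which would make the pool update
arbitrary.  The engine therefore solves a second LP at the fixed growth
optimum that minimises total absolute flux (split-variable formulation
$v = p - q$, $p, q \ge 0$).  This parsimonious solution determines the
exchange fluxes that move mass between cells and pool.

## Product potential via FVA

Production is tracked separately from the pool ledger.  At each step the
*maximum* attainable secretion flux of each tracked product is found by
flux variability analysis with the biomass flux constrained to at least
`fva_growth_fraction` (default 0.999) of the step optimum.  Cumulative
product $P_{k,i}$ accrues this FVA flux times biomass times $\Delta t$.
Keeping two ledgers — the parsimonious fluxes drive the medium, the FVA
maxima drive the product report — records production *potential* without
letting optimistic secretion distort the community dynamics; both are
exposed on the trajectory object.  The 0.999 retention fraction is
standard FVA practice: pinning biomass at exactly 100 % of an
LP-computed optimum is numerically brittle.

## State update and oversubscription

Forward Euler:
$X_i \leftarrow X_i(1 + \mu_i \Delta t)$,
$S_j \leftarrow S_j + \sum_i v_{ij} X_i \Delta t$ (uptake negative,
secretion positive), $P_{k,i} \leftarrow P_{k,i} + v_{p_k} X_i \Delta t$.

Because each species' availability term uses its *own* biomass, the sum
of independently granted uptakes can exceed the pool.  After all species
have solved, any oversubscribed metabolite triggers a proportional
tightening: each claimant's bound is scaled by its requested share, and
the affected LPs are re-solved.  A single correction can push demand onto
a *different* metabolite (the re-solved optimum may switch substrates),
so the pass repeats — bounds only ever shrink, so the loop terminates,
in practice in one or two passes — until aggregate demand respects every
pool.  A final clip at zero guards round-off; clipped amounts are logged
on the trajectory and are at floating-point noise level on the fixtures.

Infeasible steps (e.g. a forced maintenance flux whose substrate ran out)
give a species $\mu = 0$ and zero fluxes for that step, flagged
per-species; the species remains in the pool.  The terminal state is the
mean over the last `averaging_window` (default 5) *feasible* time points
(steps where at least one species' LP was feasible), which smooths the
end-of-batch discretisation noise; abundances are biomass fractions of
that averaged state.

## Fed-batch

A feeding rule `(watch_id, trigger, target)` tops the watched metabolite
back up to `target` g/L whenever it falls below `trigger` g/L after a
step (conversion via the metabolite's molar mass, computed from its
chemical formula).  Feed events are time-stamped, and yield accounting
counts fed amounts as consumed substrate.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `V_max` | 20 | mmol/gDW/h | typical reported transport capacity; per-metabolite overrides supported |
| `K_m` | 0.05 | mmol/L | typical transporter affinity |
| `dt` | 0.1 | h | 120 steps over a batch; the refinement check below justifies it |
| `horizon` | 12 | h | batch duration by which the carbon source is spent on the fixtures |
| `initial_biomass` | 0.01 | g/L | standard inoculum; per-species values supported |
| `fva_growth_fraction` | 0.999 | — | biomass retention in product FVA |
| `averaging_window` | 5 | feasible points | terminal-state smoothing |
| interaction `threshold` | 0.1 | — | ±10 % band around half the monoculture growth |
| viability | 0.1 / 0.10 | abundance / growth | floor for every member |

The step size is not stated by the underlying protocol; 0.1 h was chosen
and is validated by a convergence property: halving `dt` moves the ToyA
monoculture terminal biomass by far less than 2 % (the test suite asserts
the 2 % bound; the observed change is ~10⁻⁷ %).

# Screening semantics

**Productivity** is terminal averaged product concentration divided by
the horizon (mmol/L/h).  The divisor is the full batch time — the
simplest reading that reproduces the published unit.

**Productivity ratio** is $(\text{comm} - \max(\text{monoA},
\text{monoB})) / |\max(\text{monoA}, \text{monoB})|$.  When the best
monoculture is below $10^{-6}$ mmol/L/h and the community produces more
than ten times that floor, the ratio is reported as the sentinel category
`High` rather than a number — the denominator carries no information.

**Interaction classification** compares each member's terminal averaged
biomass in co-culture against *half* its monoculture biomass with a
±10 % band (above → `+`, below → `-`, inside → `0`).  The halved baseline
is implemented exactly as printed in the source protocol; it encodes the
view that a co-culture member has half the resources available.  One
consequence worth knowing: a member whose growth is completely unaffected
by its partner scores `+` (it beats half its solo growth), so
commensal-looking pairs classify as mutualistic, and genuine `-/-`
competition requires each member to fall below 45 % of its solo biomass.
Terminal biomass (not instantaneous growth rate) is the default measure
because it is what batch endpoints report; the classifier itself is a
pure function of the four growth measures and a threshold, so any other
measure can be supplied.  A species whose monoculture measure is zero is
unclassifiable on that side and reported `undefined` rather than forced
into a category.

**Viability** requires *every* member to keep terminal abundance ≥ 0.1
and to have grown ≥ 10 % over its inoculum.  The per-member reading (not
total-biomass) is deliberate: a community where one member washes out is
not a community.

**Cross-feeding roles** integrate each species' exchange fluxes over the
trajectory; net positive → Producer, net negative → Consumer, |net| below
tolerance → none.  A metabolite is cross-fed when both roles coexist.

**Inoculum scans** split a fixed total inoculum over a ratio grid;
**carbon scans** replace the primary carbon source (default glucose) by
each candidate at 10 mmol/L, leaving all other components untouched;
**sensitivity** draws a seeded Latin hypercube over
$V_{\max} \in [1, 50]$, $K_m \in [0.01, 1]$ and regresses terminal total
biomass on the raw parameters (OLS), reporting raw and standardised
coefficients and $R^2$ (defined as 0 when the response is numerically
constant, where the usual ratio is 0/0).

# The toy community: what it emulates, and what it does not

`generate_toy_community()` builds three fixed networks (5–9 reactions
each) whose community behaviour is engineered and analytically checkable:

* **ToyA** assimilates glucose through an overflow route that obligately
  secretes acetate and couples product P1 to growth; a slower salvage
  route re-assimilates acetate at useful yield, giving the monoculture a
  second growth phase on its own overflow — the classic
  respiro-fermentative diauxie motif.
* **ToyB** grows only on acetate (product P2).  Alone on glucose media it
  cannot grow at all; next to ToyA it thrives.  This pins the
  cross-feeding machinery, the `High` productivity category and the
  viable-only-in-community case.
* **ToyC** competes for glucose and scavenges acetate rapidly at
  near-zero biomass yield.  In co-culture with ToyA each member loses
  roughly 60 % of its solo growth — ToyC takes half the glucose and
  destroys ToyA's salvage phase; ToyA takes half of ToyC's glucose —
  which is the engineered `-/-` competition case.  The near-zero-yield
  scavenging is the load-bearing design element: with uniform yields, two
  members of a conserved-resource race cannot *both* fall below half of
  their solo growth, so a competition call would be unreachable; the
  wasteful scavenger makes the co-culture genuinely less efficient than
  either monoculture.

A companion fixture (`toy_saturated_setup()`) puts a dense inoculum
(12 g/L) on a dilute medium (0.1 mmol/L glucose) so that the availability
term undercuts the Michaelis–Menten term for *every* kinetics draw in the
sensitivity ranges; terminal biomass is then provably independent of
$(V_{\max}, K_m)$ and the regression coefficients must vanish.  This is a
deliberately degenerate regime for testing the scan, not a realistic
culture.

What the toys do *not* emulate: genome-scale redundancy (thousands of
reactions, alternate pathways), realistic biomass compositions, ATP
maintenance, pH/ion balancing, or the empirically calibrated yields of
real organisms.  Tests passing on the toys certify the *engine and
decision logic* — conservation, classification, determinism — not the
biological accuracy of predictions for real organisms, which inherits all
the usual limitations of FBA models and uniform uptake kinetics.

# Numerical choices

* **LP solver.** The package carries its own dense bounded-variable
  two-phase simplex (artificial-variable phase 1, Bland's anti-cycling
  rule, basis re-solved explicitly each iteration).  Bland's rule trades
  speed for guaranteed termination on the degenerate LPs that metabolic
  networks produce; with the basis re-solved from scratch every iteration
  there is no accumulated factorisation drift.  Dense linear algebra is
  appropriate at fixture scale (tens of reactions); the suite
  cross-checks every optimum against exhaustive vertex enumeration.
* **Tolerances.** Feasibility/optimality tolerance $10^{-7}$; "unbounded"
  flux bounds clamped at ±1000 mmol/gDW/h (the genome-scale convention).
  The biomass pin in the parsimony and FVA stages is relaxed by $10^{-8}$
  to absorb solver round-off.
* **Degenerate inputs.** Zero-concentration metabolites close their
  exchanges; zero-biomass species get zero bounds; an infeasible LP is
  reported as infeasible, distinct from a feasible zero-growth optimum;
  all-zero productivity triples report `no-production` instead of 0/0.
* **Determinism.** The engine contains no randomness.  The only seeded
  component is the Latin-hypercube sampler; one seed fixes draws,
  regression and report.  TSV outputs round to 6 significant digits so
  reruns are byte-identical.

# Problem sizes

All shipped analyses run on the toy fixtures: 120 Euler steps (12 h at
0.1 h) per simulation, networks of 5–9 reactions, pairwise screens of two
to three models, 10-draw hypercubes.  These sizes were chosen so the
whole test suite and the acceptance script each complete in well under a
minute while still exercising every code path; the engine itself is
generic in the number of species and reactions, with cost dominated by
(steps × species × (2 + products)) simplex solves.

# Known limitations

* No spatial structure, lag phases, death rates or maintenance beyond
  what a model encodes; no enzyme-level regulation.
* Uniform uptake kinetics for all metabolites is a strong simplification;
  per-metabolite overrides exist but default values dominate results.
* Quasi-steady-state FBA ignores transient metabolite pools; absolute
  titres are indicative, trends are the reliable output.
* The halved-baseline interaction bands make `+` the default verdict for
  an unaffected partner (see above); read labels with that convention in
  mind.
* The screening layer targets pairs; the engine accepts N species, but no
  exhaustive higher-order screen is provided.
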