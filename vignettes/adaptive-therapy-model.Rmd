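---
title: "An evolutionary Lotka-Volterra model of adaptive abiraterone therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evolutionary Lotka-Volterra model of adaptive abiraterone therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptlv)
```

## The model

Metastatic castrate-resistant prostate cancer under abiraterone is modeled
as an evolutionary game between three phenotypes, indexed in the fixed
order

1. **T+** — androgen-dependent cells that survive androgen deprivation only
   by consuming testosterone produced by others ("cheaters"),
2. **TP** — cells expressing CYP17A1 that produce their own testosterone
   (a public good), and
3. **T−** — androgen-independent cells, resistant to abiraterone.

Abundances $x_i$ (cells) follow Lotka–Volterra competition,

$$\frac{dx_i}{dt} = r_i x_i\left(1 - \frac{\sum_j a_{ij} x_j}{K_i}\right),$$

with unit intra-type coefficients ($a_{ii}=1$) and inter-type coefficients
$0 < a_{ij} < 1$ ($a_{ij}$ = effect of type $j$ on type $i$). Serum PSA is a
proxy for burden: every cell secretes one PSA unit per day and half the
serum pool clears per day,

$$\frac{d\,\mathrm{PSA}}{dt} = \sum_i x_i - 0.5\,\mathrm{PSA},$$

so at any population equilibrium $\mathrm{PSA}^\* = 2\sum_i x_i$ exactly.
PSA units are arbitrary; no ng/ml conversion is attempted.

The drug acts only through carrying capacities, and instantaneously (no
pharmacokinetics):

| parameter | off drug | on drug | meaning |
|---|---|---|---|
| $K_1$ | $1.5\,x_2$ | $0.5\,x_2$ | each TP cell supports 1.5 (resp. 0.5) cheaters |
| $K_2$ | 10 000 | 100 | abiraterone collapses the TP niche |
| $K_3$ | 10 000 | 10 000 | T− is unaffected |

Growth rates default to 10% of the doubling-time-derived rates of the
LNCaP, H295R and PC-3 cell lines, $r = 0.1 \times (0.278, 0.355, 0.665)$
per day; cell-line rates are upper bounds on in-vivo growth, and the
untreated equilibrium composition does not depend on $r$ at all. Whether
the $K_2$ collapse represents death or quiescence is left open; the model
is agnostic.

When $K_i$ falls below an internal floor ($10^{-9}$ cells — only possible
for T+ once TP is extinct) the logistic bracket is replaced by $-1$, i.e.
maximal per-capita decline $-r_i x_i$. This is the bounded continuous limit
of the bracket as $K \to 0$ and keeps the vector field Lipschitz.

## The admissible competition matrices

Two qualitative rules order the six inter-type coefficients: deprived of
exogenous testosterone, T+ is the weakest competitor; and T− presses harder
on TP than on T+. Formally
$a_{31}>a_{21}$, $a_{32}>a_{12}$, $a_{13}>a_{23}$, $a_{13}>a_{12}$,
$a_{23}>a_{21}$, $a_{32}>a_{31}$.
Exactly 22 of the $6! = 720$ rank assignments satisfy all six
(`enumerate_orderings()`, kept in a canonical lexicographic order so that
"ordering #k" is reproducible). Ranks are mapped onto the fixed value grid
$(0.4, 0.5, \dots, 0.9)$; ties are disallowed because the taxonomy below
counts strict orderings. The 22 arrangements are the model's notion of
patient-to-patient variability, and `sample_virtual_patient()` draws them
uniformly.

## Equilibria, invasion and the responder taxonomy

Because $K_1 \propto x_2$, every candidate community (subset of phenotypes)
has a *linear* steady-state system; `solve_community()` solves it and
rejects communities with non-positive abundances (T+ can never stand
without TP). The untreated ESS is the feasible community that is internally
stable (community Jacobian, with the $K_1$–$x_2$ coupling differentiated
through) and uninvadable: every absent type has non-positive invasion
fitness $1 - \sum_j a_{ij}\hat x_j / K_i$. Both the invasion calculation and
long-horizon forward integration are implemented and cross-checked in the
test suite; they agree on community membership (operationalizing "absence"
as a final frequency below $10^{-4}$) for every ordering except one
knife-edge case discussed below.

Patients are classified by the fate of T− at the untreated ESS:

* **best responders** — T− invasion fitness strictly negative (resistance
  structurally excluded before therapy): 12 of the 22 orderings;
* **non-responders** — T− equilibrium frequency ≥ 20%: 6 orderings;
* **responders** — everything in between: 4 orderings.

One ordering (#11 in canonical order) is a genuine knife edge: the T+/TP
boundary equilibrium satisfies the full three-type system exactly, so T−'s
invasion fitness is exactly zero and a line of equilibria connects the
boundary to the interior. We classify neutral invasion as *responder* — a
resistant clone is not excluded there, merely not amplified — which is also
what makes the partition above come out 12/4/6 rather than 13/3/6. Another
ordering sits exactly on the 20% cut and is counted as a non-responder
(the cut is "at least 20%"). Both decisions are taken with a $10^{-9}$
tolerance so floating-point noise cannot flip them.

## Initialization and the resistant inoculum

A simulated patient starts at the ESS frequencies with total burden and
PSA at 25% of their untreated equilibrium values. For best responders the
ESS contains no T− at all, yet resistance does emerge under therapy; since
the mechanism of emergence is outside the model, we seed a configurable
inoculum (default 1 cell) into $x_3$ at $t = 0$. Pre-therapy it decays
(negative invasion fitness); under drug it is released. Milestone times for
best responders scale logarithmically with this inoculum, which is why it
is exposed as a parameter rather than hidden.

## Treatment policies

All regimens share the pre-therapy phase: untreated growth until PSA first
reaches 80% of its untreated equilibrium value — the clinical trigger. The
PSA value at the trigger is the *baseline* for all later thresholds.

* **untreated** — no drug;
* **MTD** — drug on continuously from the trigger;
* **metronomic** — 240 days of continuous induction, then a fixed,
  state-blind cycle. The cycle is off-first (the induction block is itself
  a long on-block) with 84 days off / 28 days on, i.e. 25% on-time. The
  published protocol this emulates predates PSA-linked scheduling and does
  not state its interval lengths; 28/84 is this package's calibration and
  is exposed in the `regimen()` fields;
* **adaptive** — hysteresis cycling: drug stops when PSA falls to 50% of
  baseline and restarts when it returns to baseline. Continuous monitoring
  (event detection) is the default; `monitoring = "interval"` evaluates the
  rule only at 4-weekly labs, mimicking trial practice.

Dose accounting reports drug-on days as a percentage of the window from
the trigger to progression or horizon, so MTD is exactly 100% over its own
window and policies remain comparable.

Progression is declared when T− holds at least 90% of the tumor while PSA
stays above 50% of baseline continuously for 84 days (two consecutive
12-week imaging intervals); it is defined relative to therapy, so untreated
runs never "progress".

## Numerical choices

* Integration uses `deSolve`'s `lsoda`/`lsodar` (relative tolerance
  $10^{-8}$, absolute $10^{-10}$, maximal step 1 day), piecewise between
  drug switches with the state handed across; capacities change
  discontinuously at switches.
* The therapy trigger and adaptive switches are located by the
  integrator's root finder, so switch times are accurate to solver
  tolerance. Frequency milestones (5%, 90%) are refined between dense
  1-day output samples by root finding on a local spline; for the smooth
  trajectories here this is well inside the $10^{-3}$-day reporting
  target, and the tests verify milestones move by less than 0.1% under a
  10× tolerance tightening.
* The horizon defaults to 10 000 days; "indefinite" means a milestone was
  not reached by the horizon. Reported abundances are clamped at zero
  (integrator noise near extinct populations is of order the absolute
  tolerance).
* Tests and examples run the full default problem sizes: 22-ordering
  classifications, 10 000-day simulations of both representative patients
  under all four regimens, and 22 000 virtual-patient draws for the
  sampling check; the whole suite completes in well under a minute.

## What the generator emulates — and what it does not

The virtual-patient space is exactly the 22-ordering grid with default
capacities and growth rates: it captures between-patient variability in
community structure, which is what determines responder class, cycle
length and time to competitive release. It does *not* emulate measurement
noise in PSA, stochastic birth–death of small clones (a 1-cell inoculum is
treated as a continuum density), spatial structure, pharmacokinetic delays,
or inter-patient variation in growth rates and capacities. Passing tests
therefore validate the deterministic game-theoretic machinery, not the
model's fidelity to any individual clinical trajectory.

## Known limitations

The $K_2\!:10\,000 \to 100$ collapse makes the on-drug dynamics extremely
fast: the sensitive compartment crashes within days of each switch-on, and
PSA (serum half-life ~2 days) follows almost immediately. Two consequences
are worth knowing before interpreting milestone tables:

* T− is competitively suppressed only when the community is close to its
  full untreated equilibrium. Because therapy confines the tumor to a
  corridor well below that equilibrium (between 50% and 100% of the
  80%-of-equilibrium baseline), the resistant clone has positive growth
  throughout therapy for every admissible matrix, and each
  adaptive cycle adds to it. Under these equations adaptive scheduling
  *delays* competitive release relative to MTD (and uses a small fraction
  of the drug) but cannot prevent it indefinitely.
* Absolute milestone times for best responders depend on the unobservable
  T− inoculum; treat them as ordinal comparisons between policies rather
  than calendar predictions.

The transient after initialization is also worth noting: because
$r_3 > r_2 > r_1$ and $K_1$ tracks $x_2$, a tumor released at 25% of its
equilibrium overshoots in T− frequency (for representative patient 2 the
5% mark is crossed on day 26.5, long before therapy triggers on day 96.8,
with a peak near 10% before relaxing to the 2.4% equilibrium). Frequency
milestones can therefore predate therapy and are identical across regimens
whenever they fall in this shared phase — a structural property the test
suite asserts.
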