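---
title: "Discrete-time kinetics of beta-amyloid aggregation: model, stability, interventions"
author: "AbetaKinetics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time kinetics of beta-amyloid aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbetaKinetics)
```

## The model and its assumptions

Soluble β-amyloid monomers aggregate stepwise and irreversibly: a monomer
meets an $i$-mer and forms an $(i{+}1)$-mer, until $n$ monomers have been
bound into an oligomer, the species treated here as the toxic end product.
The model tracks the abundances $M_1, \ldots, M_{n-1}$ of monomers through
$(n{-}1)$-mers in discrete time (step size fixed at one unit) under four
assumptions: (i) only monomers react with higher species (no
aggregate–aggregate fusion), (ii) aggregation is irreversible (no
fragmentation, no feedback of oligomers into the monomer pool), (iii)
monomers are replenished by a saturating source, and (iv) $n$ monomers per
oligomer, with $n = 6$ the default for amyloid.

The source is the Beverton–Holt form
$f(M_1(t)) = \delta M_1(t)\,[1 - M_1(t+1)/\gamma]$, written with the
*next* monomer level inside the bracket. That implicit convention is what
makes the scheme solvable in closed form: writing every loss term at time
$t{+}1$ and every gain term at time $t$, each balance equation is linear
in its single unknown, and the update map is

$$M_1(t+1) = \frac{(\delta+1)\gamma M_1}
  {\gamma + \delta M_1 + 2\gamma K_1 M_1 + \gamma\sum_{i=2}^{n-1} K_i M_i},
\qquad
M_j(t+1) = \frac{M_j + K_{j-1} M_1 M_{j-1}}{1 + K_j M_1}.$$

All right-hand sides use time-$t$ values only; there is no sequential
in-place updating. With aggregation switched off the first component is
exactly the classical Beverton–Holt map, whose iterates rise monotonically
to the carrying capacity $\gamma$ with growth ratio falling from
$\delta+1$ toward 1. `incrementResiduals()` re-derives any step from the
balance equations independently of the closed form, and the test suite
holds the two routes together to $10^{-10}$ relative.

Two bookkeeping choices deserve emphasis. First, the scheme's mixed time
indexing means monomer-equivalent mass is *not* conserved even without the
source; we implement the scheme as stated and expose the drift through
`massAudit()` rather than silently "fixing" it. Second, the final reaction
removes mass at rate $K_{n-1} M_1(t) M_{n-1}(t+1)$ without booking it
anywhere; the package accumulates exactly that amount into the oligomer
pool `O`, which makes oligomer production measurable (for the seeding
experiment) without altering the dynamics. A consequence worth knowing:
from a monomer-only start the chain fills one species per step, so the
first oligomer flux lands at $t = n - 2$.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| $\delta$ | net monomer reproduction rate per step | 1 (example config) | dimensionless |
| $\gamma$ | monomer carrying capacity | 100 | abundance |
| $K_i$ | rate constant, monomer + $i$-mer | 0.01–0.05 | per abundance per step |
| $n$ | monomers per oligomer | 6 | count |

No empirical parameter values exist for this model; all quantities are
treated as dimensionless abundances and rates. The example configuration
uses $\delta = 1$, $\gamma = 100$ and an ascending $K$ ladder
$0.01, \ldots, 0.05$ — mid-range values for which both the stable and the
certificate-free regime are exercised. Validity is enforced throughout:
$\delta, \gamma, K_i > 0$, $n \ge 3$, `length(K) == n - 1`. Because the
equilibrium and size-inversion formulas divide by $K_1$, the
no-interaction limit is a mode switch rather than $K_i = 0$.

## Equilibria and stability

`extinctionEquilibrium()` and `coexistenceEquilibrium()` return the two
closed-form fixed points; $M_1^* = \delta\gamma/(\delta + n\gamma K_1)$
always lies strictly inside $(0, \gamma)$, and $M_i^*/M_1^* = K_1/K_i$.
Every point with $M_1 = 0$ is also fixed (nothing reacts without
monomers), which is why the equilibria census `findEquilibria()` searches
the region $M_1 > 0$: a multi-start Newton search (random nonnegative
starts plus the closed-form candidates, de-duplicated at $10^{-5}$
relative) finds exactly one equilibrium there.

Stability is local, via the Jacobian of the map. At extinction the
Jacobian is $\mathrm{diag}(\delta+1, 1, \ldots, 1)$: unstable for every
$\delta > 0$, though non-hyperbolic — the $n-2$ unit eigenvalues are
recorded, and magnitudes within $10^{-9}$ of 1 are labelled "marginal"
rather than forced into stable/unstable. At coexistence the Jacobian has a
dense first row and a bidiagonal remainder; the cross-couplings through
$M_1$ cancel exactly at the equilibrium, which the finite-difference
oracle `numericalJacobian()` confirms entrywise to $10^{-6}$.

The Gershgorin certificate bounds all eigenvalues inside the unit circle
when row 1 satisfies $a_{11} \pm r_1 \in (-1, 1)$ — algebraically the sum
condition $\sum_{i\ge 2} K_i < (\delta + 2\gamma K_1)/\gamma$, with the
lower bound reducing to the always-true inequality
$\delta(\delta + 2\gamma K_1) < (\delta+1)(\delta + n\gamma K_1)$ — and
each chain row satisfies $K_{i-1} \le K_i$. Two numerical subtleties are
handled explicitly. Equality $K_{i-1} = K_i$ places a disk tangent to the
unit circle: the report flags the boundary case and withholds the
certificate, deferring to eigenvalues. And the certificate is sufficient,
not necessary: `classifyEquilibrium()` therefore always reports the
eigenvalue truth (spectral radius, classification) alongside the theorem
flags, and `destabilizationCriterion()` — the mirrored strict inequality
$\sum_{i\ge 2} K_i > (\delta + 2\gamma K_1)/\gamma$ — is reported as a
certificate-loss condition, not as a proof of instability, since
Gershgorin has no converse. The radius used for row 1 is the one implied
by the Jacobian entries, $r_1 = M_1^* \sum_{i\ge2} K_i/(\delta+1)$, which
is the version the stability conditions themselves require.

## The size inversion and its correction mode

Solving the coexistence relation for the aggregation number gives
$n = \delta(\gamma - M_1^*)/(\gamma K_1 M_1^*)$; this is the default
(`corrected`) mode of `inferOligomerSize()` and round-trips
`coexistenceEquilibrium()` to $10^{-8}$ over randomized parameters. A
widely quoted variant omits the $\gamma$ in the denominator; substituting
the equilibrium formula into that variant returns $n\gamma$ rather than
$n$, as can be checked by hand. The variant is kept available as
`as_printed` for reference — selecting it emits a message — and the
default remains the exact inversion. The real-valued size is primary;
`sizeRounded` (half-to-even) is a labelled convenience.

## Interventions

`scanParameter()` sweeps $K_1$ (catalyst) or $\delta$ (suppressant),
reporting equilibrium level, theorem flags, destabilization flag and
spectral radius per grid point; default grids are log-spaced over two
decades around the baseline. The flag transition along a $K_1$ grid
brackets the analytic boundary
$K_1^{thr} = (\gamma\sum_{i\ge2}K_i - \delta)/(2\gamma)$ within one cell;
a nonpositive threshold is reported as "not attainable by reducing $K_1$
alone". `seedingExperiment()` operationalizes "time to aggregation" as
the first passage of the cumulative oligomer pool over a user threshold —
a definition chosen because the sigmoidal-seeding picture is otherwise
qualitative — and tests only the monotone claim: more initial monomers
never delay the crossing.

## Synthetic parameter sets, and what the tests do not show

`randomParameters()` draws $\delta \in [0.1, 10]$,
$\gamma \in [10, 1000]$, $K_i \in [10^{-4}, 10^{-1}]$ log-uniformly, wide
enough to reach both the certified-stable regime (rejection-sampled on the
theorem conditions, $K$ sorted ascending) and the destabilized regime.
These ranges are a modelling choice, not data: the generator emulates
plausible dimensionless kinetic regimes, and what the passing properties
show is internal consistency of the mathematics — fixed points, Jacobians,
certificates, monotonicities — over those regimes. They do not show that
real Aβ kinetics follow this map: the model is unvalidated against
experimental aggregation data, has no fragmentation or secondary
nucleation, and its sigmoidal/seeding phenomenology enters only through
the monotone property actually tested.

## Numerical choices

Algebraic identities are asserted at $10^{-10}$ relative, convergence
claims at $10^{-6}$ relative (both configurable in the relevant
functions); finite differences are central with step
$10^{-6}\max(1, |x_j|)$, evaluated on the raw update formulas so that
differencing at the extinction boundary admits the small negative
excursions; Gershgorin containment is checked with $10^{-12}$ slack;
trajectory tables are written at 17 significant digits so CSV/TSV output
round-trips below $10^{-12}$. Test problem sizes — 1000-draw property
loops, 100-draw Jacobian comparisons, horizons of 200 steps — were chosen
as the smallest sizes at which the asserted tolerances are meaningful.

## Known limitations

Local stability only (no center-manifold analysis at marginal points, no
global claims); irreversible aggregation only; the mass-booking drift of
the mixed-index scheme is diagnosed, not removed; and the equilibria
census is a numerical search — it cannot prove that no further fixed
points exist outside the sampled region, only that none were found.
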