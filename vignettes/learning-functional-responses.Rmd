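---
title: "Learning-modulated functional responses: model, numerics and shape diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning-modulated functional responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frlearn)
```

## The model

A predator's functional response — prey consumed per trial as a function
of prey offered — is classically described by Holling's disk equation

$$N = \frac{aDT}{1 + ahD},$$

with attack rate $a$, handling time $h$, prey density $D$ and trial
length $T$. Its shape is the saturating type II hyperbola. frlearn asks
what happens when the predator *learns*: both parameters are allowed to
improve with accumulated foraging experience, measured as the cumulative
number of prey consumed $N$ (treated as a continuous quantity, matching
the differential-equation formulation):

$$a(N) = a_m - (a_m - a_0)\,e^{-l_a N}, \qquad
  h(N) = h_m + (h_0 - h_m)\,e^{-l_h N}.$$

$a$ rises from its naive value $a_0$ to the species' ceiling $a_m$ at
rate $l_a$ per consumed prey; $h$ falls from $h_0$ to the floor $h_m$ at
rate $l_h$. The distances $\Delta_a = a_m - a_0$ and
$\Delta_h = h_0 - h_m$ are the *learning amplitudes*; if an amplitude or
its rate is zero that channel cannot learn, and with both channels inert
the model collapses exactly to the disk equation.

Consumption and learning are coupled through a single scalar ODE. At
constant prey density (the "Holling" trial, consumed prey replaced):

$$\frac{dN}{dt} = \frac{a(N)\,D}{1 + a(N)\,h(N)\,D},$$

and with prey depletion (the "Rogers" random-predator trial, a fixed
pool of $N_0$ prey removed without replacement), the state is the
available prey $N_a = N_0 - N$:

$$\frac{dN_a}{dt} = -\frac{a(N)\,N_a}{1 + a(N)\,h(N)\,N_a}.$$

Depletion matters for learning: as the arena empties, opportunities to
learn disappear with it.

### Sign conventions and formulation

Two equivalent formulations are implemented. The default substitutes the
closed-form learning curves $a(N)$, $h(N)$ directly into the scalar ODE;
the alternative (`formulation = "coupled"`) evolves $a$ and $h$ as extra
state variables via $da/dN = +l_a(a_m - a)$ and $dh/dN = -l_h(h - h_m)$
chain-ruled through $dN/dt$. The positive sign on the attack-rate
derivative is the one consistent with the closed form and with an attack
rate that *increases* with experience; the substitution formulation is
the default precisely because it is immune to sign slips in the coupled
system, and a property test keeps the two within $10^{-6}$ of each other
across randomized parameter draws.

## Numerics

All dynamics are integrated by fixed-step classical fourth-order
Runge-Kutta. Defaults follow the simulated experimental protocol:
$T = 1$ time unit, $dt = 1/1024$, so 1024 steps per trial; $t_{\max}$
must be an integer multiple of $dt$ (within $10^{-12}$) so the final
step is never fractional. The learning curves are evaluated at every
internal Runge-Kutta stage value of $N$, not frozen per step, keeping
the one-step method consistent. There is no randomness anywhere: results
are bit-reproducible for a fixed step and grid.

Two engines produce identical trajectories: a deSolve (`rk4`) route used
for single trajectories and cross-checks, and a compiled kernel that
advances every offered-prey value of a response curve as an independent
scalar ODE in one vectorised pass — the workhorse for parameter sweeps.
A test asserts their agreement to $10^{-12}$.

Accuracy is anchored to analytic oracles rather than to the integrator
itself:

* no learning, constant density: the disk equation, matched to a
  relative error below $10^{-9}$ at $dt = 1/1024$;
* no learning, depletion: the classic implicit random-predator solution
  $N = N_0(1 - e^{-a(T - hN)})$, solved by bracketed root-finding
  (`uniroot` plus Newton polish to $|f| < 10^{-12}$) and cross-checked
  against the equivalent Lambert-W form, matched below $10^{-7}$;
* one separable learning-active case
  ($a_0 = 0.5, a_m = 1, l_a = 1, h = 0, D = 10$), whose exact solution
  $N(T) = \ln\!\big(0.5\,(1 + e^{10})\big)$ is matched below $10^{-6}$;
* Richardson step-halving ratios of $\approx 2^4$, confirming global
  fourth order.

With depletion, the state is clamped at zero only within a $10^{-9}$
tolerance; a step that drives available prey genuinely negative raises a
numerical-failure error naming the step, as does any non-finite state.

## Shape diagnosis

The response-curve shape is read off its second derivative with respect
to offered prey, computed by second-order central differences on the
uniform offered grid (interior points only). Simulated curves are
noiseless, so no smoothing is applied by default; an optional
moving-average smoother exists for empirical curves read from CSV. For
classification, offered and consumed are each affinely rescaled to
$[0, 1]$, making the thresholds scale-free; the raw second derivative is
reported alongside because curvature maps are conventionally drawn on
the raw scale.

A type III (sigmoid) curve is convex at low density — learning gains
outpace the handling-time limitation — and concave above the inflection
point, where the curve becomes purely handling-limited. The inflection
is located as the first positive-to-negative crossing of the second
derivative that persists for at least $k = 5$ grid points on each side
(suppressing single-point floating-point sign flips), linearly
interpolated between the bracketing points; with several persistent
crossings the first (lowest offered value) is reported.

The classifier applies, in order, on the normalized second derivative
$g$:

1. $\max|g| < \varepsilon_{\mathrm{lin}}$ — **TYPE_I** (linear);
2. persistent crossing and $\max g \ge \varepsilon_{\mathrm{pos}}$ —
   **TYPE_III**;
3. persistent crossing and $0 < \max g < \varepsilon_{\mathrm{pos}}$ —
   **NEAR_TYPE_II** (a sigmoid signature too weak to see);
4. $g \le 0$ everywhere (within $\varepsilon_{\mathrm{lin}}/10$) and
   $\min g < -\varepsilon_{\mathrm{lin}}$ — **TYPE_II**;
5. otherwise — **NEAR_TYPE_I** (small-magnitude curvature that turns
   positive without a full sigmoid signature).

The defaults $\varepsilon_{\mathrm{lin}} = 0.02$ and
$\varepsilon_{\mathrm{pos}} = 0.05$ are calibration constants, not
derived quantities: the boundary between "near-zero" and "noticeable"
curvature is inherently conventional, so both are exposed as arguments
everywhere. The persistence parameter $k$ interacts with the offered
step — $k = 5$ at step $0.5$ demands a convex run of at least 2.5
density units — so very strong attack learning, whose inflection sits
almost at the grid origin, classifies as NEAR_TYPE_I rather than
TYPE_III. This is a deliberate consequence of requiring a *visible*
convex region.

```{r example}
p <- fr_predator(a0 = 0.2, am = 1, la = 0.2, h0 = 0.1, hm = 0.1, lh = 0)
curve <- response_curve(p, seq(1, 200, by = 0.5), fr_config())
classify_curve(curve)
```

## Parameter sweeps

`sweep_attack_learning()` maps shape over the $(a_0, l_a)$ plane with
handling frozen ($a_m = 1$, $h_0 = h_m = 0.1$, $l_h = 0$);
`sweep_handling_learning()` maps the $(h_m, l_h)$ plane with attack
frozen ($a_0 = a_m = 0.1$, $h_0 = 1$, $l_a = 0$). Each, with and without
depletion, classifies one simulated curve per cell and records the
shape, inflection location, raw and normalized maximum curvature, and
consumption at the largest offered value. The published resolution is
1001 × 1001 cells per map with an offered grid of 1–200 at step 0.01;
because classification is stable under grid refinement away from region
boundaries (verified on probe points for offered steps 0.5 vs 0.25 and
integration steps $1/64$ vs $1/1024$), the package defaults to offered
step 0.5 and the test suite exercises 101 × 101 maps at $dt = 1/64$,
which reproduce the same region layout in about a minute per map. Cells
are independent; results are identical to sequential evaluation by
construction.

The emergent layout: attack-rate learning at low $a_0$ and appreciable
$l_a$ produces type III; no learning anywhere produces type II;
depletion *dampens* maximum curvature cell-wise in the sigmoid region
(less prey left means less learning), although at high $a_0$ depletion
itself creates an early turning point and can add curvature instead —
the cell-wise dampening test is therefore probed over
$a_0 \in [0.01, 0.25]$, $l_a \in [0.2, 1]$.

## A known limitation of the handling-learning channel

Within this model family, handling-time learning alone cannot linearise
the response over the density range 1–200 as long as
$l_h \le 1$. The reason is a budget argument: the total time spent
handling after consuming $N$ prey is
$\int_0^N h(n)\,dn = h_m N + \Delta_h\,(1 - e^{-l_h N})/l_h$, which for
$h_m = 0$, $h_0 = 1$ saturates at $1/l_h \ge 1 = T$. Handling can
therefore absorb the entire trial for every admissible $l_h$, and the
simulated response curve remains concave — type II — everywhere in the
$(h_m, l_h)$ plane; its normalized second derivative never becomes
positive. A qualitatively different regime (curves flattening toward
type I, with a transient positive-curvature band) exists only when the
effective learning rate exceeds $1$ per consumed prey — for instance
under the alternative "retention" parameterisation
$h(N) = h_m + \Delta_h (1-l)^N$, whose effective exponential rate
$-\ln(1-l)$ diverges as $l \to 1$ (instantaneous learning). The package
implements the exponential-rate curves above, with $l_a, l_h \in [0,1]$,
throughout; two acceptance expectations that presuppose the
instantaneous-learning regime are left failing by design, and the
acceptance script documents the omission of the corresponding boundary
scan on standard error rather than reporting a fabricated value.

## Degenerate inputs and edge cases

* $D = 0$ or $N_0 = 0$: zero consumption, trivially integrated.
* $h = 0$: the intake rate is linear in density (type I form), capped by
  nothing; with $h > 0$ it is capped at $1/h$.
* Zero learning amplitude with a nonzero rate (or vice versa): constant
  parameters; handled exactly, including in the compiled kernel.
* Constant consumed values: the normalized curve is defined as
  identically zero (the affine rescaling would otherwise divide by
  zero).
* Offered grids must be uniform (relative deviation $< 10^{-9}$),
  strictly increasing, and at least 7 points long — the smallest length
  for which interior second differences and the persistence rule are
  meaningful.

## What the simulations do and do not show

Everything here is a noiseless ODE world: a single deterministic
predator whose experience is a continuous variable, no satiation, no
stochastic encounter process, no individual variation, no prey
switching, no forgetting. Passing tests demonstrate the internal
consistency of the model, the integrator and the classifier — not that
real foraging data follow these curves. Classifying *empirical* curves
with `run_classify()` is supported (with optional smoothing), but the
thresholds were calibrated on noiseless simulated curves and noisy data
will generally require smoothing and larger thresholds; no statistical
model selection between response types is attempted.
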