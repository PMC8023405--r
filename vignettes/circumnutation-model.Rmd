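---
title: "A morphoelastic rod model of circumnutating plant shoots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A morphoelastic rod model of circumnutating plant shoots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphorod)
```

## The model

A growing shoot is represented as an unshearable, elastically inextensible
rod with circular cross section of radius $r$: a centerline
$\mathbf{p}(s,t)$ with arc length $s \in [0, \ell(t)]$ from the clamped
base to the free apex, and an orthonormal director frame
$\{\mathbf{d}_1, \mathbf{d}_2, \mathbf{d}_3\}$ per cross section with
$\mathbf{d}_3 = \partial_s \mathbf{p}$ the tangent. The Darboux (strain)
vector $\mathbf{u}$ generates the frame along the rod,
$\partial_s \mathbf{d}_j = \mathbf{u} \times \mathbf{d}_j$; its local
components $u_1, u_2$ are the flexural strains and $u_3$ the torsional
strain. Given a strain field, `integrate_frame()` reconstructs the shape.

The visible strain splits additively into a spontaneous (intrinsic) part
$\mathbf{u}^\*$, set by differential growth, and an elastic part
$u^e_j = m_j / K_j$ produced by the bending/torsional moments of the
gravity loading. Quasi-static balance (inertia is negligible on growth
time scales) gives $\mathbf{n} = q(\ell - s)\,\mathbf{g}$ for the contact
force, with $q = \rho g A$ the weight per unit length, and the moment
equation $\partial_s \mathbf{m} = q(\ell - s)\, \mathbf{g} \times
\mathbf{d}_3$ with $\mathbf{m}(\ell) = 0$. Because $\mathbf{d}_3$ is
itself unknown, `solve_equilibrium()` iterates the coupled system to a
fixed point (details below).

Three mechanisms drive the spontaneous flexural strains, each multiplied
by the local relative elemental growth rate
$\dot\varepsilon$ (so they act only in the growth zone):

* **endogenous oscillator** — a harmonic driver of period $\tau_e$
  rotating the growth gradient around the section:
  $\dot u^\*_1 = \alpha \dot\varepsilon / r\,\cos(2\pi t/\tau_e)$,
  $\dot u^\*_2 = \alpha \dot\varepsilon / r\,\sin(2\pi t/\tau_e)$;
* **gravitropism** — reorientation toward the perceived gravity vector
  $\mathbf{h}$ (the normal of the statolith pile, relaxing viscously to
  $-\mathbf{g}$ on the avalanche time $\tau_a$, Eq. implemented in
  `step_statoliths()`), with an exponential memory kernel of width
  $\tau_m$ and a discrete reaction delay $\tau_r$;
* **proprioception** — delayed straightening against the remembered
  *visible* curvature components, with its own memory and reaction times
  $\bar\tau_m, \bar\tau_r$.

The torsional intrinsic strain is held at zero (no twining), and the
three pathways superpose without cross-talk.

Subapical growth uses a piecewise-constant REGR: zero below the growth
zone of length $\ell_g$, $1/\tau_g$ inside it. On the fixed material
domain $[0, \ell_0]$ this growth law has a closed-form solution
(`advance_growth()`): exponential elongation
$\ell = \ell_0 e^{t/\tau_g}$ while $\ell \le \ell_g$, then linear
elongation at rate $\ell_g/\tau_g$ with the sub-basal region
progressively frozen; the exit time $t^*(S)$ of each material point
feeds the lignification law
$E = E_1 - (E_1 - E_0)\,e^{-\max\{0,\,t - t^*\}/\tau_\ell}$.

## Parameters

`preset_table1()` collects the reference bundle (SI units internally;
human units at the I/O boundary): $\beta = 0.8$, $\eta = 20$,
$\tau_a = 2\,$min, $\tau_e = 20\,$min,
$\tau_m = \tau_r = \bar\tau_m = \bar\tau_r = 12\,$min,
$\tau_g = 20\,$h, $\tau_\ell = 6\,$d, $r = 0.5\,$mm, $\ell_g = 7\,$cm
(the observed range is 4–7 cm; the largest value keeps shoots up to 7 cm
entirely inside the growth zone, which the constant-length analysis
assumes), $\nu = 0.5$, $\rho = 10^3\,$kg/m³, $E_0 = 10\,$MPa,
$E_1/E_0 = 200$. The endogenous sensitivity $\alpha \in [0, 1]$ is the
free dial between purely exogenous and mixed dynamics.

A note on the shear modulus: the isotropic relation
$\mu = E/(2(1+\nu))$ is the default. The alternative convention
$\mu = 2E(1+\nu)$ is selectable
(`shear_modulus_convention = "as_printed"`) because it circulates in
parts of the rod-mechanics literature, but it makes $\mu > E$, which is
unphysical for an isotropic material at $\nu = 0.5$; torsional stiffness
barely matters in the planar/circular regimes studied here, so the
choice is surfaced rather than consequential.

## Numerical design

**Frame integration.** Each grid interval applies the exact rotation
generated by the interval-midpoint strain vector (exponential map), so
director frames are orthonormal by construction and the scheme is
second-order; a modified Gram–Schmidt pass removes the $10^{-16}$-scale
round-off drift per node. Constant-strain fields (straight rods, arcs,
helices) are reproduced exactly.

**Equilibrium.** The coupled system (moment balance + constitutive law +
frame reconstruction) is solved by fixed-point iteration with
under-relaxation 0.5, warm-started from the previous time step, and
declared converged when the tip moves less than $10^{-9}$ m between
iterates. The moment quadrature is a composite trapezoid accumulated
from the free tip, so $\mathbf{m}(\ell) = 0$ holds exactly. The
fixed-point map loses contraction as $\ell$ approaches the self-buckling
length $\ell_c$ (its leading linear eigenvalue is $(\ell/\ell_c)^3$), so
probes close to $\ell_c$ need a larger `max_iter`; non-convergence is
raised as a typed condition and interpreted as proximity to a fold.

**Delay integrals.** The distributed-delay integrals
$(1/\tau_m)\int_{-\infty}^{t-\tau_r} e^{-(t-\tau_r-\tau)/\tau_m} f(\tau)\,
d\tau$ are advanced by a recurrence that integrates the exponential
kernel exactly against the piecewise-linear interpolant of the sampled
signal, combined with a ring buffer that realizes the discrete delay
exactly (the step is snapped so that $\tau_r/\Delta t$ is an integer).
For a constant signal the kernel mass is exactly 1, which makes the
trivial upright state an exact equilibrium of the discretized system;
a plain trapezoid rule at the same step would bias the mass at the
$2\times10^{-4}$ level, above the accuracy the stability thresholds
need. Histories are primed with the initial condition's values.

**Statoliths.** The avalanche law is advanced with a classical
Runge–Kutta step on the local components (frames held fixed over the
step, the corotational reading of the component-wise law: components are
*not* re-projected when frames rotate) followed by renormalization to
$|\mathbf{h}| = 1$. The scalar projection onto gravity follows the
closed form $-\tanh((t - t_0)/\tau_a)$, which the tests verify to
$10^{-6}$.

**Time stepping.** Reduced model: $\Delta t = \min(\tau_m, \bar\tau_m,
\tau_e)/40 = 18$ s; full model: $\Delta t = \min(\tau_a, \tau_m,
\bar\tau_m, \tau_e)/20 = 6$ s. The spontaneous strains advance by an
explicit Euler step, accurate because all feedback time scales
($\ge 12$ min) are far above the step; grid defaults are 200 nodes for
shape reconstruction and 100 material nodes for the stability and
growth studies (the bisected critical length moves by less than the
$0.01$ cm bracket between 50 and 100 nodes).

**Self-buckling normalization.** The marginal coefficient
$\alpha_0 = q\ell_c^3/(EI) \approx 7.837$ is computed from the
discretized linearized bending eigenproblem
$-\theta'' = \lambda(1-s)\theta$, $\theta(0) = 0$, $\theta'(1) = 0$
(cell-centered second-order finite differences, symmetric generalized
eigensolve, 1000 cells) and cross-checked against the classical closed
form $(9/4)j^2$ with $j$ the first positive zero of the Bessel function
of order $-1/3$; the two agree to $5\times10^{-7}$ relative. With the
reference parameters $\ell_c \approx 7.93$ cm, so the 6.59 cm shoot sits
at $\ell/\ell_c \approx 0.83$.

## Stability analysis

The constant-length reduced model (`simulate_reduced()`) freezes
$\ell \le \ell_g$ and $E = E_0$, takes $\dot\varepsilon = 1/\tau_g$
along the whole rod and $\mathbf{h} = -\mathbf{g}$ (fast statoliths).
Stability is probed in the time domain: a small perturbation is applied
and the late-time envelope of the horizontal tip deflection is fitted
for an exponential rate (`fit_leading_rate()`); `critical_length()`
bisects the shoot length to a 0.01 cm bracket. The perturbation protocol
is a package choice: a uniform planar intrinsic-curvature kick of
amplitude $10^{-4}/\ell$ for rate probes, or a one-period rotating kick
at the delay-oscillator frequency to select the chirality of a limit
cycle. The fitting window is the last 40% of a horizon of 30 reference
periods; a probe is called unstable when the envelope grows by more than
1.5× over the window (or decays below 1/1.5 for stable), falling back to
the sign of the fitted rate in between — the saturation-robust criterion
matters above threshold, where the orbit settles on a limit cycle and
the late-time rate is near zero.

In **microgravity** ($\alpha = \beta = 0$, $q = 0$, $\eta > 0$) the
proprioceptive law is spatially local and linear, so the package derives
its own characteristic relation: with
$u \sim e^{\lambda t}$, $\lambda(1 + \lambda\bar\tau_m) =
-(\eta/\tau_g)\,e^{-\lambda \bar\tau_r}$, whose Hopf root satisfies
$\tan(\omega\bar\tau_r) = 1/(\omega\bar\tau_m)$ and
$\tau_g^{crit} = \eta\,\bar\tau_r \sin x / x$, $x = \omega\bar\tau_r$.
At the reference values this gives $\tau_g^{crit} \approx 3.52$ h with
an onset period of $\approx 88$ min — inside the 70–90 min band of
observed circumnutation periods. A time-domain bisection of the scalar
delay law is kept as an independent cross-check (they agree to 0.2%),
and the threshold is invariant under doubling the shoot length, since
nothing in the weightless law depends on $\ell$. At criticality
$\eta/\tau_g$ is fixed, so halving $\eta$ halves $\tau_g^{crit}$.

In the **graviceptive** case ($\alpha = \eta = 0$) the feedback acts on
the *tilt* (a spatial integral of the strains), which makes the
weightless linearized operator of Volterra type: it has no point
spectrum, perturbations show transient non-normal growth but decay
non-exponentially, and no oscillation onset exists without elastic
deflections — removing the load ($\ell_c \to \infty$) leaves the shoot
stable for every $\tau_g$. With gravity loading the elastic deflection
closes a genuinely destabilizing loop and a critical length appears.

In the **proprio-graviceptive** case (both feedbacks active, Table-style
delays) the bisection at $\tau_g = 20$ h locates
$\ell^\star \approx 6.54$ cm, and proprioception lowers the critical
length relative to the purely graviceptive case (at 6.8 cm the
proprio-graviceptive rod oscillates while the graviceptive one is
stable). Just above threshold the stable attractor is a circular limit
cycle (orbit ellipticity $> 0.98$, radius drift $\sim 0.1\%$ per
period); pendular oscillations exist but are unstable, consistent with
the planar analysis this model generalizes.

With the **endogenous oscillator active** ($\alpha > 0$) just above
$\ell^\star$, the tip spectrum carries two tones — the endogenous period
$\tau_e$ and the limit-cycle period — and traces epitrochoid-like or
hypotrochoid-like patterns depending on whether the two rotations are
concordant or discordant. The rotation direction of the exogenous cycle
is seeded by the perturbation (`spin`), the endogenous one by
`endo_sign`.

## The growing shoot

`run_simulation()` couples everything: per step the growth map and
modulus advance analytically, statoliths relax, the stimulus rates
accumulate on the material grid (strains are material properties, so no
resampling of $\mathbf{u}^\*$ is needed; the equilibrium is solved on
the material nodes' current positions), and the configuration is
re-equilibrated. Passive dilution of the intrinsic curvature by stretch
is *not* applied beyond what the rate laws prescribe — the evolution
laws are rate statements per material section, and adding a dilution
term would double-count the kinematics; this choice is testable by
construction since the frozen-growth limit must (and does) reproduce
the reduced model exactly.

The package ships a worked transition experiment: reference parameters,
$\tau_g = 20$ h, $\ell_g = 7$ cm, $\ell_0 = 5$ cm, $\alpha = 0.5$, 16 h
horizon. The shoot starts subcritical ($\ell_0 < \ell^\star$), where the
tip spectrum is dominated by the endogenous 20-min tone, and grows
through $\ell^\star$, after which the exogenous limit-cycle tone
($\approx 1.5$ h) dominates: the exogenous/endogenous amplitude ratio
crosses 1 (0.12 in the first 6 h against 14 in the last 6 h of the run
used in the tests). The exact trajectory of a published transition
experiment depends on a parameter set not given to printed precision, so
this reproduction is qualitative by design.

## The synthetic track generator and what the tests show

`make_synthetic_track()` produces the superposition of two circular
tones plus optional Gaussian noise — the idealized geometry of pendular
(counter-rotating equal tones), circular, and trochoid-like (two
incommensurate tones) patterns. It emulates the *kinematics* of observed
tip trajectories, not their physiology: real tracks carry drift,
amplitude modulation and measurement noise beyond the isotropic model,
so classifier tests on synthetic tracks validate the spectral logic
(tone recovery, chirality, mirror equivariance, scale invariance), not
field robustness. The pendular/circular ellipticity cutoffs (0.2/0.8)
are this package's operationalization of qualitative labels and are
exposed as thresholds.

## Known limitations

* No torsional spontaneous strain (twining), no tropism cross-talk, no
  phototropism, no hormone transport; memory kernels are exponential by
  parsimony.
* The equilibrium solver is a staggered fixed point, robust up to
  $\approx 0.99\,\ell_c$ with enough iterations but not a continuation
  method: post-buckling branches beyond onset and fold tracking are out
  of scope.
* Stability probing is time-domain for the elastic scenarios; only the
  microgravity case has a closed characteristic relation here.
* Problem sizes in the shipped tests (40–200 nodes, horizons of 30
  oscillation periods) were chosen so the documented thresholds are
  grid-converged at the reported precision; the bisected critical
  length shifts by well under 0.01 cm between 50 and 100 nodes.
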