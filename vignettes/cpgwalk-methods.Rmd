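---
title: "cpgwalk: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpgwalk: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`cpgwalk` simulates treadmill locomotion of the cat hindquarters: a planar
seven-link skeleton (trunk plus thigh, crus and foot on each side) actuated
by fourteen Hill-type muscles, controlled by a pair of two-level half-center
central pattern generators (CPGs) built from activity-based (non-spiking)
neuron models with a persistent sodium current.  Afferent feedback --
velocity and length signals from flexor muscles, force signals from
extensor muscles -- is injected as excitatory synaptic input into the
ipsilateral CPG.  The free parameters of the controller (seven
pattern-formation-to-motoneuron weights and six feedback gains) are
determined by CMA-ES against a cost that rewards walking long with little
muscle activation on a belt whose height under each limb is redrawn from
{-2, 0, +2} cm at every step.  A frozen-variable nullcline analysis exposes
the fast/slow structure of the rhythm-generator dynamics that underlies
adaptive responses to a sudden loss of ground support.

## The motor control model

Each side carries a rhythm generator (RG-F, RG-E), inhibitory interneurons
(IN-F, IN-E) that mediate the mutual half-center inhibition, a
pattern-formation layer (PF-F, PF-E), and one motoneuron pool per muscle.
Two commissural pathways couple the sides: C1 mediates inhibition of the
contralateral RG-F by the ipsilateral RG-F, and V3 mediates inhibition of
the contralateral RG-F by the ipsilateral RG-E through the contralateral
IN-E.  Membrane dynamics follow the activity-based formalism: for RG, PF
and MN populations

    C dV/dt = -INaP - ILeak - ISynE - ISynI,
    INaP = gNaP * mNaP(V) * h * (V - ENa),
    tau(V) dh/dt = hinf(V) - h,

with `mNaP(V) = 1/(1+exp(-(V+40)/6))`, `hinf(V) = 1/(1+exp((V+45)/4))` and
`tau(V) = 320 + 320/cosh((V+35)/15)` ms; IN and CIN populations carry no
persistent sodium current.  The population output
`f(V)` is piecewise linear between `Vth = -50` mV and `Vmax = 0` mV, and
the motor command of muscle m is `u = f(V_MN-m)`.  Synaptic currents are
conductance-based; connection weights are stored non-negative and the sign
of their action lives in the excitatory/inhibitory current expressions.
Inhibition never targets CIN or MN populations, and the supraspinal drive
`d` reaches only the RG centers.

### Parameter provenance

The structural equations above, the activation-function constants, the
time constants of the muscle activation filter (20/32 ms), the feedback
thresholds (`lth = 0.9 lmax`, the 0.6 power on normalized velocity), the
belt speed (20 cm/s), the fall criteria, the cost function with
`kappa = 20` and the 100 s trial cap are fixed by the model definition.
The numerical values of the conductances, reversal potentials, connection
weights, drives, muscle forces, segment masses and contact stiffnesses are
a *synthetic* parameter set constructed for this package in the style of
this model lineage and calibrated so that the stated network behaviors
hold with the exact kinetics above:

* an uncoupled RG-E is tonic under the supraspinal drive while an
  uncoupled RG-F bursts intrinsically (the oscillation window of the
  isolated cell sits near a drive conductance of `gamma*d` ~ 0.02-0.08);
* the coupled single-side RG alternates flexor/extensor activity with a
  period near one second;
* PF and MN populations are non-rhythmic when uncoupled (their `gNaP` is
  an order of magnitude below the RG value);
* the bilateral network locks into anti-phase through the C1/V3 pathways.

Asymmetric RG-to-IN drive (RG-F to IN-F stronger than RG-E to IN-E) is
what lets a strongly driven, tonic RG-E be rhythmically suppressed by the
intrinsically bursting RG-F; the reverse asymmetry destroys the
oscillation.  All values live in `default_params()` and serialize through
`write_params()`/`load_params()`, whose loader refuses to run with any
missing or unknown key.

## Musculoskeletal model

Muscle force is `F = Fmax (a Fl(l) Fv(v) + Fp(l))` with a bell-shaped
force-length curve, a hyperbolic concentric / saturating eccentric
force-velocity curve and an exponential passive term engaging above slack
length; the three curves are injectable so alternative forms can be
dropped in.  Lengths are fractions of `lmax`, anchored at a muscle-neutral
posture (hip 60, knee 90, ankle 100 degrees) where uni-articular muscles
sit at 0.85 and bi-articular at 0.75 of `lmax`; 2 degrees of joint motion
correspond to 1% of `lmax` (GA: 1.5 degrees at the ankle, 4.5 at the
knee), which also fixes each muscle's constant moment arm in meters per
radian as `dl/dq * lmax`.  Moment-arm signs follow each muscle's
anatomical role (a flexor lengthens as its joint extends).

The skeleton is a planar chain: trunk pitch plus hip, knee and ankle
angles per side, with the shoulder translating freely.  Joint angles
increase with extension; with the trunk horizontal and the limb straight
and perpendicular to it, hip = 135 and knee = ankle = 180 degrees.  The
equations of motion are assembled in Jacobian (virtual-work) form --
exactly equivalent to the Lagrangian equations for this chain -- and
integrated by fixed-step RK4 at 0.04 ms together with the neural and
activation states.  Soft range-of-motion stops and a small viscous joint
damping close the model (without knee/ankle stops the chain can snap
through its own singular configurations); both are configurable.

### Treadmill contact

Foot-belt contact is a one-sided viscoelastic element: normal force
`k_n * pen + c_n * d(pen)/dt`, clamped non-negative, with the damping and
the tangential coupling ramped in over the first millimetre of
penetration so forces are continuous in position at the surface.  The
tangential force is viscous, `-c_t * (vx - v_belt)`, against a belt moving
backward at 20 cm/s.  `c_t` is deliberately large (400 N s/m): the foot
then tracks the belt with ~1-2 cm/s of slip under stance-level loads, so
a standing model is inexorably carried into hyperextension and cannot
balance statically -- which is what forces the optimization toward true
stepping.  (With a weak tangential coupling and a stiff forelimb anchor,
CMA-ES reliably discovers a degenerate "lean on the anchor and stand"
solution; the strong coupling plus a soft anchor spring removes that
equilibrium.  This is also why the 0.04 ms integration step is not a
luxury: the tangential coupling adds a ~10^4/s eigenvalue at the foot.)

The forelimbs are a rigid strut fixed to the trunk; their tip is anchored
by a horizontal viscoelastic element and rests on a one-sided vertical
viscoelastic support at the platform height of 2 cm.  The vertical
support is an interpretation (only horizontal elements are part of the
stated constraint, but without vertical support the trunk cannot be
carried); it is documented here and configurable.

### Scenarios and events

* `flat`: belt at height 0.
* `random`: each limb's belt height is redrawn among -2, 0, +2 cm
  (uniformly; the distribution is this package's documented choice) at
  each of its steps.  The redraw is applied at lift-off so the new height
  is met at the next touchdown; redrawing at touchdown would teleport the
  ground into or away from a foot that just landed.
* `hole`: ground support of the left limb is absent during a time window
  (default 0.65 s, about one step, as if a hole in the belt passed under
  the foot), beginning at a configurable time.  Depth is effectively
  bottomless: the foot cannot reach support inside the window.

Touchdown and lift-off are transitions of the normal contact force
through zero, debounced over 15 ms inside the integrator to suppress
grazing-contact chatter.  A trial ends at the cap or at a fall: hip below
5 cm, or a limb airborne longer than 1.5 times its most recent step cycle
(2 s before any cycle exists).

## Initialization and the settle phase

Initial conditions are not part of the model statement.  The package
starts every trial from a standing posture (both toes on the belt, tips
on the platform, hip near 0.24 m) with V at each population's leak
reversal, h at steady state and activations at zero, then holds the
skeleton frozen for a 3 s settle period during which the CPG runs in
fictive conditions (afferents disengaged, since a frozen posture would
feed constant stretch/load signals that jam the half-centers).  Fixed
opposite 6 mV offsets on the two RG-F centers break the left-right
symmetry deterministically; anti-phase locks within about 2 s.  At
release the body is preloaded by 1.2 mm of penetration so the feet carry
weight immediately.

## Optimization

The 13 free parameters are searched by CMA-ES (implemented in the
package: standard rank-one plus rank-mu covariance updates, cumulative
step-size adaptation, box constraints by projection with a mild
out-of-bounds penalty; no pre-installed R implementation exists).  Each
candidate is scored on one randomized-surface trial whose profile seed is
refreshed every generation; the cost is
`kappa * integral(sum a^2) / (v_belt * T) - T`.  The shipped vector was
obtained by staged runs (15 s caps at 0.05 ms steps, then refinement at
longer caps) and walks the full 100 s cap on the randomized surface at
the production 0.04 ms step.  Ablation experiments re-run the search with
the ablated channel's two gains removed from the search space and pinned
at zero.

## Nullcline analysis

For a chosen population (left RG-F and right RG-E are the interesting
ones) all other state variables are frozen at their recorded values at an
analysis time.  The h-nullcline is the static sigmoid `hinf(V)`.  The
V-nullcline solves the frozen `dV/dt = 0` for `h`; it is singular at
`V = ENa` (grids containing `ENa` are rejected) and moves with synaptic
input and afferent feedback.  Intersections are located by sign change on
a uniform V grid refined by bisection and classified by the eigenvalues
of the frozen 2-by-2 Jacobian (numeric central differences): both real
parts negative is a stable node/focus, opposite signs a saddle;
tangential crossings are reported indeterminate.  Fast/slow annotation
thresholds the frozen |dV/dt| at a configurable 0.05 mV/ms: the value is
reported with the annotation, since the underlying concept (jumps between
nullcline branches vs drift along them) has no canonical cutoff.

## What the synthetic world does and does not establish

The generator's defaults *are* the stated conditions: belt at 20 cm/s,
per-step heights from {-2, 0, +2} cm, hole on the left side, 100 s cap,
RK4 at 0.04 ms.  Everything quantitative about cats that the parameter
set cannot inherit from its sources (appendix-level conductances, weight
values, segment inertials, contact stiffnesses) is synthetic, so green
tests establish that *this calibrated model* reproduces the stated
qualitative phenomena -- alternation, anti-phase coordination,
feedback-driven adaptation to ground loss, the nullcline mechanism -- not
that the numbers match any particular animal.  Joint-angle excursions and
muscle activity patterns are plausible but not fitted to measured cat
data, which is out of scope.

## Known limitations

* Sagittal plane only; no lateral balance; forelimbs are a fixed strut.
* Tangential contact is viscous (no stick/slip Coulomb friction).
* One trial per CMA-ES candidate makes the search noisy; averaging is
  configurable but slower.
* The hole response of the re-optimized ablated models is evaluated at
  desk scale (short caps, few generations, a handful of seeds).
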