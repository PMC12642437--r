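# cpgwalk

Simulation of adaptive treadmill locomotion of the cat hindquarters,
driven by a bilateral two-level half-center central pattern generator
(CPG) with structured afferent feedback, for computational
neuroscientists studying spinal control of locomotion.

## The model

A planar seven-link skeleton (trunk + thigh/crus/foot per side; forelimbs
a rigid strut resting on a platform 2 cm above the belt) walks on a
treadmill belt moving at 20 cm/s.  Fourteen Hill-type muscles
(`F = Fmax (a Fl(l) Fv(v) + Fp(l))`, constant moment arms) actuate the
hips, knees and ankles.  Each hindlimb is controlled by a two-level CPG
built from activity-based neuron models with a persistent sodium current:

    C dV/dt = -INaP - ILeak - ISynE - ISynI      (RG, PF, MN)
    INaP    = gNaP m(V) h (V - ENa),  tau(V) dh/dt = hinf(V) - h

Rhythm-generator half-centers (RG-F/RG-E) alternate through inhibitory
interneurons (IN-F/IN-E); commissural C1 and V3 populations coordinate
the two sides in anti-phase; pattern-formation populations (PF-F/PF-E)
drive the motoneuron pools, whose output `f(V)` is each muscle's motor
command.  Afferent feedback enters the ipsilateral CPG as excitatory
input: velocity (`vhat^0.6`) and length (above 0.9 lmax) channels from
flexor muscles, force channels from extensors.

Thirteen free parameters -- seven PF-to-MN weights and six feedback gains
-- are optimized by CMA-ES against

    eps = kappa * Int(sum a^2 dt) / (v_belt T) - T,    kappa = 20,

on a belt whose height under each limb is redrawn from {-2, 0, +2} cm at
every step (trial cap `T <= 100` s; falling = hip below 5 cm or a limb
airborne beyond ~1.5 step cycles).  A frozen-variable nullcline analysis
(`v_nullcline()`, `classify_intersections()`, `annotate_fast_slow()`)
exposes the fast/slow switching of the RG dynamics that underlies the
response to a sudden loss of ground support (the `hole` scenario).

All numeric constants that are not fixed by the model equations are a
calibrated *synthetic* parameter set (see the methods vignette and
`inst/extdata/*_synthetic.tsv`).

## Worked example

```r
library(cpgwalk)
p <- default_params()                     # shipped optimized vector

tr <- run_simulation(p, scenario_spec("flat"), cap = 20)
tr
#> cpg_trajectory: flat scenario, T = 20.00 s, no fall, 20001 samples, 39 events

th <- run_simulation(p, scenario_spec("hole", hole_start = 5, cap = 20),
                     cap = 20)
th$hole_window                            # when the left foot met the hole
round(subset(th$events, t > th$hole_window[1] - 1 & t < th$hole_window[1] + 2), 3)
```

`T = 20.00 s` with tens of touchdown/liftoff events means sustained
stepping for the whole cap; in the hole trial the left foot meets the
hole (window start), sinks, is pulled out early by the length-feedback
driven flexor burst, and re-lands while the contralateral limb prolongs
its extension -- `is.finite(th$fall_time)` stays `FALSE`.

Nullclines at any recorded instant:

```r
k  <- which.min(abs(th$t - th$hole_window[1] - 0.2))
s  <- feedback_at_sample(th, k, p)
nv <- v_nullcline("left:RG-F", th$V[k, ], s, p)
cls <- classify_intersections("left:RG-F", th$V[k, ], s, p)
cls$intersections                         # saddle / stable node + location
```

Optimization from scratch (desk-scaled):

```r
res <- optimize_gait(default_params(optimized = FALSE),
                     n_gen = 20, cap = 10, dt = 0.05, seed = 1)
res$fbest                                 # best cost so far (negative = walks)
```

## Command line

```sh
Rscript -e 'cpgwalk::cpgwalk_cli()' simulate --scenario hole --seed 2 \
    --cap 20 --out runs/hole2
Rscript -e 'cpgwalk::cpgwalk_cli()' optimize --generations 40 --pop 11 \
    --seed 1 --ablate none --out runs/opt.json
Rscript -e 'cpgwalk::cpgwalk_cli()' nullclines --trajectory runs/hole2 \
    --pop left:RG-F --times 5.2,5.5 --out runs/nullclines
```
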