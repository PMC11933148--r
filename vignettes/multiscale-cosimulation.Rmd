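---
title: "Multiscale cardiovascular co-simulation: model, coupling scheme and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale cardiovascular co-simulation: model, coupling scheme and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and idea

`cardiocosim` implements a two-subsystem multiscale model of the stage-1
(Norwood) univentricular circulation, coupled in the leader/follower pattern
of co-simulation interfaces such as FMI 2.0:

* the **follower** is a closed-loop lumped-parameter model (LPM) of the heart
  and the vascular beds outside the arch region, packaged behind a typed
  variable registry with `set_input()` / `do_step()` / `get_output()`
  semantics and serialisable as an FMU archive;
* the **leader** is a zero-dimensional surrogate of the domain that a 3D CFD
  solver would occupy in a full multiscale study — the aortic arch, its three
  brachiocephalic branches, the descending aorta, the modified
  Blalock–Taussig shunt (MBTS) and the two pulmonary arteries.

At every macro timestep the leader advances first under the last-known
follower boundary pressures, hands the resulting boundary *flows* to the
follower, the follower integrates internally and returns boundary
*pressures*.  Seven boundaries are exchanged: `aortic_root`, `innominate`,
`l_carotid`, `l_subclavian`, `dao`, `lpa`, `rpa`.  The package's claim is the
coupling protocol and its clinical-envelope agreement; a real CFD code could
replace the leader module behind the same seven-boundary contract.

## The follower circulation

The single ventricle is a time-varying elastance chamber,
$P = E(t)\,(V - V_0)$, with a double-cosine normalised activation: a cosine
rise over $[0, t_{peak}]$, a cosine fall over $[t_{peak}, t_{sys}]$ and zero
in diastole.  This form is smooth (RK4-friendly), periodic, and attains
exactly $E_{max}$ and $E_{min}$.  The atrium is a passive compliance — the
minimal closed loop; no atrial kick is modelled.  Valves are ideal diodes
$Q = \max(\Delta P, 0)/R$ with an optional smooth regularisation of width
`eps` (default 0; the regularised law is bounded by the ideal flow plus
$\epsilon/R$ and monotone).

Each distal boundary feeds an RCR vascular bed: a proximal resistance into a
compliance node draining through a distal resistance into the systemic or
pulmonary venous compliance; venous return to the atrium is
resistive–inertial, which exercises the inductive branch equations
$\dot Q = (\Delta P - RQ)/L$.  The aortic root is a compliance node between
the aortic valve and the `aortic_root` boundary.  State dimension is 13:
two chamber volumes, nine node pressures, two return flows.

Units are fixed internally: mmHg, mL, s (resistance mmHg·s/mL, compliance
mL/mmHg, inertance mmHg·s²/mL, quadratic loss mmHg·s²/mL²).

## The leader surrogate

Nine branches with dynamics $\dot Q = (\Delta P - RQ - k\,Q|Q|)/L$ connect a
central arch junction, an innominate junction and a pulmonary junction to
the seven boundaries; the shunt branch (innominate junction to pulmonary
junction) carries the dominant quadratic loss, standing in for the 3.5 mm
graft's pressure drop.  Junctions are rigid (no storage): each macro step is
advanced with implicit Euler per branch and a Newton iteration on the three
junction pressures until the largest junction flow residual is below
`leader.tol_rel` (default 1e-5) relative to the mean branch-flow magnitude,
with a cap of 50 iterations.  This is a concrete, testable stand-in for the
"iterate the CFD to sufficient stability per step" behaviour of a real
leader; the residual cap and tolerance are configuration values.

The macro step adapts by step doubling: every step is computed once at
$\Delta t$ and once as two halves; the flow difference is the local error
estimate, and a clamped controller (shrink factor at least 0.5, growth at
most 2, bounds `dt_min_us` = 10, `dt_max_us` = 2000) sets the next step.
The bounds bracket the follower's 100 µs internal limit.

## The coupling protocol

The default scheme is the explicit staggered (Gauss–Seidel) exchange — one
exchange per accepted macro step, leader first, inputs zero-order-held
across the step.  Two documented variants exist behind config flags, both
off by default:

* `coupling.exchange_iterations > 0` re-evaluates leader and follower within
  the step (a tighter implicit-style exchange; the follower is rewound and
  re-stepped with the refreshed flows);
* `lpm.hold = "first_order"` ramps the follower's inputs linearly from the
  previous to the current exchanged flows instead of holding them constant.

Inside the follower, every macro step $\Delta t$ is tiled by
$n = \lceil \Delta t / h_{max} \rceil$ equal classical RK4 substeps with
$h_{max}$ = 100 µs (`lpm.h_max_us`), so the internal step never exceeds the
stability threshold and the substeps sum to $\Delta t$ exactly.  Equal
substeps (rather than a trailing remainder step) keep the tiling
deterministic.

**Initialisation.** The follower starts from the configured initial state;
the leader starts from the steady network solution under the follower's
initial boundary pressures, so the first macro step sees mutually consistent
values.  The shipped initial state is the start-of-cycle state on the
settled limit cycle of the default topology, so startup transients are
negligible well before the final analysis cycle (the periodicity check
compares cycles 7 and 8 at below 1% range-normalised RMSE).

**Cycle bookkeeping** is by simulation time ($t \in [(n-1)T, nT)$), since
the period is prescribed, not emergent.

## The monolithic oracle

For verification, `run_monolithic()` integrates follower and leader as one
22-state ODE system with fixed-step RK4 at $h \le h_{max}$: the
rigid-junction constraint is index-reduced (junction pressures solved from a
3×3 linear system at every derivative evaluation, with Baumgarte
stabilisation), and after every step the branch flows are projected back
onto the junction-conservation manifold.  Because total stressed volume and
the junction sums are linear invariants, the oracle conserves blood volume
to machine precision, and the co-simulation's splitting error can be
measured against it: the final-cycle mismatch falls monotonically as the
macro-step cap shrinks and is well below 2% range-normalised RMSE at
`dt_max_us = 100`.

## Parameters, defaults and tuning

No parameter set for this specific patient is published; all circulation
parameters live in the configuration, and the shipped defaults were chosen
once as a physiologically plausible neonatal stage-1 circulation: period
$T = 0.4$ s (150 bpm), $E_{max} = 14$, $E_{min} = 0.22$ mmHg/mL,
upper-body beds of ≈26 mmHg·s/mL distal resistance, a lower-body bed of 8.5,
pulmonary beds of 1.5, and a shunt impedance (R = 2.6 mmHg·s/mL,
k = 0.14 mmHg·s²/mL²) giving a Qp/Qs near 0.9 at a mean aortic pressure
near 52 mmHg.

`tune_parameters()` is a deterministic coordinate descent on multiplicative
(log-scale) knobs over a documented tunable subset: upper-body, lower-body
and pulmonary bed resistances, shunt impedance, maximal elastance and
stressed volume.  The objective is the maximum absolute percent difference
of the seven cycle-averaged comparison variables (CO, upper-body flow,
descending-aorta flow, shunt flow, Qp/Qs, mean aortic and mean pulmonary
pressure) against the supplied clinical targets; the budget counts coupled
runs (default 200).  Tuning here is automated where a study team would tune
manually; the acceptance check keys only on the ≤ 10% envelope, not on any
particular tuned parameter values.

Measurement conventions (config-documented rather than prescribed): CO is
the cycle-averaged `aortic_root` boundary flow; systemic flow for Qp/Qs is
upper-body plus descending-aorta flow, so Qp/Qs = Q_SH / (Q_UB + Q_DAO) —
the convention consistent with the reference table's own arithmetic; mean
pulmonary pressure is read at the leader's pulmonary junction.

## Numerical choices and degenerate inputs

* Macro/micro tolerances: follower substep cap 100 µs; leader junction
  residual 1e-5 relative; leader step-doubling tolerance `step_tol` = 2e-3.
* The slave's clock must match the commanded communication time to 1e-12 s;
  violations return an error status rather than raising, as a co-simulation
  master expects.
* Ideal-diode valves introduce derivative kinks; at 100 µs substeps these
  are harmless, and a smooth `eps` regularisation is available if a stiffer
  configuration needs it.
* Degenerate requests fail loudly by name: missing or non-positive config
  keys, zero-resistance-and-loss branches, empty averaging windows, flat
  NRMSE references, non-finite states (reported with the failing component).
* Everything is deterministic; the `seed` config field is logged with runs
  for forward compatibility but no randomness exists in the pipeline.

## What the default study emulates — and what it does not

The default configuration emulates the *protocol shape* of a patient
study: eight cardiac cycles, final-cycle analysis, seven-boundary exchange,
clinical comparison of seven averaged variables.  It does not emulate 3D
flow features (no Navier–Stokes, turbulence, wall shear or geometric
derivation of the shunt coefficients), baroreflex or respiratory modulation,
or oxygen transport.  Passing tests therefore demonstrate the correctness
and convergence of the coupling machinery and the attainability of the
clinical envelope for this class of lumped model — not anatomical fidelity
of any particular patient's haemodynamics.

## Problem sizes used in tests

The test and acceptance runs use the study-sized protocol directly (8
cycles of 0.4 s; ≈1,600–13,000 macro steps depending on the step cap;
32,000 RK4 substeps for the monolithic oracle), since a full coupled run
takes on the order of a second.  The splitting-error study sweeps
`dt_max_us` over {800, 400, 200, 100}; tuning uses a budget of at most 200
coupled runs and typically converges in ≈120.

```{r, eval = FALSE}
library(cardiocosim)
sim <- run_coupled(default_config())
summary(sim)
fit <- tune_parameters(default_config(), clinical_targets(), budget = 200)
print(fit)
plot(run_coupled(fit$cfg))
```
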