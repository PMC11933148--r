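# cardiocosim

Multiscale cardiovascular co-simulation of the stage-1 (Norwood)
univentricular circulation, built around an FMI 2.0-style leader/follower
coupling.

## The problem

After the Norwood procedure, a single ventricle feeds the systemic and
pulmonary circulations in parallel through a modified Blalock–Taussig shunt
(MBTS) from the innominate to the right pulmonary artery.  Multiscale models
of this physiology couple a detailed 3D model of the arch/shunt region to a
closed-loop lumped-parameter model (LPM) of the rest of the circulation, and
the engineering question is how to couple the two solvers cleanly.
`cardiocosim` implements that coupling as a desk-scale, fully testable
system for researchers studying co-simulation methodology in haemodynamics:

* **Follower** — a closed-loop LPM: time-varying elastance ventricle
  (`P = E(t)(V - V0)` with a double-cosine activation), passive atrium,
  diode valves, six RCR vascular beds and resistive–inertial venous return;
  integrated by classical RK4 with every communication step subdivided into
  equal substeps of at most 100 µs.  Exposed through a typed variable
  registry with `set_input()` / `do_step()` / `get_output()` semantics and
  packageable as an FMU archive (`package_fmu()`, `check_fmu()`,
  `load_fmu()`).
* **Leader** — a 0D surrogate of the 3D arch/shunt domain: nine
  resistive–inertial branches (`dQ/dt = (ΔP − RQ − kQ|Q|)/L`, quadratic loss
  on the shunt) joined at rigid junctions, advanced implicitly with a Newton
  iteration on the junction pressures and an adaptive, step-doubling macro
  timestep.
* **Coupling** — explicit staggered exchange of boundary pressures (follower
  → leader) and flows (leader → follower) at seven boundaries every macro
  step, over eight cardiac cycles (`run_coupled()`); verified against a
  monolithic single-ODE reference (`run_monolithic()`).
* **Analytics & tuning** — final-cycle averages, `Qp/Qs = Q_SH/(Q_UB +
  Q_DAO)`, percent differences, range-normalised RMSE, PV-loop metrics, and
  a deterministic coordinate-descent tuner toward clinical targets
  (`tune_parameters()`).

## Worked example

```r
library(cardiocosim)
sim <- run_coupled(default_config())
summary(sim)
#> coupled run, 8 cycles; final-cycle averages:
#>     CO   Q_UB  Q_DAO   Q_SH  Qp_Qs   P_AO  P_PUL
#> 20.848  5.449  5.520  9.879  0.901 53.246 12.225
#> volume drift over run: 0.0000%
#> macro dt [min/mean/max]: 200.0 / 1918.9 / 2000.0 us; max follower substep 100.0 us
```

The seven numbers are the final-cycle averages of cardiac output, upper-body
flow, descending-aorta flow, shunt flow (mL/s), the pulmonary-to-systemic
flow ratio, and mean aortic and pulmonary pressures (mmHg).  Tuning against
the default clinical targets (CO 21, Q_UB 5.6, Q_DAO 5.7, Q_SH 9.7 mL/s,
Qp/Qs 0.9, P_AO 52, P_PUL 12 mmHg) brings every percent difference inside a
10% envelope:

```r
fit <- tune_parameters(default_config(), clinical_targets(), budget = 200)
print(fit)
#> Parameter tuning: 118 coupled-run evaluations, max |%diff| = 2.05% (within threshold at 10%)
#>       target  model diff_pct
#> CO      21.0 20.908      0.4
#> Q_UB     5.6  5.513      1.6
#> Q_DAO    5.7  5.584      2.0
#> Q_SH     9.7  9.812      1.2
#> Qp_Qs    0.9  0.884      1.8
#> P_AO    52.0 53.065      2.0
#> P_PUL   12.0 11.759      2.0
plot(run_coupled(fit$cfg))   # CO waveform, PV loop, upper-body flow, dao pressure
```

See `vignettes/multiscale-cosimulation.Rmd` for the model equations,
coupling scheme, parameter conventions and numerical choices.

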