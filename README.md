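# chemopt

Optimal chemotherapy scheduling for a tumor that *learns to resist the drug
it is given*.

## The problem

Chemotherapy selects for resistance, but a growing body of experimental work
shows that many drugs also *induce* it: dosing actively pushes sensitive
cancer cells into a resistant phenotype. `chemopt` implements a minimal
two-compartment model of this situation and the complete optimal-control
machinery around it. The tumor is described by a sensitive fraction `x1` and
a fully resistant fraction `x2` of a joint carrying capacity (scaled to 1):

```
x1' = (1 - (x1 + x2)) x1 - eps x1 - (alpha + d) u(t) x1
x2' = pr (1 - (x1 + x2)) x2 + eps x1 + alpha u(t) x1
```

The dose `u(t)` is bounded by a maximal tolerated value `M`; it kills
sensitive cells (log-kill coefficient `d`), induces transitions to
resistance at rate `alpha u`, and resistance also arises spontaneously at a
small rate `eps`. Resistant cells divide more slowly (`0 <= pr < 1`) but
cannot be treated. Because every schedule eventually produces a fully
resistant tumor, the clinically meaningful objective is not cure but delay:
maximize the **failure time** `t_c`, the first time the total burden
`V = x1 + x2` reaches a critical volume `Vc`.

Writing the dynamics as `x' = f(x) + u g(x)`, the optimal schedule can be
characterized exactly. It is a concatenation

```
(YX)^n  u_p  Y
```

of maximal-dose arcs (`Y`, `u = M`), rest arcs (`X`, `u = 0`), and a sliding
arc on the boundary `V = Vc`, where the feedback dose

```
u_p(x) = (1 - V)(x1 + pr x2) / (d x1)
```

holds the volume exactly at `Vc` until it saturates at `M` — which happens
precisely at the tangency point `x*` of the maximal-dose field on the
boundary. Singular arcs exist (confined to the line `a x1 + b x2 = c` of the
Lie-bracket decomposition `[f,g] = gamma f + beta g`) but violate the
Legendre–Clebsch condition and are provably never optimal; the package
verifies this numerically via clock-form (Stokes) time comparisons and
Pontryagin Maximum Principle diagnostics.

The package provides, as plain R functions behind a thin CLI:

* **model core** — vector fields, region predicates, validated parameters
  (`params()`, `params_preset()`, `drift_field()`, `model_rhs()`);
* **geometry** — singular line, `det A`, `gamma`/`beta`, tangency point,
  admissible singular segment, Lie derivatives (`line_coefficients()`,
  `tangency_point()`, `singular_segment()`, `lie_gamma_along()`);
* **controls** — bang arcs, boundary feedback `u_path()`, singular feedback
  `u_singular()`, and the structured family `structured_control()`;
* **simulation** — event-driven integration with boundary contact, sliding
  and failure detection (`integrate_trajectory()`, `time_to_failure()`),
  clock-form time integrals and two-arc shooting (`clock_form_time()`,
  `shoot_between()`);
* **PMP diagnostics** — adjoint/lift co-integration and the
  Legendre–Clebsch test (`find_extremal_lift()`, `legendre_clebsch_value()`);
* **optimizer** — deterministic switch-time search over the structured
  family (`optimize_dosing()`, `sweep_grid()`, `run_table2()`);
* **identifiability** — closed-form volume-output Lie derivatives and exact
  parameter recovery (`lie_observables()`, `recover_params()`).

## Worked example

A moderately cytotoxic, weakly inducing drug (`d = 0.5`, `alpha = 0.001`,
remaining parameters at the built-in preset):

```r
library(chemopt)
p <- params_preset(d = 0.5, alpha = 0.001)
res <- optimize_dosing(p, n_max = 1)
print(res)
#> optimal structured dosing: YXupY, t_c = 246.277
#>   switch times: 5.2655942
#>   (42 trajectory evaluations)
#> per-structure candidates:
#>  structure  n        t_c     times
#>          X NA   6.792352
#>          Y NA  63.189314
#>        upY  0 238.340324
#>      YXupY  1 246.276945 5.2655942
res$trajectory$events
#>       time             kind
#> 1  20.0037 BOUNDARY_CONTACT
#> 2  20.0037    SLIDING_START
#> 3 246.2774      SLIDING_END
#> 4 246.2774          FAILURE
```

Reading: doing nothing fails at `t = 6.8`; constant maximal dosing fails at
`t = 63`. The optimal schedule gives the maximal dose for 5.3 time units,
rests until the tumor reaches the critical volume at `t = 20.0`, then slides
along `V = Vc` under the feedback dose for 226 time units before the
feedback saturates at the tangency point and treatment fails at
`t_c = 246.3` — a 36-fold improvement over no treatment. The counterintuitive
headline result of the model is visible in `run_table2()`: for weakly
cytotoxic drugs the failure time *increases* with the induction rate
`alpha`, because induced transitions park tumor mass in the slower-growing
resistant compartment.

## Command-line interface

```sh
Rscript exec/chemopt optimize --set d=0.5,alpha=0.001
Rscript exec/chemopt table2 --out table2.csv
Rscript exec/chemopt check-geometry --set d=0.05   # line, x*, segment as JSON
Rscript exec/chemopt identify                      # observables + recovery
Rscript exec/chemopt simulate --control arcs.json --out traj.csv
```

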