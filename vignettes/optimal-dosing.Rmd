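---
title: "Optimal dosing under drug-induced resistance: model, geometry, and numerics"
author: "chemopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal dosing under drug-induced resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemopt)
```

## The model and its assumptions

`chemopt` works with a deliberately minimal model of a tumor under a
chemotherapy that both kills and *induces resistance*. Two compartments
share a carrying capacity scaled to one: a drug-sensitive fraction $x_1$
and a completely resistant fraction $x_2$,

$$
\begin{aligned}
\dot x_1 &= (1 - (x_1+x_2))\,x_1 - \epsilon x_1 - (\alpha + d)\,u(t)\,x_1,\\
\dot x_2 &= p_r\,(1 - (x_1+x_2))\,x_2 + \epsilon x_1 + \alpha\,u(t)\,x_1,
\end{aligned}
$$

written control-affinely as $\dot x = f(x) + u\,g(x)$. The assumptions that
matter:

* **log-kill**: drug-induced death is proportional to dose times the
  sensitive population ($d\,u\,x_1$);
* **induced resistance**: the per-capita transition rate to the resistant
  phenotype is proportional to dose ($\alpha\,u\,x_1$), on top of a small
  spontaneous rate $\epsilon x_1$;
* **complete resistance**: the drug does not touch $x_2$ at all — an
  idealization that buys a clean efficacy metric;
* **slower resistant growth**: $0 \le p_r < 1$, as observed experimentally;
* **no pharmacokinetics**: $u(t) \in [0, M]$ is controlled directly.

With $\epsilon > 0$ every schedule ends in a fully resistant tumor
($x \to (0,1)$), so the objective is to *delay*, not cure: maximize the
failure time $t_c$, the first time the volume $V = x_1 + x_2$ reaches a
critical fraction $V_c$ (with $0 < V_c < 1 - \epsilon$). The state is
confined to the triangle $\Omega_c$: $x_1, x_2 \ge 0$, $V \le V_c$.

## Parameters

| name    | meaning                                   | unit            | preset |
|---------|-------------------------------------------|-----------------|--------|
| `pr`    | relative resistant growth rate            | dimensionless   | 0.2    |
| `eps`   | spontaneous transition rate               | per time        | 1e-6   |
| `alpha` | drug-induced transition rate              | per dose-time   | 0.01   |
| `d`     | cytotoxicity (log-kill coefficient)       | per dose-time   | 1      |
| `M`     | maximal tolerated dose                    | dose units      | 5      |
| `Vc`    | critical volume                           | fraction of K   | 0.9    |
| `x10`, `x20` | initial fractions                    | fraction of K   | 0.01, 0 |

`params_preset()` ships these reference values; the grid experiments vary
`d` and `alpha` against them. `d = 0` is rejected at construction because
both the sliding feedback and the identifiability inversion divide by `d`.
Time is measured in units of the sensitive growth rate (the model is
non-dimensionalized), so "one time unit" is one sensitive doubling-scale.

## Why the optimal schedule looks the way it does

Because the dynamics are affine in $u$ and planar, the Maximum Principle
plus Lie-bracket geometry pin the optimum almost completely:

1. Where $x_1 > 0$ the fields $f, g$ form a frame
   ($\det(f\,g) = \alpha x_1^2\kappa + p_r(\alpha+d)x_1x_2\kappa +
   \epsilon d x_1^2 > 0$), so $[f,g] = \gamma f + \beta g$ with explicit
   rational $\gamma, \beta$. Interior optimal doses are bang-bang
   ($u \in \{0, M\}$, arcs written $X$ and $Y$) except where $\gamma = 0$:
   a straight line $a x_1 + b x_2 = c$.
2. On the admissible part of that line a **singular dose**
   $u_s = M L_X\gamma/(L_X\gamma - L_Y\gamma) \in (0, M)$ exists, but the
   Legendre–Clebsch quantity $L_g\gamma = (L_Y\gamma - L_X\gamma)/M$ is
   *positive* there, so dwelling on the singular line is always
   time-suboptimal. The package also verifies this metrically: the clock
   form $\omega = (g_2\,dx_1 - g_1\,dx_2)/\det(f,g)$ integrates to elapsed
   time along any trajectory, and Stokes' theorem converts the
   singular-vs-bang-bang comparison into a signed area integral of
   $-\gamma/\det(f,g)$ — computed in the test suite by independent 2-D
   quadrature.
3. On the failure boundary $N : V = V_c$ the **sliding feedback**
   $u_p(x) = (1-V)(x_1 + p_r x_2)/(d\,x_1)$ zeroes $\dot V$. On $N$ it
   decreases in $x_1$ and crosses $M$ exactly at the tangency point
   $x_1^* = p_r(1-V_c)V_c/(dM - (1-V_c)(1-p_r))$, so sliding is feasible
   only on the high-$x_1$ part of the boundary and must hand over to a
   terminal maximal-dose arc at $x^*$.

Combining these, the optimal schedule is a word $(YX)^n u_p Y$: bang
alternations, boundary sliding, terminal maximal dose. That finite
parameterization is what the optimizer searches.

## Design choices in genuinely open places

* **Activation of the sliding arc.** The schedule grammar nominally ends
  the last rest arc at a clock time, but a sliding dose only makes sense on
  the boundary. We therefore let the final $X$ arc run until boundary
  contact (detected by root-finding on $\psi = V - V_c$, with the
  requirement that $V$ is rising); any clock time given for that switch
  acts as a lower bound. A consequence we exploit: an $n$-pair schedule has
  $2n-1$ effective switch times, not $2n$.
* **Failure at the sliding exit.** When $u_p$ saturates, the state is at
  $x^*$ where $\dot V = 0$ and $\ddot V > 0$ under the maximal dose, so
  $V$ rises through $V_c$ immediately; $t_c$ is recorded at the saturation
  event after a numerical check of the sign of $\ddot V$ (the terminal $Y$
  arc contributes measure-zero time). This keeps $t_c$ well defined without
  root-finding on a tangential crossing.
* **Singular-dose formula.** Two printed forms of $u_s$ exist; we derive it
  from tangency ($a\dot x_1 + b\dot x_2 = 0$), whose denominator collapses
  algebraically to $2\alpha d(1-p_r)x_1$ — well defined precisely because
  $x_1 > 0$ — and cross-validate against the Lie-derivative form to
  $10^{-9}$ relative in the tests.
* **Admissibility of the singular segment.** The segment is defined
  operationally as the part of the line where $L_Y\gamma > 0$ (its endpoint
  $\bar s$ found by bisection to $10^{-10}$), rather than through a closed
  dose threshold; the two are equivalent and the operational form avoids
  transcription risk.
* **Recovery of $p_r$.** The identifiability inversion recovers
  $x_{10}, d, \alpha, \epsilon$ from the printed closed forms and $p_r$
  from our own re-derivation of $L_gL_fh$,
  $p_r = \left[L_gL_fh/x_{10} + (\alpha+d)(1-2x_{10}) + \alpha
  x_{10}\right]/\left[\alpha(1-x_{10})\right]$, validated by the round-trip
  property over $10^3$ random parameter draws. With $\alpha = 0$, $p_r$
  does not enter the observables and is flagged non-recoverable.
* **Extremal-lift construction.** The Maximum Principle is used as a
  *verifier*. The normalization $H(0) = 0$ leaves one free parameter in
  $\lambda(0)$; because the adjoint equation is linear, the switching value
  at the first switch time is affine in that parameter, so the verified
  lift is obtained from two trial integrations and one linear solve —
  exact and deterministic, with no grid scan.

## Numerics

* **Integrator**: `deSolve::lsodar` with `rtol = atol = 1e-10` and
  root-finding for all events (boundary contact, feedback saturation,
  singular exit); failure times are quoted to two decimals over horizons up
  to ~280 time units, and halving the tolerances moves $t_c$ by less than
  $10^{-4}$ relative (tested).
* **State hygiene**: compartments that decay below the solver's absolute
  resolution can overshoot slightly negative; post-arc states clamp
  negatives within `1e3 * atol` of zero. Region-membership tests use an
  absolute tolerance of $10^{-9}$.
* **Dense output**: condition-terminated arcs are located first (endpoints
  only) and then re-run on a dense grid to the located end, keeping the
  accurately root-located event state as the arc endpoint. Clock-form
  integrals use $\ge 2000$ points per arc, which holds the time-identity
  error below 0.5%.
* **Optimizer**: per sub-family $n$, a coarse grid of 20 points per switch
  time restricted to non-decreasing tuples, then two coordinate-wise
  golden-section passes to $10^{-4}$ time units. Grid evaluations run at
  `1e-8` tolerances; the winner is re-simulated at the tight defaults and
  that re-simulated $t_c$ is reported. Everything is deterministic — no
  random restarts — so repeated runs are byte-identical. `n_max = 2` by
  default: computed optima in this model never show more than one interior
  switch pair, and the switching-count bound per $\gamma$-sign region makes
  large $n$ pointless.
* **Problem sizes**: the shipped experiments optimize single cells
  (roughly $1.5\times10^3$–$2\times10^3$ trajectory evaluations per cell)
  and 15-cell grids; a full `run_table2()` takes a few minutes on one CPU.

## Degenerate inputs and tie-breaks

* $\alpha = 0$: the singular line is horizontal and never interior; the
  interior optimum is purely bang-bang. Geometry predicates return reasons
  rather than erroring.
* $M \le (1-V_c)(1-p_r)/d$: no tangency point exists, the sliding dose is
  nowhere feasible, and boundary contact is failure.
* $u_p = M$ exactly (the tangency point itself) is treated as feasible —
  the control set is closed — but triggers the saturation event, matching
  the hand-over into the terminal maximal-dose arc.
* Switch times may coincide: zero-length arcs are dropped, which is how the
  family degenerates to `Y`, `X u_p Y`, `YXY`, etc.

## What the tests do and do not show

The suite checks the machinery against independent oracles: closed-form
arithmetic for fields and line coefficients, finite-difference brackets and
directional derivatives, a logistic closed form for the no-dose failure
time, clock-form/Stokes identities via 2-D quadrature, PMP residuals along
solved lifts, and exact identifiability round-trips. All of this certifies
the *model's* optimal-control structure at the reference parameter scales.
It says nothing about real tumors: the model has two perfectly homogeneous
compartments, complete resistance, dose-proportional induction, no
pharmacokinetics, no delays and no stochasticity, and the reported failure
times inherit every one of those idealizations.

## Known limitations

* The optimizer searches the proven schedule family only; it is not a
  general collocation solver, and the smoothed objective
  (`evaluate_regularized()`) is evaluation-only.
* Identifiability is structural (noise-free observables at $t = 0$ with an
  all-sensitive start); estimating the Lie derivatives from noisy volume
  curves is a practical-identifiability problem the package does not
  address.
* Whether a true $YXY$ junction with a boundary contact point (rather than
  a sliding interval) can occur remains open; the schedule family admits
  the structure, and no shipped result depends on it.
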