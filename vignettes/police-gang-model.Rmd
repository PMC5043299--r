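---
title: "An eco-epidemiological model of police-gang interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An eco-epidemiological model of police-gang interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gangdyn)
```

## The model

`gangdyn` implements a predator-prey model of urban crime in which police
officers are the predators and gang members the prey, with an SI
(susceptible-infectious) social contagion running through *both*
populations. The gang population $N_g = S_g + I_g$ splits into youth not
yet committed to the gang ($S_g$) and committed core members ($I_g$);
commitment spreads by peer contact. The police force $N_p = S_p + I_p = P$
is held at constant strength — recruitment into the force exactly balances
attrition ($\gamma = \mu_2$) — and splits into susceptible officers ($S_p$)
and corrupt officers ($I_p$); corruption is transmitted to susceptible
officers by gang members (rate $\beta_2$) and by other corrupt officers
(rate $\beta_3$). Both contagions use standard incidence ($\beta S I / N$),
the form appropriate for large populations with few infectious
individuals. Arrested gang members enter the criminal-justice compartment
$Z$, a pure sink processed at rate $\mu_3$.

Arrests follow a Beddington-De Angelis-type functional response extended
for police teamwork. Officers operate in teams of size $U$; processing an
arrest costs handling time $t_h$ per head ($\lambda \ge 1$ times more for
core members, who resist arrest); pre-operation planning and communication
*save* operation time in proportion to the force size, through the
coefficient $c$. The per-officer capture rate of each gang compartment is

$$
f_i = \frac{a \, X_i}{U \, D}, \qquad
D = 1 + h\,(S_g + \lambda I_g) - cP, \qquad h = a\,t_h,
$$

with $X_1 = S_g$, $X_2 = I_g$. Because the time saving enters the total
operation time negatively, the derivation is only meaningful for $D > 0$;
the package treats $D \le 0$ as a hard error, never a clamp. Corrupt
officers still hunt, but at reduced efficiency $r \in [0,1]$, so the
effective predator abundance is $P_{\mathrm{eff}} = P - (1-r) I_p$.

The reduced state is $(S_g, I_g, I_p)$:

$$
\begin{aligned}
S_g' &= b N_g - \frac{S_g N_g}{K} - \beta_1 \frac{S_g I_g}{N_g}
        - \frac{a S_g P_{\mathrm{eff}}}{U D} - \mu_1 S_g,\\
I_g' &= \beta_1 \frac{S_g I_g}{N_g} - \frac{I_g N_g}{K}
        - \frac{a I_g P_{\mathrm{eff}}}{U D} - \mu_1 I_g,\\
I_p' &= \beta_2 \frac{(P - I_p) I_g}{P} + \beta_3 \frac{(P - I_p) I_p}{P}
        - \mu_2 I_p,
\end{aligned}
$$

with $S_p = P - I_p$ slaved by conservation and
$Z = (f_1 + f_2)\,U\,\text{(teams)}/\mu_3$ slaved at any fixed point
(`z_equilibrium()`). The standard-incidence ratio $S_g I_g / N_g$ is
defined as $0$ at $N_g = 0$ — its continuous limit — so the empty-gang
states are genuine fixed points. The model also states an auxiliary
logistic equation for the total gang population,
$N_g' = (b-\mu_1)N_g - N_g^2/K$; summing the two gang equations shows it
omits the predation losses, so the package exposes it only as a diagnostic
(`ng_logistic_residual()`), and all analysis uses the full right-hand
sides above.

A rate discussion of the per-officer attack coefficient: the boundary-state
eigenvalues of the model involve $a' = a/U$, the attack rate divided by
team size. Only this reading reproduces the numerical tipping points of the
base parameterisation, and it is the natural one (a team of $U$ officers
makes $a$ captures, i.e. $a/U$ per officer).

## Default parameters

The shipped defaults (`default_parameters()`) are the base case used for
all numerical results:

| parameter | value | meaning |
|---|---|---|
| $b$ | 0.2 | gang entry rate |
| $\mu_1$ | 0.12 | gang exit rate |
| $\mu_2 = \gamma$ | 0.0476 | police exit = entry rate |
| $\mu_3$ | 0.2 | justice-system processing rate |
| $\beta_1$ | 0.21 | core-commitment (recruitment) rate |
| $\beta_2$ | 0.105 | corruption rate by gang members |
| $\beta_3$ | 0.0525 | corruption rate by corrupt officers |
| $a$ | 0.001 | search/attack rate |
| $U$ | 10 | police team size |
| $r$ | 0.75 | corrupt-officer hunting efficiency |
| $\lambda$ | 1.5 | core-member handling multiplier |
| $t_h$ | 0.01 | handling time per arrest |
| $c$ | 0.001 | cooperation saving coefficient |
| $K$ | 50000 | gang carrying-capacity parameter |
| $P$ | 300 | police force size |

The published parameter table does not list the force size $P$. The value
300 is recovered from the published coexistence state, where
$S_p^* + I_p^* = 123 + 177 = 300$, and is confirmed by the fact that with
$P = 300$ the solver reproduces all five published equilibrium components
simultaneously (see `reproduce_paper()`); it remains an inference and is
freely configurable. Note that $K$ here is the model parameter as it
appears in the intraspecific-competition terms; the carrying capacity of
the total gang population is $(b - \mu_1)K = 4000$.

## Equilibria

Setting the derivatives to zero yields five equilibrium families:

* **E0** — everyone gone, a fully susceptible force (always exists).
* **E1** — gang extinct, corruption endemic at $I_p = \Omega P$ with
  $\Omega = (\beta_3 - \mu_2)/\beta_3$; exists iff $\beta_3 > \mu_2$.
* **E2 / E3** — susceptible gang members persist ($I_g = 0$), without /
  with endemic corruption; $S_g$ solves the quadratic balance
  $((b-\mu_1) - S_g/K)(1 + hS_g - cP) = a' P_{\mathrm{eff}}$, where roots
  are kept only if positive, below $(b-\mu_1)K$ (so $Z \ge 0$) and with
  $D > 0$.
* **E4** — interior coexistence. The corrupt-police balance gives
  $I_g = \frac{\mu_2 P - \beta_3 (P - I_p)}{\beta_2 (P - I_p)} I_p$
  (positive exactly on $I_p \in (\Omega P, P)$), and balancing the
  per-capita growth of the two gang compartments forces
  $S_g = b I_g/(\beta_1 - b)$, so coexistence needs $\beta_1 > b$. (The
  second relation is re-derived here from the per-capita balance; on the
  coexistence manifold $S_g/N_g = b/\beta_1$, which collapses the
  remaining condition to a single equation in $I_p$.)

`equilibrium_E4()` solves that last equation by **two independent
routes**: (A) a 600-point scan of $I_p$ over $(\Omega P, P)$ with each
sign change bisected to $10^{-12}$ relative tolerance, and (B) clearing
denominators to an explicit quartic in $I_p$ solved by `polyroot()`. The
quartic coefficients are obtained by polynomial expansion of

$$
\bigl[(b{-}\mu_1)\beta_2(P{-}I_p) - \tfrac{A}{K} N_1\bigr]
\bigl[(1{-}cP)\beta_2(P{-}I_p) + B N_1\bigr]
= a'\,(P - (1{-}r)I_p)\,\beta_2^2 (P{-}I_p)^2,
$$

with $A = \beta_1/(\beta_1-b)$, $B = h(b/(\beta_1-b)+\lambda)$ and
$N_1 = \beta_3 I_p^2 - (\beta_3-\mu_2)P I_p$. The two root sets must agree
to $10^{-6}$ relative; disagreement is raised as an internal error, never
silently resolved. Two numerical points deserve note: the quartic's
leading coefficient is naturally tiny (order $h/K$), so only exactly-zero
trailing coefficients are stripped before `polyroot()`; and nearly
coincident root pairs (close to a fold of the branch) can hide inside one
scan cell, so any quartic root not matched by the scan triggers a local
re-bracketing before a disagreement is declared. Up to four admissible
roots are returned if present; the base case has exactly one. Degenerate
equalities ($\beta_1 = b$, $\beta_3 = \mu_2$) return empty rather than a
limiting branch. Populations are kept real-valued throughout; rounding to
integers (nearest, half away from zero) happens only in report
formatting.

At the defaults the coexistence state is
$(S_g, I_g, S_p, I_p, Z) \approx (2124, 106, 123, 177, 395)$ after
rounding.

## Stability

$Z$ contributes a decoupled eigenvalue $-\mu_3 < 0$ and $S_p$ is slaved,
so classification uses the $3\times3$ Jacobian of the reduced system
(`jacobian_reduced()`), written analytically and verified in the test
suite against central finite differences. At empty-gang states the
incidence terms and their derivatives are taken as zero, consistent with
the definition of the dynamics there. Classification uses the largest
eigenvalue real part with a marginal band of $10^{-9}$: a state exactly at
a bifurcation is reported `marginal`, never silently rounded to stable.
Routh-Hurwitz quantities ($a_1$, $a_2$, $a_3$, $a_1 a_2 - a_3$ of the
characteristic cubic) are reported alongside and must agree with the
eigenvalue signs.

Closed-form conditions are provided for the boundary equilibria: E0 is
protected against gang invasion iff $a'P/(1-cP) > b - \mu_1$, E1 iff
$a'P(1-\Omega(1-r))/(1-cP) > b - \mu_1$, and E2/E3 are stable iff the
saturation condition $h a' P_{\mathrm{eff}}/D^2 < 1/K$ holds together with
$\beta_1 < b$. One subtlety is documented rather than hidden: the
corruption balance $\beta_3 (P - I_p) I_p / P - \mu_2 I_p$ has linear part
$(\beta_3 - \mu_2) I_p$ at $I_p = 0$, so the *exact* Jacobian at E0 and E2
carries a corruption-invasion eigenvalue $\beta_3 - \mu_2$ that the
conditions above do not see. When $\beta_3 > \mu_2$ corruption invades E0
and E2 regardless of predation pressure, and the states that can actually
be stable are E1 and E3 — which is precisely the regime split under which
the package's property tests check the closed forms against the numeric
spectra ($\beta_3 < \mu_2$: E0/E2; $\beta_3 > \mu_2$: E1/E3). The package
keeps the exact Jacobian (it is the one that matches finite differences
and the simulated dynamics) and treats the closed forms as what they are:
the predation/recruitment clauses of stability.

Hopf bifurcations are excluded at all boundary equilibria
(`hopf_excluded_no_criminal()`, `hopf_excluded_core_free()`): the relevant
$2\times2$ sub-block traces are sums of non-negative terms with at least
one strictly positive, so purely imaginary pairs are impossible; every
stability exchange in this model is through a single real eigenvalue —
transcritical, not oscillatory. At the coexistence state the analysis is
numeric; at the defaults all three eigenvalues have negative real parts.
(The three E4 eigenvalues originally reported alongside the base case sum
to a value inconsistent with the Jacobian trace of the stated equations
at that state; the package treats the qualitative sign pattern, not those
three numbers, as the reproducible content.)

## Tipping points

Solving the boundary-stability conditions as equalities gives the
closed-form transcritical thresholds at the base case:

| parameter | threshold | exchange |
|---|---|---|
| $\beta_1$ | $b = 0.2$ | E3 $\to$ E4 |
| $\mu_1$ | $b - a'P(1-\Omega(1-r))/(1-cP) = 0.158143$ | E4 $\to$ E1 |
| $P$ | $(b-\mu_1)/(a'(1-\Omega(1-r)) + c(b-\mu_1)) = 450.28143$ | E4 $\to$ E1 |
| $a$ | $U(b-\mu_1)(1-cP)/(P(1-\Omega(1-r))) \approx 0.0019$ | E4 $\to$ E1 |
| $b$ | $\mu_1 + a'P(1-\Omega(1-r))/(1-cP) = 0.16186$ and $\beta_1 = 0.21$ | E1 $\to$ E4 $\to$ E3 |

`scan_parameter()` grids one parameter, labels each grid point by the
unique stable admissible equilibrium (rows with none or several stable
states are flagged `indeterminate`, not forced — the `b` scan holds
$\beta_1$ fixed even as $b$ crosses it, and reports the degenerate point
as marginal), and `detect_transitions()` refines each regime change.
Refinement deliberately bisects the *leading eigenvalue of the boundary
equilibrium that exchanges stability* rather than the regime label: just
past each threshold the coexistence branch persists briefly before
folding, creating a thin genuinely-bistable sliver, and label bisection
would land on the fold instead of the transcritical point. The eigenvalue
crossing is the defining property of the transcritical exchange and
recovers every closed form above to the bisection tolerance
($10^{-8}$ absolute by default).

## Simulation

`simulate_model()` integrates the full 5-state system with
`deSolve::ode` (lsoda), default tolerances $10^{-8}$ relative /
$10^{-10}$ absolute. Defaults were chosen so that the slow modes near
transcritical points (leading eigenvalues of order $10^{-2}$ and smaller)
are resolved over the default regime-determination horizon of 5000 time
units; `regime_from_trajectory()` returns `"undetermined"` rather than
guessing when the horizon was too short. Sub-tolerance undershoots below
zero are absorbed by evaluating the right-hand side on the clamped state;
excursions beyond $10^{-6}$ relative, denominator sign changes and
blow-ups abort with the offending time. The perturbation experiment
(`perturbation_experiment()`) displaces an equilibrium by $+\delta$ in
every component by default (a signed per-component vector is accepted,
since the direction is not prescribed) and declares return when every
component is within $10^{-3}(1 + |x^*|)$ of the equilibrium.

## Randomness, problem sizes, and what the tests show

The model itself is deterministic; randomness enters only through
`sample_parameters()`, the property-test generator, which draws uniformly
from boxes around the defaults (chosen to keep $cP < 1$ and the other
admissibility constraints satisfiable) and is fully seed-reproducible.
The test-suite exercises 20-state Jacobian checks, 50-set quartic/scan
agreement, 50-set condition/eigenvalue agreement split by corruption
regime, and a handful of long trajectories; these sizes make the full
suite run in seconds while still probing well away from the base case.
Sampled parameter boxes are synthetic study conditions: passing tests
demonstrate internal consistency of the mathematics across those boxes,
not calibration to any observed policing data — the source
parameterisation itself is acknowledged as anecdotal, and estimating
parameters from crime data is out of scope.

## Known limitations

* The susceptible-police "hunting" of corrupt colleagues ($g_1$) that the
  model's verbal description mentions is absent from the analysed
  equations, and is therefore not implemented.
* Only local (linear) stability is computed; basins of attraction are not.
  Inside the bistable slivers the long-run outcome depends on the initial
  state, and the scan reports `indeterminate` there.
* Discrete and stochastic effects are out of scope by model assumption.
* $\gamma$ is stored but constrained equal to $\mu_2$; relaxing the
  constant-force assumption is a non-goal.
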