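---
title: "Identifiability analysis for ODE models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifiability analysis for ODE models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odeident)
```

## The problem

A mechanistic dynamic model

$$\frac{dx}{dt} = f(x, u, p), \qquad y = g(x, u, p), \qquad x(0) = x_0(p)$$

is only as useful as its parameters are estimable. **Structural
identifiability** asks whether the unknown parameters (and unknown initial
conditions) could in principle be recovered uniquely from perfect,
noise-free observations of the outputs $y$ — a property of the model
*structure* alone, decided before any data exist. **Practical
identifiability** asks whether a concrete, finite, noisy design actually
pins the parameters down with acceptable uncertainty. The two are ordered:
structural non-identifiability implies practical non-identifiability, so
the structural test comes first, and experiment design closes the loop by
choosing inputs that make the eventual estimates accurate. `odeident`
implements this upstream workflow end to end for models written as plain
symbolic ODE systems, and ships a zoo of worked fermentation and
compartmental models as executable fixtures.

## Structural identifiability: the observability rank condition

The package stacks Lie derivatives of every measured output along the
vector field: $L^0 h = h$, $L^{j+1} h = \nabla_x(L^j h)\cdot f + \sum_m
\partial_{u^{(m)}}(L^j h)\, u^{(m+1)}$. Under the `generic_smooth` input
class the input time derivatives $u^{(m)}$ enter as free indeterminates
(inputs can be excited arbitrarily); under `constant` they vanish. The
Jacobian of the stack with respect to (all states, unknown parameters) has,
at a generic point, a rank that decides local observability and
identifiability: a quantity is locally identifiable exactly when deleting
its column strictly lowers the rank.

Three design choices deserve explanation:

* **Exact rank, no tolerances.** Floating-point rank tests need a singular
  value cutoff, and the verdict can hinge on it. Instead the symbolic
  Jacobian is evaluated at random integer points in $[1, 999]$ and
  eliminated *exactly over the prime field* GF$(p)$, $p = 67{,}108{,}859$:
  all products of residues stay below $2^{53}$, so double-precision integer
  arithmetic is exact and the rank is a theorem about the evaluated matrix,
  not an opinion about a threshold. Non-rational subexpressions
  (`exp`, `log`) are assigned memoized random residues keyed by their
  argument's residue — legitimate for generic rank because such values are
  algebraically independent of the rational point. Rank is recomputed at
  three points (`n_points`); disagreement is reported, never averaged.
* **Known initial conditions are extra observations, not deleted columns.**
  Knowing $x_i(0)$ is one more measurement, taken at $t = 0$; it enters as
  a unit row for that state's column. The reported `generic_rank` then
  subtracts the known-IC count so that the invariants `generic_rank <=
  n_unknowns` and `dim(nullspace) = n_unknowns - generic_rank` hold on the
  unknown-quantity vector (unknown parameters first, then unknown ICs,
  named `<state>_0`). Because specific numeric ICs can destroy
  identifiability that holds generically, a diagnostic re-evaluates the
  rank with the declared IC values substituted and records a warning if it
  drops.
* **Stopping rule.** Derivative orders are added until the rank is
  unchanged for one extra order — the standard sufficiency argument for
  analytic systems — capped at `n_states + n_unknowns - 1`, with a node
  budget guarding against expression blow-up.

The null space of the Jacobian, restricted to the unknown quantities, is
reported as compensation directions (scaled to smallest-integer form when a
small rational form exists): for the β-casein hydrolysis fixture it is the
single direction along which $(k, K_m, k_I)$ can trade off while the output
trajectory stays fixed, and it is numerically orthogonal to the gradients
of the identifiable combinations $b_1 = k k_I/(K_m - k_I)$ and
$b_2 = K_m(k_I + x_0)/(K_m - k_I)$.

The rank verdict is *local*. For small models (at most 4 unknowns, 3
states) `count_output_equivalent_params()` sharpens it by equating the
first Taylor coefficients of the outputs at $t = 0$ between a random
rational reference parameterization and a free one, and counting the
admissible (positive real) solutions of that system. R has no
computer-algebra system, so the system is solved by dense multistart
Gauss–Newton in log space with residual certification
($\|F\|_\infty < 10^{-9}$ after polishing); two independently seeded
batches must agree on the solution *set*, otherwise the result is flagged
`symbolic-failure` rather than returned as a silent wrong count. Matching
more coefficients than unknowns (default `n_unknowns + 2`) suppresses
spurious roots of the truncated system. For the two-compartment passage
model this yields exactly the two output-equivalent parameterizations —
$(p_1, p_2, x_1(0))$ and $(p_2, p_1, x_1(0)\,p_1/p_2)$ — and a unique one
once $x_1(0)$ is known.

## Simulation and sensitivities

Right-hand sides, state Jacobians and parameter derivative blocks are
generated symbolically from the model, folded with the constants,
byte-compiled, and handed to `lsoda` (`deSolve`) with the analytic Jacobian
— the methanogenesis fixture mixes fast liquid–gas transfer with slow
microbial growth and benefits from the stiff solver. The user-facing `tol`
(default $10^{-8}$) is a *requested trajectory accuracy*: the solver runs
at `rtol = tol/10`, `atol = tol * 1e-3`, because per-step error control
under-represents the accumulated global error over a 50-hour horizon by
roughly an order of magnitude. Forward sensitivities integrate
the variational system $\dot S = (\partial f/\partial x) S + \partial
f/\partial \theta$ with $S(0)$ the identity block on unknown ICs; output
sensitivities follow by the chain rule. Self-convergence under tolerance
halving and agreement with central finite differences are part of the test
suite.

The synthetic-data generator adds seeded Gaussian noise to the noise-free
outputs — additive with constant $\sigma$ per output by default
(configurable to relative noise). This is the simplest noise model
compatible with the weighted least-squares likelihood and the Fisher
information matrix below. What it deliberately does *not* emulate:
heteroscedastic or correlated measurement error, sampling jitter,
model-structure mismatch, or outliers. Passing tests therefore demonstrate
correctness of the machinery under the stated statistical model, not
robustness of any particular biological model to real-data pathologies.

## Practical identifiability

With Gaussian noise, the objective is the weighted residual sum of squares
$\sum_k (y^{obs}_k - y_k(\theta))^2/\sigma^2$, and the Fisher information
matrix at a design with sampling times $t_k$ is
$\mathrm{FIM} = \sum_k S_y(t_k)^{\top} W S_y(t_k)$, $W =
\mathrm{diag}(1/\sigma^2)$. Cramér–Rao standard deviations are
$\sqrt{\mathrm{diag}(\mathrm{FIM}^{-1})}$, in parameter units because the
FIM uses the same weights as the objective. A singular FIM (smallest
eigenvalue below $10^{-10}$ of the largest) is a flagged result carrying
its null directions — on noise-free designs this is exactly the footprint
of structural non-identifiability, and the test suite asserts that
cross-module consistency.

Estimation is multistart weighted least squares: Latin-hypercube starts in
log-parameter space (biological rate constants are scale parameters),
refined by Levenberg–Marquardt with the *analytic* residual Jacobian from
the forward sensitivities. The analytic Jacobian matters: a
finite-difference Jacobian at machine-epsilon steps sits below the
integrator's error floor, stalls the optimizer a fraction of a standard
deviation from the optimum, and silently destroys the sampling
distribution of the estimator. All termini are kept; clusters of termini
with equal objective (merge tolerance $10^{-3}$ relative) diagnose
output-equivalent solutions, reproducing the two-cluster fit of the
two-compartment model from data alone.

Profile likelihood fixes one quantity on a grid and re-optimizes the
others, warm-starting each grid point from its neighbour and sweeping
outward from the estimate. The 95% confidence interval collects grid values
within $\Delta = 3.84$ ($\chi^2_1$) of the minimum, with endpoints linearly
interpolated; profiles whose total variation is below $\Delta/100$ are
flagged flat — the profile-likelihood signature of non-identifiability.

## D-optimal experiment design

`optimize_design()` maximizes $\log\det(\mathrm{FIM}(u))$ over constant or
piecewise-linear input signals (equally spaced nodes, values boxed) by
multistart L-BFGS-B; $\log\det$ rather than $\det$ for conditioning,
ratios reported on the determinant scale. Two numerical choices matter.
First, the finite-difference gradient steps are sized to 1% of the input
range: machine-scale steps would fall below the integration-noise floor of
the objective and freeze the search. Second, random multistarts alone find
the relevant local optima unreliably, so the piecewise search screens a
deterministic excitation catalog — constant levels (constant signals are a
subspace of piecewise-linear ones, so the optimum can never fall below the
constant optimum), bang-bang alternations, ramps, and feed pulses /
starvation dips at every node position — and seeds the refinements with
its best members. This makes the design-space nesting property
($\log\det$ non-decreasing in design-space size) hold by construction
rather than by optimizer luck. Candidate evaluation runs the sensitivity
solve at a relaxed tolerance ($10^{-6}$); the returned report is
recomputed at $10^{-8}$.

The chemostat (Monod–Haldane) example uses the package's documented
default configuration: dilution rate $D = 0.05\,h^{-1}$, initial state
$(x_1, x_2)(0) = (0.5, 1)$, horizon $[0, 50]$ h, 5 input nodes, $u \in [0,
100]$, 20 uniform sampling times, $\sigma = 0.05$ per output, nominal
$k = 2$, $k_I = 50$. Under it, the optimized dynamic input attains a higher
FIM determinant and strictly smaller Cramér–Rao SDs for both $k$ and $k_I$
than the optimized constant input — the qualitative advantage of dynamic
stimulation. The magnitude of that advantage depends strongly on the
horizon, dilution rate and noise level, so no absolute determinant values
are claimed for this configuration; published determinant and SD *ratios*
for this model class are reproduced as exact arithmetic by
`compare_designs()` on reported summaries.

## Replicate studies and problem sizes

The package's replicate experiments are sized for a single CPU: the Wald
coverage study uses 100 replicate synthetic chemostat datasets ($n = 40$
samples, $\sigma = 0.05$, replicate seeds derived deterministically from
one base seed) under the D-optimally designed dynamic input — designing first and estimating second is precisely the
upstream workflow the package exists to support, and with a weakly
exciting constant feed the $k_I$ direction is so ill-conditioned that the
FIM is near-singular in a fifth of the replicates. Each replicate is
fitted from the true parameter values (a standard reduced-cost device for
coverage studies; multistart adds nothing when the global basin is known),
and the Wald interval $\hat k \pm 1.96\,\mathrm{SD}(\hat k)$ is compared
with the truth. Solution counting uses 150 multistart points per batch;
the structural rank test uses 3 evaluation points.

## Numerical edge cases

* Degenerate design boxes (`u_min == u_max`) bypass the optimizer and
  evaluate the FIM directly.
* Grid points whose inner re-optimization fails are flagged and skipped in
  profiles; integration failures carry the last successful time.
* Unlucky rank-evaluation points that zero a denominator are redrawn; the
  transcendental-residue cache is per-point, so identical subexpressions
  always receive identical residues.
* `solution_clusters()` merges termini at $10^{-3}$ relative distance —
  coarser than optimizer precision, far finer than the separation of
  genuinely distinct solutions in the fixtures.

## Known limitations

* Verdicts are local; global identifiability certificates
  (differential-algebra methods) are out of scope, and the solution
  counter is restricted to small models by design.
* The Taylor-matching solution counter assumes positivity of all unknown
  quantities (log-space search); sign-indefinite parameters would need a
  different admissibility rule.
* The FIM-based confidence machinery is asymptotic and linearized; the
  profile likelihood is provided exactly because those assumptions can
  fail.
* Piecewise-linear inputs cover the designs used here; richer input
  parameterizations (splines, bang-bang switching times) are not
  implemented.
* No DAE, delay, or event/discontinuity support in the model grammar.
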