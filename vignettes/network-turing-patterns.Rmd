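---
title: "Turing patterns in an SIR rumor model on networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turing patterns in an SIR rumor model on networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumornet)
```

## The model

`rumornet` studies an SIR-type rumor propagation model in which the
susceptible (ignorant) class grows logistically and transmission requires
repeated exposure:

$$
\begin{aligned}
\dot S &= rS\Bigl(1 - \frac{S}{K}\Bigr) - \beta S I^2 - \mu_1 S,\\
\dot I &= \beta S I^2 - (\mu_2 + \alpha) I,\\
\dot R &= \alpha I - \mu_3 R.
\end{aligned}
$$

The incidence $\beta S I^2$ is quadratic in spreader density: under social
reinforcement an individual adopts a rumor only after repeated contact, the
standard "nonlinear incidence" mechanism.  $r$ is the growth rate of the
susceptible pool, $K$ its carrying capacity, $\mu_{1,2,3}$ are per-class
replacement (turnover) rates and $\alpha$ is the recovery (debunking) rate.
All ten parameters, including the diffusion rates $d_1, d_2, d_3$
introduced below, are strictly positive.

Space is a network rather than a continuum.  Each node carries densities
$S_i, I_i, R_i$, and movement is generated by graph Laplacians under the
*semi-negative-definite* sign convention $L = \hat A - \mathrm{Diag}(\sigma)$
(adjacency minus degree), so that the diffusion term is $d\,\sum_j l_{ij} X_j$
and the Laplacian eigenvalues $\eta \le 0$ play the role of $-k^2$
wavenumbers.  On a *homogeneous* network all three compartments share one
topology ($A = B = C$); on a *heterogeneous three-layer* network each edge
carries a permission label (a non-empty subset of $\{S, I, R\}$, the seven
color classes), and decomposing by label gives three independent Laplacians
$A$, $B$, $C$.

## Positive equilibria

At a spatially flat steady state, $S^* = (\mu_2+\alpha)/(\beta I^*)$ and
$R^* = \alpha I^*/\mu_3$, and eliminating $S$ and $R$ leaves a depressed
cubic in the spreader density,

$$
f(I) = K\beta^2 I^3 + K\beta(\mu_1 - r)\,I + r(\mu_2+\alpha) = 0 ,
$$

whose quadratic coefficient vanishes identically (the three roots sum to
zero).  Because $f(0) > 0$, positive roots require a negative linear
coefficient, i.e. $\mu_1 < r$, and additionally $f(I'') < 0$ at the positive
critical point $I'' = \sqrt{(r-\mu_1)/(3\beta)}$.  When both hold there are
exactly two positive roots, labelled the `lower` and `upper` branch; a
tangency $f(I'') = 0$ yields a single equilibrium flagged `degenerate`.
`solve_equilibria()` uses the closed-form depressed-cubic solution
(trigonometric for three real roots, Cardano otherwise) with a four-step
Newton polish; complex roots are discarded at $|\mathrm{Im}| >
10^{-9}\max(1, |\mathrm{Re}|)$.  An independent `polyroot()` route is used
in the tests, never in the implementation.

A note on provenance: the published form of this cubic carries the linear
coefficient $K\beta\mu_1 - r$; re-deriving it from the steady-state
equations gives $K\beta(\mu_1 - r)$.  We ship the re-derived coefficient:
its roots satisfy the reaction fixed-point identity to rounding error
(the published variant's do not), it makes the stated sign analysis
"$\mu_1 \ge r$ precludes positive roots" exact, and simulations initialized
at its equilibria stay put.  At the baseline parameter set below the
corrected positive roots are $I^* \in \{0.7357, 1.1632\}$.

```{r equilibria}
params <- preset_params("pattern")   # K=0.5, beta=0.8, mu1=0.4, mu2=0.1,
                                     # mu3=0.3, alpha=0.1, d1=10, d2=d3=0.1,
                                     # r=2.6
solve_equilibria(params)
```

## Linear stability and the dispersion relation

The local Jacobian at an equilibrium has a block-triangular structure whose
characteristic cubic factors as $(\lambda+\mu_3)(\lambda^2 - T\lambda + D)$
with $T = \mu_2+\alpha - rS^*/K$ and $D = (\mu_2+\alpha)(2r - 3rS^*/K -
2\mu_1)$ (both forms use the steady-state identity $r - rS^*/K - \mu_1 -
\beta I^{*2} = 0$, which gives the Jacobian's (1,1) entry as $-rS^*/K$).
The Hurwitz condition therefore reduces to

$$
\mathrm{H1}:\quad \mu_2+\alpha - \frac{rS^*}{K} < 0
\quad\text{and}\quad 2r - \frac{3rS^*}{K} - 2\mu_1 > 0 ,
$$

which for this model is *equivalent* to the full Routh–Hurwitz criterion
($a_1>0$, $a_3>0$, $a_1a_2>a_3$): the factorization shows the only
candidate for instability is the quadratic factor, and the package verifies
the equivalence against a companion-matrix eigenvalue oracle over random
parameter draws.  Both routes are exposed (`h1_check()`,
`routh_hurwitz_oracle()`) and any disagreement would surface in the test
suite.

On a homogeneous network, expanding perturbations in the Laplacian
eigenbasis reduces the $3N \times 3N$ Jacobian to, per eigenvalue $\eta_n$,
one factor $\lambda = d_3\eta_n - \mu_3 < 0$ and one quadratic
$\lambda^2 + u(\eta_n)\lambda + v(\eta_n)$ with

$$
u(\eta) = -(d_1+d_2)\eta + \frac{rS^*}{K} - \mu_2 - \alpha,\qquad
v(\eta) = d_1 d_2 \eta^2 + \Bigl(d_1(\mu_2+\alpha) -
d_2\frac{rS^*}{K}\Bigr)\eta + D .
$$

A mode grows iff $v(\eta) < 0$ (given H1, $u > 0$ throughout), and $v$, read
as a quadratic $g(\eta)$, is negative exactly on the interval
$(\eta_1^*, \eta_2^*)$ between its roots.  The four-inequality necessary
condition for Turing instability — the H1 cross condition, positive slope
coefficient, positive discriminant, and positive $D$ — is evaluated by
`turing_interval()`; `homogeneous_turing_report()` intersects the interval
with the actual spectrum.  `full_jacobian_spectrum()` assembles the dense
$3N\times 3N$ Jacobian as the ground-truth oracle; the block-reduction
identity is exact to $10^{-8}$ across the test suite.

```{r interval}
eq <- equilibrium_branch(params, "upper")
h1_check(eq, params)
turing_interval(eq, params)$interval
```

## Heterogeneous three-layer networks

When $A \neq B \neq C$ no single eigenbasis diagonalizes all blocks, so the
package follows the spectral-bound route: a norm bound
$\varphi \ge \rho(J)$ is computed as the 2-norm of the block-diagonal
diffusion part (the max over layers and modes of the absolute diagonal
entries) plus the 2-norm of the constant off-diagonal reaction block.  Two
reading notes, both verified by the $\varphi \ge \rho(J)$ property suite:

* the off-diagonal block norm is $\max\{\beta I^{*2},
  \sqrt{4(\mu_2+\alpha)^2+\alpha^2}\}$ — the radical is required (the
  block's Gram matrix is diagonal, so its singular values are exactly these
  two numbers); the radical-free variant is also computed and reported for
  comparison;
* the first term takes absolute values of all diagonal entries, which the
  norm derivation requires.

With $\varphi$ in hand, the necessary conditions for heterogeneous Turing
instability are, per S-layer eigenvalue $\theta_m$ and with
$q_m = d_1\theta_m + r - 2rS^*/K - \mu_1 - \beta I^{*2}$:
H2 — the two H1-style base inequalities plus the existence of a mode with
$d_1\theta_m + r - 2rS^*/K - \mu_1 > 0$; H3 — the base inequalities plus a
mode on the complementary branch ($b_1(\theta_m) < 0$) with
$b_2(\theta_m) = (\mu_2+\alpha)\bigl(\varphi^2 - (d_1\theta_m -
rS^*/K)(d_1\theta_m + 2r - 3rS^*/K - 2\mu_1)\bigr) > 0$.  The published
statement of H3 prints the third inequality with the same sign as H2; the
derivation (the $b_1 < 0$ branch of the linear function $\phi_m(x) = b_1 x
+ b_2$) requires the opposite sign, and we implement the derivation's
reading with every inequality itemized per mode so either reading can be
inspected.  These conditions are *necessary only*; the package pairs them
with simulation (no simulated pattern in the suite violates H2-or-H3, and a
violation fails the build).

## Simulation

`integrate_network()` advances the full system by explicit forward Euler
with layer-specific Laplacians, in a compiled (Rcpp) kernel.  Design
choices:

* **Step size.** Default $dt = 10^{-3}$; an advisory warning fires when
  $dt \cdot \max_\ell d_\ell\,|\lambda_{\min}(L_\ell)| > 0.5$ (estimated by
  the Gershgorin bound $2\max_i \sigma_i$), a deliberately conservative
  factor-4 margin below the hard explicit-stability ceiling
  $dt\,|\lambda| < 2$.  Long pattern runs in the acceptance material use
  $dt = 0.015$ on the $32\times 32$ torus (60% of the hard ceiling for
  $d_1 = 10$), which is empirically stable there with zero negativity
  clips; the warning is suppressed knowingly in those scripts.
* **Negativity.** Euler can undershoot zero; values are clipped at 0 and
  the clip count is reported on the trajectory.  The steady states of
  interest are interior, so clipping is a transient-only safeguard.
* **Initial condition.** Patterns are seeded from
  `perturbed_equilibrium_init()`: node values equal the chosen equilibrium
  branch times $1 + U(-a, a)$, default amplitude $a = 0.01$, seeded.  The
  originating study never states its initialization; this is a package
  choice.
* **Convergence.** `detect_steady()` and the integrator's early stop are
  residual-based (max-norm of the full right-hand side), so the criterion
  does not depend on $dt$; Euler fixed points are exact zeros of the
  vector field.
* **Time horizon.** On the $32\times 32$ torus at the baseline set the
  pattern's amplitude saturates by $t \approx 2000$, but relaxation of the
  residual below $10^{-7}$ takes $t \approx 5\times 10^4$ — spot patterns
  coarsen slowly through near-degenerate defect configurations.  Fixtures
  therefore cap $t$ generously and stop on residual.  The test suite's
  shared fixture uses a $16\times 16$ torus (converges by $t \approx
  5000$) to keep the default run fast; problem sizes in the acceptance
  script are $32\times 32$ for the dichotomy and $100$–$144$ nodes for the
  heterogeneous sweep.

## Graph Fourier diagnostics

`eigendecompose()` returns an orthonormal Laplacian eigenbasis with the
eigenvalues sorted decreasingly (0 first) and, on connected graphs, the
0-mode normalized to the positive constant vector $\mathbf 1/\sqrt N$.
Projections $k_i = \langle x, \gamma_i\rangle$ reconstruct exactly and obey
Parseval's identity; a state is spatially homogeneous iff all non-constant
coefficients vanish (asserted only for connected graphs, where the 0-mode
is simple).  Lattice Laplacians have high-multiplicity eigenspaces in which
individual eigenvectors are solver-dependent, so quantitative statements
use `spectral_energy()` — summed squared coefficients per distinct
eigenvalue, a rotation-invariant quantity.  `scatter_points()` reproduces
the display convention for spectra: abscissa $-\eta_i \ge 0$, ordinate
$\log_2|k_i|$, with a magnitude floor defaulting to $2^{-18}$.

## The calibration stage and its synthetic data

The cumulative-adoption observable adds $\dot N = \beta S I^2$ to the
model.  A single national time series carries no spatial information: with
flat initial data and zero-flux boundaries the diffusion terms vanish
identically, so the fit uses the four-ODE homogeneous reduction (a
network-resolved fit is out of scope).  `synthetic_series()` emulates the
study conditions: initial state $(S, I, R, N)(0) = (1, 0.1, 0.1, 0.002)$,
54 daily observations, i.i.d. Gaussian observation noise of sd 0.005
clipped at zero.  The noise level is chosen to match the reported
residual scale of the original calibration (RMSE $\approx 0.02$ against
percent-scale values); the generator does not emulate the serial
correlation or heteroskedasticity of real tweet counts, so passing
recovery tests demonstrate optimizer and model correctness, not robustness
to real-data artifacts.

`fit_random_walk_ls()` is a greedy random walk: multiplicative log-normal
proposals (relative scale 5%) around the incumbent, clipped to box bounds,
accepted only on improvement of the sum of squared errors on $N(t)$ — so
the objective trace is non-increasing by construction.  The walk's
hyperparameters are package choices; the originating description names the
strategy but fixes nothing.

**Identifiability.**  The reduction makes two parameter combinations
structurally non-identifiable from $N(t)$ alone:

* $\mu_2$ and $\alpha$ enter the observable only through $\mu_2+\alpha$
  ($R$ is latent and feeds back nowhere), so the split between them is
  arbitrary along a ridge;
* rescaling $\tilde S = S/K$ shows $\beta$ entering as the product
  $\beta K$ everywhere except through the fixed initial condition
  $S(0) = 1$, which provides only weak separate leverage.

Empirically (best-of-5 walk seeds, 20,000 iterations each, across
generator seeds) the identifiable combinations $\beta K$ and
$\mu_2+\alpha$ recover to within a few percent and the fit RMSE stays
below twice the noise sd, while $\beta$ and $\alpha$ individually land
anywhere on their ridges (relative errors from 4% to 86% were observed).
The acceptance suite retains the individual-parameter recovery check as
specified upstream — it fails for most seeds, and we regard that failure
as the correct scientific verdict on the criterion rather than a defect in
the optimizer; the package's own tests assert the identifiable
combinations.  Consistently, the shipped `indonesia2020` preset should be
read as *a* ridge point consistent with the original data, not as uniquely
determined rates.

`intervention_run()` switches $\alpha$ to a boosted value at $t = 30$ and
compares cumulative curves; the final $N$ is non-increasing in the boost,
and the check sweeps ten boost levels.

## Numerical conventions and degenerate inputs

* All stability inequalities are strict; margins are always reported so
  boundary cases are visible to the caller.
* Disconnected generated graphs (possible for Erdős–Rényi draws) are
  allowed with a warning reporting the component count, which equals the
  number of zero Laplacian eigenvalues; the homogeneity ⇔ only-$k_1$
  spectral argument is asserted only for connected graphs.
* Degree-6 lattices add the $(+1,+1)$ diagonal pair to the von-Neumann
  neighborhood; lattice boundaries default to periodic so every node has
  the nominal degree 4/6/8 (open boundaries available).  The
  Barabási–Albert seed graph is a clique of $m$ nodes, so the edge count
  is exactly $\binom{m}{2} + (n-m)m$.
* Baseline growth-rate reading: captions in the originating figures give
  $r = 0.26$/$0.4$ while the accompanying text gives $r = 2.6$/$4$.  With
  $\mu_1 = 0.4$, Theorem-type existence fails for $r = 0.26$ (no positive
  equilibrium), so the text values are the only self-consistent reading
  and the `pattern` preset defaults to $r = 2.6$; both remain accepted as
  inputs.

## Known limitations

* Explicit Euler only; stiff or adaptive integration is out of scope, and
  very stiff parameter sets require manually reduced $dt$.
* The heterogeneous-network conditions H2/H3 are necessary, not
  sufficient; the package intentionally provides no sufficiency claim.
* The dense $3N\times 3N$ eigenvalue oracle is capped (default
  $N \le 2000$).
* Weighted, directed and temporal networks are not modeled.
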