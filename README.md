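# rumornet

Turing-pattern analysis for an SIR-type rumor propagation model on complex
networks.

## The problem

Rumors on social platforms spread by repeated contact: an ignorant
(susceptible) user adopts a rumor only after reinforcement, so transmission
is quadratic in spreader density.  With logistic growth of the susceptible
pool the kinetics are

    dS/dt = r S (1 - S/K) - beta S I^2 - mu1 S
    dI/dt = beta S I^2 - (mu2 + alpha) I
    dR/dt = alpha I - mu3 R

and space is a *network*: node densities diffuse along edges through graph
Laplacians L = A_hat - Diag(sigma) (semi-negative-definite convention), at
rates d1, d2, d3 per compartment.  On a homogeneous network all three
compartments share one topology; on a heterogeneous three-layer network
each edge carries a permission label (one of the seven non-empty subsets of
{S, I, R}), and decomposing by label yields independent Laplacians A, B, C
for the three flows.

The package is a toolkit for the full analysis pipeline of this system,
aimed at researchers in network epidemiology / information dynamics:

* **netgen** — lattice (degree 4/6/8, periodic or open), Erdős–Rényi and
  Barabási–Albert generators; per-edge permission labeling; layer
  decomposition; a plain-text edge-list format.
* **kinetics** — the equilibrium cubic
  `f(I) = K beta^2 I^3 + K beta (mu1 - r) I + r (mu2 + alpha)`, closed-form
  positive equilibria with branch labels, local Jacobian, characteristic
  coefficients.
* **stability** — the Hurwitz condition H1; the dispersion relation
  `lambda^2 + u(eta) lambda + v(eta)` and the Turing interval
  `(eta1*, eta2*)` on homogeneous networks; the spectral bound `phi` and
  the necessary conditions H2/H3 on heterogeneous networks; a dense
  3N×3N Jacobian eigenvalue oracle.
* **dynamics** — compiled forward-Euler integration with residual-based
  steady-state detection and pattern-heterogeneity statistics.
* **spectral** — graph Fourier coefficients in the Laplacian eigenbasis,
  per-eigenvalue spectral energy, display scatter points.
* **fitdata** — the cumulative-adoption observable `dN/dt = beta S I^2`,
  a synthetic noisy-series generator, random-walk + least-squares
  calibration with RMSE/MAPE, and recovery-rate intervention experiments.

## Worked example

The baseline parameter set of the pattern study is shipped as a preset:

```r
library(rumornet)

params <- preset_params("pattern")   # K=0.5 beta=0.8 mu1=0.4 mu2=0.1
                                     # mu3=0.3 alpha=0.1 d1=10 d2=d3=0.1 r=2.6
solve_equilibria(params)
#> [[1]]
#> equilibrium (lower): S*=0.339802 I*=0.735723 R*=0.245241
#> [[2]]
#> equilibrium (upper): S*=0.214931 I*=1.16316 R*=0.387721

eq <- equilibrium_branch(params, "upper")
h1_check(eq, params)
#> $holds
#> [1] TRUE
#> $margin1
#> [1] -0.9176429        # mu2+alpha - r S*/K  (< 0 required)
#> $margin2
#> [1] 1.047071          # 2r - 3 r S*/K - 2 mu1  (> 0 required)

turing_interval(eq, params)$interval
#>  eta1_star  eta2_star
#> -1.7699165 -0.1183187
```

The upper branch is locally stable to homogeneous perturbations (H1 holds)
but Laplacian modes with eigenvalues inside `(-1.770, -0.118)` grow — the
Turing mechanism.  A 32×32 periodic quadrilateral lattice has many such
modes:

```r
net  <- build_lattice(32, 32, degree = 4)          # torus, all degrees 4
homogeneous_turing_report(net, eq, params)
#> dispersion analysis (upper branch): H1 holds; interval (-1.7699, -0.1183);
#> 156 unstable mode(s); Turing-capable: TRUE

init <- perturbed_equilibrium_init(eq, net$n, amplitude = 0.01, seed = 7)
traj <- integrate_network(net, params, init, dt = 0.015, t_end = 150000,
                          stride = 20000, stop_at_steady = TRUE,
                          steady_tol = 1e-7)
traj
#> trajectory: 178 snapshots to t=5.31e+04 (dt=0.015), residual 9.87e-08
#> (steady), 0 clipped
sd(final_state(traj)$I) / sd(init$I)
#> [1] 151.0467
```

The 1% perturbation grows into a stationary spot pattern whose spreader
field is ~151× more heterogeneous than the seed noise; with equal diffusion
(d1 = d2 = d3 = 0.1) the same perturbation decays back to homogeneity.
The graph Fourier spectrum localizes the pattern in the predicted band:

```r
basis <- eigendecompose(net$A)
en    <- spectral_energy(final_state(traj)$I, basis)
nc    <- en[abs(en$eigenvalue) > 1e-9, ]
nc$eigenvalue[which.max(nc$energy)]
#> [1] -0.7380274         # inside (eta1*, eta2*) = (-1.770, -0.118)
```

For the calibration stage, a noisy synthetic cumulative-adoption curve is
generated and refit:

```r
p <- preset_params("indonesia2020")
series <- synthetic_series(p, t_grid = 1:54, noise_sd = 0.005, seed = 11)
fits <- lapply(1:5, function(s)
  fit_random_walk_ls(series, list(iterations = 20000, seed = s)))
best <- fits[[which.min(sapply(fits, `[[`, "sse"))]]
best$rmse
#> [1] 0.004090624        # below the 0.005 observation noise
```

The identifiable parameter combinations recover tightly (`beta*K` and
`mu2+alpha` to within a few percent); `beta` and `alpha` individually lie
on structural ridges of the homogeneous reduction — see the methods
vignette (`vignettes/network-turing-patterns.Rmd`) for the identifiability
analysis.

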