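#' Node state constructor
#'
#' @param S,I,R numeric vectors of equal length N (per-node densities).
#' @return A `node_state` list.
#' @export
node_state <- function(S, I, R) {
  N <- length(S)
  if (length(I) != N || length(R) != N)
    stop("S, I, R must have equal length", call. = FALSE)
  if (any(!is.finite(S)) || any(!is.finite(I)) || any(!is.finite(R)))
    stop("node_state: non-finite entries", call. = FALSE)
  if (any(S < 0) || any(I < 0) || any(R < 0))
    stop("node_state: densities must be non-negative", call. = FALSE)
  structure(list(S = S, I = I, R = R), class = "node_state")
}

#' Multiplicatively perturbed homogeneous equilibrium
#'
#' Initial condition for pattern simulations: every node value is the
#' equilibrium value times `1 + uniform(-amplitude, amplitude)`, i.i.d.
#' across nodes and compartments.
#'
#' @param eq an `equilibrium_point`.
#' @param N number of nodes.
#' @param amplitude relative perturbation scale in `[0, 1)`.
#' @param seed integer seed.
#' @return A `node_state`.
#' @export
perturbed_equilibrium_init <- function(eq, N, amplitude = 0.01, seed = 1L) {
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1)", call. = FALSE)
  u <- with_seed(seed, matrix(runif(3L * N, -amplitude, amplitude), ncol = 3L))
  node_state(eq$S_star * (1 + u[, 1L]),
             eq$I_star * (1 + u[, 2L]),
             eq$R_star * (1 + u[, 3L]))
}

# general (not symmetric-storage) CSC form, as the compiled core expects
#' @importFrom Matrix Matrix
as_dgc <- function(M) {
  methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix")
}

rhs_full <- function(state, net_sparse, p) {
  rr <- reaction_rates(state$S, state$I, state$R, p)
  list(dS = as.vector(p$d1 * (net_sparse$A %*% state$S)) + rr$dS,
       dI = as.vector(p$d2 * (net_sparse$B %*% state$I)) + rr$dI,
       dR = as.vector(p$d3 * (net_sparse$C %*% state$R)) + rr$dR)
}

#' Forward-Euler integration of the network reaction-diffusion system
#'
#' Steps \eqn{X(t+dt) = X(t) + dt\,(D\,L\,X + f(X))} with the
#' layer-specific Laplacians A (for S), B (for I) and C (for R).  Explicit
#' Euler can undershoot zero; negative values are clipped at 0 and the
#' clip count is recorded.  A warning is emitted when
#' \eqn{dt \cdot \max_\ell d_\ell |\lambda_{\min}(L_\ell)| > 0.5}
#' (diffusion near the explicit-stability ceiling).
#'
#' @param net a `layered_network`.
#' @param params a [model_params].
#' @param init a `node_state`.
#' @param dt time step.
#' @param t_end final time (integration may stop earlier on convergence
#'   when `stop_at_steady` is set).
#' @param stride store every `stride`-th step (the final state is always
#'   stored).
#' @param stop_at_steady if `TRUE`, stop when the max-norm of the full
#'   right-hand side falls below `steady_tol` (checked every `stride`
#'   steps).
#' @param steady_tol residual tolerance for early stopping.
#' @return A `trajectory`: list with `times`, `states` (list of
#'   `node_state`), `dt`, `converged`, `final_residual`, `clipped`
#'   (number of negative values clipped).
#' @export
integrate_network <- function(net, params, init, dt = 1e-3, t_end = 100,
                              stride = 100L, stop_at_steady = FALSE,
                              steady_tol = 1e-7) {
  p <- as_model_params(params)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  ns <- lapply(list(A = net$A, B = net$B, C = net$C), as_dgc)
  dmax <- max(p$d1 * abs(min(diag(net$A))) * 2,
              p$d2 * abs(min(diag(net$B))) * 2,
              p$d3 * abs(min(diag(net$C))) * 2)
  if (dt * dmax > 0.5)
    warning(sprintf("dt = %g is near/above the explicit-stability ceiling (dt*max(2*d*deg) = %.3g > 0.5)",
                    dt, dt * dmax), call. = FALSE)
  n_steps <- max(1L, as.integer(ceiling(t_end / dt - 1e-9)))
  stride <- max(1L, as.integer(stride))
  core <- .euler_core(ns$A, ns$B, ns$C, unlist(unclass(p)),
                      init$S, init$I, init$R, dt, n_steps, stride,
                      stop_at_steady, steady_tol)
  states <- lapply(seq_along(core$times), function(j)
    node_state(core$S[, j], core$I[, j], core$R[, j]))
  structure(list(times = core$times, states = states, dt = dt,
                 converged = core$converged,
                 final_residual = core$final_residual,
                 clipped = as.integer(core$clipped), net = net, params = p),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d snapshots to t=%.4g (dt=%g), residual %.3g%s, %d clipped\n",
              length(x$times), max(x$times), x$dt, x$final_residual,
              if (x$converged) " (steady)" else "", x$clipped))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj a `trajectory`.
#' @export
final_state <- function(traj) traj$states[[length(traj$states)]]

#' Residual-based steady-state detection
#'
#' A trajectory is steady when the max-norm of the full right-hand side
#' (diffusion plus reaction) at its final state is below `tol`.  Being
#' residual-based rather than state-difference-based, the criterion does
#' not depend on `dt`.
#'
#' @param traj a `trajectory` from [integrate_network].
#' @param tol residual tolerance.
#' @return A list: `steady` (logical) and `residual`.
#' @export
detect_steady <- function(traj, tol = 1e-7) {
  st <- final_state(traj)
  ns <- lapply(list(A = traj$net$A, B = traj$net$B, C = traj$net$C), as_dgc)
  f <- rhs_full(st, ns, traj$params)
  resid <- max(abs(f$dS), abs(f$dI), abs(f$dR))
  list(steady = resid < tol, residual = resid)
}

#' Spatial-heterogeneity statistics of a node state
#'
#' Per-compartment mean, standard deviation (population, denominator N),
#' min and max, plus a heterogeneity flag: `sd/mean` above `threshold` in
#' any compartment marks the state as spatially heterogeneous (a Turing
#' pattern candidate).
#'
#' @param state a `node_state`.
#' @param threshold relative-sd threshold for the flag.
#' @return A list of class `pattern_stats`: data frame `stats` and logical
#'   `heterogeneous` (per compartment) and `any_heterogeneous`.
#' @export
pattern_stats <- function(state, threshold = 1e-3) {
  one <- function(x) {
    n <- length(x)
    m <- mean(x)
    c(mean = m, sd = sqrt(sum((x - m)^2) / n), min = min(x), max = max(x))
  }
  st <- rbind(S = one(state$S), I = one(state$I), R = one(state$R))
  rel <- ifelse(st[, "mean"] > 0, st[, "sd"] / st[, "mean"], st[, "sd"])
  het <- rel > threshold
  structure(list(stats = as.data.frame(st), heterogeneous = het,
                 any_heterogeneous = any(het)),
            class = "pattern_stats")
}

#' @export
print.pattern_stats <- function(x, ...) {
  print(round(x$stats, 6))
  cat("heterogeneous:", paste(names(x$heterogeneous)[x$heterogeneous],
                              collapse = " "),
      if (!x$any_heterogeneous) "(none)", "\n")
  invisible(x)
}
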