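test_that("perturbed initial conditions are reproducible and bounded", {
  eq <- upper_eq()
  a <- perturbed_equilibrium_init(eq, 50, 0.01, seed = 3)
  b <- perturbed_equilibrium_init(eq, 50, 0.01, seed = 3)
  expect_identical(a, b)
  expect_true(all(abs(a$I / eq$I_star - 1) <= 0.01))
  z <- perturbed_equilibrium_init(eq, 10, 0, seed = 1)
  expect_equal(z$S, rep(eq$S_star, 10))
  expect_error(perturbed_equilibrium_init(eq, 10, 1), "amplitude")
})

test_that("an exact homogeneous equilibrium is a fixed point of the integrator", {
  p <- pattern_params()
  eq <- upper_eq(p)
  net <- build_lattice(5, 5, 4)
  init <- perturbed_equilibrium_init(eq, net$n, 0, seed = 1)
  traj <- suppressWarnings(integrate_network(net, p, init, dt = 0.01, t_end = 2))
  expect_lt(traj$final_residual, 1e-12)
  st <- final_state(traj)
  expect_equal(st$S, init$S, tolerance = 1e-12)
  expect_true(detect_steady(traj, tol = 1e-10)$steady)
})

test_that("zero diffusion reduces to independent per-node kinetics (ODE oracle)", {
  skip_if_not_installed("deSolve")
  p0 <- pattern_params()
  p <- model_params(r = p0$r, K = p0$K, beta = p0$beta, mu1 = p0$mu1,
                    mu2 = p0$mu2, mu3 = p0$mu3, alpha = p0$alpha,
                    d1 = 1e-12, d2 = 1e-12, d3 = 1e-12)
  net <- homogeneous_network(adjacency_spec(4, rbind(c(0, 1), c(1, 2),
                                                     c(2, 3))), "path")
  set.seed(8)
  init <- node_state(runif(4, 0.1, 1), runif(4, 0.5, 2), runif(4, 0.1, 1))
  traj <- integrate_network(net, p, init, dt = 5e-4, t_end = 5,
                            stride = 10000L)
  st <- final_state(traj)
  for (i in 1:4) {
    sol <- deSolve::ode(
      y = c(S = init$S[i], I = init$I[i], R = init$R[i]),
      times = c(0, 5),
      func = function(t, y, parms) {
        rr <- reaction_rates(y[1], y[2], y[3], p)
        list(c(rr$dS, rr$dI, rr$dR))
      }, parms = NULL, rtol = 1e-10, atol = 1e-12)
    expect_equal(c(st$S[i], st$I[i], st$R[i]), unname(sol[2, 2:4]),
                 tolerance = 1e-3)
  }
})

test_that("homogeneous initial data follow the scalar kinetics on any network", {
  p <- pattern_params()
  net <- build_lattice(4, 4, 8)
  x0 <- c(S = 0.3, I = 1.5, R = 0.2)
  init <- node_state(rep(x0[1], 16), rep(x0[2], 16), rep(x0[3], 16))
  traj <- integrate_network(net, p, init, dt = 1e-3, t_end = 1,
                            stride = 1000L)
  st <- final_state(traj)
  # scalar explicit-Euler reference with the same step
  x <- x0
  for (k in 1:1000) {
    rr <- reaction_rates(x[1], x[2], x[3], p)
    x <- x + 1e-3 * c(rr$dS, rr$dI, rr$dR)
  }
  expect_equal(st$S, rep(unname(x[1]), 16), tolerance = 1e-12)
  expect_equal(st$I, rep(unname(x[2]), 16), tolerance = 1e-12)
  expect_lt(sd(st$I), 1e-14)  # diffusion term vanishes exactly
})

test_that("integration guards: stability warning and divergence error", {
  p <- pattern_params()
  eq <- upper_eq(p)
  net <- build_lattice(4, 4, 4)
  init <- perturbed_equilibrium_init(eq, net$n, 0.01, seed = 1)
  expect_warning(integrate_network(net, p, init, dt = 0.1, t_end = 0.2),
                 "ceiling")
  # a grossly unstable step undershoots: the negativity guard clips and logs
  wild <- suppressWarnings(integrate_network(net, p, init, dt = 5,
                                             t_end = 50))
  expect_gt(wild$clipped, 0)
})

test_that("steady-state detection distinguishes transients from steady states", {
  fx <- turing_fixture_small()
  expect_true(detect_steady(fx$traj, tol = 1e-7)$steady)
  early <- suppressWarnings(
    integrate_network(fx$net, fx$params, fx$init, dt = 0.01,
                      t_end = 5, stride = 500L))
  expect_false(detect_steady(early, tol = 1e-7)$steady)
})

test_that("pattern statistics are exact on hand-computable fields", {
  st <- node_state(c(0, 2), c(1, 1), c(3, 5))
  ps <- pattern_stats(st)
  expect_equal(ps$stats["S", "mean"], 1)
  expect_equal(ps$stats["S", "sd"], 1)  # population sd
  expect_equal(ps$stats["I", "sd"], 0)
  expect_false(ps$heterogeneous[["I"]])
  expect_true(ps$heterogeneous[["S"]])
  expect_equal(ps$stats["R", "min"], 3)
  expect_equal(ps$stats["R", "max"], 5)
  expect_true(all(ps$stats$min <= ps$stats$mean & ps$stats$mean <=
                    ps$stats$max))
})

test_that("Turing-capable parameters grow patterns; equal diffusion decays them", {
  fx <- turing_fixture_small()
  # growth: saturated heterogeneity well above the initial perturbation
  ratio <- sd(fx$final$I) / sd(fx$init$I)
  expect_gte(ratio, 10)
  ps <- pattern_stats(fx$final)
  expect_true(all(ps$heterogeneous))
  # decay: same perturbation, equal diffusion, no unstable modes
  p0 <- fx$params
  pd <- model_params(r = p0$r, K = p0$K, beta = p0$beta, mu1 = p0$mu1,
                     mu2 = p0$mu2, mu3 = p0$mu3, alpha = p0$alpha,
                     d1 = 0.1, d2 = 0.1, d3 = 0.1)
  eq <- equilibrium_branch(pd, "upper")
  init <- perturbed_equilibrium_init(eq, fx$net$n, 0.01, seed = 7L)
  traj <- integrate_network(fx$net, pd, init, dt = 0.01, t_end = 80,
                            stride = 1000L)
  st <- final_state(traj)
  expect_lt(sd(st$I), 1e-6)
  expect_lt(sd(st$S), 1e-6)
})

test_that("compartment layers are independently wired", {
  p <- pattern_params()
  eq <- upper_eq(p)
  adj <- adjacency_spec(9, build_lattice(3, 3, 4)$edges)
  perm <- c("S", "I", "R", "SI", "SR", "IR", "SIR", "S", "I",
            rep("SIR", nrow(adj$edges) - 9))
  lay <- decompose_layers(adj, perm)
  # swap the I and R layers
  swapped <- lay
  swapped$B <- lay$C; swapped$C <- lay$B
  init <- perturbed_equilibrium_init(eq, 9, 0.05, seed = 4)
  t1 <- final_state(suppressWarnings(
    integrate_network(lay, p, init, dt = 0.01, t_end = 3, stride = 300L)))
  t2 <- final_state(suppressWarnings(
    integrate_network(swapped, p, init, dt = 0.01, t_end = 3,
                      stride = 300L)))
  expect_gt(max(abs(t1$I - t2$I)), 1e-8)
  expect_gt(max(abs(t1$R - t2$R)), 1e-8)
})

test_that("halving dt changes the steady state at first order only", {
  fx <- turing_fixture_small()
  # restart near the converged pattern with two step sizes
  st <- fx$final
  tA <- final_state(suppressWarnings(
    integrate_network(fx$net, fx$params, st, dt = 0.02, t_end = 10,
                      stride = 500L)))
  tB <- final_state(suppressWarnings(
    integrate_network(fx$net, fx$params, st, dt = 0.01, t_end = 10,
                      stride = 1000L)))
  dAB <- max(abs(tA$I - tB$I))
  tC <- final_state(integrate_network(fx$net, fx$params, st, dt = 0.005,
                                      t_end = 10, stride = 2000L))
  dBC <- max(abs(tB$I - tC$I))
  # explicit Euler: error halves with the step (allow generous slack)
  expect_lt(dBC, dAB)
})
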