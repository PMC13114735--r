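test_that("H1 holds on the upper branch and fails on the lower at the baseline set", {
  p <- pattern_params()
  up <- h1_check(upper_eq(p), p)
  expect_true(up$holds)
  expect_equal(up$margin1, -0.9176429, tolerance = 1e-6)
  expect_equal(up$margin2, 1.0470710, tolerance = 1e-6)
  lo <- h1_check(equilibrium_branch(p, "lower"), p)
  expect_false(lo$holds)
  expect_lt(lo$margin2, 0)  # second inequality is the one that fails
})

test_that("Routh-Hurwitz oracle handles boundary and textbook cases", {
  expect_true(routh_hurwitz_oracle(c(3, 3, 1)))    # (lambda + 1)^3
  expect_false(routh_hurwitz_oracle(c(-1, 1, 1)))
  # a1 a2 = a3 boundary (purely imaginary pair) is not stable
  expect_false(routh_hurwitz_oracle(c(1, 1, 1)))
})

test_that("Routh-Hurwitz agrees with companion-matrix eigenvalues on random cubics", {
  set.seed(303)
  for (k in 1:2000) {
    a <- runif(3, -3, 3)
    lam <- eigen(rbind(c(-a[1], -a[2], -a[3]), c(1, 0, 0), c(0, 1, 0)),
                 only.values = TRUE)$values
    stable <- all(Re(lam) < 0)
    if (max(abs(Re(lam))) < 1e-8) next  # skip numerically marginal draws
    expect_identical(routh_hurwitz_oracle(a), stable)
  }
})

test_that("H1 is equivalent to the full Hurwitz criterion for this model", {
  set.seed(11)
  for (k in 1:200) {
    p <- random_params(positive_eq = TRUE)
    for (eq in solve_equilibria(p)) {
      h1 <- h1_check(eq, p)$holds
      rh <- routh_hurwitz_oracle(char_poly_coeffs(eq, p))
      expect_identical(h1, rh)
    }
  }
})

test_that("raw and simplified dispersion coefficients agree at a true equilibrium", {
  set.seed(21)
  for (k in 1:50) {
    p <- random_params(positive_eq = TRUE, diffusive = TRUE)
    eq <- equilibrium_branch(p, "upper")
    eta <- -runif(6, 0, 8)
    both <- dispersion_uv(eq, p, eta, form = "both")
    expect_equal(both$simplified$u, both$raw$u, tolerance = 1e-10)
    expect_equal(both$simplified$v, both$raw$v, tolerance = 1e-10)
  }
  expect_error(dispersion_uv(upper_eq(), pattern_params(), 0.5),
               "non-positive")
})

test_that("dispersion values at eta = 0 match the closed forms", {
  p <- pattern_params()
  eq <- upper_eq(p)
  uv0 <- dispersion_uv(eq, p, 0)
  expect_equal(uv0$u, p$r * eq$S_star / p$K - p$mu2 - p$alpha,
               tolerance = 1e-12)
  expect_equal(uv0$v, (p$mu2 + p$alpha) *
                 (2 * p$r - 3 * p$r * eq$S_star / p$K - 2 * p$mu1),
               tolerance = 1e-12)
  expect_gt(uv0$v, 0)  # positive whenever H1 holds
})

test_that("Turing interval at the baseline set matches the quadratic-formula oracle", {
  p <- pattern_params()
  ti <- turing_interval(upper_eq(p), p)
  expect_true(all(ti$conditions))
  g <- ti$g_coeffs
  oracle <- sort(Re(polyroot(c(g[["gC"]], g[["gB"]], g[["gA"]]))))
  expect_equal(unname(ti$interval), oracle, tolerance = 1e-9)
  expect_equal(unname(ti$interval), c(-1.7699165, -0.1183187),
               tolerance = 1e-6)
  # g vanishes at both roots
  gfun <- function(x) g[["gA"]] * x^2 + g[["gB"]] * x + g[["gC"]]
  expect_lt(max(abs(gfun(ti$interval))), 1e-9)
})

test_that("equal diffusion closes the Turing interval", {
  p0 <- pattern_params()
  p <- model_params(r = p0$r, K = p0$K, beta = p0$beta, mu1 = p0$mu1,
                    mu2 = p0$mu2, mu3 = p0$mu3, alpha = p0$alpha,
                    d1 = 0.1, d2 = 0.1, d3 = 0.1)
  ti <- turing_interval(equilibrium_branch(p, "upper"), p)
  expect_null(ti$interval)
  expect_false(ti$conditions[["slope"]])
})

test_that("homogeneous Turing report intersects interval and spectrum correctly", {
  p <- pattern_params()
  eq <- upper_eq(p)
  torus <- build_lattice(16, 16, 4)
  rep1 <- homogeneous_turing_report(torus, eq, p)
  expect_true(rep1$turing_capable)
  expect_gt(length(rep1$unstable_modes), 0)
  expect_true(all(rep1$eta[rep1$unstable_modes] > rep1$interval[1] &
                    rep1$eta[rep1$unstable_modes] < rep1$interval[2]))
  # g < 0 exactly on the unstable modes
  expect_true(all(rep1$g[rep1$unstable_modes] < 0))
  expect_true(all(rep1$g[-rep1$unstable_modes] >= 0))
  # K3 spectrum {0, -3, -3} misses the interval (-1.77, -0.118)
  k3 <- homogeneous_network(adjacency_spec(3, rbind(c(0, 1), c(0, 2),
                                                    c(1, 2))), "K3")
  rep2 <- homogeneous_turing_report(k3, eq, p)
  expect_length(rep2$unstable_modes, 0)
  expect_false(rep2$turing_capable)
  # a single node has only the 0 mode
  one <- homogeneous_network(adjacency_spec(1, NULL), "single")
  expect_false(homogeneous_turing_report(one, eq, p)$turing_capable)
  # heterogeneous input is rejected
  adj <- adjacency_spec(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
  het <- decompose_layers(adj, c("S", "I", "SIR"))
  expect_error(homogeneous_turing_report(het, eq, p), "heterogeneous")
})

test_that("phi reduces to the closed form on an isolated node", {
  p <- pattern_params()
  eq <- upper_eq(p)
  one <- homogeneous_network(adjacency_spec(1, NULL), "single")
  ph <- phi_bound(one, eq, p)
  j11 <- p$r - 2 * p$r * eq$S_star / p$K - p$mu1 - p$beta * eq$I_star^2
  expect_equal(ph$diag_norm, max(abs(j11), p$mu2 + p$alpha, p$mu3),
               tolerance = 1e-12)
  expect_equal(ph$offdiag_norm,
               max(p$beta * eq$I_star^2,
                   sqrt(4 * (p$mu2 + p$alpha)^2 + p$alpha^2)),
               tolerance = 1e-12)
})

test_that("off-diagonal reaction block 2-norm equals the closed form", {
  p <- pattern_params()
  eq <- upper_eq(p)
  M <- matrix(0, 3, 3)
  M[1, 2] <- -2 * (p$mu2 + p$alpha)
  M[2, 1] <- p$beta * eq$I_star^2
  M[3, 2] <- p$alpha
  expect_equal(max(svd(M)$d),
               max(p$beta * eq$I_star^2,
                   sqrt(4 * (p$mu2 + p$alpha)^2 + p$alpha^2)),
               tolerance = 1e-12)
})

test_that("phi dominates the spectral radius of the full Jacobian (random heterogeneous nets)", {
  set.seed(99)
  for (k in 1:50) {
    p <- random_params(positive_eq = TRUE, diffusive = TRUE)
    eq <- solve_equilibria(p)[[sample(2, 1)]]
    n <- sample(5:20, 1)
    adj <- random_connected_adj(n)
    lay <- decompose_layers(adj, assign_edge_permissions(adj, "uniform7",
                                                         seed = k))
    ph <- phi_bound(lay, eq, p)
    rho <- max(Mod(full_jacobian_spectrum(lay, eq, p)))
    expect_gte(ph$phi + 1e-10, rho)
  }
})

test_that("hetero report: q at the zero mode equals -rS*/K and H2/H3 are itemized", {
  p <- pattern_params()
  eq <- upper_eq(p)
  adj <- random_connected_adj(12)
  lay <- decompose_layers(adj, assign_edge_permissions(adj, "uniform7",
                                                       seed = 2))
  rep <- hetero_necessary_report(lay, eq, p)
  # theta is sorted decreasing; the first mode is 0 for a connected layer
  expect_equal(rep$modes$theta[1], 0, tolerance = 1e-8)
  expect_equal(rep$modes$q[1], -p$r * eq$S_star / p$K, tolerance = 1e-8)
  expect_lt(rep$modes$q[1], 0)
  expect_true(rep$base_holds)
  # witnesses are consistent with the stored b1/b2 columns
  if (rep$H2_holds)
    expect_true(all(rep$modes$b1[rep$H2_witness] < 0))  # b1 = -2(m2+a)*lin
  if (rep$H3_holds)
    expect_true(all(rep$modes$b2[rep$H3_witness] > 0))
})

test_that("hetero report on a homogeneous net shares the base inequalities with the interval report", {
  p <- pattern_params()
  eq <- upper_eq(p)
  torus <- build_lattice(8, 8, 4)
  het <- hetero_necessary_report(torus, eq, p)
  ti <- turing_interval(eq, p)
  expect_equal(het$base[["cross"]], ti$values[["cross"]], tolerance = 1e-12)
  expect_equal(het$base[["base"]], ti$values[["base"]], tolerance = 1e-12)
})

test_that("full-Jacobian spectrum reduces to the dispersion relation on homogeneous nets", {
  set.seed(515)
  for (k in 1:30) {
    p <- random_params(positive_eq = TRUE, diffusive = TRUE)
    eq <- solve_equilibria(p)[[sample(2, 1)]]
    n <- sample(4:15, 1)
    net <- homogeneous_network(random_connected_adj(n), "rand")
    lam <- full_jacobian_spectrum(net, eq, p)
    eta <- eigen(net$A, symmetric = TRUE, only.values = TRUE)$values
    uv <- dispersion_uv(eq, p, pmin(eta, 0))
    pred <- c(p$d3 * eta - p$mu3,
              unlist(lapply(seq_along(eta), function(i) {
                disc <- as.complex(uv$u[i]^2 - 4 * uv$v[i])
                (-uv$u[i] + c(1, -1) * sqrt(disc)) / 2
              })))
    expect_lt(spectrum_match_error(lam, as.complex(pred)), 1e-7)
    # the d3*eta - mu3 family always has negative real part
    expect_true(all(p$d3 * eta - p$mu3 < 0))
  }
})

test_that("full Jacobian degenerates correctly for single nodes and zero diffusion", {
  p <- pattern_params()
  eq <- upper_eq(p)
  one <- homogeneous_network(adjacency_spec(1, NULL), "single")
  lamJ <- sort(Re(full_jacobian_spectrum(one, eq, p)))
  lam3 <- sort(Re(eigen(local_jacobian(eq, p), only.values = TRUE)$values))
  expect_equal(lamJ, lam3, tolerance = 1e-10)
  expect_error(full_jacobian_spectrum(build_lattice(3, 3, 4), eq, p,
                                      max_n = 5), "cap")
})
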