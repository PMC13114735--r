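# shared fixtures, computed once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

pattern_params <- function(r = 2.6) preset_params("pattern", r = r)

upper_eq <- function(params = pattern_params()) {
  equilibrium_branch(params, "upper")
}

# random parameter draw; optionally resampled until a positive equilibrium
# with two branches exists
random_params <- function(positive_eq = FALSE, diffusive = FALSE) {
  repeat {
    p <- model_params(r = runif(1, 0.5, 5), K = runif(1, 0.2, 2),
                      beta = runif(1, 0.2, 2), mu1 = runif(1, 0.01, 1),
                      mu2 = runif(1, 0.01, 0.5), mu3 = runif(1, 0.05, 1),
                      alpha = runif(1, 0.01, 0.5),
                      d1 = if (diffusive) runif(1, 0.5, 12) else runif(1, 0.01, 1),
                      d2 = runif(1, 0.01, 1), d3 = runif(1, 0.01, 1))
    if (!positive_eq) return(p)
    if (length(solve_equilibria(p)) == 2L) return(p)
  }
}

# random connected graph on n nodes: random spanning tree plus extra edges
random_connected_adj <- function(n, extra = n) {
  perm <- sample(n) - 1L
  tree <- cbind(perm[2:n], perm[sapply(2:n, function(i) sample(i - 1L, 1L))])
  all_pairs <- t(combn(n, 2)) - 1L
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  avail <- all_pairs[!key(all_pairs) %in% key(tree), , drop = FALSE]
  extra <- min(extra, nrow(avail))
  edges <- rbind(tree, avail[sample(nrow(avail), extra), , drop = FALSE])
  adjacency_spec(n, edges)
}

# the central simulation fixture: Turing pattern on the 16x16 torus with the
# baseline parameter set, shared across dynamics/spectral tests
turing_fixture_small <- function() {
  fixture("turing_small", function() {
    p <- pattern_params()
    eq <- upper_eq(p)
    net <- build_lattice(16, 16, 4)
    init <- perturbed_equilibrium_init(eq, net$n, 0.01, seed = 7L)
    traj <- integrate_network(net, p, init, dt = 0.005, t_end = 8000,
                              stride = 20000L, stop_at_steady = TRUE,
                              steady_tol = 1e-8)
    list(params = p, eq = eq, net = net, init = init, traj = traj,
         final = final_state(traj))
  })
}

# greedy multiset matching distance between two complex spectra
spectrum_match_error <- function(a, b) {
  if (length(a) != length(b)) return(Inf)
  worst <- 0
  for (z in a) {
    i <- which.min(Mod(b - z))
    worst <- max(worst, Mod(b[i] - z))
    b <- b[-i]
  }
  worst
}
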