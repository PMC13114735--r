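#' @importFrom stats runif rnorm sd quantile
#' @importFrom utils head tail
NULL

PERMISSION_TOKENS <- c("S", "I", "R", "SI", "SR", "IR", "SIR")

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Adjacency specification for an unweighted simple graph
#'
#' @param n_nodes number of nodes.
#' @param edges two-column matrix of 0-based node indices, one row per
#'   undirected edge; self-loops and duplicates are rejected.
#' @return An `adjacency_spec` object with edges stored canonically
#'   (u < v, sorted).
#' @export
adjacency_spec <- function(n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L)
    stop("adjacency_spec: n_nodes must be a positive integer", call. = FALSE)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (any(is.na(edges)) || any(edges < 0L) || any(edges >= n_nodes))
    stop("adjacency_spec: edge indices must lie in [0, n_nodes)", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L]))
    stop("adjacency_spec: self-loops are not allowed", call. = FALSE)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(edges))
    stop("adjacency_spec: duplicate edges are not allowed", call. = FALSE)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(list(n_nodes = n_nodes, edges = edges), class = "adjacency_spec")
}

adjacency_matrix <- function(adj) {
  Ahat <- matrix(0, adj$n_nodes, adj$n_nodes)
  if (nrow(adj$edges)) {
    Ahat[adj$edges + 1L] <- 1
    Ahat[adj$edges[, 2:1, drop = FALSE] + 1L] <- 1
  }
  Ahat
}

#' Graph Laplacian under the semi-negative-definite convention
#'
#' Returns the adjacency matrix minus the degree diagonal, \eqn{\hat A -
#' \mathrm{Diag}(\sigma)}.  Under this sign convention the Laplacian is
#' symmetric with zero row sums and non-positive eigenvalues, so its
#' eigenvalues play the role of \eqn{-k^2} wavenumbers in the dispersion
#' analysis.
#'
#' @param adj an [adjacency_spec].
#' @return A dense symmetric `n x n` matrix.
#' @export
laplacian_from_adjacency <- function(adj) {
  if (!inherits(adj, "adjacency_spec"))
    adj <- adjacency_spec(adj$n_nodes, adj$edges)
  Ahat <- adjacency_matrix(adj)
  Ahat - diag(rowSums(Ahat), nrow = adj$n_nodes)
}

new_layered_network <- function(n, A, B, C, edges, tokens, kind = "custom") {
  structure(list(n = n, A = A, B = B, C = C,
                 edges = edges, tokens = tokens, kind = kind),
            class = "layered_network")
}

#' Homogeneous layered network from an adjacency specification
#'
#' All three compartments diffuse on the same topology (A = B = C), i.e.
#' every edge carries the full `SIR` permission.
#'
#' @param adj an [adjacency_spec].
#' @param kind free-text label describing the topology.
#' @return A `layered_network`.
#' @export
homogeneous_network <- function(adj, kind = "custom") {
  L <- laplacian_from_adjacency(adj)
  new_layered_network(adj$n_nodes, L, L, L, adj$edges,
                      rep("SIR", nrow(adj$edges)), kind)
}

#' Is a layered network homogeneous (A = B = C)?
#' @param net a `layered_network`.
#' @export
is_homogeneous <- function(net) {
  identical(net$A, net$B) && identical(net$B, net$C)
}

#' Per-node degrees of each layer
#' @param net a `layered_network`.
#' @return A list with components `S`, `I`, `R` of per-node integer degrees.
#' @export
layer_degrees <- function(net) {
  list(S = -diag(net$A), I = -diag(net$B), R = -diag(net$C))
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("layered_network (%s): %d nodes, %d edges, %s\n",
              x$kind, x$n, nrow(x$edges),
              if (is_homogeneous(x)) "homogeneous (A=B=C)"
              else "heterogeneous three-layer"))
  invisible(x)
}

lattice_offsets <- function(degree) {
  switch(as.character(degree),
    "4" = rbind(c(1, 0), c(0, 1)),
    "6" = rbind(c(1, 0), c(0, 1), c(1, 1)),
    "8" = rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1)),
    stop("degree must be 4, 6 or 8", call. = FALSE))
}

#' Build a regular lattice network
#'
#' Quadrilateral (degree 4, von-Neumann neighborhood), hexagonal-type
#' (degree 6: von-Neumann plus the (+1,+1) diagonal pair) and octagonal
#' (degree 8, Moore neighborhood) lattices.  With `boundary = "periodic"`
#' the lattice is a torus and every node has exactly the nominal degree.
#'
#' @param rows,cols lattice dimensions (each at least 3 when periodic).
#' @param degree nominal node degree: 4, 6 or 8.
#' @param boundary `"periodic"` (default) or `"open"`.
#' @return A homogeneous `layered_network` (A = B = C).
#' @export
build_lattice <- function(rows, cols, degree = 4,
                          boundary = c("periodic", "open")) {
  boundary <- match.arg(boundary)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (boundary == "periodic" && (rows < 3L || cols < 3L))
    stop("periodic lattices need rows >= 3 and cols >= 3", call. = FALSE)
  if (rows < 1L || cols < 1L) stop("rows and cols must be positive",
                                   call. = FALSE)
  off <- lattice_offsets(degree)
  idx <- function(i, j) i * cols + j  # 0-based row-major
  eu <- integer(0); ev <- integer(0)
  for (k in seq_len(nrow(off))) {
    di <- off[k, 1L]; dj <- off[k, 2L]
    for (i in 0:(rows - 1L)) for (j in 0:(cols - 1L)) {
      i2 <- i + di; j2 <- j + dj
      if (boundary == "periodic") {
        i2 <- i2 %% rows; j2 <- j2 %% cols
      } else if (i2 < 0L || i2 >= rows || j2 < 0L || j2 >= cols) next
      eu <- c(eu, idx(i, j)); ev <- c(ev, idx(i2, j2))
    }
  }
  adj <- adjacency_spec(rows * cols, cbind(eu, ev))
  homogeneous_network(adj, sprintf("%s lattice %dx%d deg%d",
                                   boundary, rows, cols, degree))
}

#' Closed-form torus spectrum of the periodic degree-4 lattice
#'
#' Eigenvalues of the quadrilateral torus Laplacian under the
#' semi-negative-definite convention:
#' \eqn{-(4 - 2\cos(2\pi k/rows) - 2\cos(2\pi l/cols))}.
#'
#' @param rows,cols torus dimensions.
#' @return Sorted (decreasing) vector of `rows * cols` eigenvalues.
#' @export
torus_spectrum_ql <- function(rows, cols) {
  k <- 0:(rows - 1L); l <- 0:(cols - 1L)
  ev <- -(4 - 2 * cos(2 * pi * outer(k, rep(1, cols)) / rows)
            - 2 * cos(2 * pi * outer(rep(1, rows), l) / cols))
  sort(as.vector(ev), decreasing = TRUE)
}

graph_to_adjacency_spec <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  adjacency_spec(igraph::vcount(g), el)
}

warn_if_disconnected <- function(adj, what) {
  g <- igraph::graph_from_edgelist(adj$edges + 1L, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, adj$n_nodes - igraph::vcount(g)))
  nc <- igraph::count_components(g)
  if (nc > 1L)
    warning(sprintf(paste0("%s graph is disconnected (%d components; the ",
                           "Laplacian has %d zero eigenvalues)"),
                    what, nc, nc), call. = FALSE)
  invisible(nc)
}

#' Build an Erdos-Renyi G(n, p) random network
#'
#' Each of the `choose(n, 2)` node pairs is an edge independently with
#' probability `p`.  A disconnected draw is allowed but triggers a warning
#' reporting the component count (equal to the number of zero Laplacian
#' eigenvalues).
#'
#' @param n number of nodes.
#' @param p edge probability.
#' @param seed integer seed; draws are reproducible.
#' @return A homogeneous `layered_network`.
#' @export
build_er <- function(n, p, seed) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  g <- with_seed(seed, igraph::sample_gnp(n, p))
  adj <- graph_to_adjacency_spec(g)
  warn_if_disconnected(adj, "ER")
  homogeneous_network(adj, sprintf("ER n=%d p=%g", n, p))
}

#' Build a Barabasi-Albert scale-free network
#'
#' Preferential-attachment growth from an initial clique of `m` nodes
#' (m0 = m); each subsequently added node attaches `m` edges to existing
#' nodes with probability proportional to their degree.  Total edge count
#' is therefore `choose(m, 2) + (n - m) * m`.
#'
#' @param n final number of nodes.
#' @param m edges added per new node, `1 <= m < n`.
#' @param seed integer seed.
#' @return A homogeneous `layered_network`.
#' @export
build_ba <- function(n, m, seed) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L || m >= n) stop("build_ba requires 1 <= m < n", call. = FALSE)
  g <- with_seed(seed, igraph::sample_pa(n, power = 1, m = m,
                                         directed = FALSE,
                                         start.graph = igraph::make_full_graph(m)))
  g <- igraph::simplify(g)
  adj <- graph_to_adjacency_spec(g)
  homogeneous_network(adj, sprintf("BA n=%d m=%d", n, m))
}

#' Assign per-edge compartment permissions
#'
#' Every edge receives exactly one non-empty subset of \{S, I, R\} naming the
#' compartments allowed to diffuse along it (the seven classes correspond to
#' the edge colors red=S, green=I, blue=R, yellow=SI, magenta=SR, cyan=IR,
#' black=SIR).
#'
#' @param adj an [adjacency_spec] (or `layered_network`, whose edge set is
#'   used).
#' @param scheme `"uniform7"` (each class equally likely) or `"fractions"`.
#' @param fractions named numeric vector over the tokens
#'   `c("S","I","R","SI","SR","IR","SIR")` summing to 1 (only for
#'   `scheme = "fractions"`; omitted tokens get probability 0).
#' @param seed integer seed.
#' @return Character vector of permission tokens, one per edge, in the
#'   canonical edge order of `adj`.
#' @export
assign_edge_permissions <- function(adj, scheme = c("uniform7", "fractions"),
                                    fractions = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (inherits(adj, "layered_network"))
    adj <- adjacency_spec(adj$n, adj$edges)
  ne <- nrow(adj$edges)
  prob <- if (scheme == "uniform7") {
    rep(1 / 7, 7)
  } else {
    if (is.null(fractions) || is.null(names(fractions)))
      stop("scheme='fractions' needs a named 'fractions' vector", call. = FALSE)
    bad <- setdiff(names(fractions), PERMISSION_TOKENS)
    if (length(bad))
      stop("unknown permission token(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (abs(sum(fractions) - 1) > 1e-9)
      stop("fractions must sum to 1", call. = FALSE)
    p <- setNames(rep(0, 7), PERMISSION_TOKENS)
    p[names(fractions)] <- fractions
    p
  }
  with_seed(seed, sample(PERMISSION_TOKENS, ne, replace = TRUE, prob = prob))
}

#' Decompose a permission-labeled network into three compartment layers
#'
#' Layer A (for S) contains an edge iff S is in the edge's permission set;
#' likewise B for I and C for R.  Each layer's Laplacian is built under the
#' semi-negative-definite convention.
#'
#' @param adj an [adjacency_spec].
#' @param permissions character vector of permission tokens, one per edge of
#'   `adj` in canonical order.
#' @return A `layered_network` with per-compartment Laplacians A, B, C.
#' @export
decompose_layers <- function(adj, permissions) {
  if (!inherits(adj, "adjacency_spec"))
    stop("decompose_layers expects an adjacency_spec", call. = FALSE)
  ne <- nrow(adj$edges)
  if (length(permissions) != ne)
    stop("need exactly one permission token per edge (", ne, " edges, ",
         length(permissions), " tokens)", call. = FALSE)
  bad <- setdiff(unique(permissions), PERMISSION_TOKENS)
  if (length(bad))
    stop("unknown permission token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  layer_lap <- function(letter) {
    keep <- grepl(letter, permissions, fixed = TRUE)
    sub <- adjacency_spec(adj$n_nodes,
                          adj$edges[keep, , drop = FALSE])
    laplacian_from_adjacency(sub)
  }
  new_layered_network(adj$n_nodes, layer_lap("S"), layer_lap("I"),
                      layer_lap("R"), adj$edges, permissions,
                      "heterogeneous")
}

#' Write / read a permission-labeled edge list
#'
#' Tab-separated text with three columns: 0-based node indices `u`, `v` and
#' a permission token from `{S, I, R, SI, SR, IR, SIR}`.  Lines starting
#' with `#` are comments; the node count is carried in a `# n_nodes:`
#' comment so that isolated nodes survive the round trip.
#'
#' @param net a `layered_network`.
#' @param path file path.
#' @return `load_edge_list` returns a `layered_network` rebuilt via
#'   [decompose_layers]; `save_edge_list` returns `path` invisibly.
#' @export
save_edge_list <- function(net, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# rumornet edge list",
               sprintf("# n_nodes: %d", net$n)), con)
  if (nrow(net$edges))
    writeLines(sprintf("%d\t%d\t%s", net$edges[, 1L], net$edges[, 2L],
                       net$tokens), con)
  invisible(path)
}

#' @rdname save_edge_list
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  n_nodes <- NA_integer_
  hdr <- grep("^#\\s*n_nodes:", lines, value = TRUE)
  if (length(hdr))
    n_nodes <- as.integer(sub("^#\\s*n_nodes:\\s*", "", hdr[1L]))
  keep <- which(!grepl("^\\s*(#|$)", lines))
  u <- integer(0); v <- integer(0); tok <- character(0)
  for (ln in keep) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop(sprintf("line %d: expected 3 tab-separated fields", ln),
           call. = FALSE)
    ui <- suppressWarnings(as.integer(parts[1L]))
    vi <- suppressWarnings(as.integer(parts[2L]))
    if (is.na(ui) || is.na(vi))
      stop(sprintf("line %d: non-integer node index", ln), call. = FALSE)
    if (!parts[3L] %in% PERMISSION_TOKENS)
      stop(sprintf("line %d: unknown permission token '%s'", ln, parts[3L]),
           call. = FALSE)
    u <- c(u, ui); v <- c(v, vi); tok <- c(tok, parts[3L])
  }
  key <- paste(pmin(u, v), pmax(u, v))
  if (anyDuplicated(key)) {
    ln <- keep[which(duplicated(key))[1L]]
    stop(sprintf("line %d: duplicate edge", ln), call. = FALSE)
  }
  if (is.na(n_nodes)) n_nodes <- if (length(u)) max(u, v) + 1L else 0L
  adj <- adjacency_spec(n_nodes, cbind(u, v))
  # restore canonical edge order for the tokens
  ord <- order(pmin(u, v), pmax(u, v))
  decompose_layers(adj, tok[ord])
}
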