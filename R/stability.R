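#' Hurwitz-derived stability condition H1 for the homogeneous equilibrium
#'
#' At a positive equilibrium the characteristic cubic factors as
#' \eqn{(\lambda + \mu_3)(\lambda^2 - T\lambda + D)} with
#' \eqn{T = \mu_2 + \alpha - rS^*/K} and
#' \eqn{D = (\mu_2+\alpha)(2r - 3rS^*/K - 2\mu_1)}, so all roots have
#' negative real part iff \eqn{T < 0} and \eqn{D > 0}.  Both strict
#' inequalities are itemized with their margins.
#'
#' @param eq an `equilibrium_point`.
#' @param params a [model_params] consistent with `eq`.
#' @return A list: `holds` (logical), `margin1` = \eqn{\mu_2+\alpha -
#'   rS^*/K} (must be < 0), `margin2` = \eqn{2r - 3rS^*/K - 2\mu_1} (must
#'   be > 0).
#' @export
h1_check <- function(eq, params) {
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  m1 <- p$mu2 + p$alpha - p$r * eq$S_star / p$K
  m2 <- 2 * p$r - 3 * p$r * eq$S_star / p$K - 2 * p$mu1
  list(holds = (m1 < 0) && (m2 > 0), margin1 = m1, margin2 = m2)
}

#' Full Routh-Hurwitz test for a cubic
#'
#' Independent stability oracle: all roots of
#' \eqn{\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3} have negative real
#' part iff \eqn{a_1 > 0}, \eqn{a_3 > 0} and \eqn{a_1 a_2 - a_3 > 0}.
#'
#' @param cp a `char_poly` or numeric vector `c(a1, a2, a3)`.
#' @return Logical.
#' @export
routh_hurwitz_oracle <- function(cp) {
  a <- unclass(cp)
  a[1] > 0 && a[3] > 0 && a[1] * a[2] - a[3] > 0
}

#' Dispersion-relation coefficients u and v at a Laplacian eigenvalue
#'
#' For a homogeneous network, perturbations along the Laplacian eigenvector
#' with eigenvalue \eqn{\eta \le 0} grow according to
#' \eqn{\lambda^2 + u(\eta)\lambda + v(\eta) = 0}.  Both the raw forms
#' (built from the unsimplified Jacobian entries) and the simplified forms
#' (using the steady-state identities) are computed; at a true equilibrium
#' they agree to rounding.
#'
#' @param eq an `equilibrium_point`.
#' @param params a [model_params].
#' @param eta non-positive Laplacian eigenvalue(s); vectorized.
#' @param form `"simplified"` (default), `"raw"`, or `"both"`.
#' @return For `"both"`, a list of data frames; otherwise a data frame with
#'   columns `eta`, `u`, `v`.
#' @export
dispersion_uv <- function(eq, params, eta,
                          form = c("simplified", "raw", "both")) {
  form <- match.arg(form)
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  if (any(eta > 1e-12))
    stop("dispersion_uv: eta must be non-positive", call. = FALSE)
  S <- eq$S_star; I <- eq$I_star
  simp <- function() {
    u <- -(p$d1 + p$d2) * eta + p$r * S / p$K - p$mu2 - p$alpha
    v <- p$d1 * p$d2 * eta^2 +
      (p$d1 * (p$mu2 + p$alpha) - p$d2 * p$r * S / p$K) * eta +
      (p$mu2 + p$alpha) * (2 * p$r - 3 * p$r * S / p$K - 2 * p$mu1)
    data.frame(eta = eta, u = u, v = v)
  }
  raw <- function() {
    j11 <- p$d1 * eta + p$r - 2 * p$r * S / p$K - p$mu1 - p$beta * I^2
    j22 <- p$d2 * eta + p$mu2 + p$alpha
    u <- -(j11 + j22)
    v <- j11 * j22 + 2 * (p$mu2 + p$alpha) * p$beta * I^2
    data.frame(eta = eta, u = u, v = v)
  }
  switch(form, simplified = simp(), raw = raw(),
         both = list(simplified = simp(), raw = raw()))
}

#' Turing interval for homogeneous networks
#'
#' Evaluates the four-inequality necessary condition for Turing instability
#' on a homogeneous network and, when all hold, the two real roots
#' \eqn{\eta_1^* \le \eta_2^* \le 0} of the mode polynomial
#' \eqn{g(\eta) = d_1 d_2 \eta^2 + (d_1(\mu_2+\alpha) - d_2 rS^*/K)\eta +
#' (\mu_2+\alpha)(2r - 3rS^*/K - 2\mu_1)}: Laplacian eigenvalues strictly
#' inside \eqn{(\eta_1^*, \eta_2^*)} give \eqn{v(\eta) < 0} and hence a
#' growing spatial mode.
#'
#' @inheritParams h1_check
#' @return A list: `interval` (`c(eta1_star, eta2_star)` or `NULL`),
#'   `g_coeffs`, `conditions` (named logical vector itemizing the four
#'   inequalities) and `values` (their left-hand sides).
#' @export
turing_interval <- function(eq, params) {
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  S <- eq$S_star
  rSK <- p$r * S / p$K
  m2a <- p$mu2 + p$alpha
  base <- 2 * p$r - 3 * rSK - 2 * p$mu1
  gA <- p$d1 * p$d2
  gB <- p$d1 * m2a - p$d2 * rSK
  gC <- m2a * base
  disc <- gB^2 - 4 * gA * gC
  vals <- c(cross = m2a - rSK, slope = gB, discriminant = disc, base = base)
  conds <- c(cross = vals[["cross"]] < 0, slope = gB > 0,
             discriminant = disc > 0, base = base > 0)
  interval <- NULL
  if (all(conds)) {
    s <- sqrt(disc)
    interval <- c(eta1_star = (-gB - s) / (2 * gA),
                  eta2_star = (-gB + s) / (2 * gA))
  }
  list(interval = interval, g_coeffs = c(gA = gA, gB = gB, gC = gC),
       conditions = conds, values = vals)
}

#' Turing diagnosis of a homogeneous network
#'
#' Intersects the Turing interval with the network's Laplacian spectrum:
#' the network supports Turing instability iff H1 holds, the interval
#' exists, and at least one eigenvalue lies strictly inside it.
#'
#' @param net a homogeneous `layered_network` (A = B = C).
#' @inheritParams h1_check
#' @return A list of class `dispersion_result` with the equilibrium branch,
#'   the spectrum `eta`, per-mode `u`, `v` and `g` values, the interval,
#'   `unstable_modes` (indices into the sorted spectrum) and
#'   `turing_capable`.
#' @export
homogeneous_turing_report <- function(net, eq, params) {
  if (!is_homogeneous(net))
    stop("network is heterogeneous; use hetero_necessary_report()",
         call. = FALSE)
  p <- as_model_params(params)
  ti <- turing_interval(eq, p)
  h1 <- h1_check(eq, p)
  eta <- eigen(net$C, symmetric = TRUE, only.values = TRUE)$values
  eta <- sort(eta, decreasing = TRUE)
  uv <- dispersion_uv(eq, p, pmin(eta, 0))
  g <- uv$v  # for A=B=C, g(eta) is exactly the v coefficient
  unstable <- if (is.null(ti$interval)) integer(0) else
    which(eta > ti$interval[1L] & eta < ti$interval[2L])
  structure(list(branch = eq$branch, eta = eta, u = uv$u, v = uv$v, g = g,
                 interval = ti$interval, conditions = ti$conditions,
                 h1 = h1, unstable_modes = unstable,
                 turing_capable = h1$holds && !is.null(ti$interval) &&
                   length(unstable) > 0L),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion analysis (%s branch): H1 %s; interval %s; %d unstable mode(s); Turing-capable: %s\n",
              x$branch, ifelse(x$h1$holds, "holds", "fails"),
              if (is.null(x$interval)) "none" else
                sprintf("(%.4f, %.4f)", x$interval[1L], x$interval[2L]),
              length(x$unstable_modes), x$turing_capable))
  invisible(x)
}

# spectra of the three layers, symmetric solver, sorted decreasing
layer_spectra <- function(net, vectors = FALSE) {
  dec <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    ord <- order(e$values, decreasing = TRUE)
    list(values = e$values[ord],
         vectors = if (vectors) e$vectors[, ord, drop = FALSE])
  }
  list(theta = dec(net$A), delta = dec(net$B), eta = dec(net$C))
}

#' Spectral bound on the full Jacobian
#'
#' Computes the norm bound \eqn{\varphi \ge \rho(J)} on the spectral radius
#' of the full 3N x 3N Jacobian: the 2-norm of the block-diagonal diffusion
#' part (max over layers and modes of the absolute diagonal entries) plus
#' the 2-norm of the constant off-diagonal reaction block, which equals
#' \eqn{\max\{\beta I^{*2}, \sqrt{4(\mu_2+\alpha)^2 + \alpha^2}\}}.  The
#' no-radical reading \eqn{\max\{\beta I^{*2}, 4(\mu_2+\alpha)^2 +
#' \alpha^2\}} of the off-diagonal term is reported alongside for
#' comparison.
#'
#' @param net a `layered_network`.
#' @inheritParams h1_check
#' @return A list: `phi` (the bound), `diag_norm`, `offdiag_norm`, and
#'   `phi_noradical`.
#' @export
phi_bound <- function(net, eq, params) {
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  S <- eq$S_star; I <- eq$I_star
  sp <- layer_spectra(net)
  j11raw <- p$r - 2 * p$r * S / p$K - p$mu1 - p$beta * I^2
  diag_norm <- max(abs(p$d1 * sp$theta$values + j11raw),
                   abs(p$d2 * sp$delta$values + p$mu2 + p$alpha),
                   abs(p$mu3 - p$d3 * sp$eta$values))
  off_sqrt <- max(p$beta * I^2,
                  sqrt(4 * (p$mu2 + p$alpha)^2 + p$alpha^2))
  off_nosqrt <- max(p$beta * I^2, 4 * (p$mu2 + p$alpha)^2 + p$alpha^2)
  list(phi = diag_norm + off_sqrt,
       diag_norm = diag_norm, offdiag_norm = off_sqrt,
       phi_noradical = diag_norm + off_nosqrt)
}

#' Necessary conditions H2/H3 for Turing instability on heterogeneous networks
#'
#' Perturbations on a three-layer network cannot be expanded in a single
#' Laplacian eigenbasis, so instability is constrained through the spectral
#' bound \eqn{\varphi} instead.  For every eigenvalue \eqn{\theta_m} of the
#' S-layer Laplacian the report computes
#' \eqn{q = d_1\theta_m + r - 2rS^*/K - \mu_1 - \beta I^{*2}},
#' \eqn{b_1(\theta_m) = -2(\mu_2+\alpha)(d_1\theta_m + r - 2rS^*/K - \mu_1)}
#' and \eqn{b_2(\theta_m) = (\mu_2+\alpha)(\varphi^2 - (d_1\theta_m -
#' rS^*/K)(d_1\theta_m + 2r - 3rS^*/K - 2\mu_1))}.  With the two base
#' inequalities \eqn{\mu_2+\alpha - rS^*/K < 0} and \eqn{2r - 3rS^*/K -
#' 2\mu_1 > 0}, condition H2 additionally requires a mode with
#' \eqn{b_1(\theta_m) > 0} (i.e. \eqn{d_1\theta_m + r - 2rS^*/K - \mu_1 >
#' 0}); condition H3 covers the complementary branch, a mode with
#' \eqn{b_1(\theta_m) < 0} and \eqn{b_2(\theta_m) > 0}.  These are
#' necessary, not sufficient, conditions.
#'
#' @param net a `layered_network`.
#' @inheritParams h1_check
#' @return A list of class `hetero_condition_report`: `phi`, per-mode data
#'   frame `modes` (`theta`, `q`, `b1`, `b2`), `base` (the two shared
#'   inequalities with margins), `H2_holds`, `H3_holds` and the witnessing
#'   mode indices `H2_witness`, `H3_witness`.
#' @export
hetero_necessary_report <- function(net, eq, params) {
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  S <- eq$S_star; I <- eq$I_star
  phi <- phi_bound(net, eq, p)
  theta <- sort(eigen(net$A, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
  rSK <- p$r * S / p$K
  m2a <- p$mu2 + p$alpha
  q <- p$d1 * theta + p$r - 2 * rSK - p$mu1 - p$beta * I^2
  lin <- p$d1 * theta + p$r - 2 * rSK - p$mu1  # b1 sign carrier
  b1 <- -2 * m2a * lin
  b2 <- m2a * (phi$phi^2 -
    (p$d1 * theta - rSK) * (p$d1 * theta + 2 * p$r - 3 * rSK - 2 * p$mu1))
  base1 <- m2a - rSK
  base2 <- 2 * p$r - 3 * rSK - 2 * p$mu1
  base_ok <- base1 < 0 && base2 > 0
  w2 <- which(lin > 0)
  w3 <- which(lin < 0 & b2 > 0)
  structure(list(phi = phi$phi, phi_noradical = phi$phi_noradical,
                 modes = data.frame(theta = theta, q = q, b1 = b1, b2 = b2),
                 base = c(cross = base1, base = base2),
                 base_holds = base_ok,
                 H2_holds = base_ok && length(w2) > 0L,
                 H3_holds = base_ok && length(w3) > 0L,
                 H2_witness = w2, H3_witness = w3),
            class = "hetero_condition_report")
}

#' @export
print.hetero_condition_report <- function(x, ...) {
  cat(sprintf("heterogeneous-network necessary conditions: phi=%.4f; base %s; H2 %s; H3 %s\n",
              x$phi, ifelse(x$base_holds, "holds", "fails"),
              ifelse(x$H2_holds, "holds", "fails"),
              ifelse(x$H3_holds, "holds", "fails")))
  invisible(x)
}

#' Assemble and diagonalize the full 3N x 3N Jacobian
#'
#' Ground-truth oracle for the reduced criteria: builds the block Jacobian
#' \deqn{J = \begin{pmatrix} d_1 A + J_{11} E & -2(\mu_2+\alpha)E & 0 \\
#' \beta I^{*2} E & d_2 B + (\mu_2+\alpha)E & 0 \\
#' 0 & \alpha E & d_3 C - \mu_3 E \end{pmatrix}}
#' with \eqn{J_{11} = r - 2rS^*/K - \mu_1 - \beta I^{*2}} and returns its
#' eigenvalues from a dense general solver.
#'
#' @param net a `layered_network` with `N` nodes.
#' @inheritParams h1_check
#' @param max_n dense-solve size cap on N.
#' @return Complex eigenvalue vector of length 3N.
#' @export
full_jacobian_spectrum <- function(net, eq, params, max_n = 2000L) {
  if (net$n > max_n)
    stop("N = ", net$n, " exceeds the dense-solve cap (", max_n,
         "); reduce the network or raise max_n", call. = FALSE)
  eigen(full_jacobian(net, eq, params), only.values = TRUE)$values
}

full_jacobian <- function(net, eq, params) {
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  S <- eq$S_star; I <- eq$I_star
  N <- net$n
  E <- diag(N)
  j11 <- p$r - 2 * p$r * S / p$K - p$mu1 - p$beta * I^2
  Z <- matrix(0, N, N)
  rbind(cbind(p$d1 * net$A + j11 * E, -2 * (p$mu2 + p$alpha) * E, Z),
        cbind(p$beta * I^2 * E, p$d2 * net$B + (p$mu2 + p$alpha) * E, Z),
        cbind(Z, p$alpha * E, p$d3 * net$C - p$mu3 * E))
}
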