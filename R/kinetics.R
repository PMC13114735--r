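#' Reaction terms of the rumor model
#'
#' Evaluates the kinetic right-hand side (no diffusion):
#' \eqn{dS = rS(1-S/K) - \beta S I^2 - \mu_1 S},
#' \eqn{dI = \beta S I^2 - \mu_2 I - \alpha I},
#' \eqn{dR = \alpha I - \mu_3 R}.  Vectorized over node states.
#'
#' @param S,I,R non-negative densities (scalars or equal-length vectors).
#' @param params a [model_params].
#' @return A list with components `dS`, `dI`, `dR`.
#' @export
reaction_rates <- function(S, I, R, params) {
  p <- as_model_params(params)
  if (any(S < 0) || any(I < 0) || any(R < 0))
    stop("reaction_rates: densities must be non-negative", call. = FALSE)
  list(dS = p$r * S * (1 - S / p$K) - p$beta * S * I^2 - p$mu1 * S,
       dI = p$beta * S * I^2 - p$mu2 * I - p$alpha * I,
       dR = p$alpha * I - p$mu3 * R)
}

#' Coefficients of the equilibrium cubic
#'
#' Eliminating S and R from the steady-state equations
#' (\eqn{S = (\mu_2+\alpha)/(\beta I)}, then multiplying the S-equation by
#' \eqn{K\beta I / S}) gives the cubic in spreader density
#' \eqn{f(I) = K\beta^2 I^3 + K\beta(\mu_1 - r) I + r(\mu_2+\alpha)};
#' its quadratic coefficient is identically zero, so the three roots always
#' sum to zero, and \eqn{\mu_1 \ge r} makes the linear coefficient
#' non-negative, precluding positive roots.
#'
#' @param params a [model_params].
#' @return Named vector `c(c3, c1, c0)` with `f(I) = c3 I^3 + c1 I + c0`.
#' @export
equilibrium_cubic_coeffs <- function(params) {
  p <- as_model_params(params)
  c(c3 = p$K * p$beta^2,
    c1 = p$K * p$beta * (p$mu1 - p$r),
    c0 = p$r * (p$mu2 + p$alpha))
}

# real roots of the depressed cubic t^3 + p t + q = 0 (closed form)
depressed_cubic_roots <- function(p, q) {
  disc <- -4 * p^3 - 27 * q^2
  if (disc > 0) {
    # three distinct real roots: trigonometric form (p < 0 here)
    m <- 2 * sqrt(-p / 3)
    theta <- acos(max(-1, min(1, 3 * q / (p * m))))
    m * cos(theta / 3 - 2 * pi * (0:2) / 3)
  } else {
    # one real root (or a repeated pair): Cardano
    s <- sqrt(max(0, q^2 / 4 + p^3 / 27))
    u <- cbrt(-q / 2 + s); v <- cbrt(-q / 2 - s)
    r1 <- u + v
    if (abs(disc) < 1e-12 * max(1, p^2)) {
      # tangency: double root at -r1/2
      c(r1, -r1 / 2, -r1 / 2)
    } else r1
  }
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Positive equilibria of the rumor model
#'
#' Solves the equilibrium cubic in closed (depressed-cubic) form with a
#' Newton polish, back-substitutes \eqn{S^* = (\mu_2+\alpha)/(\beta I^*)}
#' and \eqn{R^* = \alpha I^*/\mu_3}, and labels the smaller/larger positive
#' root as the `lower`/`upper` branch.  Diagnostics follow the sign
#' analysis of the cubic: positive roots exist only when \eqn{\mu_1 < r}
#' and \eqn{f(I'') < 0}, where \eqn{I'' = \sqrt{(r - \mu_1)/(3\beta)}} is
#' the positive critical point of f; a tangency
#' (\eqn{f(I'') = 0}) yields one equilibrium flagged `degenerate`.
#'
#' @param params a [model_params].
#' @return A list of `equilibrium_point` objects (0, 1 or 2 entries), each
#'   with fields `S_star`, `I_star`, `R_star`, `branch`, `degenerate`, and
#'   diagnostics `I_prime`, `I_dblprime`, `f_at_I_dblprime`.
#' @export
solve_equilibria <- function(params) {
  p <- as_model_params(params)
  co <- equilibrium_cubic_coeffs(p)
  f <- function(I) co[["c3"]] * I^3 + co[["c1"]] * I + co[["c0"]]
  fp <- function(I) 3 * co[["c3"]] * I^2 + co[["c1"]]
  diag_I2 <- if (p$mu1 < p$r)
    sqrt(-co[["c1"]] / (3 * co[["c3"]])) else NA_real_
  diag_f <- if (is.na(diag_I2)) NA_real_ else f(diag_I2)
  if (p$mu1 >= p$r) return(structure(list(), diagnostics = list(
    I_prime = NA_real_, I_dblprime = NA_real_, f_at_I_dblprime = NA_real_)))

  degen <- abs(diag_f) < 1e-10 * max(1, abs(co[["c0"]]))
  no_roots <- structure(list(), diagnostics = list(
    I_prime = -diag_I2, I_dblprime = diag_I2, f_at_I_dblprime = diag_f))
  if (!degen && diag_f > 0) return(no_roots)
  mk <- function(I, branch) {
    structure(list(S_star = (p$mu2 + p$alpha) / (p$beta * I),
                   I_star = I,
                   R_star = p$alpha * I / p$mu3,
                   branch = branch, degenerate = degen,
                   I_prime = -diag_I2, I_dblprime = diag_I2,
                   f_at_I_dblprime = diag_f),
              class = "equilibrium_point")
  }
  if (degen) return(list(mk(diag_I2, "lower")))
  roots <- depressed_cubic_roots(co[["c1"]] / co[["c3"]],
                                 co[["c0"]] / co[["c3"]])
  for (k in 1:4) roots <- roots - f(roots) / fp(roots)  # Newton polish
  pos <- sort(roots[roots > 1e-12])
  if (length(pos) < 2L) return(no_roots)  # numerically borderline tangency
  list(mk(pos[1L], "lower"), mk(pos[length(pos)], "upper"))
}

#' Pick an equilibrium branch from the solver output
#' @param params a [model_params].
#' @param branch `"lower"` or `"upper"`.
#' @export
equilibrium_branch <- function(params, branch = c("upper", "lower")) {
  branch <- match.arg(branch)
  eqs <- solve_equilibria(params)
  for (e in eqs) if (e$branch == branch) return(e)
  stop("no positive equilibrium on the '", branch, "' branch for these ",
       "parameters", call. = FALSE)
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf("equilibrium (%s%s): S*=%.6g I*=%.6g R*=%.6g\n", x$branch,
              if (x$degenerate) ", degenerate" else "",
              x$S_star, x$I_star, x$R_star))
  invisible(x)
}

check_equilibrium <- function(eq, params, tol = 1e-8) {
  p <- as_model_params(params)
  co <- equilibrium_cubic_coeffs(p)
  resid <- co[["c3"]] * eq$I_star^3 + co[["c1"]] * eq$I_star + co[["c0"]]
  if (abs(resid) > tol * max(1, abs(co[["c0"]])))
    stop("equilibrium point is inconsistent with the parameters ",
         sprintf("(cubic residual %.3g)", resid), call. = FALSE)
  invisible(TRUE)
}

#' Local (3x3) Jacobian of the kinetics at an equilibrium
#'
#' Entries as derived from the reaction terms; at a true equilibrium the
#' (1,1) entry \eqn{r - 2rS^*/K - \mu_1 - \beta I^{*2}} simplifies to
#' \eqn{-rS^*/K} via the steady-state identity.
#'
#' @param eq an `equilibrium_point`.
#' @param params a [model_params] consistent with `eq`.
#' @return A 3x3 matrix (rows/cols ordered S, I, R).
#' @export
local_jacobian <- function(eq, params) {
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  S <- eq$S_star; I <- eq$I_star
  matrix(c(p$r - 2 * p$r * S / p$K - p$mu1 - p$beta * I^2,
           -2 * (p$mu2 + p$alpha), 0,
           p$beta * I^2, p$mu2 + p$alpha, 0,
           0, p$alpha, -p$mu3),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("S", "I", "R"), c("S", "I", "R")))
}

#' Characteristic-polynomial coefficients at an equilibrium
#'
#' Coefficients of \eqn{\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3}, the
#' characteristic equation of the local Jacobian, in the simplified form
#' obtained with the steady-state identities:
#' \eqn{a_1 = \mu_3 - \mu_2 - \alpha + rS^*/K},
#' \eqn{a_2 = (\mu_2+\alpha)(2r - \mu_3 - 2\mu_1 - 3rS^*/K) + \mu_3 rS^*/K},
#' \eqn{a_3 = \mu_3(\mu_2+\alpha)(2r - 2\mu_1 - 3rS^*/K)}.
#'
#' @inheritParams local_jacobian
#' @return An object of class `char_poly`: named vector `c(a1, a2, a3)`.
#' @export
char_poly_coeffs <- function(eq, params) {
  p <- as_model_params(params)
  check_equilibrium(eq, p)
  S <- eq$S_star
  a1 <- p$mu3 - p$mu2 - p$alpha + p$r * S / p$K
  a2 <- (p$mu2 + p$alpha) *
    (2 * p$r - p$mu3 - 2 * p$mu1 - 3 * p$r * S / p$K) +
    p$mu3 * p$r * S / p$K
  a3 <- p$mu3 * (p$mu2 + p$alpha) *
    (2 * p$r - 2 * p$mu1 - 3 * p$r * S / p$K)
  structure(c(a1 = a1, a2 = a2, a3 = a3), class = "char_poly")
}
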