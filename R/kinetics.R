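# Core kinetics: the three-species mass-action system, its exact steady
# state, and the two-dimensional fluctuation system with diffusion
# feedback.
#
# Full system (lumped form):
#   dX/dt = -D1*W*X + p*Z - k*X
#   dY/dt =  D1*W*X - D2*Y
#   dZ/dt =  D2*Y - p*Z + k*X
# The three rates sum to zero identically, so X + Y + Z = M is conserved.
# The attachment rate carries the oligomer concentration W explicitly:
# this is the only reading under which the closed-form steady state (the
# published simulation code's formulas, whose denominator contains D1*W)
# is the exact equilibrium of the rate field for every W.  All published
# parameter sets have W = 1, where the distinction disappears.
#
# Fluctuations (x, z) about the steady state, with y = -x - z, acquire
# quadratic terms from the concentration dependence of the diffusion
# coefficients.  Two published variants of the z-equation exist and both
# are supported:
#   fig2_code (default): dz/dt = k*x + c*x^2 + d*x*z - p*z
#   paper_eq:            dz/dt = (k - c*Ye)*x + c*x^2 + c*x*z - p*z
# The x-equation is common to both (W = 1 in all published sets):
#   dx/dt = (-D1*W + a*Xe - k)*x + a*x^2 + (p - b*Xe)*z - b*x*z
# (The printed linear coefficient with "+k" is a typographical slip; the
# Jacobian given alongside it and the simulation code agree on "-k".)

.variants <- c("fig2_code", "paper_eq")

check_variant <- function(variant) {
  if (!(is.character(variant) && length(variant) == 1L &&
        variant %in% .variants))
    stop("unknown model variant; use one of: ",
         paste(.variants, collapse = ", "), call. = FALSE)
  variant
}

#' Exact steady state of the assembly model
#'
#' Evaluates the closed-form equilibrium concentrations
#' \deqn{X_e = D_2 M p / q,\quad Y_e = D_1 M p W / q,\quad
#'       Z_e = D_2 M (k + D_1 W) / q,}
#' with the common denominator \eqn{q = D_2 k + D_2 p + D_1 D_2 W + D_1 p W}.
#' The three components sum to `M` as an algebraic identity.  (Printed
#' per-species forms of these formulas circulate with mutually
#' inconsistent denominators; the single common-denominator form used by
#' the published simulation code is canonical here.)
#'
#' @param params a `cmt_params` object
#' @return an object of class `cmt_steady`: named numeric `(Xe, Ye, Ze)`
#' @export
#' @examples
#' steady_state(preset_params("fig2_code", p = 0.01))
steady_state <- function(params) {
  stopifnot(inherits(params, "cmt_params"))
  den <- with(params, D2 * k + D2 * p + D1 * D2 * W + D1 * p * W)
  if (den <= 0)
    stop("degenerate model: all steady-state rate terms are zero",
         call. = FALSE)
  out <- with(params, c(Xe = D2 * M * p / den,
                        Ye = D1 * M * p * W / den,
                        Ze = D2 * M * (k + D1 * W) / den))
  structure(out, class = "cmt_steady", M = params$M)
}

#' @export
print.cmt_steady <- function(x, ...) {
  cat("Steady state (sums to M =", format(attr(x, "M")), ")\n")
  print(format(unclass(x), digits = 12), quote = FALSE)
  invisible(x)
}

#' Right-hand side of the full three-species system
#'
#' @param state numeric `(X, Y, Z)` concentrations
#' @param params a `cmt_params` object
#' @return numeric `(dX, dY, dZ)`; the components sum to zero exactly
#' @export
full_rhs <- function(state, params) {
  stopifnot(inherits(params, "cmt_params"), length(state) == 3L)
  X <- state[[1]]; Y <- state[[2]]; Z <- state[[3]]
  dX <- with(params, -D1 * W * X + p * Z - k * X)
  dY <- with(params, D1 * W * X - D2 * Y)
  # written so that the sum cancels term-by-term in floating point
  dZ <- -dX - dY
  c(dX = dX, dY = dY, dZ = dZ)
}

#' Right-hand side of the fluctuation system
#'
#' Rates of the fluctuations `(x, z)` about a steady state; the third
#' fluctuation is `y = -x - z` by conservation.
#'
#' @param state numeric `(x, z)`
#' @param params a `cmt_params` object
#' @param steady the steady state to perturb about; recomputed from
#'   `params` when `NULL`
#' @param variant `"fig2_code"` (default) or `"paper_eq"`; see the file
#'   header for the two published z-equations
#' @return numeric `(dx, dz)`
#' @export
fluct_rhs <- function(state, params, steady = NULL,
                      variant = c("fig2_code", "paper_eq")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "cmt_params"), length(state) == 2L)
  if (is.null(steady)) steady <- steady_state(params)
  x <- state[[1]]; z <- state[[2]]
  Xe <- steady[["Xe"]]; Ye <- steady[["Ye"]]
  dx <- with(params,
             (-D1 * W + a * Xe - k) * x + a * x^2 +
               (p - b * Xe) * z - b * x * z)
  dz <- if (variant == "fig2_code") {
    with(params, k * x + c * x^2 + d * x * z - p * z)
  } else {
    with(params, (k - c * Ye) * x + c * x^2 + c * x * z - p * z)
  }
  c(dx = dx, dz = dz)
}

#' Jacobian of the fluctuation system at the origin
#'
#' Closed-form linearization
#' \deqn{L = \begin{pmatrix} -D_1 W + a X_e - k & -b X_e + p \\
#'       k - c Y_e & -p \end{pmatrix}}
#' for the `paper_eq` variant; the `fig2_code` variant has `k` alone in
#' the (2,1) entry (its feedback enters only through quadratic terms).
#'
#' @inheritParams fluct_rhs
#' @return a 2x2 numeric matrix
#' @export
linearize <- function(params, steady = NULL,
                      variant = c("fig2_code", "paper_eq")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "cmt_params"))
  if (is.null(steady)) steady <- steady_state(params)
  Xe <- steady[["Xe"]]; Ye <- steady[["Ye"]]
  c21 <- if (variant == "fig2_code") params$k else params$k - params$c * Ye
  matrix(c(-params$D1 * params$W + params$a * Xe - params$k, c21,
           -params$b * Xe + params$p,            -params$p),
         nrow = 2, ncol = 2,
         dimnames = list(c("x", "z"), c("x", "z")))
}

# quadratic coefficients of the fluctuation system per variant:
# dx += qa*x^2 - qb*x*z ; dz += qc*x^2 + qd*x*z
fluct_quad_coefs <- function(params, variant) {
  check_variant(variant)
  list(qa = params$a, qb = params$b, qc = params$c,
       qd = if (variant == "fig2_code") params$d else params$c)
}
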