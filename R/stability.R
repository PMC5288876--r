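# Eigenvalue classification of the fluctuation Jacobian, the critical
# cofactor concentration p_c (root of det L(p) = 0 with the steady state
# recomputed at every trial p), and regime sweeps over p.

.regimes <- c("stable_node", "stable_spiral", "unstable_node",
              "unstable_spiral", "saddle", "center_degenerate")

#' Classify the stability regime at a given cofactor supply
#'
#' Recomputes the steady state at `params$p`, builds the 2x2 fluctuation
#' Jacobian, and classifies the origin by trace, determinant and
#' discriminant.  Eigenvalues come from the closed-form quadratic.
#'
#' Labels: `saddle` (det < 0), `stable_node` / `stable_spiral`
#' (det > 0, trace < 0, by discriminant sign), `unstable_node` /
#' `unstable_spiral` (det > 0, trace > 0), and `center_degenerate` when
#' the trace or the determinant vanishes to within `tol` (a zero or
#' purely imaginary eigenvalue; linearization alone cannot decide).
#'
#' @inheritParams fluct_rhs
#' @param tol magnitude below which trace or determinant counts as zero
#' @return an object of class `cmt_stability` with fields `p`, `jacobian`,
#'   `trace`, `det`, `discriminant`, `eigenvalues` (complex), `regime`,
#'   `variant`
#' @export
#' @examples
#' classify(preset_params("fig2_code", p = 0.01), variant = "paper_eq")
classify <- function(params, variant = c("fig2_code", "paper_eq"),
                     tol = 1e-14) {
  variant <- match.arg(variant)
  L <- linearize(params, variant = variant)
  tr <- L[1, 1] + L[2, 2]
  dt <- L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]
  disc <- tr^2 - 4 * dt
  ev <- if (disc >= 0) {
    complex(real = (tr + c(1, -1) * sqrt(disc)) / 2, imaginary = 0)
  } else {
    complex(real = tr / 2, imaginary = c(1, -1) * sqrt(-disc) / 2)
  }
  scale <- max(abs(L)) + tol
  regime <- if (abs(dt) <= tol * scale^2 || (disc < 0 && abs(tr) <= tol * scale)) {
    "center_degenerate"
  } else if (dt < 0) {
    "saddle"
  } else if (tr < 0) {
    if (disc < 0) "stable_spiral" else "stable_node"
  } else {
    if (disc < 0) "unstable_spiral" else "unstable_node"
  }
  structure(list(p = params$p, jacobian = L, trace = tr, det = dt,
                 discriminant = disc, eigenvalues = ev, regime = regime,
                 variant = variant),
            class = "cmt_stability")
}

#' @export
print.cmt_stability <- function(x, ...) {
  cat(sprintf("Stability at p = %s (%s variant): %s\n",
              format(x$p), x$variant, x$regime))
  cat(sprintf("  trace = %.6e  det = %.6e  disc = %.6e\n",
              x$trace, x$det, x$discriminant))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' Critical cofactor concentration p_c
#'
#' Solves `det L(p) = 0` for the cofactor supply by bisection, with the
#' steady state `Xe(p)`, `Ye(p)` recomputed at every trial `p` (the
#' Jacobian entries are functions of the steady state, which itself moves
#' with `p`; freezing it yields no root near the reported critical
#' value).  The `paper_eq` Jacobian is the default because the
#' determinant condition is stated with its `k - c*Ye` entry.
#'
#' @param params a `cmt_params` object; its `p` field is ignored
#' @param variant Jacobian variant, default `"paper_eq"`
#' @param bracket length-2 interval that must bracket a sign change of
#'   the determinant
#' @param tol absolute tolerance on `p_c`
#' @return an object of class `cmt_critical` with fields `p_c`, `bracket`,
#'   `residual` (|det| at `p_c`), `eigenvalues`, `iterations`, `variant`
#' @export
#' @examples
#' find_critical_p(preset_params("fig2_code"))
find_critical_p <- function(params, variant = c("paper_eq", "fig2_code"),
                            bracket = c(1e-6, 0.1), tol = 1e-10) {
  variant <- match.arg(variant)
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2], tol > 0)
  detf <- function(p) {
    st <- classify(set_p(params, p), variant = variant)
    st$det
  }
  f_lo <- detf(bracket[1]); f_hi <- detf(bracket[2])
  if (sign(f_lo) == sign(f_hi))
    stop(sprintf(paste0("no critical point in range: det(L) has the same ",
                        "sign at both ends (det(%g) = %.6e, det(%g) = %.6e)"),
                 bracket[1], f_lo, bracket[2], f_hi), call. = FALSE)
  lo <- bracket[1]; hi <- bracket[2]; it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- detf(mid)
    it <- it + 1L
    if (f_mid == 0) { lo <- mid; hi <- mid; break }
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
    if (it > 200L) break
  }
  p_c <- (lo + hi) / 2
  st <- classify(set_p(params, p_c), variant = variant)
  structure(list(p_c = p_c, bracket = bracket, residual = abs(st$det),
                 eigenvalues = st$eigenvalues, iterations = it,
                 variant = variant),
            class = "cmt_critical")
}

#' @export
print.cmt_critical <- function(x, ...) {
  cat(sprintf("Critical cofactor concentration p_c = %.12g\n", x$p_c))
  cat(sprintf("  |det L(p_c)| = %.3e after %d bisections on [%g, %g] (%s)\n",
              x$residual, x$iterations, x$bracket[1], x$bracket[2],
              x$variant))
  cat("  eigenvalues at p_c:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' Stability sweep over cofactor concentrations
#'
#' Classifies the fluctuation Jacobian at each value of `p` and returns a
#' table (sorted by `p`; duplicated inputs give duplicated rows).
#'
#' @param params a `cmt_params` template; its `p` is replaced per row
#' @param p_values nonnegative cofactor concentrations
#' @inheritParams fluct_rhs
#' @return a data.frame with columns `p, trace, det, discriminant,
#'   re_lambda1, im_lambda1, re_lambda2, im_lambda2, regime`
#' @export
stability_sweep <- function(params, p_values,
                            variant = c("fig2_code", "paper_eq")) {
  variant <- match.arg(variant)
  if (length(p_values) == 0L)
    return(data.frame(p = numeric(0), trace = numeric(0), det = numeric(0),
                      discriminant = numeric(0), re_lambda1 = numeric(0),
                      im_lambda1 = numeric(0), re_lambda2 = numeric(0),
                      im_lambda2 = numeric(0), regime = character(0)))
  stopifnot(all(p_values >= 0))
  p_values <- sort(p_values)
  rows <- lapply(p_values, function(p) {
    st <- classify(set_p(params, p), variant = variant)
    data.frame(p = p, trace = st$trace, det = st$det,
               discriminant = st$discriminant,
               re_lambda1 = Re(st$eigenvalues[1]),
               im_lambda1 = Im(st$eigenvalues[1]),
               re_lambda2 = Re(st$eigenvalues[2]),
               im_lambda2 = Im(st$eigenvalues[2]),
               regime = st$regime)
  })
  do.call(rbind, rows)
}
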