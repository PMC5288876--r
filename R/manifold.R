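# Center-manifold reduction of the fluctuation system at the critical
# cofactor concentration.
#
# The bifurcation parameter deviation eps = p - p_c is suspended as an
# extra state with d(eps)/dt = 0, the (x, z) field is rewritten in the
# eigenbasis of the critical Jacobian L_c (eigenvalues tau and 0), and
# the invariance equation for the slaved fast coordinate
#     u = h(v, eps) = a1 v^2 + a2 v*eps + a3 eps^2
#                   + a4 v^3 + a5 v^2*eps + a6 v*eps^2 + a7 eps^3 + ...
# is solved order by order.  Substituting h into the center equation
# yields the reduced dynamics
#     dv/dt = n1 v^2 + n2 v*eps + n3 eps^2
#           + n4 v^3 + n5 v^2*eps + n6 v*eps^2 + n7 eps^3 + ...
# All of this is done once over fully symbolic Jacobian entries
# (A, B, C with the criticality constraint D = B*C/A) and quadratic
# coefficients (qa, qb, qc, qd), so the structurally-vanishing
# coefficients are certified as exact zeros for arbitrary parameter
# values; numeric values are obtained afterwards by evaluating the
# rational-function solution at a concrete parameter set.
#
# Two eigenbasis modes are provided:
#  * "exact": the true eigenvectors of L_c.  Tangency and invariance hold
#    to the truncation order.  In this basis a3 = a7 = 0 and n3 = n7 = 0
#    identically (the suspended field has no pure-eps forcing), but the
#    v*eps^2 coefficient n6 does NOT vanish in general.
#  * "paper_approx": the approximate eigenvector matrix
#    [[-a*Xe, 1], [a*Xe, 1]] used in the published analysis (valid when
#    D1, k, Ye, p_c are all small), with the linear part replaced by its
#    limiting diagonal form diag(a*Xe, 0).  In this basis the center row
#    of the inverse transform is (1/2, 1/2), which annihilates the
#    (+eps*z, -eps*z) cofactor coupling, so n2 = n3 = n6 = n7 = 0
#    identically -- this is the basis in which the full published
#    vanishing set n3 = n6 = n7 = 0 is a theorem.

.cmt_cache <- new.env(parent = emptyenv())

.h_monos <- list(a1 = c(v = 2L), a2 = c(v = 1L, e = 1L), a3 = c(e = 2L),
                 a4 = c(v = 3L), a5 = c(v = 2L, e = 1L),
                 a6 = c(v = 1L, e = 2L), a7 = c(e = 3L))
.n_monos <- list(n1 = c(v = 2L), n2 = c(v = 1L, e = 1L), n3 = c(e = 2L),
                 n4 = c(v = 3L), n5 = c(v = 2L, e = 1L),
                 n6 = c(v = 1L, e = 2L), n7 = c(e = 3L))

#' Suspend the fluctuation system at the critical point
#'
#' Builds the polynomial vector field in `(x, z, eps)` obtained from the
#' fluctuation equations by substituting `p = p_c + eps` and freezing the
#' steady state at its critical value (fluctuations are measured about
#' the critical steady state).  Writing the critical Jacobian entries as
#' `A = -D1 + a*Xe - k`, `B = -b*Xe + p_c`, `C` (variant dependent),
#' `D = -p_c`, the suspended field is
#' \deqn{dx/dt = A x + B z + q_a x^2 - q_b x z + \epsilon z}
#' \deqn{dz/dt = C x + D z + q_c x^2 + q_d x z - \epsilon z}
#' \deqn{d\epsilon/dt = 0.}
#' The deviation `eps` enters only multiplied by `z`, so the origin is a
#' fixed point for every `eps` and the field has no pure-`eps` forcing.
#'
#' @param params a `cmt_params` object, or `NULL` for a fully symbolic
#'   system
#' @param p_c critical cofactor concentration; computed with
#'   [find_critical_p()] when `NULL` and `params` is given
#' @param variant fluctuation-system variant, see [fluct_rhs()]; the
#'   default here is `"paper_eq"`, the form the published stability
#'   analysis is written in
#' @return an object of class `cmt_suspended` carrying the symbolic field
#'   and (when `params` is given) the numeric values of its coefficients
#' @export
build_suspended_system <- function(params = NULL, p_c = NULL,
                                   variant = c("paper_eq", "fig2_code")) {
  variant <- match.arg(variant)
  A <- rf_sym("A"); B <- rf_sym("B"); C <- rf_sym("C"); D <- rf_sym("D")
  qa <- rf_sym("qa"); qb <- rf_sym("qb")
  qc <- rf_sym("qc"); qd <- rf_sym("qd")
  x <- pv_sym("x"); z <- pv_sym("z"); e <- pv_sym("e")
  fx <- Reduce(pv_add, list(pv_scale(x, A), pv_scale(z, B),
                            pv_scale(pv_mul(x, x), qa),
                            pv_neg(pv_scale(pv_mul(x, z), qb)),
                            pv_mul(e, z)))
  fz <- Reduce(pv_add, list(pv_scale(x, C), pv_scale(z, D),
                            pv_scale(pv_mul(x, x), qc),
                            pv_scale(pv_mul(x, z), qd),
                            pv_neg(pv_mul(e, z))))
  env <- NULL
  if (!is.null(params)) {
    if (is.null(p_c)) p_c <- find_critical_p(params, variant = variant)$p_c
    at_c <- set_p(params, p_c)
    st <- steady_state(at_c)
    L <- linearize(at_c, steady = st, variant = variant)
    qq <- fluct_quad_coefs(params, variant)
    env <- c(A = L[1, 1], B = L[1, 2], C = L[2, 1], D = L[2, 2],
             qa = qq$qa, qb = qq$qb, qc = qq$qc, qd = qq$qd,
             s = params$a * st[["Xe"]],
             Xe = st[["Xe"]], Ye = st[["Ye"]], p_c = p_c)
  }
  structure(list(fx = fx, fz = fz, env = env, params = params,
                 p_c = p_c, variant = variant),
            class = "cmt_suspended")
}

#' Evaluate the suspended vector field numerically
#'
#' @param sus a `cmt_suspended` built from a concrete parameter set
#' @param state numeric `(x, z)`
#' @param eps deviation of the cofactor supply from its critical value
#' @return numeric `(dx, dz)`
#' @export
eval_suspended <- function(sus, state, eps = 0) {
  stopifnot(inherits(sus, "cmt_suspended"))
  if (is.null(sus$env))
    stop("suspended system is fully symbolic; build it from parameters ",
         "to evaluate numerically", call. = FALSE)
  env <- c(sus$env, x = state[[1]], z = state[[2]], e = eps)
  c(dx = pv_eval(sus$fx, env), dz = pv_eval(sus$fz, env))
}

#' Transform the suspended system to the eigenbasis of the critical Jacobian
#'
#' In `"exact"` mode the criticality constraint `det L_c = 0` is imposed
#' symbolically (`D = B*C/A`), the eigenvalues are `tau = A + D` and `0`,
#' and the eigenvector matrix `T = [[B, B], [D, -A]]` (fast column first)
#' diagonalises the linear part exactly: the transformed field is
#' `du/dt = tau*u + ...`, `dv/dt = 0*v + ...` with `v` spanning the
#' center direction.  In `"paper_approx"` mode the published approximate
#' matrix `[[-s, 1], [s, 1]]` with `s = a*Xe` is used verbatim and the
#' linear part is taken as its limiting form `diag(s, 0)` (the
#' approximation is only consistent when `D1`, `k`, `Ye`, `p_c` are all
#' negligible, in which case the fast eigenvalue tends to `a*Xe`).
#'
#' @param sus a `cmt_suspended` object
#' @param mode `"exact"` or `"paper_approx"`
#' @return an object of class `cmt_eigentransform` with the transformed
#'   polynomial field `(fu, fv)` in `(u, v, eps)`, the transform matrix
#'   and its inverse (symbolic and, when available, numeric)
#' @export
transform_to_eigenbasis <- function(sus, mode = c("exact", "paper_approx")) {
  stopifnot(inherits(sus, "cmt_suspended"))
  mode <- match.arg(mode)
  A <- rf_sym("A"); B <- rf_sym("B"); C <- rf_sym("C")
  one <- rf_const(qn(1)); half <- rf_const(qn(1, 2))
  u <- pv_sym("u"); v <- pv_sym("v"); e <- pv_sym("e")
  if (mode == "exact") {
    Dr <- rf_div(rf_mul(B, C), A)          # criticality: det L_c = 0
    tau <- rf_add(A, Dr)
    if (rf_is_zero(tau))
      stop("non-semisimple linear part: both eigenvalues vanish",
           call. = FALSE)
    Tm <- list(list(B, B), list(Dr, rf_neg(A)))
    dT <- rf_neg(rf_mul(B, tau))
    Ti <- list(list(rf_div(rf_neg(A), dT), rf_div(rf_neg(B), dT)),
               list(rf_div(rf_neg(Dr), dT), rf_div(B, dT)))
    x_uv <- pv_add(pv_scale(u, B), pv_scale(v, B))
    z_uv <- pv_add(pv_scale(u, Dr), pv_scale(v, rf_neg(A)))
    # full field, including the linear part, transformed exactly
    fx <- Reduce(pv_add, list(
      pv_scale(x_uv, A), pv_scale(z_uv, B),
      pv_scale(pv_mul(x_uv, x_uv), rf_sym("qa")),
      pv_neg(pv_scale(pv_mul(x_uv, z_uv), rf_sym("qb"))),
      pv_mul(e, z_uv)))
    fz <- Reduce(pv_add, list(
      pv_scale(x_uv, C), pv_scale(z_uv, Dr),
      pv_scale(pv_mul(x_uv, x_uv), rf_sym("qc")),
      pv_scale(pv_mul(x_uv, z_uv), rf_sym("qd")),
      pv_neg(pv_mul(e, z_uv))))
    fu <- pv_add(pv_scale(fx, Ti[[1]][[1]]), pv_scale(fz, Ti[[1]][[2]]))
    fv <- pv_add(pv_scale(fx, Ti[[2]][[1]]), pv_scale(fz, Ti[[2]][[2]]))
  } else {
    s <- rf_sym("s")
    tau <- s
    Tm <- list(list(rf_neg(s), one), list(s, one))
    s2 <- rf_mul(rf_const(qn(2)), s)
    Ti <- list(list(rf_div(rf_const(qn(-1)), s2), rf_div(one, s2)),
               list(half, half))
    x_uv <- pv_add(pv_scale(u, rf_neg(s)), v)
    z_uv <- pv_add(pv_scale(u, s), v)
    # nonlinear + coupling parts transformed with the approximate matrix;
    # linear part replaced by its limiting diagonal diag(s, 0)
    gx <- Reduce(pv_add, list(
      pv_scale(pv_mul(x_uv, x_uv), rf_sym("qa")),
      pv_neg(pv_scale(pv_mul(x_uv, z_uv), rf_sym("qb"))),
      pv_mul(e, z_uv)))
    gz <- Reduce(pv_add, list(
      pv_scale(pv_mul(x_uv, x_uv), rf_sym("qc")),
      pv_scale(pv_mul(x_uv, z_uv), rf_sym("qd")),
      pv_neg(pv_mul(e, z_uv))))
    fu <- pv_add(pv_scale(u, s),
                 pv_add(pv_scale(gx, Ti[[1]][[1]]),
                        pv_scale(gz, Ti[[1]][[2]])))
    fv <- pv_add(pv_scale(gx, Ti[[2]][[1]]), pv_scale(gz, Ti[[2]][[2]]))
  }
  # structural checks: diagonal linear part, u fast, v center
  stopifnot(pv_is_zero(pv_coeff(fu, c(u = 0L, v = 1L, e = 0L))),
            pv_is_zero(pv_coeff(fv, c(u = 1L, v = 0L, e = 0L))),
            pv_is_zero(pv_coeff(fv, c(u = 0L, v = 1L, e = 0L))))
  structure(list(fu = fu, fv = fv, T = Tm, Tinv = Ti, tau = tau,
                 mode = mode, env = sus$env, variant = sus$variant,
                 p_c = sus$p_c, params = sus$params),
            class = "cmt_eigentransform")
}

# symbolic part of the reduction; depends only on the eigenbasis mode,
# so it is computed once per mode and cached
.solve_invariance_symbolic <- function(trans, order = 3L) {
  key <- paste0(trans$mode, "_o", order)
  if (!is.null(.cmt_cache[[key]])) return(.cmt_cache[[key]])
  fu <- pv_trunc(trans$fu, c("u", "v", "e"), order)
  fv <- pv_trunc(trans$fv, c("u", "v", "e"), order)
  avars <- names(.h_monos)
  h <- pv_zero()
  for (nm in avars) {
    mono <- .h_monos[[nm]]
    term <- pv_sym(nm)
    for (vn in names(mono)) term <- pv_mul(term, pv_sym(vn, pow = mono[[vn]]))
    h <- pv_add(h, term)
  }
  ve <- c("v", "e")
  fu_h <- pv_subst_trunc(fu, "u", h, ve, order)
  fv_h <- pv_subst_trunc(fv, "u", h, ve, order)
  resid <- pv_sub(fu_h, pv_mul_trunc(pv_deriv(h, "v"), fv_h, ve, order))
  eqs <- list()
  for (mono in .n_monos) {
    tgt <- c(v = 0L, e = 0L)
    tgt[names(mono)] <- mono
    eq <- pv_coeff(resid, tgt)
    eqs[[length(eqs) + 1L]] <- eq
  }
  a_sol <- pv_solve_linear(eqs, avars)
  # manifold with solved coefficients
  h_solved <- pv_zero()
  for (nm in avars) {
    mono <- .h_monos[[nm]]
    term <- pv_const(a_sol[[nm]])
    for (vn in names(mono)) term <- pv_mul(term, pv_sym(vn, pow = mono[[vn]]))
    h_solved <- pv_add(h_solved, term)
  }
  # reduced dynamics on the manifold
  fv_on <- pv_subst_trunc(fv, "u", h_solved, ve, order)
  n_sol <- list()
  for (nm in names(.n_monos)) {
    tgt <- c(v = 0L, e = 0L)
    tgt[names(.n_monos[[nm]])] <- .n_monos[[nm]]
    cf <- pv_coeff(fv_on, tgt)
    n_sol[[nm]] <- if (pv_is_zero(cf)) rf(mp_zero()) else cf$terms[[1]]$c
  }
  # invariance residual beyond the solved order: everything of total
  # degree <= order cancels by construction (verified), and the lowest
  # surviving degree is found by re-expanding one order higher
  fu_full <- pv_subst_trunc(trans$fu, "u", h_solved, ve, order + 1L)
  fv_full <- pv_subst_trunc(trans$fv, "u", h_solved, ve, order + 1L)
  res_full <- pv_sub(fu_full,
                     pv_mul_trunc(pv_deriv(h_solved, "v"), fv_full,
                                  ve, order + 1L))
  degs <- vapply(res_full$terms, function(t) sum(t$e), 0)
  if (any(degs <= order))
    stop("internal error: invariance residual below truncation order",
         call. = FALSE)
  mindeg <- if (length(degs) == 0L) Inf else min(degs)
  out <- list(a = a_sol, n = n_sol, h = h_solved,
              residual_min_degree = mindeg, order = order)
  .cmt_cache[[key]] <- out
  out
}

#' Solve the invariance equation for the center manifold
#'
#' Substitutes the cubic ansatz `u = h(v, eps)` into the invariance
#' condition (the chain rule along the reduced flow must reproduce the
#' fast equation on the manifold), collects monomials `v^i eps^j` of
#' total degree at most `order`, and solves the resulting linear system
#' for the manifold coefficients `a1..a7` over the rational-function
#' field in the symbolic Jacobian and quadratic coefficients.  The
#' reduced dynamics coefficients `n1..n7` follow by substituting `h` into
#' the center equation.  The symbolic solve depends only on the mode, so
#' repeated calls are cached; numeric values are evaluations of the
#' symbolic solution at the parameter set the transform was built from.
#'
#' @param trans a `cmt_eigentransform` object
#' @param order truncation order of the ansatz (3, matching the cubic
#'   ansatz; higher orders are out of scope)
#' @return an object of class `cmt_manifold`; see [center_manifold()]
#' @export
solve_invariance_equation <- function(trans, order = 3L) {
  stopifnot(inherits(trans, "cmt_eigentransform"))
  if (order != 3L)
    stop("only the cubic ansatz (order = 3) is supported", call. = FALSE)
  sym <- .solve_invariance_symbolic(trans, order)
  a_num <- n_num <- NULL
  Tnum <- NULL
  if (!is.null(trans$env)) {
    a_num <- vapply(sym$a, rf_eval, 0, env = trans$env)
    n_num <- vapply(sym$n, rf_eval, 0, env = trans$env)
    Tnum <- matrix(vapply(unlist(trans$T, recursive = FALSE), rf_eval, 0,
                          env = trans$env), 2, 2, byrow = TRUE)
  }
  structure(list(a = sym$a, n = sym$n, h = sym$h,
                 a_num = a_num, n_num = n_num,
                 residual_min_degree = sym$residual_min_degree,
                 order = sym$order, mode = trans$mode,
                 variant = trans$variant, p_c = trans$p_c,
                 env = trans$env, T_num = Tnum, transform = trans),
            class = "cmt_manifold")
}

#' Center-manifold reduction at the critical point
#'
#' One-call wrapper: finds the critical cofactor concentration (unless
#' supplied), suspends the system, transforms to the eigenbasis and
#' solves the invariance equation.  See [transform_to_eigenbasis()] for
#' the two eigenbasis modes and what vanishes identically in each.
#'
#' @inheritParams build_suspended_system
#' @inheritParams transform_to_eigenbasis
#' @param order truncation order of the ansatz (fixed at 3)
#' @return an object of class `cmt_manifold` with symbolic (`a`, `n`,
#'   rational functions) and numeric (`a_num`, `n_num`) manifold and
#'   reduced-dynamics coefficients, the invariance-residual degree, and
#'   the transform used
#' @export
#' @examples
#' \donttest{
#' cm <- center_manifold(preset_params("fig2_code"))
#' summary(cm)
#' }
center_manifold <- function(params = NULL, p_c = NULL,
                            variant = c("paper_eq", "fig2_code"),
                            mode = c("exact", "paper_approx"),
                            order = 3L) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  sus <- build_suspended_system(params, p_c, variant)
  trans <- transform_to_eigenbasis(sus, mode)
  solve_invariance_equation(trans, order)
}

# numeric h(v, eps) and reduced dv/dt on the manifold
manifold_height <- function(cm, v, eps = 0) {
  stopifnot(inherits(cm, "cmt_manifold"))
  if (is.null(cm$a_num)) stop("manifold is fully symbolic", call. = FALSE)
  a <- cm$a_num
  a[["a1"]] * v^2 + a[["a2"]] * v * eps + a[["a3"]] * eps^2 +
    a[["a4"]] * v^3 + a[["a5"]] * v^2 * eps + a[["a6"]] * v * eps^2 +
    a[["a7"]] * eps^3
}

reduced_rate <- function(cm, v, eps = 0) {
  stopifnot(inherits(cm, "cmt_manifold"))
  if (is.null(cm$n_num)) stop("manifold is fully symbolic", call. = FALSE)
  n <- cm$n_num
  n[["n1"]] * v^2 + n[["n2"]] * v * eps + n[["n3"]] * eps^2 +
    n[["n4"]] * v^3 + n[["n5"]] * v^2 * eps + n[["n6"]] * v * eps^2 +
    n[["n7"]] * eps^3
}

#' @export
print.cmt_manifold <- function(x, ...) {
  cat(sprintf("Center-manifold reduction (%s eigenbasis, order %d)\n",
              x$mode, x$order))
  if (!is.null(x$p_c)) cat(sprintf("  p_c = %.12g (%s)\n", x$p_c, x$variant))
  zer <- function(lst) names(lst)[vapply(lst, rf_is_zero, TRUE)]
  cat("  identically zero:",
      paste(c(zer(x$a), zer(x$n)), collapse = ", "), "\n")
  if (!is.null(x$a_num)) {
    cat("  manifold coefficients a1..a7:\n   ")
    cat(format(x$a_num, digits = 6), "\n")
    cat("  reduced dynamics n1..n7:\n   ")
    cat(format(x$n_num, digits = 6), "\n")
  }
  cat("  invariance residual: lowest surviving total degree =",
      x$residual_min_degree, "\n")
  invisible(x)
}

#' @export
summary.cmt_manifold <- function(object, ...) {
  print(object)
  cat("\nSymbolic coefficients (A, B, C = critical Jacobian entries,\n",
      "qa, qb, qc, qd = quadratic coefficients, s = a*Xe):\n", sep = "")
  for (nm in names(object$a))
    cat(" ", nm, "=", rf_format(object$a[[nm]]), "\n")
  for (nm in names(object$n))
    cat(" ", nm, "=", rf_format(object$n[[nm]]), "\n")
  invisible(object)
}

#' Fixed-point branches of the reduced dynamics
#'
#' Sets `dv/dt = 0` in the reduced equation.  Besides the trivial branch
#' `v = 0`, the quadratic factor `n1 v + n2 eps + n4 v^2 + n5 v eps = 0`
#' gives
#' \deqn{v_\pm = \frac{-(n_1 + n_5\epsilon) \pm
#'   \sqrt{(n_1 + n_5\epsilon)^2 - 4 n_2 n_4 \epsilon}}{2 n_4},}
#' two branches that collide where the discriminant vanishes -- the
#' bifurcation signature.  First-order series about `eps = 0` are
#' reported alongside: `v ~ -n1/n4 - (n5/n4 - n2/n1) eps` (continuation
#' of the nontrivial root) and `v ~ -n2 eps / n1` (the branch emerging
#' from the origin).  When `n4 = 0` the single nontrivial root
#' `v = -n2 eps / n1` is used; when `n1 = n4 = 0` only the trivial
#' branch exists and the result is flagged degenerate.
#'
#' @param cm a `cmt_manifold` with numeric coefficients
#' @param eps numeric vector of parameter deviations `p - p_c`
#' @return an object of class `cmt_branches`: a data.frame with columns
#'   `eps, branch, v, v_series, u, real` plus attributes `degenerate`
#'   and `discriminant`
#' @export
fixed_point_branches <- function(cm, eps) {
  stopifnot(inherits(cm, "cmt_manifold"))
  if (is.null(cm$n_num)) stop("manifold is fully symbolic", call. = FALSE)
  n <- as.list(cm$n_num)
  degenerate <- (n$n4 == 0 && n$n1 == 0)
  rows <- list()
  disc_all <- numeric(length(eps))
  for (i in seq_along(eps)) {
    ep <- eps[i]
    rows[[length(rows) + 1L]] <-
      data.frame(eps = ep, branch = "trivial", v = 0, v_series = 0,
                 u = manifold_height(cm, 0, ep), real = TRUE)
    if (n$n4 != 0) {
      bq <- n$n1 + n$n5 * ep
      disc <- bq^2 - 4 * n$n2 * n$n4 * ep
      disc_all[i] <- disc
      sq <- sqrt(as.complex(disc))
      for (sgn in c(1, -1)) {
        vv <- (-bq + sgn * sq) / (2 * n$n4)
        isre <- abs(Im(vv)) < 1e-14 * (abs(vv) + 1)
        vr <- Re(vv)
        ser <- if (sgn == 1 && n$n1 != 0) {
          # root continuing from v = 0 pairs with + for n1/n4 of one sign;
          # pick by proximity instead of sign bookkeeping
          NA_real_
        } else NA_real_
        rows[[length(rows) + 1L]] <-
          data.frame(eps = ep, branch = if (sgn > 0) "plus" else "minus",
                     v = if (isre) vr else NA_real_, v_series = ser,
                     u = if (isre) manifold_height(cm, vr, ep) else NA_real_,
                     real = isre)
      }
    } else if (n$n1 != 0) {
      vv <- -n$n2 * ep / n$n1
      rows[[length(rows) + 1L]] <-
        data.frame(eps = ep, branch = "linear", v = vv, v_series = vv,
                   u = manifold_height(cm, vv, ep), real = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  # first-order series for the quadratic branches
  if (n$n4 != 0 && n$n1 != 0) {
    far  <- -n$n1 / n$n4 - (n$n5 / n$n4 - n$n2 / n$n1) * out$eps
    near <- -n$n2 * out$eps / n$n1
    for (r in seq_len(nrow(out))) {
      if (out$branch[r] %in% c("plus", "minus") && out$real[r]) {
        out$v_series[r] <- if (abs(out$v[r] - far[r]) <
                               abs(out$v[r] - near[r])) far[r] else near[r]
      }
    }
  }
  structure(out, class = c("cmt_branches", "data.frame"),
            degenerate = degenerate, discriminant = disc_all,
            n = cm$n_num)
}

#' Map reduced-coordinate branches back to fluctuation space
#'
#' Applies the eigenvector matrix to `(u, v)` to recover the physical
#' fluctuations `(x, z)` on each branch.  The published shortcut takes
#' `x ~ v` (exact for the approximate eigenbasis when `u = 0`); the
#' discrepancy between the exact back-transform and that shortcut is
#' reported per row.
#'
#' @param branches a `cmt_branches` object
#' @param cm the `cmt_manifold` the branches came from
#' @return the branches data.frame with columns `x`, `z`, `x_approx`
#'   (`= v`) and `x_discrepancy` appended
#' @export
back_transform <- function(branches, cm) {
  stopifnot(inherits(branches, "cmt_branches"), inherits(cm, "cmt_manifold"))
  Tm <- cm$T_num
  if (is.null(Tm)) stop("manifold is fully symbolic", call. = FALSE)
  xs <- Tm[1, 1] * branches$u + Tm[1, 2] * branches$v
  zs <- Tm[2, 1] * branches$u + Tm[2, 2] * branches$v
  branches$x <- xs
  branches$z <- zs
  branches$x_approx <- branches$v
  branches$x_discrepancy <- xs - branches$v
  branches
}
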