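# center-manifold reduction: suspension, eigenbasis transform, invariance
# solve, reduced dynamics, branches

cp_fig2 <- find_critical_p(preset_params("fig2_code"))

test_that("the suspended field reduces to the fluctuation field at eps = 0", {
  pr <- fig2()
  sus <- build_suspended_system(pr, p_c = cp_fig2$p_c, variant = "paper_eq")
  at_c <- set_p(pr, cp_fig2$p_c)
  stc <- steady_state(at_c)
  set.seed(31)
  for (i in 1:20) {
    s <- runif(2, -1e-3, 1e-3)
    expect_equal(unname(eval_suspended(sus, s, eps = 0)),
                 unname(fluct_rhs(s, at_c, stc, "paper_eq")),
                 tolerance = 1e-12)
    # nonzero eps shifts p but keeps the critical steady state frozen
    ep <- runif(1, -1e-3, 1e-3)
    shifted <- set_p(pr, cp_fig2$p_c + ep)
    expect_equal(unname(eval_suspended(sus, s, eps = ep)),
                 unname(fluct_rhs(s, shifted, stc, "paper_eq")),
                 tolerance = 1e-10)
    # the origin is a fixed point for every eps
    expect_equal(unname(eval_suspended(sus, c(0, 0), eps = ep)), c(0, 0))
  }
})

test_that("the exact eigenbasis diagonalises the critical linear part", {
  sus <- build_suspended_system(fig2(), p_c = cp_fig2$p_c,
                                variant = "paper_eq")
  trans <- transform_to_eigenbasis(sus, "exact")
  # fast eigenvalue on u, zero on v (structural check re-done numerically)
  env <- trans$env
  tau_num <- rf_eval(trans$tau, env)
  at_c <- set_p(fig2(), cp_fig2$p_c)
  L <- linearize(at_c, variant = "paper_eq")
  expect_equal(tau_num, sum(diag(L)), tolerance = 1e-6)
  # T diagonalises L (up to the bisection residual in det)
  Tn <- matrix(vapply(unlist(trans$T, recursive = FALSE), rf_eval, 0,
                      env = env), 2, 2, byrow = TRUE)
  D <- solve(Tn) %*% L %*% Tn
  expect_lt(abs(D[1, 2]), 1e-8)
  expect_lt(abs(D[2, 1]), 1e-8)
  expect_lt(abs(D[2, 2]), 1e-8)
  expect_equal(D[1, 1], tau_num, tolerance = 1e-6)
})

test_that("the published approximate transform inverts as printed", {
  # [-s, 1; s, 1]^-1 = (1/(2s)) [-1, 1; s, s]
  sus <- build_suspended_system(fig2(), p_c = cp_fig2$p_c,
                                variant = "paper_eq")
  trans <- transform_to_eigenbasis(sus, "paper_approx")
  env <- c(s = 0.3)
  Ti <- matrix(vapply(unlist(trans$Tinv, recursive = FALSE), rf_eval, 0,
                      env = env), 2, 2, byrow = TRUE)
  expect_equal(Ti, matrix(c(-1 / 0.6, 0.5, 1 / 0.6, 0.5), 2, 2),
               tolerance = 1e-14)
  # and a*Xe = 0.3 gives the printed eigenvector matrix [-0.3 1; 0.3 1]
  Tn <- matrix(vapply(unlist(trans$T, recursive = FALSE), rf_eval, 0,
                      env = env), 2, 2, byrow = TRUE)
  expect_equal(Tn, matrix(c(-0.3, 0.3, 1, 1), 2, 2), tolerance = 1e-14)
})

test_that("structurally vanishing coefficients are exact symbolic zeros", {
  cm <- center_manifold(fig2(), p_c = cp_fig2$p_c, mode = "exact")
  # no pure-eps forcing: the manifold has no pure-eps terms, and the
  # reduced dynamics no eps^2 or eps^3 terms, for arbitrary symbols
  expect_true(rf_is_zero(cm$a$a3))
  expect_true(rf_is_zero(cm$a$a7))
  expect_true(rf_is_zero(cm$n$n3))
  expect_true(rf_is_zero(cm$n$n7))
  # ... but the v*eps^2 coefficient survives in the exact eigenbasis
  expect_false(rf_is_zero(cm$n$n6))
  expect_gt(abs(cm$n_num[["n6"]]), 0)

  # the full published vanishing set holds in the approximate eigenbasis,
  # whose center row annihilates the cofactor coupling
  cma <- center_manifold(fig2(), p_c = cp_fig2$p_c, mode = "paper_approx")
  for (nm in c("n2", "n3", "n6", "n7"))
    expect_true(rf_is_zero(cma$n[[nm]]))
  expect_true(rf_is_zero(cma$a$a3))
  expect_true(rf_is_zero(cma$a$a7))

  # tangency: the ansatz has no constant or linear part
  for (m in list(cm, cma)) {
    degs <- vapply(m$h$terms, function(t) sum(t$e), 0)
    expect_true(all(degs >= 2))
    expect_gte(m$residual_min_degree, 4)
  }
})

test_that("order-2 coefficients obey their closed-form relations", {
  # independent arithmetic: at order 2 the triangular solve gives
  # a_i = -(coefficient of the matching monomial in f_u at u = 0) / tau
  cm <- center_manifold(fig2(), p_c = cp_fig2$p_c, mode = "exact")
  trans <- cm$transform
  env <- trans$env
  tau <- rf_eval(trans$tau, env)
  cf <- function(f, i, j)
    pv_eval(pv_coeff(f, c(u = 0L, v = i, e = j)), env)
  expect_equal(cm$a_num[["a1"]], -cf(trans$fu, 2L, 0L) / tau,
               tolerance = 1e-10)
  expect_equal(cm$a_num[["a2"]], -cf(trans$fu, 1L, 1L) / tau,
               tolerance = 1e-10)
  expect_equal(cm$a_num[["a3"]], 0)
  # and the order-2 reduced coefficients read off the center equation
  expect_equal(cm$n_num[["n1"]], cf(trans$fv, 2L, 0L), tolerance = 1e-10)
  expect_equal(cm$n_num[["n2"]], cf(trans$fv, 1L, 1L), tolerance = 1e-10)
})

test_that("a linear field has a flat center manifold", {
  trans <- structure(list(
    fu = pv_scale(pv_sym("u"), rf_sym("A")),
    fv = pv_zero(),
    T = list(list(rf_const(qn(1)), rf_const(qn(0))),
             list(rf_const(qn(0)), rf_const(qn(1)))),
    Tinv = NULL, tau = rf_sym("A"), mode = "linear_probe",
    env = NULL, variant = "paper_eq", p_c = NULL, params = NULL),
    class = "cmt_eigentransform")
  cm <- solve_invariance_equation(trans)
  expect_true(all(vapply(cm$a, rf_is_zero, TRUE)))
  expect_true(all(vapply(cm$n, rf_is_zero, TRUE)))
})

test_that("trajectories launched on the manifold stay on it to cubic order", {
  cm <- center_manifold(fig2(), p_c = cp_fig2$p_c, mode = "exact")
  Tn <- cm$T_num
  Tin <- solve(Tn)
  at_c <- set_p(fig2(), cp_fig2$p_c)
  stc <- steady_state(at_c)
  resid <- function(v0) {
    u0 <- manifold_height(cm, v0, 0)
    xz <- as.vector(Tn %*% c(u0, v0))
    f <- function(t, y, parms) list(fluct_rhs(y, at_c, stc, "paper_eq"))
    s <- deSolve::lsoda(y = c(x = xz[1], z = xz[2]),
                        times = seq(0, 200, 5), f, NULL,
                        rtol = 1e-12, atol = 1e-18)
    uv <- t(Tin %*% t(s[, 2:3]))
    max(abs(uv[, 1] - manifold_height(cm, uv[, 2], 0)))
  }
  v_grid <- seq(4e-9, 4e-8, length.out = 10)
  res <- vapply(v_grid, resid, 0)
  expect_true(all(res <= 1e13 * v_grid^3))
  # truncation error shrinks at least cubically when v is halved
  expect_gt(res[10] / resid(2e-8), 6)
})

test_that("the reduced linear rate reproduces the slow eigenvalue", {
  # on the manifold dv/dt = n2*v*eps + O(|v,eps|^3); n2*eps must equal the
  # continuation of the zero eigenvalue of the suspended linear part
  # [[A, B+eps], [C, D-eps]] (steady state frozen at p_c, as in the
  # suspension itself)
  cm <- center_manifold(fig2(), p_c = cp_fig2$p_c, mode = "exact")
  env <- cm$env
  n2 <- cm$n_num[["n2"]]
  for (ep in c(-1e-7, 1e-7, -1e-6, 1e-6)) {
    Ls <- matrix(c(env[["A"]], env[["C"]],
                   env[["B"]] + ep, env[["D"]] - ep), 2, 2)
    ev <- eigen(Ls)$values
    slow <- ev[which.min(abs(ev))]
    expect_equal(Re(slow), n2 * ep, tolerance = 0.05)
    # sign concordance: the trivial branch destabilises exactly when the
    # slow eigenvalue crosses zero
    expect_equal(sign(Re(slow)), sign(n2 * ep))
  }
})

test_that("fixed-point branches match a polynomial-root oracle", {
  syn <- structure(list(
    n_num = c(n1 = 1, n2 = 0.5, n3 = 0, n4 = 2, n5 = 0.3, n6 = 0, n7 = 0),
    a_num = c(a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, a6 = 0, a7 = 0),
    T_num = diag(2)), class = "cmt_manifold")
  eps <- c(-1e-3, 0, 1e-3)
  br <- fixed_point_branches(syn, eps)
  for (ep in eps) {
    got <- sort(br$v[br$eps == ep & br$real])
    want <- sort(c(0, Re(polyroot(c(0.5 * ep, 1 + 0.3 * ep, 2)))))
    expect_equal(got, want, tolerance = 1e-10)
    # every real branch annihilates the reduced rate to quartic order
    for (v in got)
      expect_lt(abs(reduced_rate(syn, v, ep)), 1e-12 + abs(ep)^4)
  }
  # at eps = 0 the nontrivial roots are 0 and -n1/n4
  v0 <- br$v[br$eps == 0]
  expect_true(any(abs(v0 - (-0.5)) < 1e-12))
  # series branches agree with exact roots to O(eps^2) absolute
  sm <- br[br$eps == 1e-3 & br$branch %in% c("plus", "minus"), ]
  expect_true(all(abs(sm$v - sm$v_series) < 1e-5))
  expect_true(all(abs(sm$v - sm$v_series) > 0))   # but not identical

  # discriminant sign change marks the bifurcation: at eps = 0.3 the
  # quadratic roots are complex and only the trivial branch is real
  br2 <- fixed_point_branches(syn, c(0.05, 0.3))
  n_real <- tapply(br2$real, br2$eps, sum)
  expect_equal(unname(n_real[["0.05"]]), 3)
  expect_equal(unname(n_real[["0.3"]]), 1)
  expect_gt(attr(br2, "discriminant")[1], 0)
  expect_lt(attr(br2, "discriminant")[2], 0)

  # degenerate fallbacks
  syn$n_num[c("n4")] <- 0
  br3 <- fixed_point_branches(syn, 1e-3)
  expect_true("linear" %in% br3$branch)
  expect_equal(br3$v[br3$branch == "linear"], -0.5 * 1e-3 / 1)
  syn$n_num[c("n1")] <- 0
  br4 <- fixed_point_branches(syn, 1e-3)
  expect_true(attr(br4, "degenerate"))
  expect_equal(unique(br4$branch), "trivial")
})

test_that("branches map back to two distinct fluctuation amplitudes", {
  cma <- center_manifold(fig2(), p_c = cp_fig2$p_c, mode = "paper_approx")
  br <- fixed_point_branches(cma, c(-1e-5, 1e-5))
  bt <- back_transform(br, cma)
  # the shortcut x ~ v is exact on the u = 0 trivial branch
  triv <- bt[bt$branch == "trivial", ]
  expect_equal(triv$x, triv$v)
  # nontrivial branches give a second, distinct amplitude
  for (ep in unique(bt$eps)) {
    xs <- unique(round(bt$x[bt$eps == ep & bt$real], 12))
    expect_gte(length(xs), 2)
  }
  # back-transform uses the eigenvector matrix
  expect_equal(bt$x, cma$T_num[1, 1] * bt$u + cma$T_num[1, 2] * bt$v)
})
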