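test_that("steady state matches its closed form and a linear-solve oracle", {
  st <- steady_state(fig2(p = 0.01))
  # frozen values, cross-checked against the independent linear solve below
  expect_equal(st[["Xe"]], 1.8970409404134576e-3, tolerance = 1e-12)
  expect_equal(st[["Ye"]], 4.4037292257803000e-2, tolerance = 1e-12)
  expect_equal(st[["Ze"]], 5.4065666801783541e-2, tolerance = 1e-12)
  orc <- steady_oracle(fig2(p = 0.01))
  expect_equal(unclass(st), orc, tolerance = 1e-12, ignore_attr = TRUE)

  # the critical steady state rounds to the published 0.002
  st11 <- steady_state(fig2(p = 0.011))
  expect_equal(signif(st11[["Xe"]], 1), 0.002)

  # no cofactor supply: everything sits in the released pool
  st0 <- steady_state(fig2(p = 0))
  expect_equal(unclass(st0), c(Xe = 0, Ye = 0, Ze = 0.1), ignore_attr = TRUE)

  expect_error(steady_state(model_params(D1 = 0, D2 = 0, M = 1)),
               "degenerate")
})

test_that("steady state conserves mass and zeroes the rate field", {
  set.seed(11)
  for (i in 1:1000) {
    pr <- random_params()
    st <- steady_state(pr)
    expect_lt(abs(sum(st) - pr$M), 1e-12 * pr$M)
    expect_true(all(st >= 0 & st <= pr$M))
    r <- full_rhs(st, pr)
    expect_lt(max(abs(r)), 1e-12 * pr$M)
  }
})

test_that("steady state is monotone in p with the correct large-p limit", {
  pr <- fig2()
  ps <- seq(0, 0.05, length.out = 60)
  tab <- sapply(ps, function(p) steady_state(set_p(pr, p)))
  expect_true(all(diff(tab["Xe", ]) > 0))
  expect_true(all(diff(tab["Ye", ]) > 0))
  expect_true(all(diff(tab["Ze", ]) < 0))
  xinf <- steady_state(set_p(pr, 1e6))[["Xe"]]
  expect_equal(xinf, pr$D2 * pr$M / (pr$D2 + pr$D1 * pr$W),
               tolerance = 1e-4)
})

test_that("full rate field conserves total monomer exactly", {
  set.seed(12)
  for (i in 1:200) {
    pr <- random_params()
    state <- runif(3, 0, pr$M)
    r <- full_rhs(state, pr)
    # scalar addition (not sum(), whose extended-precision accumulator
    # sees the sub-rounding residual): dZ is built as -(dX) - (dY)
    expect_identical(r[[1]] + r[[2]] + r[[3]], 0)
  }
  r <- full_rhs(c(1, 0, 0), fig2(p = 0.003))
  expect_equal(unname(r), c(-0.285, 0.28, 0.005))
})

test_that("fluctuation field fixes the origin and matches hand arithmetic", {
  pr <- fig2(p = 0.01)
  st <- steady_state(pr)
  for (variant in c("fig2_code", "paper_eq"))
    expect_equal(unname(fluct_rhs(c(0, 0), pr, st, variant)), c(0, 0))

  # independent arithmetic: linear part from the frozen Jacobian entries
  # plus the quadratic feedback, at x = z = 1e-6
  r <- fluct_rhs(c(1e-6, 1e-6), pr, st, "fig2_code")
  dx_hand <- (-4.4385893798137410e-4 - 2.8593838670449939e-1) * 1e-6 +
    (150 - 156) * 1e-12
  dz_hand <- (0.005 - 0.01) * 1e-6 + 0.1 * 1e-12
  expect_equal(r[["dx"]], dx_hand, tolerance = 1e-10)
  expect_equal(r[["dz"]], dz_hand, tolerance = 1e-10)
})

test_that("feedback-free dynamics reduce to linear mass action", {
  pr <- model_params(D1 = 0.3, D2 = 0.05, k = 0.01, p = 0.02, M = 0.5)
  st <- steady_state(pr)
  for (variant in c("fig2_code", "paper_eq")) {
    s <- c(0.01, -0.02)
    r <- fluct_rhs(s, pr, st, variant)
    L <- matrix(c(-(pr$D1 + pr$k), pr$k, pr$p, -pr$p), 2, 2)
    expect_equal(unname(r), as.vector(L %*% s), tolerance = 1e-14)
  }
})

test_that("the two variants agree when c = d = 0", {
  set.seed(13)
  for (i in 1:50) {
    pr <- random_params()
    pr <- model_params(D1 = pr$D1, D2 = pr$D2, a = pr$a, b = pr$b,
                       c = 0, d = 0, k = pr$k, p = pr$p, M = pr$M, W = pr$W)
    st <- steady_state(pr)
    s <- runif(2, -1e-3, 1e-3)
    expect_equal(fluct_rhs(s, pr, st, "fig2_code"),
                 fluct_rhs(s, pr, st, "paper_eq"))
  }
})

test_that("the nonlinear residual is exactly quadratic", {
  set.seed(14)
  for (i in 1:100) {
    pr <- random_params()
    st <- steady_state(pr)
    variant <- sample(c("fig2_code", "paper_eq"), 1)
    L <- linearize(pr, st, variant)
    s <- runif(2, -1e-2, 1e-2)
    quad1 <- fluct_rhs(s, pr, st, variant) - as.vector(L %*% s)
    quad2 <- fluct_rhs(2 * s, pr, st, variant) - as.vector(L %*% (2 * s))
    expect_equal(quad2, 4 * quad1, tolerance = 1e-9)
  }
})

test_that("the analytic Jacobian matches frozen values and simple forms", {
  L <- linearize(fig2(p = 0.01), variant = "paper_eq")
  expect_equal(unname(L),
               matrix(c(-4.4385893798137410e-4, 5.9627077421969994e-4,
                        -2.8593838670449939e-1, -0.01), 2, 2),
               tolerance = 1e-12)
  # feedback off
  pr <- model_params(D1 = 0.3, D2 = 0.05, k = 0.01, p = 0.02, M = 0.5)
  expect_equal(unname(linearize(pr, variant = "paper_eq")),
               matrix(c(-(0.3 + 0.01), 0.01, 0.02, -0.02), 2, 2))
  # lower-right entry is -p for any parameters
  set.seed(15)
  for (i in 1:50) {
    pr <- random_params()
    expect_identical(linearize(pr)[2, 2], -pr$p)
  }
})

test_that("the analytic Jacobian agrees with numerical differentiation", {
  set.seed(16)
  h <- 1e-4
  for (i in 1:1000) {
    pr <- random_params()
    st <- steady_state(pr)
    variant <- if (i %% 2 == 0) "fig2_code" else "paper_eq"
    L <- linearize(pr, st, variant)
    Jn <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      Jn[, j] <- (fluct_rhs(e, pr, st, variant) -
                  fluct_rhs(-e, pr, st, variant)) / (2 * h)
    }
    expect_lt(max(abs(Jn - L)), 1e-8 * max(max(abs(L)), 1e-8))
  }
})
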