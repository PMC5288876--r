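test_that("classification matches frozen reference points", {
  st <- classify(fig2(p = 0.01), variant = "paper_eq")
  expect_equal(st$trace, -1.0443858937981373e-2, tolerance = 1e-12)
  expect_equal(st$det, 1.7493529259923751e-4, tolerance = 1e-12)
  expect_lt(st$discriminant, 0)
  expect_equal(st$regime, "stable_spiral")

  st11 <- classify(fig2(p = 0.011), variant = "paper_eq")
  expect_equal(st11$det, -4.6239416852949459e-5, tolerance = 1e-10)
  expect_equal(st11$regime, "saddle")
})

test_that("feedback-free systems are always stable with det = D1*p", {
  set.seed(21)
  for (i in 1:100) {
    pr <- random_params()
    pr <- model_params(D1 = pr$D1, D2 = pr$D2, k = pr$k, p = pr$p,
                       M = pr$M, W = pr$W)
    st <- classify(pr, variant = "paper_eq")
    expect_lt(st$trace, 0)
    # det = (D1 W + k) p - k p = D1 W p  (the published D1*p at W = 1)
    expect_equal(st$det, pr$D1 * pr$W * pr$p, tolerance = 1e-12)
    expect_true(st$regime %in% c("stable_node", "stable_spiral"))
  }
})

test_that("eigenvalues are consistent with trace and determinant", {
  set.seed(22)
  for (i in 1:300) {
    pr <- random_params()
    st <- classify(pr, variant = sample(c("fig2_code", "paper_eq"), 1))
    scale <- max(abs(st$eigenvalues), 1e-12)
    expect_lt(abs(sum(st$eigenvalues) - st$trace), 1e-10 * scale)
    expect_lt(abs(prod(st$eigenvalues) - st$det), 1e-10 * scale^2)
  }
})

test_that("the critical cofactor concentration is found by bisection", {
  cp <- find_critical_p(fig2())
  expect_equal(cp$p_c, 0.010796942067745226, tolerance = 1e-6)
  # independent root-finder oracle on the same determinant function
  detf <- function(p) classify(set_p(fig2(), p), variant = "paper_eq")$det
  orc <- stats::uniroot(detf, c(1e-3, 0.05), tol = 1e-13)$root
  expect_equal(cp$p_c, orc, tolerance = 1e-8)
  expect_equal(signif(cp$p_c, 2), 0.011)
  expect_lt(cp$residual, 1e-10)
  expect_gte(cp$p_c, cp$bracket[1])
  expect_lte(cp$p_c, cp$bracket[2])
  # one eigenvalue is numerically zero at criticality
  expect_lt(min(abs(cp$eigenvalues)), 1e-8)
  # the published bracket works too
  cp2 <- find_critical_p(fig2(), bracket = c(1e-3, 0.05))
  expect_equal(cp2$p_c, cp$p_c, tolerance = 1e-8)
  # determinant changes sign across the root
  below <- classify(set_p(fig2(), cp$p_c - 1e-4), variant = "paper_eq")
  above <- classify(set_p(fig2(), cp$p_c + 1e-4), variant = "paper_eq")
  expect_gt(below$det, 0)
  expect_lt(above$det, 0)
  expect_equal(above$regime, "saddle")
})

test_that("a feedback-free model has no critical point", {
  pr <- model_params(D1 = 0.28, D2 = 0.012, k = 0.005, p = 0, M = 0.1)
  expect_error(find_critical_p(pr), "no critical point in range")
})

test_that("stability sweeps tabulate regimes over p", {
  pv <- c(0, 0.001, 0.002, 0.004, 0.008, 0.009, 0.01, 0.010705, 0.011)
  sw <- stability_sweep(fig2(), pv, variant = "fig2_code")
  expect_equal(nrow(sw), 9L)
  expect_equal(sw$p, sort(pv))
  stable <- sw$p <= 0.010705
  expect_true(all(pmax(sw$re_lambda1, sw$re_lambda2)[stable] <= 0))
  expect_true(all(pmax(sw$re_lambda1, sw$re_lambda2)[!stable] > 0))

  expect_equal(nrow(stability_sweep(fig2(), numeric(0))), 0L)
  dup <- stability_sweep(fig2(), c(0.01, 0.01))
  expect_equal(nrow(dup), 2L)
  expect_equal(dup[1, ], dup[2, ], ignore_attr = TRUE)
})

test_that("eigenvalues approach {a*Xe, 0} as D1, k, Ye, p vanish", {
  synth_steady <- structure(c(Xe = 0.002, Ye = 0.044, Ze = 0.054),
                            class = "cmt_steady", M = 0.1)
  prev <- Inf
  for (s in 10^-(2:6)) {
    pr <- model_params(D1 = 0.28 * s, D2 = 0.012, a = 150, b = 156,
                       c = 0.1 * s, k = 0.005 * s, p = 0.01 * s, M = 0.1)
    L <- linearize(pr, steady = synth_steady, variant = "paper_eq")
    ev <- sort(Re(eigen(L)$values), decreasing = TRUE)
    err <- max(abs(ev[1] - 150 * 0.002), abs(ev[2]))
    expect_lt(err, 0.3 * s * 10)
    expect_lt(err, prev + 1e-15)
    prev <- err
  }
})
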