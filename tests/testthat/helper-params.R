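# shared fixtures: random valid parameter sets and reference objects

random_params <- function() {
  model_params(D1 = runif(1, 0.01, 1), D2 = runif(1, 0.001, 0.1),
               a = runif(1, 0, 200), b = runif(1, 0, 200),
               c = runif(1, 0, 1), d = runif(1, 0, 1),
               k = runif(1, 0.0001, 0.05), p = runif(1, 0.0001, 0.05),
               M = runif(1, 0.01, 1), W = runif(1, 0.5, 2))
}

fig2 <- function(p = NULL) preset_params("fig2_code", p = p)

# independent steady-state oracle: solve the linear balance system
# (two independent rate equations + conservation) numerically
steady_oracle <- function(params) {
  A <- with(params, matrix(c(-(D1 * W + k), 0,  p,
                             D1 * W,       -D2, 0,
                             1,             1,  1), 3, 3, byrow = TRUE))
  setNames(solve(A, c(0, 0, params$M)), c("Xe", "Ye", "Ze"))
}
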