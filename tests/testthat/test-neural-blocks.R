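# Reference numeric blocks: hand-computed examples and structural
# invariants, plus equivalence between templated and dense paths.

test_that("linear_forward applies the affine map", {
  sp <- linear_spec(diag(3))
  X <- matrix(rnorm(12), 4)
  expect_equal(linear_forward(X, sp), X)
  sp2 <- linear_spec(matrix(c(1, 0, 0, 2), 2), c(0.5, 0.5))
  expect_equal(linear_forward(c(1, 2), sp2), c(1.5, 4.5))
  expect_error(linear_forward(c(1, 2, 3), sp2), "feature dim")
})

test_that("templated linear with a delta kernel equals its dense twin", {
  set.seed(31)
  tpl <- sps_template(3, 8, 8)
  k <- sps_kernel(tpl, c(1, 8, 8), activation = "identity", init = "zeros")
  k$values[2, 1, 1, 1] <- 1
  W <- sps_generate(tpl, k)[1, , ]
  expect_identical(W, tpl$values[2, , ])
  X <- matrix(rnorm(16), 2)
  expect_equal(linear_forward(X, linear_spec(W, templated = TRUE)),
               linear_forward(X, linear_spec(tpl$values[2, , ])))
})

test_that("conv1d is same-padded and consistent with linear at width 1", {
  set.seed(32)
  n <- 3
  X <- matrix(rnorm(5 * n), 5)
  # zero kernel: constant output = bias
  cs0 <- conv1d_spec(array(0, c(3, n, n)), c(1, 2, 3))
  expect_equal(conv1d_forward(X, cs0),
               matrix(c(1, 2, 3), 5, 3, byrow = TRUE))
  # width-1 kernel is a position-wise linear map
  W1 <- array(rnorm(n * n), c(1, n, n))
  expect_equal(conv1d_forward(X, conv1d_spec(W1)),
               linear_forward(X, linear_spec(matrix(W1[1, , ], n))))
  # impulse input: the kernel taps appear centred at the impulse
  W3 <- array(rnorm(3 * n * n), c(3, n, n))
  imp <- matrix(0, 7, n)
  imp[4, 2] <- 1
  out <- conv1d_forward(imp, conv1d_spec(W3))
  expect_equal(out[3, ], W3[3, 2, ])  # future tap reaches the earlier row
  expect_equal(out[4, ], W3[2, 2, ])
  expect_equal(out[5, ], W3[1, 2, ])
  expect_equal(out[1, ], rep(0, n))
  expect_error(conv1d_forward(matrix(0, 3, 5), conv1d_spec(W3)), "channels")
})

test_that("lstm_cell_step reproduces the scalar brute-force example", {
  one <- function() matrix(1)
  p <- lstm_cell_params(W = list(f = one(), d = one(), i = one(), o = one()),
                        U = list(f = one(), d = one(), i = one(), o = one()),
                        b = list(f = 0, d = 0, i = 0, o = 0))
  st <- lstm_cell_step(lstm_state(0, 0), 1, p)
  sig1 <- 1 / (1 + exp(-1))
  expect_equal(st$c, tanh(1) * sig1, tolerance = 1e-12)       # ~0.5568
  expect_equal(st$h, sig1 * tanh(tanh(1) * sig1), tolerance = 1e-12) # ~0.3696
  # all-zero parameters force a zero update
  zero <- function() matrix(0)
  pz <- lstm_cell_params(W = list(f = zero(), d = zero(), i = zero(), o = zero()),
                         U = list(f = zero(), d = zero(), i = zero(), o = zero()),
                         b = list(f = 0, d = 0, i = 0, o = 0))
  stz <- lstm_cell_step(lstm_state(0, 0), 5, pz)
  expect_equal(stz$c, 0)
  expect_equal(stz$h, 0)
  # repeated zero inputs decay |c| monotonically (forget gate < 1)
  st <- lstm_state(0.5, 0.9)
  prev <- abs(st$c)
  for (i in 1:10) {
    st <- lstm_cell_step(st, 0, p)
    expect_lt(abs(st$c), prev)
    prev <- abs(st$c)
  }
  # non-finite state is rejected
  expect_error(lstm_cell_step(lstm_state(NaN, 0), 1, p), "non-finite")
})

test_that("bilstm_encode aligns directions and doubles the channels", {
  set.seed(33)
  n <- 2
  mk <- function() {
    ps <- lapply(c(f = 1, d = 2, i = 3, o = 4), function(i) {
      matrix(rnorm(n * n) * 0.4, n)
    })
    names(ps) <- c("f", "d", "i", "o")
    ps
  }
  params <- lstm_cell_params(mk(), mk(),
                             list(f = rep(0, n), d = rep(0, n),
                                  i = rep(0, n), o = rep(0, n)))
  F <- matrix(rnorm(6 * n), 6)
  Z <- bilstm_encode(F, params, params)
  expect_equal(dim(Z), c(6L, 2L * n))
  # palindromic input with tied parameters: reversal swaps the two tracks
  P <- rbind(F[1:3, ], F[3:1, ])
  Zp <- bilstm_encode(P, params, params)
  Zrev <- bilstm_encode(P[6:1, ], params, params)
  expect_equal(Zp, Zrev[6:1, c(n + 1:n, 1:n)], tolerance = 1e-12)
  expect_error(bilstm_encode(matrix(0, 0, n), params, params), "empty")
})

test_that("attention is row-stochastic, causal, and handles edge cases", {
  set.seed(34)
  Q <- matrix(rnorm(12), 3)
  K <- matrix(rnorm(16), 4)
  V <- matrix(rnorm(8), 4)
  res <- attention(Q, K, V, return_weights = TRUE)
  expect_equal(rowSums(res$weights), rep(1, 3), tolerance = 1e-6)
  # rows of the output are convex combinations of V rows
  expect_true(all(res$output >= min(V) - 1e-12 & res$output <= max(V) + 1e-12))
  # single key/value: the output is V regardless of Q
  expect_equal(attention(Q, K[1, , drop = FALSE], V[1, , drop = FALSE]),
               matrix(V[1, ], 3, 2, byrow = TRUE))
  # all-equal scores: the column mean of V
  u <- attention(matrix(0, 2, 4), matrix(0, 4, 4), V)
  expect_equal(u, matrix(colMeans(V), 2, 2, byrow = TRUE), tolerance = 1e-12)
  # causal: row 1 only sees V row 1
  Kc <- matrix(rnorm(12), 3)
  resc <- attention(Kc, Kc, V[1:3, ], causal = TRUE, return_weights = TRUE)
  expect_equal(resc$output[1, ], V[1, ])
  expect_true(all(resc$weights[upper.tri(resc$weights)] == 0))
  expect_error(attention(Q, K[, 1:3], V), "dimensions")
  expect_error(attention(Q, K, V[1:3, , drop = FALSE]), "lengths")
})

test_that("ffn_forward composes two linears with a rectifier", {
  set.seed(35)
  # zero weights: constant output = second-layer bias
  z3 <- linear_spec(matrix(0, 3, 3), c(1, 2, 3))
  expect_equal(ffn_forward(matrix(rnorm(6), 2), ffn_spec(z3, z3)),
               matrix(c(1, 2, 3), 2, 3, byrow = TRUE))
  # identity composition leaves nonnegative input unchanged
  id3 <- linear_spec(diag(3))
  Xp <- abs(matrix(rnorm(9), 3))
  expect_equal(ffn_forward(Xp, ffn_spec(id3, id3)), Xp)
  # random instance equals chained linear_forward calls
  a <- linear_spec(matrix(rnorm(9), 3), rnorm(3))
  b <- linear_spec(matrix(rnorm(9), 3), rnorm(3))
  X <- matrix(rnorm(12), 4)
  expect_equal(ffn_forward(X, ffn_spec(a, b)),
               linear_forward(pmax(linear_forward(X, a), 0), b))
})
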