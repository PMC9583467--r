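# The shape calculus, SPS weight generation against the brute-force
# cross-correlation oracle, binding management and parameter accounting.

test_that("kernel shape calculus follows the valid-correlation rule", {
  expect_equal(unname(kernel_shape_for_target(c(10, 105, 105),
                                              c(1, 100, 100))),
               c(10L, 1L, 6L, 6L))
  # a full-extent target forces a 1x1 spatial kernel
  expect_equal(unname(kernel_shape_for_target(c(7, 33, 21), c(1, 33, 21))),
               c(7L, 1L, 1L, 1L))
  # verified by running a valid stride-1 cross-correlation of those shapes
  expect_equal(unname(kernel_shape_for_target(c(4, 8, 8), c(2, 5, 3))),
               c(4L, 2L, 4L, 6L))
  E <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  M <- array(rnorm(4 * 2 * 4 * 6), c(4, 2, 4, 6))
  expect_equal(dim(naive_xcorr(E, M)), c(2L, 5L, 3L))
  expect_error(kernel_shape_for_target(c(10, 261, 261), c(1, 300, 300)),
               "rows")
  expect_error(kernel_shape_for_target(c(10, 261, 261), c(1, 200, 300)),
               "columns")
})

test_that("sps_generate matches the naive cross-correlation oracle", {
  set.seed(101)
  for (trial in 1:25) {
    p <- sample(1:4, 1)
    r <- sample(4:12, 1)
    cc <- sample(4:12, 1)
    p0 <- sample(1:3, 1)
    r0 <- sample(1:r, 1)
    c0 <- sample(1:cc, 1)
    tpl <- sps_template(p, r, cc)
    k <- sps_kernel(tpl, c(p0, r0, c0), activation = "identity")
    expected <- naive_xcorr(tpl$values, k$values) + as.vector(k$bias)
    for (method in c("direct", "fft")) {
      got <- sps_generate(tpl, k, method = method)
      expect_equal(dim(got), c(p0, r0, c0))
      expect_rel_equal(got, expected, tol = 1e-9)
    }
  }
})

test_that("activations and bias broadcast per output slice", {
  set.seed(7)
  tpl <- sps_template(2, 6, 6)
  k <- sps_kernel(tpl, c(2, 4, 4), activation = "tanh")
  k$bias <- c(0.3, -0.2)
  raw <- naive_xcorr(tpl$values, k$values)
  raw[1, , ] <- raw[1, , ] + 0.3
  raw[2, , ] <- raw[2, , ] - 0.2
  expect_rel_equal(sps_generate(tpl, k), tanh(raw), tol = 1e-9)
  k$activation <- "sigmoid"
  expect_rel_equal(sps_generate(tpl, k), 1 / (1 + exp(-raw)), tol = 1e-9)
})

test_that("one-hot kernels copy template windows bit-for-bit", {
  set.seed(13)
  tpl <- sps_template(4, 9, 9)
  # full-extent delta kernel selects a slice exactly
  k <- sps_kernel(tpl, c(1, 9, 9), activation = "identity", init = "zeros")
  k$values[3, 1, 1, 1] <- 1
  expect_identical(sps_generate(tpl, k)[1, , ], tpl$values[3, , ])
  # an offset one-hot kernel copies the shifted sub-window exactly
  k2 <- sps_kernel(tpl, c(1, 6, 6), activation = "identity", init = "zeros")
  k2$values[2, 1, 3, 4] <- 1
  expect_identical(sps_generate(tpl, k2)[1, , ], tpl$values[2, 3:8, 4:9])
  # zero template, tanh: all-zero output
  z <- sps_template(2, 5, 5, init = "zeros")
  kz <- sps_kernel(z, c(1, 4, 4))
  expect_true(all(sps_generate(z, kz) == 0))
})

test_that("bindings validate shapes and reject duplicates", {
  bank <- sps_bank(sps_template(10, 105, 105))
  b <- bind_module(bank, "attn.Wq", "linear", c(100, 100))
  expect_equal(dim(b$kernel$values), c(10L, 1L, 6L, 6L))
  bank2 <- sps_bank(sps_template(8, 96, 96))
  b2 <- bind_module(bank2, "conv", "conv1d", c(64, 64, 3))
  expect_equal(dim(b2$kernel$values), c(8L, 3L, 33L, 33L))
  expect_error(bind_module(bank, "attn.Wq", "linear", c(50, 50)),
               "duplicate")
  bank3 <- sps_bank(sps_template(10, 261, 261))
  expect_error(bind_module(bank3, "big", "linear", c(300, 300)), "exceed")
})

test_that("parameter accounting matches closed forms and the crossover", {
  # dense 100x100 linear with bias: 10,100 parameters
  bank <- sps_bank(sps_template(10, 105, 105))
  bind_module(bank, "lin1", "linear", c(100, 100))
  rep1 <- count_parameters(bank)
  expect_equal(rep1$template_params, 110250)
  m <- rep1$modules
  expect_equal(m$kernel_params, 360)        # 10 * 1 * 6 * 6
  expect_equal(m$sps_bias, 1)
  expect_equal(m$local_bias, 100)
  expect_equal(m$module_shared, 461)
  expect_equal(m$dense_equivalent, 10100)
  # T identical modules: shared beats dense once T exceeds the crossover
  expect_equal(sharing_crossover(rep1), 110250 / (10100 - 461),
               tolerance = 1e-12)
  for (t in 2:14) bind_module(bank, paste0("lin", t), "linear", c(100, 100))
  repT <- count_parameters(bank)
  # affine growth with slope = per-module shared cost
  expect_equal(repT$total_shared, 110250 + 14 * 461)
  expect_equal(repT$dense_equivalent_params, 14 * 10100)
  expect_lt(repT$total_shared, repT$dense_equivalent_params)  # 14 > 11.4
})

test_that("gradients flow from generated weights back into the template", {
  set.seed(3)
  tpl <- sps_template(3, 10, 10)
  bank <- sps_bank(tpl)
  bind_module(bank, "w", "linear", c(6, 6))
  tape <- softshare:::ad_tape()
  tnode <- softshare:::ad_leaf(tape, tpl$values, "template")
  knode <- softshare:::ad_leaf(tape, bank$bindings$w$kernel$values, "kernel")
  multi <- softshare:::ad_sps_multi(tnode, list(knode))
  w <- softshare:::ad_sps_pick(multi, 1)
  # scalar function of the generated weight: sum of entries
  loss <- softshare:::ad_node(tape, sum(w$value), list(w), function(nd) {
    softshare:::ad_accum(w, array(nd$grad, dim(w$value)))
  })
  softshare:::ad_backward(loss)
  expect_true(any(tnode$grad != 0))
  expect_true(any(knode$grad != 0))
})

test_that("randomized targets always generate the exact requested shape", {
  set.seed(77)
  for (trial in 1:30) {
    p <- sample(1:5, 1)
    r <- sample(3:14, 1)
    cc <- sample(3:14, 1)
    tgt <- c(sample(1:4, 1), sample(1:r, 1), sample(1:cc, 1))
    tpl <- sps_template(p, r, cc)
    k <- sps_kernel(tpl, tgt, activation = "identity")
    expect_identical(dim(sps_generate(tpl, k)), as.integer(tgt))
  }
})
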