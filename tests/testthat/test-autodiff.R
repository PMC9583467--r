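# The reverse-mode tape: every fused op is checked against central finite
# differences on small random instances.

fd_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_op_grad <- function(build, params, tol = 1e-5) {
  # build(params) must return the scalar loss node given plain arrays
  tape_loss <- function(vals) {
    softshare:::ad_value(build(vals, record = FALSE))
  }
  nodes <- build(params, record = TRUE)
  softshare:::ad_backward(nodes$loss)
  for (nm in names(params)) {
    fd <- fd_grad(function(x) {
      p2 <- params
      p2[[nm]] <- x
      tape_loss(p2)
    }, params[[nm]])
    got <- nodes$leaves[[nm]]$grad
    expect_lt(max(abs(fd - got)), tol * max(1, max(abs(fd))))
  }
}

test_that("fused affine, FFN and attention ops differentiate correctly", {
  set.seed(21)
  B <- 3L; Tq <- 4L; Tk <- 5L; n <- 4L
  params <- list(X = matrix(rnorm(B * Tq * n), B * Tq),
                 Z = matrix(rnorm(B * Tk * n), B * Tk),
                 Wq = matrix(rnorm(n * n) * 0.5, n),
                 Wk = matrix(rnorm(n * n) * 0.5, n),
                 Wv = matrix(rnorm(n * n) * 0.5, n),
                 bq = rnorm(n), bk = rnorm(n), bv = rnorm(n))
  km <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), each = B)
  build_cross <- function(p, record) {
    tape <- softshare:::ad_tape()
    lv <- lapply(names(p), function(nm) softshare:::ad_leaf(tape, p[[nm]], nm))
    names(lv) <- names(p)
    out <- softshare:::ad_attn_fused(lv$X, lv$Z, lv$Wq, lv$bq, lv$Wk, lv$bk,
                                     lv$Wv, lv$bv, B, Tq, Tk,
                                     key_mask = km)
    g0 <- matrix(seq_len(B * Tq * n) / (B * Tq * n), B * Tq)
    loss <- softshare:::ad_node(tape, sum(out$value * g0), list(out),
                                function(nd) {
      softshare:::ad_accum(out, g0 * nd$grad)
    })
    if (record) list(loss = loss, leaves = lv) else loss
  }
  check_op_grad(build_cross, params)

  # causal self-attention
  params_self <- params[c("X", "Wq", "Wk", "Wv", "bq", "bk", "bv")]
  build_self <- function(p, record) {
    tape <- softshare:::ad_tape()
    lv <- lapply(names(p), function(nm) softshare:::ad_leaf(tape, p[[nm]], nm))
    names(lv) <- names(p)
    out <- softshare:::ad_attn_fused(lv$X, lv$X, lv$Wq, lv$bq, lv$Wk, lv$bk,
                                     lv$Wv, lv$bv, B, Tq, Tq, causal = TRUE)
    g0 <- matrix(rep(0.1, B * Tq * n), B * Tq)
    loss <- softshare:::ad_node(tape, sum(out$value * g0), list(out),
                                function(nd) {
      softshare:::ad_accum(out, g0 * nd$grad)
    })
    if (record) list(loss = loss, leaves = lv) else loss
  }
  check_op_grad(build_self, params_self)

  params_ffn <- list(X = params$X,
                     W1 = matrix(rnorm(n * n) * 0.5, n), b1 = rnorm(n),
                     W2 = matrix(rnorm(n * n) * 0.5, n), b2 = rnorm(n))
  build_ffn <- function(p, record) {
    tape <- softshare:::ad_tape()
    lv <- lapply(names(p), function(nm) softshare:::ad_leaf(tape, p[[nm]], nm))
    names(lv) <- names(p)
    out <- softshare:::ad_ffn_fused(lv$X, lv$W1, lv$b1, lv$W2, lv$b2)
    loss <- softshare:::ad_node(tape, sum(out$value^2), list(out),
                                function(nd) {
      softshare:::ad_accum(out, 2 * out$value * nd$grad)
    })
    if (record) list(loss = loss, leaves = lv) else loss
  }
  check_op_grad(build_ffn, params_ffn)
})

test_that("fused LSTM sequence matches finite differences", {
  set.seed(22)
  B <- 2L; T <- 4L; n <- 3L
  params <- list(X = matrix(rnorm(B * T * n), B * T),
                 W = matrix(rnorm(n * 4 * n) * 0.4, n),
                 U = matrix(rnorm(n * 4 * n) * 0.4, n),
                 b = rnorm(4 * n) * 0.2,
                 h0 = matrix(rnorm(B * n) * 0.3, B))
  build <- function(p, record) {
    tape <- softshare:::ad_tape()
    lv <- lapply(names(p), function(nm) softshare:::ad_leaf(tape, p[[nm]], nm))
    names(lv) <- names(p)
    H <- softshare:::ad_lstm_seq(lv$X, lv$W, lv$U, lv$b, B, T, h0 = lv$h0)
    g0 <- matrix(seq_len(B * T * n) / (B * T * n), B * T)
    loss <- softshare:::ad_node(tape, sum(H$value * g0), list(H),
                                function(nd) {
      softshare:::ad_accum(H, g0 * nd$grad)
    })
    if (record) list(loss = loss, leaves = lv) else loss
  }
  check_op_grad(build, params)
})

test_that("conv1d, maxpool and embedding ops match finite differences", {
  set.seed(23)
  B <- 2L; T <- 5L; n <- 3L; k <- 3L
  mask <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), each = B)
  params <- list(X = matrix(rnorm(B * T * n), B * T),
                 W = array(rnorm(k * n * n) * 0.4, c(k, n, n)),
                 b = rnorm(n))
  build <- function(p, record) {
    tape <- softshare:::ad_tape()
    lv <- lapply(names(p), function(nm) softshare:::ad_leaf(tape, p[[nm]], nm))
    names(lv) <- names(p)
    Y <- softshare:::ad_conv1d_seq(lv$X, lv$W, lv$b, B, T)
    pooled <- softshare:::ad_maxpool_time(Y, B, T, mask)
    loss <- softshare:::ad_node(tape, sum(pooled$value^2), list(pooled),
                                function(nd) {
      softshare:::ad_accum(pooled, 2 * pooled$value * nd$grad)
    })
    if (record) list(loss = loss, leaves = lv) else loss
  }
  check_op_grad(build, params)

  V <- 6L
  ids <- c(2L, 5L, 2L, 1L, 3L, 6L)
  paramsE <- list(W = matrix(rnorm(V * n), V))
  buildE <- function(p, record) {
    tape <- softshare:::ad_tape()
    lv <- list(W = softshare:::ad_leaf(tape, p$W, "W"))
    X <- softshare:::ad_embed(lv$W, ids)
    loss <- softshare:::ad_node(tape, sum(X$value^2), list(X), function(nd) {
      softshare:::ad_accum(X, 2 * X$value * nd$grad)
    })
    if (record) list(loss = loss, leaves = lv) else loss
  }
  check_op_grad(buildE, paramsE)
})

test_that("cross-entropy node agrees with the R closed form and grads", {
  set.seed(24)
  R <- 7L; V <- 5L
  L <- matrix(rnorm(R * V), R)
  tg <- sample.int(V, R, replace = TRUE)
  mask <- c(rep(TRUE, 5), FALSE, TRUE)
  tape <- softshare:::ad_tape()
  ln <- softshare:::ad_leaf(tape, L, "L")
  loss <- softshare:::ad_ce_loss(ln, tg, mask)
  expect_equal(softshare:::ad_value(loss), cross_entropy_loss(L, tg, mask),
               tolerance = 1e-12)
  softshare:::ad_backward(loss)
  fd <- fd_grad(function(x) cross_entropy_loss(matrix(x, R), tg, mask), L)
  expect_lt(max(abs(fd - ln$grad)), 1e-6)
})
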