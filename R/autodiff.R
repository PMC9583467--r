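# Reverse-mode automatic differentiation on a tape of array-valued nodes.
#
# Design notes:
#  * a node is an environment: $value (numeric array/matrix/vector), $grad
#    (NULL until backward reaches it), $parents, $backward (closure), $tape.
#  * constants enter ops as plain numerics; only nodes receive gradients.
#  * sequence batches use a time-major block layout: the row of (time t,
#    batch item b) in a (B*T) x n matrix is (t - 1) * B + b, so each time
#    step is a contiguous row block and per-item series are strided slices.
#  * heavy recurrent / attention / convolution ops are fused: one tape node
#    runs an internal loop in forward and backward, keeping tape overhead
#    negligible next to BLAS time.

`%||%` <- function(a, b) if (is.null(a)) b else a

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

is_ad_node <- function(x) is.environment(x) && !is.null(x$is_node)

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$is_node <- TRUE
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

ad_leaf <- function(tape, value, name = NULL) {
  nd <- ad_node(tape, value)
  nd$name <- name
  nd
}

ad_value <- function(x) if (is_ad_node(x)) x$value else x

tape_of <- function(...) {
  for (x in list(...)) if (is_ad_node(x)) return(x$tape)
  stop("no tape found among operands")
}

ad_accum <- function(nd, g) {
  if (!is_ad_node(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# run backward over the tape from a scalar loss node
ad_backward <- function(loss) {
  stopifnot(is_ad_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  tape <- loss$tape
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

## ---- elementwise and affine ops ------------------------------------------

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape_of(a, b), av %*% bv, list(a, b), function(nd) {
    g <- nd$grad
    if (is_ad_node(a)) ad_accum(a, g %*% t(bv))
    if (is_ad_node(b)) ad_accum(b, crossprod(av, g))
  })
}

ad_add <- function(a, b) {
  ad_node(tape_of(a, b), ad_value(a) + ad_value(b), list(a, b), function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  })
}

# add a length-ncol bias vector to every row
ad_bias_rows <- function(a, bias) {
  av <- ad_value(a)
  v <- av + rep(ad_value(bias), each = nrow(av))
  ad_node(tape_of(a, bias), v, list(a, bias), function(nd) {
    ad_accum(a, nd$grad)
    if (is_ad_node(bias)) ad_accum(bias, colSums(nd$grad))
  })
}

ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape_of(a, b), av * bv, list(a, b), function(nd) {
    if (is_ad_node(a)) ad_accum(a, nd$grad * bv)
    if (is_ad_node(b)) ad_accum(b, nd$grad * av)
  })
}

ad_scale <- function(a, k) {
  ad_node(tape_of(a), ad_value(a) * k, list(a), function(nd) {
    ad_accum(a, nd$grad * k)
  })
}

ad_tanh <- function(a) {
  v <- tanh(ad_value(a))
  ad_node(tape_of(a), v, list(a), function(nd) {
    ad_accum(a, nd$grad * (1 - v * v))
  })
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ad_value(a)))
  ad_node(tape_of(a), v, list(a), function(nd) {
    ad_accum(a, nd$grad * v * (1 - v))
  })
}

ad_relu <- function(a) {
  av <- ad_value(a)
  pos <- av > 0
  ad_node(tape_of(a), av * pos, list(a), function(nd) {
    ad_accum(a, nd$grad * pos)
  })
}

ad_identity_act <- function(a) a

ad_activation <- function(a, activation) {
  switch(activation,
    identity = a,
    tanh = ad_tanh(a),
    sigmoid = ad_sigmoid(a),
    relu = ad_relu(a),
    stop("unknown activation: ", activation)
  )
}

ad_reshape <- function(a, dims) {
  v <- ad_value(a)
  od <- dim(v) %||% length(v)
  ad_node(tape_of(a), array(v, dims), list(a), function(nd) {
    ad_accum(a, array(nd$grad, od))
  })
}

ad_dropout <- function(a, rate, training = TRUE) {
  if (!training || rate <= 0) return(a)
  av <- ad_value(a)
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(av)), nrow(av)) < keep) / keep
  ad_node(tape_of(a), av * mask, list(a), function(nd) {
    ad_accum(a, nd$grad * mask)
  })
}

# parameter-free row normalization: (x - mean) / sd per row. Stabilizes the
# residual Transformer blocks without adding learnable gain/bias.
ad_layernorm <- function(a, eps = 1e-6) {
  x <- ad_value(a)
  m <- rowMeans(x)
  xc <- x - m
  sd <- sqrt(rowMeans(xc * xc) + eps)
  y <- xc / sd
  ad_node(tape_of(a), y, list(a), function(nd) {
    g <- nd$grad
    gx <- (g - rowMeans(g) - y * rowMeans(g * y)) / sd
    ad_accum(a, gx)
  })
}

## ---- gather / scatter ----------------------------------------------------

# row gather with implicit zero row: idx == 0L selects a zero row
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  nc <- ncol(av)
  v <- matrix(0, length(idx), nc)
  keep <- idx > 0L
  v[keep, ] <- av[idx[keep], , drop = FALSE]
  ad_node(tape_of(a), v, list(a), function(nd) {
    g <- nd$grad
    rs <- rowsum(g[keep, , drop = FALSE], group = idx[keep])
    gX <- matrix(0, nrow(av), nc)
    gX[as.integer(rownames(rs)), ] <- rs
    ad_accum(a, gX)
  })
}

# embedding lookup: rows of a (V x n) parameter matrix
ad_embed <- function(W, ids) {
  Wv <- ad_value(W)
  v <- Wv[ids, , drop = FALSE]
  ad_node(tape_of(W), v, list(W), function(nd) {
    rs <- rowsum(nd$grad, group = ids)
    gW <- matrix(0, nrow(Wv), ncol(Wv))
    gW[as.integer(rownames(rs)), ] <- rs
    ad_accum(W, gW)
  })
}

ad_cbind_list <- function(nodes) {
  vals <- lapply(nodes, ad_value)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape_of(nodes[[1]]), do.call(cbind, vals), nodes, function(nd) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], nd$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_rbind_list <- function(nodes) {
  vals <- lapply(nodes, ad_value)
  hs <- vapply(vals, nrow, 0L)
  ends <- cumsum(hs)
  starts <- ends - hs + 1L
  ad_node(tape_of(nodes[[1]]), do.call(rbind, vals), nodes, function(nd) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], nd$grad[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ad_slice_cols <- function(a, j1, j2) {
  av <- ad_value(a)
  ad_node(tape_of(a), av[, j1:j2, drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(av), ncol(av))
    g[, j1:j2] <- nd$grad
    ad_accum(a, g)
  })
}

## ---- losses --------------------------------------------------------------

# mean token-level cross-entropy (natural log) over masked positions;
# forward and the ready-scaled gradient in one C++ pass
ad_ce_loss <- function(logits, targets, mask) {
  res <- cpp_ce_loss(ad_value(logits), as.integer(targets), mask)
  ad_node(tape_of(logits), res$loss, list(logits), function(nd) {
    g <- if (identical(nd$grad, 1)) res$grad else res$grad * nd$grad
    ad_accum(logits, g)
  })
}

ad_mse_loss <- function(pred, target) {
  pv <- ad_value(pred)
  d <- pv - target
  ad_node(tape_of(pred), mean(d * d), list(pred), function(nd) {
    ad_accum(pred, nd$grad * 2 * d / length(d))
  })
}

# weighted sum of scalar loss nodes
ad_wsum <- function(nodes, weights) {
  v <- sum(vapply(nodes, function(n) ad_value(n), 0) * weights)
  ad_node(tape_of(nodes[[1]]), v, nodes, function(nd) {
    for (i in seq_along(nodes)) ad_accum(nodes[[i]], nd$grad * weights[i])
  })
}

## ---- fused affine / FFN / attention blocks -------------------------------

# X %*% W + row-broadcast bias, one node
ad_affine <- function(X, W, b) {
  Xv <- ad_value(X); Wv <- ad_value(W); bv <- ad_value(b)
  v <- Xv %*% Wv
  cpp_add_bias_rows(v, bv)
  ad_node(tape_of(X, W, b), v, list(X, W, b), function(nd) {
    g <- nd$grad
    if (is_ad_node(X)) ad_accum(X, g %*% t(Wv))
    ad_accum(W, crossprod(Xv, g))
    ad_accum(b, colSums(g))
  })
}

# position-wise feed-forward: affine -> ReLU -> (inverted) dropout -> affine
ad_ffn_fused <- function(X, W1, b1, W2, b2, rate = 0, training = FALSE) {
  Xv <- ad_value(X)
  W1v <- ad_value(W1); b1v <- ad_value(b1)
  W2v <- ad_value(W2); b2v <- ad_value(b2)
  H <- Xv %*% W1v
  cpp_add_bias_rows(H, b1v)
  M <- (H > 0) * 1
  if (training && rate > 0) {
    keep <- 1 - rate
    M <- M * ((matrix(stats::runif(length(H)), nrow(H)) < keep) / keep)
  }
  Hd <- H * M
  out <- Hd %*% W2v
  cpp_add_bias_rows(out, b2v)
  ad_node(tape_of(X, W1, b1, W2, b2), out, list(X, W1, b1, W2, b2),
          function(nd) {
    g <- nd$grad
    ad_accum(W2, crossprod(Hd, g))
    ad_accum(b2, colSums(g))
    gH <- (g %*% t(W2v)) * M
    ad_accum(W1, crossprod(Xv, gH))
    ad_accum(b1, colSums(gH))
    if (is_ad_node(X)) ad_accum(X, gH %*% t(W1v))
  })
}

# fused single-head attention block including the Q/K/V projections.
# Xq supplies queries; Xkv keys and values (identical node for
# self-attention: its gradient accumulates both paths).
ad_attn_fused <- function(Xq, Xkv, Wq, bq, Wk, bk, Wv, bv, B, Tq, Tk,
                          causal = FALSE, key_mask = NULL) {
  Xqv <- ad_value(Xq); Xkvv <- ad_value(Xkv)
  self_attn <- identical(Xq, Xkv)
  Wc <- cbind(ad_value(Wq), ad_value(Wk), ad_value(Wv))
  bc <- c(ad_value(bq), ad_value(bk), ad_value(bv))
  n <- ncol(Wc) / 3L
  iq <- 1:n; ik <- n + iq; iv <- 2L * n + iq
  if (self_attn) {
    QKV <- Xqv %*% Wc
    cpp_add_bias_rows(QKV, bc)
    Qv <- QKV[, iq, drop = FALSE]
    Kv <- QKV[, ik, drop = FALSE]
    Vv <- QKV[, iv, drop = FALSE]
  } else {
    Qv <- Xqv %*% Wc[, iq, drop = FALSE]
    cpp_add_bias_rows(Qv, bc[iq])
    KV <- Xkvv %*% Wc[, c(ik, iv), drop = FALSE]
    cpp_add_bias_rows(KV, bc[c(ik, iv)])
    Kv <- KV[, 1:n, drop = FALSE]
    Vv <- KV[, n + 1:n, drop = FALSE]
  }
  fw <- cpp_attn_forward(Qv, Kv, Vv, B, Tq, Tk, causal, key_mask)
  out <- fw$out
  parents <- list(Xq, Xkv, Wq, bq, Wk, bk, Wv, bv)
  ad_node(tape_of(Xq, Wq), out, parents, function(nd) {
    bw <- cpp_attn_backward(nd$grad, Qv, Kv, Vv, fw$ctx)
    gQ <- bw$gQ
    gK <- bw$gK
    gV <- bw$gV
    if (self_attn) {
      gQKV <- cbind(gQ, gK, gV)
      if (is_ad_node(Xq)) ad_accum(Xq, gQKV %*% t(Wc))
      gWc <- crossprod(Xqv, gQKV)
      gbc <- colSums(gQKV)
    } else {
      gKV <- cbind(gK, gV)
      if (is_ad_node(Xq)) ad_accum(Xq, gQ %*% t(Wc[, iq, drop = FALSE]))
      if (is_ad_node(Xkv)) {
        ad_accum(Xkv, gKV %*% t(Wc[, c(ik, iv), drop = FALSE]))
      }
      gWc <- cbind(crossprod(Xqv, gQ), crossprod(Xkvv, gKV))
      gbc <- c(colSums(gQ), colSums(gKV))
    }
    ad_accum(Wq, gWc[, iq, drop = FALSE])
    ad_accum(Wk, gWc[, ik, drop = FALSE])
    ad_accum(Wv, gWc[, iv, drop = FALSE])
    ad_accum(bq, gbc[iq])
    ad_accum(bk, gbc[ik])
    ad_accum(bv, gbc[iv])
  })
}

## ---- fused sequence ops --------------------------------------------------

# full LSTM pass over a padded batch in time-major block layout.
# X: (B*T) x n inputs; W, U: n x 4n (gate order f, d, i, o); b: length 4n.
# Returns the (B*T) x n hidden-state sequence; h0 (B x n) seeds the state.
# Forward and truncated-free BPTT run in C++.
ad_lstm_seq <- function(X, W, U, b, B, T, h0 = NULL) {
  Xv <- ad_value(X); Wv <- ad_value(W); Uv <- ad_value(U); bv <- ad_value(b)
  h0v <- if (is.null(h0)) NULL else ad_value(h0)
  fw <- cpp_lstm_forward(Xv, Wv, Uv, bv, h0v, B, T)
  parents <- list(X, W, U, b)
  if (!is.null(h0)) parents <- c(parents, list(h0))
  ad_node(tape_of(X, W, U, b), fw$H, parents, function(nd) {
    bw <- cpp_lstm_backward(nd$grad, Xv, Wv, Uv, fw$H, fw$ctx)
    if (is_ad_node(X)) ad_accum(X, bw$gX)
    ad_accum(W, bw$gW)
    ad_accum(U, bw$gU)
    ad_accum(b, as.numeric(bw$gb))
    if (!is.null(h0)) ad_accum(h0, bw$gh0)
  })
}

# same-padded 1-D convolution over time. W is a (k, n, n) array (tap j is
# the n x n matrix W[j, , ]); offsets are centred so output length == T.
ad_conv1d_seq <- function(X, W, b, B, T) {
  Xv <- ad_value(X); Wv <- ad_value(W); bv <- ad_value(b)
  k <- dim(Wv)[1]
  n_in <- dim(Wv)[2]
  ctr <- (k + 1L) %/% 2L
  R <- B * T
  shift_idx <- vector("list", k)
  for (j in seq_len(k)) {
    off <- j - ctr
    tsrc <- seq_len(T) + off
    ok <- tsrc >= 1L & tsrc <= T
    idx <- integer(R)
    for (t in seq_len(T)) {
      rows <- ((t - 1L) * B + 1L):(t * B)
      idx[rows] <- if (ok[t]) ((tsrc[t] - 1L) * B + 1L):(tsrc[t] * B) else 0L
    }
    shift_idx[[j]] <- idx
  }
  out <- matrix(rep(bv, each = R), R)
  for (j in seq_len(k)) {
    idx <- shift_idx[[j]]
    keep <- idx > 0L
    Xs <- matrix(0, R, n_in)
    Xs[keep, ] <- Xv[idx[keep], , drop = FALSE]
    out <- out + Xs %*% matrix(Wv[j, , ], n_in)
  }
  ad_node(tape_of(X, W, b), out, list(X, W, b), function(nd) {
    g <- nd$grad
    gW <- array(0, dim(Wv))
    gX <- matrix(0, R, n_in)
    for (j in seq_len(k)) {
      idx <- shift_idx[[j]]
      keep <- idx > 0L
      Xs <- matrix(0, R, n_in)
      Xs[keep, ] <- Xv[idx[keep], , drop = FALSE]
      gW[j, , ] <- crossprod(Xs, g)
      gshift <- g %*% t(matrix(Wv[j, , ], n_in))
      gX[idx[keep], ] <- gX[idx[keep], ] + gshift[keep, , drop = FALSE]
    }
    if (is_ad_node(X)) ad_accum(X, gX)
    ad_accum(W, gW)
    ad_accum(b, colSums(g))
  })
}

# masked global max-pool over time: (B*T) x n -> B x n
ad_maxpool_time <- function(X, B, T, mask) {
  Xv <- ad_value(X)
  n <- ncol(Xv)
  vals <- matrix(-Inf, B, n)
  arg <- matrix(0L, B, n)
  for (t in seq_len(T)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    Xt <- Xv[rows, , drop = FALSE]
    Xt[!mask[rows], ] <- -Inf
    upd <- Xt > vals
    vals[upd] <- Xt[upd]
    arg[upd] <- t
  }
  ad_node(tape_of(X), vals, list(X), function(nd) {
    g <- nd$grad
    gX <- matrix(0, B * T, n)
    rows <- (arg - 1L) * B + matrix(seq_len(B), B, n)
    gX[cbind(as.vector(rows), as.vector(col(arg)))] <- as.vector(g)
    ad_accum(X, gX)
  })
}

## ---- SPS weight generation (multi-output fused op) -----------------------

# generate raw (pre-bias, pre-activation) weights for several bindings from
# one template node; gradients flow back into the template and every kernel.
ad_sps_multi <- function(template_node, kernel_nodes) {
  Ev <- ad_value(template_node)
  FE <- cpp_fft_slices(Ev)
  kvals <- lapply(kernel_nodes, ad_value)
  fw <- cpp_sps_forward_multi(FE, kvals)
  nd <- ad_node(tape_of(template_node), fw$weights,
                c(list(template_node), kernel_nodes), NULL)
  nd$grad_list <- vector("list", length(kernel_nodes))
  nd$backward <- function(node) {
    gouts <- node$grad_list
    if (all(vapply(gouts, is.null, TRUE))) return(invisible(NULL))
    bw <- cpp_sps_backward_multi(FE, kvals, fw$kfft, gouts)
    ad_accum(template_node, bw$dE)
    for (i in seq_along(kernel_nodes)) {
      if (!is.null(gouts[[i]])) ad_accum(kernel_nodes[[i]], bw$dM[[i]])
    }
  }
  # the backward loop triggers on $grad; give the multi node a sentinel that
  # pick nodes set when they deposit into $grad_list
  nd
}

ad_sps_pick <- function(multi, i) {
  v <- multi$value[[i]]
  ad_node(multi$tape, v, list(multi), function(nd) {
    multi$grad_list[[i]] <- if (is.null(multi$grad_list[[i]])) nd$grad else
      multi$grad_list[[i]] + nd$grad
    multi$grad <- 1  # mark the multi node live for the backward sweep
  })
}

# slice-broadcast SPS bias: out[q, , ] = raw[q, , ] + bias[q]
ad_bias_slices <- function(raw, bias) {
  rv <- ad_value(raw)
  p0 <- dim(rv)[1]
  v <- rv + as.vector(ad_value(bias))  # recycles along the first dim
  ad_node(tape_of(raw, bias), v, list(raw, bias), function(nd) {
    ad_accum(raw, nd$grad)
    if (is_ad_node(bias)) {
      ad_accum(bias, rowSums(matrix(nd$grad, p0)))
    }
  })
}
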