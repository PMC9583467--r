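# User-facing numeric primitives: single-sequence forward passes for the
# linear / conv1d / LSTM / attention / FFN blocks that the task networks are
# assembled from. Training runs through the fused autodiff ops; these plain
# implementations are the reference semantics and are cross-checked against
# the fused path in the test-suite.

#' Linear layer specification
#'
#' @param weight `n x m` weight matrix, either dense or produced by
#'   [sps_generate()].
#' @param bias length-`m` local bias `b_l`.
#' @param templated logical flag recording whether `weight` came from the
#'   shared template.
#' @return object of class `linear_spec`.
#' @export
linear_spec <- function(weight, bias = numeric(ncol(weight)),
                        templated = FALSE) {
  weight <- as.matrix(weight)
  stopifnot(length(bias) == ncol(weight))
  structure(list(weight = weight, bias = bias, templated = templated),
            class = "linear_spec")
}

#' Linear forward: `X %*% W + b`, position-wise
#'
#' @param X numeric matrix (rows are positions) or vector of length `n`.
#' @param spec a [linear_spec()].
#' @return matrix with `m` columns (or length-`m` vector for vector input).
#' @export
linear_forward <- function(X, spec) {
  vec_in <- is.null(dim(X))
  if (vec_in) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(spec$weight)) {
    stop(sprintf("input feature dim %d does not match weight rows %d",
                 ncol(X), nrow(spec$weight)))
  }
  out <- X %*% spec$weight + rep(spec$bias, each = nrow(X))
  if (vec_in) drop(out) else out
}

#' 1-D convolution specification
#'
#' The kernel is stored tap-first as a `(k, n, n)` array: `weight[j, , ]` is
#' the `n x n` channel map of tap `j`, matching the layout produced by
#' [sps_generate()] for conv1d bindings (`p0 = k`, `r0 = c0 = n`).
#'
#' @param weight `(k, n, n)` array.
#' @param bias length-`n` local bias `b_c`.
#' @param templated logical provenance flag.
#' @return object of class `conv1d_spec`.
#' @export
conv1d_spec <- function(weight, bias = numeric(dim(weight)[2]),
                        templated = FALSE) {
  stopifnot(length(dim(weight)) == 3, dim(weight)[2] == dim(weight)[3],
            length(bias) == dim(weight)[2])
  structure(list(weight = weight, bias = bias, templated = templated),
            class = "conv1d_spec")
}

#' Same-padded temporal convolution: output length equals input length
#'
#' @param X `T x n` matrix (time by channels).
#' @param spec a [conv1d_spec()].
#' @return `T x n` matrix.
#' @export
conv1d_forward <- function(X, spec) {
  W <- spec$weight
  k <- dim(W)[1]
  n <- dim(W)[2]
  if (ncol(X) != n) {
    stop(sprintf("input channels %d do not match kernel channels %d",
                 ncol(X), n))
  }
  Tn <- nrow(X)
  ctr <- (k + 1L) %/% 2L
  out <- matrix(rep(spec$bias, each = Tn), Tn)
  for (j in seq_len(k)) {
    off <- j - ctr
    tsrc <- seq_len(Tn) + off
    ok <- tsrc >= 1L & tsrc <= Tn
    if (!any(ok)) next
    out[ok, ] <- out[ok, ] + X[tsrc[ok], , drop = FALSE] %*% matrix(W[j, , ], n)
  }
  out
}

#' LSTM cell parameters (gate order: forget, candidate, input, output)
#'
#' Each gate is the sum of two linear maps, one on the input and one on the
#' previous hidden state, plus a bias; all eight `n x n` weight matrices can
#' be SPS-generated.
#'
#' @param W,U lists with elements `f`, `d`, `i`, `o`, each an `n x n`
#'   matrix (`W` acts on the input, `U` on the recurrent state).
#' @param b list with elements `f`, `d`, `i`, `o`, each a length-`n` bias.
#' @return object of class `lstm_cell_params`.
#' @export
lstm_cell_params <- function(W, U, b) {
  stopifnot(all(c("f", "d", "i", "o") %in% names(W)),
            all(c("f", "d", "i", "o") %in% names(U)),
            all(c("f", "d", "i", "o") %in% names(b)))
  structure(list(W = W, U = U, b = b), class = "lstm_cell_params")
}

#' LSTM state (hidden and cell vectors)
#' @param h,c numeric vectors of equal length.
#' @export
lstm_state <- function(h, c) {
  stopifnot(length(h) == length(c))
  structure(list(h = h, c = c), class = "lstm_state")
}

#' One LSTM recurrence step
#'
#' Gates: `g = x W + h U + b`, with logistic squashing on the forget, input
#' and output gates and tanh on the candidate. Updates
#' `c_t = c_{t-1} * g_f + g_d * g_i` and `h_t = g_o * tanh(c_t)`.
#'
#' @param state an [lstm_state()].
#' @param x_t input vector of length `n`.
#' @param params an [lstm_cell_params()].
#' @return the updated [lstm_state()].
#' @export
lstm_cell_step <- function(state, x_t, params) {
  if (!all(is.finite(state$h)) || !all(is.finite(state$c))) {
    stop("non-finite LSTM state")
  }
  gate <- function(g, act) {
    pre <- drop(x_t %*% params$W[[g]]) + drop(state$h %*% params$U[[g]]) +
      params$b[[g]]
    act(pre)
  }
  sigm <- function(z) 1 / (1 + exp(-z))
  f <- gate("f", sigm)
  d <- gate("d", tanh)
  i <- gate("i", sigm)
  o <- gate("o", sigm)
  c_t <- state$c * f + d * i
  lstm_state(h = o * tanh(c_t), c = c_t)
}

lstm_run <- function(X, params, state = NULL) {
  n <- ncol(params$W$f)
  if (is.null(state)) state <- lstm_state(numeric(n), numeric(n))
  H <- matrix(0, nrow(X), n)
  for (t in seq_len(nrow(X))) {
    state <- lstm_cell_step(state, X[t, ], params)
    H[t, ] <- state$h
  }
  H
}

#' Bidirectional LSTM encoding
#'
#' Runs one LSTM over the sequence and a second over its reversal
#' (re-reversed to align positions) and concatenates the two hidden-state
#' tracks along the channel dimension.
#'
#' @param F `T x n` embedded input sequence (nonempty).
#' @param fwd_params,bwd_params [lstm_cell_params()] for the two directions.
#' @return `T x 2n` matrix.
#' @export
bilstm_encode <- function(F, fwd_params, bwd_params = fwd_params) {
  if (nrow(F) < 1) stop("empty input sequence")
  Hf <- lstm_run(F, fwd_params)
  Hb <- lstm_run(F[rev(seq_len(nrow(F))), , drop = FALSE], bwd_params)
  cbind(Hf, Hb[rev(seq_len(nrow(F))), , drop = FALSE])
}

#' Scaled dot-product attention (single head)
#'
#' `softmax(Q K^T / sqrt(n)) V`, rows of the attention matrix summing to 1;
#' with `causal = TRUE` position `i` only attends to keys `j <= i`.
#'
#' @param Q `Tq x n`, `K` `Tk x n`, `V` `Tk x m` matrices.
#' @param K,V key and value matrices.
#' @param causal logical; requires `Tq == Tk`.
#' @param return_weights if `TRUE`, return
#'   `list(output, weights)`.
#' @return `Tq x m` matrix (or a list when `return_weights`).
#' @export
attention <- function(Q, K, V, causal = FALSE, return_weights = FALSE) {
  if (ncol(Q) != ncol(K)) stop("Q and K feature dimensions differ")
  if (nrow(K) != nrow(V)) stop("K and V lengths differ")
  S <- tcrossprod(Q, K) / sqrt(ncol(Q))
  if (causal) {
    if (nrow(Q) != nrow(K)) stop("causal attention requires Tq == Tk")
    S[upper.tri(S)] <- -Inf
  }
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P <- P / rowSums(P)
  out <- P %*% V
  if (return_weights) list(output = out, weights = P) else out
}

#' Position-wise feed-forward specification: linear, ReLU, linear
#'
#' @param inner,outer [linear_spec()]s applied in order with a rectifier
#'   between.
#' @return object of class `ffn_spec`.
#' @export
ffn_spec <- function(inner, outer) {
  structure(list(inner = inner, outer = outer), class = "ffn_spec")
}

#' Feed-forward forward pass
#' @param X input matrix (rows are positions).
#' @param spec an [ffn_spec()].
#' @export
ffn_forward <- function(X, spec) {
  H <- linear_forward(X, spec$inner)
  linear_forward(pmax(H, 0), spec$outer)
}
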