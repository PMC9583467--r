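# The three task networks, assembled from SPS-backed blocks over one shared
# template bank:
#   summary  - BiLSTM encoder + LSTM decoder (Finding -> Impression)
#   severity - two same-padded Conv1D stacks + pooled FFN head (-> scalar)
#   atr      - encoder-decoder Transformer (Finding + Impression -> Treatment)
#
# Every internal n x n weight (LSTM gates, attention projections, FFN
# linears) and every n x n x k convolution kernel is generated from the
# template; embeddings, the 2n -> n encoder-state projection and the output
# heads (vocabulary / scalar) are module-local dense parameters.

#' Model configuration
#'
#' @param n hidden size (must not exceed the template spatial extent when
#'   templated).
#' @param L layer count for the convolution stacks and Transformer blocks.
#' @param vocab_size output vocabulary size `V`.
#' @param conv_k temporal convolution width.
#' @param max_decode maximum decoded length.
#' @param flags_enabled wrap sequences with `<start>`/`<end>`.
#' @param templated generate internal weights from the shared template
#'   (otherwise dense module-local weights of the same shapes).
#' @param dropout dropout rate after embeddings and FFN inner layers
#'   (training only).
#' @return object of class `ss_model_config`.
#' @export
model_config <- function(n = 64, L = 2, vocab_size, conv_k = 3,
                         max_decode = 80, flags_enabled = TRUE,
                         templated = TRUE, dropout = 0.1) {
  stopifnot(n >= 1, L >= 1, vocab_size > length(RESERVED_TOKENS),
            conv_k >= 1)
  structure(list(n = as.integer(n), L = as.integer(L),
                 vocab_size = as.integer(vocab_size),
                 conv_k = as.integer(conv_k),
                 max_decode = as.integer(max_decode),
                 flags_enabled = isTRUE(flags_enabled),
                 templated = isTRUE(templated), dropout = dropout),
            class = "ss_model_config")
}

new_model <- function(task, config, bank) {
  m <- new.env(parent = emptyenv())
  m$task <- task
  m$config <- config
  m$bank <- bank
  m$store <- new.env(parent = emptyenv())
  m$binding_ids <- character()
  class(m) <- "ss_model"
  m
}

#' @export
print.ss_model <- function(x, ...) {
  cat(sprintf("<ss_model:%s> n=%d L=%d V=%d %s\n", x$task, x$config$n,
              x$config$L, x$config$vocab_size,
              if (x$config$templated) "templated" else "dense"))
  invisible(x)
}

par_init <- function(model, name, value) {
  assign(name, value, envir = model$store)
  invisible(NULL)
}

# register an internal module: an SPS binding when templated, otherwise a
# dense local weight of the same shape; always a local activation bias
reg_mod <- function(model, id, kind, dims) {
  qid <- paste(model$task, id, sep = ".")
  if (model$config$templated) {
    bind_module(model$bank, qid, kind, dims)
    model$binding_ids <- c(model$binding_ids, qid)
  } else {
    w <- if (kind == "linear") {
      matrix(xavier_uniform(dims[1] * dims[2], dims[1], dims[2]), dims[1])
    } else {
      array(xavier_uniform(prod(dims), dims[1] * dims[3], dims[2] * dims[3]),
            c(dims[3], dims[1], dims[2]))
    }
    par_init(model, paste0("w/", id), w)
  }
  nb <- if (kind == "linear") dims[2] else dims[1]
  par_init(model, paste0("b/", id), numeric(nb))
  invisible(NULL)
}

dense_linear <- function(model, name, n_in, n_out, scale = 1) {
  par_init(model, paste0("w/", name),
           matrix(scale * xavier_uniform(n_in * n_out, n_in, n_out), n_in))
  par_init(model, paste0("b/", name), numeric(n_out))
}

lstm_block <- function(model, id) {
  n <- model$config$n
  for (g in c("Wf", "Wd", "Wi", "Wo", "Uf", "Ud", "Ui", "Uo")) {
    qid <- paste(model$task, paste0(id, ".", g), sep = ".")
    if (model$config$templated) {
      bind_module(model$bank, qid, "linear", c(n, n))
      model$binding_ids <- c(model$binding_ids, qid)
    } else {
      par_init(model, paste0("w/", id, ".", g),
               matrix(xavier_uniform(n * n, n, n), n))
    }
  }
  # gate biases as one length-4n vector (order f, d, i, o); forget portion
  # starts at 1 so early training keeps cell memory
  b <- numeric(4L * n)
  b[seq_len(n)] <- 1
  par_init(model, paste0("b/", id), b)
}

#' Build the Summary task model (BiLSTM encoder-decoder)
#'
#' @param config a [model_config()].
#' @param bank the shared [sps_bank()].
#' @return an `ss_model`.
#' @export
summary_model <- function(config, bank) {
  m <- new_model("summary", config, bank)
  n <- config$n
  V <- config$vocab_size
  par_init(m, "emb", matrix(xavier_uniform(V * n, V, n), V))
  lstm_block(m, "encf")
  lstm_block(m, "encb")
  lstm_block(m, "dec")
  dense_linear(m, "h0proj", 2L * n, n)
  reg_mod(m, "ffn1", "linear", c(n, n))
  dense_linear(m, "out", n, V)
  m
}

#' Build the Severity task model (dual Conv1D regressor)
#'
#' @inheritParams summary_model
#' @export
severity_model <- function(config, bank) {
  m <- new_model("severity", config, bank)
  n <- config$n
  V <- config$vocab_size
  par_init(m, "emb", matrix(xavier_uniform(V * n, V, n), V))
  for (l in seq_len(config$L)) {
    reg_mod(m, paste0("convF", l), "conv1d", c(n, n, config$conv_k))
    reg_mod(m, paste0("convI", l), "conv1d", c(n, n, config$conv_k))
  }
  reg_mod(m, "head1", "linear", c(n, n))
  # small-scale head: pooled ReLU-conv features have magnitude well above 1,
  # and a full-scale random head starts with exploding MSE gradients that
  # thrash the shared template before the head calibrates
  dense_linear(m, "out", n, 1L, scale = 0.02)
  m
}

#' Build the ATR task model (encoder-decoder Transformer)
#'
#' @inheritParams summary_model
#' @export
atr_model <- function(config, bank) {
  m <- new_model("atr", config, bank)
  n <- config$n
  V <- config$vocab_size
  par_init(m, "emb", matrix(xavier_uniform(V * n, V, n), V))
  for (src in c("F", "I")) {
    for (l in seq_len(config$L)) {
      base <- paste0("enc", src, l)
      for (w in c("Wq", "Wk", "Wv", "ffn1", "ffn2")) {
        reg_mod(m, paste0(base, ".", w), "linear", c(n, n))
      }
    }
  }
  for (l in seq_len(config$L)) {
    base <- paste0("dec", l)
    for (w in c("selfq", "selfk", "selfv", "ffnA1", "ffnA2",
                "crossq", "crossk", "crossv", "ffnB1", "ffnB2")) {
      reg_mod(m, paste0(base, ".", w), "linear", c(n, n))
    }
  }
  dense_linear(m, "out", n, V)
  m
}

## ---- batch context: parameters as tape leaves ----------------------------

# Build one tape spanning one or more models. All templated bindings are
# generated in a single fused SPS op so the template FFT is shared; every
# parameter becomes a named leaf for the optimizer.
model_context <- function(models, training = FALSE) {
  if (inherits(models, "ss_model")) models <- list(models)
  tape <- ad_tape()
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$training <- training
  ctx$params <- list()
  ctx$weights <- list()
  bank <- models[[1]]$bank
  kernel_ids <- unlist(lapply(models, function(m) {
    if (m$config$templated) m$binding_ids else character()
  }))
  if (length(kernel_ids)) {
    tnode <- ad_leaf(tape, bank$template$values, "template")
    ctx$params[["template"]] <- tnode
    knodes <- vector("list", length(kernel_ids))
    for (i in seq_along(kernel_ids)) {
      id <- kernel_ids[i]
      knodes[[i]] <- ad_leaf(tape, bank$bindings[[id]]$kernel$values,
                             paste0("kernel/", id))
      ctx$params[[paste0("kernel/", id)]] <- knodes[[i]]
    }
    multi <- ad_sps_multi(tnode, knodes)
    for (i in seq_along(kernel_ids)) {
      id <- kernel_ids[i]
      bnd <- bank$bindings[[id]]
      sb <- ad_leaf(tape, bnd$kernel$bias, paste0("spsb/", id))
      ctx$params[[paste0("spsb/", id)]] <- sb
      w <- ad_activation(ad_bias_slices(ad_sps_pick(multi, i), sb),
                         bnd$kernel$activation)
      if (bnd$kind == "linear") w <- ad_reshape(w, bnd$target_shape[2:3])
      ctx$weights[[id]] <- w
    }
  }
  for (m in models) {
    for (nm in sort(ls(m$store))) {
      key <- paste0(m$task, "/", nm)
      ctx$params[[key]] <- ad_leaf(tape, get(nm, envir = m$store), key)
    }
  }
  ctx
}

ctx_w <- function(ctx, model, id) {
  w <- if (model$config$templated) {
    ctx$weights[[paste(model$task, id, sep = ".")]]
  }
  # modules outside the template (heads, projections) and dense models keep
  # local weights
  w <- w %||% ctx$params[[paste0(model$task, "/w/", id)]]
  if (is.null(w)) stop("unknown module weight: ", model$task, ".", id)
  w
}

ctx_p <- function(ctx, model, nm) ctx$params[[paste0(model$task, "/", nm)]]

ctx_linear <- function(ctx, model, id, X) {
  ad_affine(X, ctx_w(ctx, model, id), ctx_p(ctx, model, paste0("b/", id)))
}

# fused FFN over two registered linear modules
ctx_ffn <- function(ctx, model, id1, id2, X) {
  ad_ffn_fused(X, ctx_w(ctx, model, id1), ctx_p(ctx, model, paste0("b/", id1)),
               ctx_w(ctx, model, id2), ctx_p(ctx, model, paste0("b/", id2)),
               rate = model$config$dropout, training = ctx$training)
}

# fused attention block over three registered projection modules
ctx_attn <- function(ctx, model, ids, Xq, Xkv, B, Tq, Tk, causal = FALSE,
                     key_mask = NULL) {
  ad_attn_fused(Xq, Xkv,
                ctx_w(ctx, model, ids[1]), ctx_p(ctx, model, paste0("b/", ids[1])),
                ctx_w(ctx, model, ids[2]), ctx_p(ctx, model, paste0("b/", ids[2])),
                ctx_w(ctx, model, ids[3]), ctx_p(ctx, model, paste0("b/", ids[3])),
                B, Tq, Tk, causal = causal, key_mask = key_mask)
}

# write optimizer-updated leaf values back into the bank and model stores
ctx_sync_back <- function(ctx, models) {
  if (inherits(models, "ss_model")) models <- list(models)
  bank <- models[[1]]$bank
  for (key in names(ctx$params)) {
    v <- ctx$params[[key]]$value
    if (key == "template") {
      bank$template$values <- v
    } else if (startsWith(key, "kernel/")) {
      bank$bindings[[substring(key, 8L)]]$kernel$values <- v
    } else if (startsWith(key, "spsb/")) {
      bank$bindings[[substring(key, 6L)]]$kernel$bias <- v
    } else {
      parts <- regmatches(key, regexpr("/", key), invert = TRUE)[[1]]
      m <- models[[which(vapply(models, function(mm) mm$task, "") == parts[1])]]
      assign(parts[2], v, envir = m$store)
    }
  }
  invisible(NULL)
}

## ---- shared forward pieces -----------------------------------------------

.posenc_cache <- new.env(parent = emptyenv())

# positional encoding expanded to the time-major batch layout, memoised
posenc_batch <- function(T, B, n) {
  key <- paste(T, B, n, sep = "x")
  hit <- get0(key, envir = .posenc_cache)
  if (!is.null(hit)) return(hit)
  P <- sinusoid_encoding(T, n)[rep(seq_len(T), each = B), , drop = FALSE]
  assign(key, P, envir = .posenc_cache)
  P
}

sinusoid_encoding <- function(T, n) {
  pos <- seq_len(T)
  P <- matrix(0, T, n)
  for (i in seq_len(ceiling(n / 2))) {
    w <- 1 / 10000^((2 * (i - 1)) / n)
    P[, 2 * i - 1] <- sin(pos * w)
    if (2 * i <= n) P[, 2 * i] <- cos(pos * w)
  }
  P
}

# `zero_pads` multiplies pad positions away; needed where downstream ops mix
# neighbouring positions unmasked (the convolution stacks). The attention
# paths mask pad keys and the losses mask pad targets, so the LSTM and
# Transformer inputs skip the extra pass.
embed_masked <- function(ctx, model, ids, mask, B, T, posenc = FALSE,
                         zero_pads = FALSE) {
  X <- ad_embed(ctx_p(ctx, model, "emb"), ids)
  if (posenc) {
    # scale token embeddings up to the positional-encoding magnitude so
    # position does not drown token identity (the blocks have no residual
    # path to carry it)
    X <- ad_scale(X, sqrt(model$config$n))
    X <- ad_add(X, posenc_batch(T, B, model$config$n))
  }
  if (zero_pads && !all(mask)) {
    X <- ad_mul(X, matrix(as.numeric(mask), length(mask), model$config$n))
  }
  ad_dropout(X, model$config$dropout, ctx$training)
}

lstm_weights <- function(ctx, model, id) {
  Wc <- ad_cbind_list(lapply(c("Wf", "Wd", "Wi", "Wo"), function(g) {
    ctx_w(ctx, model, paste0(id, ".", g))
  }))
  Uc <- ad_cbind_list(lapply(c("Uf", "Ud", "Ui", "Uo"), function(g) {
    ctx_w(ctx, model, paste0(id, ".", g))
  }))
  list(W = Wc, U = Uc, b = ctx_p(ctx, model, paste0("b/", id)))
}


## ---- summary task --------------------------------------------------------

fwd_summary <- function(ctx, model, src, tgt) {
  B <- src$B
  X <- embed_masked(ctx, model, src$ids, src$mask, B, src$T)
  wf <- lstm_weights(ctx, model, "encf")
  Hf <- ad_lstm_seq(X, wf$W, wf$U, wf$b, B, src$T)
  Xr <- ad_rows(X, src$rev_idx)
  wb <- lstm_weights(ctx, model, "encb")
  Hb <- ad_rows(ad_lstm_seq(Xr, wb$W, wb$U, wb$b, B, src$T), src$rev_idx)
  hf_last <- ad_rows(Hf, src$last_idx)
  hb_first <- ad_rows(Hb, seq_len(B))
  enc_final <- ad_cbind_list(list(hf_last, hb_first))
  h0 <- ad_tanh(ctx_linear(ctx, model, "h0proj", enc_final))
  Xt <- embed_masked(ctx, model, tgt$ids_in, tgt$mask, B, tgt$T)
  wd <- lstm_weights(ctx, model, "dec")
  Hd <- ad_lstm_seq(Xt, wd$W, wd$U, wd$b, B, tgt$T, h0 = h0)
  ctx_ffn(ctx, model, "ffn1", "out", Hd)
}

## ---- severity task -------------------------------------------------------

conv_stack <- function(ctx, model, prefix, src) {
  X <- embed_masked(ctx, model, src$ids, src$mask, src$B, src$T,
                    zero_pads = TRUE)
  # re-zero pad positions after every layer so convolution windows never
  # carry pad-derived values back into valid positions
  M <- if (all(src$mask)) NULL else
    matrix(as.numeric(src$mask), length(src$mask), model$config$n)
  for (l in seq_len(model$config$L)) {
    id <- paste0(prefix, l)
    X <- ad_relu(ad_conv1d_seq(X, ctx_w(ctx, model, id),
                               ctx_p(ctx, model, paste0("b/", id)),
                               src$B, src$T))
    if (!is.null(M)) X <- ad_mul(X, M)
  }
  X
}

fwd_severity <- function(ctx, model, srcF, srcI) {
  Xf <- conv_stack(ctx, model, "convF", srcF)
  Xi <- conv_stack(ctx, model, "convI", srcI)
  Z <- ad_rbind_list(list(Xf, Xi))
  pooled <- ad_maxpool_time(Z, srcF$B, srcF$T + srcI$T,
                            c(srcF$mask, srcI$mask))
  # linear regression head: an output squashing would saturate and stall
  # the MSE gradient; predictions are clamped to [0, 1] at reporting time
  ad_reshape(ctx_ffn(ctx, model, "head1", "out", pooled), srcF$B)
}

## ---- ATR task ------------------------------------------------------------

atr_encode <- function(ctx, model, srcF, srcI) {
  B <- srcF$B
  enc_one <- function(src, tag) {
    X <- embed_masked(ctx, model, src$ids, src$mask, B, src$T, posenc = TRUE)
    for (l in seq_len(model$config$L)) {
      base <- paste0("enc", tag, l)
      Xn <- ad_layernorm(X)
      A <- ad_add(X, ctx_attn(ctx, model, paste0(base, c(".Wq", ".Wk", ".Wv")),
                              Xn, Xn, B, src$T, src$T, key_mask = src$mask))
      X <- ad_add(A, ctx_ffn(ctx, model, paste0(base, ".ffn1"),
                             paste0(base, ".ffn2"), ad_layernorm(A)))
    }
    ad_layernorm(X)
  }
  Z <- ad_rbind_list(list(enc_one(srcF, "F"), enc_one(srcI, "I")))
  list(Z = Z, T = srcF$T + srcI$T, mask = c(srcF$mask, srcI$mask))
}

fwd_atr <- function(ctx, model, srcF, srcI, tgt) {
  B <- srcF$B
  mem <- atr_encode(ctx, model, srcF, srcI)
  X <- embed_masked(ctx, model, tgt$ids_in, tgt$mask, B, tgt$T,
                    posenc = TRUE)
  for (l in seq_len(model$config$L)) {
    base <- paste0("dec", l)
    Xn <- ad_layernorm(X)
    A <- ad_add(X, ctx_attn(ctx, model,
                            paste0(base, c(".selfq", ".selfk", ".selfv")),
                            Xn, Xn, B, tgt$T, tgt$T, causal = TRUE,
                            key_mask = tgt$mask))
    A <- ad_add(A, ctx_ffn(ctx, model, paste0(base, ".ffnA1"),
                           paste0(base, ".ffnA2"), ad_layernorm(A)))
    A2 <- ad_add(A, ctx_attn(ctx, model,
                             paste0(base, c(".crossq", ".crossk", ".crossv")),
                             ad_layernorm(A), mem$Z, B, tgt$T, mem$T,
                             key_mask = mem$mask))
    X <- ad_add(A2, ctx_ffn(ctx, model, paste0(base, ".ffnB1"),
                            paste0(base, ".ffnB2"), ad_layernorm(A2)))
  }
  ctx_linear(ctx, model, "out", ad_layernorm(X))
}

# per-token encoder representation of one record's Finding (diagnostics)
atr_encode_representation <- function(model, bank, record) {
  flags <- model$config$flags_enabled
  srcF <- collate_source(record$finding, flags)
  srcI <- collate_source(record$impression, flags)
  ctx <- model_context(model, training = FALSE)
  mem <- atr_encode(ctx, model, srcF, srcI)
  ad_value(mem$Z)[seq_len(srcF$T), , drop = FALSE]
}

## ---- public forwards (single batch, teacher forcing) ---------------------

#' Teacher-forced forward pass of the Summary model
#'
#' Encodes the Finding with the BiLSTM, initializes the decoder LSTM from
#' the projected final encoder state, consumes the shifted gold Impression
#' and returns per-position vocabulary logits.
#'
#' @param F list of Finding token id sequences (or a single integer
#'   vector).
#' @param I_teacher list of gold Impression sequences aligned with `F`.
#' @param model an `ss_model` from [summary_model()].
#' @return for a single record, a `T x V` logits matrix; for a batch, the
#'   stacked time-major matrix with attribute `batch` describing the
#'   layout.
#' @export
summary_forward <- function(F, I_teacher, model) {
  single <- !is.list(F)
  if (single) {
    F <- list(as.integer(F))
    I_teacher <- list(as.integer(I_teacher))
  }
  check_token_ids(c(F, I_teacher), model$config$vocab_size)
  flags <- model$config$flags_enabled
  src <- collate_source(F, flags)
  tgt <- collate_target(I_teacher, flags)
  ctx <- model_context(model, training = FALSE)
  logits <- ad_value(fwd_summary(ctx, model, src, tgt))
  finish_logits(logits, tgt, single)
}

#' Forward pass of the Severity model
#'
#' @param F,I lists of Finding / Impression token id sequences (or single
#'   integer vectors).
#' @param model an `ss_model` from [severity_model()].
#' @return numeric vector of severity scores in (0, 1), one per record.
#' @export
severity_forward <- function(F, I, model) {
  single <- !is.list(F)
  if (single) {
    F <- list(as.integer(F))
    I <- list(as.integer(I))
  }
  if (any(lengths(F) == 0) || any(lengths(I) == 0)) stop("empty input")
  check_token_ids(c(F, I), model$config$vocab_size)
  flags <- model$config$flags_enabled
  srcF <- collate_source(F, flags)
  srcI <- collate_source(I, flags)
  ctx <- model_context(model, training = FALSE)
  pmin(pmax(as.numeric(ad_value(fwd_severity(ctx, model, srcF, srcI))), 0), 1)
}

#' Teacher-forced forward pass of the ATR model
#'
#' @param F,I lists of source token id sequences.
#' @param T_teacher list of gold Treatment sequences.
#' @param model an `ss_model` from [atr_model()].
#' @return logits as in [summary_forward()].
#' @export
atr_forward <- function(F, I, T_teacher, model) {
  single <- !is.list(F)
  if (single) {
    F <- list(as.integer(F))
    I <- list(as.integer(I))
    T_teacher <- list(as.integer(T_teacher))
  }
  if (any(lengths(F) == 0) || any(lengths(I) == 0) ||
      any(lengths(T_teacher) == 0)) {
    stop("empty input sequence")
  }
  check_token_ids(c(F, I, T_teacher), model$config$vocab_size)
  flags <- model$config$flags_enabled
  srcF <- collate_source(F, flags)
  srcI <- collate_source(I, flags)
  tgt <- collate_target(T_teacher, flags)
  ctx <- model_context(model, training = FALSE)
  logits <- ad_value(fwd_atr(ctx, model, srcF, srcI, tgt))
  finish_logits(logits, tgt, single)
}

check_token_ids <- function(seq_list, V) {
  mx <- max(unlist(seq_list), 0L)
  if (mx > V) stop(sprintf("token id %d exceeds vocabulary size %d", mx, V))
  invisible(NULL)
}

finish_logits <- function(logits, tgt, single) {
  if (single) {
    # B == 1: time-major rows are already 1..T
    logits[seq_len(tgt$lengths[1]), , drop = FALSE]
  } else {
    attr(logits, "batch") <- tgt
    logits
  }
}

#' Greedy autoregressive decoding
#'
#' Starts from `<start>` (flags mode) or an empty context, appends the
#' argmax token at each step and stops at `<end>` or `max_len`.
#' Deterministic given the model.
#'
#' @param model an `ss_model` (summary or atr).
#' @param sources named list: `finding` for summary; `finding` and
#'   `impression` for atr (single integer vectors).
#' @param max_len maximum generated length (>= 1).
#' @return integer vector of generated token ids (sentinels stripped).
#' @export
greedy_decode <- function(model, sources, max_len = model$config$max_decode) {
  stopifnot(max_len >= 1)
  flags <- model$config$flags_enabled
  gen <- integer()
  for (step in seq_len(max_len)) {
    logits <- if (model$task == "summary") {
      decode_step_logits(model, list(F = sources$finding), gen)
    } else {
      decode_step_logits(model, list(F = sources$finding,
                                     I = sources$impression), gen)
    }
    nxt <- which.max(logits)
    if (flags && nxt == END_ID) break
    gen <- c(gen, nxt)
  }
  gen[gen > length(RESERVED_TOKENS)]
}

decode_step_logits <- function(model, src_list, gen) {
  flags <- model$config$flags_enabled
  # teacher input = <start>/<pad> then generated-so-far; logits of the last
  # position score the next token
  tgt <- list(
    ids_in = c(if (flags) START_ID else PAD_ID, gen),
    mask = rep(TRUE, length(gen) + 1L)
  )
  tgt$ids_out <- c(gen, PAD_ID)
  tgt$lengths <- length(tgt$ids_in)
  tgt$B <- 1L
  tgt$T <- length(tgt$ids_in)
  ctx <- model_context(model, training = FALSE)
  logits <- if (model$task == "summary") {
    src <- collate_source(list(src_list$F), flags)
    ad_value(fwd_summary(ctx, model, src, tgt))
  } else {
    srcF <- collate_source(list(src_list$F), flags)
    srcI <- collate_source(list(src_list$I), flags)
    ad_value(fwd_atr(ctx, model, srcF, srcI, tgt))
  }
  logits[nrow(logits), ]
}

## ---- checkpoint plumbing -------------------------------------------------

model_state <- function(model) {
  list(task = model$task, config = model$config,
       locals = as.list(model$store, sorted = TRUE),
       binding_ids = model$binding_ids)
}

model_restore <- function(state, bank) {
  m <- new_model(state$task, state$config, bank)
  for (nm in names(state$locals)) assign(nm, state$locals[[nm]], m$store)
  m$binding_ids <- state$binding_ids
  m
}
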