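# Losses, the MLL metric, the epoch-indexed learning-rate schedule, the
# per-task training loop (regenerate shared weights -> forward -> backward ->
# joint Adam update of template, kernels and module-local parameters), and
# the independent / collaborative multi-task orchestration with the
# auxiliary-first ordering Summary -> Severity -> ATR.

#' Training configuration
#'
#' @param initial_lr initial learning rate (default 0.01).
#' @param epoch_max horizon of the learning-rate schedule (default 40).
#' @param decay_factor,decay_base constants of the schedule
#'   `lr_{i+1} = decay_factor * lr_i * decay_base^((i + 0.01)/(epoch_max + 0.01))`.
#' @param batch_size minibatch size.
#' @param mode auxiliary-task preference: `"none"`, `"summary"`,
#'   `"severity"`, or `"both"`.
#' @param schedule `"independent"` (tasks trained one-by-one on the evolving
#'   template) or `"collaborative"` (per-batch weighted loss sum).
#' @param flags_enabled wrap sequences with `<start>`/`<end>` sentinels.
#' @param loss_weights named weights (summary, severity, atr) for the
#'   collaborative loss sum.
#' @param epochs named epoch counts per phase (summary, severity, atr).
#' @param grad_clip global gradient-norm clip.
#' @param lr_floor epochs whose scheduled learning rate falls below this
#'   floor are skipped: with Adam the parameter drift of such an epoch is
#'   bounded by roughly `lr * batches` (about 1e-4 at the default floor),
#'   numerically negligible next to the parameter scale. Set to 0 to run
#'   every epoch regardless.
#' @param seed integer seed for all randomness of the run.
#' @return object of class `ss_train_config`.
#' @export
train_config <- function(initial_lr = 0.01, epoch_max = 40,
                         decay_factor = 0.8, decay_base = 0.01,
                         batch_size = 32,
                         mode = c("both", "none", "summary", "severity"),
                         schedule = c("independent", "collaborative"),
                         flags_enabled = TRUE,
                         loss_weights = c(summary = 1, severity = 1, atr = 1),
                         epochs = c(summary = 40, severity = 40, atr = 40),
                         grad_clip = 1.0, lr_floor = 1e-5, seed = 1L) {
  mode <- match.arg(mode)
  schedule <- match.arg(schedule)
  stopifnot(epoch_max >= 1, all(loss_weights >= 0), all(epochs >= 0),
            batch_size >= 1)
  structure(list(initial_lr = initial_lr, epoch_max = as.integer(epoch_max),
                 decay_factor = decay_factor, decay_base = decay_base,
                 batch_size = as.integer(batch_size), mode = mode,
                 schedule = schedule, flags_enabled = isTRUE(flags_enabled),
                 loss_weights = loss_weights, epochs = epochs,
                 grad_clip = grad_clip, lr_floor = lr_floor,
                 seed = as.integer(seed)),
            class = "ss_train_config")
}

#' Learning rate at an epoch index
#'
#' `lr_0 = initial_lr`, then
#' `lr_{i+1} = decay_factor * lr_i * decay_base^((i + 0.01) / (epoch_max + 0.01))`;
#' strictly decreasing.
#'
#' @param i epoch index from 0 (`0 <= i <= epoch_max`).
#' @param cfg a [train_config()] (fields `initial_lr`, `epoch_max`,
#'   `decay_factor`, `decay_base`).
#' @return the learning rate for epoch `i`.
#' @examples
#' lr_at_epoch(0, train_config()) # 0.01
#' @export
lr_at_epoch <- function(i, cfg = train_config()) {
  if (i < 0) stop("negative epoch index")
  lr_schedule(i + 1, initial_lr = cfg$initial_lr,
              epoch_max = cfg$epoch_max, decay_factor = cfg$decay_factor,
              decay_base = cfg$decay_base)[i + 1]
}

lr_schedule <- function(n, initial_lr = 0.01, epoch_max = 40,
                        decay_factor = 0.8, decay_base = 0.01) {
  lr <- numeric(n)
  lr[1] <- initial_lr
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      lr[i + 1] <- decay_factor * lr[i] *
        decay_base^((i - 1 + 0.01) / (epoch_max + 0.01))
    }
  }
  lr
}

#' Minus-log-loss score
#'
#' `MLL(loss) = -log(loss)` (natural log of the mean loss); larger is
#' better.
#'
#' @param loss positive mean loss.
#' @return numeric MLL.
#' @export
mll_score <- function(loss) {
  if (any(!is.finite(loss)) || any(loss <= 0)) {
    stop("mll_score is defined for positive finite losses only")
  }
  -log(loss)
}

#' Mean token-level cross-entropy from logits (natural log)
#'
#' @param logits `R x V` matrix of unnormalized scores.
#' @param targets integer target ids (length `R`).
#' @param mask logical vector; positions with `FALSE` (e.g. padding) are
#'   excluded from the mean.
#' @return mean negative log-likelihood over the masked positions.
#' @export
cross_entropy_loss <- function(logits, targets, mask = NULL) {
  R <- nrow(logits)
  if (is.null(mask)) mask <- rep(TRUE, R)
  mx <- logits[cbind(seq_len(R), max.col(logits, ties.method = "first"))]
  Ls <- logits - mx
  lp <- Ls[cbind(seq_len(R), targets)] - log(rowSums(exp(Ls)))
  -mean(lp[mask])
}

#' Per-task loss on a batch of records
#'
#' Summary / ATR: mean token-level cross-entropy over non-pad teacher-forced
#' target positions. Severity: mean squared error on the label normalized
#' to `[0, 1]` (divided by 5).
#'
#' @param task `"summary"`, `"severity"`, or `"atr"`.
#' @param records corpus tibble rows with the fields the task needs.
#' @param model the matching `ss_model`.
#' @return numeric scalar loss (evaluation mode: no dropout).
#' @export
task_loss <- function(task, records, model) {
  ctx <- model_context(model, training = FALSE)
  ad_value(task_loss_node(ctx, model, task, records))
}

task_loss_node <- function(ctx, model, task, records) {
  flags <- model$config$flags_enabled
  if (task == "summary") {
    if (any(lengths(records$finding) == 0)) stop("empty finding sequence")
    src <- collate_source(records$finding, flags)
    tgt <- collate_target(records$impression, flags)
    logits <- fwd_summary(ctx, model, src, tgt)
    ad_ce_loss(logits, tgt$ids_out, tgt$mask)
  } else if (task == "severity") {
    srcF <- collate_source(records$finding, flags)
    srcI <- collate_source(records$impression, flags)
    pred <- fwd_severity(ctx, model, srcF, srcI)
    ad_mse_loss(pred, records$severity / 5)
  } else if (task == "atr") {
    srcF <- collate_source(records$finding, flags)
    srcI <- collate_source(records$impression, flags)
    tgt <- collate_target(records$treatment, flags)
    logits <- fwd_atr(ctx, model, srcF, srcI, tgt)
    ad_ce_loss(logits, tgt$ids_out, tgt$mask)
  } else {
    stop("unknown task: ", task)
  }
}

## ---- Adam ----------------------------------------------------------------

# shuffled length-bucketed minibatches: shuffle, pool, sort each pool by
# record length, cut batches, shuffle batch order. Keeps SGD stochastic
# while trimming padding waste.
make_batches <- function(records, batch_size, pool_factor = 8L) {
  n <- nrow(records)
  lens <- lengths(records$finding) + lengths(records$impression) +
    lengths(records$treatment)
  ord <- sample.int(n)
  pool_size <- pool_factor * batch_size
  batches <- list()
  for (start in seq(1, n, by = pool_size)) {
    pool <- ord[start:min(start + pool_size - 1, n)]
    pool <- pool[order(lens[pool])]
    for (bs in seq(1, length(pool), by = batch_size)) {
      batches[[length(batches) + 1]] <-
        pool[bs:min(bs + batch_size - 1, length(pool))]
    }
  }
  batches[sample.int(length(batches))]
}

adam_new <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- list()
  st$v <- list()
  st$t <- 0L
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st
}

adam_step <- function(opt, ctx, lr, grad_clip = 1.0) {
  grads <- list()
  for (key in names(ctx$params)) {
    g <- ctx$params[[key]]$grad
    if (!is.null(g)) grads[[key]] <- g
  }
  if (!length(grads)) return(invisible(0))
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (!is.finite(gnorm)) stop("non-finite gradient norm")
  scale <- if (gnorm > grad_clip) grad_clip / gnorm else 1
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(opt$m[[key]])) {
      opt$m[[key]] <- numeric(length(g))
      opt$v[[key]] <- numeric(length(g))
    }
    # updates value (and the bank/store arrays it aliases), m, v in place
    cpp_adam_update(ctx$params[[key]]$value, g, opt$m[[key]], opt$v[[key]],
                    lr, opt$beta1, opt$beta2, opt$eps, bc1, bc2, scale)
  }
  invisible(gnorm)
}

## ---- evaluation ----------------------------------------------------------

#' Evaluate a task model on a corpus split
#'
#' Teacher-forced loss (dropout off), pooled over all target tokens of the
#' split, and its MLL. Deterministic.
#'
#' @param model an `ss_model`.
#' @param records corpus tibble (e.g. a dev or test split).
#' @param task task name; defaults to the model's own task.
#' @param batch_size evaluation batch size.
#' @return one-row tibble with `task`, `loss`, `mll`, `n_records`.
#' @export
evaluate <- function(model, records, task = model$task, batch_size = 64) {
  n <- nrow(records)
  tot <- 0
  wt <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    batch <- records[idx, ]
    ctx <- model_context(model, training = FALSE)
    l <- ad_value(task_loss_node(ctx, model, task, batch))
    w <- if (task == "severity") length(idx) else {
      tgt <- collate_target(
        if (task == "summary") batch$impression else batch$treatment,
        model$config$flags_enabled)
      sum(tgt$mask)
    }
    tot <- tot + l * w
    wt <- wt + w
  }
  loss <- tot / wt
  tibble::tibble(task = task, loss = loss, mll = mll_score(loss),
                 n_records = n)
}

## ---- per-task training loop ----------------------------------------------

#' Train one task on the shared template
#'
#' For each epoch and minibatch the shared weights are regenerated from the
#' template through every binding's kernel, the loss is evaluated with
#' teacher forcing, and the gradients update template, kernels, SPS biases
#' and module-local parameters jointly through Adam with the epoch-indexed
#' learning-rate schedule.
#'
#' @param task `"summary"`, `"severity"`, or `"atr"`.
#' @param splits list with `train` and `dev` corpus tibbles.
#' @param model the task's `ss_model` (its bank holds the template).
#' @param cfg a [train_config()].
#' @param n_epochs epoch count (default from `cfg$epochs`); 0 leaves every
#'   parameter untouched.
#' @param lr_override optional learning rate(s) replacing the schedule
#'   (scalar, or one value per epoch; used by small overfitting
#'   diagnostics).
#' @param epoch_max_override horizon for the schedule; defaults to
#'   `cfg$epoch_max` (the schedule horizon is a fixed constant, not the
#'   phase length).
#' @return metrics tibble (class `ss_metrics`) with one row per epoch.
#' @export
train_task <- function(task, splits, model, cfg = train_config(),
                       n_epochs = cfg$epochs[[task]], lr_override = NULL,
                       epoch_max_override = NULL) {
  if (n_epochs == 0) {
    return(empty_metrics())
  }
  opt <- adam_new()
  lrs <- if (is.null(lr_override)) {
    lr_schedule(n_epochs, cfg$initial_lr,
                epoch_max_override %||% cfg$epoch_max, cfg$decay_factor,
                cfg$decay_base)
  } else rep(lr_override, length.out = n_epochs)
  train <- splits$train
  out <- vector("list", n_epochs)
  for (ep in seq_len(n_epochs)) {
    if (lrs[ep] < (cfg$lr_floor %||% 0)) break
    batch_losses <- c()
    for (idx in make_batches(train, cfg$batch_size)) {
      ctx <- model_context(model, training = TRUE)
      loss <- task_loss_node(ctx, model, task, train[idx, ])
      lv <- ad_value(loss)
      if (!is.finite(lv)) {
        stop(sprintf("divergence: non-finite %s loss at epoch %d (lr %.3g)",
                     task, ep, lrs[ep]))
      }
      ad_backward(loss)
      adam_step(opt, ctx, lrs[ep], cfg$grad_clip)
      ctx_sync_back(ctx, model)
      batch_losses <- c(batch_losses, lv)
    }
    dev <- if (!is.null(splits$dev) && nrow(splits$dev) > 0) {
      evaluate(model, splits$dev, task)
    } else tibble::tibble(loss = NA_real_, mll = NA_real_)
    out[[ep]] <- tibble::tibble(task = task, epoch = ep, lr = lrs[ep],
                                train_loss = mean(batch_losses),
                                dev_loss = dev$loss, dev_mll = dev$mll)
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(empty_metrics())
  structure(do.call(rbind, out), class = c("ss_metrics", class(out[[1]])))
}

empty_metrics <- function() {
  structure(tibble::tibble(task = character(), epoch = integer(),
                           lr = numeric(), train_loss = numeric(),
                           dev_loss = numeric(), dev_mll = numeric()),
            class = c("ss_metrics", class(tibble::tibble())))
}

## ---- multi-task orchestration --------------------------------------------

#' Run a full multi-task training schedule
#'
#' Builds the template bank and the models the preference asks for, then
#' trains. Independent schedule: full training of Summary, then Severity,
#' then ATR, each on the evolving shared template, with the optimizer reset
#' between phases. Collaborative schedule: per epoch and per minibatch, the
#' weighted sum of the task losses (same task order) is backpropagated in
#' one step. Preference `"none"` trains the ATR model alone.
#'
#' @param corpus corpus tibble (with its generator config attached) or a
#'   list of precomputed splits (`train`, `dev`, `test`).
#' @param cfg a [train_config()].
#' @param mcfg a [model_config()]; its `flags_enabled` is overridden by
#'   `cfg$flags_enabled`.
#' @param template_shape `(p, r, c)` of the global template.
#' @param vocab optional vocabulary stored with checkpoints.
#' @param log_dev evaluate the development split after every epoch (turn
#'   off to trade the per-epoch MLL log for speed; final dev/test MLL is
#'   always reported).
#' @return a run object (class `ss_run`): `bank`, `models`, `metrics`,
#'   `final` (dev/test MLL of the ATR task), `config`, `seed`.
#' @export
run_schedule <- function(corpus, cfg = train_config(), mcfg = NULL,
                         template_shape = c(8, 96, 96), vocab = NULL,
                         log_dev = TRUE) {
  set.seed(cfg$seed)
  splits <- if (is.data.frame(corpus)) split_corpus(corpus) else corpus
  if (is.null(mcfg)) {
    stop("mcfg (model_config) is required")
  }
  mcfg$flags_enabled <- cfg$flags_enabled
  bank <- sps_bank(sps_template(template_shape[1], template_shape[2],
                                template_shape[3]))
  tasks <- switch(cfg$mode,
    none = "atr",
    summary = c("summary", "atr"),
    severity = c("severity", "atr"),
    both = c("summary", "severity", "atr")
  )
  models <- list()
  for (task in tasks) {
    models[[task]] <- switch(task,
      summary = summary_model(mcfg, bank),
      severity = severity_model(mcfg, bank),
      atr = atr_model(mcfg, bank)
    )
  }
  phase_splits <- if (log_dev) splits else list(train = splits$train)
  metrics <- empty_metrics()
  if (cfg$schedule == "independent" || length(tasks) == 1) {
    for (task in tasks) {
      ph <- train_task(task, phase_splits, models[[task]], cfg,
                       n_epochs = cfg$epochs[[task]])
      metrics <- rbind(metrics, ph)
    }
  } else {
    metrics <- train_collaborative(tasks, phase_splits, models, cfg)
  }
  final <- rbind(
    cbind(split = "dev", evaluate(models$atr, splits$dev)),
    cbind(split = "test", evaluate(models$atr, splits$test))
  )
  structure(list(bank = bank, models = models, metrics = metrics,
                 final = tibble::as_tibble(final), vocab = vocab,
                 config = list(train = cfg, model = mcfg,
                               template_shape = template_shape),
                 seed = cfg$seed),
            class = "ss_run")
}

#' @export
print.ss_run <- function(x, ...) {
  cat(sprintf("<ss_run> mode=%s schedule=%s flags=%s\n",
              x$config$train$mode, x$config$train$schedule,
              x$config$train$flags_enabled))
  print(x$final)
  invisible(x)
}

train_collaborative <- function(tasks, splits, models, cfg) {
  opt <- adam_new()
  n_epochs <- cfg$epochs[["atr"]]
  lrs <- lr_schedule(n_epochs, cfg$initial_lr, cfg$epoch_max,
                     cfg$decay_factor, cfg$decay_base)
  train <- splits$train
  wts <- cfg$loss_weights[tasks]
  out <- vector("list", n_epochs)
  for (ep in seq_len(n_epochs)) {
    if (lrs[ep] < (cfg$lr_floor %||% 0)) break
    batch_losses <- c()
    for (idx in make_batches(train, cfg$batch_size)) {
      ctx <- model_context(unname(models), training = TRUE)
      parts <- lapply(tasks, function(task) {
        task_loss_node(ctx, models[[task]], task, train[idx, ])
      })
      loss <- ad_wsum(parts, wts)
      lv <- ad_value(loss)
      if (!is.finite(lv)) {
        stop(sprintf("divergence: non-finite collaborative loss at epoch %d",
                     ep))
      }
      ad_backward(loss)
      adam_step(opt, ctx, lrs[ep], cfg$grad_clip)
      ctx_sync_back(ctx, unname(models))
      batch_losses <- c(batch_losses, lv)
    }
    dev <- if (!is.null(splits$dev)) evaluate(models$atr, splits$dev) else
      tibble::tibble(loss = NA_real_, mll = NA_real_)
    out[[ep]] <- tibble::tibble(task = "collaborative", epoch = ep,
                                lr = lrs[ep],
                                train_loss = mean(batch_losses),
                                dev_loss = dev$loss, dev_mll = dev$mll)
  }
  structure(do.call(rbind, out), class = c("ss_metrics", class(out[[1]])))
}

## ---- parameter reporting over a run --------------------------------------

#' Parameter report for trained models
#'
#' One row per module: templated modules show kernel + SPS-bias + local-bias
#' counts next to their dense equivalents; module-local parameters
#' (embeddings, projections, heads) are their own dense cost. The template
#' is counted once, globally.
#'
#' @param run an `ss_run`, or a named list of `ss_model`s sharing one bank.
#' @return tibble (class `ss_param_report_table`) with attribute `totals`.
#' @export
param_report <- function(run) {
  models <- if (inherits(run, "ss_run")) run$models else run
  bank <- models[[1]]$bank
  rows <- list()
  for (b in bank$bindings) {
    ts <- b$target_shape
    rows[[length(rows) + 1]] <- tibble::tibble(
      module_id = b$module_id, kind = b$kind,
      stored_params = prod(dim(b$kernel$values)) + ts[1],
      dense_equivalent = prod(ts))
  }
  for (m in models) {
    for (nm in sort(ls(m$store))) {
      v <- get(nm, envir = m$store)
      rows[[length(rows) + 1]] <- tibble::tibble(
        module_id = paste(m$task, nm, sep = "/"), kind = "local",
        stored_params = length(v), dense_equivalent = length(v))
    }
  }
  tab <- do.call(rbind, rows)
  tpl <- bank$template
  template_params <- if (length(bank$bindings)) tpl$p * tpl$r * tpl$c else 0
  totals <- list(
    template_params = template_params,
    total_shared = template_params + sum(tab$stored_params),
    dense_equivalent_params = sum(tab$dense_equivalent)
  )
  attr(tab, "totals") <- totals
  class(tab) <- c("ss_param_report_table", class(tab))
  tab
}
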