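# Schedule closed forms, the MLL metric, task losses, optimizer behaviour,
# knowledge propagation through the shared template, and evaluation.

test_that("the learning-rate schedule matches its closed forms", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 0.01)
  # one recurrence step: 0.8 * 0.01 * 0.01^(0.01 / 40.01)
  expect_equal(lr_at_epoch(1, cfg), 0.8 * 0.01 * 0.01^(0.01 / 40.01),
               tolerance = 1e-12)
  expect_equal(lr_at_epoch(1, cfg), 0.0079908, tolerance = 1e-4)
  lrs <- vapply(0:40, lr_at_epoch, 0, cfg = cfg)
  expect_true(all(diff(lrs) < 0))
  expect_error(lr_at_epoch(-1, cfg), "negative")
  # monotone for any horizon
  for (em in c(1, 5, 17)) {
    l <- softshare:::lr_schedule(em + 1, epoch_max = em)
    expect_true(all(diff(l) < 0))
  }
})

test_that("mll_score is the negative natural log of the loss", {
  expect_equal(mll_score(1), 0)
  expect_equal(mll_score(exp(-2)), 2)
  expect_equal(mll_score(0.1), 2.302585, tolerance = 1e-6)
  grid <- seq(0.05, 2, by = 0.05)
  expect_equal(exp(-mll_score(grid)), grid, tolerance = 1e-12)
  expect_error(mll_score(0), "positive")
  expect_error(mll_score(-1), "positive")
})

test_that("task losses have the expected closed forms", {
  # perfect one-hot logits give zero cross-entropy
  V <- 6L
  tg <- c(2L, 4L, 1L)
  hot <- matrix(-1e6, 3, V)
  hot[cbind(1:3, tg)] <- 0
  expect_equal(cross_entropy_loss(hot, tg), 0, tolerance = 1e-9)
  # uniform logits give ln(V)
  expect_equal(cross_entropy_loss(matrix(0, 3, V), tg), log(V),
               tolerance = 1e-12)
  # exact severity predictions give zero MSE
  s <- tiny_setup()
  m <- severity_model(s$mcfg, s$bank)
  recs <- s$corpus[1:4, ]
  l <- task_loss("severity", recs, m)
  pred <- severity_forward(recs$finding, recs$impression, m)
  expect_equal(l, mean((pred - recs$severity / 5)^2), tolerance = 1e-10)
  expect_error(task_loss("nonsense", recs, m), "unknown task")
})

test_that("zero epochs leave the template untouched bit-for-bit", {
  s <- tiny_setup()
  m <- summary_model(s$mcfg, s$bank)
  before <- s$bank$template$values + 0  # force a copy
  met <- train_task("summary", list(train = s$corpus), m,
                    train_config(batch_size = 8), n_epochs = 0)
  expect_identical(s$bank$template$values, before)
  expect_equal(nrow(met), 0L)
})

test_that("training one task propagates into another task's weights", {
  s <- tiny_setup(seed = 55)
  sm <- summary_model(s$mcfg, s$bank)
  at <- atr_model(s$mcfg, s$bank)
  tpl_before <- s$bank$template$values + 0
  watr <- function() {
    ctx <- softshare:::model_context(at, training = FALSE)
    softshare:::ad_value(ctx$weights[["atr.encF1.Wq"]])
  }
  w_before <- watr()
  set.seed(55)
  train_task("summary", list(train = s$corpus[1:8, ]), sm,
             train_config(batch_size = 8), n_epochs = 1, lr_override = 0.01)
  expect_false(identical(s$bank$template$values, tpl_before))
  # ATR kernels were never trained, yet regenerated ATR weights moved
  w_after <- watr()
  expect_gt(max(abs(w_after - w_before)), 0)
  # every independent phase leaves its mark on the shared template
  sv <- severity_model(s$mcfg, s$bank)
  cks <- function() sum(s$bank$template$values^2)
  c1 <- cks()
  train_task("severity", list(train = s$corpus[1:8, ]), sv,
             train_config(batch_size = 8), n_epochs = 1, lr_override = 0.01)
  c2 <- cks()
  expect_false(identical(c1, c2))
  train_task("atr", list(train = s$corpus[1:8, ]), at,
             train_config(batch_size = 8), n_epochs = 1, lr_override = 0.01)
  expect_false(identical(c2, cks()))
})

test_that("collaborative loss is the weighted sum of the task losses", {
  s <- tiny_setup(seed = 66)
  models <- list(summary = summary_model(s$mcfg, s$bank),
                 severity = severity_model(s$mcfg, s$bank),
                 atr = atr_model(s$mcfg, s$bank))
  recs <- s$corpus[1:5, ]
  w <- c(summary = 1, severity = 2, atr = 0.5)
  ctx <- softshare:::model_context(unname(models), training = FALSE)
  parts <- lapply(names(models), function(task) {
    softshare:::task_loss_node(ctx, models[[task]], task, recs)
  })
  total <- softshare:::ad_value(softshare:::ad_wsum(parts, w))
  indiv <- vapply(names(models), function(task) {
    task_loss(task, recs, models[[task]])
  }, 0)
  expect_equal(total, sum(w * indiv), tolerance = 1e-9)
})

test_that("run_schedule honours the preference mode and phase order", {
  s <- tiny_setup(n_records = 24, seed = 77)
  tcfg <- train_config(batch_size = 8, mode = "none",
                       epochs = c(summary = 1, severity = 1, atr = 1),
                       seed = 77)
  run_none <- run_schedule(s$corpus, tcfg, s$mcfg,
                           template_shape = c(3, 12, 12))
  expect_named(run_none$models, "atr")
  expect_true(all(startsWith(names(run_none$bank$bindings), "atr.")))
  tcfg$mode <- "both"
  run_both <- run_schedule(s$corpus, tcfg, s$mcfg,
                           template_shape = c(3, 12, 12))
  expect_setequal(names(run_both$models), c("summary", "severity", "atr"))
  expect_equal(unique(run_both$metrics$task),
               c("summary", "severity", "atr"))
  expect_true(all(is.finite(run_both$final$mll)))
})

test_that("evaluation is deterministic and inverts through exp", {
  s <- tiny_setup(seed = 88)
  m <- atr_model(s$mcfg, s$bank)
  e1 <- evaluate(m, s$corpus[1:10, ])
  e2 <- evaluate(m, s$corpus[1:10, ])
  expect_identical(e1, e2)
  expect_equal(exp(-e1$mll), e1$loss, tolerance = 1e-12)
})
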