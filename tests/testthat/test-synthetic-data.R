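# The synthetic report generator: determinism, label coverage, the severity
# formula, length statistics, splits, and the cross-field coupling that
# makes auxiliary transfer possible.

test_that("attribute draws respect ranges and cover all severity labels", {
  set.seed(41)
  a <- sample_attributes(10000)
  expect_true(all(a$size_class %in% 0:2))
  expect_true(all(a$margin %in% 0:1))
  expect_true(all(a$calcification %in% 0:1))
  expect_true(all(a$hypoechoic %in% 0:1))
  expect_true(all(a$vascular %in% 0:1))
  expect_true(all(a$nodule_count %in% 1:3))
  sev <- compute_severity(a)
  expect_setequal(unique(sev), 0:5)
  expect_true(all(table(sev) / nrow(a) >= 0.01))
  # repeatable under a fixed seed
  set.seed(41)
  expect_identical(sample_attributes(10000), a)
})

test_that("compute_severity follows the clipped additive formula", {
  a0 <- tibble::tibble(size_class = 0, margin = 0, calcification = 0,
                       hypoechoic = 0, vascular = 0, nodule_count = 1)
  expect_equal(compute_severity(a0), 0L)
  a5 <- a0
  a5$size_class <- 2; a5$margin <- 1; a5$calcification <- 1
  expect_equal(compute_severity(a5), 5L)  # 2 + 2 + 1
  amax <- tibble::tibble(size_class = 2, margin = 1, calcification = 1,
                         hypoechoic = 1, vascular = 1, nodule_count = 3)
  expect_equal(compute_severity(amax), 5L)  # clipped from 7
})

test_that("impressions and treatments are deterministic given attributes", {
  cfg <- generator_config(noise_rate = 0)
  set.seed(42)
  a <- sample_attributes(30)
  sev <- compute_severity(a)
  i1 <- derive_impression(a, cfg)
  i2 <- derive_impression(a, cfg)
  expect_identical(i1, i2)
  t1 <- derive_treatment(a, sev, cfg)
  expect_identical(t1, derive_treatment(a, sev, cfg))
  # findings with zero noise are repeatable under the same RNG state
  set.seed(7); f1 <- render_finding(a, cfg)
  set.seed(7); f2 <- render_finding(a, cfg)
  expect_identical(f1, f2)
  # severity bands key distinct impression openings
  bands <- sev %/% 2
  openings <- vapply(i1, function(x) paste(x[1:4], collapse = ","), "")
  expect_equal(length(unique(openings)), length(unique(bands)))
  for (b in unique(bands)) {
    expect_equal(length(unique(openings[bands == b])), 1L)
  }
})

test_that("the default corpus matches the emulated corpus statistics", {
  cfg <- generator_config()
  corpus <- generate_corpus(cfg)
  expect_equal(nrow(corpus), 513L)
  expect_setequal(unique(corpus$severity), 0:5)
  expect_lt(abs(mean(lengths(corpus$finding)) - 60), 3)
  expect_lt(abs(mean(lengths(corpus$impression)) - 31), 2)
  expect_lt(abs(mean(lengths(corpus$treatment)) - 53), 4)
  expect_true(all(lengths(corpus$finding) > 0))
  # byte-identical regeneration
  expect_identical(generate_corpus(cfg)$finding, corpus$finding)
  # severity equals the formula applied to the latent attributes
  expect_identical(corpus$severity,
                   compute_severity(attr(corpus, "attributes")))
})

test_that("split_corpus uses the stated rounding rule and partitions", {
  cfg <- generator_config()
  corpus <- generate_corpus(cfg)
  sp <- split_corpus(corpus, cfg)
  expect_equal(nrow(sp$dev), 51L)    # round(0.1 * 513)
  expect_equal(nrow(sp$test), 103L)  # round(0.2 * 513)
  expect_equal(nrow(sp$train), 359L)
  key <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      paste(c(df$finding[[i]], 99L, df$impression[[i]]), collapse = "-")
    }, "")
  }
  all_keys <- c(key(sp$train), key(sp$dev), key(sp$test))
  expect_equal(sort(all_keys), sort(key(corpus)))
  cfg10 <- generator_config(n_records = 10)
  sp10 <- split_corpus(generate_corpus(cfg10), cfg10)
  expect_equal(vapply(sp10, nrow, 0L), c(train = 7L, dev = 1L, test = 2L))
})

test_that("a dense summary model can memorize a 16-record subset", {
  set.seed(43)
  cfg <- generator_config(seed = 9)
  corpus <- generate_corpus(cfg)[1:16, ]
  vocab <- generator_vocabulary(cfg)
  mcfg <- model_config(n = 64, L = 2, vocab_size = vocab_size(vocab),
                       dropout = 0, templated = FALSE)
  bank <- sps_bank(sps_template(2, 64, 64))
  m <- summary_model(mcfg, bank)
  tcfg <- train_config(batch_size = 16, seed = 9)
  met <- train_task("summary", list(train = corpus), m, tcfg,
                    n_epochs = 450, lr_override = 0.005)
  expect_lt(tail(met$train_loss, 1), 0.05)
})
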