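# Independent oracles and tiny fixtures used across the suite.

# brute-force valid cross-correlation of a (p, r, c) template with a
# (p, p0, kh, kw) kernel; the reference semantics for SPS generation
naive_xcorr <- function(E, M) {
  d <- dim(E)
  p <- d[1]; r <- d[2]; cc <- d[3]
  k <- dim(M)
  p0 <- k[2]; kh <- k[3]; kw <- k[4]
  r0 <- r - kh + 1
  c0 <- cc - kw + 1
  W <- array(0, c(p0, r0, c0))
  for (q in seq_len(p0)) {
    for (i in seq_len(r0)) {
      for (j in seq_len(c0)) {
        acc <- 0
        for (s in seq_len(p)) {
          for (a in seq_len(kh)) {
            for (b in seq_len(kw)) {
              acc <- acc + E[s, i + a - 1, j + b - 1] * M[s, q, a, b]
            }
          }
        }
        W[q, i, j] <- acc
      }
    }
  }
  W
}

# small shared-template fixture: three tiny models over one bank
tiny_setup <- function(n = 8, L = 2, template = c(3, 12, 12),
                       n_records = 20, seed = 42, dropout = 0,
                       templated = TRUE, flags = TRUE) {
  set.seed(seed)
  gcfg <- generator_config(n_records = n_records, seed = seed)
  corpus <- generate_corpus(gcfg)
  vocab <- generator_vocabulary(gcfg)
  mcfg <- model_config(n = n, L = L, vocab_size = vocab_size(vocab),
                       dropout = dropout, templated = templated,
                       flags_enabled = flags)
  bank <- sps_bank(sps_template(template[1], template[2], template[3]))
  list(gcfg = gcfg, corpus = corpus, vocab = vocab, mcfg = mcfg, bank = bank)
}

expect_rel_equal <- function(x, y, tol = 1e-6) {
  expect_lt(max(abs(x - y)) / max(1e-12, max(abs(y))), tol)
}
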