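# Synthetic ultrasound-report corpus with learnable cross-field structure.
#
# Each record is driven by a latent clinical attribute vector (nodule size
# class, margin irregularity, calcification, hypoechogenicity, vascularity,
# nodule count). The Finding renders every attribute as a fixed token phrase
# plus Poisson filler and a little substitution noise; the Impression is a
# deterministic summary of the same attributes; the Treatment is a
# deterministic phrase bank keyed by severity band plus attribute
# qualifiers; the Severity label is a deterministic function of the
# attributes. Severity and Treatment thus depend on exactly the information
# rendered in the Finding — the structural precondition for auxiliary-task
# transfer.

#' Generator configuration
#'
#' Defaults emulate the scale of a small clinical corpus: 513 reports, mean
#' token lengths of about 60 (Finding), 31 (Impression), 53 (Treatment),
#' six severity levels, token-pool sizes near the per-field distinct-token
#' counts (353/263/277), and a 70/10/20 train/dev/test split.
#'
#' @param n_records number of reports (>= 10).
#' @param mean_finding,mean_impression,mean_treatment target mean token
#'   lengths per field.
#' @param pool_finding,pool_impression,pool_treatment token-pool sizes
#'   approximating per-field vocabulary richness.
#' @param noise_rate per-token substitution probability in the Finding.
#' @param split named fractions (train, dev, test) summing to 1.
#' @param seed integer seed; the corpus is a pure function of this config.
#' @return object of class `report_generator_config`.
#' @export
generator_config <- function(n_records = 513, mean_finding = 60,
                             mean_impression = 31, mean_treatment = 53,
                             pool_finding = 353, pool_impression = 263,
                             pool_treatment = 277, noise_rate = 0.02,
                             split = c(train = 0.7, dev = 0.1, test = 0.2),
                             seed = 1L) {
  stopifnot(n_records >= 10, abs(sum(split) - 1) < 1e-8, noise_rate >= 0,
            noise_rate < 1)
  structure(list(n_records = as.integer(n_records),
                 mean_finding = mean_finding,
                 mean_impression = mean_impression,
                 mean_treatment = mean_treatment,
                 pool_finding = as.integer(pool_finding),
                 pool_impression = as.integer(pool_impression),
                 pool_treatment = as.integer(pool_treatment),
                 noise_rate = noise_rate, split = split,
                 seed = as.integer(seed)),
            class = "report_generator_config")
}

# deterministic id layout: 4 reserved tokens, then the three field pools
RESERVED_TOKENS <- c("<pad>", "<unk>", "<start>", "<end>")
PAD_ID <- 1L
UNK_ID <- 2L
START_ID <- 3L
END_ID <- 4L

#' Vocabulary of a generator configuration
#'
#' Token ids are stable: 4 reserved tokens first, then the Finding,
#' Impression and Treatment pools.
#'
#' @param cfg a [generator_config()].
#' @return a `vocabulary` object (see [vocabulary()]).
#' @export
generator_vocabulary <- function(cfg) {
  vocabulary(c(sprintf("f%03d", seq_len(cfg$pool_finding)),
               sprintf("i%03d", seq_len(cfg$pool_impression)),
               sprintf("t%03d", seq_len(cfg$pool_treatment))))
}

# pool id offsets within the vocabulary
pool_offset <- function(cfg, field) {
  switch(field,
    finding = 4L,
    impression = 4L + cfg$pool_finding,
    treatment = 4L + cfg$pool_finding + cfg$pool_impression
  )
}

# deterministic pseudo-hash phrase: `len` token ids from a field pool,
# keyed by (attribute, value, variant); no RNG involved
phrase_ids <- function(cfg, field, key, variant, len) {
  off <- pool_offset(cfg, field)
  pool <- switch(field, finding = cfg$pool_finding,
                 impression = cfg$pool_impression,
                 treatment = cfg$pool_treatment)
  idx <- (key * 131L + variant * 31L + seq_len(len) * 7L) %% pool
  off + idx + 1L
}

#' Sample latent attribute vectors
#'
#' Independent categorical draws with probabilities chosen so that every
#' severity label 0..5 occurs with probability at least 0.02.
#'
#' @param n number of draws (uses the current RNG state; seed upstream).
#' @return tibble with columns `size_class` (0..2), `margin` (0/1),
#'   `calcification` (0/1), `hypoechoic` (0/1), `vascular` (0/1),
#'   `nodule_count` (1..3).
#' @export
sample_attributes <- function(n = 1) {
  tibble::tibble(
    size_class = sample(0:2, n, replace = TRUE),
    margin = stats::rbinom(n, 1, 0.4),
    calcification = stats::rbinom(n, 1, 0.5),
    hypoechoic = stats::rbinom(n, 1, 0.5),
    vascular = stats::rbinom(n, 1, 0.5),
    nodule_count = sample(1:3, n, replace = TRUE)
  )
}

#' Severity label from attributes
#'
#' `severity = min(5, size_class + 2*margin + calcification + hypoechoic +
#' vascular)`; deterministic, six attainable levels.
#'
#' @param a tibble of attributes (as from [sample_attributes()]).
#' @return integer vector in 0..5.
#' @export
compute_severity <- function(a) {
  pmin(5L, a$size_class + 2L * a$margin + a$calcification + a$hypoechoic +
         a$vascular)
}

severity_band <- function(severity) severity %/% 2L  # 0: 0-1, 1: 2-3, 2: 4-5

# attribute keys used by the phrase hash (stable small integers)
attr_items <- function(a, row) {
  list(c(1L, a$size_class[row]), c(2L, a$margin[row]),
       c(3L, a$calcification[row]), c(4L, a$hypoechoic[row]),
       c(5L, a$vascular[row]), c(6L, a$nodule_count[row]))
}

#' Render a Finding token sequence
#'
#' Concatenates one 6-token phrase per attribute, inserts Poisson filler
#' tokens at random positions to reach the configured mean length, and
#' applies per-token substitution noise.
#'
#' @param a attribute tibble.
#' @param cfg a [generator_config()].
#' @return list of integer id vectors, one per attribute row.
#' @export
render_finding <- function(a, cfg) {
  core_len <- 6L * 6L
  lambda <- max(0, cfg$mean_finding - core_len)
  lapply(seq_len(nrow(a)), function(row) {
    core <- unlist(lapply(attr_items(a, row), function(it) {
      phrase_ids(cfg, "finding", it[1] * 10L + it[2], 0L, 6L)
    }))
    n_fill <- stats::rpois(1, lambda)
    if (n_fill > 0) {
      fill <- pool_offset(cfg, "finding") +
        sample.int(cfg$pool_finding, n_fill, replace = TRUE)
      pos <- sort(sample.int(length(core) + n_fill, n_fill))
      out <- integer(length(core) + n_fill)
      out[pos] <- fill
      out[-pos] <- core
    } else {
      out <- core
    }
    if (cfg$noise_rate > 0) {
      hit <- stats::runif(length(out)) < cfg$noise_rate
      if (any(hit)) {
        out[hit] <- pool_offset(cfg, "finding") +
          sample.int(cfg$pool_finding, sum(hit), replace = TRUE)
      }
    }
    out
  })
}

#' Derive an Impression token sequence (deterministic)
#'
#' A severity-band key phrase followed by one 4-token summary phrase per
#' attribute, plus short qualifiers for multiple nodules and irregular
#' margins. Noise-free: identical attributes always give the identical
#' impression.
#'
#' @param a attribute tibble.
#' @param cfg a [generator_config()].
#' @return list of integer id vectors.
#' @export
derive_impression <- function(a, cfg) {
  sev <- compute_severity(a)
  band <- severity_band(sev)
  lapply(seq_len(nrow(a)), function(row) {
    out <- phrase_ids(cfg, "impression", 100L + band[row], 0L, 4L)
    for (it in attr_items(a, row)) {
      out <- c(out, phrase_ids(cfg, "impression", it[1] * 10L + it[2], 1L, 4L))
    }
    if (a$nodule_count[row] > 1) {
      out <- c(out, phrase_ids(cfg, "impression", 200L + a$nodule_count[row],
                               2L, 3L))
    }
    if (a$margin[row] == 1) {
      out <- c(out, phrase_ids(cfg, "impression", 300L, 3L, 2L))
    }
    out
  })
}

#' Derive a Treatment Recommendation token sequence (deterministic)
#'
#' A long phrase bank keyed by severity band (watchful waiting / follow-up
#' biopsy / referral, abstractly) plus one 3-token qualifier per positive
#' attribute. Noise-free given attributes and severity.
#'
#' @param a attribute tibble.
#' @param severity integer vector as from [compute_severity()].
#' @param cfg a [generator_config()].
#' @return list of integer id vectors.
#' @export
derive_treatment <- function(a, severity, cfg) {
  band <- severity_band(severity)
  # expected qualifier count under the attribute distribution
  exp_qual <- 3 * (2 / 3 + 0.4 + 0.5 + 0.5 + 0.5 + 2 / 3)
  base_len <- max(6L, as.integer(round(cfg$mean_treatment - exp_qual)))
  lapply(seq_len(nrow(a)), function(row) {
    out <- phrase_ids(cfg, "treatment", 400L + band[row], 0L, base_len)
    if (a$size_class[row] >= 1) {
      out <- c(out, phrase_ids(cfg, "treatment", 10L + a$size_class[row], 1L, 3L))
    }
    if (a$margin[row] == 1) out <- c(out, phrase_ids(cfg, "treatment", 21L, 1L, 3L))
    if (a$calcification[row] == 1) out <- c(out, phrase_ids(cfg, "treatment", 31L, 1L, 3L))
    if (a$hypoechoic[row] == 1) out <- c(out, phrase_ids(cfg, "treatment", 41L, 1L, 3L))
    if (a$vascular[row] == 1) out <- c(out, phrase_ids(cfg, "treatment", 51L, 1L, 3L))
    if (a$nodule_count[row] > 1) {
      out <- c(out, phrase_ids(cfg, "treatment", 60L + a$nodule_count[row], 1L, 3L))
    }
    out
  })
}

#' Generate a synthetic report corpus
#'
#' @param cfg a [generator_config()].
#' @return tibble with list-columns `finding`, `impression`, `treatment`
#'   (integer token id sequences) and integer column `severity`; the latent
#'   attributes are attached as `attr(corpus, "attributes")`.
#' @examples
#' corpus <- generate_corpus(generator_config(n_records = 20))
#' nrow(corpus)
#' @export
generate_corpus <- function(cfg = generator_config()) {
  if (!inherits(cfg, "report_generator_config")) stop("invalid config")
  withr_seed <- cfg$seed
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  a <- sample_attributes(cfg$n_records)
  sev <- compute_severity(a)
  corpus <- tibble::tibble(
    finding = render_finding(a, cfg),
    impression = derive_impression(a, cfg),
    treatment = derive_treatment(a, sev, cfg),
    severity = sev
  )
  attr(corpus, "attributes") <- a
  attr(corpus, "config") <- cfg
  corpus
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Split a corpus into train / dev / test
#'
#' Shuffles by seed, then takes `round(dev_frac * n)` development and
#' `round(test_frac * n)` test records; the remainder trains.
#'
#' @param records corpus tibble.
#' @param cfg a [generator_config()] (for fractions and seed), or NULL to
#'   use the config attached to `records`.
#' @return named list of tibbles `train`, `dev`, `test` (disjoint, covering).
#' @export
split_corpus <- function(records, cfg = NULL) {
  cfg <- cfg %||% attr(records, "config")
  n <- nrow(records)
  n_dev <- round(cfg$split[["dev"]] * n)
  n_test <- round(cfg$split[["test"]] * n)
  if (n_dev < 1 || n_test < 1 || n - n_dev - n_test < 1) {
    stop("corpus too small for nonempty splits")
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  ord <- sample.int(n)
  dev_idx <- ord[seq_len(n_dev)]
  test_idx <- ord[n_dev + seq_len(n_test)]
  train_idx <- ord[(n_dev + n_test + 1):n]
  list(train = records[train_idx, ], dev = records[dev_idx, ],
       test = records[test_idx, ])
}
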