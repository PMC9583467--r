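# Corpus / vocabulary I/O, batching, checkpoints, and diagnostics export.

#' Vocabulary with reserved sentinel tokens
#'
#' Token ids are 1-based; ids 1..4 are reserved for `<pad>`, `<unk>`,
#' `<start>`, `<end>` and are stable across save/load.
#'
#' @param tokens character vector of non-reserved tokens (unique).
#' @return object of class `vocabulary`: `tokens` (including reserved),
#'   lookup environment `index`.
#' @export
vocabulary <- function(tokens) {
  tokens <- as.character(tokens)
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary")
  if (any(tokens %in% RESERVED_TOKENS)) {
    stop("reserved tokens are added automatically")
  }
  all_tokens <- c(RESERVED_TOKENS, tokens)
  index <- new.env(parent = emptyenv())
  for (i in seq_along(all_tokens)) assign(all_tokens[i], i, envir = index)
  structure(list(tokens = all_tokens, index = index), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (4 reserved)\n", length(x$tokens)))
  invisible(x)
}

#' @rdname vocabulary
#' @param vocab a `vocabulary`.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Encode tokens to ids / decode ids to tokens
#'
#' Unknown tokens map to `<unk>`; with `flags = TRUE` the sequence is
#' wrapped in `<start>`/`<end>`. Decoding strips all reserved tokens.
#'
#' @param tokens character vector.
#' @param vocab a [vocabulary()].
#' @param flags add start/end sentinels?
#' @return integer id vector.
#' @export
encode_text <- function(tokens, vocab, flags = FALSE) {
  ids <- vapply(as.character(tokens), function(tk) {
    v <- get0(tk, envir = vocab$index, inherits = FALSE)
    if (is.null(v)) UNK_ID else v
  }, 0L, USE.NAMES = FALSE)
  if (flags) ids <- c(START_ID, ids, END_ID)
  ids
}

#' @rdname encode_text
#' @param ids integer id vector.
#' @export
decode_ids <- function(ids, vocab) {
  ids <- ids[ids > length(RESERVED_TOKENS)]
  vocab$tokens[ids]
}

#' Save / load a vocabulary as a token-per-line text file
#' @param vocab a [vocabulary()].
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path, encoding = "UTF-8")
  if (!identical(tokens[seq_along(RESERVED_TOKENS)], RESERVED_TOKENS)) {
    stop("vocabulary file does not start with the reserved tokens")
  }
  vocabulary(tokens[-seq_along(RESERVED_TOKENS)])
}

## ---- corpus JSON-Lines ---------------------------------------------------

#' Write a corpus as JSON-Lines
#'
#' One JSON object per record with fields `finding`, `impression`,
#' `treatment` (integer token id arrays) and `severity` (integer 0..5).
#'
#' @param records corpus tibble (as from [generate_corpus()]).
#' @param path output path.
#' @export
write_corpus <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    line <- jsonlite::toJSON(
      list(finding = records$finding[[i]],
           impression = records$impression[[i]],
           treatment = records$treatment[[i]],
           severity = jsonlite::unbox(records$severity[[i]])),
      auto_unbox = FALSE)
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a JSON-Lines corpus
#'
#' Malformed lines are reported with their line numbers; an empty file
#' yields an empty corpus.
#'
#' @param path input path.
#' @return corpus tibble.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(finding = list(), impression = list(),
                          treatment = list(), severity = integer()))
  }
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("line %d: invalid JSON (%s)", i,
                                   conditionMessage(e)), call. = FALSE)
                    })
    for (f in c("finding", "impression", "treatment", "severity")) {
      if (is.null(obj[[f]])) {
        stop(sprintf("line %d: missing field '%s'", i, f), call. = FALSE)
      }
    }
    sev <- obj$severity
    if (length(sev) != 1 || !is.numeric(sev) || sev != as.integer(sev)) {
      stop(sprintf("line %d: severity must be a single integer", i),
           call. = FALSE)
    }
    if (sev < 0 || sev > 5) {
      stop(sprintf("line %d: severity %d outside 0..5", i, as.integer(sev)),
           call. = FALSE)
    }
    list(finding = as.integer(obj$finding),
         impression = as.integer(obj$impression),
         treatment = as.integer(obj$treatment),
         severity = as.integer(sev))
  })
  tibble::tibble(
    finding = lapply(recs, `[[`, "finding"),
    impression = lapply(recs, `[[`, "impression"),
    treatment = lapply(recs, `[[`, "treatment"),
    severity = vapply(recs, `[[`, 0L, "severity")
  )
}

## ---- batching ------------------------------------------------------------

# Pad a list of id sequences into the time-major block layout used by the
# fused autodiff ops. Returns ids vector (length B*T), the pad mask, per-item
# lengths, and index maps for sequence reversal (valid prefix only) and for
# the final valid position of each item.
collate_source <- function(seqs, flags = FALSE) {
  if (flags) seqs <- lapply(seqs, function(s) c(START_ID, s, END_ID))
  B <- length(seqs)
  lens <- lengths(seqs)
  T <- max(lens)
  mat <- matrix(PAD_ID, B, T)
  for (b in seq_len(B)) mat[b, seq_len(lens[b])] <- seqs[[b]]
  ids <- as.vector(mat)  # v[(t-1)*B + b] == mat[b, t]
  mask <- as.vector(t(outer(seq_len(T), lens, `<=`)))  # same layout
  rev_idx <- integer(B * T)
  for (b in seq_len(B)) {
    tpos <- seq_len(T)
    src <- ifelse(tpos <= lens[b], lens[b] - tpos + 1L, tpos)
    rev_idx[(tpos - 1L) * B + b] <- (src - 1L) * B + b
  }
  last_idx <- (lens - 1L) * B + seq_len(B)
  list(ids = ids, mask = mask, lengths = lens, B = B, T = T,
       rev_idx = rev_idx, last_idx = last_idx)
}

# Teacher-forced target collation: inputs are the gold sequence shifted
# right (led by <start>, or <pad> when flags are off), outputs are the gold
# sequence (closed by <end> when flags are on).
collate_target <- function(seqs, flags = FALSE) {
  ins <- lapply(seqs, function(s) {
    if (flags) c(START_ID, s) else c(PAD_ID, s[-length(s)])
  })
  outs <- lapply(seqs, function(s) if (flags) c(s, END_ID) else s)
  B <- length(ins)
  lens <- lengths(ins)
  T <- max(lens)
  mat_in <- matrix(PAD_ID, B, T)
  mat_out <- matrix(PAD_ID, B, T)
  for (b in seq_len(B)) {
    mat_in[b, seq_len(lens[b])] <- ins[[b]]
    mat_out[b, seq_len(lens[b])] <- outs[[b]]
  }
  mask <- as.vector(t(outer(seq_len(T), lens, `<=`)))
  list(ids_in = as.vector(mat_in), ids_out = as.vector(mat_out),
       mask = mask, lengths = lens, B = B, T = T)
}

## ---- checkpoints ---------------------------------------------------------

#' Save a training checkpoint
#'
#' Stores the template, every binding's kernel, all module-local model
#' parameters, the vocabulary and configuration, and seed metadata in one
#' self-describing file (RDS). Round-trips exactly.
#'
#' @param run a trained run object (as returned by [run_schedule()]) or a
#'   list with elements `bank`, `models`, `vocab`, `config`, `seed`.
#' @param path output file.
#' @export
save_checkpoint <- function(run, path) {
  payload <- list(
    format = "softshare-checkpoint-1",
    template = run$bank$template,
    bindings = run$bank$bindings,
    models = lapply(run$models, model_state),
    vocab_tokens = if (!is.null(run$vocab)) run$vocab$tokens else NULL,
    config = run$config,
    seed = run$seed
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file.
#' @return list with `bank`, `models` (restored model objects), `vocab`,
#'   `config`, `seed`.
#' @export
load_checkpoint <- function(path) {
  payload <- tryCatch(suppressWarnings(readRDS(path)), error = function(e) {
    stop("unreadable checkpoint: ", conditionMessage(e), call. = FALSE)
  })
  if (!identical(payload$format, "softshare-checkpoint-1")) {
    stop("not a softshare checkpoint")
  }
  bank <- sps_bank(payload$template)
  bank$bindings <- payload$bindings
  vocab <- if (!is.null(payload$vocab_tokens)) {
    vocabulary(payload$vocab_tokens[-seq_along(RESERVED_TOKENS)])
  } else NULL
  models <- lapply(payload$models, model_restore, bank = bank)
  list(bank = bank, models = models, vocab = vocab,
       config = payload$config, seed = payload$seed)
}

## ---- diagnostics export --------------------------------------------------

#' Export template, kernel, and representation diagnostics as CSV grids
#'
#' Writes each template slice as an `r x c` numeric grid, each binding's
#' kernel as a `(p*p0) x (kh*kw)` flattened grid, and (optionally) the
#' per-token encoder representation of one record, ready for heat-mapping.
#'
#' @param checkpoint path to a checkpoint file, or the loaded list.
#' @param outdir output directory (created if missing).
#' @param record optional single-row corpus tibble whose Finding is run
#'   through the treatment-recommendation encoder to export a token-by-
#'   feature representation matrix.
#' @return (invisibly) character vector of files written.
#' @export
export_diagnostics <- function(checkpoint, outdir, record = NULL) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else
    checkpoint
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  tpl <- ck$bank$template
  for (s in seq_len(tpl$p)) {
    f <- file.path(outdir, sprintf("template_slice_%02d.csv", s - 1L))
    utils::write.table(tpl$values[s, , ], f, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, f)
  }
  for (b in ck$bank$bindings) {
    kd <- dim(b$kernel$values)
    flat <- matrix(aperm(b$kernel$values, c(2, 1, 3, 4)), kd[1] * kd[2],
                   kd[3] * kd[4])
    f <- file.path(outdir, sprintf("kernel_%s.csv", gsub("[^A-Za-z0-9_]", "_",
                                                         b$module_id)))
    utils::write.table(flat, f, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(record)) {
    atr <- ck$models[["atr"]]
    if (!is.null(atr)) {
      rep_mat <- atr_encode_representation(atr, ck$bank, record)
      f <- file.path(outdir, "representation_finding.csv")
      utils::write.table(rep_mat, f, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
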