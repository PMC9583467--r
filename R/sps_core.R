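#' @useDynLib softshare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a global SPS template
#'
#' The template is the single shared parameter store of the framework: a
#' tensor of `p` slices, each an `r` x `c` real matrix. Every soft-shared
#' module carves its own weight tensor out of this template by valid
#' cross-correlation with a module-specific kernel, so knowledge learned by
#' one task is readable (and writable, through gradients) by every other.
#'
#' @param p number of slices (template depth).
#' @param r,c spatial extent of each slice. They bound the largest module
#'   that can be generated: an `n` x `m` weight needs `r >= n` and `c >= m`.
#' @param init `"xavier"` (uniform Xavier/Glorot over the slice fan) or
#'   `"zeros"`.
#' @param values optional explicit array of dim `(p, r, c)`; overrides
#'   `init`.
#' @return an object of class `sps_template` with element `values`, an array
#'   of dim `(p, r, c)`.
#' @examples
#' tpl <- sps_template(10, 105, 105)
#' dim(tpl$values)
#' @export
sps_template <- function(p, r, c, init = c("xavier", "zeros"), values = NULL) {
  stopifnot(p >= 1, r >= 1, c >= 1)
  init <- match.arg(init)
  if (is.null(values)) {
    values <- if (init == "zeros") {
      array(0, c(p, r, c))
    } else {
      array(xavier_uniform(p * r * c, fan_in = r, fan_out = c), c(p, r, c))
    }
  } else {
    values <- array(as.numeric(values), c(p, r, c))
  }
  if (!all(is.finite(values))) stop("template entries must be finite")
  structure(list(values = values, p = as.integer(p), r = as.integer(r),
                 c = as.integer(c)),
            class = "sps_template")
}

xavier_uniform <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' @export
print.sps_template <- function(x, ...) {
  cat(sprintf("<sps_template> %d slice(s) of %d x %d (%s parameters)\n",
              x$p, x$r, x$c, format(x$p * x$r * x$c, big.mark = ",")))
  invisible(x)
}

#' Kernel shape for a target weight tensor
#'
#' The SPS kernel that maps a template of shape `(p, r, c)` onto a target
#' weight tensor of shape `(p0, r0, c0)` under valid (no padding, stride 1)
#' cross-correlation must have spatial extent `kh = r - r0 + 1`,
#' `kw = c - c0 + 1`; the canonical kernel shape is `(p, p0, kh, kw)`.
#'
#' @param template_shape integer vector `(p, r, c)`.
#' @param target_shape integer vector `(p0, r0, c0)`.
#' @return named integer vector `(p, p0, kh, kw)`.
#' @examples
#' kernel_shape_for_target(c(10, 105, 105), c(1, 100, 100)) # 10 1 6 6
#' @export
kernel_shape_for_target <- function(template_shape, target_shape) {
  stopifnot(length(template_shape) == 3, length(target_shape) == 3)
  p <- as.integer(template_shape[1])
  r <- as.integer(template_shape[2])
  c <- as.integer(template_shape[3])
  p0 <- as.integer(target_shape[1])
  r0 <- as.integer(target_shape[2])
  c0 <- as.integer(target_shape[3])
  if (p0 < 1) stop("target slice count p0 must be >= 1")
  if (r0 > r) {
    stop(sprintf("target rows r0 = %d exceed template rows r = %d", r0, r))
  }
  if (c0 > c) {
    stop(sprintf("target columns c0 = %d exceed template columns c = %d",
                 c0, c))
  }
  c(p = p, p0 = p0, kh = r - r0 + 1L, kw = c - c0 + 1L)
}

#' Create an SPS kernel for a target shape
#'
#' @param template an `sps_template`.
#' @param target_shape `(p0, r0, c0)` of the weight tensor to generate.
#' @param activation squashing applied to the generated weights: one of
#'   `"tanh"` (default; generated weights must carry both signs),
#'   `"identity"`, `"sigmoid"`.
#' @param init `"xavier"`, `"zeros"`, or an explicit array of the kernel
#'   shape.
#' @return an object of class `sps_kernel` with fields `values` (array of
#'   dim `(p, p0, kh, kw)`), `bias` (length `p0`, one scalar per output
#'   slice, broadcast), `activation`, `target_shape`.
#' @export
sps_kernel <- function(template, target_shape,
                       activation = c("tanh", "identity", "sigmoid"),
                       init = "xavier") {
  activation <- match.arg(activation)
  ks <- unname(kernel_shape_for_target(c(template$p, template$r, template$c),
                                       target_shape))
  names(ks) <- c("p", "p0", "kh", "kw")
  if (is.numeric(init) && !is.character(init)) {
    values <- array(as.numeric(init), unname(ks))
  } else if (identical(init, "zeros")) {
    values <- array(0, unname(ks))
  } else {
    fan_in <- ks[["p"]] * ks[["kh"]] * ks[["kw"]]
    fan_out <- ks[["p0"]] * ks[["kh"]] * ks[["kw"]]
    values <- array(xavier_uniform(prod(ks), fan_in, fan_out), unname(ks))
  }
  structure(list(values = values, bias = numeric(ks[["p0"]]),
                 activation = activation,
                 target_shape = as.integer(target_shape)),
            class = "sps_kernel")
}

#' Generate a module weight tensor from the template
#'
#' Computes `activation(valid_xcorr(E, M) + b)` where `E` is the template,
#' `M` the kernel and `b` the per-slice kernel bias. The result has exactly
#' the kernel's `target_shape` `(p0, r0, c0)`.
#'
#' The `"direct"` method skips zero kernel entries (so one-hot kernels copy
#' template windows bit-for-bit); the `"fft"` method evaluates the same
#' correlation in the frequency domain. `"auto"` picks `"direct"` for
#' sparse or small kernels and `"fft"` otherwise.
#'
#' @param template an `sps_template`.
#' @param kernel an `sps_kernel` bound to a template of matching extent.
#' @param method `"auto"`, `"direct"`, or `"fft"`.
#' @return numeric array of dim `target_shape`.
#' @export
sps_generate <- function(template, kernel, method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  E <- template$values
  M <- kernel$values
  if (!all(is.finite(E))) stop("template entries must be finite")
  kd <- dim(M)
  ks <- kernel_shape_for_target(c(template$p, template$r, template$c),
                                kernel$target_shape)
  if (!identical(as.integer(kd), as.integer(unname(ks)))) {
    stop("kernel shape inconsistent with template and target")
  }
  if (method == "auto") {
    nnz <- sum(M != 0)
    work <- prod(kd) * prod(kernel$target_shape[2:3])
    method <- if (nnz <= 32 || work <= 2^22) "direct" else "fft"
  }
  raw <- if (method == "direct") {
    cpp_sps_xcorr_direct(E, M)
  } else {
    cpp_sps_xcorr_fft(E, M)
  }
  out <- raw + as.vector(kernel$bias)  # recycled along the slice dimension
  switch(kernel$activation,
    identity = out,
    tanh = tanh(out),
    sigmoid = 1 / (1 + exp(-out))
  )
}

## ---- binding registry ----------------------------------------------------

#' Create a binding bank over one template
#'
#' A bank registers all soft-shared modules (bindings) that generate their
#' weights from a single template.
#'
#' @param template an `sps_template`.
#' @return an environment of class `sps_bank`.
#' @export
sps_bank <- function(template) {
  bank <- new.env(parent = emptyenv())
  bank$template <- template
  bank$bindings <- list()
  class(bank) <- "sps_bank"
  bank
}

#' @export
print.sps_bank <- function(x, ...) {
  cat(sprintf("<sps_bank> template (%d, %d, %d), %d binding(s)\n",
              x$template$p, x$template$r, x$template$c, length(x$bindings)))
  invisible(x)
}

#' Bind a module to the template
#'
#' Registers a linear (`n` x `m`) or 1-D convolution (`n` x `n` x `k`)
#' module and creates a freshly Xavier-initialized kernel of the shape the
#' calculus dictates. Linear targets map to `(p0 = 1, r0 = n, c0 = m)`;
#' conv1d targets of shape `(n, n, k)` map to `(p0 = k, r0 = n, c0 = n)`.
#'
#' @param bank an `sps_bank`.
#' @param module_id unique module name.
#' @param kind `"linear"` or `"conv1d"`.
#' @param dims for linear: `c(n, m)`; for conv1d: `c(n, n, k)`.
#' @param activation activation of the generated weights (default tanh).
#' @return the new binding (invisibly), a list with `module_id`, `kind`,
#'   `target_shape`, `kernel`, `templated`.
#' @export
bind_module <- function(bank, module_id, kind = c("linear", "conv1d"), dims,
                        activation = "tanh") {
  kind <- match.arg(kind)
  if (module_id %in% names(bank$bindings)) {
    stop("duplicate module_id: ", module_id)
  }
  target_shape <- if (kind == "linear") {
    stopifnot(length(dims) == 2)
    c(1L, dims[1], dims[2])
  } else {
    stopifnot(length(dims) == 3, dims[1] == dims[2])
    c(dims[3], dims[1], dims[2])
  }
  kernel <- sps_kernel(bank$template, target_shape, activation = activation)
  binding <- list(module_id = module_id, kind = kind,
                  target_shape = as.integer(target_shape), kernel = kernel,
                  templated = TRUE)
  class(binding) <- "sps_binding"
  bank$bindings[[module_id]] <- binding
  invisible(binding)
}

#' Parameter accounting for a bank of shared modules
#'
#' Counts the template once, each binding's kernel plus its `p0` SPS bias
#' scalars, and each module's local activation bias, and compares the total
#' with what the same modules would cost as dense (non-shared) layers. The
#' shared total grows affinely in the number of modules with slope equal to
#' the kernel size, which is far below the dense slope.
#'
#' @param bank an `sps_bank`.
#' @return object of class `sps_param_report`: a list with
#'   `template_params`, `total_shared`, `dense_equivalent_params`, and
#'   `modules`, a tibble with one row per binding.
#' @export
count_parameters <- function(bank) {
  bd <- bank$bindings
  rows <- lapply(bd, function(b) {
    ts <- b$target_shape
    kparams <- prod(dim(b$kernel$values))
    local_bias <- if (b$kind == "linear") ts[3] else ts[2]
    dense <- prod(ts) + local_bias
    tibble::tibble(module_id = b$module_id, kind = b$kind,
                   p0 = ts[1], r0 = ts[2], c0 = ts[3],
                   kernel_params = kparams, sps_bias = ts[1],
                   local_bias = local_bias,
                   module_shared = kparams + ts[1] + local_bias,
                   dense_equivalent = dense)
  })
  modules <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(module_id = character(), kind = character(),
                   p0 = integer(), r0 = integer(), c0 = integer(),
                   kernel_params = numeric(), sps_bias = numeric(),
                   local_bias = numeric(), module_shared = numeric(),
                   dense_equivalent = numeric())
  tpl <- bank$template
  template_params <- tpl$p * tpl$r * tpl$c
  structure(list(template_params = template_params,
                 total_shared = template_params + sum(modules$module_shared),
                 dense_equivalent_params = sum(modules$dense_equivalent),
                 modules = modules),
            class = "sps_param_report")
}

#' @export
print.sps_param_report <- function(x, ...) {
  cat(sprintf(
    "<sps_param_report> template %s | shared total %s | dense equivalent %s\n",
    format(x$template_params, big.mark = ","),
    format(x$total_shared, big.mark = ","),
    format(x$dense_equivalent_params, big.mark = ",")))
  print(x$modules)
  invisible(x)
}

#' Module count at which sharing beats dense storage
#'
#' For a homogeneous set of modules, sharing pays off once the one-time
#' template cost is amortized: the crossover count is
#' `template_params / (dense_per_module - shared_per_module)`.
#'
#' @param report an `sps_param_report` whose bindings are homogeneous.
#' @return the (real-valued) module count above which `total_shared` is
#'   smaller than the dense equivalent.
#' @export
sharing_crossover <- function(report) {
  m <- report$modules
  dense <- m$dense_equivalent[1]
  shared <- m$module_shared[1]
  report$template_params / (dense - shared)
}
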