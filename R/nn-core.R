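# Minimal reverse-mode neural-network core.
#
# Modules are environments carrying named parameter slots (`params`), named
# child modules (`children`) and named persistent buffers (`buffers`, e.g.
# batch-norm running statistics). Each layer implements `nn_forward()` and
# `nn_backward()`; forward caches whatever the analytic backward needs.
# Tensors use the layout [C, H, W, N] (channel fastest), so a per-channel
# view is simply `matrix(x, nrow = C)`.

new_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "nn_param"
  e
}

new_module <- function(.class, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  if (is.null(m$params)) m$params <- list()
  if (is.null(m$children)) m$children <- list()
  if (is.null(m$buffers)) m$buffers <- character(0)
  m$training <- FALSE
  class(m) <- c(.class, "nn_module")
  m
}

#' Forward / backward pass through a network module
#'
#' Low-level entry points of the package's reverse-mode engine. `nn_forward`
#' computes a module's output (caching what the analytic gradient needs when
#' the module is in training mode is the module's own business);
#' `nn_backward` consumes the gradient of the loss with respect to the output
#' and returns the gradient with respect to the input, accumulating parameter
#' gradients along the way.
#'
#' @param m a network module.
#' @param x input tensor, layout `[C, H, W, N]` (or `[C, B]` for token/vector
#'   layers).
#' @param dy gradient with respect to the module output, same layout as the
#'   output.
#' @param ... passed to methods.
#' @return `nn_forward`: the output tensor; `nn_backward`: the input gradient.
#' @keywords internal
#' @export
nn_forward <- function(m, x, ...) UseMethod("nn_forward")

#' @rdname nn_forward
#' @export
nn_backward <- function(m, dy, ...) UseMethod("nn_backward")

# Flat named list of parameter slots, names joined with "."
nn_parameters <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) {
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  }
  for (nm in names(m$children)) {
    out <- c(out, nn_parameters(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

nn_num_params <- function(m) {
  sum(vapply(nn_parameters(m), function(p) length(p$value), numeric(1)))
}

nn_zero_grad <- function(m) {
  for (p in nn_parameters(m)) p$grad <- NULL
  invisible(m)
}

nn_set_training <- function(m, on = TRUE) {
  m$training <- on
  for (ch in m$children) nn_set_training(ch, on)
  invisible(m)
}

accumulate_grad <- function(p, g) {
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(p)
}

# State dict: parameters plus named buffers, flattened with dotted names.
nn_state_dict <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]$value
  for (nm in m$buffers) out[[paste0(prefix, nm)]] <- get(nm, envir = m)
  for (nm in names(m$children)) {
    out <- c(out, nn_state_dict(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

nn_load_state_dict <- function(m, state, prefix = "") {
  for (nm in names(m$params)) {
    key <- paste0(prefix, nm)
    if (is.null(state[[key]])) stop("state dict is missing '", key, "'")
    val <- state[[key]]
    if (length(val) != length(m$params[[nm]]$value)) {
      stop("state dict entry '", key, "' has length ", length(val),
           ", expected ", length(m$params[[nm]]$value))
    }
    dim(val) <- dim(m$params[[nm]]$value)
    m$params[[nm]]$value <- val
  }
  for (nm in m$buffers) {
    key <- paste0(prefix, nm)
    if (!is.null(state[[key]])) assign(nm, state[[key]], envir = m)
  }
  for (nm in names(m$children)) {
    nn_load_state_dict(m$children[[nm]], state, paste0(prefix, nm, "."))
  }
  invisible(m)
}

# Sequential container -------------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_module")) {
    layers <- layers[[1]]
  }
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- sprintf("l%02d", seq_along(layers))
  }
  new_module("nn_sequential", children = layers)
}

#' @export
nn_forward.nn_sequential <- function(m, x, ...) {
  for (ch in m$children) x <- nn_forward(ch, x)
  x
}

#' @export
nn_backward.nn_sequential <- function(m, dy, ...) {
  for (ch in rev(m$children)) dy <- nn_backward(ch, dy)
  dy
}

# Initialisers ---------------------------------------------------------------

kaiming_matrix <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# AdamW ----------------------------------------------------------------------

adamw_init <- function(params, lr = 1e-4, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, wd = weight_decay,
       beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) 0),
       v = lapply(params, function(p) 0))
}

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    step <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$value <- p$value - opt$lr * (step + opt$wd * p$value)
  }
  opt
}
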