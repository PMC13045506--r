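# Backbone: shallow stem (7x7 conv -> batch norm -> ReLU -> 3x3/2 max pool)
# followed by four hierarchical stages of bottleneck residual blocks
# (ResNet-101 composition 3/4/23/3, expansion 4), emitting the multi-scale
# feature pyramid consumed by the fusion head.

#' Width presets for the backbone
#'
#' The `reference` preset uses the published widths (stem 64; stage outputs
#' 256/512/1024/2048). The `tiny` preset divides every channel count by 8 so
#' the full pipeline runs at desk scale on a CPU; all shape and fusion logic
#' is width-agnostic.
#'
#' @param name `"reference"` or `"tiny"`.
#' @return list with `stem`, `mids` and `outs` channel counts and the stage
#'   block counts.
#' @export
width_preset <- function(name = c("reference", "tiny")) {
  name <- match.arg(name)
  base <- list(stem = 64L,
               mids = c(64L, 128L, 256L, 512L),
               outs = c(256L, 512L, 1024L, 2048L),
               blocks = c(3L, 4L, 23L, 3L))
  if (name == "tiny") {
    base$stem <- base$stem %/% 8L
    base$mids <- base$mids %/% 8L
    base$outs <- base$outs %/% 8L
  }
  base$name <- name
  base
}

# Stem: the 7x7 convolution carries no bias (the batch-norm affine pair
# immediately follows), which is what makes the stem's trainable-parameter
# count come out at 7*7*3*64 + 2*64 = 9,536 in the reference preset.
build_stem <- function(c_out) {
  nn_sequential(list(
    conv = nn_conv2d(3L, c_out, k = 7L, stride = 2L, pad = 3L, bias = FALSE),
    bn = nn_batchnorm(c_out),
    relu = nn_relu(),
    pool = nn_maxpool(k = 3L, stride = 2L, pad = 1L)))
}

# Bottleneck residual block: 1x1 reduce -> 3x3 (stride s) -> 1x1 expand,
# batch norm after every conv, projection shortcut when shape changes.
# The last batch-norm gain starts at zero so every block is identity-like at
# initialisation (zero-init residual), which is what lets the 33-block stack
# train from scratch in few epochs.
nn_bottleneck <- function(c_in, c_mid, c_out, stride = 1L) {
  ch <- list(
    conv1 = nn_conv2d(c_in, c_mid, 1L, bias = FALSE),
    bn1 = nn_batchnorm(c_mid),
    r1 = nn_relu(),
    conv2 = nn_conv2d(c_mid, c_mid, 3L, stride = stride, pad = 1L, bias = FALSE),
    bn2 = nn_batchnorm(c_mid),
    r2 = nn_relu(),
    conv3 = nn_conv2d(c_mid, c_out, 1L, bias = FALSE),
    bn3 = nn_batchnorm(c_out),
    r3 = nn_relu())
  ch$bn3$params$gamma$value[] <- 0  # zero-init residual
  project <- (stride != 1L) || (c_in != c_out)
  if (project) {
    ch$down_conv <- nn_conv2d(c_in, c_out, 1L, stride = stride, bias = FALSE)
    ch$down_bn <- nn_batchnorm(c_out)
  }
  new_module("nn_bottleneck", children = ch, project = project)
}

#' @export
nn_forward.nn_bottleneck <- function(m, x, ...) {
  ch <- m$children
  out <- nn_forward(ch$r1, nn_forward(ch$bn1, nn_forward(ch$conv1, x)))
  out <- nn_forward(ch$r2, nn_forward(ch$bn2, nn_forward(ch$conv2, out)))
  out <- nn_forward(ch$bn3, nn_forward(ch$conv3, out))
  sc <- if (m$project) {
    nn_forward(ch$down_bn, nn_forward(ch$down_conv, x))
  } else {
    x
  }
  nn_forward(ch$r3, out + sc)
}

#' @export
nn_backward.nn_bottleneck <- function(m, dy, ...) {
  ch <- m$children
  dsum <- nn_backward(ch$r3, dy)
  db <- nn_backward(ch$bn3, dsum)
  db <- nn_backward(ch$conv3, db)
  db <- nn_backward(ch$r2, db)
  db <- nn_backward(ch$bn2, db)
  db <- nn_backward(ch$conv2, db)
  db <- nn_backward(ch$r1, db)
  db <- nn_backward(ch$bn1, db)
  db <- nn_backward(ch$conv1, db)
  dsc <- if (m$project) {
    nn_backward(ch$down_conv, nn_backward(ch$down_bn, dsum))
  } else {
    dsum
  }
  db + dsc
}

build_stage <- function(c_in, c_mid, c_out, n_blocks, stride) {
  blocks <- vector("list", n_blocks)
  blocks[[1]] <- nn_bottleneck(c_in, c_mid, c_out, stride = stride)
  for (i in seq_len(n_blocks - 1L)) {
    blocks[[i + 1L]] <- nn_bottleneck(c_out, c_mid, c_out, stride = 1L)
  }
  names(blocks) <- sprintf("b%02d", seq_len(n_blocks))
  nn_sequential(blocks)
}

# The four stages: conv2_x keeps the stem's spatial resolution (the stem's
# max pool already divided by 4); conv3_x..conv5_x each downsample by 2 at
# their first block.
build_backbone <- function(preset) {
  w <- preset
  new_module("nn_backbone",
             children = list(
               stage2 = build_stage(w$stem, w$mids[1], w$outs[1], w$blocks[1], 1L),
               stage3 = build_stage(w$outs[1], w$mids[2], w$outs[2], w$blocks[2], 2L),
               stage4 = build_stage(w$outs[2], w$mids[3], w$outs[3], w$blocks[3], 2L),
               stage5 = build_stage(w$outs[3], w$mids[4], w$outs[4], w$blocks[4], 2L)),
             preset = w$name)
}

# Returns the pyramid as list(c2, c3, c4, c5)
#' @export
nn_forward.nn_backbone <- function(m, x, ...) {
  c2 <- nn_forward(m$children$stage2, x)
  c3 <- nn_forward(m$children$stage3, c2)
  c4 <- nn_forward(m$children$stage4, c3)
  c5 <- nn_forward(m$children$stage5, c4)
  list(c2 = c2, c3 = c3, c4 = c4, c5 = c5)
}

# dy is a list with (possibly NULL) gradients for each pyramid level.
#' @export
nn_backward.nn_backbone <- function(m, dy, ...) {
  add0 <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b
  d <- nn_backward(m$children$stage5, dy$c5)
  d <- nn_backward(m$children$stage4, add0(dy$c4, d))
  d <- nn_backward(m$children$stage3, add0(dy$c3, d))
  nn_backward(m$children$stage2, add0(dy$c2, d))
}

# Validation -----------------------------------------------------------------

check_image_tensor <- function(x, what = "image") {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop(what, " must be a [3, H, W] or [3, H, W, N] array")
  }
  if (d[1] != 3L) {
    stop(what, " must have exactly 3 channels, got ", d[1], " (dimension 1)")
  }
  if (d[2] %% 32L != 0L) {
    stop(what, " height ", d[2], " (dimension 2) is not divisible by 32")
  }
  if (d[3] %% 32L != 0L) {
    stop(what, " width ", d[3], " (dimension 3) is not divisible by 32")
  }
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

as_batch <- function(x) {
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    attr(x, "was_single") <- TRUE
  }
  x
}

drop_batch <- function(y, single) {
  attr(y, "was_single") <- NULL
  if (single) {
    d <- dim(y)
    dim(y) <- d[-length(d)]
  }
  y
}

#' Run the shallow stem over an image
#'
#' Applies the 7x7/2 convolution, batch normalisation, ReLU and 3x3/2 max
#' pooling, mapping a `[3, H, W]` image to a `[stem, H/4, W/4]` feature map
#' (64 channels in the reference preset).
#'
#' @param model a model built by [build_model()].
#' @param image numeric array `[3, H, W]` (values in `[0, 1]`) or a batch
#'   `[3, H, W, N]`; `H` and `W` must be divisible by 32.
#' @return feature array `[stem, H/4, W/4]` (batch dimension preserved when
#'   given).
#' @export
stem_forward <- function(model, image) {
  check_image_tensor(image)
  x <- as_batch(image)
  single <- isTRUE(attr(x, "was_single"))
  drop_batch(nn_forward(model$children$stem, x), single)
}

#' Run the hierarchical stages over a stem feature map
#'
#' Propagates a stem output through the four bottleneck stages
#' (block counts 3/4/23/3), producing the multi-scale feature pyramid
#' `{c2, c3, c4, c5}` with channels 256/512/1024/2048 in the reference
#' preset, each level halving the spatial size of the previous one.
#'
#' @param model a model built by [build_model()].
#' @param stem stem feature array `[C_stem, H/4, W/4]` (or batched).
#' @return named list `c2..c5` of feature arrays.
#' @export
hierarchical_forward <- function(model, stem) {
  x <- as_batch(stem)
  single <- isTRUE(attr(x, "was_single"))
  pyr <- nn_forward(model$children$backbone, x)
  lapply(pyr, drop_batch, single = single)
}
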