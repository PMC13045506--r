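# Primitive layers. Tensor layout [C, H, W, N]; vector/token layout [C, B].
# Forward passes cache intermediates on the module environment; backward
# passes consume and rely on them (one backward per forward).

conv_out_size <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# 2-D convolution, weight stored as [C_out, C_in*k*k] with column index
# c + C_in*(kh + k*kw), matching im2col_nchw's row order.
nn_conv2d <- function(c_in, c_out, k, stride = 1L, pad = 0L, bias = TRUE) {
  params <- list(weight = new_param(kaiming_matrix(c_out, c_in * k * k,
                                                   fan_in = c_in * k * k)))
  if (bias) params$bias <- new_param(numeric(c_out))
  new_module("nn_conv2d", params = params, c_in = c_in, c_out = c_out,
             k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad), use_bias = bias)
}

#' @export
nn_forward.nn_conv2d <- function(m, x, ...) {
  d <- dim(x)
  if (d[1] != m$c_in) {
    stop("conv2d: input has ", d[1], " channels, layer expects ", m$c_in)
  }
  cols <- im2col_nchw(x, d[1], d[2], d[3], d[4], m$k, m$stride, m$pad)
  y <- m$params$weight$value %*% cols
  if (m$use_bias) y <- y + m$params$bias$value
  m$in_dim <- d
  if (m$training) m$cols <- cols
  dim(y) <- c(m$c_out, conv_out_size(d[2], m$k, m$stride, m$pad),
              conv_out_size(d[3], m$k, m$stride, m$pad), d[4])
  y
}

#' @export
nn_backward.nn_conv2d <- function(m, dy, ...) {
  d <- m$in_dim
  dym <- matrix(dy, nrow = m$c_out)
  accumulate_grad(m$params$weight, dym %*% t(m$cols))
  if (m$use_bias) accumulate_grad(m$params$bias, rowSums(dym))
  dcols <- crossprod(m$params$weight$value, dym)
  m$cols <- NULL
  dx <- col2im_nchw(dcols, d[1], d[2], d[3], d[4], m$k, m$stride, m$pad)
  dim(dx) <- d
  dx
}

# Batch normalisation over (H, W, N) per channel; also serves as the head's
# feature-wise normalisation with H = W = 1. Normalisation uses the biased
# batch variance; running statistics use the same estimate (momentum 0.1).
nn_batchnorm <- function(c, eps = 1e-5, momentum = 0.1) {
  m <- new_module("nn_batchnorm",
                  params = list(gamma = new_param(rep(1, c)),
                                beta = new_param(numeric(c))),
                  c = c, eps = eps, momentum = momentum,
                  buffers = c("running_mean", "running_var"))
  m$running_mean <- numeric(c)
  m$running_var <- rep(1, c)
  m
}

#' @export
nn_forward.nn_batchnorm <- function(m, x, ...) {
  d <- dim(x)
  xm <- matrix(x, nrow = m$c)
  if (m$training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
    m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
  } else {
    mu <- m$running_mean
    v <- m$running_var
  }
  invstd <- 1 / sqrt(v + m$eps)
  xhat <- (xm - mu) * invstd
  y <- m$params$gamma$value * xhat + m$params$beta$value
  if (m$training) {
    m$xhat <- xhat
    m$invstd <- invstd
  }
  dim(y) <- d
  y
}

#' @export
nn_backward.nn_batchnorm <- function(m, dy, ...) {
  d <- dim(dy)
  dym <- matrix(dy, nrow = m$c)
  xhat <- m$xhat
  accumulate_grad(m$params$gamma, rowSums(dym * xhat))
  accumulate_grad(m$params$beta, rowSums(dym))
  dxhat <- dym * m$params$gamma$value
  nb <- ncol(dym)
  dx <- (m$invstd / nb) *
    (nb * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  m$xhat <- NULL
  dim(dx) <- d
  dx
}

nn_relu <- function() new_module("nn_relu")

#' @export
nn_forward.nn_relu <- function(m, x, ...) {
  y <- x * (x > 0)
  if (m$training) m$mask <- x > 0
  y
}

#' @export
nn_backward.nn_relu <- function(m, dy, ...) {
  dx <- dy * m$mask
  m$mask <- NULL
  dx
}

nn_sigmoid <- function() new_module("nn_sigmoid")

#' @export
nn_forward.nn_sigmoid <- function(m, x, ...) {
  y <- 1 / (1 + exp(-x))
  if (m$training) m$y <- y
  y
}

#' @export
nn_backward.nn_sigmoid <- function(m, dy, ...) {
  dx <- dy * m$y * (1 - m$y)
  m$y <- NULL
  dx
}

# Exact GELU: x * Phi(x)
nn_gelu <- function() new_module("nn_gelu")

#' @export
nn_forward.nn_gelu <- function(m, x, ...) {
  p <- stats::pnorm(x)
  if (m$training) m$x <- x
  x * p
}

#' @export
nn_backward.nn_gelu <- function(m, dy, ...) {
  x <- m$x
  m$x <- NULL
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}

# Fully connected layer on [C_in, B]
nn_linear <- function(c_in, c_out, bias = TRUE) {
  params <- list(weight = new_param(kaiming_matrix(c_out, c_in, fan_in = c_in)))
  if (bias) params$bias <- new_param(numeric(c_out))
  new_module("nn_linear", params = params, c_in = c_in, c_out = c_out,
             use_bias = bias)
}

#' @export
nn_forward.nn_linear <- function(m, x, ...) {
  if (nrow(x) != m$c_in) {
    stop("linear: input has ", nrow(x), " features, layer expects ", m$c_in)
  }
  y <- m$params$weight$value %*% x
  if (m$use_bias) y <- y + m$params$bias$value
  if (m$training) m$x <- x
  y
}

#' @export
nn_backward.nn_linear <- function(m, dy, ...) {
  accumulate_grad(m$params$weight, dy %*% t(m$x))
  if (m$use_bias) accumulate_grad(m$params$bias, rowSums(dy))
  m$x <- NULL
  crossprod(m$params$weight$value, dy)
}

# Layer normalisation over the feature (row) dimension of [C, B] tokens.
nn_layernorm <- function(c, eps = 1e-5) {
  new_module("nn_layernorm",
             params = list(gamma = new_param(rep(1, c)),
                           beta = new_param(numeric(c))),
             c = c, eps = eps)
}

#' @export
nn_forward.nn_layernorm <- function(m, x, ...) {
  mu <- colMeans(x)
  xc <- x - rep(mu, each = m$c)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + m$eps)
  xhat <- xc * rep(invstd, each = m$c)
  if (m$training) {
    m$xhat <- xhat
    m$invstd <- invstd
  }
  m$params$gamma$value * xhat + m$params$beta$value
}

#' @export
nn_backward.nn_layernorm <- function(m, dy, ...) {
  xhat <- m$xhat
  accumulate_grad(m$params$gamma, rowSums(dy * xhat))
  accumulate_grad(m$params$beta, rowSums(dy))
  dxhat <- dy * m$params$gamma$value
  nc <- m$c
  t1 <- rep(colMeans(dxhat), each = nc)
  t2 <- xhat * rep(colMeans(dxhat * xhat), each = nc)
  dx <- (dxhat - t1 - t2) * rep(m$invstd, each = nc)
  m$xhat <- NULL
  dx
}

# Inverted dropout (identity in inference mode)
nn_dropout <- function(rate) new_module("nn_dropout", rate = rate)

#' @export
nn_forward.nn_dropout <- function(m, x, ...) {
  if (!m$training || m$rate <= 0) return(x)
  keep <- 1 - m$rate
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  m$mask <- mask
  x * mask
}

#' @export
nn_backward.nn_dropout <- function(m, dy, ...) {
  if (!m$training || m$rate <= 0) return(dy)
  dx <- dy * m$mask
  m$mask <- NULL
  dx
}

nn_maxpool <- function(k, stride, pad = 0L) {
  new_module("nn_maxpool", k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad))
}

#' @export
nn_forward.nn_maxpool <- function(m, x, ...) {
  d <- dim(x)
  res <- maxpool_fwd(x, d[1], d[2], d[3], d[4], m$k, m$stride, m$pad)
  m$in_len <- length(x)
  if (m$training) m$argmax <- res$argmax
  y <- res$y
  dim(y) <- c(d[1], conv_out_size(d[2], m$k, m$stride, m$pad),
              conv_out_size(d[3], m$k, m$stride, m$pad), d[4])
  m$in_dim <- d
  y
}

#' @export
nn_backward.nn_maxpool <- function(m, dy, ...) {
  dx <- maxpool_bwd(dy, m$argmax, m$in_len)
  m$argmax <- NULL
  dim(dx) <- m$in_dim
  dx
}

# Average pooling by an integer factor (used for scale alignment); input
# spatial sizes must be multiples of the factor.
nn_avgpool_factor <- function(f) new_module("nn_avgpool_factor", f = as.integer(f))

#' @export
nn_forward.nn_avgpool_factor <- function(m, x, ...) {
  d <- dim(x)
  f <- m$f
  m$in_dim <- d
  if (f == 1L) return(x)
  if (d[2] %% f != 0 || d[3] %% f != 0) {
    stop("avgpool: spatial size ", d[2], "x", d[3],
         " not divisible by factor ", f)
  }
  oh <- d[2] %/% f
  ow <- d[3] %/% f
  x6 <- x
  dim(x6) <- c(d[1], f, oh, f, ow, d[4])
  y <- aperm(x6, c(1, 3, 5, 6, 2, 4))
  dim(y) <- c(d[1] * oh * ow * d[4], f * f)
  y <- rowMeans(y)
  dim(y) <- c(d[1], oh, ow, d[4])
  y
}

#' @export
nn_backward.nn_avgpool_factor <- function(m, dy, ...) {
  d <- m$in_dim
  f <- m$f
  if (f == 1L) return(dy)
  oh <- d[2] %/% f
  ow <- d[3] %/% f
  g <- as.vector(dy) / (f * f)
  dx <- array(0, dim = c(d[1], oh, ow, d[4], f, f))
  dx[] <- g  # recycles over the two trailing factor dimensions
  dx <- aperm(dx, c(1, 5, 2, 6, 3, 4))
  dim(dx) <- d
  dx
}

# Global average pooling [C,H,W,N] -> [C,N]
nn_gap <- function() new_module("nn_gap")

#' @export
nn_forward.nn_gap <- function(m, x, ...) {
  d <- dim(x)
  m$in_dim <- d
  y <- aperm(x, c(1, 4, 2, 3))
  dim(y) <- c(d[1] * d[4], d[2] * d[3])
  y <- rowMeans(y)
  dim(y) <- c(d[1], d[4])
  y
}

#' @export
nn_backward.nn_gap <- function(m, dy, ...) {
  d <- m$in_dim
  hw <- d[2] * d[3]
  dx <- array(0, dim = c(d[1], d[4], hw))
  dx[] <- as.vector(dy) / hw
  dx <- aperm(dx, c(1, 3, 2))
  dim(dx) <- d
  dx
}

# Broadcast helpers for attention gating ------------------------------------

# x [C,H,W,N] * gate [C,N] broadcast over space; returns list(y) and a
# closure-free backward via explicit helper functions.
mul_channel_gate <- function(x, gate) {
  d <- dim(x)
  hw <- d[2] * d[3]
  xm <- matrix(x, nrow = d[1])
  gexp <- gate[, rep(seq_len(d[4]), each = hw), drop = FALSE]
  y <- xm * gexp
  dim(y) <- d
  y
}

mul_channel_gate_bwd <- function(dy, x, gate) {
  d <- dim(x)
  hw <- d[2] * d[3]
  dym <- matrix(dy, nrow = d[1])
  gexp <- gate[, rep(seq_len(d[4]), each = hw), drop = FALSE]
  dx <- dym * gexp
  dim(dx) <- d
  prod <- dym * matrix(x, nrow = d[1])
  dim(prod) <- c(d[1] * hw, d[4])
  dgate <- prod
  dim(dgate) <- c(d[1], hw, d[4])
  dgate <- apply(dgate, c(1, 3), sum)
  list(dx = dx, dgate = dgate)
}

# x [C,H,W,N] * sal [1,H,W,N] broadcast over channels
mul_spatial_gate <- function(x, sal) {
  d <- dim(x)
  y <- matrix(x, nrow = d[1]) * rep(as.vector(sal), each = d[1])
  dim(y) <- d
  y
}

mul_spatial_gate_bwd <- function(dy, x, sal) {
  d <- dim(x)
  sv <- rep(as.vector(sal), each = d[1])
  dx <- matrix(dy, nrow = d[1]) * sv
  dim(dx) <- d
  dsal <- colSums(matrix(dy, nrow = d[1]) * matrix(x, nrow = d[1]))
  dim(dsal) <- c(1, d[2], d[3], d[4])
  list(dx = dx, dgate = dsal)
}
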