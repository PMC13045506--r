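# Multi-head self-attention over token tensors [C, T, N] (C = model dim,
# T = tokens, N = batch) and a pre-norm transformer encoder layer with
# learned positional embeddings. Used by the cross-scale interaction block
# to model long-range dependencies across flattened spatial positions.

softmax_rows <- function(S) {
  S <- exp(S - apply(S, 1, max))
  S / rowSums(S)
}

nn_mhsa <- function(c, heads) {
  stopifnot(c %% heads == 0)
  new_module("nn_mhsa",
             params = list(
               wq = new_param(kaiming_matrix(c, c, fan_in = c)),
               bq = new_param(numeric(c)),
               wk = new_param(kaiming_matrix(c, c, fan_in = c)),
               bk = new_param(numeric(c)),
               wv = new_param(kaiming_matrix(c, c, fan_in = c)),
               bv = new_param(numeric(c)),
               wo = new_param(kaiming_matrix(c, c, fan_in = c)),
               bo = new_param(numeric(c))),
             c = c, heads = as.integer(heads), dh = c %/% heads)
}

#' @export
nn_forward.nn_mhsa <- function(m, x, ...) {
  d <- dim(x)
  tt <- d[2]
  nn <- d[3]
  xm <- matrix(x, nrow = m$c)
  q <- m$params$wq$value %*% xm + m$params$bq$value
  k <- m$params$wk$value %*% xm + m$params$bk$value
  v <- m$params$wv$value %*% xm + m$params$bv$value
  o <- matrix(0, m$c, tt * nn)
  scale <- 1 / sqrt(m$dh)
  attn <- if (m$training) vector("list", nn * m$heads) else NULL
  for (n in seq_len(nn)) {
    cols <- ((n - 1L) * tt + 1L):(n * tt)
    for (h in seq_len(m$heads)) {
      rows <- ((h - 1L) * m$dh + 1L):(h * m$dh)
      a <- softmax_rows(crossprod(q[rows, cols, drop = FALSE],
                                  k[rows, cols, drop = FALSE]) * scale)
      o[rows, cols] <- v[rows, cols, drop = FALSE] %*% t(a)
      if (m$training) attn[[(n - 1L) * m$heads + h]] <- a
    }
  }
  y <- m$params$wo$value %*% o + m$params$bo$value
  if (m$training) {
    m$xm <- xm; m$q <- q; m$k <- k; m$v <- v; m$o <- o; m$attn <- attn
    m$tok <- tt; m$batch <- nn
  }
  dim(y) <- d
  y
}

#' @export
nn_backward.nn_mhsa <- function(m, dy, ...) {
  d <- dim(dy)
  tt <- m$tok
  nn <- m$batch
  dym <- matrix(dy, nrow = m$c)
  accumulate_grad(m$params$wo, dym %*% t(m$o))
  accumulate_grad(m$params$bo, rowSums(dym))
  do <- crossprod(m$params$wo$value, dym)
  dq <- matrix(0, m$c, tt * nn)
  dk <- matrix(0, m$c, tt * nn)
  dv <- matrix(0, m$c, tt * nn)
  scale <- 1 / sqrt(m$dh)
  for (n in seq_len(nn)) {
    cols <- ((n - 1L) * tt + 1L):(n * tt)
    for (h in seq_len(m$heads)) {
      rows <- ((h - 1L) * m$dh + 1L):(h * m$dh)
      a <- m$attn[[(n - 1L) * m$heads + h]]
      doh <- do[rows, cols, drop = FALSE]
      vh <- m$v[rows, cols, drop = FALSE]
      dv[rows, cols] <- doh %*% a
      da <- crossprod(doh, vh)
      ds <- a * (da - rowSums(da * a))
      dq[rows, cols] <- m$k[rows, cols, drop = FALSE] %*% t(ds) * scale
      dk[rows, cols] <- m$q[rows, cols, drop = FALSE] %*% ds * scale
    }
  }
  accumulate_grad(m$params$wq, dq %*% t(m$xm))
  accumulate_grad(m$params$bq, rowSums(dq))
  accumulate_grad(m$params$wk, dk %*% t(m$xm))
  accumulate_grad(m$params$bk, rowSums(dk))
  accumulate_grad(m$params$wv, dv %*% t(m$xm))
  accumulate_grad(m$params$bv, rowSums(dv))
  dx <- crossprod(m$params$wq$value, dq) +
    crossprod(m$params$wk$value, dk) +
    crossprod(m$params$wv$value, dv)
  m$xm <- NULL; m$q <- NULL; m$k <- NULL; m$v <- NULL
  m$o <- NULL; m$attn <- NULL
  dim(dx) <- d
  dx
}

# One pre-norm transformer encoder layer:
#   x  <- x + pos
#   x1 <- x + MHSA(LN1(x))
#   x2 <- x1 + Lin2(GELU(Lin1(LN2(x1))))
# Feed-forward width = ffn_mult * C. Positional embeddings are a learned
# [C, T] table added to the token tensor on entry.
nn_tf_encoder <- function(c, tokens, heads = 8L, ffn_mult = 1) {
  ffn <- as.integer(round(ffn_mult * c))
  new_module("nn_tf_encoder",
             params = list(pos = new_param(
               matrix(stats::rnorm(c * tokens, sd = 0.02), c, tokens))),
             children = list(
               ln1 = nn_layernorm(c),
               attn = nn_mhsa(c, heads),
               ln2 = nn_layernorm(c),
               ffn1 = nn_linear(c, ffn),
               gelu = nn_gelu(),
               ffn2 = nn_linear(ffn, c)),
             c = c, tokens = as.integer(tokens))
}

#' @export
nn_forward.nn_tf_encoder <- function(m, x, ...) {
  d <- dim(x)
  if (d[2] != m$tokens) {
    stop("transformer encoder: got ", d[2], " tokens, expected ", m$tokens)
  }
  xp <- x + as.vector(m$params$pos$value)  # recycled over the batch dim
  xpm <- matrix(xp, nrow = m$c)
  a <- nn_forward(m$children$ln1, xpm)
  dim(a) <- d
  a <- nn_forward(m$children$attn, a)
  x1 <- xp + a
  x1m <- matrix(x1, nrow = m$c)
  f <- nn_forward(m$children$ln2, x1m)
  f <- nn_forward(m$children$ffn1, f)
  f <- nn_forward(m$children$gelu, f)
  f <- nn_forward(m$children$ffn2, f)
  y <- x1 + array(f, dim = d)
  m$batch <- d[3]
  y
}

#' @export
nn_backward.nn_tf_encoder <- function(m, dy, ...) {
  d <- dim(dy)
  dym <- matrix(dy, nrow = m$c)
  df <- nn_backward(m$children$ffn2, dym)
  df <- nn_backward(m$children$gelu, df)
  df <- nn_backward(m$children$ffn1, df)
  df <- nn_backward(m$children$ln2, df)
  dx1 <- dy + array(df, dim = d)
  da <- nn_backward(m$children$attn, dx1)
  da <- nn_backward(m$children$ln1, matrix(da, nrow = m$c))
  dxp <- dx1 + array(da, dim = d)
  dpos <- matrix(dxp, nrow = m$c * m$tokens)
  accumulate_grad(m$params$pos,
                  matrix(rowSums(dpos), m$c, m$tokens))
  dxp
}
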