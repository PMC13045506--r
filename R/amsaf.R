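# Adaptive multi-scale attention fusion (AMSAF).
#
# The four pyramid levels are aligned to the deepest level's spatial
# resolution and unified to a common channel width; a global context map is
# built from their channel-wise concatenation; squeeze-and-excitation channel
# attention and a channel-pooled spatial saliency map are derived from the
# global context and used to recalibrate each aligned scale (cross-scale
# interaction block, CSIB), whose gated output is flattened to h*w tokens and
# refined by a per-scale transformer encoder; finally a weighted feature
# aggregation (WFA) branch produces content-adaptive softmax weights over the
# four refined maps and fuses them as a convex combination.

#' AMSAF hyperparameters
#'
#' @param se_ratio squeeze-and-excitation bottleneck reduction ratio.
#' @param spatial_kernel kernel size of the spatial-saliency convolution
#'   (odd; padding keeps the map size).
#' @param tf_layers number of transformer encoder layers per scale.
#' @param tf_heads attention heads per encoder layer.
#' @param tf_ffn_mult feed-forward width as a multiple of the model dim.
#' @param share_tf share one encoder across the four scales (inference only;
#'   the default keeps unshared per-scale encoders).
#' @return list of settings for [build_model()].
#' @export
amsaf_config <- function(se_ratio = 16L, spatial_kernel = 7L, tf_layers = 1L,
                         tf_heads = 8L, tf_ffn_mult = 1, share_tf = FALSE) {
  stopifnot(spatial_kernel %% 2L == 1L, tf_layers >= 1L)
  list(se_ratio = as.integer(se_ratio),
       spatial_kernel = as.integer(spatial_kernel),
       tf_layers = as.integer(tf_layers),
       tf_heads = as.integer(tf_heads),
       tf_ffn_mult = tf_ffn_mult,
       share_tf = isTRUE(share_tf))
}

# Squeeze-and-excitation gate: global average pool -> C/r -> ReLU -> C ->
# sigmoid. Forward maps [C,H,W,N] to a gate [C,N]; backward maps the gate
# gradient back to the input.
nn_se <- function(c, ratio = 16L) {
  hidden <- max(1L, c %/% ratio)
  new_module("nn_se",
             children = list(gap = nn_gap(),
                             fc1 = nn_linear(c, hidden),
                             relu = nn_relu(),
                             fc2 = nn_linear(hidden, c),
                             sig = nn_sigmoid()),
             c = c, hidden = hidden)
}

#' @export
nn_forward.nn_se <- function(m, x, ...) {
  ch <- m$children
  s <- nn_forward(ch$gap, x)
  nn_forward(ch$sig,
             nn_forward(ch$fc2,
                        nn_forward(ch$relu, nn_forward(ch$fc1, s))))
}

#' @export
nn_backward.nn_se <- function(m, dy, ...) {
  ch <- m$children
  d <- nn_backward(ch$sig, dy)
  d <- nn_backward(ch$fc2, d)
  d <- nn_backward(ch$relu, d)
  d <- nn_backward(ch$fc1, d)
  nn_backward(ch$gap, d)
}

# Spatial attention: channel-wise mean and max maps, stacked [2,H,W,N],
# kxk convolution, sigmoid -> saliency [1,H,W,N].
nn_spatial_attn <- function(k = 7L) {
  new_module("nn_spatial_attn",
             children = list(
               conv = nn_conv2d(2L, 1L, k, pad = (k - 1L) %/% 2L, bias = TRUE),
               sig = nn_sigmoid()),
             k = as.integer(k))
}

#' @export
nn_forward.nn_spatial_attn <- function(m, x, ...) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  mean_map <- colMeans(xm)
  amax <- max.col(t(xm), ties.method = "first")
  max_map <- xm[cbind(amax, seq_along(amax))]
  s <- rbind(mean_map, max_map)
  dim(s) <- c(2L, d[2], d[3], d[4])
  if (m$training) {
    m$amax <- amax
    m$in_dim <- d
  }
  nn_forward(m$children$sig, nn_forward(m$children$conv, s))
}

#' @export
nn_backward.nn_spatial_attn <- function(m, dy, ...) {
  d <- m$in_dim
  ds <- nn_backward(m$children$conv, nn_backward(m$children$sig, dy))
  dsm <- matrix(ds, nrow = 2L)
  dx <- matrix(rep(dsm[1L, ] / d[1], each = d[1]), nrow = d[1])
  idx <- cbind(m$amax, seq_along(m$amax))
  dx[idx] <- dx[idx] + dsm[2L, ]
  m$amax <- NULL
  dim(dx) <- d
  dx
}

# Column-wise softmax for the WFA weights [4, N]
softmax_cols <- function(z) {
  z <- exp(z - rep(apply(z, 2, max), each = nrow(z)))
  z / rep(colSums(z), each = nrow(z))
}

build_csib_encoder <- function(c, tokens, cfg) {
  layers <- lapply(seq_len(cfg$tf_layers), function(i) {
    nn_tf_encoder(c, tokens, heads = cfg$tf_heads, ffn_mult = cfg$tf_ffn_mult)
  })
  if (cfg$tf_layers == 1L) layers[[1]] else nn_sequential(layers)
}

# The full AMSAF head. `in_channels` are the four pyramid widths, `c` the
# unified width (deepest level), `hw` the deepest level's spatial size.
nn_amsaf <- function(in_channels, c, hw, cfg = amsaf_config()) {
  tokens <- hw[1] * hw[2]
  half <- max(1L, c %/% 2L)
  ch <- list()
  factors <- c(8L, 4L, 2L, 1L)
  for (n in 1:4) {
    ch[[paste0("align", n)]] <- nn_sequential(list(
      pool = nn_avgpool_factor(factors[n]),
      conv = nn_conv2d(in_channels[n], c, 1L, bias = TRUE),
      relu = nn_relu()))
  }
  ch$gconv <- nn_conv2d(4L * c, c, 1L, bias = TRUE)
  ch$grelu <- nn_relu()
  ch$se <- nn_se(c, cfg$se_ratio)
  ch$spa <- nn_spatial_attn(cfg$spatial_kernel)
  if (cfg$share_tf) {
    ch$enc <- build_csib_encoder(c, tokens, cfg)
  } else {
    for (n in 1:4) ch[[paste0("enc", n)]] <- build_csib_encoder(c, tokens, cfg)
  }
  for (n in 1:4) {
    ch[[paste0("red", n)]] <- nn_sequential(list(
      conv = nn_conv2d(c, half, 1L, bias = TRUE),
      relu = nn_relu()))
    ch[[paste0("wgap", n)]] <- nn_gap()
  }
  ch$wlin <- nn_linear(4L * half, 4L)
  new_module("nn_amsaf", children = ch, c = c, half = half, hw = hw,
             tokens = tokens, cfg = cfg)
}

amsaf_encoder <- function(m, n) {
  if (m$cfg$share_tf) m$children$enc else m$children[[paste0("enc", n)]]
}

# Forward over a pyramid list(c2..c5); returns list(fused, weights).
#' @export
nn_forward.nn_amsaf <- function(m, x, ...) {
  ch <- m$children
  al <- lapply(1:4, function(n) nn_forward(ch[[paste0("align", n)]], x[[n]]))
  d <- dim(al[[1]])
  cc <- array(0, dim = c(4L * m$c, d[2], d[3], d[4]))
  for (n in 1:4) cc[((n - 1L) * m$c + 1L):(n * m$c), , , ] <- al[[n]]
  g <- nn_forward(ch$grelu, nn_forward(ch$gconv, cc))
  ca <- nn_forward(ch$se, g)
  sa <- nn_forward(ch$spa, g)
  if (m$training && m$cfg$share_tf) {
    stop("share_tf = TRUE supports inference only (per-scale gradient caches)")
  }
  gated <- vector("list", 4L)
  refined <- vector("list", 4L)
  for (n in 1:4) {
    g1 <- mul_channel_gate(al[[n]], ca)
    g2 <- mul_spatial_gate(g1, sa)
    dim(g2) <- c(m$c, m$tokens, d[4])
    r <- nn_forward(amsaf_encoder(m, n), g2)
    dim(r) <- d
    dim(g2) <- d
    gated[[n]] <- g1
    refined[[n]] <- r
  }
  pooled <- vector("list", 4L)
  for (n in 1:4) {
    rn <- nn_forward(ch[[paste0("red", n)]], refined[[n]])
    pooled[[n]] <- nn_forward(ch[[paste0("wgap", n)]], rn)
  }
  z <- nn_forward(ch$wlin, do.call(rbind, pooled))
  wts <- softmax_cols(z)
  chw <- m$c * d[2] * d[3]
  fused <- array(0, dim = d)
  for (n in 1:4) fused <- fused + refined[[n]] * rep(wts[n, ], each = chw)
  if (m$training) {
    m$al <- al
    m$ca <- ca
    m$sa <- sa
    m$gated <- gated
    m$refined <- refined
    m$wts <- wts
    m$dims <- d
  }
  list(fused = fused, weights = wts)
}

# dy: list(fused = gradient wrt fused map). Returns pyramid gradients.
#' @export
nn_backward.nn_amsaf <- function(m, dy, ...) {
  ch <- m$children
  d <- m$dims
  chw <- m$c * d[2] * d[3]
  df <- dy$fused
  wts <- m$wts
  drefined <- vector("list", 4L)
  dwts <- matrix(0, 4L, d[4])
  for (n in 1:4) {
    drefined[[n]] <- df * rep(wts[n, ], each = chw)
    dwts[n, ] <- colSums(matrix(df * m$refined[[n]], nrow = chw))
  }
  dz <- wts * (dwts - rep(colSums(dwts * wts), each = 4L))
  dpc <- nn_backward(ch$wlin, dz)
  for (n in 1:4) {
    rows <- ((n - 1L) * m$half + 1L):(n * m$half)
    drn <- nn_backward(ch[[paste0("wgap", n)]], dpc[rows, , drop = FALSE])
    drefined[[n]] <- drefined[[n]] + nn_backward(ch[[paste0("red", n)]], drn)
  }
  dca <- 0
  dsa <- 0
  dal <- vector("list", 4L)
  for (n in 1:4) {
    dr <- drefined[[n]]
    dim(dr) <- c(m$c, m$tokens, d[4])
    dtok <- nn_backward(amsaf_encoder(m, n), dr)
    dim(dtok) <- d
    sb <- mul_spatial_gate_bwd(dtok, m$gated[[n]], m$sa)
    cb <- mul_channel_gate_bwd(sb$dx, m$al[[n]], m$ca)
    dal[[n]] <- cb$dx
    dca <- dca + cb$dgate
    dsa <- dsa + sb$dgate
  }
  dg <- nn_backward(ch$se, dca) + nn_backward(ch$spa, dsa)
  dcc <- nn_backward(ch$gconv, nn_backward(ch$grelu, dg))
  dpyr <- vector("list", 4L)
  for (n in 1:4) {
    dal[[n]] <- dal[[n]] +
      dcc[((n - 1L) * m$c + 1L):(n * m$c), , , , drop = FALSE]
    dpyr[[n]] <- nn_backward(ch[[paste0("align", n)]], dal[[n]])
  }
  m$al <- NULL; m$gated <- NULL; m$refined <- NULL
  names(dpyr) <- c("c2", "c3", "c4", "c5")
  dpyr
}

# User-facing staged operations ----------------------------------------------

get_amsaf <- function(model) {
  am <- model$children$amsaf
  if (is.null(am)) {
    stop("this model variant ('", model$config$variant,
         "') has no multi-scale fusion head")
  }
  am
}

pyramid_as_batch <- function(pyramid) {
  single <- length(dim(pyramid[[1]])) == 3L
  list(pyr = lapply(pyramid, as_batch), single = single)
}

#' Align and unify the feature pyramid
#'
#' Downsamples each pyramid level to the deepest level's spatial resolution
#' (area-style average pooling) and maps it to the unified channel width with
#' a learned 1x1 convolution + ReLU (the deepest level also passes through
#' its own 1x1 transform).
#'
#' @param model a model with a fusion head (`amsaf` variant).
#' @param pyramid list `c2..c5` as returned by [hierarchical_forward()].
#' @return list of four aligned feature maps of identical shape.
#' @export
align_and_unify <- function(model, pyramid) {
  am <- get_amsaf(model)
  pb <- pyramid_as_batch(pyramid)
  out <- lapply(1:4, function(n) {
    nn_forward(am$children[[paste0("align", n)]], pb$pyr[[n]])
  })
  names(out) <- paste0("scale", 1:4)
  lapply(out, drop_batch, single = pb$single)
}

#' Build the global context map
#'
#' Channel-concatenates the four aligned scales and reconciles them with a
#' 1x1 convolution + ReLU into one `[C, h, w]` global context map.
#'
#' @param model a model with a fusion head.
#' @param aligned list of four aligned maps from [align_and_unify()].
#' @return global context array with the shape of one aligned scale.
#' @export
build_global_context <- function(model, aligned) {
  am <- get_amsaf(model)
  single <- length(dim(aligned[[1]])) == 3L
  al <- lapply(aligned, as_batch)
  d <- dim(al[[1]])
  cc <- array(0, dim = c(4L * am$c, d[2], d[3], d[4]))
  for (n in 1:4) cc[((n - 1L) * am$c + 1L):(n * am$c), , , ] <- al[[n]]
  g <- nn_forward(am$children$grelu, nn_forward(am$children$gconv, cc))
  drop_batch(g, single)
}

#' Channel attention gate from the global context
#'
#' Squeeze-and-excitation: global average pooling followed by a two-layer
#' bottleneck and a sigmoid, yielding one gate per channel in `(0, 1)`.
#'
#' @param model a model with a fusion head.
#' @param g global context array from [build_global_context()].
#' @return gate array `[C, 1, 1]` (or `[C, 1, 1, N]` for batches).
#' @export
channel_attention <- function(model, g) {
  am <- get_amsaf(model)
  single <- length(dim(g)) == 3L
  gate <- nn_forward(am$children$se, as_batch(g))
  dim(gate) <- c(am$c, 1L, 1L, ncol(gate))
  drop_batch(gate, single)
}

#' Spatial attention map from the global context
#'
#' Channel-wise mean and max maps are stacked and convolved into a sigmoid
#' saliency map with one value per spatial location.
#'
#' @param model a model with a fusion head.
#' @param g global context array.
#' @return saliency array `[1, h, w]` (batched when `g` is).
#' @export
spatial_attention <- function(model, g) {
  am <- get_amsaf(model)
  single <- length(dim(g)) == 3L
  drop_batch(nn_forward(am$children$spa, as_batch(g)), single)
}

#' Refine one aligned scale (cross-scale interaction block)
#'
#' Multiplies the scale by the channel gate (broadcast over space), then by
#' the spatial saliency map (broadcast over channels), flattens the result to
#' `h*w` tokens of dimension `C` and passes them through the scale's
#' transformer encoder.
#'
#' @param model a model with a fusion head.
#' @param scale one aligned feature map `[C, h, w]`.
#' @param ca channel gate from [channel_attention()].
#' @param sa spatial map from [spatial_attention()].
#' @param n scale index in `1:4`.
#' @return refined feature map, same shape as `scale`.
#' @export
csib_refine <- function(model, scale, ca, sa, n) {
  stopifnot(n %in% 1:4)
  am <- get_amsaf(model)
  single <- length(dim(scale)) == 3L
  x <- as_batch(scale)
  d <- dim(x)
  gate <- as_batch(ca)
  dim(gate) <- c(am$c, dim(gate)[4])
  g1 <- mul_channel_gate(x, gate)
  g2 <- mul_spatial_gate(g1, as_batch(sa))
  if (d[2] * d[3] != am$tokens) {
    stop("csib: ", d[2] * d[3], " tokens after flattening, encoder expects ",
         am$tokens)
  }
  dim(g2) <- c(am$c, am$tokens, d[4])
  r <- nn_forward(amsaf_encoder(am, n), g2)
  dim(r) <- d
  drop_batch(r, single)
}

#' Confidence-weighted fusion of the refined scales
#'
#' Each refined map is channel-reduced to `C/2` by a dedicated 1x1
#' convolution + ReLU, globally pooled, and the four pooled vectors are
#' concatenated and passed through a linear layer + softmax to produce one
#' weight per scale; the fused map is the convex combination of the
#' full-width refined maps under those weights.
#'
#' @param model a model with a fusion head.
#' @param refined list of four refined maps from [csib_refine()].
#' @return list with `fused` (feature map) and `weights` (length-4 simplex
#'   vector, or `[4, N]` matrix for batches).
#' @export
wfa_fuse <- function(model, refined) {
  am <- get_amsaf(model)
  single <- length(dim(refined[[1]])) == 3L
  rf <- lapply(refined, as_batch)
  d <- dim(rf[[1]])
  pooled <- lapply(1:4, function(n) {
    rn <- nn_forward(am$children[[paste0("red", n)]], rf[[n]])
    nn_forward(am$children[[paste0("wgap", n)]], rn)
  })
  z <- nn_forward(am$children$wlin, do.call(rbind, pooled))
  wts <- softmax_cols(z)
  chw <- prod(d[1:3])
  fused <- array(0, dim = d)
  for (n in 1:4) fused <- fused + rf[[n]] * rep(wts[n, ], each = chw)
  list(fused = drop_batch(fused, single),
       weights = if (single) drop(wts) else wts)
}

#' Full fusion-head forward pass
#'
#' Composition of [align_and_unify()], [build_global_context()],
#' [channel_attention()], [spatial_attention()], [csib_refine()] and
#' [wfa_fuse()] in that order.
#'
#' @param model a model with a fusion head.
#' @param pyramid list `c2..c5` of backbone features.
#' @return list with `fused` feature map and the simplex `weights`.
#' @export
amsaf_forward <- function(model, pyramid) {
  am <- get_amsaf(model)
  pb <- pyramid_as_batch(pyramid)
  out <- nn_forward(am, pb$pyr)
  list(fused = drop_batch(out$fused, pb$single),
       weights = if (pb$single) drop(out$weights) else out$weights)
}
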