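# Independent layer-shape enumeration oracle: walks the declared layer list
# of a configuration and sums k*k*C_in*C_out (+ C_out bias) convolution
# terms and 2*C normalisation/affine terms analytically, without touching
# any built module. Used to audit the counts the engine itself reports.

#' Enumerate parameter counts analytically from a configuration
#'
#' Produces a per-layer table of trainable parameter counts derived from the
#' architecture's declared shapes (convolution `k*k*C_in*C_out + bias`,
#' affine normalisation `2*C`, linear `C_in*C_out + C_out`, positional
#' embedding `C*T`), plus per-module totals. Entirely independent of the
#' network-building code.
#'
#' @param cfg a [model_config()].
#' @return list with `layers` (data frame `module`, `layer`, `params`) and
#'   `modules` (named vector of per-module totals including `total`).
#' @export
enumerate_param_counts <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "wheat_model_config"))
  w <- width_preset(cfg$width_preset)
  rows <- list()
  add <- function(module, layer, params) {
    rows[[length(rows) + 1L]] <<- data.frame(module = module, layer = layer,
                                             params = params)
  }
  conv <- function(k, cin, cout, bias = FALSE) k * k * cin * cout +
    if (bias) cout else 0
  norm <- function(c) 2 * c
  lin <- function(cin, cout, bias = TRUE) cin * cout + if (bias) cout else 0

  add("stem", "conv7x7", conv(7, 3, w$stem))
  add("stem", "norm", norm(w$stem))

  cin <- w$stem
  for (i in 1:4) {
    mid <- w$mids[i]
    out <- w$outs[i]
    for (b in seq_len(w$blocks[i])) {
      tag <- sprintf("stage%d.block%d", i + 1L, b)
      add("hierarchical", paste0(tag, ".conv1"), conv(1, cin, mid) + norm(mid))
      add("hierarchical", paste0(tag, ".conv2"), conv(3, mid, mid) + norm(mid))
      add("hierarchical", paste0(tag, ".conv3"), conv(1, mid, out) + norm(out))
      if (b == 1L) {
        add("hierarchical", paste0(tag, ".proj"), conv(1, cin, out) + norm(out))
      }
      cin <- out
    }
  }

  c5 <- w$outs[4]
  acfg <- cfg$amsaf
  se_hidden <- max(1, c5 %/% acfg$se_ratio)
  se_params <- lin(c5, se_hidden) + lin(se_hidden, c5)
  spa_params <- conv(acfg$spatial_kernel, 2, 1, bias = TRUE)
  if (cfg$variant == "channel_attention") {
    add("amsaf", "se", se_params)
  } else if (cfg$variant == "spatial_attention") {
    add("amsaf", "spatial", spa_params)
  } else if (cfg$variant == "multiscale_fusion") {
    for (n in 1:4) add("amsaf", paste0("align", n), conv(1, w$outs[n], c5, TRUE))
  } else if (cfg$variant == "amsaf") {
    for (n in 1:4) add("amsaf", paste0("align", n), conv(1, w$outs[n], c5, TRUE))
    add("amsaf", "global_ctx", conv(1, 4 * c5, c5, TRUE))
    add("amsaf", "se", se_params)
    add("amsaf", "spatial", spa_params)
    tokens <- (cfg$image_size %/% 32L)^2
    ffn <- round(acfg$tf_ffn_mult * c5)
    enc <- c5 * tokens +                      # positional embedding
      2 * norm(c5) +                          # two layer norms
      4 * lin(c5, c5) +                       # q, k, v, o projections
      lin(c5, ffn) + lin(ffn, c5)             # feed-forward
    enc <- enc * acfg$tf_layers
    n_enc <- if (acfg$share_tf) 1L else 4L
    for (n in seq_len(n_enc)) add("amsaf", paste0("encoder", n), enc)
    half <- max(1, c5 %/% 2L)
    for (n in 1:4) add("amsaf", paste0("reduce", n), conv(1, c5, half, TRUE))
    add("amsaf", "weight_fc", lin(4 * half, 4))
  }

  add("head", "norm", norm(c5))
  add("head", "fc", lin(c5, cfg$num_classes))

  layers <- do.call(rbind, rows)
  modules <- tapply(layers$params, layers$module, sum)
  all_mods <- c("stem", "hierarchical", "amsaf", "head")
  out <- stats::setNames(numeric(length(all_mods)), all_mods)
  out[names(modules)] <- modules
  out <- c(out, total = sum(out))
  list(layers = layers, modules = out)
}
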