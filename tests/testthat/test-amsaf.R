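# Fusion-head behaviour: alignment, global context, dual attention gates,
# transformer refinement and confidence-weighted aggregation, checked on the
# tiny preset against closed forms and structural identities.

rand_pyramid <- function(side = 64L, n = 1L, sd = 1) {
  list(c2 = rand4(32, side / 4, side / 4, n, sd),
       c3 = rand4(64, side / 8, side / 8, n, sd),
       c4 = rand4(128, side / 16, side / 16, n, sd),
       c5 = rand4(256, side / 32, side / 32, n, sd))
}

drop_n <- function(p) lapply(p, function(a) {
  d <- dim(a)
  dim(a) <- d[-4]
  a
})

test_that("alignment produces four identical-shape maps; zeros map to per-channel constants", {
  m <- tiny_model()
  set.seed(21)
  pyr <- drop_n(rand_pyramid())
  al <- align_and_unify(m, pyr)
  for (a in al) expect_equal(dim(a), c(256, 2, 2))

  zeros <- lapply(pyr, function(x) array(0, dim = dim(x)))
  alz <- align_and_unify(m, zeros)
  for (n in 1:4) {
    a <- alz[[n]]
    bias <- m$children$amsaf$children[[paste0("align", n)]]$children$conv$params$bias$value
    expect_equal(a, array(pmax(bias, 0), dim = dim(a)), tolerance = 1e-12)
  }
  gz <- build_global_context(m, alz)
  expect_equal(dim(gz), c(256, 2, 2))
})

test_that("global context fusion reduces to identity when built to average identical blocks", {
  # concat + 1x1 fusion: with the 1x1 kernel set to average the four stacked
  # blocks and zero bias, four copies of X reconstruct X exactly.
  am <- wheatstage:::nn_amsaf(c(32L, 64L, 128L, 256L), 8L, c(2L, 2L),
                              amsaf_config(tf_heads = 2L))
  gconv <- am$children$gconv
  wmat <- matrix(0, 8, 32)
  for (b in 0:3) wmat[cbind(1:8, b * 8 + 1:8)] <- 0.25
  gconv$params$weight$value <- wmat
  gconv$params$bias$value <- numeric(8)
  x <- rand4(8, 2, 2, 1)
  x <- x * (x > 0)  # nonnegative so the closing ReLU is transparent
  cc <- array(0, dim = c(32, 2, 2, 1))
  for (b in 0:3) cc[b * 8 + 1:8, , , ] <- x
  g <- nn_forward(am$children$grelu, nn_forward(gconv, cc))
  expect_equal(g, x, tolerance = 1e-12)
})

test_that("channel gate lies in (0,1), is spatially permutation-invariant, and matches the closed form at zero", {
  m <- tiny_model()
  set.seed(22)
  g <- array(rnorm(256 * 2 * 2), dim = c(256, 2, 2))
  ca <- channel_attention(m, g)
  expect_equal(dim(ca), c(256, 1, 1))
  expect_true(all(ca > 0 & ca < 1))

  gp <- g[, c(2, 1), c(2, 1), drop = FALSE]  # spatial permutation
  expect_equal(channel_attention(m, gp), ca, tolerance = 1e-12)

  se <- m$children$amsaf$children$se$children
  z1 <- pmax(se$fc1$params$bias$value, 0)
  z2 <- se$fc2$params$weight$value %*% z1 + se$fc2$params$bias$value
  expected <- 1 / (1 + exp(-z2))
  ca0 <- channel_attention(m, array(0, dim = c(256, 2, 2)))
  expect_equal(as.vector(ca0), as.vector(expected), tolerance = 1e-12)
})

test_that("spatial saliency lies in (0,1) and ignores channel permutations", {
  m <- tiny_model()
  set.seed(23)
  g <- array(rnorm(256 * 2 * 2), dim = c(256, 2, 2))
  sa <- spatial_attention(m, g)
  expect_equal(dim(sa), c(1, 2, 2))
  expect_true(all(sa > 0 & sa < 1))
  perm <- sample(256)
  expect_equal(spatial_attention(m, g[perm, , , drop = FALSE]), sa,
               tolerance = 1e-12)
})

test_that("csib with unit gates equals the bare transformer on flattened tokens", {
  m <- tiny_model()
  set.seed(24)
  x <- array(rnorm(256 * 2 * 2), dim = c(256, 2, 2))
  ones_ca <- array(1, dim = c(256, 1, 1))
  ones_sa <- array(1, dim = c(1, 2, 2))
  r <- csib_refine(m, x, ones_ca, ones_sa, n = 2)
  tok <- x
  dim(tok) <- c(256, 4, 1)
  direct <- nn_forward(m$children$amsaf$children$enc2, tok)
  dim(direct) <- c(256, 2, 2)
  expect_equal(r, direct, tolerance = 1e-12)
  expect_equal(dim(r), dim(x))
})

test_that("transformer refinement is equivariant to a joint permutation of tokens and positional embeddings", {
  enc1 <- wheatstage:::nn_tf_encoder(8L, 4L, heads = 2L)
  enc2 <- wheatstage:::nn_tf_encoder(8L, 4L, heads = 2L)
  wheatstage:::nn_load_state_dict(enc2, wheatstage:::nn_state_dict(enc1))
  perm <- c(3L, 1L, 4L, 2L)
  enc2$params$pos$value <- enc1$params$pos$value[, perm]
  set.seed(25)
  x <- array(rnorm(8 * 4 * 2), dim = c(8, 4, 2))
  y1 <- nn_forward(enc1, x)
  y2 <- nn_forward(enc2, x[, perm, , drop = FALSE])
  expect_equal(y2, y1[, perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("fusion weights live on the 4-simplex and identical refined maps fuse to themselves", {
  m <- tiny_model()
  set.seed(26)
  for (rep in 1:10) {
    pyr <- rand_pyramid(n = 10L)
    out <- amsaf_forward(m, pyr)
    expect_equal(dim(out$fused), c(256, 2, 2, 10))
    expect_true(all(out$weights > 0))
    expect_equal(colSums(out$weights), rep(1, 10), tolerance = 1e-6)
    # batch-mean weights stay on the simplex
    expect_equal(sum(rowMeans(out$weights)), 1, tolerance = 1e-6)
  }

  x <- array(rnorm(256 * 2 * 2), dim = c(256, 2, 2))
  res <- wfa_fuse(m, list(x, x, x, x))
  expect_equal(res$fused, x, tolerance = 1e-5)
  expect_equal(sum(res$weights), 1, tolerance = 1e-6)
})

test_that("softmax weighting matches hand-derived values", {
  z <- matrix(c(2, 0, 0, 0), 4, 1)
  w <- wheatstage:::softmax_cols(z)
  expect_equal(as.vector(w),
               c(exp(2), 1, 1, 1) / (exp(2) + 3), tolerance = 1e-12)
  expect_equal(w[1, 1], 0.7112, tolerance = 1e-4)
})

test_that("fusion weights respond to content in a single scale", {
  m <- tiny_model()
  set.seed(27)
  zero <- lapply(rand_pyramid(), function(a) array(0, dim = dim(a)))
  sig <- zero
  sig$c3 <- rand4(64, 8, 8, 1, sd = 2)
  w1 <- amsaf_forward(m, sig)$weights
  sig2 <- sig
  sig2$c3 <- sig$c3 + rand4(64, 8, 8, 1, sd = 1)
  w2 <- amsaf_forward(m, sig2)$weights
  expect_gt(max(abs(w1 - w2)), 1e-8)
})

test_that("with identity-initialised encoders and unit gates the head reduces to a learned-weight average of aligned scales", {
  mod <- build_model(model_config(variant = "amsaf", width_preset = "tiny",
                                  image_size = 64L, seed = 31L))
  am <- mod$children$amsaf
  for (n in 1:4) {  # zero the residual branches: encoder becomes identity
    enc <- am$children[[paste0("enc", n)]]
    enc$params$pos$value[] <- 0
    enc$children$attn$params$wo$value[] <- 0
    enc$children$attn$params$bo$value[] <- 0
    enc$children$ffn2$params$weight$value[] <- 0
    enc$children$ffn2$params$bias$value[] <- 0
  }
  set.seed(32)
  pyr <- drop_n(rand_pyramid())
  al <- align_and_unify(mod, pyr)
  ones_ca <- array(1, dim = c(256, 1, 1))
  ones_sa <- array(1, dim = c(1, 2, 2))
  refined <- lapply(1:4, function(n) csib_refine(mod, al[[n]], ones_ca,
                                                 ones_sa, n))
  for (n in 1:4) expect_equal(refined[[n]], al[[n]], tolerance = 1e-12)
  res <- wfa_fuse(mod, refined)
  manual <- Reduce(`+`, lapply(1:4, function(n) res$weights[n] * al[[n]]))
  expect_equal(res$fused, manual, tolerance = 1e-10)
})
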