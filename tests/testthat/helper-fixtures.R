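# Shared test helpers: finite-difference gradient checking for the
# reverse-mode engine, small cached models, and a toy metadata CSV.

# Central-difference gradient check of a module: loss = sum(w * forward(x)).
# Verifies the input gradient and every parameter gradient.
gradcheck <- function(module, x, eps = 1e-5, tol = 1e-5,
                      forward = function(m, x) nn_forward(m, x)) {
  wheatstage:::nn_set_training(module, TRUE)
  y <- forward(module, x)
  w <- array(stats::rnorm(length(y)), dim = dim(y) %||% length(y))
  loss_of <- function() sum(w * forward(module, x))
  dy <- w
  dim(dy) <- dim(y)
  wheatstage:::nn_zero_grad(module)
  y2 <- forward(module, x)  # fresh caches for the analytic pass
  dx <- nn_backward(module, dy)

  num_dx <- array(0, dim = dim(x) %||% length(x))
  idx <- sample(length(x), min(length(x), 25L))
  for (i in idx) {
    x0 <- x[i]
    x[i] <- x0 + eps; lp <- loss_of()
    x[i] <- x0 - eps; lm <- loss_of()
    x[i] <- x0
    num_dx[i] <- (lp - lm) / (2 * eps)
  }
  expect_equal(as.vector(dx)[idx], as.vector(num_dx)[idx], tolerance = tol)

  params <- wheatstage:::nn_parameters(module)
  for (nm in names(params)) {
    p <- params[[nm]]
    expect_false(is.null(p$grad), label = paste("grad present for", nm))
    pid <- sample(length(p$value), min(length(p$value), 10L))
    for (i in pid) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; lp <- loss_of()
      p$value[i] <- v0 - eps; lm <- loss_of()
      p$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      expect_equal(unname(as.vector(p$grad)[i]), unname(num),
                   tolerance = max(tol, tol * abs(num)),
                   label = sprintf("analytic grad of %s[%d]", nm, i))
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand4 <- function(c, h, w, n, sd = 1) {
  array(stats::rnorm(c * h * w * n, sd = sd), dim = c(c, h, w, n))
}

# One tiny amsaf model per session (64x64 input), reused across tests.
tiny_model <- local({
  cache <- new.env()
  function(variant = "amsaf", seed = 11L) {
    key <- paste0(variant, "_", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_model(model_config(
        variant = variant, width_preset = "tiny", image_size = 64L,
        seed = seed))
    }
    cache[[key]]
  }
})

# Toy metadata CSV with both quality tiers; returns its path.
write_toy_csv <- function(dir = withr::local_tempdir()) {
  df <- data.frame(
    image_id = sprintf("img%02d", 1:6),
    stage = c(2L, 1L, 3L, 5L, 6L, 7L),
    label_quality = c(2L, 1L, 2L, 2L, 1L, 2L))
  path <- file.path(dir, "Train.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
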