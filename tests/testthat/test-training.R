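# Schedule state machine against hand-simulated metric sequences, the
# cross-entropy objective, and small end-to-end training runs (determinism,
# checkpoint round trip, chance-level sanity).

test_that("plateau decay fires at the end of each non-improving stretch", {
  cfg <- train_config(plateau_patience = 2L, early_stop_patience = 20L,
                      learning_rate = 1e-4, lr_decay_factor = 0.8)
  # improve at epochs 1-2, then flat: decay at the epoch closing each
  # 2-epoch non-improving stretch (epochs 4, 6, 8, ...)
  hist <- simulate_schedule(c(.5, .6, .6, .6, .6, .6, .6), cfg)
  expect_equal(hist$lr, 1e-4 * c(1, 1, 1, .8, .8, .64, .64), tolerance = 1e-12)
  expect_equal(which(hist$decayed), c(4L, 6L))
  expect_equal(attr(hist, "best_epoch"), 2L)
})

test_that("an always-improving run never decays and stops at max_epochs", {
  cfg <- train_config(max_epochs = 30L)
  hist <- simulate_schedule(seq(0.1, 0.9, length.out = 40), cfg)
  expect_equal(nrow(hist), 30L)
  expect_true(all(hist$lr == cfg$learning_rate))
  expect_equal(attr(hist, "stop_reason"), "max_epochs")
  expect_true(all(diff(hist$lr) <= 0))  # non-increasing by contract
})

test_that("a flat sequence stops after exactly 20 non-improving epochs past the best", {
  cfg <- train_config(early_stop_patience = 20L, plateau_patience = 10L)
  hist <- simulate_schedule(rep(0.5, 60), cfg)
  expect_equal(attr(hist, "stop_epoch"), 21L)  # best at epoch 1 + 20 flat
  expect_equal(attr(hist, "stop_reason"), "early_stop")
  expect_equal(attr(hist, "best_epoch"), 1L)
  # decays at epochs 11 and 21; ties never count as improvement
  expect_equal(which(hist$decayed), c(11L, 21L))
  expect_equal(hist$lr[21], cfg$learning_rate * 0.8^2, tolerance = 1e-12)
})

test_that("plateau patience must not exceed early-stopping patience", {
  expect_error(train_config(plateau_patience = 30L, early_stop_patience = 20L))
})

test_that("cross-entropy value and gradient match a direct evaluation", {
  set.seed(71)
  logits <- matrix(rnorm(15), 3, 5)
  y <- c(0L, 2L, 1L, 1L, 0L)
  ce <- wheatstage:::cross_entropy(logits, y)
  probs <- apply(logits, 2, function(z) exp(z) / sum(exp(z)))
  expect_equal(ce$loss, -mean(log(probs[cbind(y + 1L, 1:5)])))
  eps <- 1e-6
  for (i in c(1L, 7L, 12L)) {
    l2 <- logits
    l2[i] <- logits[i] + eps
    expect_equal(ce$grad[i],
                 (wheatstage:::cross_entropy(l2, y)$loss - ce$loss) / eps,
                 tolerance = 1e-4)
  }
})

make_mini_set <- function(n_per_class = 3L, size = 64L, seed = 81L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  res <- synth_dataset(n_per_class, dir, image_size = size, seed = seed,
                       difficulty = 0.1)
  make_dataset(res$metadata, size)
}

test_that("two training runs with identical seeds produce identical histories", {
  ds <- make_mini_set()
  cfg <- train_config(max_epochs = 2L, batch_size = 8L, learning_rate = 1e-3,
                      seed = 5L)
  f1 <- train_model(build_model(model_config(variant = "baseline",
                                             width_preset = "tiny",
                                             image_size = 64L, seed = 2L)),
                    ds, cfg = cfg)
  f2 <- train_model(build_model(model_config(variant = "baseline",
                                             width_preset = "tiny",
                                             image_size = 64L, seed = 2L)),
                    ds, cfg = cfg)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-12)
  expect_equal(f1$history$val_top1, f2$history$val_top1)
  expect_s3_class(f1, "wheat_fit")
  expect_true(all(diff(f1$history$lr) <= 0))
})

test_that("the amsaf variant trains one epoch and logs simplex fusion weights", {
  ds <- make_mini_set(2L)
  cfg <- train_config(max_epochs = 1L, batch_size = 5L, seed = 6L)
  fit <- train_model(tiny_model_fresh <- build_model(
    model_config(variant = "amsaf", width_preset = "tiny",
                 image_size = 64L, seed = 3L)), ds, cfg = cfg)
  h <- fit$history
  expect_true(all(c("wfa_w1", "wfa_w2", "wfa_w3", "wfa_w4") %in% names(h)))
  expect_equal(h$wfa_w1 + h$wfa_w2 + h$wfa_w3 + h$wfa_w4, 1, tolerance = 1e-6)
})

test_that("evaluation is deterministic and a checkpoint round-trip reproduces it exactly", {
  ds <- make_mini_set()
  m <- tiny_model("baseline")
  r1 <- suppressWarnings(evaluate_model(m, ds))
  r2 <- suppressWarnings(evaluate_model(m, ds))
  expect_identical(r1$top1, r2$top1)
  expect_identical(unclass(r1$confusion)[, ], unclass(r2$confusion)[, ])

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  r3 <- suppressWarnings(evaluate_model(load_checkpoint(path), ds))
  expect_equal(r3$per_class, r1$per_class, tolerance = 1e-12)
})

test_that("a constant-score model scores at chance on balanced data", {
  ds <- make_mini_set(4L)
  m <- build_model(model_config(variant = "baseline", width_preset = "tiny",
                                image_size = 64L, seed = 4L))
  # zero the head's linear layer: every image gets identical logits, the
  # argmax tie resolves to class 0
  m$children$head$children$fc$params$weight$value[] <- 0
  m$children$head$children$fc$params$bias$value[] <- 0
  rep <- suppressWarnings(evaluate_model(m, ds))
  expect_equal(rep$top1, 0.2)
  expect_true(all(rep$confusion[, 1] == rowSums(unclass(rep$confusion))))
})

test_that("training aborts with a diagnostic when the loss diverges", {
  ds <- make_mini_set(2L)
  m <- build_model(model_config(variant = "baseline", width_preset = "tiny",
                                image_size = 64L, seed = 8L))
  m$children$head$children$fc$params$weight$value[] <- Inf  # force NaN logits
  cfg <- train_config(max_epochs = 1L, batch_size = 5L, seed = 9L)
  expect_error(train_model(m, ds, cfg = cfg), "diverged.*non-finite")
})
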