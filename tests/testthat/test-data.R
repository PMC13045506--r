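# Metadata loading/validation, expert filtering, stage remapping, the
# stratified split and the augmentation pipeline.

test_that("metadata loading validates the schema and collects rejects", {
  dir <- withr::local_tempdir()
  csv <- write_toy_csv(dir)
  records <- load_metadata(csv)
  expect_equal(nrow(records), 6L)
  expect_equal(records$label_quality, c(2L, 1L, 2L, 2L, 1L, 2L))
  expect_equal(nrow(attr(records, "rejects")), 0L)

  # a malformed stage lands in the rejects table, not the records
  df <- utils::read.csv(csv)
  df$stage[2] <- 9L
  utils::write.csv(df, csv, row.names = FALSE)
  expect_warning(r2 <- load_metadata(csv), "rejected")
  expect_equal(nrow(r2), 5L)
  expect_equal(attr(r2, "rejects")$reason, "stage out of range")

  # missing column is a schema error naming the column
  utils::write.csv(df[, c("image_id", "stage")], csv, row.names = FALSE)
  expect_error(load_metadata(csv), "label_quality")

  # empty file warns and yields an empty frame
  utils::write.csv(df[0, ], csv, row.names = FALSE)
  expect_warning(r0 <- load_metadata(csv), "no rows")
  expect_equal(nrow(r0), 0L)
})

test_that("expert filtering keeps quality 2 and rejects contract-breaking stages", {
  dir <- withr::local_tempdir()
  records <- load_metadata(write_toy_csv(dir))
  expert <- filter_expert(records)
  expect_equal(nrow(expert), 4L)
  expect_true(all(expert$label_quality == 2L))
  expect_true(all(expert$stage %in% c(2L, 3L, 5L, 7L)))

  all_q1 <- records[records$label_quality == 1L, ]
  expect_warning(e0 <- filter_expert(all_q1), "no expert")
  expect_equal(nrow(e0), 0L)

  bad <- records
  bad$label_quality[5] <- 2L  # stage 6 marked expert: contract violation
  expect_error(filter_expert(bad), "stage 6.*absent from the expert subset")
})

test_that("stage remapping is the bijection {2,3,4,5,7} -> {0..4}", {
  expect_equal(remap_stage(c(2L, 3L, 4L, 5L, 7L)), 0:4)
  expect_equal(remap_stage(2L), 0L)
  expect_equal(remap_stage(7L), 4L)
  expect_error(remap_stage(6L), "stage 6 is not a retained stage")
  expect_error(remap_stage(1L), "not a retained stage")
  sm <- stage_map()
  expect_equal(sm$names[remap_stage(7L) + 1L], "Milking")
})

test_that("stratified split applies per-class round-half-up and is seed-deterministic", {
  rec <- data.frame(image_id = sprintf("r%02d", 1:15),
                    stage = c(rep(2L, 10), rep(5L, 5)),
                    label_quality = 2L, path = NA_character_)
  sp <- stratified_split(rec, 0.8, seed = 9L)
  expect_equal(sum(sp$train$stage == 2L), 8L)
  expect_equal(sum(sp$test$stage == 2L), 2L)
  expect_equal(sum(sp$train$stage == 5L), 4L)
  expect_equal(sum(sp$test$stage == 5L), 1L)
  expect_equal(sort(c(sp$train$image_id, sp$test$image_id)), rec$image_id)

  sp2 <- stratified_split(rec, 0.8, seed = 9L)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(rec, 0.8, seed = 10L)
  expect_false(identical(sp$train$image_id, sp3$train$image_id))
  expect_equal(table(sp3$train$stage), table(sp$train$stage))

  single <- data.frame(image_id = "x", stage = 2L, label_quality = 2L,
                       path = NA_character_)
  expect_warning(stratified_split(single, 0.8, 1L), "fewer than 2")
})

test_that("one class of 10 splits 8/2 at the exact ratio", {
  rec <- data.frame(image_id = sprintf("r%02d", 1:10), stage = 3L,
                    label_quality = 2L, path = NA_character_)
  sp <- stratified_split(rec, 0.8, seed = 1L)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
})

test_that("the identity augmentation is exact and randomized settings keep shape and range", {
  set.seed(61)
  x <- array(runif(3 * 64 * 64), dim = c(3, 64, 64))
  expect_identical(augment_image(x, wheatstage:::identity_augment(), 5L), x)

  cfg <- augment_config(seed = 3L)
  for (s in 1:5) {
    y <- augment_image(x, cfg, s)
    expect_equal(dim(y), dim(x))
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("a pure horizontal flip mirrors the image and is an involution", {
  set.seed(62)
  x <- array(runif(3 * 32 * 32), dim = c(3, 32, 32))
  flip_only <- augment_config(rotation = 0, translation = 0, scale = c(1, 1),
                              flip_p = 1, erase_frac = c(0, 0), erase_p = 0,
                              gray_p = 0, jitter = 0, noise_sd = 0)
  y <- augment_image(x, flip_only, 1L)
  expect_identical(y, x[, , 32:1])
  expect_identical(augment_image(y, flip_only, 1L), x)
})

test_that("augmentation is bitwise reproducible from its seeds and leaves the global RNG alone", {
  set.seed(63)
  x <- array(runif(3 * 32 * 32), dim = c(3, 32, 32))
  cfg <- augment_config(seed = 7L)
  before <- .Random.seed
  y1 <- augment_image(x, cfg, 11L)
  expect_identical(.Random.seed, before)
  y2 <- augment_image(x, cfg, 11L)
  expect_identical(y1, y2)
  y3 <- augment_image(x, cfg, 12L)
  expect_false(identical(y1, y3))
})

test_that("image save/load round-trips through letterboxing", {
  dir <- withr::local_tempdir()
  set.seed(64)
  x <- array(runif(3 * 32 * 32), dim = c(3, 32, 32))
  p <- file.path(dir, "img.png")
  save_image(x, p)
  y <- load_image(p, size = 32L)
  expect_equal(dim(y), c(3, 32, 32))
  expect_equal(y, x, tolerance = 0.01)  # 8-bit quantisation
  # non-square input letterboxes onto black
  z <- load_image(p, size = 64L)
  expect_equal(dim(z), c(3, 64, 64))
})
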