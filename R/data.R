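# Metadata handling: loading and validating the Train.csv-style table,
# label-quality filtering, growth-stage remapping and stratified splitting.

RETAINED_STAGES <- c(2L, 3L, 4L, 5L, 7L)

#' Growth-stage mapping
#'
#' The expert-labelled subset spans five stages; they are mapped to
#' contiguous class indices: Tillering (2) -> 0, Mid Vegetative (3) -> 1,
#' Booting (4) -> 2, Heading (5) -> 3, Milking (7) -> 4. Stages 1 (Crown
#' Root Initiation) and 6 (Anthesis) are absent from the expert subset and
#' are rejected.
#'
#' @return list with `stages`, `indices` and display `names`.
#' @export
stage_map <- function() {
  list(stages = RETAINED_STAGES,
       indices = 0:4,
       names = STAGE_NAMES)
}

#' Remap a raw growth stage to a class index
#'
#' @param stage integer vector of raw stages; must be in `{2,3,4,5,7}`.
#' @param map a [stage_map()].
#' @return 0-based class indices.
#' @export
remap_stage <- function(stage, map = stage_map()) {
  idx <- match(stage, map$stages)
  if (anyNA(idx)) {
    bad <- stage[is.na(idx)][1]
    stop("stage ", bad, " is not a retained stage (expected one of ",
         paste(map$stages, collapse = ", "), ")")
  }
  map$indices[idx]
}

#' Load an image-metadata table
#'
#' Reads a CSV with the `Train.csv` schema (`image_id`, `stage`,
#' `label_quality`; header required), validates each row (stage in 1..7,
#' label quality in \{1, 2\}) and resolves each image's file path next to the
#' CSV (`<image_id>.png` / `.jpg` / `.jpeg`). Malformed rows are collected
#' into a rejects table attached as the `"rejects"` attribute.
#'
#' @param csv path to the metadata CSV.
#' @param image_dir directory holding the images; defaults to the CSV's
#'   directory.
#' @return data frame of valid records (`image_id`, `stage`,
#'   `label_quality`, `path`) with attribute `rejects`.
#' @export
load_metadata <- function(csv, image_dir = dirname(csv)) {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  required <- c("image_id", "stage", "label_quality")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("metadata file '", csv, "' contains no rows")
  }
  reason <- rep(NA_character_, nrow(df))
  stage <- suppressWarnings(as.integer(df$stage))
  quality <- suppressWarnings(as.integer(df$label_quality))
  reason[is.na(stage) | stage < 1L | stage > 7L] <- "stage out of range"
  reason[is.na(reason) & (is.na(quality) | !quality %in% c(1L, 2L))] <-
    "label_quality not in {1, 2}"
  reason[is.na(reason) & (is.na(df$image_id) | df$image_id == "")] <-
    "empty image_id"
  ok <- is.na(reason)
  records <- data.frame(image_id = as.character(df$image_id[ok]),
                        stage = stage[ok],
                        label_quality = quality[ok],
                        stringsAsFactors = FALSE)
  records$path <- vapply(records$image_id, function(id) {
    for (ext in c(".png", ".jpg", ".jpeg")) {
      p <- file.path(image_dir, paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  rejects <- data.frame(row = which(!ok),
                        image_id = as.character(df$image_id[!ok]),
                        reason = reason[!ok],
                        stringsAsFactors = FALSE)
  if (nrow(rejects)) {
    warning(nrow(rejects), " metadata row(s) rejected; see attr(x, 'rejects')")
  }
  attr(records, "rejects") <- rejects
  records
}

#' Keep only expert-validated records
#'
#' Retains records with `label_quality == 2`. The expert subset by contract
#' contains no stage-1 or stage-6 samples; encountering one is an error.
#'
#' @param records metadata data frame from [load_metadata()].
#' @return the expert-labelled subset.
#' @export
filter_expert <- function(records) {
  out <- records[records$label_quality == 2L, , drop = FALSE]
  bad <- out$stage %in% c(1L, 6L)
  if (any(bad)) {
    stop("stage ", out$stage[bad][1], " (record '", out$image_id[bad][1],
         "') is absent from the expert subset")
  }
  if (nrow(out) == 0L) warning("no expert-labelled (quality 2) records found")
  rownames(out) <- NULL
  attr(out, "rejects") <- attr(records, "rejects")
  out
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Stratified train/test split
#'
#' Splits records class-by-class: with `n_c` records of class `c`,
#' `round(ratio * n_c)` (round-half-up) go to the training side and the
#' remainder to the test side. Deterministic given `seed`; the same seed
#' reproduces the same partition.
#'
#' @param records metadata data frame (stratified on `stage`).
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with `train` and `test` data frames (disjoint, exhaustive).
#' @export
stratified_split <- function(records, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, nrow(records) >= 1L)
  train_idx <- integer(0)
  with_seed(seed, {
    for (s in sort(unique(records$stage))) {
      idx <- which(records$stage == s)
      if (length(idx) < 2L) {
        warning("class (stage ", s, ") has fewer than 2 records; ",
                "its test side may be empty")
      }
      n_train <- floor(ratio * length(idx) + 0.5)  # round half up
      n_train <- min(n_train, length(idx))
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train <- records[sort(train_idx), , drop = FALSE]
  test <- records[setdiff(seq_len(nrow(records)), train_idx), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}
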