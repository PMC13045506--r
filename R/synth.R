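# Synthetic field-image generator. Emulates the visual structure of
# ground-level wheat imagery with a black-masked trapezoidal region of
# interest: class-dependent stripe frequency (canopy row density), bright
# ellipse blobs (emerging spikes) and a green-to-yellow hue shift
# (maturation), plus additive Gaussian noise scaled by a difficulty knob.
# The per-stage visual parameters ship as a data table
# (inst/extdata/synth_class_params.csv), not code constants.

#' Per-stage visual parameters of the synthetic generator
#'
#' @return data frame with `stage`, `name`, `stripe_freq` (canopy stripe
#'   cycles per image), `blob_count` (expected spike blobs) and `hue_mix`
#'   (0 = green canopy, 1 = fully senesced yellow).
#' @export
synth_class_params <- function() {
  utils::read.csv(system.file("extdata", "synth_class_params.csv",
                              package = "wheatstage"),
                  stringsAsFactors = FALSE)
}

# Random trapezoid (wide-bottom) vertex set, jittered around the canonical
# geometry by +/- 10% of the side length. Fractions of the image side,
# (x, y) with y growing downward.
synth_trapezoid <- function(jitter = 0.1) {
  base <- matrix(c(0.25, 0.32,   # top-left
                   0.75, 0.32,   # top-right
                   0.98, 0.98,   # bottom-right
                   0.02, 0.98),  # bottom-left
                 ncol = 2, byrow = TRUE)
  base + matrix(stats::runif(8, -jitter, jitter), ncol = 2)
}

# Mask of pixels inside a convex quadrilateral; rows = y, cols = x.
quad_mask <- function(verts, size) {
  gx <- matrix(rep((seq_len(size) - 0.5) / size, each = size), size)
  gy <- matrix(rep((seq_len(size) - 0.5) / size, times = size), size)
  inside <- TRUE
  for (i in 1:4) {
    a <- verts[i, ]
    b <- verts[if (i == 4) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
    inside <- inside & (cross >= 0)
  }
  inside
}

# One synthetic image for a given stage. Uses the current RNG stream.
synth_image <- function(stage, size = 256L, difficulty = 0.25,
                        params = synth_class_params(), param_jitter = 0.1) {
  p <- params[params$stage == stage, ]
  stopifnot(nrow(p) == 1L)
  jit <- function(v, rel) v * (1 + stats::runif(1, -rel, rel))
  freq <- jit(p$stripe_freq, param_jitter)
  hue <- min(1, max(0, p$hue_mix + stats::runif(1, -1, 1) *
                      (0.03 + 0.08 * difficulty)))
  green <- c(0.20, 0.55, 0.15)
  yellow <- c(0.80, 0.72, 0.20)
  col <- (1 - hue) * green + hue * yellow

  xs <- (seq_len(size) - 0.5) / size
  phase <- stats::runif(1, 0, 2 * pi)
  stripe <- 0.75 + 0.25 * sin(2 * pi * freq * xs + phase)  # over columns
  img <- array(0, dim = c(3L, size, size))
  for (c in 1:3) img[c, , ] <- col[c] * rep(stripe, each = size)

  n_blobs <- stats::rpois(1, jit(p$blob_count, param_jitter) + 1e-9)
  if (n_blobs > 0) {
    r <- 0.035 * size
    ys <- matrix(rep(seq_len(size), times = size), size)
    xg <- matrix(rep(seq_len(size), each = size), size)
    for (b in seq_len(n_blobs)) {
      cx <- stats::runif(1, 0.15, 0.85) * size
      cy <- stats::runif(1, 0.35, 0.95) * size
      rx <- r * stats::runif(1, 0.7, 1.3)
      ry <- r * stats::runif(1, 0.4, 0.8)
      blob <- ((xg - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      for (c in 1:3) {
        ch <- img[c, , ]
        ch[blob] <- 0.6 * ch[blob] + 0.4 * c(0.95, 0.92, 0.75)[c]
        img[c, , ] <- ch
      }
    }
  }

  if (difficulty > 0) {
    img <- img + stats::rnorm(length(img), sd = 0.25 * difficulty)
  }
  img <- pmin(pmax(img, 0), 1)

  mask <- quad_mask(synth_trapezoid(), size)
  for (c in 1:3) img[c, , ] <- img[c, , ] * mask
  img
}

#' Generate a synthetic wheat growth-stage dataset
#'
#' Writes `n_per_class` PNG images for each of the five retained stages
#' (label quality 2) plus, optionally, noisier farmer-quality images spanning
#' all seven stages (label quality 1), together with a `Train.csv`-style
#' metadata file (`image_id`, `stage`, `label_quality`). Pixels outside the
#' trapezoidal region of interest are exactly zero in all channels.
#'
#' @param n_per_class expert-quality images per retained stage.
#' @param out_dir output directory (created).
#' @param image_size image side length (default 256; use 64 for desk-scale
#'   work).
#' @param seed integer seed; the full output is deterministic given it.
#' @param difficulty noise level knob in `[0, 1]`: Gaussian pixel noise of
#'   standard deviation `0.25 * difficulty` plus wider per-image parameter
#'   jitter.
#' @param n_quality1_per_stage farmer-quality images per stage 1..7
#'   (default 0 = none).
#' @return invisibly, a list with `metadata` (data frame including paths) and
#'   `csv` (metadata file path).
#' @export
synth_dataset <- function(n_per_class, out_dir, image_size = 256L, seed = 1L,
                          difficulty = 0.25, n_quality1_per_stage = 0L) {
  stopifnot(n_per_class >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- synth_class_params()
  rows <- list()
  with_seed(seed, {
    for (s in RETAINED_STAGES) {
      for (i in seq_len(n_per_class)) {
        id <- sprintf("synth_q2_s%d_%04d", s, i)
        img <- synth_image(s, image_size, difficulty, params)
        save_image(img, file.path(out_dir, paste0(id, ".png")))
        rows[[length(rows) + 1L]] <-
          data.frame(image_id = id, stage = s, label_quality = 2L)
      }
    }
    if (n_quality1_per_stage > 0L) {
      for (s in 1:7) {
        for (i in seq_len(n_quality1_per_stage)) {
          id <- sprintf("synth_q1_s%d_%04d", s, i)
          img <- synth_image(s, image_size, min(1, difficulty * 2 + 0.2),
                             params, param_jitter = 0.3)
          save_image(img, file.path(out_dir, paste0(id, ".png")))
          rows[[length(rows) + 1L]] <-
            data.frame(image_id = id, stage = s, label_quality = 1L)
        }
      }
    }
  })
  metadata <- do.call(rbind, rows)
  csv <- file.path(out_dir, "Train.csv")
  utils::write.csv(metadata, csv, row.names = FALSE)
  metadata$path <- file.path(out_dir, paste0(metadata$image_id, ".png"))
  invisible(list(metadata = metadata, csv = csv))
}
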