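# Image I/O and the geometric + photometric augmentation suite.
#
# Images are numeric arrays [3, H, W] with values in [0, 1]. EBImage stores
# [x (width), y (height), channel]; conversion is a transpose of the two
# spatial axes.

to_ebimage <- function(x) {
  EBImage::Image(aperm(x, c(3, 2, 1)), colormode = "Color")
}

from_ebimage <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), dim = c(dim(d), 3L))
  aperm(d, c(3, 2, 1))
}

#' Read an image and letterbox it to a square
#'
#' Decodes a PNG/JPEG/TIFF image, converts it to three channels, rescales it
#' preserving the aspect ratio and pads onto a black canvas of
#' `size` x `size` (black padding harmonises with the datasets' black
#' region-of-interest exterior).
#'
#' @param path image file.
#' @param size output side length (default 256).
#' @return numeric array `[3, size, size]`, values in `[0, 1]`.
#' @export
load_image <- function(path, size = 256L) {
  img <- EBImage::readImage(path)
  x <- from_ebimage(img)
  if (dim(x)[1] > 3L) x <- x[1:3, , , drop = FALSE]  # drop alpha
  h <- dim(x)[2]
  w <- dim(x)[3]
  s <- size / max(h, w)
  nh <- max(1L, round(h * s))
  nw <- max(1L, round(w * s))
  if (nh != h || nw != w) {
    img <- EBImage::resize(to_ebimage(x), w = nw, h = nh)
    x <- from_ebimage(img)
  }
  out <- array(0, dim = c(3L, size, size))
  oh <- (size - nh) %/% 2L
  ow <- (size - nw) %/% 2L
  out[, (oh + 1L):(oh + nh), (ow + 1L):(ow + nw)] <- x
  pmin(pmax(out, 0), 1)
}

#' Write an image array to a PNG file
#'
#' @param x numeric array `[3, H, W]` in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(x, path) {
  png::writePNG(aperm(pmin(pmax(x, 0), 1), c(2, 3, 1)), path)
  invisible(path)
}

#' Augmentation configuration
#'
#' Geometric transforms (rotation, translation, scaling, horizontal flip,
#' region erasure) run first, photometric transforms (grayscale conversion,
#' brightness/contrast/saturation jitter, Gaussian noise) second. Magnitudes
#' follow common practice for field imagery and are all overridable. A
#' setting of zero (or probability zero) disables its transform exactly.
#'
#' @param rotation max absolute rotation, degrees.
#' @param translation max translation as a fraction of the image side.
#' @param scale length-2 multiplicative zoom range.
#' @param flip_p horizontal-flip probability.
#' @param erase_frac length-2 range of the erased-region area fraction.
#' @param erase_p probability of applying region erasure.
#' @param gray_p probability of grayscale conversion.
#' @param jitter max relative brightness/contrast/saturation perturbation.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param seed master seed combined with each sample's own seed.
#' @return an `augment_config` list.
#' @export
augment_config <- function(rotation = 15, translation = 0.1,
                           scale = c(0.9, 1.1), flip_p = 0.5,
                           erase_frac = c(0.02, 0.10), erase_p = 0.5,
                           gray_p = 0.1, jitter = 0.2, noise_sd = 0.02,
                           seed = 0L) {
  stopifnot(rotation >= 0, translation >= 0, length(scale) == 2L,
            scale[1] <= scale[2], flip_p >= 0, flip_p <= 1,
            length(erase_frac) == 2L, erase_frac[1] <= erase_frac[2],
            gray_p >= 0, gray_p <= 1, jitter >= 0, noise_sd >= 0)
  structure(list(rotation = rotation, translation = translation,
                 scale = scale, flip_p = flip_p, erase_frac = erase_frac,
                 erase_p = erase_p, gray_p = gray_p, jitter = jitter,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "augment_config")
}

identity_augment <- function() {
  augment_config(rotation = 0, translation = 0, scale = c(1, 1), flip_p = 0,
                 erase_frac = c(0, 0), erase_p = 0, gray_p = 0, jitter = 0,
                 noise_sd = 0)
}

#' Augment one image
#'
#' Applies the configured geometric-then-photometric pipeline. Output shape
#' equals input shape and values are clipped to `[0, 1]`. Fully reproducible
#' from `(cfg$seed, sample_seed)`; the global RNG state is left untouched.
#'
#' @param image numeric array `[3, H, W]`.
#' @param cfg an [augment_config()].
#' @param sample_seed per-sample seed.
#' @return augmented array, same shape.
#' @export
augment_image <- function(image, cfg = augment_config(), sample_seed = 0L) {
  stopifnot(inherits(cfg, "augment_config"))
  d <- dim(image)
  h <- d[2]
  w <- d[3]
  with_seed((cfg$seed * 1000003L + as.integer(sample_seed)) %% 2147483647L, {
    x <- image

    if (cfg$rotation > 0) {
      ang <- stats::runif(1, -cfg$rotation, cfg$rotation)
      img <- EBImage::rotate(to_ebimage(x), ang, output.dim = c(w, h),
                             bg.col = "black")
      x <- from_ebimage(img)
    }
    if (cfg$translation > 0) {
      dx <- round(stats::runif(1, -cfg$translation, cfg$translation) * w)
      dy <- round(stats::runif(1, -cfg$translation, cfg$translation) * h)
      img <- EBImage::translate(to_ebimage(x), v = c(dx, dy), bg.col = "black")
      x <- from_ebimage(img)
    }
    if (cfg$scale[1] != 1 || cfg$scale[2] != 1) {
      s <- stats::runif(1, cfg$scale[1], cfg$scale[2])
      nh <- max(1L, round(h * s))
      nw <- max(1L, round(w * s))
      img <- EBImage::resize(to_ebimage(x), w = nw, h = nh)
      z <- from_ebimage(img)
      if (s >= 1) {  # centre crop back
        oh <- (nh - h) %/% 2L
        ow <- (nw - w) %/% 2L
        x <- z[, (oh + 1L):(oh + h), (ow + 1L):(ow + w), drop = FALSE]
      } else {       # centre pad on black
        x <- array(0, dim = d)
        oh <- (h - nh) %/% 2L
        ow <- (w - nw) %/% 2L
        x[, (oh + 1L):(oh + nh), (ow + 1L):(ow + nw)] <- z
      }
    }
    if (cfg$flip_p > 0 && stats::runif(1) < cfg$flip_p) {
      x <- x[, , w:1, drop = FALSE]  # exact horizontal mirror
    }
    if (cfg$erase_p > 0 && cfg$erase_frac[2] > 0 &&
        stats::runif(1) < cfg$erase_p) {
      frac <- stats::runif(1, cfg$erase_frac[1], cfg$erase_frac[2])
      aspect <- stats::runif(1, 0.5, 2)
      eh <- min(h, max(1L, round(sqrt(frac * h * w * aspect))))
      ew <- min(w, max(1L, round(sqrt(frac * h * w / aspect))))
      top <- sample.int(h - eh + 1L, 1L)
      left <- sample.int(w - ew + 1L, 1L)
      x[, top:(top + eh - 1L), left:(left + ew - 1L)] <- 0
    }

    if (cfg$gray_p > 0 && stats::runif(1) < cfg$gray_p) {
      g <- 0.299 * x[1, , ] + 0.587 * x[2, , ] + 0.114 * x[3, , ]
      x[1, , ] <- g
      x[2, , ] <- g
      x[3, , ] <- g
    }
    if (cfg$jitter > 0) {
      x <- x + stats::runif(1, -cfg$jitter, cfg$jitter)          # brightness
      x <- (x - 0.5) * stats::runif(1, 1 - cfg$jitter, 1 + cfg$jitter) + 0.5
      g <- 0.299 * x[1, , ] + 0.587 * x[2, , ] + 0.114 * x[3, , ]
      s <- stats::runif(1, 1 - cfg$jitter, 1 + cfg$jitter)       # saturation
      for (c in 1:3) x[c, , ] <- g + s * (x[c, , ] - g)
    }
    if (cfg$noise_sd > 0) {
      x <- x + stats::rnorm(length(x), sd = cfg$noise_sd)
    }
    pmin(pmax(x, 0), 1)
  })
}
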