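# Dataset I/O, preprocessing and the paired augmentation protocol.
#
# Images are (H, W, 3) arrays in [0, 1]; masks are binary (H, W) matrices.
# Geometric transforms are delegated to EBImage; because EBImage stores
# images x-major we transpose on the way in and out.

to_eb <- function(a) {
  if (length(dim(a)) == 3L) {
    EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  } else {
    EBImage::Image(t(a), colormode = "Grayscale")
  }
}

from_eb <- function(img, channels) {
  a <- EBImage::imageData(img)
  if (channels == 3L) aperm(a, c(2, 1, 3)) else t(a)
}

read_image_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    from_eb(EBImage::readImage(path), channels = 3L)
  }
  if (is.matrix(a)) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE] # drop alpha
  a
}

#' Load an image/mask pair
#'
#' Reads a PNG or JPEG endoscopy image and its PNG ground-truth mask.  The
#' image is normalized to `[0, 1]`; the mask is binarized at 127/255 (any
#' pixel brighter than that counts as polyp).
#'
#' @param image_path Path to the RGB image (PNG or JPEG).
#' @param mask_path Path to the mask PNG.
#' @param source_id Identifier stored on the record; defaults to the image
#'   file stem.
#' @return A `sample_record`: list with `image` `(H, W, 3)`, binary `mask`
#'   `(H, W)`, `source_id` and `split` (initially `NA`).
#' @export
load_pair <- function(image_path, mask_path, source_id = NULL) {
  img <- read_image_file(image_path)
  m <- read_image_file(mask_path)[, , 1]
  if (!identical(dim(img)[1:2], dim(m))) {
    stop("image and mask sizes differ", call. = FALSE)
  }
  new_record(
    image = img,
    mask = (m > 127 / 255) + 0,
    source_id = source_id %||% sub("\\.[^.]+$", "", basename(image_path))
  )
}

new_record <- function(image, mask, source_id, split = NA_character_) {
  structure(list(image = image, mask = mask, source_id = source_id,
                 split = split),
            class = "sample_record")
}

#' Resize an image/mask pair
#'
#' Bilinear for the image, nearest neighbour for the mask (then
#' re-binarized), matching the uniform 256x256 input convention.
#'
#' @param record A `sample_record`.
#' @param size Target side length in pixels.
#' @return The resized `sample_record`.
#' @export
resize_pair <- function(record, size = 256L) {
  d <- dim(record$mask)
  if (d[1] == size && d[2] == size) return(record)
  img <- from_eb(EBImage::resize(to_eb(record$image), w = size, h = size,
                                 filter = "bilinear"), channels = 3L)
  m <- from_eb(EBImage::resize(to_eb(record$mask), w = size, h = size,
                               filter = "none"), channels = 1L)
  record$image <- pmin(pmax(img, 0), 1)
  record$mask <- (m > 0.5) + 0
  record
}

#' Augmentation settings
#'
#' Each variant samples an independent transform chain: a rotation by an
#' angle uniform in `[-rotation_max_deg, +rotation_max_deg]` (always
#' applied; image bilinear, mask nearest), a center crop to `crop_size`
#' followed by a resize back to the original size (probability 1/2), and a
#' Gaussian blur with the given kernel applied to the image only
#' (probability 1/2).  The canonical settings are a (160, 160) crop, 30
#' degree rotation, (3, 3) blur kernel and 20 variants per image.
#'
#' @param crop_size Length-2 integer crop size (rows, cols).
#' @param rotation_max_deg Maximum absolute rotation angle in degrees.
#' @param blur_kernel Length-2 odd kernel size for the Gaussian blur.
#' @param blur_sigma Gaussian standard deviation in pixels; the default
#'   derives from the kernel size by the usual `0.3*((k-1)/2 - 1) + 0.8`
#'   convention (0.8 for a 3x3 kernel).
#' @param variants_per_image Number of augmented variants per record.
#' @param seed Integer seed; augmentation is fully deterministic given the
#'   seed and the record's `source_id`.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(crop_size = c(160L, 160L), rotation_max_deg = 30,
                         blur_kernel = c(3L, 3L), blur_sigma = NULL,
                         variants_per_image = 20L, seed = 1L) {
  if (variants_per_image < 1L) {
    stop("variants_per_image must be >= 1", call. = FALSE)
  }
  k <- as.integer(blur_kernel[1])
  structure(
    list(crop_size = as.integer(crop_size),
         rotation_max_deg = rotation_max_deg,
         blur_kernel = as.integer(blur_kernel),
         blur_sigma = blur_sigma %||% (0.3 * ((k - 1) / 2 - 1) + 0.8),
         variants_per_image = as.integer(variants_per_image),
         seed = as.integer(seed)),
    class = "augment_spec"
  )
}

# Small deterministic string hash so each record gets its own substream.
string_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 1000000007
  h
}

gaussian_kernel <- function(k, sigma) {
  r <- (k - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k2 <- outer(g, g)
  k2 / sum(k2)
}

# Direct small-kernel 2-D convolution with replicate boundary (a 3x3 blur is
# nine shifted adds; far cheaper than an FFT round trip at these sizes).
convolve_small <- function(a, kern) {
  d <- dim(a)
  nr <- d[1]; nc <- d[2]
  r <- (nrow(kern) - 1L) %/% 2L
  out <- array(0, d)
  clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)
  for (di in -r:r) {
    ri <- clamp_idx(seq_len(nr) + di, nr)
    for (dj in -r:r) {
      cj <- clamp_idx(seq_len(nc) + dj, nc)
      w <- kern[di + r + 1L, dj + r + 1L]
      if (length(d) == 3L) {
        out <- out + w * a[ri, cj, , drop = FALSE]
      } else {
        out <- out + w * a[ri, cj, drop = FALSE]
      }
    }
  }
  out
}

rotate_arr <- function(a, angle, channels, bilinear = TRUE) {
  d <- if (channels == 3L) dim(a)[1:2] else dim(a)
  out <- EBImage::rotate(to_eb(a), angle,
                         filter = if (bilinear) "bilinear" else "none",
                         output.dim = c(d[2], d[1]), bg.col = 0)
  from_eb(out, channels)
}

center_crop <- function(a, crop) {
  d <- dim(a)
  r0 <- (d[1] - crop[1]) %/% 2L
  c0 <- (d[2] - crop[2]) %/% 2L
  if (length(d) == 3L) {
    a[r0 + seq_len(crop[1]), c0 + seq_len(crop[2]), , drop = FALSE]
  } else {
    a[r0 + seq_len(crop[1]), c0 + seq_len(crop[2]), drop = FALSE]
  }
}

resize_arr <- function(a, h, w, channels, bilinear = TRUE) {
  from_eb(EBImage::resize(to_eb(a), w = w, h = h,
                          filter = if (bilinear) "bilinear" else "none"),
          channels)
}

#' Augment an image/mask pair
#'
#' Produces exactly `spec$variants_per_image` variants of `record`, applying
#' identical geometric transforms to image and mask (see [augment_spec()]).
#' The mask stays strictly binary through every transform.  Output is
#' bit-identical across calls with the same spec and record.
#'
#' @param record A `sample_record`.
#' @param spec An [augment_spec()].
#' @return List of `variants_per_image` new `sample_record`s.
#' @export
augment <- function(record, spec) {
  d <- dim(record$mask)
  if (any(spec$crop_size > d)) {
    stop("crop_size exceeds the image size", call. = FALSE)
  }
  kern <- gaussian_kernel(spec$blur_kernel[1], spec$blur_sigma)
  base <- (spec$seed * 7919 + string_hash(record$source_id)) %% 2147480000
  lapply(seq_len(spec$variants_per_image), function(v) {
    set.seed((base + v) %% 2147483647)
    angle <- stats::runif(1, -spec$rotation_max_deg, spec$rotation_max_deg)
    do_crop <- stats::runif(1) < 0.5
    do_blur <- stats::runif(1) < 0.5
    img <- rotate_arr(record$image, angle, 3L, bilinear = TRUE)
    m <- rotate_arr(record$mask, angle, 1L, bilinear = FALSE)
    if (do_crop) {
      img <- center_crop(img, spec$crop_size)
      m <- center_crop(m, spec$crop_size)
      img <- resize_arr(img, d[1], d[2], 3L, bilinear = TRUE)
      m <- resize_arr(m, d[1], d[2], 1L, bilinear = FALSE)
    }
    if (do_blur) {
      img <- convolve_small(img, kern)
    }
    new_record(
      image = pmin(pmax(img, 0), 1),
      mask = (m > 0.5) + 0,
      source_id = sprintf("%s#aug%02d", record$source_id, v),
      split = record$split
    )
  })
}

#' Dataset split settings
#'
#' @param fractions Train/validation/test fractions; must sum to 1 (within
#'   rounding).  Canonical `c(0.8, 0.1, 0.1)`.
#' @param seed Shuffling seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must be three values summing to 1", call. = FALSE)
  }
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split records into train / validation / test sets
#'
#' Shuffles by the spec's seed, then assigns `round(n * f)` records to the
#' validation and test sets and the remainder to training.  Splitting
#' happens at the source-image level, so augmented variants derived later
#' never leak across splits.
#'
#' @param records List of `sample_record`s (at least 10).
#' @param spec A [split_spec()].
#' @return List with `train`, `val`, `test`: disjoint, exhaustive, each
#'   record's `split` field set.
#' @export
split_dataset <- function(records, spec = split_spec()) {
  n <- length(records)
  if (n < 10L) stop("need at least 10 records to split", call. = FALSE)
  set.seed(spec$seed)
  ord <- sample.int(n)
  n_val <- round(n * spec$fractions[2])
  n_test <- round(n * spec$fractions[3])
  n_train <- n - n_val - n_test
  lab <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  out <- list(train = list(), val = list(), test = list())
  for (i in seq_len(n)) {
    r <- records[[ord[i]]]
    r$split <- lab[i]
    out[[lab[i]]] <- c(out[[lab[i]]], list(r))
  }
  out
}
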