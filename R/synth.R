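#' Generate synthetic endoscopy-style image/mask pairs
#'
#' Emulates the structure of public polyp benchmarks without any downloads:
#' each sample is a mucosa-like background (low-frequency smooth noise in
#' pink/red hues) carrying 1-3 elliptical lesions with randomized size
#' (jointly 8-35% of the image area), a low-contrast hue shift against the
#' background, Gaussian-feathered borders and a scatter of specular
#' highlight speckles.  The ground-truth mask is the union of the lesion
#' ellipses before feathering, so mask borders are crisp while image borders
#' are blurred — the property that makes real polyp segmentation hard.
#'
#' Output is fully deterministic given `seed`.
#'
#' @param n Number of samples (>= 1).
#' @param size Side length in pixels.
#' @param seed Integer seed.
#' @return List of `n` `sample_record`s with non-empty masks.
#' @export
synth_generate <- function(n, size = 256L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    set.seed(as.integer((seed * 1000003 + i * 97) %% 2147483647))
    synth_one(as.integer(size), sprintf("synth_%05d", i))
  })
}

# Smooth random field in [-1, 1]-ish range via bilinear upsampling of a
# coarse Gaussian grid.
smooth_field <- function(size, cells = 8L) {
  g <- matrix(stats::rnorm(cells * cells), cells, cells)
  a <- array(g, c(cells, cells, 1L, 1L))
  matrix(bilinear_resize_cpp(a, cells, cells, 1L, 1L, size, size),
         size, size)
}

synth_one <- function(size, id) {
  base <- c(stats::runif(1, 0.62, 0.85), stats::runif(1, 0.32, 0.5),
            stats::runif(1, 0.3, 0.46))
  shared <- smooth_field(size)
  img <- array(0, c(size, size, 3L))
  for (c in 1:3) {
    img[, , c] <- base[c] + 0.08 * shared + 0.05 * smooth_field(size, 12L)
  }

  n_lesions <- sample.int(3L, 1L)
  total_frac <- stats::runif(1, 0.08, 0.35)
  w <- stats::runif(n_lesions, 0.5, 1)
  fracs <- total_frac * w / sum(w)
  rows <- matrix(rep(seq_len(size), size), size, size)
  cols <- t(rows)
  mask <- matrix(0, size, size)
  lesion_shift <- stats::runif(3, -0.1, 0.1) # low contrast vs background
  for (l in seq_len(n_lesions)) {
    area <- fracs[l] * size^2
    aspect <- stats::runif(1, 0.55, 1)
    a <- sqrt(area / (pi * aspect))
    b <- a * aspect
    th <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, 0.28, 0.72) * size
    cy <- stats::runif(1, 0.28, 0.72) * size
    dr <- rows - cy
    dc <- cols - cx
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    mask[(u / a)^2 + (v / b)^2 <= 1] <- 1
  }

  # feathered lesion blend: crisp mask, blurred image border
  alpha <- matrix(
    EBImage::imageData(EBImage::gblur(EBImage::Image(t(mask)),
                                      sigma = max(2, size / 48))),
    size, size, byrow = TRUE
  )
  lesion <- img
  for (c in 1:3) {
    lesion[, , c] <- img[, , c] + lesion_shift[c] +
      0.04 * smooth_field(size, 10L)
  }
  for (c in 1:3) {
    img[, , c] <- img[, , c] * (1 - alpha) + lesion[, , c] * alpha
  }

  # specular highlights: small bright Gaussian speckles
  for (s in seq_len(sample(3:9, 1L))) {
    sx <- stats::runif(1, 2, size - 2)
    sy <- stats::runif(1, 2, size - 2)
    r2 <- stats::runif(1, 1, 2.5)^2
    amp <- stats::runif(1, 0.35, 0.8)
    spot <- amp * exp(-((rows - sy)^2 + (cols - sx)^2) / (2 * r2))
    for (c in 1:3) img[, , c] <- img[, , c] + spot
  }
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(size, size, 3L)
  new_record(image = img, mask = mask, source_id = id)
}
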