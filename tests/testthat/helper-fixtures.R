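# Shared fixtures and independent oracles.

.cache <- new.env(parent = emptyenv())

# The canonical full-size network is expensive to build; share one instance
# across test files.
canonical_network <- function() {
  if (is.null(.cache$net)) {
    .cache$net <- build_network(network_spec(), seed = 1L)
  }
  .cache$net
}

random_mask <- function(h, w, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# Brute-force per-pixel confusion tally (explicit loop; the oracle for the
# vectorized implementation).
oracle_confusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1L
      else if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Enumerate the k - 2^n connection rule directly over all candidate n.
oracle_link_targets <- function(k) {
  out <- integer(0)
  for (n in 0:31) {
    p <- 2^n
    if (p > k) break
    if (k %% p == 0 && k - p >= 0) out <- c(out, as.integer(k - p))
  }
  sort(unique(out), decreasing = TRUE)
}

# All binary masks on a 2x2 grid.
all_masks_2x2 <- function() {
  lapply(0:15, function(b) {
    matrix(as.integer(intToBits(b)[1:4]), 2, 2)
  })
}

# A tiny deterministic record set for training smoke tests.
synth_set <- function(n, size = 96L, seed = 11L) {
  synth_generate(n, size = size, seed = seed)
}

tmp_png_pair <- function(h = 36L, w = 48L, seed = 1L, mask_values = c(0, 1)) {
  set.seed(seed)
  img <- array(runif(h * w * 3), c(h, w, 3))
  mask <- matrix(sample(mask_values, h * w, replace = TRUE), h, w)
  ip <- tempfile(fileext = ".png")
  mp <- tempfile(fileext = ".png")
  png::writePNG(img, ip)
  png::writePNG(mask, mp)
  list(image = ip, mask = mp, img = img, mask_mat = mask)
}
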