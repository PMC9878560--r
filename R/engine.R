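#' Training configuration
#'
#' The canonical regime: Adam with learning rate 1e-4, mini-batches of 4, up
#' to 300 epochs, early stopping when the validation mDice fails to improve
#' for 50 consecutive epochs.
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs; must be smaller than
#'   `max_epochs`.
#' @param learning_rate Adam step size (> 0).
#' @param seed Root seed governing shuffling (weight initialization is
#'   seeded at [build_network()]).
#' @param max_steps Optional cap on total optimization steps, for quick
#'   CPU-scale fits; `Inf` disables it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, max_epochs = 300L, patience = 50L,
                         learning_rate = 1e-4, seed = 1L, max_steps = Inf) {
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (patience >= max_epochs) {
    stop("patience must be smaller than max_epochs", call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 seed = as.integer(seed), max_steps = max_steps),
            class = "train_config")
}

records_to_batch <- function(records, idx) {
  d <- dim(records[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], 3L, length(idx)))
  t <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (k in seq_along(idx)) {
    x[, , , k] <- records[[idx[k]]]$image
    t[, , 1L, k] <- records[[idx[k]]]$mask
  }
  list(x = x, t = t)
}

# Mean Dice of thresholded predictions over a record set (inference mode).
model_mdice <- function(model, records, threshold = 0.5,
                        batch_size = 4L) {
  n <- length(records)
  scores <- numeric(n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch_size - 1L, n)
    b <- records_to_batch(records, idx)
    prob <- network_forward(model, tg_leaf(b$x), training = FALSE)$v
    for (k in seq_along(idx)) {
      cm <- confusion(predict_mask(prob[, , 1L, k], threshold),
                      records[[idx[k]]]$mask)
      scores[idx[k]] <- dice_coefficient(cm)
    }
    i <- i + batch_size
  }
  mean(scores)
}

#' Train the segmentation network
#'
#' Minimizes the compound Dice + focal loss with Adam over mini-batches.
#' After every epoch the validation mDice is evaluated; training stops at
#' `max_epochs`, when `max_steps` optimization steps have run, or when the
#' validation metric has not improved for `patience` consecutive epochs.
#' The returned model carries the weights of the best validation epoch.
#'
#' @param model A [build_network()] model (modified in place and returned).
#' @param train_set,val_set Non-empty lists of `sample_record`s whose
#'   spatial size matches the model input and is divisible by 32.
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param val_metric_fn Optional `function(model, epoch)` overriding the
#'   validation metric (used to test the early-stopping contract against a
#'   scripted metric series).
#' @param verbose Print one line per epoch to stderr.
#' @return An object of class `polyp_fit`: list with `model`, `history`
#'   (tibble: epoch, loss, val_metric), `best_epoch`, `best_val`,
#'   `stopped_epoch` and `steps`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(),
                  loss_cfg = loss_config(), val_metric_fn = NULL,
                  verbose = FALSE) {
  if (!length(train_set) || !length(val_set)) {
    stop("train_set and val_set must be non-empty", call. = FALSE)
  }
  params <- collect_params(model)
  opt <- adam_state()
  set.seed(cfg$seed)
  n <- length(train_set)
  best_val <- -Inf
  best_epoch <- 0L
  best_snap <- snapshot_weights(model)
  since_best <- 0L
  steps <- 0L
  hist_epoch <- integer(0)
  hist_loss <- numeric(0)
  hist_val <- numeric(0)
  step_losses <- numeric(0)
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    perm <- sample.int(n)
    epoch_losses <- numeric(0)
    i <- 1L
    while (i <= n && steps < cfg$max_steps) {
      idx <- perm[i:min(i + cfg$batch_size - 1L, n)]
      b <- records_to_batch(train_set, idx)
      zero_grads(params)
      tg_start_tape()
      pred <- network_forward(model, tg_leaf(b$x), training = TRUE)
      loss <- tg_seg_loss(pred, b$t, loss_cfg)
      if (!is.finite(loss$v)) {
        tg_stop_tape()
        stop(sprintf(
          "training aborted: non-finite loss at epoch %d step %d",
          epoch, steps + 1L), call. = FALSE)
      }
      tg_backward(loss)
      tg_stop_tape()
      adam_step(params, opt, cfg$learning_rate)
      epoch_losses <- c(epoch_losses, loss$v)
      steps <- steps + 1L
      i <- i + cfg$batch_size
    }
    step_losses <- c(step_losses, epoch_losses)
    val <- if (is.null(val_metric_fn)) {
      model_mdice(model, val_set)
    } else {
      val_metric_fn(model, epoch)
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, mean(epoch_losses))
    hist_val <- c(hist_val, val)
    if (val > best_val) {
      best_val <- val
      best_epoch <- epoch
      best_snap <- snapshot_weights(model)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f  (best %.4f @%d)",
                      epoch, mean(epoch_losses), val, best_val, best_epoch))
    }
    if (since_best >= cfg$patience) break
    if (steps >= cfg$max_steps) break
  }
  restore_weights(model, best_snap)
  structure(
    list(model = model,
         history = tibble::tibble(epoch = hist_epoch, loss = hist_loss,
                                  val_metric = hist_val),
         step_losses = step_losses,
         best_epoch = best_epoch, best_val = best_val,
         stopped_epoch = epoch, steps = steps),
    class = "polyp_fit"
  )
}

#' @export
print.polyp_fit <- function(x, ...) {
  cat("<polyp_fit>\n")
  cat(sprintf("  epochs run : %d (%d steps)\n", x$stopped_epoch, x$steps))
  cat(sprintf("  best epoch : %d (val metric %.4f)\n", x$best_epoch,
              x$best_val))
  invisible(x)
}

#' Per-epoch training history
#'
#' @param x A `polyp_fit`.
#' @param ... Unused.
#' @return The history tibble (epoch, loss, val_metric).
#' @export
tidy.polyp_fit <- function(x, ...) x$history

#' @rdname tidy.polyp_fit
#' @export
glance.polyp_fit <- function(x, ...) {
  tibble::tibble(epochs = x$stopped_epoch, steps = x$steps,
                 best_epoch = x$best_epoch, best_val = x$best_val,
                 final_loss = x$history$loss[nrow(x$history)])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Plot the training history
#'
#' Loss and validation-metric curves over epochs.
#'
#' @param object A `polyp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polyp_fit <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  }
  h <- object$history
  long <- tibble::tibble(
    epoch = rep(h$epoch, 2L),
    value = c(h$loss, h$val_metric),
    series = rep(c("training loss", "validation mDice"),
                 each = nrow(h))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Run inference and write probability/mask PNGs
#'
#' Each input image is resized to the model input size, passed through the
#' network, and written out as an 8-bit grayscale probability PNG
#' (`<stem>_prob.png`) and a binary mask PNG (`<stem>_mask.png`).
#'
#' @param model A `polyp_network`.
#' @param inputs Directory of images, or a character vector of image paths.
#' @param out_dir Output directory (created if missing).
#' @param threshold Mask binarization threshold in `(0, 1)`.
#' @return Tibble with columns `input`, `prob_png`, `mask_png`.
#' @export
predict_to_dir <- function(model, inputs, out_dir, threshold = 0.5) {
  paths <- if (length(inputs) == 1L && dir.exists(inputs)) {
    list.files(inputs, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    inputs
  }
  if (!length(paths)) stop("no input images found", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  size <- model$spec$input_size
  rows <- lapply(paths, function(p) {
    img <- read_image_file(p)
    if (!identical(dim(img)[1:2], c(size, size))) {
      img <- resize_arr(img, size, size, 3L)
      img <- pmin(pmax(img, 0), 1)
    }
    prob <- predict_probs(model, img)
    stem <- sub("\\.[^.]+$", "", basename(p))
    prob_png <- file.path(out_dir, paste0(stem, "_prob.png"))
    mask_png <- file.path(out_dir, paste0(stem, "_mask.png"))
    png::writePNG(prob, prob_png)
    png::writePNG(predict_mask(prob, threshold) + 0, mask_png)
    tibble::tibble(input = p, prob_png = prob_png, mask_png = mask_png)
  })
  do.call(rbind, rows)
}

#' Evaluate predictions stored on disk
#'
#' Pairs same-named PNGs from a prediction directory (8-bit probability
#' maps) and a ground-truth directory (binary masks) and computes the six
#' segmentation measures.  Prediction files may carry the `_prob` suffix
#' that [predict_to_dir()] writes; the suffix is ignored when pairing (a
#' bare `<stem>.png` wins over `<stem>_prob.png` if both exist, and
#' `_mask` files are never paired).
#'
#' @param pred_dir,gt_dir Directories of PNG files with matching names.
#' @param threshold Binarization threshold for the count-based measures.
#' @return A one-row tibble as from [evaluate_set()].
#' @export
evaluate_dirs <- function(pred_dir, gt_dir, threshold = 0.5) {
  preds <- list.files(pred_dir, pattern = "\\.png$", ignore.case = TRUE)
  preds <- preds[!grepl("_mask\\.png$", preds, ignore.case = TRUE)]
  pred_stems <- sub("_prob\\.png$", ".png", preds, ignore.case = TRUE)
  keep <- !duplicated(pred_stems) | preds == pred_stems
  preds <- preds[keep]
  pred_stems <- pred_stems[keep]
  gts <- list.files(gt_dir, pattern = "\\.png$", ignore.case = TRUE)
  hit <- match(gts, pred_stems)
  if (!any(!is.na(hit))) {
    stop("no same-named PNG files in the two directories", call. = FALSE)
  }
  pairs <- lapply(which(!is.na(hit)), function(i) {
    p <- read_image_file(file.path(pred_dir, preds[hit[i]]))[, , 1]
    g <- read_image_file(file.path(gt_dir, gts[i]))[, , 1]
    list(pred = p, gt = (g > 127 / 255) + 0)
  })
  evaluate_set(pairs, threshold = threshold)
}
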