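test_that("train_config validates the regime invariants", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$max_epochs, 300L)
  expect_equal(cfg$patience, 50L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(patience = 300, max_epochs = 300), "patience")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("early stopping follows the scripted metric series", {
  recs <- synth_set(4, size = 32, seed = 71)
  net <- build_network(network_spec_tiny(32), seed = 7)
  series <- c(0.5, 0.6, 0.6, 0.6, 0.7)
  fit <- train(net, recs, recs,
               cfg = train_config(batch_size = 4, max_epochs = 10,
                                  patience = 2, learning_rate = 1e-5,
                                  seed = 1),
               val_metric_fn = function(model, epoch) series[epoch])
  # improvement at epochs 1 and 2, stagnation at 3 and 4 -> stop after 4
  expect_equal(fit$stopped_epoch, 4L)
  expect_equal(fit$best_epoch, 2L)
  expect_equal(fit$best_val, 0.6)
  expect_equal(nrow(fit$history), 4L)
})

test_that("max_epochs = 1 runs exactly one epoch regardless of patience", {
  recs <- synth_set(4, size = 32, seed = 72)
  net <- build_network(network_spec_tiny(32), seed = 8)
  fit <- train(net, recs, recs,
               cfg = train_config(max_epochs = 1, patience = 0,
                                  learning_rate = 1e-5, seed = 1))
  expect_equal(fit$stopped_epoch, 1L)
  expect_equal(fit$steps, 1L) # 4 records / batch 4
})

test_that("the returned checkpoint never undercuts an earlier epoch", {
  recs <- synth_set(4, size = 32, seed = 73)
  net <- build_network(network_spec_tiny(32), seed = 9)
  set.seed(99)
  series <- runif(12)
  fit <- train(net, recs, recs,
               cfg = train_config(max_epochs = 12, patience = 4,
                                  learning_rate = 1e-5, seed = 2),
               val_metric_fn = function(model, epoch) series[epoch])
  expect_equal(fit$best_val, max(series[seq_len(fit$stopped_epoch)]))
  expect_equal(fit$best_epoch,
               which.max(series[seq_len(fit$stopped_epoch)]))
})

test_that("an Adam step with zero learning rate leaves weights bit-identical", {
  ns <- asNamespace("polypseg")
  set.seed(74)
  net <- build_network(network_spec_tiny(32), seed = 10)
  params <- ns$collect_params(net)
  before <- lapply(params, function(p) p$value)
  rec <- synth_set(1, size = 32, seed = 74)[[1]]
  b <- ns$records_to_batch(list(rec), 1L)
  ns$zero_grads(params)
  ns$tg_start_tape()
  loss <- ns$tg_seg_loss(
    ns$network_forward(net, ns$tg_leaf(b$x), training = TRUE),
    b$t, loss_config())
  ns$tg_backward(loss)
  ns$tg_stop_tape()
  # gradients flowed...
  expect_gt(max(vapply(params, function(p) max(abs(p$grad)), numeric(1))), 0)
  ns$adam_step(params, ns$adam_state(), lr = 0)
  after <- lapply(params, function(p) p$value)
  expect_identical(after, before) # ...but a zero step moves nothing
})

test_that("training trajectories reproduce under a fixed seed", {
  recs <- synth_set(4, size = 32, seed = 75)
  f <- function() {
    net <- build_network(network_spec_tiny(32), seed = 11)
    train(net, recs, recs,
          cfg = train_config(max_epochs = 3, patience = 2,
                             learning_rate = 1e-3, seed = 5))$history
  }
  expect_equal(f(), f(), tolerance = 1e-12)
})

test_that("training rejects empty inputs", {
  net <- build_network(network_spec_tiny(32), seed = 12)
  recs <- synth_set(2, size = 32, seed = 76)
  expect_error(train(net, list(), recs), "non-empty")
  expect_error(train(net, recs, list()), "non-empty")
})

test_that("fit accessors expose history and summary", {
  recs <- synth_set(4, size = 32, seed = 77)
  net <- build_network(network_spec_tiny(32), seed = 13)
  fit <- train(net, recs, recs,
               cfg = train_config(max_epochs = 2, patience = 1,
                                  learning_rate = 1e-4, seed = 3))
  h <- tidy(fit)
  expect_s3_class(h, "tbl_df")
  expect_named(h, c("epoch", "loss", "val_metric"))
  g <- glance(fit)
  expect_equal(g$epochs, fit$stopped_epoch)
  expect_equal(g$best_epoch, fit$best_epoch)
})

test_that("predict_to_dir writes paired probability and mask PNGs", {
  net <- build_network(network_spec_tiny(32), seed = 14)
  recs <- synth_set(3, size = 32, seed = 78)
  in_dir <- file.path(tempdir(), "pp_in")
  out_dir <- file.path(tempdir(), "pp_out")
  dir.create(in_dir, showWarnings = FALSE)
  for (i in seq_along(recs)) {
    png::writePNG(recs[[i]]$image, file.path(in_dir, sprintf("im%d.png", i)))
  }
  res <- predict_to_dir(net, in_dir, out_dir)
  expect_equal(nrow(res), 3L)
  expect_true(all(file.exists(res$prob_png)))
  expect_true(all(file.exists(res$mask_png)))
  # 8-bit round trip distorts probabilities by at most half a quantum
  p_mem <- predict_probs(net, recs[[1]]$image)
  p_disk <- png::readPNG(res$prob_png[res$input ==
                                        file.path(in_dir, "im1.png")])
  expect_lte(max(abs(p_disk - p_mem)), 1 / 255)
  # masks on disk are strictly binary
  m_disk <- png::readPNG(res$mask_png[1])
  expect_true(all(m_disk %in% c(0, 1)))
  # a near-zero threshold marks everything foreground
  res0 <- predict_to_dir(net, in_dir, out_dir, threshold = 1e-6)
  expect_true(all(png::readPNG(res0$mask_png[1]) == 1))
  unlink(c(in_dir, out_dir), recursive = TRUE)
})

test_that("evaluate_dirs pairs same-named files and reports the six measures", {
  net <- build_network(network_spec_tiny(32), seed = 15)
  recs <- synth_set(3, size = 32, seed = 79)
  pd <- file.path(tempdir(), "pp_pred")
  gd <- file.path(tempdir(), "pp_gt")
  dir.create(pd, showWarnings = FALSE)
  dir.create(gd, showWarnings = FALSE)
  for (i in seq_along(recs)) {
    prob <- predict_probs(net, recs[[i]]$image)
    png::writePNG(prob, file.path(pd, sprintf("s%d.png", i)))
    png::writePNG(recs[[i]]$mask, file.path(gd, sprintf("s%d.png", i)))
  }
  rep <- evaluate_dirs(pd, gd)
  expect_equal(rep$n_images, 3L)
  expect_true(all(unlist(rep[, 1:6]) >= 0 & unlist(rep[, 1:6]) <= 1))
  # perfect predictions give a perfect report
  for (i in seq_along(recs)) {
    png::writePNG(recs[[i]]$mask, file.path(pd, sprintf("s%d.png", i)))
  }
  perfect <- evaluate_dirs(pd, gd)
  expect_equal(perfect$mdice, 1)
  expect_equal(perfect$mae, 0)
  empty <- file.path(tempdir(), "pp_empty")
  dir.create(empty, showWarnings = FALSE)
  expect_error(evaluate_dirs(empty, gd), "same-named")
  unlink(c(pd, gd, empty), recursive = TRUE)
})
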