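# training loop: plateau schedule, determinism, loss descent

test_that("the plateau schedule halves the LR after 5 non-improving epochs", {
  # freezing the weights forces a monotonically non-improving validation
  # loss; with patience 5 the LR must drop 0.001 -> 0.0005 for epoch 7
  tr <- phantom_samples(1, shape = c(16, 16, 16))[1:4]
  va <- phantom_samples(2, shape = c(16, 16, 16))[1:2]
  mod <- train_model(net_config("unet2d", depth = 2, base_filters = 4),
                     list(train = tr, val = va),
                     train_config(epochs = 7, seed = 3, augment = FALSE),
                     freeze_weights = TRUE)
  expect_equal(mod$history$lr, c(rep(0.001, 6), 0.0005))
  expect_equal(diff(mod$history$val_loss), rep(0, 6))  # frozen = flat loss
})

test_that("identical seeds reproduce identical loss histories", {
  tr <- phantom_samples(1, shape = c(16, 16, 16))[1:6]
  va <- phantom_samples(2, shape = c(16, 16, 16))[1:2]
  cfg <- train_config(epochs = 3, seed = 17)
  m1 <- train_model(net_config("unet2d", depth = 2, base_filters = 4),
                    list(train = tr, val = va), cfg)
  m2 <- train_model(net_config("unet2d", depth = 2, base_filters = 4),
                    list(train = tr, val = va), cfg)
  expect_identical(m1$history, m2$history)
  m3 <- train_model(net_config("unet2d", depth = 2, base_filters = 4),
                    list(train = tr, val = va),
                    train_config(epochs = 3, seed = 18))
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("a tiny 2D net learns phantom slices (loss decreases)", {
  tr <- phantom_samples(1:2, shape = c(32, 32, 32))
  mod <- train_model(net_config("unet2d", depth = 2, base_filters = 4),
                     list(train = tr),
                     train_config(epochs = 4, seed = 5, augment = FALSE))
  expect_lt(tail(mod$history$train_loss, 1), mod$history$train_loss[1])
  expect_identical(nrow(mod$history), 4L)
})

test_that("3D training runs with batch size 1 and decreasing loss", {
  mk <- function(seeds) lapply(seeds, function(s) {
    ph <- small_phantom(seed = s, shape = c(16, 16, 16))
    v <- normalize_intensity(ph$volume)
    d <- dim(v$data)
    y <- array(0, c(d, 3))
    y[, , , 1] <- ph$labels$channels$background
    y[, , , 2] <- ph$labels$channels$ms
    y[, , , 3] <- ph$labels$channels$msa
    list(x = array(v$data, c(d, 1)), y = y)
  })
  mod <- train_model(net_config("unet3d", depth = 2, base_filters = 4),
                     list(train = mk(1:3)),
                     train_config(epochs = 4, seed = 2, augment = FALSE))
  expect_lt(tail(mod$history$train_loss, 1), mod$history$train_loss[1])
  # prediction plumbing
  ph <- small_phantom(seed = 9, shape = c(16, 16, 16))
  pv <- predict_3d(mod, normalize_intensity(ph$volume))
  expect_identical(pv$provenance, "3d")
  expect_identical(dim(pv$data), c(16L, 16L, 16L, 3L))
  expect_error(train_model(net_config("unet2d"), list(train = list()),
                           train_config(epochs = 1)), "at least one")
})

test_that("stub and trained models satisfy the prediction contracts", {
  v <- volume(array(runif(12 * 16 * 20), c(12, 16, 20)))
  st <- extract_slices(v, "sagittal")
  pv <- predict_plane(stub_model(0.7), st)
  expect_identical(dim(pv$data), c(12L, 16L, 20L, 3L))  # volume, not slice, shape
  expect_true(all(pv$data == 0.7))
  expect_identical(pv$provenance, "sagittal")
  pv3 <- predict_3d(stub_model(c(0.1, 0.9, 0.2)), v)
  expect_true(all(pv3$data[, , , 2] == 0.9))
  # a trained-2D model refuses volumetric prediction and vice versa
  m2 <- build_model(net_config("unet2d", depth = 2, base_filters = 4))
  expect_error(predict_3d(m2, v), "predict_3d needs a 3D model")
  m3 <- build_model(net_config("unet3d", depth = 2, base_filters = 4))
  expect_error(predict_plane(m3, st), "predict_plane needs a 2D model")
})
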