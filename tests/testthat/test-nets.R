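# network builders, Dice loss, augmentation

test_that("multi-label Dice loss matches direct summation on a toy batch", {
  # 8-voxel toy, hand-evaluated with the documented eps = 1 smoothing:
  # uniform prediction 0.5 against half-ones truth on each channel gives
  # per-channel dice (2*0.25*8 + 1) / (0.5*8 + 0.5*8 + 1) = 5/9
  pred <- array(0.5, c(2, 2, 2, 3))
  truth <- array(rep(c(1, 0), 4), c(2, 2, 2, 3))
  expect_equal(sum(truth[, , , 1]), 4)
  expect_equal(multi_label_dice_loss(pred, truth), 1 - 5 / 9)
  # eps -> 0 recovers the textbook value 0.5
  expect_equal(multi_label_dice_loss(pred, truth, eps = 1e-12), 0.5,
               tolerance = 1e-9)
  # perfect binary prediction: loss ~ 0 (exactly 0 up to eps)
  expect_lt(multi_label_dice_loss(truth, truth), 1e-9)
  # complement prediction: per-channel overlap 0, loss -> 1 as eps -> 0
  expect_gt(multi_label_dice_loss(1 - truth, truth), 0.8)
  # independent direct-summation oracle on random values
  set.seed(8)
  p <- array(runif(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  t <- array(rbinom(4 * 4 * 2 * 3, 1, 0.4), c(4, 4, 2, 3))
  s <- vapply(1:3, function(ch) {
    pp <- p[, , , ch]; tt <- t[, , , ch]
    (2 * sum(pp * tt) + 1) / (sum(pp) + sum(tt) + 1)
  }, numeric(1))
  expect_equal(multi_label_dice_loss(p, t), 1 - mean(s))
  expect_error(multi_label_dice_loss(p, t[, , , 1:2]), "match")
})

test_that("loss is permutation-invariant and decreases toward the truth", {
  set.seed(9)
  t <- array(rbinom(6 * 6 * 3, 1, 0.5), c(6, 6, 1, 3))
  p <- array(runif(6 * 6 * 3), c(6, 6, 1, 3))
  ord <- sample(36)
  pp <- p; tt <- t
  for (ch in 1:3) {
    pp[, , 1, ch] <- array(p[, , 1, ch][ord], c(6, 6))
    tt[, , 1, ch] <- array(t[, , 1, ch][ord], c(6, 6))
  }
  expect_equal(multi_label_dice_loss(p, t), multi_label_dice_loss(pp, tt))
  # convex path from complement to truth: loss strictly decreases
  lambdas <- seq(0, 1, by = 0.2)
  losses <- vapply(lambdas, function(l)
    multi_label_dice_loss((1 - l) * (1 - t) + l * t, t), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("the loss gradient agrees with finite differences (double path)", {
  set.seed(10)
  p <- array(runif(4 * 4 * 1 * 3, 0.2, 0.8), c(4, 4, 1, 3))
  t <- array(rbinom(48, 1, 0.5), c(4, 4, 1, 3))
  dl <- triplanr:::.dice_loss(p, t, 4L)
  for (idx in sample(length(p), 5)) {
    eps <- 1e-6
    pp <- p; pp[idx] <- p[idx] + eps
    pm <- p; pm[idx] <- p[idx] - eps
    num <- (triplanr:::.dice_loss(pp, t, 4L)$loss -
            triplanr:::.dice_loss(pm, t, 4L)$loss) / (2 * eps)
    expect_equal(dl$grad[idx], num, tolerance = 1e-5)
  }
})

test_that("builders honour the configuration across all four families", {
  for (fam in c("unet2d", "unetpp2d", "unet3d", "vnet3d")) {
    m <- build_model(net_config(fam, depth = 2, base_filters = 4), seed = 1)
    x <- if (m$rank == 2L) array(runif(16 * 16 * 2), c(16, 16, 2, 1))
         else array(runif(16 * 16 * 16), c(16, 16, 16, 1))
    out <- triplanr:::.forward(m$graph, m$params, x, want_cache = FALSE)$out
    expect_identical(dim(out)[4], 3L)                # 3 sigmoid channels
    expect_identical(dim(out)[1:3], dim(x)[1:3])     # resolution preserved
    expect_true(all(out > 0 & out < 1))              # sigmoid range
  }
  # parameter-count properties
  n_unet <- n_params(build_model(net_config("unet2d", depth = 3, base_filters = 8)))
  n_pp <- n_params(build_model(net_config("unetpp2d", depth = 3, base_filters = 8)))
  n_deep <- n_params(build_model(net_config("unet2d", depth = 4, base_filters = 8)))
  expect_gt(n_pp, n_unet)        # dense skips add blocks, hence parameters
  expect_false(n_deep == n_unet) # depth changes the count
  n_res <- n_params(build_model(net_config("unet2d", depth = 3, base_filters = 8,
                                           backbone = "resnet_style")))
  expect_gt(n_res, n_unet)       # projection shortcuts add parameters
  expect_error(net_config("unet2d", depth = 1), "depth")
  expect_error(net_config("unet2d", base_filters = 2), "base_filters")
})

test_that("engine gradients are consistent with a descent direction", {
  # float32 conv kernels make per-element finite differences noisy, so check
  # the directional derivative along the full gradient instead
  set.seed(12)
  for (fam in c("unet2d", "vnet3d")) {
    m <- build_model(net_config(fam, depth = 2, base_filters = 4), seed = 2)
    x <- if (m$rank == 2L) array(runif(16 * 16 * 2), c(16, 16, 2, 1))
         else array(runif(8 * 8 * 8), c(8, 8, 8, 1))
    yd <- dim(x); yd[4] <- 3L
    y <- array(rbinom(prod(yd), 1, 0.5), yd)
    fw <- triplanr:::.forward(m$graph, m$params, x)
    dl <- triplanr:::.dice_loss(fw$out, y, 4L)
    gr <- triplanr:::.backward(m$graph, m$params, fw, dl$grad)
    gnorm2 <- sum(vapply(gr, function(g) sum(g^2), numeric(1)))
    a <- 1e-3 / sqrt(gnorm2)
    p2 <- m$params
    for (nm in names(gr)) p2[[nm]] <- p2[[nm]] - a * gr[[nm]]
    l2 <- triplanr:::.dice_loss(
      triplanr:::.forward(m$graph, p2, x, want_cache = FALSE)$out, y, 4L)$loss
    drop <- dl$loss - l2
    expect_gt(drop, 0)                                  # descent direction
    expect_equal(drop, a * gnorm2, tolerance = 0.05)    # matches <g,g> locally
  }
})

test_that("augmentation honours its identity, clipping and mask contracts", {
  set.seed(13)
  img <- matrix(runif(32 * 32, 0, 0.9), 32, 32)
  dim(img) <- c(32, 32, 1)
  mask <- array(rbinom(32 * 32 * 3, 1, 0.3), c(32, 32, 3))
  id <- augment_pair(img, mask, angle = 0, factor = 1)
  expect_identical(id$image, img)
  expect_identical(id$mask, mask)
  # any rotation keeps masks strictly binary (nearest neighbour)
  rot <- augment_pair(img, mask, angle = 17.3, factor = 1)
  expect_true(all(rot$mask %in% c(0, 1)))
  expect_identical(dim(rot$image), dim(img))
  # brightness clips at 1 and never touches the mask
  bright <- augment_pair(img, mask, angle = 0, factor = 1.2)
  expect_identical(bright$mask, mask)
  expect_equal(max(bright$image), 1)
  expect_equal(bright$image[img < 0.8], 1.2 * img[img < 0.8])
  # seeded draws are reproducible and land in the documented ranges
  a1 <- augment_pair(img, mask, seed = 5)
  a2 <- augment_pair(img, mask, seed = 5)
  expect_identical(a1$image, a2$image)
  expect_true(abs(a1$angle) <= 20)
  expect_true(a1$factor >= 0.8 && a1$factor <= 1.2)
})
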