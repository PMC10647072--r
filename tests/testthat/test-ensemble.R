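# voting fusion: truth tables, nesting, symmetry

test_that("all 8 voter combinations match brute-force truth-table oracles", {
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  oracle <- list(
    unanimous = function(a, b, c) as.integer(a & b & c),
    affirmative = function(a, b, c) as.integer(a | b | c),
    majority = function(a, b, c) as.integer(a + b + c >= 2))
  for (rule in names(oracle)) {
    got <- vapply(seq_len(nrow(combos)), function(i) {
      masks <- lapply(combos[i, ], function(v) array(as.integer(v), c(1, 1, 1)))
      vote(unname(masks), rule)[1]
    }, integer(1))
    want <- with(combos, oracle[[rule]](a, b, c))
    expect_identical(got, want, info = rule)
  }
})

test_that("unanimous <= majority <= affirmative pointwise on random triples", {
  set.seed(99)
  for (rep in 1:100) {
    masks <- lapply(1:3, function(i) random_mask(c(6, 6, 6), p = runif(1)))
    u <- vote(masks, "unanimous")
    m <- vote(masks, "majority")
    a <- vote(masks, "affirmative")
    expect_true(all(u <= m))
    expect_true(all(m <= a))
  }
})

test_that("voting is permutation-invariant and idempotent on equal inputs", {
  set.seed(7)
  masks <- lapply(1:3, function(i) random_mask(c(5, 5, 5)))
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  for (rule in c("unanimous", "affirmative", "majority")) {
    base <- vote(masks, rule)
    for (p in perms) expect_identical(vote(masks[p], rule), base)
    same <- masks[c(1, 1, 1)]
    expect_identical(vote(same, rule), masks[[1]])
  }
  # commutes with voxel permutation applied to all inputs
  ord <- sample(125)
  shuffled <- lapply(masks, function(m) array(m[ord], dim(m)))
  for (rule in c("unanimous", "majority")) {
    direct <- array(vote(masks, rule)[ord], c(5, 5, 5))
    expect_identical(vote(shuffled, rule), direct)
  }
})

test_that("vote validates its inputs", {
  m <- random_mask(c(3, 3, 3), seed = 1)
  expect_error(vote(list(m, m), "majority"), "exactly 3")
  expect_error(vote(list(m, m, m, m), "majority"), "exactly 3")
  bad <- m; bad[1] <- 2L
  expect_error(vote(list(m, m, bad), "majority"), "binary")
  expect_error(vote(list(m, m, random_mask(c(2, 3, 3))), "majority"), "shape")
})

test_that("binarize thresholds inclusively and is idempotent", {
  p <- array(c(0.49, 0.5, 0.51, 0, 1, 0.25), c(1, 2, 3))
  b <- binarize(p, 0.5)
  expect_identical(as.vector(b), c(0L, 1L, 1L, 0L, 1L, 0L))
  expect_identical(binarize(b, 0.5), b)
  expect_error(binarize(p, 0), "threshold")
  expect_error(binarize(p, 1), "threshold")
  # probability volumes keep their class and provenance
  pv <- predict_plane(stub_model(c(0.2, 0.7, 0.4)),
                      extract_slices(volume(array(0, c(4, 4, 4))), "axial"))
  bv <- binarize(pv)
  expect_s3_class(bv, "tpl_prob_volume")
  expect_identical(unique(as.vector(bv$data[, , , 2])), 1L)
  expect_identical(unique(as.vector(bv$data[, , , 3])), 0L)
})
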