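# synthetic phantom generator: label topology, determinism, intensities

test_that("label topology holds voxel-wise for every style", {
  for (style in c("none", "mucosal_shell", "polypoid", "mixed")) {
    ph <- small_phantom(seed = 7, style = style, masks_only = TRUE)
    ms <- ph$labels$channels$ms
    msa <- ph$labels$channels$msa
    msl <- msl_channel(ph$labels)
    expect_true(all(msa <= ms))                       # MSA subset of MS
    expect_identical(msl, array(ms * (1L - msa), dim(ms)))  # MSL = MS \ MSA
    expect_true(all(msl <= ms))
    if (style == "none") {
      expect_identical(msa, ms)
      expect_identical(sum(msl), 0L)
    } else {
      expect_gt(sum(ms), 0)
    }
  }
})

test_that("mucosal shells stay within the stated thickness of the MS boundary", {
  spec <- phantom_spec(shape = c(32, 32, 32), lesion_style = "mucosal_shell",
                       shell_thickness_range = c(2L, 2L), seed = 11)
  ph <- generate_phantom(spec, masks_only = TRUE)
  ms <- ph$labels$channels$ms == 1L
  msl <- msl_channel(ph$labels) == 1L
  # oracle: brute-force Chebyshev erosion by radius 2 with a direct
  # neighbourhood scan (independent of the generator's separable erosion)
  d <- dim(ms)
  interior <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!ms[i, j, k]) next
    lo <- c(i, j, k) - 2L; hi <- c(i, j, k) + 2L
    if (any(lo < 1L) || any(hi > d)) next
    interior[i, j, k] <- all(ms[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }
  expect_identical(msl, ms & !interior)
})

test_that("generation is deterministic in the seed and varies across seeds", {
  spec <- phantom_spec(shape = c(24, 24, 24), seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$channels, b$labels$channels)
  spec2 <- phantom_spec(shape = c(24, 24, 24), seed = 6)
  c <- generate_phantom(spec2)
  expect_false(identical(a$volume$data, c$volume$data))
  # generation must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_phantom(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("intensity tiers are ordered air < soft tissue < bone under noise", {
  for (seed in c(2, 9)) {
    ph <- small_phantom(seed = seed, style = "mixed", noise = 10)
    img <- ph$volume$data
    msa <- ph$labels$channels$msa == 1L
    msl <- msl_channel(ph$labels) == 1L
    bone <- ph$labels$channels$ms == 0L
    if (sum(msl) > 0) {
      expect_lt(mean(img[msa]), mean(img[msl]))
      expect_lt(mean(img[msl]), mean(img[bone]))
    } else {
      expect_lt(mean(img[msa]), mean(img[bone]))
    }
  }
})

test_that("mixed-style lesion volume fractions span at least [0.01, 0.4]", {
  fr <- vapply(1:20, function(i) {
    ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 100 + i,
                                        lesion_style = "mixed"),
                           masks_only = TRUE)
    sum(msl_channel(ph$labels)) / sum(ph$labels$channels$ms)
  }, numeric(1))
  expect_lte(min(fr), 0.01)
  expect_gte(max(fr), 0.4)
})

test_that("cohorts are written with exact split counts and deterministic manifests", {
  dir <- withr::local_tempdir()
  m <- make_cohort(file.path(dir, "a"), n = 6, shape = c(16, 16, 16),
                   split = c(train = 1 / 3, validation = 1 / 3, test = 1 / 3))
  expect_identical(as.vector(table(m$split)[c("train", "validation", "test")]),
                   c(2L, 2L, 2L))
  expect_true(all(file.exists(file.path(dir, "a", m$ms_mask))))
  expect_true(all(file.exists(file.path(dir, "a", m$volume))))
  m2 <- make_cohort(file.path(dir, "b"), n = 6, shape = c(16, 16, 16),
                    split = c(train = 1 / 3, validation = 1 / 3, test = 1 / 3))
  expect_identical(m$seed, m2$seed)
  expect_identical(m$split, m2$split)
  # the paper-style split arithmetic: 67 cases -> 39/14/14
  counts <- triplanr:::.split_counts(67, c(39, 14, 14) / 67)
  expect_identical(counts, c(39L, 14L, 14L))
  expect_error(generate_cohort(2, phantom_spec(shape = c(16, 16, 16)),
                               file.path(dir, "c")),
               "smaller than the number of nonzero split groups")
  expect_error(generate_cohort(5, phantom_spec(shape = c(16, 16, 16)),
                               file.path(dir, "d"), split = c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("masks-only cohorts omit the intensity volume but keep readable masks", {
  dir <- withr::local_tempdir()
  sp <- phantom_spec(shape = c(16, 16, 16), seed = 2)
  m <- generate_cohort(3, sp, dir, split = c(train = 1), masks_only = TRUE)
  expect_true(all(m$volume == ""))
  lab <- read_label_volume(file.path(dir, "case001"))
  expect_identical(dim(lab$channels$ms), c(16L, 16L, 16L))
})
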