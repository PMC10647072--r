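# volume containers, NIfTI/NRRD round trips, orientation, resizing

test_that("write/read round-trips data and spacing in both formats", {
  set.seed(1)
  v <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(0.3, 0.4, 0.5))
  for (ext in c(".nii", ".nii.gz", ".nrrd")) {
    p <- withr::local_tempfile(fileext = ext)
    write_volume(v, p)
    r <- read_volume(p)
    expect_equal(r$data, v$data, tolerance = 1e-6)
    expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  }
  # uint8 mask round trip is exact
  m <- random_mask(c(4, 5, 6), seed = 2)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(volume(m + 0), p, dtype = "uint8")
  expect_identical(array(as.integer(read_volume(p)$data), dim(m)), m)
})

test_that("label volumes round-trip channel-wise with their invariants", {
  ph <- small_phantom(seed = 3, masks_only = TRUE)
  pre <- file.path(withr::local_tempdir(), "case")
  write_label_volume(ph$labels, pre)
  lab <- read_label_volume(pre)
  expect_identical(lab$channels$ms, ph$labels$channels$ms)
  expect_identical(lab$channels$msa, ph$labels$channels$msa)
  expect_true(all(lab$channels$msa <= lab$channels$ms))
  expect_true(all(lab$channels$background + lab$channels$ms == 1L))
})

test_that("flipped/permuted on-disk orientations are mapped to canonical axes", {
  set.seed(4)
  v <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(0.3, 0.4, 0.5))
  # axis 1 flipped; voxel axis 2 -> world IS, voxel axis 3 -> world AP
  aff <- cbind(matrix(c(-0.3, 0, 0, 0, 0, 0.5, 0, 0.4, 0), 3, 3), c(0, 0, 0))
  p <- withr::local_tempfile(fileext = ".nii")
  triplanr:::.nifti_write(v, p, dtype = "float32", affine = aff)
  r <- read_volume(p)
  manual <- aperm(v$data[4:1, , ], c(1, 3, 2))   # independent reorientation
  expect_equal(r$data, manual, tolerance = 1e-6)
  expect_equal(r$spacing, c(0.3, 0.4, 0.5), tolerance = 1e-6)
  # header-only read agrees
  sh <- triplanr:::.nifti_read_shape(p)
  expect_identical(sh$dim, dim(manual))

  # same idea through NRRD space directions
  p2 <- withr::local_tempfile(fileext = ".nrrd")
  triplanr:::.nrrd_write(v, p2, dtype = "float32",
                         directions = matrix(c(-0.3, 0, 0, 0, 0, 0.5, 0, 0.4, 0), 3, 3))
  r2 <- read_volume(p2)
  expect_equal(r2$data, manual, tolerance = 1e-6)
})

test_that("unreadable and truncated files raise format errors naming the path", {
  p <- withr::local_tempfile(fileext = ".nii")
  writeBin(raw(100), p)
  expect_error(read_volume(p), "truncated|NIfTI")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "exist")
  p2 <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: float", "dimension: 3"), p2)
  expect_error(read_volume(p2), "truncated|sizes|NRRD")
  expect_error(read_volume(withr::local_tempfile(fileext = ".xyz")),
               "cannot infer")
})

test_that("resize_volume honours shape, mode and spacing contracts", {
  ph <- small_phantom(seed = 5, shape = c(24, 20, 16))
  v <- ph$volume
  r <- resize_volume(v, c(12, 10, 8))
  expect_identical(dim(r$data), c(12L, 10L, 8L))
  expect_equal(r$spacing, v$spacing * c(2, 2, 2))
  # identity resize
  r2 <- resize_volume(v, dim(v$data))
  expect_equal(r2$data, v$data)
  # nearest-neighbour keeps masks binary
  m <- resize_volume(volume(ph$labels$channels$ms + 0), c(17, 13, 9),
                     mode = "label")
  expect_true(all(m$data %in% c(0, 1)))
  expect_error(resize_volume(v, c(0, 10, 8)), "positive")
})

test_that("round-trip resize keeps coarse mask structure (Dice >= 0.9)", {
  for (seed in 1:3) {
    # sinus semiaxes all >= 8 voxels: the property is stated for structures
    # of at least that radius
    sp <- phantom_spec(shape = c(48, 48, 48), seed = seed,
                       sinus_semiaxes_range = rbind(c(8, 12), c(9, 14), c(9, 14)))
    ph <- generate_phantom(sp, masks_only = TRUE)
    ms <- ph$labels$channels$ms
    down <- resize_volume(volume(ms + 0), c(24, 24, 24), mode = "label")
    back <- resize_volume(down, c(48, 48, 48), mode = "label")
    dsc <- seg_metrics(confusion(array(as.integer(back$data), dim(ms)), ms))[["DSC"]]
    expect_gte(dsc, 0.9)
  }
})

test_that("normalize_intensity maps to [0,1] and zeroes constant volumes", {
  v <- volume(array(c(100, 200, 300, 250, 150, 101), c(1, 2, 3)))
  n <- normalize_intensity(v)
  expect_equal(range(n$data), c(0, 1))
  expect_equal(n$data[1, 2, 1], 0.5)   # 200 between 100 and 300
  const <- normalize_intensity(volume(array(7, c(2, 2, 2))))
  expect_true(all(const$data == 0))
})

test_that("volume and label constructors enforce their invariants", {
  expect_error(volume(array(1, c(2, 2))), "3D")
  expect_error(volume(array(NA_real_, c(2, 2, 2))), "non-finite")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  m <- array(1L, c(2, 2, 2))
  expect_error(label_volume(list(ms = m * 0L, msa = m)), "subset")
  expect_error(label_volume(list(ms = m * 2L, msa = m * 0L)), "binary")
})
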