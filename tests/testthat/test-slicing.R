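# tri-planar slicing: geometry, exact inverse, cohort slice counts

test_that("slice counts and shapes follow the plane geometry", {
  v <- volume(array(seq_len(8 * 10 * 12), c(8, 10, 12)))
  ax <- extract_slices(v, "axial")
  sg <- extract_slices(v, "sagittal")
  co <- extract_slices(v, "coronal")
  expect_length(ax$slices, 12)
  expect_identical(dim(ax$slices[[1]]), c(8L, 10L))
  expect_length(sg$slices, 8)
  expect_identical(dim(sg$slices[[1]]), c(10L, 12L))
  expect_length(co$slices, 10)
  expect_identical(dim(co$slices[[1]]), c(8L, 12L))
  # slice content is a pure re-indexing
  expect_identical(ax$slices[[3]], v$data[, , 3])
  expect_identical(sg$slices[[5]], v$data[5, , ])
  expect_error(extract_slices(v, "oblique"))
})

test_that("extract/reassemble is an exact bijection on random volumes", {
  set.seed(42)
  for (rep in 1:10) {
    d <- sample(2:9, 3, replace = TRUE)
    x <- array(rnorm(prod(d)), d)
    for (pl in c("axial", "sagittal", "coronal")) {
      rt <- reassemble(extract_slices(volume(x), pl))
      expect_identical(rt$data, x)
    }
  }
  # label channels survive slicing bit-exactly (no interpolation anywhere)
  ph <- small_phantom(seed = 3, shape = c(16, 16, 16), masks_only = TRUE)
  ms <- ph$labels$channels$ms
  rt <- reassemble(extract_slices(ms, "coronal"))
  expect_identical(array(as.integer(rt$data), dim(ms)), ms)
})

test_that("reassembly rejects inconsistent stacks", {
  v <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  st <- extract_slices(v, "axial")
  st$slices <- st$slices[-1]
  expect_error(reassemble(st), "slice count")
  st2 <- extract_slices(v, "axial")
  st2$slices[[2]] <- st2$slices[[2]][-1, ]
  expect_error(reassemble(st2), "shape")
})

test_that("cohort slice counting sums header extents per plane", {
  dir <- withr::local_tempdir()
  m <- generate_cohort(3, phantom_spec(shape = c(16, 20, 24), seed = 1), dir,
                       split = c(train = 1), masks_only = TRUE)
  manifest_path <- file.path(dir, "manifest.csv")
  expect_identical(count_cohort_slices(manifest_path, "axial"), 3L * 24L)
  expect_identical(count_cohort_slices(manifest_path, "sagittal"), 3L * 16L)
  expect_identical(count_cohort_slices(manifest_path, "coronal"), 3L * 20L)
  expect_identical(count_cohort_slices(manifest_path, "axial", split = "test"), 0L)
  # missing file is reported with the case id
  m2 <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  m2$ms_mask <- file.path(dir, m2$ms_mask)
  m2$ms_mask[2] <- file.path(dir, "gone.nii.gz")
  m2$volume <- ""
  expect_error(count_cohort_slices(m2, "axial"), "case002")
})
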