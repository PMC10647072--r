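.infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("nifti", "nrrd")))
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  if (grepl("\\.nrrd(\\.gz)?$", path)) return("nrrd")
  stop("cannot infer volume format from path: ", path, call. = FALSE)
}

#' Read a volume from NIfTI or NRRD
#'
#' Whatever the on-disk orientation metadata says, the returned volume is
#' permuted/flipped into the canonical (LR, AP, IS) axis order, so "axial
#' slice k" always means `data[, , k]` downstream. Files without orientation
#' metadata are assumed canonical with a warning.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param format `"nifti"` or `"nrrd"`; inferred from the extension when `NULL`.
#' @return a `tpl_volume`.
#' @export
read_volume <- function(path, format = NULL) {
  fmt <- .infer_format(path, format)
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  switch(fmt,
         nifti = .nifti_read(path),
         nrrd = .nrrd_read(path))
}

#' Write a volume to NIfTI or NRRD
#'
#' @inheritParams read_volume
#' @param v a `tpl_volume` (or a bare binary 3D array, stored as labels).
#' @param dtype `"float32"` for intensities, `"uint8"` for binary masks.
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path, format = NULL, dtype = c("float32", "uint8")) {
  dtype <- match.arg(dtype)
  if (is.array(v) && !inherits(v, "tpl_volume")) v <- volume(v)
  stopifnot(inherits(v, "tpl_volume"))
  switch(.infer_format(path, format),
         nifti = .nifti_write(v, path, dtype = dtype),
         nrrd = .nrrd_write(v, path, dtype = dtype))
  invisible(path)
}

# Canonical dims/spacing from the header only (fast path for cohort-level
# slice counting).
read_volume_shape <- function(path, format = NULL) {
  fmt <- .infer_format(path, format)
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  switch(fmt,
         nifti = .nifti_read_shape(path),
         nrrd = .nrrd_read_shape(path))
}

#' Read / write a label volume as per-channel mask files
#'
#' The on-disk layout is one binary file per structure:
#' `<case>_ms.nii.gz` and `<case>_msa.nii.gz` (or `.nrrd`). The background
#' channel is reconstructed as the complement of the sinus mask.
#'
#' @param prefix path prefix `<dir>/<case>`.
#' @param ext file extension, e.g. `".nii.gz"` or `".nrrd"`.
#' @param check forwarded to [label_volume()].
#' @return `read_label_volume()` returns a `tpl_labels`.
#' @export
read_label_volume <- function(prefix, ext = ".nii.gz", check = TRUE) {
  ms <- read_volume(paste0(prefix, "_ms", ext))
  msa <- read_volume(paste0(prefix, "_msa", ext))
  if (!identical(dim(ms$data), dim(msa$data)))
    stop("ms/msa mask shapes differ for prefix ", prefix, call. = FALSE)
  label_volume(list(ms = .as_binary(ms$data), msa = .as_binary(msa$data)),
               spacing = ms$spacing, check = check)
}

#' @rdname read_label_volume
#' @param labels a `tpl_labels`.
#' @export
write_label_volume <- function(labels, prefix, ext = ".nii.gz") {
  stopifnot(inherits(labels, "tpl_labels"))
  for (nm in c("ms", "msa")) {
    # channels are already validated binary arrays; bypass the numeric
    # conversion and finiteness re-check of volume()
    v <- structure(list(data = labels$channels[[nm]],
                        spacing = as.numeric(labels$spacing)),
                   class = "tpl_volume")
    write_volume(v, paste0(prefix, "_", nm, ext), dtype = "uint8")
  }
  invisible(prefix)
}

.as_binary <- function(x) {
  y <- array(as.integer(x != 0), dim(x))
  y
}
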