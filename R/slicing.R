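#' Orthogonal-plane slice stacks
#'
#' A 2.5D strategy trains the same 2D network three times, once per
#' anatomical plane, on slice stacks pulled from the canonical volume:
#'
#' * `axial`   iterates axis 3 (IS); each slice is the (LR, AP) plane,
#'   ordered inferior to superior.
#' * `sagittal` iterates axis 1 (LR); each slice is the (AP, IS) plane.
#' * `coronal` iterates axis 2 (AP); each slice is the (LR, IS) plane.
#'
#' Extraction is a pure re-indexing (no interpolation), and
#' [reassemble()] inverts it exactly, so per-plane predictions land back in
#' the one canonical orientation where they can be voted voxel-by-voxel.
#'
#' @param v a `tpl_volume`, or a bare 3D array (e.g. one label channel).
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @return a `tpl_slices`: list of 2D matrices plus geometry
#'   (`plane`, `source_shape`, `index_axis`).
#' @examples
#' v <- volume(array(seq_len(4 * 5 * 6), c(4, 5, 6)))
#' s <- extract_slices(v, "axial")
#' length(s$slices)   # 6
#' @export
extract_slices <- function(v, plane = c("axial", "sagittal", "coronal")) {
  plane <- match.arg(plane)
  x <- if (inherits(v, "tpl_volume")) v$data else v
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("extract_slices needs a 3D volume", call. = FALSE)
  d <- dim(x)
  axis <- switch(plane, axial = 3L, sagittal = 1L, coronal = 2L)
  slices <- lapply(seq_len(d[axis]), function(k) {
    switch(plane,
           axial = x[, , k],
           sagittal = x[k, , ],
           coronal = x[, k, ])
  })
  structure(list(plane = plane, slices = slices, source_shape = d,
                 index_axis = axis),
            class = "tpl_slices")
}

#' @rdname extract_slices
#' @param stack a `tpl_slices`.
#' @return `reassemble()` returns a `tpl_volume` in canonical orientation.
#' @export
reassemble <- function(stack) {
  stopifnot(inherits(stack, "tpl_slices"))
  d <- stack$source_shape
  axis <- stack$index_axis
  if (length(stack$slices) != d[axis])
    stop("slice count does not match source shape along index axis", call. = FALSE)
  in_plane <- d[-axis]
  for (s in stack$slices)
    if (!identical(dim(s), as.integer(in_plane)) && !identical(dim(s), in_plane))
      stop("slice shape inconsistent with source shape", call. = FALSE)
  out <- array(0, d)
  for (k in seq_len(d[axis])) {
    switch(stack$plane,
           axial = {out[, , k] <- stack$slices[[k]]},
           sagittal = {out[k, , ] <- stack$slices[[k]]},
           coronal = {out[, k, ] <- stack$slices[[k]]})
  }
  volume(out)
}

#' @export
print.tpl_slices <- function(x, ...) {
  cat(sprintf("<tpl_slices> %d %s slices of %s (source %s)\n",
              length(x$slices), x$plane,
              paste(dim(x$slices[[1]]), collapse = "x"),
              paste(x$source_shape, collapse = "x")))
  invisible(x)
}

#' Total slice count of a cohort along one plane
#'
#' Sums, over every case in a manifest, the volume extent along the plane's
#' index axis. For a 67-case cohort at 256 x 256 x 192 this reproduces the
#' published per-plane training-image counts: 67 x 192 = 12,864 axial and
#' 67 x 256 = 17,152 sagittal or coronal slices. Only file headers are read.
#'
#' @param manifest a cohort manifest `data.frame` (see [generate_cohort()])
#'   or the path to its CSV. Must have columns `case_id` and `volume` (or
#'   `ms_mask`) with file paths relative to the manifest's directory.
#' @param plane plane identifier.
#' @param split optional subset, e.g. `"train"`; `NULL` counts every case.
#' @return integer slice count.
#' @export
count_cohort_slices <- function(manifest, plane = c("axial", "sagittal", "coronal"),
                                split = NULL) {
  plane <- match.arg(plane)
  axis <- switch(plane, axial = 3L, sagittal = 1L, coronal = 2L)
  manifest <- .load_manifest(manifest)
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, , drop = FALSE]
  if (nrow(manifest) == 0L) return(0L)
  path_col <- if ("volume" %in% names(manifest) &&
                  any(nzchar(manifest$volume))) "volume" else "ms_mask"
  total <- 0L
  for (i in seq_len(nrow(manifest))) {
    p <- manifest[[path_col]][i]
    if (!file.exists(p))
      stop("missing case file for '", manifest$case_id[i], "': ", p, call. = FALSE)
    total <- total + read_volume_shape(p)$dim[axis]
  }
  as.integer(total)
}

.load_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    dir <- dirname(manifest)
    m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    for (col in intersect(c("volume", "ms_mask", "msa_mask"), names(m))) {
      v <- as.character(m[[col]])
      v[is.na(v)] <- ""
      m[[col]] <- ifelse(nzchar(v), file.path(dir, v), v)
    }
    m
  } else {
    as.data.frame(manifest)
  }
}
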