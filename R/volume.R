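#' Volume and label containers
#'
#' A `tpl_volume` is a 3D scalar intensity grid with per-axis voxel spacing in
#' millimetres. The axis convention is fixed throughout the package:
#' axis 1 = left-right (LR), axis 2 = anterior-posterior (AP),
#' axis 3 = inferior-superior (IS). With that convention "axial slice k" is
#' `data[, , k]`, ordered inferior to superior.
#'
#' A `tpl_labels` object holds the per-structure binary masks as named
#' channels: `background`, `ms` (whole maxillary sinus) and `msa` (air region
#' inside the sinus). The channels are stored separately - not as one integer
#' map - because the structures overlap: the air region is a subset of the
#' sinus, and the lesion is derived as their set difference.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @return `volume()` returns a `tpl_volume`; `label_volume()` a `tpl_labels`.
#' @examples
#' v <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(0.3, 0.3, 0.3))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all volume extents must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume data contains non-finite values", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "tpl_volume")
}

#' @rdname volume
#' @param channels named list of binary 3D arrays; must contain `ms` and
#'   `msa`, all with identical dimensions. `background` is derived as the
#'   complement of `ms` when absent.
#' @param check when `TRUE` (default) enforce the ground-truth invariants
#'   (binary channels, `msa` a subset of `ms`). Predicted masks that may
#'   violate the subset relation should be combined with [derive_msl()], not
#'   stored as a `tpl_labels`.
#' @export
label_volume <- function(channels, spacing = c(1, 1, 1), check = TRUE) {
  if (!all(c("ms", "msa") %in% names(channels)))
    stop("label channels must include 'ms' and 'msa'", call. = FALSE)
  dims <- dim(channels$ms)
  if (is.null(channels$background)) {
    channels$background <- 1L - channels$ms
    storage.mode(channels$background) <- storage.mode(channels$ms)
  }
  channels <- channels[c("background", "ms", "msa")]
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.array(ch) || !identical(dim(ch), dims))
      stop("channel '", nm, "' has mismatched dimensions", call. = FALSE)
    if (check && any(ch != 0 & ch != 1))
      stop("channel '", nm, "' is not binary", call. = FALSE)
  }
  if (check) {
    if (any(channels$msa > channels$ms))
      stop("label invariant violated: msa must be a subset of ms", call. = FALSE)
    if (any(channels$background + channels$ms != 1))
      stop("label invariant violated: background must complement ms", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  structure(list(channels = channels, spacing = spacing), class = "tpl_labels")
}

#' @export
print.tpl_volume <- function(x, ...) {
  cat(sprintf("<tpl_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.tpl_labels <- function(x, ...) {
  counts <- vapply(x$channels, sum, numeric(1))
  cat(sprintf("<tpl_labels> %s voxels; |ms|=%d |msa|=%d |msl|=%d\n",
              paste(dim(x$channels$ms), collapse = "x"),
              as.integer(counts[["ms"]]), as.integer(counts[["msa"]]),
              as.integer(counts[["ms"]] - sum(x$channels$ms * x$channels$msa))))
  invisible(x)
}

#' Derived lesion channel of a label volume
#'
#' The lesion (MSL) is not stored: it is the set difference `ms & !msa`,
#' recomputed on demand so it can never drift out of sync with its parents.
#'
#' @param labels a `tpl_labels`.
#' @return binary 3D array.
#' @export
msl_channel <- function(labels) {
  stopifnot(inherits(labels, "tpl_labels"))
  m <- labels$channels$ms * (1L - labels$channels$msa)
  storage.mode(m) <- "integer"
  array(m, dim(labels$channels$ms))
}

# Source coordinates for one axis of a resize: half-voxel centre alignment,
# so identical source/target extents map index i -> i exactly.
.resize_coords <- function(n_src, n_dst) {
  (seq_len(n_dst) - 0.5) * (n_src / n_dst) - 0.5
}

#' Resize a volume to a target grid
#'
#' Intensity volumes are resampled with trilinear interpolation; label masks
#' with nearest-neighbour so the output stays binary. Anisotropic targets are
#' allowed (a 670x670x400 scan resized to 256x256x192 changes the aspect
#' ratio per axis); voxel spacing is rescaled by the extent ratio so physical
#' size is preserved.
#'
#' @param v a `tpl_volume`.
#' @param target_shape integer length-3, all >= 1.
#' @param mode `"intensity"` (trilinear) or `"label"` (nearest-neighbour).
#' @return a `tpl_volume` with `dim(v$data) == target_shape`.
#' @export
resize_volume <- function(v, target_shape, mode = c("intensity", "label")) {
  stopifnot(inherits(v, "tpl_volume"))
  mode <- match.arg(mode)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(is.na(target_shape)) || any(target_shape < 1L))
    stop("target_shape must be 3 positive integers", call. = FALSE)
  src <- dim(v$data)
  out_spacing <- v$spacing * src / target_shape
  if (identical(src, target_shape) && mode == "intensity")
    return(volume(v$data, out_spacing))
  cs <- lapply(1:3, function(a) .resize_coords(src[a], target_shape[a]))
  if (mode == "label") {
    # floor(x + 0.5): half-way samples resolve consistently to the upper
    # voxel (round() would alternate by parity and roughen boundaries)
    idx <- lapply(1:3, function(a) pmin(pmax(floor(cs[[a]] + 0.5) + 1, 1), src[a]))
    out <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- target_shape
  } else {
    out <- .trilinear_sample(v$data, cs[[1]], cs[[2]], cs[[3]])
  }
  volume(out, out_spacing)
}

# Separable trilinear resampling on an axis-aligned target grid. cx/cy/cz are
# 0-based fractional source coordinates per output axis; edge-clamped.
.trilinear_sample <- function(x, cx, cy, cz) {
  interp_axis <- function(arr, coords, axis) {
    n <- dim(arr)[axis]
    c0 <- pmin(pmax(floor(coords), 0), n - 1)
    c1 <- pmin(c0 + 1, n - 1)
    w <- pmin(pmax(coords - c0, 0), 1)
    i0 <- as.integer(c0 + 1); i1 <- as.integer(c1 + 1)
    if (axis == 1L) {
      a0 <- arr[i0, , , drop = FALSE]; a1 <- arr[i1, , , drop = FALSE]
      sweep_w <- array(w, dim(a0))
    } else if (axis == 2L) {
      a0 <- arr[, i0, , drop = FALSE]; a1 <- arr[, i1, , drop = FALSE]
      sweep_w <- array(rep(w, each = dim(a0)[1]), dim(a0))
    } else {
      a0 <- arr[, , i0, drop = FALSE]; a1 <- arr[, , i1, drop = FALSE]
      sweep_w <- array(rep(w, each = dim(a0)[1] * dim(a0)[2]), dim(a0))
    }
    a0 + sweep_w * (a1 - a0)
  }
  out <- interp_axis(x, cx, 1L)
  out <- interp_axis(out, cy, 2L)
  interp_axis(out, cz, 3L)
}

#' Min-max intensity normalization
#'
#' Per-volume linear rescale to \[0, 1\]. A constant volume maps to all
#' zeros. Raw CBCT gray levels vary per scan, so downstream training always
#' operates on normalized volumes.
#'
#' @param v a `tpl_volume`.
#' @return a `tpl_volume` with data in \[0, 1\].
#' @export
normalize_intensity <- function(v) {
  stopifnot(inherits(v, "tpl_volume"))
  rng <- range(v$data)
  if (rng[2] <= rng[1]) {
    return(volume(array(0, dim(v$data)), v$spacing))
  }
  volume((v$data - rng[1]) / (rng[2] - rng[1]), v$spacing)
}
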