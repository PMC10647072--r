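#' Rotation + brightness augmentation for an image/mask pair
#'
#' Applies one in-plane rotation (about the IS axis for volumes, i.e. the
#' same angle to every axial plane) and one brightness change:
#'
#' * rotation angle drawn from `U(-20, 20)` degrees; the image is resampled
#'   bilinearly with zero fill outside the field of view, the mask with
#'   nearest-neighbour so labels stay strictly binary;
#' * brightness is a multiplicative factor drawn from `U(0.8, 1.2)` applied
#'   to the (normalized) image and clipped back to \[0, 1\]; the mask is
#'   never brightness-adjusted.
#'
#' @param image 2D matrix or 3D array with values in \[0, 1\].
#' @param mask matching array (may have a trailing channel axis with one
#'   more dimension than `image`; each channel is rotated with the image).
#' @param seed RNG seed for the two draws (ignored when both `angle` and
#'   `factor` are forced).
#' @param angle,factor force the rotation angle (degrees) / brightness
#'   factor instead of sampling; `angle = 0, factor = 1` is the identity.
#' @param rotation_range,brightness_range sampling half-ranges.
#' @return list with augmented `image` and `mask`.
#' @export
augment_pair <- function(image, mask, seed = NULL, angle = NULL, factor = NULL,
                         rotation_range = 20, brightness_range = 0.2) {
  draw <- function() {
    if (is.null(angle))
      angle <<- stats::runif(1, -rotation_range, rotation_range)
    if (is.null(factor))
      factor <<- stats::runif(1, 1 - brightness_range, 1 + brightness_range)
  }
  if (is.null(angle) || is.null(factor)) {
    if (!is.null(seed)) .with_seed(seed, draw()) else draw()
  }
  if (angle != 0) {
    image <- .rotate_inplane(image, angle, "bilinear")
    mask <- .rotate_inplane(mask, angle, "nearest")
  }
  image <- pmin(pmax(image * factor, 0), 1)
  list(image = image, mask = mask, angle = angle, factor = factor)
}

# Rotate the first two axes of an array by `angle` degrees about the centre,
# applied identically to every remaining-axis slab. Zero fill outside.
.rotate_inplane <- function(x, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(x)
  if (is.null(d)) stop("augmentation input must be an array", call. = FALSE)
  h <- d[1]; w <- d[2]
  rest <- if (length(d) > 2L) prod(d[-c(1, 2)]) else 1L
  xm <- matrix(x, h * w, rest)
  th <- angle * pi / 180
  cth <- cos(th); sth <- sin(th)
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  gi <- rep(seq_len(h), w) - cx
  gj <- rep(seq_len(w), each = h) - cy
  # inverse mapping: source coords of each target pixel
  si <- cth * gi + sth * gj + cx
  sj <- -sth * gi + cth * gj + cy
  out <- matrix(0, h * w, rest)
  if (interp == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= h & rj >= 1 & rj <= w
    idx <- (rj[ok] - 1) * h + ri[ok]
    out[ok, ] <- xm[idx, , drop = FALSE]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      ii <- i0 + corner[1]; jj <- j0 + corner[2]
      wt <- (if (corner[1] == 0) 1 - fi else fi) *
            (if (corner[2] == 0) 1 - fj else fj)
      ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w & wt > 0
      if (!any(ok)) next
      idx <- (jj[ok] - 1) * h + ii[ok]
      out[ok, ] <- out[ok, , drop = FALSE] + wt[ok] * xm[idx, , drop = FALSE]
    }
  }
  array(out, d)
}
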