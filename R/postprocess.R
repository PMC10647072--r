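#' Derive the lesion mask by label subtraction
#'
#' The lesion (MSL) is obtained from the fused predictions by pixel-wise
#' subtraction of the air region (MSA) from the whole sinus (MS):
#' a voxel is lesion iff it is sinus but not air. Subtraction is implemented
#' as clamped set difference (`ms & !msa`), never arithmetic, so voxels the
#' model predicts as air outside the sinus cannot produce negative labels;
#' their count is reported as a prediction inconsistency instead.
#'
#' No morphological cleanup (component filtering, hole filling) is applied:
#' raw false positives/negatives propagate to the evaluation on purpose.
#'
#' @param ms binary sinus mask.
#' @param msa binary air mask, same shape.
#' @param quiet suppress the message emitted when clamping occurred.
#' @return binary integer array; attribute `clamped` carries the number of
#'   voxels where `msa` was set outside `ms`.
#' @export
derive_msl <- function(ms, msa, quiet = FALSE) {
  .check_binary_pair(ms, msa)
  msl <- array(as.integer(ms == 1L & msa == 0L), dim(ms))
  clamped <- sum(msa == 1L & ms == 0L)
  if (clamped > 0 && !quiet)
    message("derive_msl: clamped ", clamped, " air voxels predicted outside the sinus")
  attr(msl, "clamped") <- as.integer(clamped)
  msl
}

#' Voxel bookkeeping for an MS/MSA prediction pair
#'
#' @inheritParams derive_msl
#' @return named list: `n_ms`, `n_msa`, `n_msl`, and `inconsistency`
#'   (`|MSA \ MS|`, zero for any well-formed ground truth).
#' @export
consistency_report <- function(ms, msa) {
  .check_binary_pair(ms, msa)
  list(
    n_ms = as.integer(sum(ms)),
    n_msa = as.integer(sum(msa)),
    n_msl = as.integer(sum(ms == 1L & msa == 0L)),
    inconsistency = as.integer(sum(msa == 1L & ms == 0L))
  )
}

.check_binary_pair <- function(ms, msa) {
  if (!identical(dim(ms), dim(msa)))
    stop("ms and msa masks must share one shape", call. = FALSE)
  if (!all(ms == 0L | ms == 1L) || !all(msa == 0L | msa == 1L))
    stop("masks must be binary 0/1", call. = FALSE)
  invisible(TRUE)
}
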