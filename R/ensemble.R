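#' Binarize a probability volume
#'
#' Thresholds each channel independently; the boundary is inclusive
#' (`value >= threshold` maps to 1).
#'
#' @param p a `tpl_prob_volume` (see [predict_plane()]) or a bare numeric
#'   array with values in \[0, 1\].
#' @param threshold scalar strictly inside (0, 1).
#' @return object of the same shape with integer 0/1 entries; probability
#'   volumes keep their channel names.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  bin <- function(x) {
    y <- array(as.integer(x >= threshold), dim(x))
    y
  }
  if (inherits(p, "tpl_prob_volume")) {
    p$data <- bin(p$data)
    p$binary <- TRUE
    return(p)
  }
  bin(p)
}

#' Voxel-wise voting over the three plane predictions
#'
#' Fuses exactly three binarized masks - one per anatomical plane, all in
#' canonical orientation - per voxel:
#'
#' * `unanimous`: positive iff all three predictions are positive (AND),
#' * `affirmative`: positive iff at least one is positive (OR),
#' * `majority`: positive iff at least two of the three are positive.
#'
#' The rules are nested: every unanimous-positive voxel is majority-positive
#' and every majority-positive voxel is affirmative-positive, which is why
#' unanimous fusion trades recall for precision and affirmative the reverse.
#'
#' @param preds list of exactly 3 binary arrays of identical shape
#'   (conventionally axial, sagittal, coronal; all rules are symmetric in
#'   their inputs).
#' @param rule `"unanimous"`, `"affirmative"` or `"majority"`.
#' @return binary integer array of the common shape.
#' @examples
#' a <- array(c(1L, 1L), c(2, 1, 1)); b <- array(c(1L, 0L), c(2, 1, 1))
#' vote(list(a, a, b), "majority")
#' @export
vote <- function(preds, rule = c("unanimous", "affirmative", "majority")) {
  rule <- match.arg(rule)
  if (!is.list(preds) || length(preds) != 3L)
    stop("vote requires exactly 3 plane predictions", call. = FALSE)
  if (length(preds) %% 2L == 0L)
    stop("even voter counts are rejected (majority ties)", call. = FALSE)
  d <- dim(preds[[1]])
  for (p in preds) {
    if (!identical(dim(p), d))
      stop("vote inputs must share one shape", call. = FALSE)
    if (!all(p == 0L | p == 1L))
      stop("vote inputs must be binary 0/1 masks", call. = FALSE)
  }
  tally <- preds[[1]] + preds[[2]] + preds[[3]]
  need <- switch(rule, unanimous = 3L, affirmative = 1L,
                 majority = as.integer(floor(length(preds) / 2) + 1L))
  out <- array(as.integer(tally >= need), d)
  out
}
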