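#' Voxel confusion counts
#'
#' @param pred,truth binary masks of identical shape.
#' @return list with integer fields `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth masks must share one shape", call. = FALSE)
  if (!all(pred == 0L | pred == 1L) || !all(truth == 0L | truth == 1L))
    stop("masks must be binary 0/1", call. = FALSE)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  list(TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
       TN = as.integer(length(pred) - tp - fp - fn))
}

#' Overlap metrics from confusion counts
#'
#' Computes the four volume-based metrics
#' `JC = TP / (TP + FN + FP)`, `DSC = 2 TP / (2 TP + FN + FP)`,
#' `PR = TP / (TP + FP)` and `RC = TP / (TP + FN)`.
#'
#' Degenerate cases (not defined by the formulas) follow a fixed policy:
#' an empty truth met by an empty prediction scores 1 on all four metrics;
#' `PR` is 0 when nothing was predicted but foreground exists, and `RC` is 0
#' when truth is empty but something was predicted.
#'
#' @param c confusion counts from [confusion()].
#' @return named numeric vector `c(JC=, DSC=, PR=, RC=)`, all in \[0, 1\].
#' @examples
#' seg_metrics(list(TP = 8L, FP = 2L, FN = 2L, TN = 0L))
#' @export
seg_metrics <- function(c) {
  tp <- c$TP; fp <- c$FP; fn <- c$FN
  if (tp + fp + fn == 0L)
    return(c(JC = 1, DSC = 1, PR = 1, RC = 1))
  jc <- tp / (tp + fn + fp)
  dsc <- 2 * tp / (2 * tp + fn + fp)
  pr <- if (tp + fp > 0L) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0L) tp / (tp + fn) else 0
  c(JC = jc, DSC = dsc, PR = pr, RC = rc)
}

#' Per-slice Dice profile along the axial axis
#'
#' One DSC per axial slice, ordered inferior to superior, using the same
#' formula and degenerate-case policy as [seg_metrics()] (so slices empty in
#' both masks score 1).
#'
#' @inheritParams confusion
#' @return numeric vector of length `dim(pred)[3]`.
#' @export
per_slice_dsc <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth masks must share one shape", call. = FALSE)
  vapply(seq_len(dim(pred)[3]), function(k)
    seg_metrics(confusion(pred[, , k, drop = FALSE],
                          truth[, , k, drop = FALSE]))[["DSC"]],
    numeric(1))
}

#' Aggregate a metrics table to mean +/- SD
#'
#' @param rows a metrics `data.frame` with columns `method`, `structure`,
#'   `case` and metric columns `JC`, `DSC`, `PR`, `RC` (one row per
#'   case-structure-method, as produced by [run_experiment()]).
#' @return `data.frame` with one row per (method, structure) and columns
#'   `<metric>_mean` / `<metric>_sd` (SD is the sample SD; 0 for a single
#'   case).
#' @export
aggregate_metrics <- function(rows) {
  stopifnot(all(c("method", "structure") %in% names(rows)))
  metrics <- intersect(c("JC", "DSC", "PR", "RC"), names(rows))
  keys <- unique(rows[c("method", "structure")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- rows[rows$method == keys$method[i] & rows$structure == keys$structure[i], ]
    stats_row <- keys[i, , drop = FALSE]
    stats_row$n <- nrow(sub)
    for (m in metrics) {
      stats_row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      stats_row[[paste0(m, "_sd")]] <- if (nrow(sub) > 1L) stats::sd(sub[[m]]) else 0
    }
    stats_row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tukey boxplot statistics
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7) by default;
#' `hinges = TRUE` switches to Tukey hinges (`stats::fivenum`). Whiskers
#' extend to the most extreme data points within 1.5 IQR of the quartiles;
#' values beyond are reported as outliers.
#'
#' @param values numeric vector, length >= 1.
#' @param hinges use Tukey hinges instead of interpolated quartiles.
#' @return list: `q1`, `median`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
boxplot_stats <- function(values, hinges = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(is.na(values)))
    stop("boxplot_stats needs at least one non-missing value", call. = FALSE)
  if (hinges) {
    fn <- stats::fivenum(values)
    q1 <- fn[2]; med <- fn[3]; q3 <- fn[4]
  } else {
    qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    q1 <- qs[1]; med <- qs[2]; q3 <- qs[3]
  }
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(q1 = q1, median = med, q3 = q3,
       whisker_lo = min(values[inside]),
       whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Compare methods with one-way ANOVA or a paired t-test
#'
#' @param table metrics `data.frame` (same schema as [aggregate_metrics()]
#'   input) restricted by `structure` and scored on `metric`.
#' @param design `"anova_oneway"` (>= 2 method groups) or
#'   `"paired_t_twotailed"` (exactly 2 methods with matching cases).
#' @param metric which metric column to compare (default `"DSC"`).
#' @param structure optional structure filter (`"MS"`, `"MSA"`, `"MSL"`).
#' @param alpha significance level for the flag.
#' @return list: `statistic`, `p_value`, `significant`, `design`, `df`.
#' @export
compare_methods <- function(table, design = c("anova_oneway", "paired_t_twotailed"),
                            metric = "DSC", structure = NULL, alpha = 0.05) {
  design <- match.arg(design)
  if (!is.null(structure)) table <- table[table$structure == structure, , drop = FALSE]
  if (!metric %in% names(table)) stop("metric column not found: ", metric, call. = FALSE)
  methods <- unique(table$method)
  if (design == "anova_oneway") {
    if (length(methods) < 2L)
      stop("one-way ANOVA needs at least 2 method groups", call. = FALSE)
    fit <- stats::aov(y ~ g, data = data.frame(y = table[[metric]],
                                               g = factor(table$method)))
    s <- summary(fit)[[1]]
    stat <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
    df <- unname(s[["Df"]][1:2])
  } else {
    if (length(methods) != 2L)
      stop("paired t-test needs exactly 2 methods", call. = FALSE)
    a <- table[table$method == methods[1], c("case", metric)]
    b <- table[table$method == methods[2], c("case", metric)]
    if (nrow(a) != nrow(b) || !setequal(a$case, b$case))
      stop("paired t-test needs matching cases in both methods", call. = FALSE)
    a <- a[order(a$case), ]; b <- b[order(b$case), ]
    diffs <- a[[metric]] - b[[metric]]
    if (all(diffs == 0)) {
      stat <- 0; p <- 1; df <- nrow(a) - 1L
    } else if (stats::sd(diffs) == 0) {
      # constant nonzero difference: degenerate but unambiguous
      stat <- sign(mean(diffs)) * Inf; p <- 0; df <- nrow(a) - 1L
    } else {
      tt <- stats::t.test(a[[metric]], b[[metric]], paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
    }
  }
  list(statistic = stat, p_value = p, significant = p < alpha,
       design = design, df = df)
}
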