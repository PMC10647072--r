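# volumetric metrics, aggregation, boxplot statistics, significance tests

test_that("confusion matches a per-voxel loop oracle on random masks", {
  set.seed(31)
  for (rep in 1:5) {
    pred <- random_mask(c(10, 10, 10), p = runif(1))
    truth <- random_mask(c(10, 10, 10), p = runif(1))
    c1 <- confusion(pred, truth)
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(pred)) {          # brute-force loop oracle
      if (pred[i] == 1L && truth[i] == 1L) tp <- tp + 1L
      else if (pred[i] == 1L) fp <- fp + 1L
      else if (truth[i] == 1L) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(c1, list(TP = tp, FP = fp, FN = fn, TN = tn))
  }
  expect_error(confusion(random_mask(c(2, 2, 2)), random_mask(c(2, 2, 3))),
               "shape")
})

test_that("metric formulas evaluate exactly, including degenerate policies", {
  m <- seg_metrics(list(TP = 8L, FP = 2L, FN = 2L, TN = 0L))
  expect_equal(m[["JC"]], 8 / 12)
  expect_equal(m[["DSC"]], 0.8)
  expect_equal(m[["PR"]], 0.8)
  expect_equal(m[["RC"]], 0.8)
  # perfect prediction
  expect_equal(unname(seg_metrics(list(TP = 5L, FP = 0L, FN = 0L, TN = 5L))),
               rep(1, 4))
  # both empty -> all 1; one-sided emptiness -> 0
  expect_equal(unname(seg_metrics(list(TP = 0L, FP = 0L, FN = 0L, TN = 9L))),
               rep(1, 4))
  e1 <- seg_metrics(list(TP = 0L, FP = 0L, FN = 3L, TN = 6L))
  expect_equal(unname(e1), c(0, 0, 0, 0))
  e2 <- seg_metrics(list(TP = 0L, FP = 3L, FN = 0L, TN = 6L))
  expect_equal(unname(e2), c(0, 0, 0, 0))
})

test_that("per-volume identities link the four metrics", {
  set.seed(32)
  for (rep in 1:20) {
    pred <- random_mask(c(8, 8, 8), p = runif(1, 0.1, 0.9))
    truth <- random_mask(c(8, 8, 8), p = runif(1, 0.1, 0.9))
    m <- seg_metrics(confusion(pred, truth))
    expect_equal(m[["DSC"]], 2 * m[["JC"]] / (1 + m[["JC"]]))
    expect_lte(m[["JC"]], m[["DSC"]])
    if (m[["PR"]] + m[["RC"]] > 0)
      expect_equal(m[["DSC"]],
                   2 * m[["PR"]] * m[["RC"]] / (m[["PR"]] + m[["RC"]]))
    # invariance under joint voxel permutation
    ord <- sample(length(pred))
    m2 <- seg_metrics(confusion(array(pred[ord], dim(pred)),
                                array(truth[ord], dim(truth))))
    expect_identical(m, m2)
  }
})

test_that("per-slice Dice profiles agree with a slice-loop oracle", {
  ph <- small_phantom(seed = 4, masks_only = TRUE)
  truth <- ph$labels$channels$ms
  pred <- truth
  pred[, , 10:16] <- random_mask(c(32, 32, 7), p = 0.3, seed = 5)
  prof <- per_slice_dsc(pred, truth)
  expect_length(prof, dim(truth)[3])
  oracle <- vapply(seq_len(dim(truth)[3]), function(k)
    seg_metrics(confusion(pred[, , k, drop = FALSE],
                          truth[, , k, drop = FALSE]))[["DSC"]], numeric(1))
  expect_identical(prof, oracle)
  ident <- per_slice_dsc(truth, truth)
  expect_true(all(ident == 1))
})

test_that("aggregation reproduces a two-pass mean/sd oracle", {
  set.seed(33)
  rows <- expand.grid(case = sprintf("c%02d", 1:25),
                      method = c("a", "b"), structure = c("MS", "MSL"),
                      stringsAsFactors = FALSE)
  for (m in c("JC", "DSC", "PR", "RC")) rows[[m]] <- runif(nrow(rows))
  agg <- aggregate_metrics(rows)
  for (i in seq_len(nrow(agg))) {
    sub <- rows[rows$method == agg$method[i] & rows$structure == agg$structure[i], ]
    expect_equal(agg$DSC_mean[i], sum(sub$DSC) / nrow(sub))
    expect_equal(agg$DSC_sd[i],
                 sqrt(sum((sub$DSC - mean(sub$DSC))^2) / (nrow(sub) - 1)))
  }
  single <- aggregate_metrics(rows[1, ])
  expect_identical(single$DSC_sd, 0)
  two <- aggregate_metrics(rows[rows$case %in% c("c01", "c02") &
                                rows$method == "a" & rows$structure == "MS", ])
  expect_equal(two$JC_mean, mean(rows$JC[rows$case %in% c("c01", "c02") &
                                         rows$method == "a" &
                                         rows$structure == "MS"]))
})

test_that("boxplot statistics follow the 1.5 IQR whisker convention", {
  b <- boxplot_stats(1:9)
  expect_equal(b$median, 5)
  expect_equal(b$q1, 3); expect_equal(b$q3, 7)
  expect_equal(b$whisker_lo, 1); expect_equal(b$whisker_hi, 9)
  expect_length(b$outliers, 0)
  # hand-derived: type-7 quartiles of {1,2,3,4,100} are 2 and 4, IQR 2,
  # fences [-1, 7] -> 100 is the only outlier, upper whisker at 4
  b2 <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(b2$q1, 2); expect_equal(b2$q3, 4)
  expect_equal(b2$whisker_hi, 4)
  expect_identical(b2$outliers, 100)
  const <- boxplot_stats(rep(3, 5))
  expect_equal(const$q1, 3); expect_length(const$outliers, 0)
  expect_error(boxplot_stats(numeric(0)), "at least one")
})

test_that("one-way ANOVA matches a sum-of-squares oracle", {
  # small fixed 3-group dataset; oracle computes F from the SS decomposition
  g <- rep(c("m1", "m2", "m3"), each = 5)
  y <- c(0.91, 0.88, 0.90, 0.93, 0.89,
         0.95, 0.96, 0.94, 0.97, 0.95,
         0.85, 0.83, 0.86, 0.84, 0.87)
  tab <- data.frame(case = rep(sprintf("c%d", 1:5), 3), method = g,
                    structure = "MS", DSC = y)
  r <- compare_methods(tab, "anova_oneway", metric = "DSC")
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(r$statistic, f_oracle)
  expect_identical(r$df, c(2, 12))
  expect_true(r$significant)
  # identical groups -> F = 0
  tab0 <- tab; tab0$DSC <- rep(y[1:5], 3)
  expect_equal(compare_methods(tab0, "anova_oneway", metric = "DSC")$statistic, 0)
})

test_that("paired t-test handles identical and shifted samples", {
  tab <- data.frame(case = rep(sprintf("c%d", 1:6), 2),
                    method = rep(c("a", "b"), each = 6),
                    structure = "MSL",
                    DSC = c(0.8, 0.82, 0.78, 0.81, 0.79, 0.8,
                            0.8, 0.82, 0.78, 0.81, 0.79, 0.8))
  r <- compare_methods(tab, "paired_t_twotailed", metric = "DSC")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  tab2 <- tab
  tab2$DSC[tab2$method == "b"] <- tab2$DSC[tab2$method == "b"] +
    c(0.05, 0.06, 0.04, 0.05, 0.07, 0.05)
  r2 <- compare_methods(tab2, "paired_t_twotailed", metric = "DSC")
  # constant shift of paired data: t = -Inf-like huge magnitude, p ~ 0
  expect_true(r2$significant)
  tab3 <- tab[-1, ]
  expect_error(compare_methods(tab3, "paired_t_twotailed", metric = "DSC"),
               "matching cases")
})
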