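#' Experiment configuration
#'
#' Describes one end-to-end segmentation experiment over a phantom (or real)
#' cohort manifest:
#'
#' * `"2d"`: train one 2D network on a single plane, predict, binarize,
#'   subtract air from sinus, evaluate.
#' * `"2.5d"`: train the same 2D network three times (axial, sagittal,
#'   coronal), predict each plane volumetrically, fuse the MS and MSA
#'   channels per voxel with the chosen voting rule, then subtract. Fusion
#'   happens before subtraction, never on the derived lesion mask.
#' * `"3d"`: train one volumetric network (batch size 1) and do the same.
#'
#' @param strategy `"2d"`, `"2.5d"` or `"3d"`.
#' @param net a [net_config()] (2D family for 2d/2.5d, 3D family for 3d).
#' @param train a [train_config()].
#' @param manifest path to a cohort manifest CSV (see [generate_cohort()]).
#' @param plane required for 2d: which plane to train on.
#' @param rule required for 2.5d: the voting rule.
#' @param target_shape optional resize target applied to every volume/mask.
#' @param threshold binarization threshold for predictions.
#' @param output_dir where artifacts (metrics, histories, provenance) are
#'   written; `NULL` for in-memory only.
#' @return a `tpl_experiment_config`.
#' @export
experiment_config <- function(strategy = c("2.5d", "2d", "3d"),
                              net = net_config(),
                              train = train_config(),
                              manifest = NULL,
                              plane = NULL, rule = NULL,
                              target_shape = NULL, threshold = 0.5,
                              output_dir = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "2d" && is.null(plane))
    stop("strategy '2d' requires a plane", call. = FALSE)
  if (strategy == "2.5d" && is.null(rule))
    stop("strategy '2.5d' requires an ensemble rule", call. = FALSE)
  if (!is.null(plane)) plane <- match.arg(plane, c("axial", "sagittal", "coronal"))
  if (!is.null(rule)) rule <- match.arg(rule, c("unanimous", "affirmative", "majority"))
  if (strategy %in% c("2d", "2.5d") && !net$family %in% c("unet2d", "unetpp2d"))
    stop("2d/2.5d strategies need a 2D network family", call. = FALSE)
  if (strategy == "3d" && !net$family %in% c("unet3d", "vnet3d"))
    stop("3d strategy needs a 3D network family", call. = FALSE)
  structure(list(strategy = strategy, net = net, train = train,
                 manifest = manifest, plane = plane, rule = rule,
                 target_shape = target_shape, threshold = threshold,
                 output_dir = output_dir),
            class = "tpl_experiment_config")
}

# Load one case: normalized volume + labels, optionally resized.
.load_case <- function(dir_or_manifest_row, target_shape = NULL) {
  row <- dir_or_manifest_row
  v <- read_volume(row$volume)
  ext <- sub("^.*_ms", "", basename(row$ms_mask))
  prefix <- substr(row$ms_mask, 1L, nchar(row$ms_mask) - nchar(ext) - 3L)
  lab <- read_label_volume(prefix, ext = ext, check = FALSE)
  if (!is.null(target_shape)) {
    v <- resize_volume(v, target_shape, mode = "intensity")
    ms <- resize_volume(volume(lab$channels$ms + 0), target_shape, mode = "label")
    msa <- resize_volume(volume(lab$channels$msa + 0), target_shape, mode = "label")
    lab <- label_volume(list(ms = .as_binary(ms$data), msa = .as_binary(msa$data)),
                        check = FALSE)
  }
  list(volume = normalize_intensity(v), labels = lab)
}

.slices_to_samples <- function(vol, labels, plane) {
  xs <- extract_slices(vol, plane)
  ys <- lapply(c("background", "ms", "msa"), function(nm)
    extract_slices(labels$channels[[nm]], plane))
  lapply(seq_along(xs$slices), function(k) {
    d2 <- dim(xs$slices[[k]])
    y <- array(0, c(d2, 3L))
    for (c in 1:3) y[, , c] <- ys[[c]]$slices[[k]]
    list(x = array(xs$slices[[k]], c(d2, 1L)), y = y)
  })
}

.volume_sample <- function(vol, labels) {
  d <- dim(vol$data)
  y <- array(0, c(d, 3L))
  y[, , , 1] <- labels$channels$background
  y[, , , 2] <- labels$channels$ms
  y[, , , 3] <- labels$channels$msa
  list(x = array(vol$data, c(d, 1L)), y = y)
}

.case_metrics <- function(case_id, method, pred_ms, pred_msa, labels) {
  msl_pred <- derive_msl(pred_ms, pred_msa, quiet = TRUE)
  truth <- list(MS = labels$channels$ms, MSA = labels$channels$msa,
                MSL = msl_channel(labels))
  pred <- list(MS = pred_ms, MSA = pred_msa, MSL = msl_pred)
  rows <- lapply(names(truth), function(st) {
    m <- seg_metrics(confusion(pred[[st]], truth[[st]]))
    data.frame(case = case_id, method = method, structure = st,
               JC = m[["JC"]], DSC = m[["DSC"]], PR = m[["PR"]], RC = m[["RC"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run one experiment end-to-end
#'
#' Trains on the manifest's `train` cases (validating on `validation`),
#' predicts every `test` case, fuses (for 2.5d), subtracts MSA from MS, and
#' scores JC/DSC/PR/RC per test case for MS, MSA and MSL. When
#' `cfg$output_dir` is set, metrics, per-model training histories and a
#' provenance log (config, seed, package version) are written there.
#'
#' @param cfg an [experiment_config()].
#' @param trainer optional override used in tests: a
#'   `function(net_cfg, data, train_cfg)` returning a model for
#'   [predict_plane()]/[predict_3d()]. An `oracle` attribute-free
#'   [stub_model()] or a ground-truth lookup (class `tpl_oracle_model`,
#'   see [oracle_model()]) short-circuits training entirely.
#' @param keep_plane_preds for 2.5d: also score each single plane's
#'   prediction (returned as `plane_metrics`), used to study the
#'   ensemble-versus-single-plane effect.
#' @return list with `metrics` (per-case data.frame), `aggregate`,
#'   `histories`, and for 2.5d optionally `plane_metrics`.
#' @export
run_experiment <- function(cfg, trainer = NULL, keep_plane_preds = FALSE) {
  stopifnot(inherits(cfg, "tpl_experiment_config"))
  manifest <- .load_manifest(cfg$manifest)
  required <- c("case_id", "split", "volume", "ms_mask")
  if (!all(required %in% names(manifest)))
    stop("manifest lacks columns: ",
         paste(setdiff(required, names(manifest)), collapse = ", "), call. = FALSE)
  cases <- lapply(seq_len(nrow(manifest)), function(i)
    .load_case(manifest[i, ], cfg$target_shape))
  names(cases) <- manifest$case_id
  split <- split(manifest$case_id, manifest$split)
  if (length(split$train) == 0L) stop("manifest has no train cases", call. = FALSE)
  if (length(split$test) == 0L) stop("manifest has no test cases", call. = FALSE)

  method <- switch(cfg$strategy,
                   "2d" = paste0("2d-", cfg$plane),
                   "2.5d" = paste0("2.5d-", cfg$rule),
                   "3d" = paste0("3d-", cfg$net$family))
  planes <- switch(cfg$strategy,
                   "2d" = cfg$plane,
                   "2.5d" = c("axial", "sagittal", "coronal"),
                   "3d" = NULL)
  fit_one <- function(net_cfg, data) {
    if (!is.null(trainer)) trainer(net_cfg, data, cfg$train)
    else train_model(net_cfg, data, cfg$train)
  }

  histories <- list()
  models <- list()
  if (cfg$strategy %in% c("2d", "2.5d")) {
    for (pl in planes) {
      data <- list(
        train = do.call(c, lapply(split$train, function(id)
          .slices_to_samples(cases[[id]]$volume, cases[[id]]$labels, pl))),
        val = if (length(split$validation))
          do.call(c, lapply(split$validation, function(id)
            .slices_to_samples(cases[[id]]$volume, cases[[id]]$labels, pl)))
          else NULL)
      models[[pl]] <- fit_one(cfg$net, data)
      if (inherits(models[[pl]], "tpl_model") && !is.null(models[[pl]]$history))
        histories[[pl]] <- models[[pl]]$history
    }
  } else {
    data <- list(
      train = lapply(split$train, function(id)
        .volume_sample(cases[[id]]$volume, cases[[id]]$labels)),
      val = if (length(split$validation))
        lapply(split$validation, function(id)
          .volume_sample(cases[[id]]$volume, cases[[id]]$labels)) else NULL)
    models[["3d"]] <- fit_one(cfg$net, data)
    if (inherits(models[["3d"]], "tpl_model") && !is.null(models[["3d"]]$history))
      histories[["3d"]] <- models[["3d"]]$history
  }

  predict_case <- function(model, id, plane = NULL) {
    if (inherits(model, "tpl_oracle_model")) {
      lab <- cases[[id]]$labels
      probs <- array(0, c(dim(lab$channels$ms), 3L))
      probs[, , , 1] <- lab$channels$background
      probs[, , , 2] <- lab$channels$ms
      probs[, , , 3] <- lab$channels$msa
      return(.prob_volume(probs, plane %||% "3d"))
    }
    if (is.null(plane)) predict_3d(model, cases[[id]]$volume)
    else predict_plane(model, extract_slices(cases[[id]]$volume, plane))
  }

  metrics <- list(); plane_metrics <- list()
  for (id in split$test) {
    if (cfg$strategy == "2.5d") {
      preds <- lapply(planes, function(pl)
        binarize(predict_case(models[[pl]], id, pl), cfg$threshold))
      names(preds) <- planes
      # fuse each structure channel across planes, then subtract
      fused_ms <- vote(lapply(preds, function(p) p$data[, , , 2]), cfg$rule)
      fused_msa <- vote(lapply(preds, function(p) p$data[, , , 3]), cfg$rule)
      metrics[[id]] <- .case_metrics(id, method, fused_ms, fused_msa,
                                     cases[[id]]$labels)
      if (keep_plane_preds) {
        for (pl in planes) {
          plane_metrics[[paste(id, pl)]] <- .case_metrics(
            id, paste0("2d-", pl), preds[[pl]]$data[, , , 2],
            preds[[pl]]$data[, , , 3], cases[[id]]$labels)
        }
      }
    } else {
      pl <- if (cfg$strategy == "2d") cfg$plane else NULL
      model <- models[[pl %||% "3d"]]
      pb <- binarize(predict_case(model, id, pl), cfg$threshold)
      metrics[[id]] <- .case_metrics(id, method, pb$data[, , , 2],
                                     pb$data[, , , 3], cases[[id]]$labels)
    }
  }
  metrics <- do.call(rbind, c(metrics, make.row.names = FALSE))
  agg <- aggregate_metrics(metrics)
  result <- list(metrics = metrics, aggregate = agg, histories = histories,
                 method = method, config = cfg)
  if (keep_plane_preds && length(plane_metrics))
    result$plane_metrics <- do.call(rbind, c(plane_metrics,
                                             make.row.names = FALSE))
  if (!is.null(cfg$output_dir)) .write_experiment(result, cfg)
  result
}

.write_experiment <- function(result, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metrics, file.path(cfg$output_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$aggregate, file.path(cfg$output_dir, "aggregate.csv"),
                   row.names = FALSE)
  for (nm in names(result$histories))
    utils::write.csv(result$histories[[nm]],
                     file.path(cfg$output_dir, paste0("history_", nm, ".csv")),
                     row.names = FALSE)
  prov <- list(method = result$method, strategy = cfg$strategy,
               plane = cfg$plane, rule = cfg$rule,
               net = unclass(cfg$net), train = unclass(cfg$train),
               threshold = cfg$threshold,
               package_version = as.character(utils::packageVersion("triplanr")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(NULL)
}

#' Ground-truth oracle model (testing aid)
#'
#' A pseudo-model that, inside [run_experiment()], predicts each case's own
#' ground-truth labels with probability 1. Passing it through the full
#' pipeline must yield metrics of exactly 1.0 everywhere - a plumbing test
#' for slicing, voting, subtraction and scoring.
#'
#' @return a `tpl_oracle_model`.
#' @export
oracle_model <- function() structure(list(), class = "tpl_oracle_model")

#' Compare strategies on a shared test split
#'
#' Runs a one-way ANOVA over the per-case values of `metric` for each
#' structure across all supplied experiment results, plus pairwise paired
#' two-tailed t-tests, at significance level `alpha`.
#'
#' @param results list of [run_experiment()] results (>= 2) sharing one test
#'   split.
#' @param metric metric column to compare.
#' @param alpha significance level.
#' @return list with `table` (combined per-case metrics), `anova`
#'   (per-structure data.frame) and `pairwise` (paired t-tests).
#' @export
compare_strategies <- function(results, metric = "DSC", alpha = 0.05) {
  if (length(results) < 2L)
    stop("compare_strategies needs at least 2 experiment results", call. = FALSE)
  tabs <- lapply(results, `[[`, "metrics")
  case_sets <- lapply(tabs, function(t) sort(unique(t$case)))
  for (cs in case_sets[-1])
    if (!identical(cs, case_sets[[1]]))
      stop("experiments do not share one test split", call. = FALSE)
  combined <- do.call(rbind, c(tabs, make.row.names = FALSE))
  structures <- unique(combined$structure)
  anova_rows <- lapply(structures, function(st) {
    r <- compare_methods(combined, "anova_oneway", metric = metric,
                         structure = st, alpha = alpha)
    data.frame(structure = st, F = r$statistic, p = r$p_value,
               significant = r$significant)
  })
  methods <- unique(combined$method)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  pair_rows <- lapply(structures, function(st) {
    do.call(rbind, lapply(pairs, function(pr) {
      sub <- combined[combined$method %in% pr & combined$structure == st, ]
      r <- compare_methods(sub, "paired_t_twotailed", metric = metric,
                           alpha = alpha)
      data.frame(structure = st, method_a = pr[1], method_b = pr[2],
                 t = r$statistic, p = r$p_value, significant = r$significant)
    }))
  })
  list(table = combined,
       anova = do.call(rbind, anova_rows),
       pairwise = do.call(rbind, pair_rows),
       metric = metric, alpha = alpha)
}
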