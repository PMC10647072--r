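#' Synthetic sinus phantom specification
#'
#' Describes a CBCT-like phantom: two ellipsoidal sinus cavities (left/right)
#' in a bone-tier background, an air-tier interior, and an optional
#' soft-tissue-tier lesion grown inside the sinus. The ground-truth topology
#' mirrors the clinical labelling: the air region (MSA) is a strict subset of
#' the whole sinus (MS) whenever a lesion is present, and the lesion (MSL) is
#' exactly the set difference MS minus MSA.
#'
#' @param shape integer length-3 volume extents (each >= 16).
#' @param n_sinuses number of cavities (2 = paired left/right).
#' @param sinus_semiaxes_range 3x2 matrix of per-axis semiaxis ranges in
#'   voxels; default scales with `shape`.
#' @param lesion_style `"none"`, `"mucosal_shell"` (a thin rind of mucosa,
#'   1-3 voxels by default), `"polypoid"` (a blob growing from the sinus
#'   floor) or `"mixed"` (per-phantom archetype sampling spanning tiny
#'   polyps to near-filling disease).
#' @param shell_thickness_range integer range of mucosal shell thickness in
#'   voxels.
#' @param intensity_tiers named mean gray levels for `air`, `soft` (lesion)
#'   and `bone` (everything outside the sinus).
#' @param noise_sd additive Gaussian noise standard deviation (gray levels).
#' @param contrast_jitter fractional range of the per-volume multiplicative
#'   contrast factor, drawn from `U(1 - j, 1 + j)`.
#' @param seed integer RNG seed; the same spec generates bit-identical
#'   phantoms.
#' @return a `tpl_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         n_sinuses = 2L,
                         sinus_semiaxes_range = NULL,
                         lesion_style = c("mixed", "none", "mucosal_shell", "polypoid"),
                         shell_thickness_range = c(1L, 3L),
                         intensity_tiers = c(air = 40, soft = 120, bone = 220),
                         noise_sd = 10,
                         contrast_jitter = 0.15,
                         seed = 1L) {
  lesion_style <- match.arg(lesion_style)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("phantom shape must be 3 extents, each >= 16", call. = FALSE)
  if (is.null(sinus_semiaxes_range)) {
    lr_hi <- if (n_sinuses > 1L) 0.17 else 0.28
    sinus_semiaxes_range <- rbind(
      c(0.10, lr_hi) * shape[1],
      c(0.16, 0.30) * shape[2],
      c(0.16, 0.30) * shape[3])
  }
  sinus_semiaxes_range <- matrix(as.numeric(sinus_semiaxes_range), 3L, 2L)
  if (any(sinus_semiaxes_range < 1))
    stop("sinus semiaxes must be >= 1 voxel", call. = FALSE)
  shell_thickness_range <- as.integer(shell_thickness_range)
  if (length(shell_thickness_range) != 2L || shell_thickness_range[1] < 0L)
    stop("shell_thickness_range must be two non-negative integers", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (contrast_jitter < 0 || contrast_jitter >= 1)
    stop("contrast_jitter must be in [0, 1)", call. = FALSE)
  stopifnot(all(c("air", "soft", "bone") %in% names(intensity_tiers)))
  structure(list(shape = shape, n_sinuses = as.integer(n_sinuses),
                 sinus_semiaxes_range = sinus_semiaxes_range,
                 lesion_style = lesion_style,
                 shell_thickness_range = shell_thickness_range,
                 intensity_tiers = intensity_tiers,
                 noise_sd = noise_sd, contrast_jitter = contrast_jitter,
                 seed = as.integer(seed)),
            class = "tpl_phantom_spec")
}

# Evaluate expr with a private RNG stream; global .Random.seed is restored.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rotation3 <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax); cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Rotated-ellipsoid interior mask, built slice-by-slice from the quadratic
# form so full coordinate grids are never materialized.
.ellipsoid_mask <- function(shape, center, semiaxes, R = diag(3)) {
  M <- R %*% diag(1 / semiaxes^2) %*% t(R)
  vx <- seq_len(shape[1]) - center[1]
  vy <- seq_len(shape[2]) - center[2]
  vz <- seq_len(shape[3]) - center[3]
  Qxy <- M[1, 1] * matrix(vx^2, shape[1], shape[2]) +
    M[2, 2] * matrix(vy^2, shape[1], shape[2], byrow = TRUE) +
    2 * M[1, 2] * outer(vx, vy)
  Qxz <- 2 * M[1, 3] * outer(vx, vz)
  Qyz <- 2 * M[2, 3] * outer(vy, vz)
  out <- array(FALSE, shape)
  # only slices the ellipsoid can reach (its IS half-extent is the norm of
  # the third row of R %*% diag(semiaxes))
  zmax <- sqrt(sum((R %*% diag(semiaxes))[3, ]^2)) + 1
  for (k in which(abs(vz) <= zmax)) {
    Q <- Qxy + Qxz[, k] + rep(Qyz[, k] + M[3, 3] * vz[k]^2, each = shape[1])
    out[, , k] <- Q <= 1
  }
  out
}

# One step of binary erosion with the 3x3x3 box (Chebyshev ball radius 1);
# voxels outside the array count as background.
.erode1_box <- function(m) {
  d <- dim(m)
  for (a in 1:3) {
    n <- d[a]
    lo <- switch(a, m[c(1, seq_len(n - 1)), , , drop = FALSE],
                 m[, c(1, seq_len(n - 1)), , drop = FALSE],
                 m[, , c(1, seq_len(n - 1)), drop = FALSE])
    hi <- switch(a, m[c(seq_len(n - 1) + 1, n), , , drop = FALSE],
                 m[, c(seq_len(n - 1) + 1, n), , drop = FALSE],
                 m[, , c(seq_len(n - 1) + 1, n), drop = FALSE])
    m <- m & lo & hi
    # outside the array counts as background: clear the border planes
    switch(a,
           {m[1, , ] <- FALSE; m[n, , ] <- FALSE},
           {m[, 1, ] <- FALSE; m[, n, ] <- FALSE},
           {m[, , 1] <- FALSE; m[, , n] <- FALSE})
  }
  m
}

.erode_box <- function(m, r) {
  r <- as.integer(r)
  while (r > 0L) {
    m <- .erode1_box(m)
    r <- r - 1L
  }
  m
}

# Lesion region for one phantom; always returned clipped to ms.
.make_lesion <- function(ms, spec, sinus_geoms) {
  style <- spec$lesion_style
  shape <- spec$shape
  if (style == "mixed") {
    archetype <- sample(c("tiny_polyp", "shell", "shell_partial", "severe"),
                        1L, prob = c(0.25, 0.25, 0.25, 0.25))
  } else {
    archetype <- switch(style, none = "none", mucosal_shell = "shell",
                        polypoid = "polyp")
  }
  if (archetype == "none") return(array(FALSE, shape))
  shell <- function(thick) {
    # erode inside the sinus bounding box only; outside it nothing changes
    idx <- lapply(1:3, function(a) {
      r <- range(which(apply(ms, a, any)))
      seq(max(1L, r[1] - 1L), min(shape[a], r[2] + 1L))
    })
    sub <- ms[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out <- array(FALSE, shape)
    out[idx[[1]], idx[[2]], idx[[3]]] <- sub & !.erode_box(sub, thick)
    out
  }
  polyp <- function(scale) {
    g <- sinus_geoms[[sample.int(length(sinus_geoms), 1L)]]
    semi <- pmax(1.5, g$semiaxes * scale)
    # seed the polyp near the sinus floor (low IS), where dependent lesions sit
    ctr <- g$center + c(stats::runif(1, -0.3, 0.3) * g$semiaxes[1],
                        stats::runif(1, -0.3, 0.3) * g$semiaxes[2],
                        -stats::runif(1, 0.4, 0.8) * g$semiaxes[3])
    .ellipsoid_mask(shape, ctr, semi, .rotation3(stats::runif(1, -0.3, 0.3),
                                                 stats::runif(1, -0.3, 0.3),
                                                 stats::runif(1, -0.3, 0.3)))
  }
  thick_choices <- seq(spec$shell_thickness_range[1],
                       spec$shell_thickness_range[2])
  thick <- thick_choices[sample.int(length(thick_choices), 1L)]
  lesion <- switch(archetype,
    tiny_polyp = polyp(stats::runif(1, 0.12, 0.25)),
    polyp = polyp(stats::runif(1, 0.2, 0.8)),
    shell = shell(max(1L, thick)),
    shell_partial = {
      sh <- shell(max(1L, thick))
      zcut <- stats::runif(1, 0.2, 0.6) * shape[3]
      keep <- array(rep(seq_len(shape[3]) <= zcut, each = shape[1] * shape[2]),
                    shape)
      sh & keep
    },
    severe = shell(max(2L, thick)) | polyp(stats::runif(1, 0.6, 0.95)))
  lesion & ms
}

#' Generate one synthetic sinus phantom
#'
#' @param spec a [phantom_spec()].
#' @param masks_only skip intensity synthesis and return only the label
#'   volume (used for geometry-only cohorts, e.g. slice counting).
#' @return a list with elements `volume` (a `tpl_volume`, `NULL` when
#'   `masks_only`) and `labels` (a `tpl_labels` whose lesion channel is
#'   recoverable via [msl_channel()]).
#' @export
generate_phantom <- function(spec, masks_only = FALSE) {
  stopifnot(inherits(spec, "tpl_phantom_spec"))
  .with_seed(spec$seed, {
    shape <- spec$shape
    geoms <- vector("list", spec$n_sinuses)
    centers_lr <- if (spec$n_sinuses == 2L) c(0.28, 0.72)
      else seq(0.5 / spec$n_sinuses, 1 - 0.5 / spec$n_sinuses,
               length.out = spec$n_sinuses)
    ms <- array(FALSE, shape)
    for (s in seq_len(spec$n_sinuses)) {
      semi <- stats::runif(3, spec$sinus_semiaxes_range[, 1],
                           spec$sinus_semiaxes_range[, 2])
      ctr <- c(centers_lr[s] * shape[1], 0.5 * shape[2], 0.5 * shape[3]) +
        stats::runif(3, -0.04, 0.04) * shape
      R <- .rotation3(stats::runif(1, -0.17, 0.17),
                      stats::runif(1, -0.17, 0.17),
                      stats::runif(1, -0.17, 0.17))
      geoms[[s]] <- list(center = ctr, semiaxes = semi, R = R)
      ms <- ms | .ellipsoid_mask(shape, ctr, semi, R)
    }
    lesion <- .make_lesion(ms, spec, geoms)
    msa <- ms & !lesion
    msi <- array(as.integer(ms), shape)
    msai <- array(as.integer(msa), shape)
    # invariants hold by construction (msa = ms & !lesion); skip the O(n)
    # re-validation, which dominates at full working resolution
    labels <- label_volume(list(ms = msi, msa = msai), check = FALSE)
    vol <- NULL
    if (!masks_only) {
      tiers <- spec$intensity_tiers
      img <- array(tiers[["bone"]], shape)
      img[ms] <- tiers[["soft"]]        # lesion tier; overwritten where air
      img[msa] <- tiers[["air"]]
      factor <- stats::runif(1, 1 - spec$contrast_jitter, 1 + spec$contrast_jitter)
      img <- img * factor
      if (spec$noise_sd > 0)
        img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
      vol <- volume(img)
    }
    list(volume = vol, labels = labels)
  })
}

.split_counts <- function(n, fractions) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_cases` seeded phantoms plus a manifest CSV assigning each case
#' to a train/validation/test split. The default split fractions mirror a
#' 67-case cohort divided into 39 training, 14 validation and 14 test cases.
#'
#' @param n_cases number of cases.
#' @param spec a [phantom_spec()]; case `i` is generated with seed
#'   `spec$seed + 7919 * i` so cohorts are reproducible case-by-case.
#' @param dir output directory (created if needed).
#' @param split named fractions summing to 1.
#' @param ext `".nii.gz"`, `".nii"` or `".nrrd"`.
#' @param masks_only write only the ms/msa masks (no intensity volume).
#' @return the manifest `data.frame` (also written to `dir/manifest.csv`)
#'   with columns case_id, split, seed, lesion_style, volume, ms_mask,
#'   msa_mask (paths relative to `dir`).
#' @export
generate_cohort <- function(n_cases, spec, dir,
                            split = c(train = 39 / 67, validation = 14 / 67,
                                      test = 14 / 67),
                            ext = ".nii.gz", masks_only = FALSE) {
  stopifnot(inherits(spec, "tpl_phantom_spec"))
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  groups <- names(split)[split > 0]
  if (n_cases < length(groups))
    stop("n_cases is smaller than the number of nonzero split groups", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- .split_counts(n_cases, split[split > 0])
  assignment <- rep(groups, counts)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case_id <- sprintf("case%03d", i)
    cspec <- spec
    cspec$seed <- spec$seed + 7919L * i
    ph <- generate_phantom(cspec, masks_only = masks_only)
    vol_file <- ""
    if (!masks_only) {
      vol_file <- paste0(case_id, "_vol", ext)
      write_volume(ph$volume, file.path(dir, vol_file))
    }
    write_label_volume(ph$labels, file.path(dir, case_id), ext = ext)
    rows[[i]] <- data.frame(
      case_id = case_id, split = assignment[i], seed = cspec$seed,
      lesion_style = spec$lesion_style, volume = vol_file,
      ms_mask = paste0(case_id, "_ms", ext),
      msa_mask = paste0(case_id, "_msa", ext),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
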