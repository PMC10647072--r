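# Shared fixtures: everything is generated in code at test time.

random_mask <- function(dims, p = 0.5, seed = NULL) {
  gen <- function() array(as.integer(stats::runif(prod(dims)) < p), dims)
  if (is.null(seed)) gen() else withr_seed(seed, gen)
}

# minimal local stand-in for withr::with_seed (withr not a hard dependency)
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

small_phantom <- function(seed = 1, shape = c(32, 32, 32), style = "mixed",
                          noise = 5, masks_only = FALSE) {
  generate_phantom(phantom_spec(shape = shape, seed = seed,
                                lesion_style = style, noise_sd = noise),
                   masks_only = masks_only)
}

# slice/label samples for 2D training tests
phantom_samples <- function(seeds, plane = "axial", shape = c(32, 32, 32),
                            noise = 5) {
  out <- list()
  for (s in seeds) {
    ph <- small_phantom(seed = s, shape = shape, noise = noise)
    v <- normalize_intensity(ph$volume)
    xs <- extract_slices(v, plane)
    ys <- lapply(c("background", "ms", "msa"), function(nm)
      extract_slices(ph$labels$channels[[nm]], plane))
    for (k in seq_along(xs$slices)) {
      d2 <- dim(xs$slices[[k]])
      y <- array(0, c(d2, 3))
      for (c in 1:3) y[, , c] <- ys[[c]]$slices[[k]]
      out[[length(out) + 1]] <- list(x = array(xs$slices[[k]], c(d2, 1)), y = y)
    }
  }
  out
}

make_cohort <- function(dir, n = 4, shape = c(32, 32, 32), seed = 1,
                        split = c(train = 0.5, validation = 0.25, test = 0.25),
                        noise = 5, ext = ".nii.gz") {
  generate_cohort(n, phantom_spec(shape = shape, seed = seed, noise_sd = noise),
                  dir, split = split, ext = ext)
}
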