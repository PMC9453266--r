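# Synthetic brain-phantom cohorts: seeded, class-imbalanced 3D volumes that
# emulate intensity-normalized, Gaussian-smoothed T1-like images with
# class-dependent regional atrophy, plus the two preprocessing operations
# (global-mean intensity normalization, FWHM Gaussian smoothing) and NIfTI
# input/output. The phantom geometry (brain ellipsoid + a deep-gray blob + a
# cortical rim shell) is deliberately schematic and not anatomically
# meaningful; it only provides a spatially localized, class-dependent signal.

#' Cohort specification
#'
#' @param n_total number of subjects (must split exactly by the ratio).
#' @param imbalance_ratio `c(minority, majority)` class ratio, default
#'   `c(1, 3)` (diseased : controls).
#' @param volume_shape spatial grid, default `c(32, 40, 32)` (reduced grid
#'   with the canonical 121:145:121 aspect ratio).
#' @param effect_size fractional atrophy `delta` in `[0, 1)`: minority-class
#'   region intensity is scaled by `1 - delta` and region radius by
#'   `1 - delta/2`.
#' @param noise_sd additive Gaussian noise level before smoothing.
#' @param smooth_fwhm_vox Gaussian smoothing FWHM in voxels.
#' @param seed integer seed; all cohort randomness derives from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total = 160L, imbalance_ratio = c(1L, 3L),
                        volume_shape = c(32L, 40L, 32L), effect_size = 0.3,
                        noise_sd = 0.1, smooth_fwhm_vox = 2, seed = 1L) {
  stopifnot(n_total >= 2, length(imbalance_ratio) == 2, all(imbalance_ratio >= 1),
            length(volume_shape) == 3, all(volume_shape >= 8),
            effect_size >= 0, effect_size < 1, noise_sd >= 0, smooth_fwhm_vox >= 0)
  structure(list(n_total = as.integer(n_total),
                 imbalance_ratio = as.integer(imbalance_ratio),
                 volume_shape = as.integer(volume_shape),
                 effect_size = effect_size, noise_sd = noise_sd,
                 smooth_fwhm_vox = smooth_fwhm_vox, seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_counts <- function(spec) {
  r <- spec$imbalance_ratio
  parts <- sum(r)
  if (spec$n_total %% parts != 0L) {
    lo <- (spec$n_total %/% parts) * parts
    stop(sprintf(
      "n_total = %d cannot be split %d:%d exactly; nearest achievable totals are %d and %d",
      spec$n_total, r[1], r[2], lo, lo + parts), call. = FALSE)
  }
  k <- spec$n_total %/% parts
  c(minority = k * r[1], majority = k * r[2])
}

ellipsoid_dist <- function(shape, center_frac, semi_frac) {
  cx <- (shape - 1) * center_frac + 1
  ax <- shape * semi_frac
  g1 <- ((seq_len(shape[1]) - cx[1]) / ax[1])^2
  g2 <- ((seq_len(shape[2]) - cx[2]) / ax[2])^2
  g3 <- ((seq_len(shape[3]) - cx[3]) / ax[3])^2
  outer(outer(g1, g2, "+"), g3, "+")  # squared normalized radius
}

phantom_image <- function(shape, atten, shrink, jitter) {
  # brain ellipsoid with slight per-subject size jitter
  brain_d <- ellipsoid_dist(shape, rep(0.5, 3), rep(0.42, 3) * jitter$brain)
  brain <- brain_d <= 1
  # central deep-gray blob
  deep_d <- ellipsoid_dist(shape, rep(0.5, 3), rep(0.14, 3) * shrink)
  deep <- deep_d <= 1
  # cortical rim: shell just inside the brain boundary; atrophy thins it
  rim_lo <- 0.85 + (1 - shrink) * 0.1
  rim <- brain_d <= 1 & brain_d >= rim_lo^2
  img <- array(0, shape)
  img[brain] <- 1
  img[deep] <- img[deep] + 1.0 * atten * jitter$amp
  img[rim] <- img[rim] + 0.4 * atten * jitter$amp
  list(img = img, masks = list(deep_gray = deep, cortex_rim = rim), brain = brain)
}

#' Generate a synthetic phantom cohort
#'
#' Deterministic given `spec$seed`. Each volume is a brain ellipsoid with two
#' brighter interior regions (`deep_gray`, `cortex_rim`); minority-class
#' (label 1) volumes carry the atrophy effect (reduced region intensity and
#' radius), followed by additive Gaussian noise, Gaussian smoothing and
#' global-mean intensity normalization. Per-subject anatomy jitter (brain size
#' and region amplitude) makes subjects distinct beyond voxel noise.
#'
#' @param spec a [cohort_spec()].
#' @return list with `volumes` (list of phantoms: `image`, `label`,
#'   `subject_id`, `region_masks`), and `manifest` (data.frame with
#'   `subject_id`, `label`, `class`).
#' @export
generate_cohort <- function(spec) {
  counts <- cohort_counts(spec)
  labels <- c(rep(1L, counts["minority"]), rep(0L, counts["majority"]))
  n <- spec$n_total
  with_seed(spec$seed, {
    ord <- sample.int(n)
    labels <- labels[ord]
    volumes <- vector("list", n)
    for (i in seq_len(n)) {
      lab <- labels[i]
      atten <- if (lab == 1L) 1 - spec$effect_size else 1
      shrink <- if (lab == 1L) 1 - spec$effect_size / 2 else 1
      jitter <- list(brain = exp(stats::rnorm(1, sd = 0.015)),
                     amp = exp(stats::rnorm(1, sd = 0.03)))
      ph <- phantom_image(spec$volume_shape, atten, shrink, jitter)
      img <- ph$img + array(stats::rnorm(prod(spec$volume_shape), sd = spec$noise_sd),
                            spec$volume_shape)
      img <- gaussian_smooth(img, spec$smooth_fwhm_vox)
      img <- img - min(img)  # keep intensities non-negative before normalization
      img <- intensity_normalize(img)
      volumes[[i]] <- structure(list(
        image = img, label = lab,
        subject_id = sprintf("sub-%04d", i),
        region_masks = ph$masks), class = "phantom_volume")
    }
  })
  manifest <- data.frame(
    subject_id = vapply(volumes, `[[`, character(1), "subject_id"),
    label = labels,
    class = ifelse(labels == 1L, "AD", "NC"),
    stringsAsFactors = FALSE)
  list(volumes = volumes, manifest = manifest)
}

#' Global-mean intensity normalization
#'
#' Divides every voxel by the volume's global mean, so the output mean is
#' exactly 1; a monotone transform that preserves voxel ordering.
#'
#' @param volume numeric array with positive mean.
#' @return rescaled array.
#' @export
intensity_normalize <- function(volume) {
  m <- mean(volume)
  if (!is.finite(m) || m <= 0)
    stop("intensity normalization requires a positive global mean", call. = FALSE)
  volume / m
}

#' Separable Gaussian smoothing
#'
#' Smooths a 3D volume with a normalized separable Gaussian kernel of the
#' given full width at half maximum (in voxels), `sigma = fwhm / (2 sqrt(2
#' ln 2))`, using reflective boundaries (which conserve total intensity).
#' `fwhm_vox = 0` returns the input unchanged.
#'
#' @param volume numeric 3D array.
#' @param fwhm_vox non-negative FWHM in voxels.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm_vox) {
  if (fwhm_vox < 0) stop("fwhm must be non-negative", call. = FALSE)
  if (fwhm_vox == 0) return(volume)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  sh <- dim(volume)
  out <- volume
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    # symmetric (edge-repeating) reflective padding conserves total intensity
    # for a normalized kernel; then kernel-weighted row shifts
    ridx <- c(pmin(pmax(seq(r, 1, by = -1), 1), d[1]), seq_len(d[1]),
              pmin(pmax(seq(d[1], d[1] - r + 1, by = -1), 1), d[1]))
    mp <- m[ridx, , drop = FALSE]
    sm <- matrix(0, d[1], ncol(m))
    for (t in seq_along(k))
      sm <- sm + k[t] * mp[t:(t + d[1] - 1), , drop = FALSE]
    out <- aperm(array(sm, d), order(perm))
  }
  out
}

#' Write phantom volumes as NIfTI files
#'
#' One `.nii.gz` per volume (affine = identity scaled by the voxel size) plus
#' a `manifest.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param directory output directory (created if needed).
#' @param voxel_size isotropic voxel size in mm (default 1.5).
#' @return invisibly, the manifest with a `path` column.
#' @export
write_nifti_cohort <- function(cohort, directory, voxel_size = 1.5) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- file.path(directory, paste0(man$subject_id, ".nii.gz"))
  for (i in seq_along(cohort$volumes)) {
    img <- RNifti::asNifti(cohort$volumes[[i]]$image)
    RNifti::pixdim(img) <- rep(voxel_size, 3)
    aff <- structure(diag(c(rep(voxel_size, 3), 1)), code = 2L)
    RNifti::qform(img) <- aff
    RNifti::sform(img) <- aff
    RNifti::writeNifti(img, man$path[i])
  }
  utils::write.csv(man[, c("subject_id", "label", "class", "path")],
                   file.path(directory, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a single-subject NIfTI volume
#'
#' Reorients the image to the RAS canonical axis order and returns the voxel
#' array; 4D (or higher) series are rejected.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return numeric 3D array with attribute `voxel_size`.
#' @export
read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot parse NIfTI '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s' is a %dD series; expected a single 3D volume", path, length(d)),
         call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size") <- unname(RNifti::pixdim(img))
  out
}

# Stack a cohort into a feature volume + label vector for training.
cohort_tensors <- function(cohort) {
  sh <- dim(cohort$volumes[[1]]$image)
  n <- length(cohort$volumes)
  x <- array(0, c(sh, 1, n))
  for (i in seq_len(n)) x[, , , 1, i] <- cohort$volumes[[i]]$image
  list(x = x, labels = vapply(cohort$volumes, `[[`, integer(1), "label"))
}
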