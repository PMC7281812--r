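#' Configuration for synthetic lesion phantoms
#'
#' Phantoms emulate the structure of spatially normalized T1-weighted scans
#' used for chronic stroke lesion segmentation: a bright brain ellipsoid on a
#' dark background, one or more hypointense lesion blobs with smooth,
#' randomly perturbed surfaces, and additive Gaussian noise. Defaults mirror
#' the characteristics of the spatially normalized stroke cohort the package
#' targets: a 197 x 233 x 189 grid of 1 mm^3 voxels and lesion volumes
#' spanning 10 mm^3 to 2.8e5 mm^3.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 8).
#' @param spacing_mm numeric length-3, voxel spacing in mm.
#' @param n_lesions non-negative integer, lesions per phantom.
#' @param lesion_volume_range_mm3 numeric length-2 `(min, max)`, both > 0;
#'   per-lesion target volumes are drawn log-uniformly over this range so
#'   small and large lesions are both represented.
#' @param lesion_contrast lesion-minus-brain mean intensity (arbitrary
#'   units). Negative by default: chronic stroke lesions are hypointense on
#'   T1-weighted images.
#' @param noise_sd standard deviation of additive Gaussian voxel noise.
#' @param surface_irregularity relative amplitude of the smoothed random
#'   radial perturbation applied to each lesion's spherical surface.
#' @param max_place_attempts rejection-sampling cap for non-overlapping
#'   lesion placement before an error is raised.
#' @param seed default RNG seed used when a generator is called without one.
#' @return A `phantom_config` list.
#' @examples
#' cfg <- phantom_config(grid_shape = c(32, 32, 32),
#'                       lesion_volume_range_mm3 = c(50, 500))
#' ph <- generate_phantom(cfg, seed = 1)
#' sum(ph$mask$data)
#' @export
phantom_config <- function(grid_shape = c(197, 233, 189),
                           spacing_mm = c(1, 1, 1),
                           n_lesions = 1,
                           lesion_volume_range_mm3 = c(10, 2.8e5),
                           lesion_contrast = -0.4,
                           noise_sd = 0.05,
                           surface_irregularity = 0.15,
                           max_place_attempts = 100,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers, each >= 8")
  check_spacing(spacing_mm)
  if (n_lesions < 0) stop("n_lesions must be non-negative")
  r <- as.numeric(lesion_volume_range_mm3)
  if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
    stop("lesion_volume_range_mm3 must satisfy 0 < min <= max")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(grid_shape = grid_shape,
                 spacing_mm = as.numeric(spacing_mm),
                 n_lesions = as.integer(n_lesions),
                 lesion_volume_range_mm3 = r,
                 lesion_contrast = as.numeric(lesion_contrast),
                 noise_sd = as.numeric(noise_sd),
                 surface_irregularity = as.numeric(surface_irregularity),
                 max_place_attempts = as.integer(max_place_attempts),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Binary ellipsoid occupancy grid centered mid-grid with semi-axes given in
# voxels per axis.
brain_ellipsoid <- function(grid_shape, semi_frac = 0.42) {
  ax <- semi_frac * grid_shape
  ctr <- (grid_shape + 1) / 2
  q1 <- ((seq_len(grid_shape[1]) - ctr[1]) / ax[1])^2
  q2 <- ((seq_len(grid_shape[2]) - ctr[2]) / ax[2])^2
  q3 <- ((seq_len(grid_shape[3]) - ctr[3]) / ax[3])^2
  outer(outer(q1, q2, "+"), q3, "+") <= 1
}

# Place one lesion blob of `k` voxels: a sphere whose radius is modulated by
# a smooth random even function of direction, grown voxel-by-voxel (k
# smallest values of the modulated radial distance field) so the realized
# voxel count is exact. Returns voxel indices or NULL if placement failed.
place_lesion_blob <- function(k, eligible, grid_shape, spacing, amp) {
  dims <- grid_shape
  vox_vol <- prod(spacing)
  r0 <- (3 * k * vox_vol / (4 * pi))^(1 / 3)       # mm
  cand <- which(eligible)
  if (length(cand) < k) return(NULL)
  ctr_idx <- cand[sample.int(length(cand), 1)]
  ctr <- arrayInd(ctr_idx, dims)
  # bounding box generous enough for the perturbed radius
  half <- pmin(dims, ceiling(1.8 * r0 * (1 + amp) / spacing) + 1L)
  lo <- pmax(1L, ctr - half)
  hi <- pmin(dims, ctr + half)
  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  nb <- c(length(ii), length(jj), length(kk))
  ox <- (ii - ctr[1]) * spacing[1]
  oy <- (jj - ctr[2]) * spacing[2]
  oz <- (kk - ctr[3]) * spacing[3]
  X <- array(rep(ox, times = nb[2] * nb[3]), nb)
  Y <- array(rep(rep(oy, each = nb[1]), times = nb[3]), nb)
  Z <- array(rep(oz, each = nb[1] * nb[2]), nb)
  rr <- sqrt(X^2 + Y^2 + Z^2)
  rr_safe <- pmax(rr, 1e-9)
  # smooth even directional modulation from a few random quadratic lobes
  nlobe <- 6L
  wv <- matrix(rnorm(3 * nlobe), 3, nlobe)
  wv <- sweep(wv, 2, sqrt(colSums(wv^2)), "/")
  av <- rnorm(nlobe)
  g <- 0
  for (m in seq_len(nlobe)) {
    dot <- (X * wv[1, m] + Y * wv[2, m] + Z * wv[3, m]) / rr_safe
    g <- g + av[m] * dot^2
  }
  g <- g - mean(g)
  g <- g / max(sd(g), 1e-9)
  dfield <- rr / (r0 * pmax(1 + amp * g, 0.3))
  # map bbox voxels to linear indices in the full grid
  lin <- outer(outer(ii, (jj - 1L) * dims[1], "+"),
               (kk - 1L) * dims[1] * dims[2], "+")
  ok <- eligible[lin]
  dvals <- dfield[ok]
  lins <- lin[ok]
  if (length(lins) < k) return(NULL)
  ord <- order(dvals, lins)           # deterministic tie-break
  sel <- lins[ord[seq_len(k)]]
  # reject placements that had to stretch far beyond the nominal surface
  if (dvals[ord[k]] > 1.5) return(NULL)
  sel
}

#' Generate a synthetic brain phantom with lesion mask
#'
#' Builds a bright brain ellipsoid on a dark background, carves `n_lesions`
#' non-overlapping lesion blobs (volumes drawn log-uniformly over the
#' configured range; surfaces smooth but irregular), applies the configured
#' lesion/brain intensity contrast and additive Gaussian noise. The realized
#' voxel count of each lesion equals its target volume divided by the voxel
#' volume (rounded to the nearest feasible count within the configured
#' range), and every lesion voxel lies inside the brain ellipsoid.
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed; identical `(config, seed)` pairs give
#'   bit-identical phantoms.
#' @param scan_id identifier stored on the outputs.
#' @return A list with elements `volume` ([les_volume()]), `mask`
#'   ([les_mask()]) and `lesion_voxels` (integer vector of per-lesion voxel
#'   counts).
#' @export
generate_phantom <- function(config, seed = config$seed, scan_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    dims <- config$grid_shape
    spacing <- config$spacing_mm
    vox_vol <- prod(spacing)
    brain <- brain_ellipsoid(dims)
    n_brain <- sum(brain)
    rng <- config$lesion_volume_range_mm3
    kmin <- max(1L, as.integer(ceiling(rng[1] / vox_vol - 1e-9)))
    kmax <- as.integer(floor(rng[2] / vox_vol + 1e-9))
    if (kmax < kmin)
      stop("lesion_volume_range_mm3 admits no whole number of voxels")
    lesion <- array(FALSE, dims)
    lesion_voxels <- integer(0)
    for (j in seq_len(config$n_lesions)) {
      v_target <- exp(runif(1, log(rng[1]), log(rng[2])))
      k <- min(max(as.integer(round(v_target / vox_vol)), kmin), kmax)
      if (k > n_brain - sum(lesion))
        stop(sprintf(
          "requested lesion volume (%d voxels) exceeds available brain region",
          k))
      sel <- NULL
      for (att in seq_len(config$max_place_attempts)) {
        sel <- place_lesion_blob(k, brain & !lesion, dims, spacing,
                                 config$surface_irregularity)
        if (!is.null(sel)) break
      }
      if (is.null(sel))
        stop(sprintf("could not place lesion %d after %d attempts", j,
                     config$max_place_attempts))
      lesion[sel] <- TRUE
      lesion_voxels <- c(lesion_voxels, length(sel))
    }
    vol <- array(0, dims)
    vol[brain] <- 1
    vol[lesion] <- 1 + config$lesion_contrast
    if (config$noise_sd > 0)
      vol <- vol + rnorm(length(vol), 0, config$noise_sd)
    list(volume = les_volume(vol, spacing, scan_id),
         mask = les_mask(array(as.numeric(lesion), dims), spacing, scan_id),
         lesion_voxels = lesion_voxels)
  })
}

#' Generate a cohort of phantoms
#'
#' Each phantom gets a unique, stable `scan_id` and its own sub-seed derived
#' deterministically from `seed`, so the whole cohort is reproducible
#' bit-exactly from `(n, config, seed)`.
#'
#' @param n number of phantoms (>= 1).
#' @inheritParams generate_phantom
#' @param id_prefix prefix for generated scan ids.
#' @return A list of `n` elements, each as returned by [generate_phantom()]
#'   plus a `scan_id` field.
#' @export
generate_cohort <- function(n, config, seed = config$seed,
                            id_prefix = "phantom") {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    id <- sprintf("%s%03d", id_prefix, i)
    ph <- generate_phantom(config, seed = derive_seed(seed, i), scan_id = id)
    ph$scan_id <- id
    ph
  })
}

#' Write a phantom cohort as NIfTI pairs
#'
#' Writes `<id>_t1w.nii.gz` and `<id>_mask.nii.gz` per phantom, with voxel
#' spacing recorded in the headers, and returns a manifest data frame.
#'
#' @param cohort list from [generate_cohort()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a data frame with columns `scan_id`, `volume_path`,
#'   `mask_path`.
#' @export
write_cohort_nifti <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ph) {
    vp <- file.path(out_dir, paste0(ph$scan_id, "_t1w.nii.gz"))
    mp <- file.path(out_dir, paste0(ph$scan_id, "_mask.nii.gz"))
    write_volume(ph$volume, vp)
    write_mask(ph$mask, mp)
    data.frame(scan_id = ph$scan_id, volume_path = vp, mask_path = mp,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}
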