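#' Read and write volumes and masks in NIfTI-1 format
#'
#' Volumes are written as double-precision NIfTI so a write-then-read round
#' trip preserves the grid bit-exactly; masks are written as unsigned 8-bit.
#' Voxel spacing is recorded in (and recovered from) the header. Reading a
#' mask rejects non-binary data unless `binarize = TRUE`, in which case
#' voxels are thresholded at 0.5 (the same threshold used when binarizing
#' probability maps).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param scan_id identifier to attach; defaults to the file name stripped
#'   of its extension and any `_t1w`/`_mask` suffix.
#' @param binarize logical; threshold mask data at 0.5 instead of rejecting
#'   non-binary values.
#' @return [les_volume()] or [les_mask()] objects; writers return the path
#'   invisibly.
#' @name nifti_io
NULL

infer_scan_id <- function(path) {
  id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sub("_(t1w|mask|prob|pred)$", "", id)
}

#' @rdname nifti_io
#' @export
read_volume <- function(path, scan_id = infer_scan_id(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  data <- array(as.vector(img), dim = dim(img))
  les_volume(data, RNifti::pixdim(img)[1:3], scan_id)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path, binarize = FALSE, scan_id = infer_scan_id(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI mask: ", path)
  data <- array(as.vector(img), dim = dim(img))
  if (!all(data %in% c(0, 1))) {
    if (!binarize)
      stop("mask file contains non-binary values (set binarize = TRUE to threshold at 0.5): ",
           path)
    data <- (data >= 0.5) * 1
  }
  les_mask(data, RNifti::pixdim(img)[1:3], scan_id)
}

write_nifti_grid <- function(data, spacing, path, datatype) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname nifti_io
#' @param x a [les_volume()], [les_mask()] or [les_probmap()].
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("les_volume", "les_probmap")))
  write_nifti_grid(x$data, x$spacing, path, "double")
}

#' @rdname nifti_io
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "les_mask"))
  write_nifti_grid(x$data, x$spacing, path, "uint8")
}

#' Split a cohort into train/dev/test sets
#'
#' Set sizes are the nearest-integer rounding of `fraction * N`, with any
#' conservation residue assigned to the training set so the three sizes
#' always sum to `N` (239 scans at (0.76, 0.11, 0.13) give 182/26/31).
#' Assignment is a seeded uniform shuffle.
#'
#' @param ids character vector of scan ids (length >= 3, no duplicates).
#' @param fractions numeric length-3 `(train, dev, test)` summing to 1
#'   within 1e-6.
#' @param seed integer RNG seed.
#' @return A `split_manifest` list with `train_ids`, `dev_ids`, `test_ids`.
#' @examples
#' sp <- split_cohort(sprintf("s%03d", 1:239), c(0.76, 0.11, 0.13), seed = 1)
#' lengths(sp)
#' @export
split_cohort <- function(ids, fractions = c(0.76, 0.11, 0.13), seed = 1L) {
  ids <- as.character(ids)
  if (length(ids) < 3L) stop("need at least 3 ids to split")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(fractions) != 3L || any(fractions < 0))
    stop("fractions must be 3 non-negative reals")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1 (within 1e-6)")
  n <- length(ids)
  sizes <- round(fractions * n)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  if (sizes[1] < 0) stop("rounding produced a negative training set")
  shuffled <- with_seed(seed, sample(ids))
  structure(list(train_ids = shuffled[seq_len(sizes[1])],
                 dev_ids = shuffled[seq_len(sizes[2]) + sizes[1]],
                 test_ids = shuffled[seq_len(sizes[3]) + sizes[1] + sizes[2]]),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat(sprintf("<split_manifest> train %d / dev %d / test %d\n",
              length(x$train_ids), length(x$dev_ids), length(x$test_ids)))
  invisible(x)
}

#' Cohort manifest input/output
#'
#' The manifest is a CSV of `(scan_id, volume_path, mask_path, split)`.
#'
#' @param manifest data frame with at least `scan_id`, `volume_path`,
#'   `mask_path`; `split` optional.
#' @param split a `split_manifest` used to fill the `split` column.
#' @param path CSV file path.
#' @return `read_manifest` returns the manifest data frame;
#'   `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path, split = NULL) {
  if (!is.null(split)) {
    s <- rep(NA_character_, nrow(manifest))
    s[manifest$scan_id %in% split$train_ids] <- "train"
    s[manifest$scan_id %in% split$dev_ids] <- "dev"
    s[manifest$scan_id %in% split$test_ids] <- "test"
    manifest$split <- s
  }
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "volume_path", "mask_path")
  if (!all(need %in% names(df)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  df
}

# Read a (volume, mask) pair, enforcing matched shape and spacing.
read_scan_pair <- function(volume_path, mask_path, binarize = FALSE) {
  vol <- read_volume(volume_path)
  msk <- read_mask(mask_path, binarize = binarize, scan_id = vol$scan_id)
  check_same_grid(vol, msk)
  list(volume = vol, mask = msk)
}
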