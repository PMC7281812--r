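#' Center-crop specification for inference
#'
#' Offset per axis is `floor((shape - crop) / 2)` (floor resolves the
#' 1-voxel ambiguity on odd differences; e.g. a 144 x 172 x 168 window on a
#' 197 x 233 x 189 scan starts at offsets 26, 30, 10).
#'
#' @param volume_shape integer length-3.
#' @param crop_size integer length-3, `<= volume_shape`.
#' @return A [crop_spec()].
#' @export
center_crop_spec <- function(volume_shape, crop_size) {
  volume_shape <- as.integer(volume_shape)
  crop_size <- as.integer(crop_size)
  if (any(crop_size > volume_shape))
    stop("center crop larger than volume on axis ",
         paste(which(crop_size > volume_shape), collapse = ","))
  crop_spec((volume_shape - crop_size) %/% 2L, crop_size, volume_shape)
}

# Largest crop of `shape` compatible with the network's divisibility
# constraint (used as the default inference window).
default_infer_crop <- function(network, shape) {
  div <- 2L^(network$config$n_levels - 1L)
  pmax(div, (as.integer(shape) %/% div) * div)
}

#' Whole-volume prediction by center-crop inference
#'
#' The network is applied to a centered sub-volume; every voxel outside the
#' cropping window is classified negative (probability exactly 0). The
#' returned probability map has the same shape and spacing as the input
#' volume.
#'
#' @param object a `resunet`.
#' @param volume a [les_volume()].
#' @param crop_size inference window (integer length-3); defaults to the
#'   largest network-compatible centered window.
#' @param ... unused.
#' @return A [les_probmap()].
#' @export
predict.resunet <- function(object, volume, crop_size = NULL, ...) {
  stopifnot(inherits(volume, "les_volume"))
  shape <- dim(volume$data)
  if (is.null(crop_size)) crop_size <- default_infer_crop(object, shape)
  crop_size <- as.integer(crop_size)
  check_input_shape(object, crop_size)
  spec <- center_crop_spec(shape, crop_size)
  x <- apply_crop(standardize_input(volume$data), spec)
  dim(x) <- c(crop_size, 1L)
  inner <- net_forward(object, x)$prob
  out <- array(0, shape)
  o <- spec$offset
  out[o[1] + seq_len(crop_size[1]), o[2] + seq_len(crop_size[2]),
      o[3] + seq_len(crop_size[3])] <- inner
  les_probmap(out, volume$spacing, volume$scan_id)
}

#' Snapshot-ensemble prediction
#'
#' Voxelwise arithmetic mean of the member probability maps; the
#' outside-crop rule is preserved (all members share the same window, so
#' outside voxels stay exactly 0). A single-member ensemble equals
#' [predict.resunet()].
#'
#' @param snapshots non-empty list of `resunet` networks.
#' @inheritParams predict.resunet
#' @return A [les_probmap()].
#' @export
ensemble_predict <- function(snapshots, volume, crop_size = NULL) {
  if (length(snapshots) == 0) stop("empty snapshot list")
  maps <- lapply(snapshots, predict, volume = volume, crop_size = crop_size)
  avg <- Reduce(`+`, lapply(maps, function(m) m$data)) / length(maps)
  les_probmap(avg, volume$spacing, volume$scan_id)
}

#' Binarize a probability map
#'
#' Voxel = 1 iff `p >= threshold` (ties map to positive).
#'
#' @param prob_map a [les_probmap()] or bare probability array.
#' @param threshold scalar in (0, 1); default 0.5.
#' @return A [les_mask()] (or bare binary array for bare input).
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (inherits(prob_map, "les_probmap"))
    les_mask((prob_map$data >= threshold) * 1, prob_map$spacing,
             prob_map$scan_id)
  else (grid_data(prob_map) >= threshold) * 1
}
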