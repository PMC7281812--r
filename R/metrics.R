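#' Dice similarity coefficient
#'
#' `2|P intersect R| / (|P| + |R|)` on voxel counts. Two empty masks are in
#' perfect agreement by convention (DSC = 1).
#'
#' @param pred,ref binary grids ([les_mask()] or bare arrays) of matching
#'   shape.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(pred, ref) {
  check_same_grid(pred, ref)
  p <- grid_data(pred); r <- grid_data(ref)
  np <- sum(p); nr <- sum(r)
  if (np + nr == 0) return(1)
  2 * sum(p * r) / (np + nr)
}

#' Maximal Dice over binarization thresholds
#'
#' Sweeps a threshold grid over the probability map and returns the best
#' achievable DSC. With 0.5 in the grid, mDSC always dominates the
#' default-threshold DSC.
#'
#' @param prob_map probability grid ([les_probmap()] or array).
#' @param ref reference binary mask.
#' @param thresholds non-empty numeric grid, each value in (0, 1).
#' @return Scalar in `[0, 1]`.
#' @export
max_dsc <- function(prob_map, ref, thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  p <- grid_data(prob_map)
  max(vapply(thresholds,
             function(t) dsc((p >= t) * 1, grid_data(ref)), numeric(1)))
}

#' Surface voxels of a binary mask
#'
#' A mask voxel belongs to the surface if at least one of its 6
#' face-adjacent neighbors is outside the mask; the volume border counts as
#' outside. Distances between masks are measured between surface voxel
#' centers.
#'
#' @param mask binary grid ([les_mask()] or array).
#' @return Integer matrix (n x 3) of 1-based voxel coordinates (also
#'   retrievable as a logical array via `attr(, "grid")`).
#' @export
surface_voxels <- function(mask) {
  m <- grid_data(mask) > 0
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
  inner <- pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[2 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 2 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 2 + seq_len(d[3])]
  surf <- m & !inner
  coords <- which(surf, arr.ind = TRUE)
  dimnames(coords) <- NULL
  attr(coords, "grid") <- surf
  coords
}

# Directed surface distances: for every surface voxel of `from`, the exact
# Euclidean distance (mm) to the nearest surface voxel of `to`.
surface_distances <- function(surf_from, surf_to_grid, spacing) {
  edt <- cpp_edt3(surf_to_grid, dim(surf_to_grid), as.numeric(spacing))
  idx <- surf_from
  attributes(idx) <- list(dim = dim(surf_from))
  edt[idx]
}

surface_pair <- function(pred, ref) {
  check_same_grid(pred, ref)
  sp <- surface_voxels(pred)
  sr <- surface_voxels(ref)
  if (nrow(sp) == 0 || nrow(sr) == 0) return(NULL)
  list(sp = sp, sr = sr)
}

#' Hausdorff distance between mask surfaces (mm)
#'
#' Maximum over both directions of the largest surface-voxel-center to
#' nearest-surface distance, scaled by the voxel spacing. Undefined
#' (`NA`) when either mask is empty.
#'
#' @inheritParams dsc
#' @param spacing voxel spacing in mm; defaults to the masks' spacing.
#' @return Non-negative scalar in mm, or `NA_real_`.
#' @export
hausdorff_mm <- function(pred, ref, spacing = grid_spacing(pred)) {
  sp2 <- surface_pair(pred, ref)
  if (is.null(sp2)) return(NA_real_)
  gp <- attr(sp2$sp, "grid"); gr <- attr(sp2$sr, "grid")
  d1 <- surface_distances(sp2$sp, gr, spacing)
  d2 <- surface_distances(sp2$sr, gp, spacing)
  max(max(d1), max(d2))
}

#' Average symmetric surface distance (mm)
#'
#' Mean of all nearest surface-to-surface distances pooled over both
#' directions: `(sum_p d(p, S(R)) + sum_r d(r, S(P))) / (|S(P)| + |S(R)|)`.
#' Undefined (`NA`) when either mask is empty.
#'
#' @inheritParams hausdorff_mm
#' @return Non-negative scalar in mm, or `NA_real_`.
#' @export
assd_mm <- function(pred, ref, spacing = grid_spacing(pred)) {
  sp2 <- surface_pair(pred, ref)
  if (is.null(sp2)) return(NA_real_)
  gp <- attr(sp2$sp, "grid"); gr <- attr(sp2$sr, "grid")
  d1 <- surface_distances(sp2$sp, gr, spacing)
  d2 <- surface_distances(sp2$sr, gp, spacing)
  (sum(d1) + sum(d2)) / (length(d1) + length(d2))
}

confusion_counts <- function(pred, ref) {
  check_same_grid(pred, ref)
  p <- grid_data(pred) > 0; r <- grid_data(ref) > 0
  c(tp = sum(p & r), fp = sum(p & !r), fn = sum(!p & r))
}

#' Voxelwise true positive rate (sensitivity)
#'
#' `TP / (TP + FN)`; `NA` when the reference is empty (no positives to
#' recover).
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]` or `NA_real_`.
#' @export
tpr <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  if (cc["tp"] + cc["fn"] == 0) return(NA_real_)
  unname(cc["tp"] / (cc["tp"] + cc["fn"]))
}

#' Voxelwise precision (positive predictive value)
#'
#' `TP / (TP + FP)`; `NA` when the prediction is empty.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]` or `NA_real_`.
#' @export
precision <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  if (cc["tp"] + cc["fp"] == 0) return(NA_real_)
  unname(cc["tp"] / (cc["tp"] + cc["fp"]))
}

#' Micro-averaged Dice over a cohort
#'
#' DSC computed on voxel counts pooled across all scans:
#' `2*sum(TP) / (2*sum(TP) + sum(FP) + sum(FN))`. A per-voxel global
#' statistic, less sensitive to lesion size than the per-scan mean DSC.
#'
#' @param pairs non-empty list; each element a list with binary `pred` and
#'   `ref` grids of matching shape.
#' @return Scalar in `[0, 1]`.
#' @export
micro_dsc <- function(pairs) {
  if (length(pairs) == 0) stop("empty list of mask pairs")
  cc <- Reduce(`+`, lapply(pairs, function(pr)
    confusion_counts(pr$pred, pr$ref)))
  if (2 * cc["tp"] + cc["fp"] + cc["fn"] == 0) return(1)
  unname(2 * cc["tp"] / (2 * cc["tp"] + cc["fp"] + cc["fn"]))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `n_boot` times (seeded), takes the
#' mean of each resample, and returns the `(1 - level)/2` and
#' `1 - (1 - level)/2` percentiles. The evaluation protocol uses 1000
#' iterations at the 95% level.
#'
#' @param values non-empty numeric vector (no NAs).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level in (0, 1).
#' @param seed RNG seed.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, level = 0.95, seed = 1L) {
  if (length(values) == 0) stop("empty input to bootstrap_ci")
  if (anyNA(values)) stop("bootstrap_ci input contains NA")
  stopifnot(n_boot >= 1, level > 0, level < 1)
  n <- length(values)
  means <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(values[sample.int(n, n, replace = TRUE)]), numeric(1)))
  alpha <- (1 - level) / 2
  q <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(lo = q[1], hi = q[2])
}

# Mean with bootstrap CI over values that may contain NAs (undefined
# metrics are excluded; the exclusion count is reported).
summarize_metric <- function(values, n_boot, seed) {
  ok <- values[!is.na(values)]
  if (length(ok) == 0)
    return(list(mean = NA_real_, lo = NA_real_, hi = NA_real_,
                n = 0L, n_excluded = sum(is.na(values))))
  ci <- bootstrap_ci(ok, n_boot = n_boot, seed = seed)
  list(mean = mean(ok), lo = ci[["lo"]], hi = ci[["hi"]],
       n = length(ok), n_excluded = sum(is.na(values)))
}

#' Stratify per-scan metrics by reference lesion size
#'
#' Scans are rank-ordered by `lesion_voxels_ref` (ties broken by
#' `scan_id`) and cut into four contiguous groups at the quartile ranks:
#' group g covers ranks `ceil((g-1) n / 4) + 1 .. ceil(g n / 4)` (8 scans
#' give groups of 2/2/2/2; 31 give 8/8/8/7).
#'
#' @param scan_metrics data frame with columns `scan_id`,
#'   `lesion_voxels_ref` and metric columns (`dsc`, `hd_mm`, ...); >= 4
#'   rows.
#' @param n_boot,seed bootstrap settings for the per-group CIs.
#' @return List of 4 groups, each with `scan_ids`, `size_range` and a
#'   `summary` list of per-metric mean/CI.
#' @export
stratify_by_size <- function(scan_metrics, n_boot = 1000L, seed = 1L) {
  n <- nrow(scan_metrics)
  if (is.null(n) || n < 4) stop("need at least 4 scans to stratify")
  ord <- order(scan_metrics$lesion_voxels_ref, scan_metrics$scan_id)
  sm <- scan_metrics[ord, , drop = FALSE]
  cuts <- ceiling(n * (0:4) / 4)
  metric_cols <- intersect(c("dsc", "mdsc", "hd_mm", "assd_mm", "tpr",
                             "precision"), names(sm))
  lapply(seq_len(4), function(g) {
    rows <- sm[(cuts[g] + 1):cuts[g + 1], , drop = FALSE]
    list(percentile = sprintf("%d-%d%%", (g - 1) * 25, g * 25),
         scan_ids = rows$scan_id,
         size_range = range(rows$lesion_voxels_ref),
         summary = lapply(stats::setNames(metric_cols, metric_cols),
                          function(mc) summarize_metric(rows[[mc]],
                                                        n_boot, seed)))
  })
}

#' Ordinary least squares of DSC on log10 lesion size
#'
#' Regresses per-scan DSC on the base-10 logarithm of the reference lesion
#' voxel count and returns the coefficient of determination. Scans with
#' zero lesion voxels are excluded (log undefined); the exclusion count is
#' attached as an attribute.
#'
#' @param scan_metrics data frame with `dsc` and `lesion_voxels_ref`.
#' @return `r_squared` scalar with attribute `n_excluded`.
#' @export
size_dsc_regression <- function(scan_metrics) {
  keep <- scan_metrics$lesion_voxels_ref > 0 & !is.na(scan_metrics$dsc)
  n_excl <- sum(!keep)
  df <- scan_metrics[keep, , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 scans with positive lesion counts")
  fit <- lm(dsc ~ log10(lesion_voxels_ref), data = df)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((df$dsc - mean(df$dsc))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  structure(r2, n_excluded = n_excl)
}

#' Evaluate one predicted scan against its reference
#'
#' @param prob_map predicted probability map ([les_probmap()]).
#' @param ref reference [les_mask()].
#' @param threshold binarization threshold for DSC/TPR/precision/surface
#'   metrics.
#' @param thresholds grid for the maximal-DSC sweep.
#' @return One-row data frame of per-scan metrics.
#' @export
evaluate_scan <- function(prob_map, ref, threshold = 0.5,
                          thresholds = seq(0.01, 0.99, by = 0.01)) {
  check_same_grid(prob_map, ref)
  pred <- binarize(prob_map, threshold)
  data.frame(scan_id = ref$scan_id,
             dsc = dsc(pred, ref),
             mdsc = max_dsc(prob_map, ref, thresholds),
             hd_mm = hausdorff_mm(pred, ref),
             assd_mm = assd_mm(pred, ref),
             tpr = tpr(pred, ref),
             precision = precision(pred, ref),
             lesion_voxels_ref = sum(ref$data),
             lesion_voxels_pred = sum(pred$data),
             stringsAsFactors = FALSE)
}

#' Evaluate a cohort of predictions
#'
#' Computes per-scan metrics plus cohort aggregates: per-metric means with
#' 95% percentile-bootstrap confidence intervals (1000 iterations by
#' default; undefined per-scan values are excluded from aggregation with a
#' recorded count), micro-averaged DSC, lesion-size quartile stratification
#' (when >= 4 scans) and the DSC vs log10 lesion size regression (when >= 3
#' scans have lesions).
#'
#' @param prob_maps list of [les_probmap()].
#' @param refs list of [les_mask()] in the same order.
#' @param threshold binarization threshold.
#' @param n_boot,level,seed bootstrap settings.
#' @param thresholds maximal-DSC threshold grid.
#' @return A `cohort_report`: list with `scans` (data frame), `summary`,
#'   `micro_dsc`, `size_groups`, `r_squared`.
#' @export
evaluate_cohort <- function(prob_maps, refs, threshold = 0.5,
                            n_boot = 1000L, level = 0.95, seed = 1L,
                            thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(prob_maps) == length(refs), length(refs) >= 1)
  scans <- do.call(rbind, Map(function(pm, rf)
    evaluate_scan(pm, rf, threshold, thresholds), prob_maps, refs))
  metric_cols <- c("dsc", "mdsc", "hd_mm", "assd_mm", "tpr", "precision")
  summary <- lapply(stats::setNames(metric_cols, metric_cols), function(mc)
    summarize_metric(scans[[mc]], n_boot, seed))
  pairs <- Map(function(pm, rf)
    list(pred = binarize(pm, threshold), ref = rf), prob_maps, refs)
  mdsc_global <- micro_dsc(pairs)
  size_groups <- if (nrow(scans) >= 4)
    stratify_by_size(scans, n_boot = n_boot, seed = seed) else NULL
  r2 <- if (sum(scans$lesion_voxels_ref > 0 & !is.na(scans$dsc)) >= 3)
    size_dsc_regression(scans) else NULL
  structure(list(scans = scans, summary = summary, micro_dsc = mdsc_global,
                 size_groups = size_groups, r_squared = r2,
                 threshold = threshold, n_boot = n_boot, level = level),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d scans, threshold %.2f\n",
              nrow(x$scans), x$threshold))
  for (mc in names(x$summary)) {
    s <- x$summary[[mc]]
    excl <- if (s$n_excluded > 0)
      sprintf("  [%d undefined excluded]", s$n_excluded) else ""
    cat(sprintf("  %-10s %6.3f  (%.3f-%.3f, 95%% bootstrap CI, n=%d)%s\n",
                mc, s$mean, s$lo, s$hi, s$n, excl))
  }
  cat(sprintf("  microDSC   %6.3f\n", x$micro_dsc))
  if (!is.null(x$r_squared))
    cat(sprintf("  R^2 (DSC ~ log10 lesion voxels): %.3f\n",
                as.numeric(x$r_squared)))
  invisible(x)
}

#' @export
summary.cohort_report <- function(object, ...) {
  df <- do.call(rbind, lapply(names(object$summary), function(mc) {
    s <- object$summary[[mc]]
    data.frame(metric = mc, mean = s$mean, ci_lo = s$lo, ci_hi = s$hi,
               n = s$n, n_excluded = s$n_excluded)
  }))
  rbind(df, data.frame(metric = "micro_dsc", mean = object$micro_dsc,
                       ci_lo = NA, ci_hi = NA, n = nrow(object$scans),
                       n_excluded = 0L))
}
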