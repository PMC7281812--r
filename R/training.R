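#' Training stage configuration
#'
#' One stage of the two-stage zoom-in&out schedule. The reference settings
#' for full-size scans are: zoom-in on 128^3 crops (24% of a
#' 197 x 233 x 189 scan) for 1200 epochs at initial learning rate 1e-3,
#' then zoom-out finetuning on 144 x 172 x 168 crops (48%) for 150 epochs
#' at 1e-4, both with Adam and a cosine-annealing warm-restart schedule.
#' Desk-scale runs use the same structure with smaller crops and epoch
#' counts (see the vignette).
#'
#' @param crop_size integer length-3 crop in voxels; must fit every
#'   training volume and satisfy the network's divisibility constraint.
#' @param epochs number of epochs (one random crop per training scan per
#'   epoch by default).
#' @param initial_lr learning-rate maximum at each warm restart.
#' @param lr_min learning-rate floor of the cosine schedule.
#' @param restart_period_T0 length of the first cosine cycle, in epochs.
#' @param restart_mult_Tmult multiplicative growth of cycle length after
#'   each restart (>= 1).
#' @param batch_size crops per optimizer step.
#' @param crops_per_scan random crops drawn from each scan per epoch.
#' @param seed RNG seed for crop sampling in this stage.
#' @return A `stage_config` list.
#' @export
stage_config <- function(crop_size, epochs, initial_lr,
                         lr_min = 0, restart_period_T0 = 50L,
                         restart_mult_Tmult = 2, batch_size = 1L,
                         crops_per_scan = 1L, seed = 1L) {
  crop_size <- as.integer(crop_size)
  stopifnot(length(crop_size) == 3L, all(crop_size >= 1L), epochs >= 0,
            initial_lr > 0, lr_min >= 0, restart_period_T0 >= 1,
            restart_mult_Tmult >= 1, batch_size >= 1, crops_per_scan >= 1)
  structure(list(crop_size = crop_size, epochs = as.integer(epochs),
                 initial_lr = initial_lr, lr_min = lr_min,
                 restart_period_T0 = as.integer(restart_period_T0),
                 restart_mult_Tmult = restart_mult_Tmult,
                 batch_size = as.integer(batch_size),
                 crops_per_scan = as.integer(crops_per_scan),
                 seed = as.integer(seed)),
            class = "stage_config")
}

#' Sub-volume crop specification
#'
#' `offset` is 0-based; the crop `[offset, offset + size)` must lie fully
#' inside a volume of shape `shape` on every axis.
#'
#' @param offset integer length-3, 0-based voxel offsets.
#' @param size integer length-3 crop size.
#' @param shape optional volume shape to validate against.
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(offset, size, shape = NULL) {
  offset <- as.integer(offset); size <- as.integer(size)
  stopifnot(length(offset) == 3L, length(size) == 3L,
            all(offset >= 0L), all(size >= 1L))
  if (!is.null(shape) && any(offset + size > shape))
    stop("crop extends outside the volume")
  structure(list(offset = offset, size = size), class = "crop_spec")
}

#' Sample a uniformly random crop position
#'
#' The offset on each axis is uniform over all valid positions,
#' independently per axis, drawn from the current RNG state (seed the RNG
#' to reproduce sequences).
#'
#' @param volume_shape integer length-3.
#' @param crop_size integer length-3, `<= volume_shape` componentwise.
#' @return A [crop_spec()].
#' @export
sample_crop <- function(volume_shape, crop_size) {
  volume_shape <- as.integer(volume_shape)
  crop_size <- as.integer(crop_size)
  if (any(crop_size > volume_shape))
    stop("crop larger than volume on axis ",
         paste(which(crop_size > volume_shape), collapse = ","))
  offset <- vapply(volume_shape - crop_size,
                   function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
  crop_spec(offset, crop_size, volume_shape)
}

apply_crop <- function(arr, spec) {
  o <- spec$offset; s <- spec$size
  arr[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]), o[3] + seq_len(s[3]),
      drop = FALSE]
}

#' Crop volume fraction in percent
#'
#' `100 * prod(crop_size) / prod(volume_shape)`, rounded to the nearest
#' integer percent (the convention used when quoting sub-volume sizes,
#' e.g. a 128^3 crop of a 197 x 233 x 189 scan is 24%, and a
#' 144 x 172 x 168 crop is 48%).
#'
#' @param crop_size integer length-3.
#' @param volume_shape integer length-3.
#' @return Percentage rounded to the nearest integer.
#' @export
crop_fraction <- function(crop_size, volume_shape) {
  round(100 * prod(as.numeric(crop_size)) / prod(as.numeric(volume_shape)))
}

#' Cosine-annealing learning rate within one warm-restart cycle
#'
#' `lr_min + (lr_max - lr_min) / 2 * (1 + cos(pi * t_cur / t_i))`: the rate
#' starts at `lr_max` (cycle start, `t_cur = 0`), decays along a half
#' cosine, and reaches `lr_min` at the cycle end (`t_cur = t_i`). At each
#' restart the rate jumps back to `lr_max`.
#'
#' @param t_cur epochs elapsed in the current cycle (0 <= t_cur <= t_i).
#' @param t_i current cycle length in epochs.
#' @param lr_max learning-rate maximum.
#' @param lr_min learning-rate floor.
#' @return Learning rate.
#' @export
cosine_warm_restart_lr <- function(t_cur, t_i, lr_max, lr_min = 0) {
  if (t_cur < 0 || t_cur > t_i)
    stop("t_cur must lie in [0, t_i]")
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t_cur / t_i))
}

#' Learning rate at a given epoch of a warm-restart schedule
#'
#' Cycle lengths start at `restart_period_T0` and grow by
#' `restart_mult_Tmult` after each restart; epoch 0 is the start of the
#' first cycle.
#'
#' @param epoch 0-based epoch index.
#' @param stage a [stage_config()].
#' @return Learning rate at that epoch.
#' @export
lr_at_epoch <- function(epoch, stage) {
  stopifnot(epoch >= 0)
  t_i <- stage$restart_period_T0
  start <- 0
  while (epoch >= start + t_i) {
    start <- start + t_i
    t_i <- max(1, round(t_i * stage$restart_mult_Tmult))
  }
  cosine_warm_restart_lr(epoch - start, t_i, stage$initial_lr, stage$lr_min)
}

adam_init <- function() {
  list(m = list(), v = list(), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in ls(grads)) {
    g <- grads[[nm]]
    m <- if (is.null(state$m[[nm]])) g * 0 else state$m[[nm]]
    v <- if (is.null(state$v[[nm]])) g * 0 else state$v[[nm]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  state
}

# Accumulate gradient environments (sums `add` into `acc` in place).
grads_accumulate <- function(acc, add) {
  for (nm in ls(add)) {
    acc[[nm]] <- if (exists(nm, envir = acc, inherits = FALSE))
      acc[[nm]] + add[[nm]] else add[[nm]]
  }
  acc
}

grads_scale <- function(acc, s) {
  for (nm in ls(acc)) acc[[nm]] <- acc[[nm]] * s
  acc
}

# One training step on a list of (x, y) crops: mean loss/grads over the
# batch, Dice computed per sample then averaged.
train_batch <- function(network, batch, loss_cfg, adam, lr) {
  nb <- length(batch)
  acc <- new_param_set()
  tot <- c(loss = 0, bce = 0, dice = 0)
  for (item in batch) {
    fw <- net_forward(network, item$x, want_cache = TRUE)
    prob <- fw$prob
    dim(prob) <- dim(item$y)
    lb <- bce_loss(prob, item$y, loss_cfg$prob_clip_eps)
    ld <- dice_loss(prob, item$y, loss_cfg$smooth_eps)
    tot <- tot + c(loss_cfg$lambda_bce * lb + (1 - loss_cfg$lambda_bce) * ld,
                   lb, ld)
    dprob <- combined_loss_grad(prob, item$y, loss_cfg) / nb
    dim(dprob) <- dim(fw$prob)
    grads_accumulate(acc, net_backward(network, fw$cache, dprob))
  }
  state <- adam_step(network$params, acc, adam, lr)
  list(adam = state, losses = tot / nb)
}

#' Train the network for one stage
#'
#' Per epoch, each training scan contributes `crops_per_scan` random
#' sub-volume crops; crops are batched `batch_size` at a time and optimized
#' with Adam under the stage's cosine-annealing warm-restart schedule. The
#' run is fully reproducible under fixed seeds. Snapshot checkpoints (deep
#' parameter copies) are captured at the requested epochs.
#'
#' @param network a `resunet` (not modified in place; the trained copy is
#'   returned).
#' @param cohort list of scans, each with `volume` ([les_volume()]) and
#'   `mask` ([les_mask()]).
#' @param stage a [stage_config()].
#' @param loss a [loss_config()].
#' @param snapshot_epochs integer epochs (1-based, within this stage) at
#'   which to capture snapshots.
#' @param stage_name label recorded in the history.
#' @param verbose print per-epoch loss.
#' @return List with `network`, `history` (data frame: epoch, stage, lr,
#'   loss, bce, dice), and `snapshots` (named list of `resunet`).
#' @export
train_stage <- function(network, cohort, stage, loss = loss_config(),
                        snapshot_epochs = integer(0), stage_name = "stage",
                        verbose = FALSE) {
  stopifnot(inherits(network, "resunet"), inherits(stage, "stage_config"))
  if (length(cohort) == 0) stop("empty training cohort")
  if (length(snapshot_epochs) && max(snapshot_epochs) > stage$epochs)
    stop("snapshot epoch exceeds stage length")
  for (sc in cohort) {
    if (any(stage$crop_size > dim(sc$volume$data)))
      stop("crop_size exceeds the shape of scan ", sc$volume$scan_id)
  }
  check_input_shape(network, stage$crop_size)
  net <- clone_network(network)
  history <- vector("list", stage$epochs)
  snapshots <- list()
  adam <- adam_init()
  # intensities are standardized once per scan (zero mean, unit variance
  # over the whole volume) before any cropping, matching inference
  std_vols <- lapply(cohort, function(sc) standardize_input(sc$volume$data))
  with_seed(stage$seed, {
    for (ep in seq_len(stage$epochs)) {
      lr <- lr_at_epoch(ep - 1, stage)
      crops <- list()
      for (si in seq_along(cohort)) {
        sc <- cohort[[si]]
        vshape <- dim(sc$volume$data)
        for (r in seq_len(stage$crops_per_scan)) {
          spec <- sample_crop(vshape, stage$crop_size)
          xv <- apply_crop(std_vols[[si]], spec)
          dim(xv) <- c(stage$crop_size, 1L)
          crops[[length(crops) + 1]] <-
            list(x = xv, y = apply_crop(sc$mask$data, spec))
        }
      }
      ep_loss <- c(loss = 0, bce = 0, dice = 0)
      nb <- 0L
      idx <- seq_along(crops)
      for (b0 in seq(1, length(crops), by = stage$batch_size)) {
        batch <- crops[idx[b0:min(b0 + stage$batch_size - 1, length(crops))]]
        st <- train_batch(net, batch, loss, adam, lr)
        adam <- st$adam
        ep_loss <- ep_loss + st$losses
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      history[[ep]] <- data.frame(epoch = ep, stage = stage_name, lr = lr,
                                  loss = ep_loss[["loss"]],
                                  bce = ep_loss[["bce"]],
                                  dice = ep_loss[["dice"]])
      if (verbose)
        message(sprintf("[%s] epoch %d  lr %.2e  loss %.4f (bce %.4f dice %.4f)",
                        stage_name, ep, lr, ep_loss[["loss"]],
                        ep_loss[["bce"]], ep_loss[["dice"]]))
      net$epoch <- ep
      net$stage <- stage_name
      if (ep %in% snapshot_epochs)
        snapshots[[paste0("epoch", ep)]] <- clone_network(net)
    }
  })
  list(network = net, history = do.call(rbind, history), snapshots = snapshots)
}

#' Two-stage zoom-in&out training
#'
#' Trains on small random crops (zoom-in), then finetunes the same
#' parameters on larger crops (zoom-out) with a fresh Adam optimizer at the
#' zoom-out stage's own initial learning rate. Snapshot checkpoints are
#' captured at the listed zoom-out epochs; when the last snapshot epoch
#' equals the zoom-out stage length, the final model is identical to the
#' last snapshot.
#'
#' @inheritParams train_stage
#' @param stage_in zoom-in [stage_config()].
#' @param stage_out zoom-out [stage_config()]; `crop_size` must be >= the
#'   zoom-in crop on every axis.
#' @param snapshot_epochs zoom-out epochs at which to capture snapshots.
#' @return List with `network` (final), `network_zoom_in` (after stage one),
#'   `snapshots`, and `history` covering both stages.
#' @export
zoom_in_out <- function(network, cohort, stage_in, stage_out,
                        snapshot_epochs = integer(0), loss = loss_config(),
                        verbose = FALSE) {
  if (any(stage_out$crop_size < stage_in$crop_size))
    stop("zoom-out crop must be >= zoom-in crop on every axis")
  if (length(snapshot_epochs) && max(snapshot_epochs) > stage_out$epochs)
    stop("snapshot epoch exceeds zoom-out stage length")
  if (stage_in$epochs > 0) {
    s1 <- train_stage(network, cohort, stage_in, loss,
                      stage_name = "zoom_in", verbose = verbose)
  } else {
    s1 <- list(network = clone_network(network), history = NULL)
  }
  s2 <- train_stage(s1$network, cohort, stage_out, loss,
                    snapshot_epochs = snapshot_epochs,
                    stage_name = "zoom_out", verbose = verbose)
  list(network = s2$network, network_zoom_in = s1$network,
       snapshots = s2$snapshots, history = rbind(s1$history, s2$history))
}
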