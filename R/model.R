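#' Architecture configuration for the 3D residual U-Net
#'
#' The network is an encoder-decoder with residual blocks that use group
#' normalization inside the transform path, strided-convolution
#' down-sampling, transposed-convolution up-sampling, channel-concatenation
#' skip connections, and a sigmoid one-channel output head.
#'
#' The default configuration is the package's 52-convolution reference
#' layout: 4 resolution levels, 3 residual blocks per level, base width 16
#' doubling per level, and a head made of one residual block plus a 1x1x1
#' output convolution. Under the documented counting rule (see
#' [count_conv_layers()]) this totals 52 convolution layers:
#' 1 stem + 24 encoder + 3 down + 3 up + 18 decoder + 2 head + 1 output.
#'
#' @param n_levels encoder depth (resolution levels).
#' @param base_channels channels at the first level.
#' @param channel_growth multiplier on channels per level.
#' @param blocks_per_level residual blocks per encoder/decoder level.
#' @param gn_groups group-normalization groups; must divide every channel
#'   count in the network.
#' @param conv_layer_count_target optional; if set, [build_network()] checks
#'   that the built network counts exactly this many convolution layers.
#' @return A `network_config` list.
#' @examples
#' cfg <- network_config(n_levels = 2, base_channels = 4,
#'                       blocks_per_level = 1, gn_groups = 2)
#' net <- build_network(cfg, seed = 1)
#' count_conv_layers(net)
#' @export
network_config <- function(n_levels = 4L, base_channels = 16L,
                           channel_growth = 2L, blocks_per_level = 3L,
                           gn_groups = 8L,
                           conv_layer_count_target = if (n_levels == 4L &&
                             blocks_per_level == 3L) 52L else NULL) {
  stopifnot(n_levels >= 1, base_channels >= 1, channel_growth >= 1,
            blocks_per_level >= 1, gn_groups >= 1)
  ch <- base_channels * channel_growth^(seq_len(n_levels) - 1)
  if (any(ch %% gn_groups != 0))
    stop("gn_groups must divide every channel count; got channels ",
         paste(ch, collapse = ", "), " with gn_groups = ", gn_groups)
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channel_growth = as.integer(channel_growth),
                 blocks_per_level = as.integer(blocks_per_level),
                 gn_groups = as.integer(gn_groups),
                 channels = as.integer(ch),
                 conv_layer_count_target =
                   if (is.null(conv_layer_count_target)) NULL
                   else as.integer(conv_layer_count_target)),
            class = "network_config")
}

new_param_set <- function() new.env(parent = emptyenv())

add_res_block <- function(params, registry, prefix, cin, cout, groups) {
  params[[paste0(prefix, ".conv1.W")]] <- he_conv(3, cin, cout)
  params[[paste0(prefix, ".conv1.b")]] <- numeric(cout)
  params[[paste0(prefix, ".gn1.gamma")]] <- rep(1, cout)
  params[[paste0(prefix, ".gn1.beta")]] <- numeric(cout)
  params[[paste0(prefix, ".conv2.W")]] <- he_conv(3, cout, cout)
  params[[paste0(prefix, ".conv2.b")]] <- numeric(cout)
  params[[paste0(prefix, ".gn2.gamma")]] <- rep(1, cout)
  params[[paste0(prefix, ".gn2.beta")]] <- numeric(cout)
  registry[[length(registry) + 1]] <- list(name = paste0(prefix, ".conv1"),
                                           kind = "conv", counted = TRUE)
  registry[[length(registry) + 1]] <- list(name = paste0(prefix, ".conv2"),
                                           kind = "conv", counted = TRUE)
  if (cin != cout) {
    params[[paste0(prefix, ".proj.W")]] <- he_conv(1, cin, cout)
    params[[paste0(prefix, ".proj.b")]] <- numeric(cout)
    registry[[length(registry) + 1]] <- list(name = paste0(prefix, ".proj"),
                                             kind = "proj", counted = FALSE)
  }
  registry
}

#' Build a 3D residual U-Net
#'
#' Parameter initialization is deterministic under `seed` (He-scaled normal
#' weights, unit group-norm gains, zero biases). The forward pass maps an
#' input grid of shape S to a probability grid of the same shape S; every
#' spatial input dimension must be divisible by `2^(n_levels - 1)`.
#'
#' @param config a [network_config()].
#' @param seed integer RNG seed for initialization.
#' @return A `resunet` object.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    params <- new_param_set()
    registry <- list()
    ch <- config$channels
    L <- config$n_levels
    B <- config$blocks_per_level
    params[["stem.W"]] <- he_conv(3, 1, ch[1])
    params[["stem.b"]] <- numeric(ch[1])
    registry[[1]] <- list(name = "stem", kind = "conv", counted = TRUE)
    for (l in seq_len(L)) {
      for (b in seq_len(B))
        registry <- add_res_block(params, registry,
                                  sprintf("enc%d.b%d", l, b),
                                  ch[l], ch[l], config$gn_groups)
      if (l < L) {
        params[[sprintf("down%d.W", l)]] <- he_conv(3, ch[l], ch[l + 1])
        params[[sprintf("down%d.b", l)]] <- numeric(ch[l + 1])
        registry[[length(registry) + 1]] <-
          list(name = sprintf("down%d", l), kind = "conv", counted = TRUE)
      }
    }
    for (l in rev(seq_len(L - 1))) {
      params[[sprintf("up%d.W", l)]] <- he_upconv(ch[l], ch[l + 1])
      params[[sprintf("up%d.b", l)]] <- numeric(ch[l])
      registry[[length(registry) + 1]] <-
        list(name = sprintf("up%d", l), kind = "upconv", counted = TRUE)
      for (b in seq_len(B))
        registry <- add_res_block(params, registry,
                                  sprintf("dec%d.b%d", l, b),
                                  if (b == 1) 2 * ch[l] else ch[l],
                                  ch[l], config$gn_groups)
    }
    registry <- add_res_block(params, registry, "head.b", ch[1], ch[1],
                              config$gn_groups)
    params[["out.W"]] <- he_conv(1, ch[1], 1)
    params[["out.b"]] <- numeric(1)
    registry[[length(registry) + 1]] <-
      list(name = "out", kind = "conv", counted = TRUE)
    net <- structure(list(config = config, params = params,
                          registry = registry, epoch = 0L, stage = "init"),
                     class = "resunet")
    tgt <- config$conv_layer_count_target
    if (!is.null(tgt) && count_conv_layers(net) != tgt)
      stop(sprintf("built network has %d convolution layers, target is %d",
                   count_conv_layers(net), tgt))
    net
  })
}

#' Count convolution layers of a built network
#'
#' Counting rule: every learned convolution on the transform path is
#' counted -- the stem, the two 3x3x3 convolutions of each residual block,
#' strided down-sampling convolutions, transposed up-sampling convolutions,
#' the head residual block, and the 1x1x1 output convolution. The 1x1x1
#' projections inside residual shortcuts belong to the identity path and
#' are not counted. The package's default configuration totals 52.
#'
#' @param network a `resunet`.
#' @return Integer layer count.
#' @export
count_conv_layers <- function(network) {
  stopifnot(inherits(network, "resunet"))
  sum(vapply(network$registry, function(e) isTRUE(e$counted), logical(1)))
}

n_parameters <- function(network) {
  sum(vapply(ls(network$params), function(nm) length(network$params[[nm]]),
             numeric(1)))
}

#' @export
print.resunet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<resunet> %d levels x %d blocks, base %d channels ",
                     "(x%d/level), %d conv layers, %s parameters\n"),
              cfg$n_levels, cfg$blocks_per_level, cfg$base_channels,
              cfg$channel_growth, count_conv_layers(x),
              format(n_parameters(x), big.mark = ",")))
  cat(sprintf("  group norm: %d groups; trained: %s (epoch %d)\n",
              cfg$gn_groups, x$stage, x$epoch))
  invisible(x)
}

check_input_shape <- function(network, dims) {
  div <- 2^(network$config$n_levels - 1)
  bad <- which(dims[1:3] %% div != 0)
  if (length(bad))
    stop(sprintf(
      "input axis %s has size %s, not divisible by %d (network has %d levels)",
      paste(bad, collapse = ","),
      paste(dims[bad], collapse = ","), div, network$config$n_levels))
  invisible(TRUE)
}

res_block_fwd <- function(p, prefix, x, groups) {
  W1 <- p[[paste0(prefix, ".conv1.W")]]
  h <- conv3_fwd(x, W1, p[[paste0(prefix, ".conv1.b")]])
  g1 <- gn_fwd(h, p[[paste0(prefix, ".gn1.gamma")]],
               p[[paste0(prefix, ".gn1.beta")]], groups)
  r1 <- relu_fwd(g1$y)
  h2 <- conv3_fwd(r1$y, p[[paste0(prefix, ".conv2.W")]],
                  p[[paste0(prefix, ".conv2.b")]])
  g2 <- gn_fwd(h2, p[[paste0(prefix, ".gn2.gamma")]],
               p[[paste0(prefix, ".gn2.beta")]], groups)
  has_proj <- exists(paste0(prefix, ".proj.W"), envir = p, inherits = FALSE)
  s <- if (has_proj)
    conv3_fwd(x, p[[paste0(prefix, ".proj.W")]],
              p[[paste0(prefix, ".proj.b")]], pad = 0L)
  else x
  out <- relu_fwd(s + g2$y)
  list(y = out$y,
       cache = list(x = x, g1 = g1, m1 = r1$mask, r1y = r1$y, g2 = g2,
                    mout = out$mask, has_proj = has_proj))
}

res_block_bwd <- function(p, prefix, cache, dy, groups, grads) {
  dsum <- relu_bwd(cache$mout, dy)
  gb2 <- gn_bwd(cache$g2, p[[paste0(prefix, ".gn2.gamma")]], dsum)
  grads[[paste0(prefix, ".gn2.gamma")]] <- gb2$dgamma
  grads[[paste0(prefix, ".gn2.beta")]] <- gb2$dbeta
  cb2 <- conv3_bwd(cache$r1y, p[[paste0(prefix, ".conv2.W")]], gb2$dx)
  grads[[paste0(prefix, ".conv2.W")]] <- cb2$dW
  grads[[paste0(prefix, ".conv2.b")]] <- cb2$db
  dg1y <- relu_bwd(cache$m1, cb2$dx)
  gb1 <- gn_bwd(cache$g1, p[[paste0(prefix, ".gn1.gamma")]], dg1y)
  grads[[paste0(prefix, ".gn1.gamma")]] <- gb1$dgamma
  grads[[paste0(prefix, ".gn1.beta")]] <- gb1$dbeta
  cb1 <- conv3_bwd(cache$x, p[[paste0(prefix, ".conv1.W")]], gb1$dx)
  grads[[paste0(prefix, ".conv1.W")]] <- cb1$dW
  grads[[paste0(prefix, ".conv1.b")]] <- cb1$db
  dx <- cb1$dx
  if (cache$has_proj) {
    pb <- conv3_bwd(cache$x, p[[paste0(prefix, ".proj.W")]], dsum, pad = 0L)
    grads[[paste0(prefix, ".proj.W")]] <- pb$dW
    grads[[paste0(prefix, ".proj.b")]] <- pb$db
    dx <- dx + pb$dx
  } else {
    dx <- dx + dsum
  }
  dx
}

# Full forward pass. `x` is a 4D array [D, H, W, 1]. Returns the sigmoid
# probability grid and (when requested) the cache needed for backprop.
net_forward <- function(network, x, want_cache = FALSE) {
  cfg <- network$config
  p <- network$params
  G <- cfg$gn_groups
  L <- cfg$n_levels
  B <- cfg$blocks_per_level
  check_input_shape(network, dim(x))
  caches <- if (want_cache) list(x_in = x) else NULL

  a <- conv3_fwd(x, p[["stem.W"]], p[["stem.b"]])
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    for (b in seq_len(B)) {
      rb <- res_block_fwd(p, sprintf("enc%d.b%d", l, b), a, G)
      if (want_cache) caches[[sprintf("enc%d.b%d", l, b)]] <- rb$cache
      a <- rb$y
    }
    if (l < L) {
      skips[[l]] <- a
      if (want_cache) caches[[sprintf("down%d.x", l)]] <- a
      a <- conv3_fwd(a, p[[sprintf("down%d.W", l)]],
                     p[[sprintf("down%d.b", l)]], stride = 2L)
    }
  }
  for (l in rev(seq_len(L - 1))) {
    if (want_cache) caches[[sprintf("up%d.x", l)]] <- a
    u <- upconv2_fwd(a, p[[sprintf("up%d.W", l)]], p[[sprintf("up%d.b", l)]])
    a <- concat_ch(u, skips[[l]])
    for (b in seq_len(B)) {
      rb <- res_block_fwd(p, sprintf("dec%d.b%d", l, b), a, G)
      if (want_cache) caches[[sprintf("dec%d.b%d", l, b)]] <- rb$cache
      a <- rb$y
    }
  }
  rb <- res_block_fwd(p, "head.b", a, G)
  if (want_cache) caches[["head.b"]] <- rb$cache
  if (want_cache) caches[["out.x"]] <- rb$y
  z <- conv3_fwd(rb$y, p[["out.W"]], p[["out.b"]], pad = 0L)
  prob <- sigmoid_fwd(z)
  if (want_cache) {
    caches[["prob"]] <- prob
    list(prob = prob, cache = caches)
  } else {
    list(prob = prob)
  }
}

# Backward pass from dL/dprob; returns gradients for every parameter.
net_backward <- function(network, cache, dprob) {
  cfg <- network$config
  p <- network$params
  G <- cfg$gn_groups
  L <- cfg$n_levels
  B <- cfg$blocks_per_level
  grads <- new_param_set()
  dz <- sigmoid_bwd(cache$prob, dprob)
  ob <- conv3_bwd(cache$out.x, p[["out.W"]], dz, pad = 0L)
  grads[["out.W"]] <- ob$dW
  grads[["out.b"]] <- ob$db
  da <- res_block_bwd(p, "head.b", cache[["head.b"]], ob$dx, G, grads)
  dskip <- vector("list", L)
  for (l in seq_len(L - 1)) {
    for (b in rev(seq_len(B)))
      da <- res_block_bwd(p, sprintf("dec%d.b%d", l, b),
                          cache[[sprintf("dec%d.b%d", l, b)]], da, G, grads)
    ch_up <- cfg$channels[l]
    sp <- split_ch(da, ch_up)
    dskip[[l]] <- sp[[2]]
    ub <- upconv2_bwd(cache[[sprintf("up%d.x", l)]],
                      p[[sprintf("up%d.W", l)]], sp[[1]])
    grads[[sprintf("up%d.W", l)]] <- ub$dW
    grads[[sprintf("up%d.b", l)]] <- ub$db
    da <- ub$dx
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      db_ <- conv3_bwd(cache[[sprintf("down%d.x", l)]],
                       p[[sprintf("down%d.W", l)]], da, stride = 2L)
      grads[[sprintf("down%d.W", l)]] <- db_$dW
      grads[[sprintf("down%d.b", l)]] <- db_$db
      da <- db_$dx + dskip[[l]]
    }
    for (b in rev(seq_len(B)))
      da <- res_block_bwd(p, sprintf("enc%d.b%d", l, b),
                          cache[[sprintf("enc%d.b%d", l, b)]], da, G, grads)
  }
  sb <- conv3_bwd(cache$x_in, p[["stem.W"]], da)
  grads[["stem.W"]] <- sb$dW
  grads[["stem.b"]] <- sb$db
  grads
}

#' Forward pass over one or more volumes
#'
#' Applies the network to full input grids (no cropping) and returns
#' per-voxel lesion probabilities in `[0, 1]` with the same spatial shape
#' as each input. Inputs are standardized (zero mean, unit variance) before
#' entering the network; see the package vignette.
#'
#' @param network a `resunet`.
#' @param volumes a [les_volume()], a bare 3D array, or a list of either.
#' @return A single [les_probmap()] (or bare array for bare-array input),
#'   or a list of them for list input.
#' @export
forward <- function(network, volumes) {
  stopifnot(inherits(network, "resunet"))
  if (is.list(volumes) && !inherits(volumes, "les_volume"))
    return(lapply(volumes, forward, network = network))
  one <- function(v) {
    arr <- grid_data(v)
    x <- standardize_input(arr)
    dim(x) <- c(dim(arr), 1L)
    out <- net_forward(network, x)$prob
    dim(out) <- dim(arr)
    out
  }
  if (inherits(volumes, "les_volume"))
    les_probmap(one(volumes), volumes$spacing, volumes$scan_id)
  else one(volumes)
}

# Per-input standardization applied before every forward pass (training and
# inference alike): zero mean, unit variance, guarded for flat inputs.
standardize_input <- function(arr) {
  s <- sd(arr)
  (arr - mean(arr)) / (if (is.finite(s) && s > 1e-8) s else 1)
}

#' Save / load network checkpoints
#'
#' A checkpoint is a single file holding the parameter arrays, the
#' `network_config`, and the training stage/epoch at capture time.
#'
#' @param network a `resunet`.
#' @param path checkpoint file path (`.rds`).
#' @return `load_checkpoint` returns the restored `resunet`;
#'   `save_checkpoint` returns `path` invisibly.
#' @export
save_checkpoint <- function(network, path) {
  stopifnot(inherits(network, "resunet"))
  pl <- mget(ls(network$params), envir = network$params)
  saveRDS(list(format = "lesionseg-checkpoint-1", config = network$config,
               params = pl, epoch = network$epoch, stage = network$stage),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "lesionseg-checkpoint-1"))
    stop("not a lesionseg checkpoint: ", path)
  net <- build_network(ck$config, seed = 1L)
  for (nm in names(ck$params)) net$params[[nm]] <- ck$params[[nm]]
  net$epoch <- ck$epoch
  net$stage <- ck$stage
  net
}

# Deep-copy a network (parameters live in an environment).
clone_network <- function(network) {
  params <- new_param_set()
  for (nm in ls(network$params)) params[[nm]] <- network$params[[nm]]
  network$params <- params
  network
}
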