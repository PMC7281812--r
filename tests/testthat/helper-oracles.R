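# Independent brute-force oracles and small fixture generators used across
# the test files. The oracles deliberately share no code with the package:
# surface extraction by explicit neighbor loops, distances by all-pairs.

oracle_surface <- function(m) {
  m <- if (is.list(m)) m$data else m
  d <- dim(m)
  coords <- which(m > 0, arr.ind = TRUE)
  if (nrow(coords) == 0) return(coords)
  keep <- apply(coords, 1, function(v) {
    for (ax in 1:3) {
      for (dd in c(-1L, 1L)) {
        w <- v
        w[ax] <- w[ax] + dd
        if (w[ax] < 1 || w[ax] > d[ax]) return(TRUE)
        if (m[w[1], w[2], w[3]] == 0) return(TRUE)
      }
    }
    FALSE
  })
  coords[keep, , drop = FALSE]
}

oracle_surface_dists <- function(pred, ref, spacing = c(1, 1, 1)) {
  sp <- oracle_surface(pred)
  sr <- oracle_surface(ref)
  if (nrow(sp) == 0 || nrow(sr) == 0)
    return(list(hd = NA_real_, assd = NA_real_))
  X <- sweep(sp, 2, spacing, "*")
  Y <- sweep(sr, 2, spacing, "*")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  dmat <- sqrt(pmax(d2, 0))
  d_pr <- apply(dmat, 1, min)
  d_rp <- apply(dmat, 2, min)
  list(hd = max(max(d_pr), max(d_rp)),
       assd = (sum(d_pr) + sum(d_rp)) / (length(d_pr) + length(d_rp)))
}

oracle_confusion <- function(pred, ref) {
  p <- (if (is.list(pred)) pred$data else pred) > 0
  r <- (if (is.list(ref)) ref$data else ref) > 0
  c(tp = sum(p & r), fp = sum(p & !r), fn = sum(!p & r))
}

# Random binary test masks: sparse noise or a random box, sometimes empty.
random_mask_array <- function(dims, style = c("noise", "box", "empty")) {
  style <- match.arg(style)
  m <- array(0, dims)
  if (style == "noise") {
    m[runif(prod(dims)) < 0.15] <- 1
  } else if (style == "box") {
    lo <- sapply(dims, function(n) sample.int(n, 1))
    hi <- pmin(dims, lo + sapply(dims, function(n) sample.int(4, 1)))
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  }
  m
}

# Small phantom settings reused by several test files: a 32^3 grid with
# lesion volumes scaled to fit the phantom brain.
small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(32, 32, 32),
                 lesion_volume_range_mm3 = c(50, 800), ...)
}

with_seed_arr <- function(seed, expr) {
  set.seed(seed)
  expr
}

tiny_network_config <- function(...) {
  network_config(n_levels = 2L, base_channels = 4L, blocks_per_level = 1L,
                 gn_groups = 2L, conv_layer_count_target = NULL, ...)
}
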