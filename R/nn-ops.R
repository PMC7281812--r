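# Differentiable primitives for the 3D segmentation network. Activations
# are 4D arrays [D, H, W, C]; every *_fwd returns the output plus whatever
# the matching *_bwd needs. Convolution weights are 5D arrays
# (k, k, k, C_in, C_out); transposed-convolution weights (2, 2, 2, C_out,
# C_in). Heavy lifting (im2col + GEMM) is in compiled code.

as_conv_mat <- function(W5) {
  d <- dim(W5)
  matrix(W5, nrow = d[1] * d[2] * d[3] * d[4], ncol = d[5])
}

conv3_fwd <- function(x, W5, b, stride = 1L, pad = NULL) {
  k <- dim(W5)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  cpp_conv3_fwd(x, dim(x), as_conv_mat(W5), b, k, as.integer(stride),
                as.integer(pad))
}

conv3_bwd <- function(x, W5, dy, stride = 1L, pad = NULL) {
  k <- dim(W5)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  out <- cpp_conv3_bwd(x, dim(x), as_conv_mat(W5), dy, k,
                       as.integer(stride), as.integer(pad))
  dW <- out$dW
  dim(dW) <- dim(W5)
  list(dx = out$dx, dW = dW, db = out$db)
}

# Group normalization over (spatial x channels-in-group), one sample.
gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  n_sp <- prod(d[1:3])
  cg <- C %/% groups
  gm <- matrix(x, nrow = n_sp * cg, ncol = groups)
  mu <- colMeans(gm)
  va <- colMeans(gm * gm) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(gm, 2, mu, "-"), 2, inv, "*")
  y <- xhat
  dim(y) <- c(n_sp, C)
  y <- y * rep(gamma, each = n_sp) + rep(beta, each = n_sp)
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, dims = d)
}

gn_bwd <- function(cache, gamma, dy) {
  d <- cache$dims
  C <- d[4]
  n_sp <- prod(d[1:3])
  groups <- length(cache$inv)
  cg <- C %/% groups
  dym <- matrix(dy, nrow = n_sp, ncol = C)
  xhat_ch <- cache$xhat
  dim(xhat_ch) <- c(n_sp, C)
  dgamma <- colSums(dym * xhat_ch)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = n_sp)
  dim(dxhat) <- c(n_sp * cg, groups)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, m1, "-") - sweep(cache$xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cache$inv, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, mask = mask)
}

relu_bwd <- function(mask, dy) {
  dy[!mask] <- 0
  dy
}

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

sigmoid_bwd <- function(y, dy) dy * y * (1 - y)

# Transposed convolution, kernel 2, stride 2 (exact x2 upsampling).
upconv2_fwd <- function(x, W, b) {
  d <- dim(x)
  cin <- d[4]
  cout <- dim(W)[4]
  n <- prod(d[1:3])
  Wm <- matrix(W, nrow = 8 * cout, ncol = cin)
  P <- matrix(x, nrow = n, ncol = cin) %*% t(Wm)   # n x 8*cout
  dim(P) <- c(d[1], d[2], d[3], 2, 2, 2, cout)
  y <- aperm(P, c(4, 1, 5, 2, 6, 3, 7))
  dim(y) <- c(2 * d[1], 2 * d[2], 2 * d[3], cout)
  y + rep(b, each = 8 * n)
}

upconv2_bwd <- function(x, W, dy) {
  d <- dim(x)
  cin <- d[4]
  cout <- dim(W)[4]
  n <- prod(d[1:3])
  db <- colSums(matrix(dy, ncol = cout))
  dim(dy) <- c(2, d[1], 2, d[2], 2, d[3], cout)
  dP <- aperm(dy, c(2, 4, 6, 1, 3, 5, 7))
  dim(dP) <- c(n, 8 * cout)
  Wm <- matrix(W, nrow = 8 * cout, ncol = cin)
  dx <- dP %*% Wm
  dim(dx) <- d
  dW <- t(dP) %*% matrix(x, nrow = n, ncol = cin)
  dim(dW) <- dim(W)
  list(dx = dx, dW = dW, db = db)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- c(a, b)
  dim(y) <- c(da[1:3], da[4] + db[4])
  y
}

split_ch <- function(dy, c1) {
  d <- dim(dy)
  n <- prod(d[1:3])
  m <- matrix(dy, nrow = n)
  a <- m[, seq_len(c1), drop = FALSE]
  b <- m[, -seq_len(c1), drop = FALSE]
  dim(a) <- c(d[1:3], c1)
  dim(b) <- c(d[1:3], d[4] - c1)
  list(a, b)
}

# He-style initialization, deterministic under the caller's RNG state.
he_conv <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

he_upconv <- function(cout, cin) {
  array(rnorm(8 * cout * cin, sd = sqrt(2 / cin)),
        dim = c(2, 2, 2, cout, cin))
}
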