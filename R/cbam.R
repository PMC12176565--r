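#' Convolutional Block Attention Module (CBAM)
#'
#' CBAM refines a feature map with two sequential multiplicative attention
#' submodules. Channel attention pools the map spatially (global average and
#' global max), passes both pooled vectors through a shared bottleneck MLP,
#' sums the branches and applies a sigmoid, giving one weight per channel.
#' Spatial attention then pools the channel-refined map across channels
#' (mean and max), convolves the two-channel result with a single k x k
#' kernel and applies a sigmoid, giving one weight per pixel. Both weight
#' maps lie strictly in (0, 1), so CBAM is an elementwise contraction.
#'
#' @name cbam
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Channel-attention parameters
#'
#' The shared MLP is `w1 %*% relu(w0 %*% x)` with `w0` of shape
#' `(C/r) x C` and `w1` of shape `C x (C/r)`, no biases. For layers narrower
#' than `r` the hidden width is clamped to 1; otherwise `r` must divide `C`.
#'
#' @param n_channels number of channels C of the feature map
#' @param r reduction ratio (default 16)
#' @param w0,w1 optional weight matrices (random Glorot init if omitted)
#' @return an object of class `channel_attention_params`
#' @export
channel_attention_params <- function(n_channels, r = 16L, w0 = NULL, w1 = NULL) {
  C <- as.integer(n_channels)
  r <- as.integer(r)
  if (r <= 0) stop("reduction ratio must be positive")
  if (C >= r && C %% r != 0L) {
    stop(sprintf("reduction ratio %d does not divide channel count %d", r, C))
  }
  hidden <- max(1L, C %/% r)
  if (is.null(w0)) w0 <- matrix(rnorm(hidden * C, sd = sqrt(2 / (C + hidden))),
                                hidden, C)
  if (is.null(w1)) w1 <- matrix(rnorm(C * hidden, sd = sqrt(2 / (C + hidden))),
                                C, hidden)
  stopifnot(nrow(w0) == hidden, ncol(w0) == C,
            nrow(w1) == C, ncol(w1) == hidden)
  structure(list(w0 = w0, w1 = w1, r = r), class = "channel_attention_params")
}

#' Spatial-attention parameters
#'
#' A single k x k convolution over the 2-channel (mean-pool, max-pool)
#' stack, with one bias. `k` must be odd so "same" zero padding centres the
#' kernel.
#'
#' @param k kernel size (odd, default 7)
#' @param kernel optional `k x k x 2` array (random Glorot init if omitted)
#' @param bias scalar bias (default 0)
#' @return an object of class `spatial_attention_params`
#' @export
spatial_attention_params <- function(k = 7L, kernel = NULL, bias = 0) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("spatial attention kernel size must be odd")
  if (is.null(kernel)) {
    kernel <- array(rnorm(k * k * 2, sd = sqrt(2 / (k * k * 2 + 1))), c(k, k, 2))
  }
  stopifnot(identical(dim(kernel), c(k, k, 2L)) ||
              identical(dim(kernel), as.integer(c(k, k, 2))))
  structure(list(kernel = kernel, bias = bias, k = k),
            class = "spatial_attention_params")
}

#' Channel attention weights
#'
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with the MLP shared
#' between branches; pooling is global over the spatial dimensions.
#'
#' @param fmap feature map, array of dim `c(H, W, C)`
#' @param p a [channel_attention_params()]
#' @return numeric vector of length C, entries strictly in (0, 1)
#' @export
channel_attention <- function(fmap, p) {
  stopifnot(length(dim(fmap)) == 3L, inherits(p, "channel_attention_params"))
  C <- dim(fmap)[3]
  stopifnot(ncol(p$w0) == C)
  fm <- matrix(fmap, ncol = C)
  avg <- colMeans(fm)
  mxv <- apply(fm, 2, max)
  mlp <- function(x) as.vector(p$w1 %*% pmax(p$w0 %*% x, 0))
  sigmoid(mlp(avg) + mlp(mxv))
}

#' Spatial attention map
#'
#' `Ms = sigmoid(conv2d_same(cbind(mean_C(F), max_C(F)), kernel) + bias)`,
#' zero-padded "same" convolution.
#'
#' @param fmap feature map, array of dim `c(H, W, C)`
#' @param p a [spatial_attention_params()]
#' @return `H x W` matrix, entries strictly in (0, 1)
#' @export
spatial_attention <- function(fmap, p) {
  stopifnot(length(dim(fmap)) == 3L, inherits(p, "spatial_attention_params"))
  d <- dim(fmap)
  fm <- matrix(fmap, ncol = d[3])
  s <- array(c(rowMeans(fm), apply(fm, 1, max)), c(d[1], d[2], 2))
  km <- matrix(p$kernel, p$k * p$k * 2L, 1L)
  z <- conv2d_fwd(s, km, p$bias, p$k)
  matrix(sigmoid(as.vector(z)), d[1], d[2])
}

#' Apply CBAM to a feature map
#'
#' Channel attention first (`F1 = Mc * F`, broadcast over space), then
#' spatial attention computed from the channel-refined map
#' (`F2 = Ms * F1`, broadcast over channels). Output shape equals input
#' shape, and every nonzero entry shrinks in magnitude.
#'
#' @param fmap feature map, array of dim `c(H, W, C)`
#' @param cp a [channel_attention_params()]
#' @param sp a [spatial_attention_params()]
#' @return refined feature map, same dim as `fmap`
#' @export
apply_cbam <- function(fmap, cp, sp) {
  d <- dim(fmap)
  mc <- channel_attention(fmap, cp)
  f1 <- array(as.vector(fmap) * rep(mc, each = d[1] * d[2]), d)
  ms <- spatial_attention(f1, sp)
  array(as.vector(f1) * rep(as.vector(ms), d[3]), d)
}

# ---- training-time forward/backward (shared parameter layout) ------------

cbam_init <- function(C, r, k) {
  cp <- channel_attention_params(C, r)
  sp <- spatial_attention_params(k)
  list(w0 = cp$w0, w1 = cp$w1, kernel = sp$kernel, bias = sp$bias)
}

cbam_fwd <- function(fmap, pars, k) {
  d <- dim(fmap)
  hw <- d[1] * d[2]
  C <- d[3]
  fm <- matrix(fmap, hw, C)
  avg <- colMeans(fm)
  mxidx_c <- apply(fm, 2, which.max)
  mxv <- fm[cbind(mxidx_c, seq_len(C))]
  h_a <- as.vector(pars$w0 %*% avg)
  h_m <- as.vector(pars$w0 %*% mxv)
  a <- as.vector(pars$w1 %*% pmax(h_a, 0)) + as.vector(pars$w1 %*% pmax(h_m, 0))
  mc <- sigmoid(a)
  f1m <- fm * rep(mc, each = hw)
  avg_map <- rowMeans(f1m)
  mxidx_s <- max.col(f1m, ties.method = "first")
  mx_map <- f1m[cbind(seq_len(hw), mxidx_s)]
  s <- array(c(avg_map, mx_map), c(d[1], d[2], 2))
  km <- matrix(pars$kernel, length(pars$kernel), 1L)
  z <- conv2d_fwd(s, km, pars$bias, k)
  ms <- as.vector(z)
  ms <- sigmoid(ms)
  out <- array(as.vector(f1m) * rep(ms, C), d)
  cache <- list(d = d, fm = fm, f1m = f1m, avg = avg, mxv = mxv,
                mxidx_c = mxidx_c, mxidx_s = mxidx_s, h_a = h_a, h_m = h_m,
                mc = mc, ms = ms, s = s, k = k)
  list(out = out, cache = cache)
}

cbam_bwd <- function(dout, cache, pars) {
  d <- cache$d
  hw <- d[1] * d[2]
  C <- d[3]
  doutm <- matrix(dout, hw, C)
  # spatial attention
  dms <- rowSums(doutm * cache$f1m)
  df1m <- doutm * cache$ms
  dz <- dms * cache$ms * (1 - cache$ms)
  km <- matrix(pars$kernel, length(pars$kernel), 1L)
  cb <- conv2d_bwd(cache$s, km, array(dz, c(d[1], d[2], 1)), cache$k)
  ds <- cb$dx
  dkernel <- array(cb$dw, dim(pars$kernel))
  dbias <- cb$db
  davg_map <- as.vector(ds[, , 1])
  dmx_map <- as.vector(ds[, , 2])
  df1m <- df1m + matrix(davg_map / C, hw, C)
  df1m[cbind(seq_len(hw), cache$mxidx_s)] <-
    df1m[cbind(seq_len(hw), cache$mxidx_s)] + dmx_map
  # channel attention
  dmc <- colSums(df1m * cache$fm)
  dfm <- df1m * rep(cache$mc, each = hw)
  da <- dmc * cache$mc * (1 - cache$mc)
  hr_a <- pmax(cache$h_a, 0)
  hr_m <- pmax(cache$h_m, 0)
  dhr <- as.vector(crossprod(pars$w1, da))
  dh_a <- dhr * (cache$h_a > 0)
  dh_m <- dhr * (cache$h_m > 0)
  dw1 <- outer(da, hr_a) + outer(da, hr_m)
  dw0 <- outer(dh_a, cache$avg) + outer(dh_m, cache$mxv)
  dp_avg <- as.vector(crossprod(pars$w0, dh_a))
  dp_max <- as.vector(crossprod(pars$w0, dh_m))
  dfm <- dfm + matrix(dp_avg / hw, hw, C, byrow = TRUE)
  dfm[cbind(cache$mxidx_c, seq_len(C))] <-
    dfm[cbind(cache$mxidx_c, seq_len(C))] + dp_max
  list(dx = array(dfm, d),
       grads = list(w0 = dw0, w1 = dw1, kernel = dkernel, bias = dbias))
}
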