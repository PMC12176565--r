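test_that("zero parameters give attention 0.5 everywhere", {
  f <- random_feature_map(3, 4, 4)
  cp <- channel_attention_params(4, r = 2,
                                 w0 = matrix(0, 2, 4), w1 = matrix(0, 4, 2))
  expect_equal(channel_attention(f, cp), rep(0.5, 4))
  sp <- spatial_attention_params(k = 3, kernel = array(0, c(3, 3, 2)),
                                 bias = 0)
  expect_equal(spatial_attention(f, sp), matrix(0.5, 3, 4))
})

test_that("spatially-constant maps collapse avg and max branches", {
  set.seed(31)
  C <- 4
  vals <- rnorm(C)
  f <- array(rep(vals, each = 6), c(2, 3, C))
  cp <- channel_attention_params(C, r = 2)
  mc <- channel_attention(f, cp)
  mlp <- function(x) as.vector(cp$w1 %*% pmax(cp$w0 %*% x, 0))
  expect_equal(mc, 1 / (1 + exp(-2 * mlp(vals))), tolerance = 1e-12)
})

test_that("vectorized attention matches the scalar-loop oracle", {
  set.seed(32)
  for (i in 1:25) {
    h <- sample(2:6, 1)
    w <- sample(2:6, 1)
    C <- sample(c(2, 4, 6, 8), 1)
    f <- random_feature_map(h, w, C)
    cp <- channel_attention_params(C, r = 2)
    expect_equal(channel_attention(f, cp),
                 oracle_channel_attention(f, cp$w0, cp$w1),
                 tolerance = 1e-10)
    k <- sample(c(3, 5), 1)
    sp <- spatial_attention_params(k = k)
    expect_equal(spatial_attention(f, sp),
                 oracle_spatial_attention(f, sp$kernel, sp$bias),
                 tolerance = 1e-10)
  }
})

test_that("full CBAM equals the composition of its submodules", {
  set.seed(33)
  f <- random_feature_map(2, 2, 2)
  cp <- channel_attention_params(2, r = 2)
  sp <- spatial_attention_params(k = 3)
  out <- apply_cbam(f, cp, sp)
  mc <- oracle_channel_attention(f, cp$w0, cp$w1)
  f1 <- f
  for (c in 1:2) f1[, , c] <- f[, , c] * mc[c]
  ms <- oracle_spatial_attention(f1, sp$kernel, sp$bias)
  f2 <- f1
  for (c in 1:2) f2[, , c] <- f1[, , c] * ms
  expect_equal(out, f2, tolerance = 1e-10)
})

test_that("CBAM preserves shape and strictly contracts nonzero entries", {
  set.seed(34)
  f <- random_feature_map(5, 4, 4)
  cp <- channel_attention_params(4, r = 2)
  sp <- spatial_attention_params(k = 7)
  out <- apply_cbam(f, cp, sp)
  expect_equal(dim(out), dim(f))
  nz <- f != 0
  expect_true(all(abs(out[nz]) < abs(f[nz])))
  expect_equal(apply_cbam(array(0, dim(f)), cp, sp), array(0, dim(f)))
})

test_that("channel attention is equivariant under channel permutation", {
  set.seed(35)
  C <- 6
  f <- random_feature_map(3, 3, C)
  cp <- channel_attention_params(C, r = 2)
  perm <- sample(C)
  fp <- f[, , perm]
  cpp <- channel_attention_params(C, r = 2,
                                  w0 = cp$w0[, perm], w1 = cp$w1[perm, ])
  expect_equal(channel_attention(fp, cpp), channel_attention(f, cp)[perm],
               tolerance = 1e-12)
})

test_that("invalid attention parameters are rejected at construction", {
  expect_error(channel_attention_params(6, r = 4), "does not divide")
  expect_error(spatial_attention_params(k = 4), "odd")
  # clamping: hidden width 1 when the layer is narrower than r
  cp <- channel_attention_params(8, r = 16)
  expect_equal(nrow(cp$w0), 1L)
})

test_that("training-time CBAM gradients match finite differences", {
  set.seed(36)
  f <- random_feature_map(4, 5, 4)
  pars <- pcgcbam:::cbam_init(4, 2, 3)
  fw <- pcgcbam:::cbam_fwd(f, pars, 3)
  dout <- random_feature_map(4, 5, 4)
  bw <- pcgcbam:::cbam_bwd(dout, fw$cache, pars)
  lossfn <- function(p) sum(pcgcbam:::cbam_fwd(f, p, 3)$out * dout)
  h <- 1e-6
  for (field in c("w0", "w1", "kernel", "bias")) {
    g <- bw$grads[[field]]
    for (i in seq_len(min(5, length(g)))) {
      p2 <- pars
      p2[[field]][i] <- p2[[field]][i] + h
      p3 <- pars
      p3[[field]][i] <- p3[[field]][i] - h
      fd <- (lossfn(p2) - lossfn(p3)) / (2 * h)
      expect_equal(as.numeric(g[i]), fd, tolerance = 1e-5)
    }
  }
})
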