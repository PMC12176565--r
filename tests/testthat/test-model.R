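tiny_shape <- c(16L, 24L)

test_that("model ids map to the expected CBAM module counts and widths", {
  m1 <- build_model(model_from_id(1, input_shape = tiny_shape), seed = 1)
  expect_equal(count_cbam_modules(m1), 0)
  m7 <- build_model(model_from_id(7, input_shape = tiny_shape), seed = 1)
  expect_equal(count_cbam_modules(m7), 3)
  widths <- vapply(which(m7$cfg$cbam_mask),
                   function(i) ncol(m7$params$cbam[[i]]$w0), integer(1))
  expect_equal(widths, c(32L, 32L, 64L))
  expect_error(model_from_id(0), "1..12")
  expect_error(model_from_id(13), "1..12")
})

test_that("parameter counts follow the closed-form layer arithmetic", {
  m1 <- build_model(model_from_id(1, input_shape = tiny_shape), seed = 1)
  # first conv block: 32 filters of 3x3x1 plus biases
  expect_equal(length(m1$params$conv[[1]]$W) + length(m1$params$conv[[1]]$b),
               320)
  conv_total <- sum(vapply(m1$params$conv, function(l)
    length(l$W) + length(l$b), integer(1)))
  expect_equal(conv_total, 286432)
  m12 <- build_model(model_from_id(12, input_shape = tiny_shape), seed = 1)
  expect_gt(count_parameters(m12), count_parameters(m1))
})

test_that("softmax outputs are a probability vector for arbitrary inputs", {
  m <- build_model(model_from_id(7, input_shape = tiny_shape), seed = 2)
  for (x in list(matrix(0, 16, 24), matrix(rnorm(16 * 24), 16, 24))) {
    p <- model_predict(m, x)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("checkpoints reload to identical forward passes", {
  m <- build_model(model_from_id(7, input_shape = tiny_shape), seed = 3)
  x <- matrix(rnorm(16 * 24), 16, 24)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(model_predict(m, x), model_predict(m2, x))
})

test_that("inputs that do not survive three poolings are rejected", {
  expect_error(build_model(model_config(input_shape = c(4, 64))),
               "stage")
})

test_that("network gradients match finite differences end to end", {
  cfg <- model_config(input_shape = c(8L, 12L), filters = c(4, 4, 6, 6, 8, 8),
                      cbam_mask = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
                      cbam_r = 2, cbam_k = 3, conv_dropout = 0, fc_dropout = 0,
                      fc_units = 7)
  m <- build_model(cfg, seed = 3)
  set.seed(9)
  x <- matrix(rnorm(8 * 12), 8, 12)
  lossfn <- function(model) {
    -log(pcgcbam:::net_forward(model, x, training = TRUE)$prob[2])
  }
  fw <- pcgcbam:::net_forward(m, x, training = TRUE)
  g <- pcgcbam:::net_backward(m, fw$caches, fw$prob - c(0, 1))
  h <- 1e-6
  spots <- list(
    list(get = function(mm) mm$params$conv[[2]]$W,
         set = function(mm, v) { mm$params$conv[[2]]$W[] <- v; mm },
         grad = g$conv[[2]]$W),
    list(get = function(mm) mm$params$cbam[[3]]$w1,
         set = function(mm, v) { mm$params$cbam[[3]]$w1[] <- v; mm },
         grad = g$cbam[[3]]$w1),
    list(get = function(mm) mm$params$cbam[[6]]$kernel,
         set = function(mm, v) { mm$params$cbam[[6]]$kernel[] <- v; mm },
         grad = g$cbam[[6]]$kernel),
    list(get = function(mm) mm$params$fc1$W,
         set = function(mm, v) { mm$params$fc1$W[] <- v; mm },
         grad = g$fc1$W))
  for (sp in spots) {
    idx <- sample(length(sp$get(m)), 4)
    for (i in idx) {
      m2 <- m; v <- sp$get(m2); v[i] <- v[i] + h; m2 <- sp$set(m2, v)
      m3 <- m; v <- sp$get(m3); v[i] <- v[i] - h; m3 <- sp$set(m3, v)
      fd <- (lossfn(m2) - lossfn(m3)) / (2 * h)
      expect_equal(as.numeric(sp$grad[i]), fd, tolerance = 1e-4)
    }
  }
})
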