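#' CBAM placement mask for one of the twelve ablation models
#'
#' The backbone has six convolutional blocks, ordered 1-1, 1-2, 2-1, 2-2,
#' 3-1, 3-2. Each of the twelve models toggles CBAM after a different subset
#' of blocks: model 1 is the plain backbone, model 12 attaches CBAM after
#' every block, and model 7 (the strongest placement) attaches it after
#' blocks 1-1, 1-2 and 2-1.
#'
#' @param model_id integer in 1..12
#' @param ... overrides passed to [model_config()]
#' @return a [model_config()] with the corresponding `cbam_mask`
#' @export
model_from_id <- function(model_id, ...) {
  masks <- matrix(c(
    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,  # 1
    TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE,  # 2
    FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE,  # 3
    TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE,  # 4
    FALSE, FALSE, TRUE,  FALSE, FALSE, FALSE,  # 5
    FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE,  # 6
    TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE,  # 7
    TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE,  # 8
    FALSE, FALSE, FALSE, FALSE, TRUE,  FALSE,  # 9
    FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,   # 10
    TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  FALSE,  # 11
    TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE    # 12
  ), nrow = 12, byrow = TRUE)
  if (!is.numeric(model_id) || length(model_id) != 1 ||
      model_id < 1 || model_id > 12 || model_id != round(model_id)) {
    stop("model_id must be an integer in 1..12")
  }
  model_config(cbam_mask = masks[model_id, ], ...)
}

#' Backbone configuration
#'
#' Three convolutional stages of two 3x3 conv blocks each (32/32, 64/64,
#' 128/128 filters, stride 1, "same" padding, ReLU), each stage followed by
#' 2x2 max pooling and dropout 0.2; then a 500-unit fully connected layer
#' with ReLU and dropout 0.3, and a softmax output. CBAM modules are
#' attached after the activation of the blocks flagged in `cbam_mask`
#' (before pooling).
#'
#' @param input_shape `c(height, width)` of the input image (single channel)
#' @param filters filter counts for the six conv blocks
#' @param kernel conv kernel size (odd)
#' @param conv_dropout,fc_dropout dropout rates
#' @param fc_units fully connected width
#' @param n_classes number of output classes
#' @param cbam_mask logical vector of length 6 (blocks 1-1 … 3-2)
#' @param cbam_r CBAM reduction ratio
#' @param cbam_k CBAM spatial kernel size (odd)
#' @return an object of class `model_config`
#' @export
model_config <- function(input_shape = c(126L, 216L),
                         filters = c(32L, 32L, 64L, 64L, 128L, 128L),
                         kernel = 3L, conv_dropout = 0.2, fc_units = 500L,
                         fc_dropout = 0.3, n_classes = 2L,
                         cbam_mask = rep(FALSE, 6L),
                         cbam_r = 16L, cbam_k = 7L) {
  stopifnot(length(input_shape) == 2, length(filters) == 6,
            length(cbam_mask) == 6, kernel %% 2 == 1, cbam_k %% 2 == 1,
            n_classes >= 2)
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 conv_dropout = conv_dropout, fc_units = as.integer(fc_units),
                 fc_dropout = fc_dropout, n_classes = as.integer(n_classes),
                 cbam_mask = as.logical(cbam_mask),
                 cbam_r = as.integer(cbam_r), cbam_k = as.integer(cbam_k)),
            class = "model_config")
}

# spatial dims after each stage; errors if pooling exhausts the input
stage_dims <- function(cfg) {
  h <- cfg$input_shape[1]
  w <- cfg$input_shape[2]
  dims <- vector("list", 3)
  for (s in 1:3) {
    h <- h %/% 2L
    w <- w %/% 2L
    if (h < 1L || w < 1L) {
      stop(sprintf("input %dx%d too small: spatial size vanishes at stage %d",
                   cfg$input_shape[1], cfg$input_shape[2], s))
    }
    dims[[s]] <- c(h, w)
  }
  dims
}

#' Build a trainable model from a configuration
#'
#' Initializes conv/FC weights (He and Glorot) and, for every masked block,
#' a CBAM parameter set. Call `set.seed()` beforehand (or pass `seed`) for a
#' reproducible initialization.
#'
#' @param cfg a [model_config()]
#' @param seed optional integer seed for the weight initialization
#' @return an object of class `pcg_model`
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  dims <- stage_dims(cfg)
  k <- cfg$kernel
  cin <- c(1L, cfg$filters[-6])
  conv <- vector("list", 6)
  cbam <- vector("list", 6)
  for (i in 1:6) {
    fan_in <- k * k * cin[i]
    conv[[i]] <- list(
      W = array(rnorm(k * k * cin[i] * cfg$filters[i], sd = sqrt(2 / fan_in)),
                c(k, k, cin[i], cfg$filters[i])),
      b = numeric(cfg$filters[i]))
    if (cfg$cbam_mask[i]) {
      cbam[[i]] <- cbam_init(cfg$filters[i], cfg$cbam_r, cfg$cbam_k)
    }
  }
  flat <- dims[[3]][1] * dims[[3]][2] * cfg$filters[6]
  params <- list(
    conv = conv, cbam = cbam,
    fc1 = list(W = matrix(rnorm(flat * cfg$fc_units, sd = sqrt(2 / flat)),
                          flat, cfg$fc_units),
               b = numeric(cfg$fc_units)),
    fc2 = list(W = matrix(rnorm(cfg$fc_units * cfg$n_classes,
                                sd = sqrt(1 / cfg$fc_units)),
                          cfg$fc_units, cfg$n_classes),
               b = numeric(cfg$n_classes)))
  structure(list(cfg = cfg, params = params), class = "pcg_model")
}

#' Count trainable parameters
#'
#' @param model a `pcg_model`
#' @return total number of trainable scalars
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.numeric(x)) {
      n <<- n + length(x)
    }
  }
  walk(model$params)
  n
}

#' Number of CBAM modules in a model
#'
#' @param model a `pcg_model`
#' @return integer count
#' @export
count_cbam_modules <- function(model) sum(model$cfg$cbam_mask)

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Forward pass for one sample. x: array c(H, W, 1) or matrix H x W.
# Returns prob, stage-3 features (flattened, pre-FC), and caches when
# training = TRUE. Dropout uses the current RNG stream (training only).
net_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(identical(dim(x)[1:2], as.integer(cfg$input_shape)))
  k <- cfg$kernel
  a <- x
  caches <- if (training) list(conv = vector("list", 6),
                               relu = vector("list", 6),
                               cbam = vector("list", 6),
                               pool = vector("list", 3),
                               drop = vector("list", 5)) else NULL
  for (s in 1:3) {
    for (bk in 1:2) {
      li <- (s - 1L) * 2L + bk
      wm <- matrix(p$conv[[li]]$W, k * k * dim(a)[3], cfg$filters[li])
      z <- conv2d_fwd(a, wm, p$conv[[li]]$b, k)
      if (training) caches$conv[[li]] <- a
      a <- z * (z > 0)
      if (training) caches$relu[[li]] <- z > 0
      if (cfg$cbam_mask[li]) {
        cf <- cbam_fwd(a, p$cbam[[li]], cfg$cbam_k)
        a <- cf$out
        if (training) caches$cbam[[li]] <- cf$cache
      }
    }
    mp <- maxpool2_fwd(a)
    if (training) caches$pool[[s]] <- list(idx = mp$idx, dim = dim(a))
    a <- mp$y
    if (training) {
      mask <- array((runif(length(a)) > cfg$conv_dropout) /
                      (1 - cfg$conv_dropout), dim(a))
      caches$drop[[s]] <- mask
      a <- a * mask
    }
  }
  flat <- as.vector(a)
  h1 <- as.vector(crossprod(p$fc1$W, flat)) + p$fc1$b
  r1 <- h1 * (h1 > 0)
  if (training) {
    m1 <- (runif(length(r1)) > cfg$fc_dropout) / (1 - cfg$fc_dropout)
    caches$drop[[4]] <- m1
    r1d <- r1 * m1
  } else {
    r1d <- r1
  }
  z2 <- as.vector(crossprod(p$fc2$W, r1d)) + p$fc2$b
  prob <- softmax(z2)
  if (training) {
    caches$flat <- flat
    caches$dim3 <- dim(a)
    caches$h1 <- h1
    caches$r1d <- r1d
  }
  list(prob = prob, features = flat, caches = caches)
}

# Backward pass for one sample given dlogits (= prob - onehot for CE).
# Returns a gradient tree matching model$params.
net_backward <- function(model, caches, dlogits) {
  cfg <- model$cfg
  p <- model$params
  k <- cfg$kernel
  g <- list(conv = vector("list", 6), cbam = vector("list", 6),
            fc1 = NULL, fc2 = NULL)
  g$fc2 <- list(W = outer(caches$r1d, dlogits), b = dlogits)
  dr1d <- as.vector(p$fc2$W %*% dlogits)
  dr1 <- dr1d * caches$drop[[4]]
  dh1 <- dr1 * (caches$h1 > 0)
  g$fc1 <- list(W = outer(caches$flat, dh1), b = dh1)
  da <- array(as.vector(p$fc1$W %*% dh1), caches$dim3)
  for (s in 3:1) {
    da <- da * caches$drop[[s]]
    pd <- caches$pool[[s]]
    da <- maxpool2_bwd(da, pd$idx, pd$dim[1], pd$dim[2], pd$dim[3])
    for (bk in 2:1) {
      li <- (s - 1L) * 2L + bk
      if (cfg$cbam_mask[li]) {
        cb <- cbam_bwd(da, caches$cbam[[li]], p$cbam[[li]])
        da <- cb$dx
        g$cbam[[li]] <- cb$grads
      }
      dz <- da * caches$relu[[li]]
      xin <- caches$conv[[li]]
      wm <- matrix(p$conv[[li]]$W, k * k * dim(xin)[3], cfg$filters[li])
      cw <- conv2d_bwd(xin, wm, dz, k)
      g$conv[[li]] <- list(W = array(cw$dw, dim(p$conv[[li]]$W)), b = cw$db)
      da <- cw$dx
    }
  }
  g
}

#' Class probabilities for a list of images
#'
#' @param model a `pcg_model`
#' @param xs list of input matrices/arrays (or a single one)
#' @return matrix `n x n_classes` of softmax probabilities
#' @export
model_predict <- function(model, xs) {
  if (!is.list(xs)) xs <- list(xs)
  t(vapply(xs, function(x) net_forward(model, x)$prob,
           numeric(model$cfg$n_classes)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the configuration and all parameter arrays; a
#' reloaded model reproduces forward passes exactly.
#'
#' @param model a `pcg_model`
#' @param path checkpoint path
#' @return `path` invisibly (save); a `pcg_model` (load)
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pcg_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$cfg, "model_config"), is.list(obj$params))
  structure(list(cfg = obj$cfg, params = obj$params), class = "pcg_model")
}
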