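#' Extract last-convolutional-stage features
#'
#' Runs the network in inference mode (dropout off) and returns the
#' activations after the third stage's max pooling, flattened — the feature
#' space whose class separability the t-SNE statistics quantify.
#'
#' @param model a fitted `pcg_model`
#' @param data list with `x` (list of input matrices)
#' @return numeric matrix, one row per sample
#' @export
extract_features <- function(model, data) {
  xs <- data$x
  t(vapply(xs, function(x) net_forward(model, x)$features,
           numeric(feature_dim(model))))
}

feature_dim <- function(model) {
  d <- stage_dims(model$cfg)[[3]]
  d[1] * d[2] * model$cfg$filters[6]
}

#' Exact t-SNE embedding to two dimensions
#'
#' Exact (O(n^2)) t-SNE: per-point Gaussian bandwidths found by bisection to
#' match the target perplexity, symmetrized affinities, early exaggeration
#' (factor 4 for the first 100 iterations), and momentum gradient descent.
#' Fully seeded; identical inputs, parameters and seed give identical
#' coordinates.
#'
#' @param features numeric matrix, one row per sample
#' @param perplexity target perplexity (requires `nrow >= 3 * perplexity`)
#' @param n_iter gradient-descent iterations
#' @param seed integer seed for the initial coordinates
#' @param learning_rate gradient-descent step size
#' @return object of class `embedded_points`: `coords` (n x 2), and the
#'   parameters used
#' @export
tsne_embed <- function(features, perplexity = 30, n_iter = 1000L, seed = 0L,
                       learning_rate = 200) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3 * perplexity) {
    stop(sprintf("t-SNE needs at least %d points for perplexity %g (got %d)",
                 ceiling(3 * perplexity), perplexity, n))
  }
  d2 <- as.matrix(stats::dist(features))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (it in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta_hi <- beta; beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))   # Shannon entropy = log(perp)
      if (abs(h - target) < 1e-5) break
      if (h > target) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100) P * 4 else P
    dy2 <- as.matrix(stats::dist(Y))^2
    qnum <- 1 / (1 + dy2)
    diag(qnum) <- 0
    Q <- pmax(qnum / sum(qnum), 1e-12)
    M <- (Pe - Q) * qnum
    grad <- 4 * (Y * rowSums(M) - M %*% Y)
    momentum <- if (iter <= 250) 0.5 else 0.8
    inc <- momentum * inc - learning_rate * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  structure(list(coords = Y,
                 tsne_params = list(perplexity = perplexity, n_iter = n_iter,
                                    seed = seed)),
            class = "embedded_points")
}

#' Class-separability distances in an embedding
#'
#' With class centroids `mu_0` (normal) and `mu_1` (abnormal), the
#' intra-class distance of a class is the mean Euclidean distance of its
#' points to its centroid (`method = "centroid"`, default) or the mean
#' pairwise distance within the class (`method = "pairwise"`); the
#' inter-class centre distance is `||mu_0 - mu_1||`. All three statistics
#' are translation invariant and scale linearly with the coordinates.
#'
#' @param coords numeric matrix of embedded points (n x d), or an
#'   `embedded_points` object
#' @param labels binary labels (0/1), both classes present
#' @param method intra-class distance definition
#' @return named numeric vector: `intra_class_0`, `intra_class_1`,
#'   `inter_class_center_distance`
#' @export
class_distances <- function(coords, labels,
                            method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  if (inherits(coords, "embedded_points")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(labels), all(labels %in% 0:1))
  if (sum(labels == 0) == 0 || sum(labels == 1) == 0) {
    stop("both classes must be present")
  }
  intra <- function(x) {
    if (method == "centroid") {
      mu <- colMeans(x)
      mean(sqrt(rowSums(sweep(x, 2, mu)^2)))
    } else {
      if (nrow(x) < 2) 0 else mean(stats::dist(x))
    }
  }
  x0 <- coords[labels == 0, , drop = FALSE]
  x1 <- coords[labels == 1, , drop = FALSE]
  mu0 <- colMeans(x0)
  mu1 <- colMeans(x1)
  c(intra_class_0 = intra(x0), intra_class_1 = intra(x1),
    inter_class_center_distance = sqrt(sum((mu0 - mu1)^2)))
}
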