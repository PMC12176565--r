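# Independent scalar-loop reference implementations used as oracles.
# Deliberately naive: plain loops, no shared code with the package internals.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

oracle_channel_attention <- function(fmap, w0, w1) {
  d <- dim(fmap)
  C <- d[3]
  avg <- numeric(C)
  mx <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    m <- -Inf
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        v <- fmap[i, j, c]
        s <- s + v
        if (v > m) m <- v
      }
    }
    avg[c] <- s / (d[1] * d[2])
    mx[c] <- m
  }
  mlp <- function(x) {
    h <- numeric(nrow(w0))
    for (a in seq_len(nrow(w0))) {
      acc <- 0
      for (b in seq_len(ncol(w0))) acc <- acc + w0[a, b] * x[b]
      h[a] <- max(acc, 0)
    }
    out <- numeric(nrow(w1))
    for (a in seq_len(nrow(w1))) {
      acc <- 0
      for (b in seq_len(ncol(w1))) acc <- acc + w1[a, b] * h[b]
      out[a] <- acc
    }
    out
  }
  oracle_sigmoid(mlp(avg) + mlp(mx))
}

oracle_spatial_attention <- function(fmap, kernel, bias) {
  d <- dim(fmap)
  k <- dim(kernel)[1]
  p <- (k - 1) / 2
  pooled <- array(0, c(d[1], d[2], 2))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      pooled[i, j, 1] <- mean(fmap[i, j, ])
      pooled[i, j, 2] <- max(fmap[i, j, ])
    }
  }
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      acc <- bias
      for (di in seq_len(k)) {
        for (dj in seq_len(k)) {
          si <- i + di - 1 - p
          sj <- j + dj - 1 - p
          if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2]) {
            acc <- acc + kernel[di, dj, 1] * pooled[si, sj, 1] +
              kernel[di, dj, 2] * pooled[si, sj, 2]
          }
        }
      }
      out[i, j] <- oracle_sigmoid(acc)
    }
  }
  out
}

# AUC by exhaustive pair counting (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Power in a frequency band from the periodogram of the whole signal
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  mean(spec[sel])
}

random_feature_map <- function(h, w, c) array(rnorm(h * w * c), c(h, w, c))
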