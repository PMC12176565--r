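#' Training configuration
#'
#' Optimization schedule for all models: Adam (lr 0.001), batch size 10,
#' categorical cross-entropy, plateau learning-rate decay (factor 0.5 after
#' 5 epochs without validation-loss improvement, floored at 1e-7) and early
#' stopping after 15 epochs without improvement, restoring the best-epoch
#' weights. "Improvement" means a strict decrease of the monitored loss by
#' more than 1e-9.
#'
#' @param learning_rate initial Adam learning rate
#' @param batch_size minibatch size
#' @param lr_factor multiplicative learning-rate decay factor in (0, 1)
#' @param lr_patience epochs without improvement before decaying
#' @param min_lr learning-rate floor
#' @param es_patience epochs without improvement before stopping
#' @param max_epochs hard epoch cap (early stopping usually fires first)
#' @param seed integer seed for shuffling, dropout and weight init
#' @return an object of class `train_config`
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 10L,
                         lr_factor = 0.5, lr_patience = 5L, min_lr = 1e-7,
                         es_patience = 15L, max_epochs = 100L, seed = 0L) {
  stopifnot(lr_factor > 0, lr_factor < 1, lr_patience > 0, es_patience > 0,
            min_lr > 0, learning_rate > 0, batch_size > 0, max_epochs > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), min_lr = min_lr,
                 es_patience = as.integer(es_patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

IMPROVE_TOL <- 1e-9

new_schedule_state <- function(cfg) {
  list(best = Inf, best_epoch = 0L, epoch = 0L, wait_lr = 0L, wait_es = 0L,
       lr = cfg$learning_rate, stop = FALSE)
}

# One end-of-epoch step of the plateau scheduler + early stopping.
schedule_step <- function(st, loss, cfg) {
  st$epoch <- st$epoch + 1L
  improved <- is.finite(loss) && loss < st$best - IMPROVE_TOL
  if (improved) {
    st$best <- loss
    st$best_epoch <- st$epoch
    st$wait_lr <- 0L
    st$wait_es <- 0L
  } else {
    st$wait_lr <- st$wait_lr + 1L
    st$wait_es <- st$wait_es + 1L
    if (st$wait_lr >= cfg$lr_patience) {
      st$lr <- max(st$lr * cfg$lr_factor, cfg$min_lr)
      st$wait_lr <- 0L
    }
    if (st$wait_es >= cfg$es_patience) st$stop <- TRUE
  }
  st$improved <- improved
  st
}

#' Replay the learning-rate schedule over a scripted loss sequence
#'
#' Pure function used to reason about (and test) the plateau decay and
#' early-stopping semantics without any training: feeds `losses` epoch by
#' epoch through the same stepper the training loop uses.
#'
#' @param losses numeric vector of per-epoch monitored (validation) losses
#' @param cfg a [train_config()]
#' @return list with `trace` (data frame: epoch, lr in force during that
#'   epoch, improved), `stopped_epoch` (NA if never), `best_epoch`
#' @export
simulate_schedule <- function(losses, cfg = train_config()) {
  st <- new_schedule_state(cfg)
  rows <- vector("list", length(losses))
  stopped <- NA_integer_
  for (e in seq_along(losses)) {
    lr_used <- st$lr
    st <- schedule_step(st, losses[e], cfg)
    rows[[e]] <- data.frame(epoch = e, lr = lr_used, improved = st$improved)
    if (st$stop) {
      stopped <- e
      break
    }
  }
  list(trace = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       stopped_epoch = stopped, best_epoch = st$best_epoch)
}

# ---- Adam over nested parameter trees ------------------------------------

tree_map <- function(f, a, b = NULL) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- tree_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    }
    return(out)
  }
  f(a, b)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- tree_map(function(m, ...) m / bc1, state$m)
  vh <- tree_map(function(v, ...) v / bc2, state$v)
  step <- tree_map(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  params <- tree_map(function(p, s) p - s, params, step)
  list(params = params, state = state)
}

tree_add <- function(a, b) tree_map(function(x, y) x + y, a, b)
tree_scale <- function(a, s) tree_map(function(x, ...) x * s, a)
tree_zero <- function(a) tree_map(function(x, ...) x * 0, a)

one_hot <- function(y, n_classes) {
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

eval_loss_acc <- function(model, data) {
  probs <- model_predict(model, data$x)
  eps <- 1e-12
  ll <- -mean(log(pmax(probs[cbind(seq_along(data$y), data$y + 1L)], eps)))
  pred <- predict_classes(probs)
  list(loss = ll, acc = mean(pred == data$y))
}

#' Train a model with plateau decay and early stopping
#'
#' Minibatch Adam on categorical cross-entropy. After each epoch the
#' validation loss drives the plateau learning-rate schedule and early
#' stopping; the best-validation-loss weights are restored at the end.
#' Fully seeded: shuffling and dropout derive from `cfg$seed`.
#'
#' @param model a `pcg_model` from [build_model()]
#' @param train_set,val_set lists with `x` (list of input matrices) and `y`
#'   (integer labels, 0 = normal, 1 = abnormal); must be disjoint
#' @param cfg a [train_config()]
#' @param verbose print per-epoch progress
#' @return list with `model` (best weights), `history` (data frame: epoch,
#'   train_loss, train_acc, val_loss, val_acc, lr), `stopped_epoch`,
#'   `best_epoch`
#' @export
train <- function(model, train_set, val_set, cfg = train_config(),
                  verbose = FALSE) {
  n <- length(train_set$x)
  if (n == 0L) stop("empty training set")
  stopifnot(length(train_set$y) == n, length(val_set$x) == length(val_set$y))
  set.seed(cfg$seed)
  nc <- model$cfg$n_classes
  yoh <- one_hot(train_set$y, nc)
  adam <- list(t = 0L, m = tree_zero(model$params),
               v = tree_zero(model$params))
  st <- new_schedule_state(cfg)
  best_params <- model$params
  history <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    lr_used <- st$lr
    idx <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      bidx <- idx[b0:min(b0 + cfg$batch_size - 1L, n)]
      grads <- NULL
      for (i in bidx) {
        fw <- net_forward(model, train_set$x[[i]], training = TRUE)
        pi_true <- fw$prob[train_set$y[i] + 1L]
        li <- -log(max(pi_true, 1e-12))
        if (!is.finite(li)) {
          stop(sprintf("non-finite loss at epoch %d (sample %d); aborting",
                       epoch, i))
        }
        ep_loss <- ep_loss + li
        ep_correct <- ep_correct + (which.max(fw$prob) == train_set$y[i] + 1L)
        dlogits <- (fw$prob - yoh[i, ]) / length(bidx)
        g <- net_backward(model, fw$caches, dlogits)
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      upd <- adam_update(model$params, grads, adam, lr_used)
      model$params <- upd$params
      adam <- upd$state
    }
    val <- eval_loss_acc(model, val_set)
    st <- schedule_step(st, val$loss, cfg)
    if (st$improved) best_params <- model$params
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = val$loss, val_acc = val$acc, lr = lr_used)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f  lr %g",
                      epoch, ep_loss / n, ep_correct / n, val$loss, val$acc,
                      lr_used))
    }
    if (st$stop) break
  }
  model$params <- best_params
  list(model = model,
       history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
       stopped_epoch = st$epoch, best_epoch = st$best_epoch)
}

#' Stratified k-fold cross-validation of one placement model
#'
#' Builds a stratified split (grouped by recording unless
#' `split_by = "segment"`), then trains and evaluates the model on each of
#' `folds_to_run` folds under identical conditions.
#'
#' @param dataset list with `x`, `y` and (for grouped splits) `recording`
#' @param model_id placement model (1..12); see [model_from_id()]
#' @param cfg a [train_config()]
#' @param k number of folds
#' @param split_by `"recording"` (default) or `"segment"`
#' @param folds_to_run which folds to train (defaults to all k)
#' @param verbose print training progress
#' @return list with `reports` (one `eval_report` per fold run), `histories`,
#'   `folds` (the assignment), and `summary` (data frame of per-fold metrics
#'   with mean and sd rows)
#' @export
crossvalidate <- function(dataset, model_id, cfg = train_config(), k = 10L,
                          split_by = c("recording", "segment"),
                          folds_to_run = seq_len(k), verbose = FALSE) {
  split_by <- match.arg(split_by)
  groups <- if (split_by == "recording") dataset$recording else NULL
  folds <- make_folds(dataset$y, groups = groups, k = k, seed = cfg$seed)
  input_shape <- dim(dataset$x[[1]])
  reports <- list()
  histories <- list()
  for (f in folds_to_run) {
    tr <- dataset_subset(dataset, folds != f)
    va <- dataset_subset(dataset, folds == f)
    model <- build_model(model_from_id(model_id, input_shape = input_shape),
                         seed = cfg$seed + f)
    fit <- train(model, tr, va, cfg, verbose = verbose)
    reports[[length(reports) + 1L]] <- evaluate_model(fit$model, va)
    histories[[length(histories) + 1L]] <- fit$history
  }
  per_fold <- data.frame(
    fold = folds_to_run,
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    loss = vapply(reports, `[[`, numeric(1), "loss"),
    sensitivity = vapply(reports, `[[`, numeric(1), "recall"),
    precision = vapply(reports, `[[`, numeric(1), "precision"),
    f1 = vapply(reports, `[[`, numeric(1), "f1"),
    auc = vapply(reports, `[[`, numeric(1), "auc"))
  summary <- rbind(per_fold,
                   cbind(fold = NA, t(colMeans(per_fold[-1], na.rm = TRUE))),
                   cbind(fold = NA, t(apply(per_fold[-1], 2, sd))))
  summary$stat <- c(rep("fold", nrow(per_fold)), "mean", "sd")
  list(reports = reports, histories = histories, folds = folds,
       summary = summary)
}

#' Stratified (optionally grouped) k-fold assignment
#'
#' Folds are stratified by class. With `groups` given (e.g. the source
#' recording of each segment), all samples of one group land in the same
#' fold, so no recording is split between training and validation.
#'
#' @param labels integer/character class labels, one per sample
#' @param groups optional group ids, one per sample; groups must be
#'   label-pure
#' @param k number of folds
#' @param seed integer seed for the shuffle
#' @return integer vector of fold ids in 1..k, one per sample
#' @export
make_folds <- function(labels, groups = NULL, k = 10L, seed = 0L) {
  n <- length(labels)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  groups <- as.character(groups)
  glab <- tapply(as.character(labels), groups, function(l) {
    u <- unique(l)
    if (length(u) > 1L) stop("group spans multiple labels")
    u
  })
  set.seed(seed)
  gfold <- integer(0)
  gnames <- character(0)
  for (cls in unique(glab)) {
    gc <- names(glab)[glab == cls]
    if (length(gc) < k) {
      stop(sprintf("class '%s' has %d groups, fewer than k = %d folds",
                   cls, length(gc), k))
    }
    gc <- sample(gc)
    gfold <- c(gfold, rep_len(seq_len(k), length(gc)))
    gnames <- c(gnames, gc)
  }
  unname(gfold[match(groups, gnames)])
}
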