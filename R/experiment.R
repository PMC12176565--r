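#' Convert spectrogram images to a model-ready dataset
#'
#' @param images list of `spectrogram_image`
#' @return list with `x` (list of pixel matrices), `y` (integer labels,
#'   0 = normal, 1 = abnormal), `recording` (parent recording ids)
#' @export
spectra_to_dataset <- function(images) {
  list(x = lapply(images, function(im) im$pixels),
       y = vapply(images, function(im) as.integer(im$label == "abnormal"),
                  integer(1)),
       recording = vapply(images, function(im) im$parent_id, character(1)))
}

#' Synthetic end-to-end dataset: generator -> segments -> spectrograms
#'
#' Convenience pipeline used by the examples and the scaled-down ablation:
#' generates recordings, cuts them into fixed windows, and computes
#' spectrograms.
#'
#' @param synth_cfg a [synth_config()]
#' @param spec_cfg a [spectrogram_config()]
#' @param window_seconds segmentation window in seconds
#' @return dataset as from [spectra_to_dataset()]
#' @export
synthetic_spectrogram_dataset <- function(synth_cfg,
                                          spec_cfg = spectrogram_config(),
                                          window_seconds = 5) {
  recs <- generate_dataset(synth_cfg)
  segs <- segment_dataset(recs, window_seconds)$segments
  spectra_to_dataset(compute_spectrograms(segs, spec_cfg))
}

#' Desk-scale ablation conditions
#'
#' The study conditions used for the scaled-down placement ablation that the
#' package runs on one CPU: the corpus class balance shrunk 100-fold
#' (26 normal / 7 abnormal recordings), 10–30 s recordings, a strong
#' (+15 dB) systolic murmur so the classes are clearly separable, 24 x 36
#' spectrogram images, and a 5-fold grouped split (one fold evaluated).
#'
#' @param seed integer seed for the generator and the split
#' @return list with `synth_cfg`, `spec_cfg`, `k`, and `train_cfg`
#' @export
desk_scale_conditions <- function(seed = 42L) {
  list(
    synth_cfg = table1_preset(scale = 0.01, seed = seed,
                              duration_range_s = c(10, 30),
                              murmur_snr_db = 15),
    spec_cfg = spectrogram_config(height = 24L, width = 36L),
    k = 5L,
    train_cfg = train_config(max_epochs = 15L, seed = seed))
}

dataset_subset <- function(data, idx) {
  list(x = data$x[idx], y = data$y[idx], recording = data$recording[idx])
}

auto_perplexity <- function(n) max(2, min(30, floor((n - 1) / 3)))

write_run_manifest <- function(out_dir, entries) {
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("pcgcbam")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), entries)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the CBAM-placement ablation under identical conditions
#'
#' Trains and evaluates the requested placement models on identical folds,
#' with identical weight-initialization seeds and hyperparameters — the only
#' thing that varies across models is the CBAM mask. By default one fold of
#' the stratified k-fold split is evaluated (`eval_folds = 1`); increase
#' `eval_folds` for full cross-validation.
#'
#' For each model the validation fold is also embedded with t-SNE (features
#' from the last convolutional stage) and the three class-separability
#' distances are added to the report.
#'
#' @param dataset a dataset from [spectra_to_dataset()]
#' @param model_ids integer vector of placement models (1..12), non-empty
#' @param train_cfg a [train_config()]
#' @param k folds in the stratified split
#' @param eval_folds how many folds to actually train/evaluate
#' @param split_by `"recording"` (default; no recording is split across
#'   folds) or `"segment"`
#' @param tsne compute separability distances (skipped when the validation
#'   fold is too small)
#' @param out_dir optional output directory for the report CSV, per-model
#'   histories and a run manifest
#' @param verbose print training progress
#' @return list with `report` (data frame, one row per model), `results`
#'   (per-model details), `failures` (named list of error messages), and
#'   `exit_status` (0 = all ok, 2 = partial failures)
#' @export
run_ablation <- function(dataset, model_ids = 1:12,
                         train_cfg = train_config(), k = 10L,
                         eval_folds = 1L,
                         split_by = c("recording", "segment"),
                         tsne = TRUE, out_dir = NULL, verbose = FALSE) {
  split_by <- match.arg(split_by)
  if (length(model_ids) == 0) stop("empty model list")
  n <- length(dataset$x)
  stopifnot(n > 0)
  input_shape <- dim(dataset$x[[1]])
  groups <- if (split_by == "recording") dataset$recording else NULL
  folds <- make_folds(dataset$y, groups = groups, k = k,
                      seed = train_cfg$seed)
  eval_folds <- min(eval_folds, k)
  results <- list()
  failures <- list()
  for (id in model_ids) {
    res <- tryCatch({
      fold_reports <- vector("list", eval_folds)
      histories <- vector("list", eval_folds)
      for (f in seq_len(eval_folds)) {
        tr <- dataset_subset(dataset, folds != f)
        va <- dataset_subset(dataset, folds == f)
        cfg <- model_from_id(id, input_shape = input_shape)
        model <- build_model(cfg, seed = train_cfg$seed + f)
        fit <- train(model, tr, va, train_cfg, verbose = verbose)
        rep <- evaluate_model(fit$model, va)
        if (tsne) {
          perp <- auto_perplexity(length(va$y))
          feats <- extract_features(fit$model, va)
          emb <- tsne_embed(feats, perplexity = perp,
                            seed = train_cfg$seed)
          rep$separability <- class_distances(emb, va$y)
          rep$embedding <- emb
        }
        fold_reports[[f]] <- rep
        histories[[f]] <- fit$history
      }
      list(reports = fold_reports, histories = histories,
           summary = aggregate_reports(fold_reports))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(id)]] <- conditionMessage(res)
    } else {
      results[[as.character(id)]] <- res
    }
  }
  ok_ids <- as.integer(names(results))
  report <- report_table(lapply(results, `[[`, "summary"), ok_ids)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report, file.path(out_dir, "ablation_report.csv"),
              row.names = FALSE)
    for (id in names(results)) {
      hist <- do.call(rbind, lapply(seq_along(results[[id]]$histories),
        function(f) cbind(fold = f, results[[id]]$histories[[f]])))
      write.csv(hist, file.path(out_dir, sprintf("history_model%s.csv", id)),
                row.names = FALSE)
    }
    write_run_manifest(out_dir, list(
      stage = "ablation", model_ids = model_ids, k = k,
      eval_folds = eval_folds, split_by = split_by,
      seed = train_cfg$seed, train_config = unclass(train_cfg),
      input_shape = input_shape, n_samples = n,
      failures = if (length(failures)) failures else NULL))
  }
  list(report = report, results = results, failures = failures,
       exit_status = if (length(failures) > 0) 2L else 0L)
}

# mean of per-fold metrics; separability averaged when present on all folds
aggregate_reports <- function(reports) {
  if (length(reports) == 1L) return(reports[[1]])
  fields <- c("accuracy", "loss", "recall", "precision", "f1", "auc")
  out <- reports[[1]]
  for (f in fields) {
    out[[f]] <- mean(vapply(reports, function(r) as.numeric(r[[f]]),
                            numeric(1)), na.rm = TRUE)
  }
  seps <- lapply(reports, `[[`, "separability")
  if (!any(vapply(seps, is.null, logical(1)))) {
    out$separability <- colMeans(do.call(rbind, seps))
  }
  out
}

#' Train on one dataset and evaluate once on an independent test set
#'
#' A leakage guard refuses recording ids shared between the two sets. The
#' training set is internally split 9:1 (stratified, grouped by recording)
#' into training and validation for the schedule, then the fitted model is
#' evaluated once on the untouched test set.
#'
#' @param train_data,test_data datasets from [spectra_to_dataset()] with
#'   disjoint recording ids
#' @param model_id placement model (1..12)
#' @param train_cfg a [train_config()]
#' @param out_dir optional output directory (report JSON + manifest)
#' @param verbose print training progress
#' @return list with `report` (an `eval_report`), `roc` (data frame fpr/tpr),
#'   `confusion`, and `history`
#' @export
run_holdout <- function(train_data, test_data, model_id,
                        train_cfg = train_config(), out_dir = NULL,
                        verbose = FALSE) {
  overlap <- intersect(unique(train_data$recording),
                       unique(test_data$recording))
  if (length(overlap) > 0) {
    stop("train and test sets share recording ids: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  if (length(unique(test_data$y)) < 2) {
    stop("test set contains a single class; AUC requires both classes")
  }
  input_shape <- dim(train_data$x[[1]])
  folds <- make_folds(train_data$y, groups = train_data$recording, k = 10L,
                      seed = train_cfg$seed)
  tr <- dataset_subset(train_data, folds != 1L)
  va <- dataset_subset(train_data, folds == 1L)
  cfg <- model_from_id(model_id, input_shape = input_shape)
  model <- build_model(cfg, seed = train_cfg$seed)
  fit <- train(model, tr, va, train_cfg, verbose = verbose)
  rep <- evaluate_model(fit$model, test_data)
  roc <- roc_points(rep$scores, test_data$y)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      accuracy = rep$accuracy, sensitivity = rep$recall,
      precision = rep$precision, f1 = rep$f1, auc = rep$auc,
      loss = rep$loss, confusion = unclass(rep$confusion)),
      file.path(out_dir, "holdout_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    write.csv(roc, file.path(out_dir, "roc_curve.csv"), row.names = FALSE)
    write_run_manifest(out_dir, list(
      stage = "holdout", model_id = model_id, seed = train_cfg$seed,
      train_config = unclass(train_cfg), input_shape = input_shape,
      n_train = length(train_data$y), n_test = length(test_data$y)))
  }
  list(report = rep, roc = roc, confusion = rep$confusion,
       history = fit$history)
}
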