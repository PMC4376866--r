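#' Train the compound-pair similarity classifier
#'
#' A random forest over [compound_pair_features()] output that predicts
#' whether two small molecules are likely to bind the same target binding
#' site; its probability becomes the weight of query-to-cluster edges.
#'
#' @param labeled_pairs tibble containing the pair feature columns and a
#'   logical/0-1 `label` column (TRUE = similar / same-pocket binders).
#' @param features feature column names (default
#'   [pair_feature_names()], intersected with what is present).
#' @param num_trees forest size (default 500).
#' @param seed integer seed; training and prediction are deterministic
#'   given the seed.
#' @param ... passed to [ranger::ranger()].
#' @return a `pp_pair_model` (list: `model`, `features`, `seed`, `oob`).
#' @export
train_pair_classifier <- function(labeled_pairs, features = NULL,
                                  num_trees = 500, seed = 1, ...) {
  stopifnot("label" %in% names(labeled_pairs))
  features <- features %||% intersect(pair_feature_names(), names(labeled_pairs))
  if (length(features) == 0) abort("no feature columns found")
  y <- as.logical(labeled_pairs$label)
  if (length(unique(y)) < 2) abort("training set must contain both classes")
  dat <- as.data.frame(labeled_pairs[, features, drop = FALSE])
  dat$.label <- factor(y, levels = c(FALSE, TRUE))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = num_trees, probability = TRUE, seed = seed,
    importance = "impurity", num.threads = 1, ...
  )
  inform(sprintf("pair classifier: OOB Brier = %.4f on %d pairs",
                 fit$prediction.error, nrow(dat)))
  structure(
    list(model = fit, features = features, seed = seed,
         oob_error = fit$prediction.error, n = nrow(dat)),
    class = "pp_pair_model"
  )
}

#' Probability that a compound pair is similar
#'
#' @param model a `pp_pair_model`.
#' @param pair_features tibble with the model's feature columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_pair_probability <- function(model, pair_features) {
  stopifnot(inherits(model, "pp_pair_model"))
  miss <- setdiff(model$features, names(pair_features))
  if (length(miss) > 0) {
    abort(paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(pair_features) == 0) return(numeric(0))
  dat <- as.data.frame(pair_features[, model$features, drop = FALSE])
  pr <- stats::predict(model$model, data = dat, seed = model$seed,
                       num.threads = 1)$predictions
  unname(pr[, "TRUE"])
}

#' @export
print.pp_pair_model <- function(x, ...) {
  cat("<compound-pair random forest>\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  trained on %d pairs, OOB Brier %.4f, seed %d\n",
              x$n, x$oob_error, x$seed))
  invisible(x)
}

#' @export
tidy.pp_pair_model <- function(x, ...) {
  imp <- ranger::importance(x$model)
  tibble(term = names(imp), importance = unname(imp)) |>
    arrange(desc(.data$importance))
}

#' @export
glance.pp_pair_model <- function(x, ...) {
  tibble(n_pairs = x$n, num_trees = x$model$num.trees,
         oob_brier = x$oob_error, seed = x$seed)
}

meta_feature_frame <- function(rows, use_compound_id, id_buckets = 64L,
                               features = c("score", "global_z", "local_z")) {
  miss <- setdiff(features, names(rows))
  if (length(miss) > 0) {
    abort(paste0("missing score column(s): ", paste(miss, collapse = ", ")))
  }
  dat <- as.data.frame(rows[, features, drop = FALSE])
  if (use_compound_id) {
    if (!"query_id" %in% names(rows)) {
      abort("use_compound_id = TRUE but no query_id column present")
    }
    # fixed level set so train/predict frames are compatible
    dat$compound_hash <- factor(hash_id(rows$query_id, buckets = id_buckets),
                                levels = 0:(id_buckets - 1))
  }
  dat
}

#' Train the binder/non-binder meta-classifier
#'
#' A random forest over the three path-derived scores — raw score, global
#' Z, local Z — optionally augmented with the query compound identity
#' (hashed to an integer feature). The identity-aware variant can exploit
#' per-compound regularities and is expected to outperform the anonymous
#' one whenever the same compounds occur in training and test; the
#' anonymous variant simulates predictions for compounds never seen
#' before. Performance is estimated by stratified 10-fold
#' cross-validation (precision, recall, AUC per fold); the returned model
#' is refit on all rows.
#'
#' @param labeled_predictions prediction tibble with `score`, `global_z`,
#'   `local_z`, `query_id` and a logical `label` column from the
#'   benchmark truth.
#' @param use_compound_id include the hashed compound identity feature.
#' @param features score columns fed to the forest; the default is the
#'   full score triple, a single name gives the single-score classifier
#'   the benchmark tables compare against.
#' @param num_trees forest size (default 500).
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed controlling folds and forests.
#' @param id_buckets hash width for the identity feature.
#' @return a `pp_meta_model` (fields `model`, `use_compound_id`, `cv`
#'   per-fold metrics tibble, `schema`, `seed`).
#' @export
train_meta_classifier <- function(labeled_predictions, use_compound_id = FALSE,
                                  num_trees = 500, n_folds = 10, seed = 1,
                                  id_buckets = 64L,
                                  features = c("score", "global_z", "local_z")) {
  stopifnot("label" %in% names(labeled_predictions))
  y <- as.logical(labeled_predictions$label)
  if (length(unique(y)) < 2) abort("training set must contain both classes")
  dat <- meta_feature_frame(labeled_predictions, use_compound_id, id_buckets,
                            features)
  dat$.label <- factor(y, levels = c(FALSE, TRUE))

  folds <- stratified_folds(y, n_folds, seed)
  cv <- purrr::map_dfr(seq_len(n_folds), function(f) {
    test <- folds == f
    if (length(unique(dat$.label[!test])) < 2 || !any(test)) {
      return(tibble(fold = f, precision = NA_real_, recall = NA_real_,
                    auc = NA_real_))
    }
    fit <- ranger::ranger(dependent.variable.name = ".label",
                          data = dat[!test, , drop = FALSE],
                          num.trees = num_trees, probability = TRUE,
                          respect.unordered.factors = "order",
                          seed = seed + f, num.threads = 1)
    pr <- stats::predict(fit, data = dat[test, , drop = FALSE],
                         num.threads = 1)$predictions[, "TRUE"]
    m <- binary_metrics(y[test], pr, threshold = 0.5)
    tibble(fold = f, precision = m$precision, recall = m$recall, auc = m$auc)
  })

  fit <- ranger::ranger(dependent.variable.name = ".label", data = dat,
                        num.trees = num_trees, probability = TRUE,
                        respect.unordered.factors = "order",
                        seed = seed, num.threads = 1)
  msg <- cv |>
    summarise(across(c("precision", "recall", "auc"),
                     list(mean = ~ mean(.x, na.rm = TRUE),
                          sd = ~ sd(.x, na.rm = TRUE))))
  inform(sprintf(
    "meta classifier (%s): CV precision %.2f+-%.2f, recall %.2f+-%.2f, AUC %.2f+-%.2f",
    if (use_compound_id) "id-aware" else "anonymous",
    msg$precision_mean, msg$precision_sd, msg$recall_mean, msg$recall_sd,
    msg$auc_mean, msg$auc_sd))
  structure(
    list(model = fit, use_compound_id = use_compound_id, cv = cv,
         schema = names(dat)[names(dat) != ".label"], features = features,
         seed = seed, id_buckets = id_buckets, n = nrow(dat)),
    class = "pp_meta_model"
  )
}

# Stratified, disjoint, exhaustive fold assignment.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      i <- which(y == cls)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  folds
}

#' Classify prediction rows as binders / non-binders
#'
#' Applies a trained meta-classifier to prediction rows, adding
#' `classifier_prob` and `classifier_label`. The label threshold is
#' inclusive: probability exactly at `threshold` is called positive.
#'
#' @param model a `pp_meta_model`.
#' @param predictions prediction tibble (row order preserved).
#' @param threshold probability cut for the Boolean call (default 0.5).
#' @return `predictions` with `classifier_prob`, `classifier_label`.
#' @export
classify_predictions <- function(model, predictions, threshold = 0.5) {
  stopifnot(inherits(model, "pp_meta_model"))
  if (nrow(predictions) == 0) {
    predictions$classifier_prob <- numeric(0)
    predictions$classifier_label <- logical(0)
    return(predictions)
  }
  dat <- meta_feature_frame(predictions, model$use_compound_id,
                            model$id_buckets, model$features)
  if (!identical(sort(names(dat)), sort(model$schema))) {
    abort("prediction columns do not match the model's feature schema")
  }
  pr <- stats::predict(model$model, data = dat,
                       num.threads = 1)$predictions[, "TRUE"]
  predictions$classifier_prob <- unname(pr)
  predictions$classifier_label <- unname(pr) >= threshold
  predictions
}

#' @export
print.pp_meta_model <- function(x, ...) {
  cat("<binder/non-binder meta random forest>\n")
  cat("  features:", paste(x$schema, collapse = ", "), "\n")
  g <- glance(x)
  cat(sprintf("  %d rows; CV AUC %.3f +- %.3f (%d folds)\n",
              x$n, g$auc_mean, g$auc_sd, nrow(x$cv)))
  invisible(x)
}

#' @export
tidy.pp_meta_model <- function(x, ...) x$cv

#' @export
glance.pp_meta_model <- function(x, ...) {
  tibble(
    n = x$n,
    use_compound_id = x$use_compound_id,
    precision_mean = mean(x$cv$precision, na.rm = TRUE),
    precision_sd = sd(x$cv$precision, na.rm = TRUE),
    recall_mean = mean(x$cv$recall, na.rm = TRUE),
    recall_sd = sd(x$cv$recall, na.rm = TRUE),
    auc_mean = mean(x$cv$auc, na.rm = TRUE),
    auc_sd = sd(x$cv$auc, na.rm = TRUE),
    seed = x$seed
  )
}

#' Persist / restore a trained model
#'
#' Writes the fitted forest as an RDS artifact plus a JSON sidecar
#' recording the feature schema, seed and parameters, so a stored model
#' is self-describing.
#'
#' @param model a `pp_pair_model` or `pp_meta_model`.
#' @param path artifact path (`.rds`); the sidecar is `<path>.json`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("pp_pair_model", "pp_meta_model")))
  saveRDS(model, path)
  side <- list(
    class = class(model)[1],
    version = as.character(utils::packageVersion("pocketpath")),
    features = model$features %||% model$schema,
    seed = model$seed,
    n = model$n
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, c("pp_pair_model", "pp_meta_model")))
  model
}
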