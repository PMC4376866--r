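make_pair_training <- function(n_compounds = 60, n_pairs = 500, seed = 21) {
  cmp <- fake_featurized_compounds(n_compounds, seed = seed, fp_bits = 96)
  set.seed(seed + 1)
  pairs <- tibble::tibble(
    id_a = sample(cmp$id, n_pairs * 2, replace = TRUE),
    id_b = sample(cmp$id, n_pairs * 2, replace = TRUE)
  )
  pairs <- utils::head(pairs[pairs$id_a != pairs$id_b, ], n_pairs)
  # plant similar pairs: clones with a few flipped bits
  clones <- lapply(seq_len(150), function(i) {
    src <- sample(nrow(cmp), 1)
    fp <- cmp$fingerprint[[src]]
    flip <- sample(length(fp), 4)
    fp[flip] <- 1L - fp[flip]
    list(src = cmp$id[src], fp = fp)
  })
  clone_rows <- tibble::tibble(
    id = sprintf("clone%03d", seq_along(clones)),
    smiles = NA_character_, wqed = 0.5,
    fingerprint = lapply(clones, `[[`, "fp"),
    mw = cmp$mw[match(vapply(clones, `[[`, "", "src"), cmp$id)],
    logp = 0, tpsa = 50, hba = 2, hbd = 1, rotb = 3, arom = 1
  )
  all_cmp <- dplyr::bind_rows(cmp, clone_rows)
  extra <- tibble::tibble(
    id_a = vapply(clones, `[[`, "", "src"),
    id_b = clone_rows$id
  )
  feats <- compound_pair_features(all_cmp, dplyr::bind_rows(pairs, extra))
  feats$label <- feats$tanimoto > 0.7
  list(compounds = all_cmp, features = feats)
}

test_that("the pair classifier recovers a Tanimoto-defined label", {
  tr <- make_pair_training()
  feats <- tr$features
  expect_gt(sum(feats$label), 50)
  expect_gt(sum(!feats$label), 50)
  # 5-fold CV accuracy
  folds <- pocketpath:::stratified_folds(feats$label, 5, seed = 2)
  acc <- vapply(1:5, function(f) {
    fit <- suppressMessages(train_pair_classifier(feats[folds != f, ], seed = 3))
    p <- predict_pair_probability(fit, feats[folds == f, ])
    mean((p >= 0.5) == feats$label[folds == f])
  }, numeric(1))
  expect_gt(mean(acc), 0.9)
})

test_that("an identical pair outranks every non-identical pair", {
  tr <- make_pair_training()
  fit <- suppressMessages(train_pair_classifier(tr$features, seed = 3))
  self <- compound_pair_features(tr$compounds,
                                 tibble::tibble(id_a = "c001", id_b = "c001"))
  p_self <- predict_pair_probability(fit, self)
  others <- tr$features[!tr$features$label, ]
  p_others <- predict_pair_probability(fit, utils::head(others, 50))
  expect_true(all(p_self >= p_others))
})

test_that("pair-classifier training and prediction are deterministic under a seed", {
  tr <- make_pair_training(n_compounds = 30, n_pairs = 150)
  f1 <- suppressMessages(train_pair_classifier(tr$features, seed = 9))
  f2 <- suppressMessages(train_pair_classifier(tr$features, seed = 9))
  expect_identical(predict_pair_probability(f1, tr$features),
                   predict_pair_probability(f2, tr$features))
})

test_that("single-class training sets are rejected", {
  tr <- make_pair_training(n_compounds = 30, n_pairs = 150)
  pos <- tr$features[tr$features$label, ]
  expect_error(train_pair_classifier(pos, seed = 1), "both classes")
})

test_that("a separable meta-label is recovered almost perfectly", {
  set.seed(4)
  n <- 400
  rows <- tibble::tibble(
    query_id = sample(sprintf("q%02d", 1:20), n, replace = TRUE),
    score = runif(n),
    global_z = rnorm(n),
    local_z = rnorm(n)
  )
  rows$label <- rows$score > 0.5
  m <- suppressMessages(suppressWarnings(
    train_meta_classifier(rows, use_compound_id = FALSE, seed = 5)))
  g <- glance(m)
  expect_gt(g$precision_mean, 0.95)
  expect_gt(g$recall_mean, 0.95)
  expect_gt(g$auc_mean, 0.99)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(6)
  n <- 300
  rows <- tibble::tibble(
    query_id = sample(sprintf("q%02d", 1:15), n, replace = TRUE),
    score = runif(n), global_z = rnorm(n), local_z = rnorm(n),
    label = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
  m <- suppressMessages(suppressWarnings(
    train_meta_classifier(rows, use_compound_id = FALSE, seed = 7)))
  expect_lt(abs(glance(m)$auc_mean - 0.5), 0.15)
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  set.seed(8)
  y <- runif(237) < 0.3
  folds <- pocketpath:::stratified_folds(y, 10, seed = 1)
  expect_equal(length(folds), length(y))
  expect_setequal(unique(folds), 1:10)
  pos_per_fold <- table(folds[y])
  expect_lte(diff(range(pos_per_fold)), 1)
  neg_per_fold <- table(folds[!y])
  expect_lte(diff(range(neg_per_fold)), 1)
})

test_that("classification preserves rows, applies an inclusive threshold, handles empties", {
  set.seed(9)
  n <- 200
  rows <- tibble::tibble(
    query_id = sample(sprintf("q%02d", 1:10), n, replace = TRUE),
    site_id = sample(sprintf("t%02d", 1:8), n, replace = TRUE),
    score = runif(n), global_z = rnorm(n), local_z = rnorm(n)
  )
  rows$label <- rows$score > 0.5
  m <- suppressMessages(suppressWarnings(
    train_meta_classifier(rows, use_compound_id = FALSE, seed = 2)))
  out <- classify_predictions(m, rows)
  expect_equal(out$query_id, rows$query_id)
  # inclusive threshold: a row exactly at the cut is called positive
  thr <- out$classifier_prob[5]
  out2 <- classify_predictions(m, rows, threshold = thr)
  expect_true(out2$classifier_label[5])

  empty <- classify_predictions(m, rows[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("classifier_prob", "classifier_label") %in% names(empty)))
})

test_that("probability is monotone in score for a monotone label", {
  set.seed(10)
  n <- 500
  rows <- tibble::tibble(
    query_id = sample(sprintf("q%02d", 1:10), n, replace = TRUE),
    score = runif(n), global_z = rnorm(n), local_z = rnorm(n)
  )
  rows$label <- rows$score > 0.5
  m <- suppressMessages(suppressWarnings(
    train_meta_classifier(rows, use_compound_id = FALSE, seed = 3)))
  grid <- tibble::tibble(query_id = "q01",
                         score = seq(0.05, 0.95, by = 0.05),
                         global_z = 0, local_z = 0)
  p <- classify_predictions(m, grid)$classifier_prob
  # non-decreasing within forest-vote granularity
  expect_true(all(diff(p) >= -0.02))
  expect_lt(p[1], 0.1)
  expect_gt(p[length(p)], 0.9)
})

test_that("schema mismatches and missing id columns are fatal", {
  set.seed(11)
  rows <- tibble::tibble(query_id = rep(c("a", "b"), 50),
                         score = runif(100), global_z = rnorm(100),
                         local_z = rnorm(100))
  rows$label <- rows$score > 0.5
  expect_error(
    suppressMessages(train_meta_classifier(
      dplyr::select(rows, -"query_id"), use_compound_id = TRUE, seed = 1)),
    "query_id")
  m <- suppressMessages(suppressWarnings(
    train_meta_classifier(rows, use_compound_id = FALSE, seed = 1)))
  expect_error(classify_predictions(m, dplyr::select(rows, -"score")), "score")
})

test_that("models persist with a JSON sidecar and reload identically", {
  set.seed(12)
  rows <- tibble::tibble(query_id = rep(c("a", "b"), 60),
                         score = runif(120), global_z = rnorm(120),
                         local_z = rnorm(120))
  rows$label <- rows$score > 0.5
  m <- suppressMessages(suppressWarnings(
    train_meta_classifier(rows, use_compound_id = FALSE, seed = 4)))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$class, "pp_meta_model")
  m2 <- load_model(f)
  expect_identical(classify_predictions(m2, rows)$classifier_prob,
                   classify_predictions(m, rows)$classifier_prob)
})
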