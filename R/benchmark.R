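#' Build the positive benchmark set
#'
#' Deduplicated (drug, protein) pairs from annotated interaction records,
#' restricted to a drug whitelist.
#'
#' @param records tibble with columns `drug_id`, `protein_id` (an
#'   `evidence` column is carried along if present).
#' @param drug_whitelist drug ids admitted to the benchmark.
#' @return tibble of unique `drug_id`, `protein_id` pairs.
#' @export
build_positive_set <- function(records, drug_whitelist) {
  stopifnot(all(c("drug_id", "protein_id") %in% names(records)))
  records |>
    filter(.data$drug_id %in% drug_whitelist) |>
    distinct(.data$drug_id, .data$protein_id)
}

#' Sample the negative benchmark set
#'
#' Uniform sample, without replacement, of (drug, protein) combinations
#' that carry no annotation, reproducible by seed.
#'
#' @param drugs,proteins the id universes whose cross product defines all
#'   candidate pairs.
#' @param positives tibble of annotated pairs to exclude.
#' @param n number of negatives to draw.
#' @param seed integer seed.
#' @return tibble of `n` unannotated `drug_id`, `protein_id` pairs.
#' @export
build_negative_set <- function(drugs, proteins, positives, n, seed = 1) {
  universe <- tidyr::expand_grid(drug_id = unique(drugs),
                                 protein_id = unique(proteins))
  pool <- anti_join(universe, positives, by = c("drug_id", "protein_id"))
  if (nrow(pool) < n) {
    abort(sprintf("cannot draw %d negatives from %d unannotated pairs",
                  n, nrow(pool)))
  }
  idx <- with_seed(seed, sample(nrow(pool), n))
  pool[idx, , drop = FALSE]
}

#' Screen negatives for likely miss-annotations
#'
#' A sampled "negative" (drug, target) pair is suspicious when some
#' compound similar to the drug has an annotated interaction with that
#' same target — the pair is then probably an undocumented true
#' interaction rather than a non-binder. The same notion of "similar" is
#' used as during network construction (pair-classifier probability above
#' the edge-creation threshold).
#'
#' @param negatives tibble `drug_id`, `protein_id`.
#' @param similar_pairs tibble `a`, `b` (+ optional `prob`) of compound
#'   pairs called similar.
#' @param interactions tibble `drug_id`, `protein_id` of annotated
#'   interactions.
#' @param threshold minimum `prob` for a pair to count as similar (used
#'   only when a `prob` column is present).
#' @param remove drop flagged rows instead of only labelling them.
#' @return `negatives` with a logical `flagged` column (flagged rows
#'   removed when `remove = TRUE`; the flagged count is attached as
#'   attribute `"n_flagged"`).
#' @export
screen_negatives <- function(negatives, similar_pairs, interactions,
                             threshold = 0.5, remove = FALSE) {
  stopifnot(all(c("a", "b") %in% names(similar_pairs)))
  if ("prob" %in% names(similar_pairs)) {
    similar_pairs <- similar_pairs[similar_pairs$prob >= threshold, , drop = FALSE]
  }
  sym <- bind_rows(
    tibble(drug = similar_pairs$a, other = similar_pairs$b),
    tibble(drug = similar_pairs$b, other = similar_pairs$a)
  )
  annotated <- paste(interactions$drug_id, interactions$protein_id)
  flagged <- vapply(seq_len(nrow(negatives)), function(i) {
    sims <- sym$other[sym$drug == negatives$drug_id[i]]
    any(paste(sims, negatives$protein_id[i]) %in% annotated)
  }, logical(1))
  out <- negatives
  out$flagged <- flagged
  if (remove) out <- out[!flagged, , drop = FALSE]
  attr(out, "n_flagged") <- sum(flagged)
  out
}

#' Remove identity links of benchmark entities
#'
#' Benchmark fairness rule: a benchmark ligand must not be connected to
#' an identical network ligand (pair probability exactly 1 / canonical
#' structure equality), nor a benchmark site to an identical network
#' site, otherwise the search would trivially rediscover the annotation
#' through a zero-information hop. Identity edges incident to the listed
#' entities are removed; everything else is untouched.
#'
#' @param net a `ppnet` with benchmark entities integrated.
#' @param benchmark_ligands,benchmark_sites ids of benchmark entities.
#' @return the pruned network; removal count attached as attribute
#'   `"n_removed"` and reported.
#' @export
exclude_identity_links <- function(net, benchmark_ligands = character(),
                                   benchmark_sites = character()) {
  stopifnot(inherits(net, "ppnet"))
  ids <- c(benchmark_ligands, benchmark_sites)
  e <- net$edges
  drop <- e$identity & (e$a %in% ids | e$b %in% ids)
  net$edges <- e[!drop, , drop = FALSE]
  inform(paste0("exclude_identity_links: removed ", sum(drop), " edge(s)"))
  net <- validate_network(net)
  attr(net, "n_removed") <- sum(drop)
  net
}

# Confusion-matrix metrics + threshold-swept ROC for one score vector.
binary_metrics <- function(truth, score, threshold = 0.5,
                           higher_is_better = TRUE) {
  stopifnot(length(truth) == length(score))
  truth <- as.logical(truth)
  s <- if (higher_is_better) score else -score
  call_pos <- s >= (if (higher_is_better) threshold else -threshold)
  tp <- sum(call_pos & truth)
  fp <- sum(call_pos & !truth)
  fn <- sum(!call_pos & truth)
  tn <- sum(!call_pos & !truth)
  roc <- roc_points(truth, s)
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn,
    roc = roc,
    auc = trapezoid_auc(roc)
  )
}

# ROC swept over all distinct score values plus infinite endpoints.
roc_points <- function(truth, score) {
  p <- sum(truth)
  n <- sum(!truth)
  if (p == 0 || n == 0) {
    return(tibble(threshold = numeric(), tpr = numeric(), fpr = numeric()))
  }
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(score >= t & truth) / p, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & !truth) / n, numeric(1))
  tibble(threshold = thr, tpr = tpr, fpr = fpr)
}

trapezoid_auc <- function(roc) {
  if (nrow(roc) < 2) return(NA_real_)
  ord <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[ord]
  y <- roc$tpr[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Evaluate predictions against a benchmark truth table
#'
#' Matches prediction rows to labelled (drug, protein) pairs and computes
#' the full battery: precision and recall of the Boolean calls, a
#' threshold-swept ROC with trapezoid AUC, and the enrichment curve
#' (fraction of known positives recovered as a function of the fraction
#' of the ranked list examined). Truth pairs never reached by any
#' prediction are false negatives (score `-Inf`, so they sit at the
#' bottom of every ranking).
#'
#' @param predictions prediction tibble (`query_id`, `protein_id`,
#'   `site_id`, score columns, optionally `classifier_prob` /
#'   `classifier_label`).
#' @param truth tibble `query_id`, `protein_id` (or `site_id` with
#'   `level = "site"`), logical `label`.
#' @param score_col which score ranks the list (default `"score"`).
#' @param higher_is_better orientation of `score_col` (local Z is often
#'   swept low-to-high; set `FALSE` then).
#' @param level `"protein"` (default): a predicted site counts for its
#'   parent protein, scores aggregate by max; `"site"`: strict site-level
#'   matching.
#' @param threshold Boolean call: `classifier_label` when present,
#'   otherwise oriented `score_col >= threshold`.
#' @return a `pp_eval` object: fields `precision`, `recall`, `auc`,
#'   `roc` (tibble), `enrichment` (tibble `frac_screened`, `frac_found`),
#'   `confusion`, `pairs` (the matched table).
#' @export
evaluate_predictions <- function(predictions, truth, score_col = "score",
                                 higher_is_better = TRUE,
                                 level = c("protein", "site"),
                                 threshold = 0.5) {
  level <- match.arg(level)
  key <- if (level == "protein") "protein_id" else "site_id"
  stopifnot(all(c("query_id", key, "label") %in% names(truth)))
  stopifnot(score_col %in% names(predictions))

  pred <- predictions
  pred$.score <- pred[[score_col]]
  if (!higher_is_better) pred$.score <- -pred$.score
  has_call <- "classifier_label" %in% names(pred) &&
    !all(is.na(pred$classifier_label))
  pred$.call <- if (has_call) pred$classifier_label else pred$.score >= threshold
  agg <- pred |>
    group_by(query_id = .data$query_id, target = .data[[key]]) |>
    summarise(.score = max(.data$.score), .call = any(.data$.call),
              .groups = "drop")

  pairs <- truth |>
    transmute(query_id = .data$query_id, target = .data[[key]],
              label = as.logical(.data$label)) |>
    left_join(agg, by = c("query_id", "target")) |>
    mutate(.score = ifelse(is.na(.data$.score), -Inf, .data$.score),
           .call = !is.na(.data$.call) & .data$.call)

  tp <- sum(pairs$.call & pairs$label)
  fp <- sum(pairs$.call & !pairs$label)
  fn <- sum(!pairs$.call & pairs$label)
  tn <- sum(!pairs$.call & !pairs$label)
  roc <- roc_points(pairs$label, pairs$.score)
  auc <- if (length(unique(pairs$label)) < 2) NA_real_ else trapezoid_auc(roc)

  ord <- order(-pairs$.score)
  npos <- sum(pairs$label)
  enr <- tibble(
    frac_screened = seq_len(nrow(pairs)) / nrow(pairs),
    frac_found = if (npos > 0) cumsum(pairs$label[ord]) / npos else
      rep(NA_real_, nrow(pairs))
  )

  structure(
    list(
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      auc = auc,
      roc = roc,
      enrichment = enr,
      confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
      pairs = pairs,
      score_col = score_col,
      level = level
    ),
    class = "pp_eval"
  )
}

#' @export
print.pp_eval <- function(x, ...) {
  cat("<benchmark evaluation>\n")
  cat(sprintf("  score: %s (%s-level matching)\n", x$score_col, x$level))
  cat(sprintf("  precision %.3f, recall %.3f, AUC %s\n",
              x$precision, x$recall,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["fn"],
              x$confusion["tn"]))
  invisible(x)
}

#' @export
tidy.pp_eval <- function(x, ...) x$roc

#' @export
glance.pp_eval <- function(x, ...) {
  tibble(precision = x$precision, recall = x$recall, auc = x$auc,
         tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
         fn = x$confusion[["fn"]], tn = x$confusion[["tn"]],
         score_col = x$score_col, level = x$level)
}

#' Write evaluation metrics to disk
#'
#' JSON for the scalar metrics plus TSVs for the ROC and enrichment
#' curves, next to each other.
#'
#' @param eval a `pp_eval`.
#' @param path base path; writes `<path>.json`, `<path>_roc.tsv`,
#'   `<path>_enrichment.tsv`.
#' @export
write_evaluation <- function(eval, path) {
  stopifnot(inherits(eval, "pp_eval"))
  jsonlite::write_json(
    list(precision = eval$precision, recall = eval$recall, auc = eval$auc,
         confusion = as.list(eval$confusion), score_col = eval$score_col,
         level = eval$level),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_tsv(eval$roc, paste0(path, "_roc.tsv"), progress = FALSE)
  readr::write_tsv(eval$enrichment, paste0(path, "_enrichment.tsv"),
                   progress = FALSE)
  invisible(path)
}
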