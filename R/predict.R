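#' Distance-bounded shortest paths from one source node
#'
#' Dijkstra search over the network's distance weights, truncated at
#' `d_max`: any node whose shortest distance exceeds the bound is treated
#' as unreachable (this is what keeps proteome-scale searches fast and
#' what limits how far similarity evidence is allowed to propagate).
#' Among equal-distance paths the one with fewer hops wins, then the
#' lexicographically smallest node sequence, so the reported provenance
#' path is deterministic.
#'
#' @param net a `ppnet`.
#' @param source id of the start node (usually a query compound).
#' @param d_max maximum total path distance (default 10).
#' @return tibble with one row per reachable node: `node`, `distance`,
#'   `n_hops`, `path` (list-column: node sequence from `source`).
#' @export
bounded_dijkstra <- function(net, source, d_max = 10) {
  stopifnot(inherits(net, "ppnet"), d_max > 0)
  ids <- net$nodes$id
  if (!source %in% ids) abort(paste0("unknown source node: ", source))
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  adj <- vector("list", n)
  e <- net$edges
  if (nrow(e) > 0) {
    stopifnot(all(e$distance >= .pp_eps))
    ai <- idx[e$a]; bi <- idx[e$b]
    for (i in seq_len(nrow(e))) {
      adj[[ai[i]]] <- rbind(adj[[ai[i]]], c(bi[i], e$distance[i]))
      adj[[bi[i]]] <- rbind(adj[[bi[i]]], c(ai[i], e$distance[i]))
    }
  }
  dist <- rep(Inf, n)
  hops <- rep(Inf, n)
  pkey <- rep(NA_character_, n)
  paths <- vector("list", n)
  done <- rep(FALSE, n)
  s <- idx[[source]]
  dist[s] <- 0; hops[s] <- 0; pkey[s] <- source; paths[[s]] <- source
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0) break
    # min by (distance, hops, lexicographic path)
    u <- open[order(dist[open], hops[open], pkey[open])][1]
    if (dist[u] > d_max) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      v <- nb[j, 1]
      if (done[v]) next
      nd <- dist[u] + nb[j, 2]
      if (nd > d_max) next
      np <- c(paths[[u]], ids[v])
      nk <- paste(np, collapse = "\r")
      if (nd < dist[v] ||
          (nd == dist[v] && (hops[u] + 1 < hops[v] ||
                             (hops[u] + 1 == hops[v] && nk < pkey[v])))) {
        dist[v] <- nd
        hops[v] <- hops[u] + 1
        pkey[v] <- nk
        paths[[v]] <- np
      }
    }
  }
  keep <- which(done)
  tibble(node = ids[keep], distance = dist[keep], n_hops = hops[keep],
         path = paths[keep])
}

#' Score a path by its total distance
#'
#' The raw prediction score is the inverse of the summed edge distances
#' along the path. Because every edge distance is at least 1, scores lie
#' in `(0, 1]`: 1 means a single perfect-similarity hop, and longer or
#' weaker paths score lower.
#'
#' @param distance positive path distance(s).
#' @return `1 / distance`.
#' @export
score_path <- function(distance) {
  if (any(!is.finite(distance)) || any(distance <= 0)) {
    abort("path distance must be positive and finite")
  }
  1 / distance
}

#' Attach global and local Z-scores to a prediction table
#'
#' The (optionally min-max normalized) raw score `s` is standardized two
#' ways: the global Z-score `Gz = (s - mu_G) / sigma_G` uses the mean and
#' standard deviation over the entire prediction population of the run
#' (how good is this hit compared to everything the network proposes);
#' the local Z-score `Lz = (s - mu_L) / sigma_L` uses the score
#' distribution of the one target the row points at (flags promiscuous
#' pockets, whose many inbound hits inflate `mu_L`). Any group with zero
#' standard deviation yields Z = 0 with a warning.
#'
#' @param predictions tibble with at least `score` and a target column.
#' @param normalize `"minmax"` (default) rescales scores to `[0, 1]` over
#'   the run before standardizing; `"none"` uses raw scores. Z-scores are
#'   invariant to this affine choice; it only affects the reported
#'   `score_norm` column.
#' @param local_by `"site"` (default) or `"protein"`: the grouping that
#'   defines one local target population.
#' @return the table with columns `score_norm`, `global_z`, `local_z`
#'   added; the underlying statistics are attached as attribute
#'   `"score_stats"` (fields `mu_g`, `sigma_g` and a per-target tibble
#'   `local`).
#' @export
zscore_predictions <- function(predictions, normalize = c("minmax", "none"),
                               local_by = c("site", "protein")) {
  normalize <- match.arg(normalize)
  local_by <- match.arg(local_by)
  if (nrow(predictions) == 0) abort("empty prediction set")
  target_col <- if (local_by == "site") "site_id" else "protein_id"
  stopifnot(all(c("score", target_col) %in% names(predictions)))
  s <- predictions$score
  if (normalize == "minmax") {
    rng <- range(s)
    sn <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else s
  } else {
    sn <- s
  }
  mu_g <- mean(sn)
  sigma_g <- sd_pop(sn)
  if (sigma_g == 0) {
    warn("global score standard deviation is 0; global Z set to 0")
    gz <- rep(0, length(sn))
  } else {
    gz <- (sn - mu_g) / sigma_g
  }
  grp <- predictions[[target_col]]
  local <- tibble(target = grp, s = sn) |>
    group_by(target = .data$target) |>
    summarise(mu_l = mean(.data$s), sigma_l = sd_pop(.data$s),
              n = dplyr::n(), .groups = "drop")
  mu_l <- local$mu_l[match(grp, local$target)]
  sig_l <- local$sigma_l[match(grp, local$target)]
  lz <- ifelse(sig_l > 0, (sn - mu_l) / sig_l, 0)
  if (any(sig_l == 0)) {
    warn(paste0(sum(local$sigma_l == 0),
                " target group(s) with zero score spread; local Z set to 0"))
  }
  out <- predictions
  out$score_norm <- sn
  out$global_z <- gz
  out$local_z <- lz
  attr(out, "score_stats") <- list(mu_g = mu_g, sigma_g = sigma_g,
                                   local = local, local_by = local_by)
  out
}

# Population (divide-by-n) standard deviation: the Z-scores standardize a
# full prediction population, not a sample.
sd_pop <- function(x) {
  if (length(x) < 2) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' Run the full query-to-target search
#'
#' For every query node, runs the bounded shortest-path search, keeps the
#' target binding-site nodes (role `site_model`), scores each hit by
#' inverse path distance, aggregates a per-protein score (maximum over
#' that protein's sites — the best-pocket convention), and attaches
#' global/local Z-scores over the whole run.
#'
#' @param net an assembled and integrated `ppnet`.
#' @param d_max maximum path distance (default 10).
#' @param queries query node ids; default all `query`-role nodes.
#' @param normalize passed to [zscore_predictions()].
#' @param local_by passed to [zscore_predictions()].
#' @return prediction tibble: `query_id`, `site_id`, `protein_id`,
#'   `distance`, `score`, `protein_score`, `score_norm`, `global_z`,
#'   `local_z`, `path` (list-column). Unreachable queries contribute no
#'   rows (and are reported).
#' @export
predict_all <- function(net, d_max = 10, queries = NULL,
                        normalize = c("minmax", "none"),
                        local_by = c("site", "protein")) {
  stopifnot(inherits(net, "ppnet"))
  queries <- queries %||% net$nodes$id[net$nodes$role == "query"]
  targets <- net$nodes[net$nodes$role == "site_model", ]
  if (length(queries) == 0) abort("no query nodes to predict for")
  rows <- purrr::map(queries, function(q) {
    hits <- bounded_dijkstra(net, q, d_max = d_max)
    hits <- hits[hits$node %in% targets$id & hits$node != q, , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    tibble(query_id = q, site_id = hits$node,
           protein_id = targets$protein_id[match(hits$node, targets$id)],
           distance = hits$distance, score = score_path(hits$distance),
           path = hits$path)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    inform(paste0("predict_all: ", sum(empty), " query/ies reached no target"))
  }
  pred <- bind_rows(rows)
  if (nrow(pred) == 0) {
    return(tibble(query_id = character(), site_id = character(),
                  protein_id = character(), distance = numeric(),
                  score = numeric(), protein_score = numeric(),
                  score_norm = numeric(), global_z = numeric(),
                  local_z = numeric(), path = list()))
  }
  pred <- pred |>
    group_by(.data$query_id, .data$protein_id) |>
    mutate(protein_score = max(.data$score)) |>
    ungroup()
  pred <- zscore_predictions(pred, normalize = normalize, local_by = local_by)
  pred[, c("query_id", "site_id", "protein_id", "distance", "score",
           "protein_score", "score_norm", "global_z", "local_z", "path")]
}

#' Write a prediction table as TSV
#'
#' Columns: `query_id`, `protein_id`, `site_id`, `score`, `global_z`,
#' `local_z`, `classifier_prob`, `classifier_label`, `path` (node sequence
#' joined by `->`). Classifier columns are `NA` when the rows have not
#' been classified yet.
#'
#' @param predictions prediction tibble.
#' @param path output file.
#' @export
write_predictions <- function(predictions, path) {
  grab <- function(col, default) {
    if (col %in% names(predictions)) predictions[[col]] else default
  }
  out <- tibble(
    query_id = predictions$query_id,
    protein_id = predictions$protein_id,
    site_id = predictions$site_id,
    score = predictions$score,
    global_z = predictions$global_z,
    local_z = predictions$local_z,
    classifier_prob = grab("classifier_prob", NA_real_),
    classifier_label = grab("classifier_label", NA),
    path = vapply(predictions$path, paste, character(1), collapse = "->")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
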