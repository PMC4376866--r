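#' Group mutually similar nodes into cluster vertices
#'
#' Redundancy reduction of one sub-network. Two modes:
#'
#' * `clique` (default): a greedy maximal-clique cover — every pair of
#'   nodes inside a multi-node cluster shares a similarity edge. Maximal
#'   cliques are visited largest first (ties broken by the
#'   lexicographically smallest sorted member list); each node joins the
#'   first clique that reaches it.
#' * `kcore`: nodes of coreness `>= k` are grouped into the connected
#'   components of the k-core subgraph; all remaining nodes become
#'   singletons.
#'
#' Either way the result is a partition: every node belongs to exactly one
#' cluster, singletons allowed.
#'
#' @param edges tibble of undirected similarity edges (`a`, `b`, `value`).
#' @param node_ids all node ids (so isolated nodes get singleton
#'   clusters); defaults to the ids present in `edges`.
#' @param mode `"clique"` or `"kcore"`.
#' @param k minimum degree for `kcore` mode (`>= 1`).
#' @param prefix cluster-id prefix.
#' @return tibble with columns `member_id`, `cluster_id`; clusters are
#'   numbered by descending size then smallest member id.
#' @export
find_clusters <- function(edges, node_ids = NULL, mode = c("clique", "kcore"),
                          k = 2, prefix = "C") {
  mode <- match.arg(mode)
  if (k < 1) abort("k must be >= 1")
  node_ids <- sort(unique(c(node_ids, edges$a, edges$b)))
  if (length(node_ids) == 0) {
    return(tibble(member_id = character(), cluster_id = character()))
  }
  if (nrow(edges) > 0 && any(edges$a == edges$b)) abort("graph must be simple")
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = node_ids)
  )
  g <- igraph::simplify(g)
  groups <- switch(mode,
    clique = clique_cover(g),
    kcore = kcore_components(g, k)
  )
  # Deterministic cluster numbering: size desc, then smallest member id.
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  tibble(
    member_id = unlist(groups),
    cluster_id = rep(sprintf("%s%04d", prefix, seq_along(groups)), lengths(groups))
  )
}

# Greedy cover by maximal cliques, largest first, lexicographic tie-break.
clique_cover <- function(g) {
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  key <- vapply(cl, paste, character(1), collapse = "\r")
  cl <- cl[order(-lengths(cl), key)]
  assigned <- character(0)
  groups <- list()
  for (clique in cl) {
    left <- setdiff(clique, assigned)
    if (length(left) > 0) {
      groups[[length(groups) + 1]] <- left
      assigned <- c(assigned, left)
    }
  }
  leftover <- setdiff(igraph::V(g)$name, assigned)
  c(groups, as.list(leftover))
}

# Multi-node clusters = connected components of the k-core; rest singleton.
kcore_components <- function(g, k) {
  core <- igraph::coreness(g)
  in_core <- names(core)[core >= k]
  groups <- list()
  if (length(in_core) > 0) {
    sub <- igraph::induced_subgraph(g, in_core)
    comp <- igraph::components(sub)
    groups <- split(names(comp$membership), comp$membership)
    groups <- unname(lapply(groups, as.character))
  }
  singles <- setdiff(igraph::V(g)$name, in_core)
  c(groups, as.list(singles))
}

#' Collapse a similarity graph onto its clusters
#'
#' Builds the cluster-level graph: clusters are joined iff at least one
#' original edge crosses them, and the cluster edge takes the maximum
#' value over all crossing member pairs. Intra-cluster edges vanish; no
#' self-loops are produced.
#'
#' @param edges original similarity edges (`a`, `b`, `value`).
#' @param clusters membership tibble from [find_clusters()].
#' @return tibble of cluster edges (`a`, `b`, `value`) with `a < b`.
#' @export
condense_network <- function(edges, clusters) {
  stopifnot(all(c("member_id", "cluster_id") %in% names(clusters)))
  if (nrow(edges) == 0) {
    return(tibble(a = character(), b = character(), value = numeric()))
  }
  missing <- setdiff(unique(c(edges$a, edges$b)), clusters$member_id)
  if (length(missing) > 0) {
    abort(paste0("node(s) absent from every cluster: ",
                 paste(missing, collapse = ", ")))
  }
  ca <- clusters$cluster_id[match(edges$a, clusters$member_id)]
  cb <- clusters$cluster_id[match(edges$b, clusters$member_id)]
  keep <- ca != cb
  crossing <- tibble(a = pmin(ca[keep], cb[keep]),
                     b = pmax(ca[keep], cb[keep]),
                     value = edges$value[keep])
  out <- if (nrow(crossing) == 0) {
    crossing
  } else {
    crossing |>
      group_by(.data$a, .data$b) |>
      summarise(value = max(.data$value), .groups = "drop")
  }
  inform(paste0("condense_network: ", length(unique(clusters$cluster_id)),
                " clusters, ", nrow(out), " cluster edges"))
  out
}

#' Write cluster membership as a two-column TSV
#'
#' @param clusters membership tibble (`member_id`, `cluster_id`).
#' @param path output file.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(clusters[, c("member_id", "cluster_id")], path,
                   progress = FALSE)
  invisible(path)
}
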