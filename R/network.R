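#' Construct a bipartite ligand/binding-site network
#'
#' The central container of the pipeline: two node partitions (`ligand`,
#' `site`) joined by typed edges. Similarity edges (`ligand`, `site`,
#' `site_model` kinds) must stay within a partition; `interaction` edges
#' must cross it. The graph is simple: no self-loops, no parallel edges
#' (undirected; `a`/`b` order is canonicalized).
#'
#' @param nodes tibble with columns `id`, `partition` (`"ligand"`/`"site"`),
#'   `role` (`"cluster"`, `"query"`, `"site_model"`), `protein_id`
#'   (sites only, else `NA`), `members` (list-column of member ids),
#'   `unreachable` (logical).
#' @param edges tibble with columns `a`, `b`, `kind`, `similarity`,
#'   `distance`, `evidence` (list-column of character vectors),
#'   `identity` (logical: created by exact structure identity).
#' @return an object of class `ppnet`.
#' @export
bipartite_network <- function(nodes = NULL, edges = NULL) {
  nodes <- nodes %||% empty_nodes()
  edges <- edges %||% empty_edges()
  nodes <- as_tibble(nodes)
  if (!"protein_id" %in% names(nodes)) nodes$protein_id <- NA_character_
  if (!"members" %in% names(nodes)) nodes$members <- as.list(nodes$id)
  if (!"unreachable" %in% names(nodes)) nodes$unreachable <- FALSE
  edges <- normalize_edges(as_tibble(edges))
  net <- structure(list(nodes = nodes, edges = edges), class = "ppnet")
  validate_network(net)
}

empty_nodes <- function() {
  tibble(id = character(), partition = character(), role = character(),
         protein_id = character(), members = list(), unreachable = logical())
}

empty_edges <- function() {
  tibble(a = character(), b = character(), kind = character(),
         similarity = numeric(), distance = numeric(), evidence = list(),
         identity = logical())
}

normalize_edges <- function(edges) {
  if (!"similarity" %in% names(edges)) edges$similarity <- NA_real_
  if (!"distance" %in% names(edges)) {
    edges$distance <- similarity_to_distance(edges$similarity)
  }
  if (!"evidence" %in% names(edges)) edges$evidence <- rep(list(character()), nrow(edges))
  if (!"identity" %in% names(edges)) edges$identity <- FALSE
  if (nrow(edges) > 0) {
    lo <- pmin(edges$a, edges$b)
    hi <- pmax(edges$a, edges$b)
    edges$a <- lo
    edges$b <- hi
  }
  edges[, c("a", "b", "kind", "similarity", "distance", "evidence", "identity")]
}

#' Validate bipartite-network invariants
#'
#' Fails with the offending edge/node when any structural invariant is
#' violated: unknown endpoints, self-loops, parallel edges, a similarity
#' edge crossing partitions, an interaction edge inside one partition, or
#' overlapping cluster member sets.
#'
#' @param net a `ppnet`.
#' @return `net`, invisibly usable in pipes.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "ppnet"))
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  if (!all(nodes$partition %in% c("ligand", "site"))) {
    abort("node partition must be 'ligand' or 'site'")
  }
  members <- unlist(nodes$members[nodes$role == "cluster"])
  if (anyDuplicated(members)) {
    abort(paste0("cluster member sets overlap: ",
                 paste(unique(members[duplicated(members)]), collapse = ", ")))
  }
  if (nrow(edges) == 0) return(invisible(net))
  bad <- setdiff(c(edges$a, edges$b), nodes$id)
  if (length(bad) > 0) {
    abort(paste0("edge endpoint(s) not in node table: ", paste(bad, collapse = ", ")))
  }
  if (any(edges$a == edges$b)) abort("self-loop edge")
  key <- paste(edges$a, edges$b)
  if (anyDuplicated(key)) {
    abort(paste0("parallel edges: ", key[duplicated(key)][1]))
  }
  pa <- nodes$partition[match(edges$a, nodes$id)]
  pb <- nodes$partition[match(edges$b, nodes$id)]
  cross <- pa != pb
  is_int <- edges$kind == "interaction"
  if (any(!is_int & cross)) {
    i <- which(!is_int & cross)[1]
    abort(paste0("similarity edge crosses partitions: ",
                 edges$a[i], " -- ", edges$b[i]))
  }
  if (any(is_int & !cross)) {
    i <- which(is_int & !cross)[1]
    abort(paste0("interaction edge inside one partition: ",
                 edges$a[i], " -- ", edges$b[i]))
  }
  if (any(edges$distance < 1 - 1e-12)) abort("edge distance below 1")
  invisible(net)
}

#' @export
print.ppnet <- function(x, ...) {
  n <- x$nodes
  e <- x$edges
  cat("<bipartite ligand/site network>\n")
  cat("  nodes:", nrow(n),
      sprintf("(%d ligand, %d site)", sum(n$partition == "ligand"),
              sum(n$partition == "site")), "\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(n$role)), table(n$role)),
                        collapse = ", "), "\n")
  cat("  edges:", nrow(e),
      if (nrow(e) > 0) {
        paste0("(", paste(sprintf("%s=%d", names(table(e$kind)), table(e$kind)),
                          collapse = ", "), ")")
      } else "", "\n")
  invisible(x)
}

#' Add nodes/edges to a network (internal constructor helpers)
#' @noRd
add_nodes <- function(net, nodes) {
  net$nodes <- bind_rows(net$nodes, nodes)
  net
}

#' @noRd
add_edges <- function(net, edges) {
  net$edges <- bind_rows(net$edges, normalize_edges(edges))
  net
}

#' Serialize a network to disk
#'
#' Two formats: a JSON dialect (nodes and edges as records; lossless,
#' diff-able) and GraphML (interoperable with graph tooling). Numeric
#' weights survive a round-trip to better than 1e-9.
#'
#' @param net a `ppnet`.
#' @param path output file.
#' @param format `"json"` or `"graphml"`; default guessed from the
#'   extension.
#' @export
write_network <- function(net, path, format = NULL) {
  validate_network(net)
  format <- format %||% guess_net_format(path)
  switch(format,
    json = write_network_json(net, path),
    graphml = write_network_graphml(net, path),
    abort(paste0("unknown network format: ", format))
  )
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' Invariants are re-checked on read, so a corrupted file (for example a
#' similarity edge crossing partitions) fails loudly.
#'
#' @param path file produced by [write_network()].
#' @param format `"json"` or `"graphml"`; default guessed from extension.
#' @return a `ppnet`.
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  format <- format %||% guess_net_format(path)
  switch(format,
    json = read_network_json(path),
    graphml = read_network_graphml(path),
    abort(paste0("unknown network format: ", format))
  )
}

guess_net_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json")) return("json")
  if (ext %in% c("graphml", "xml")) return("graphml")
  abort(paste0("cannot guess network format from extension: ", path))
}

write_network_json <- function(net, path) {
  payload <- list(
    format = "pocketpath-network",
    version = 1L,
    nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
      n <- net$nodes[i, ]
      list(id = n$id, partition = n$partition, role = n$role,
           protein_id = n$protein_id, members = as.list(n$members[[1]]),
           unreachable = n$unreachable)
    }),
    edges = lapply(seq_len(nrow(net$edges)), function(i) {
      e <- net$edges[i, ]
      list(a = e$a, b = e$b, kind = e$kind, similarity = e$similarity,
           distance = e$distance, evidence = as.list(e$evidence[[1]]),
           identity = e$identity)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_network_json <- function(path) {
  p <- jsonlite::read_json(path)
  if (!identical(p$format, "pocketpath-network")) {
    abort("not a pocketpath network JSON file")
  }
  nodes <- bind_rows(lapply(p$nodes, function(n) {
    tibble(id = n$id, partition = n$partition, role = n$role,
           protein_id = n$protein_id %||% NA_character_,
           members = list(as.character(unlist(n$members))),
           unreachable = isTRUE(n$unreachable))
  }))
  edges <- bind_rows(lapply(p$edges, function(e) {
    tibble(a = e$a, b = e$b, kind = e$kind,
           similarity = as.numeric(e$similarity %||% NA_real_),
           distance = as.numeric(e$distance),
           evidence = list(as.character(unlist(e$evidence))),
           identity = isTRUE(e$identity))
  }))
  bipartite_network(if (length(p$nodes) > 0) nodes else empty_nodes(),
                    if (length(p$edges) > 0) edges else empty_edges())
}

# GraphML: node data keys partition/role/protein_id/members/unreachable,
# edge keys kind/similarity/distance/evidence/identity. List columns are
# "|"-joined (ids never contain "|").
write_network_graphml <- function(net, path) {
  num <- function(x) sprintf("%.17g", x)
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("d_part", "node", "partition", "string"),
    c("d_role", "node", "role", "string"),
    c("d_prot", "node", "protein_id", "string"),
    c("d_memb", "node", "members", "string"),
    c("d_unre", "node", "unreachable", "boolean"),
    c("d_kind", "edge", "kind", "string"),
    c("d_sim", "edge", "similarity", "double"),
    c("d_dist", "edge", "distance", "double"),
    c("d_evid", "edge", "evidence", "string"),
    c("d_iden", "edge", "identity", "boolean")
  )
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(net$nodes))) {
    n <- net$nodes[i, ]
    nd <- xml2::xml_add_child(g, "node", id = n$id)
    xml2::xml_add_child(nd, "data", n$partition, key = "d_part")
    xml2::xml_add_child(nd, "data", n$role, key = "d_role")
    if (!is.na(n$protein_id)) xml2::xml_add_child(nd, "data", n$protein_id, key = "d_prot")
    xml2::xml_add_child(nd, "data", paste(n$members[[1]], collapse = "|"), key = "d_memb")
    xml2::xml_add_child(nd, "data", tolower(as.character(n$unreachable)), key = "d_unre")
  }
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    ed <- xml2::xml_add_child(g, "edge", source = e$a, target = e$b)
    xml2::xml_add_child(ed, "data", e$kind, key = "d_kind")
    if (!is.na(e$similarity)) xml2::xml_add_child(ed, "data", num(e$similarity), key = "d_sim")
    xml2::xml_add_child(ed, "data", num(e$distance), key = "d_dist")
    xml2::xml_add_child(ed, "data", paste(e$evidence[[1]], collapse = "|"), key = "d_evid")
    xml2::xml_add_child(ed, "data", tolower(as.character(e$identity)), key = "d_iden")
  }
  xml2::write_xml(doc, path)
}

read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("./data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  split_bar <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
  }
  node_xml <- xml2::xml_find_all(doc, ".//graph/node")
  nodes <- bind_rows(lapply(node_xml, function(n) {
    tibble(
      id = xml2::xml_attr(n, "id"),
      partition = get_data(n, "d_part"),
      role = get_data(n, "d_role"),
      protein_id = get_data(n, "d_prot"),
      members = list(split_bar(get_data(n, "d_memb"))),
      unreachable = identical(get_data(n, "d_unre"), "true")
    )
  }))
  edge_xml <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- bind_rows(lapply(edge_xml, function(e) {
    tibble(
      a = xml2::xml_attr(e, "source"),
      b = xml2::xml_attr(e, "target"),
      kind = get_data(e, "d_kind"),
      similarity = as.numeric(get_data(e, "d_sim")),
      distance = as.numeric(get_data(e, "d_dist")),
      evidence = list(split_bar(get_data(e, "d_evid"))),
      identity = identical(get_data(e, "d_iden"), "true")
    )
  }))
  bipartite_network(if (length(node_xml) > 0) nodes else empty_nodes(),
                    if (length(edge_xml) > 0) edges else empty_edges())
}
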