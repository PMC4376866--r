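#' Assemble the bipartite network from two condensed sub-networks
#'
#' Turns cluster memberships and cluster-level similarity edges for the
#' ligand and binding-site partitions into one `ppnet`, ready for
#' interaction linking and query/target integration.
#'
#' @param ligand_clusters,site_clusters membership tibbles from
#'   [find_clusters()] (columns `member_id`, `cluster_id`).
#' @param ligand_edges,site_edges cluster-level similarity edges from
#'   [condense_network()] (columns `a`, `b`, `value`).
#' @return a `ppnet` with one `cluster` node per cluster and intra-partition
#'   similarity edges.
#' @export
assemble_network <- function(ligand_clusters, ligand_edges,
                             site_clusters, site_edges) {
  cl_nodes <- function(clusters, partition) {
    if (nrow(clusters) == 0) return(empty_nodes())
    clusters |>
      group_by(cluster_id = .data$cluster_id) |>
      summarise(members = list(sort(.data$member_id)), .groups = "drop") |>
      transmute(id = .data$cluster_id, partition = partition, role = "cluster",
                protein_id = NA_character_, members = .data$members,
                unreachable = FALSE)
  }
  sim_edges <- function(edges, kind) {
    if (nrow(edges) == 0) return(empty_edges())
    tibble(a = edges$a, b = edges$b, kind = kind, similarity = edges$value,
           distance = similarity_to_distance(edges$value),
           evidence = rep(list(character()), nrow(edges)), identity = FALSE)
  }
  bipartite_network(
    bind_rows(cl_nodes(ligand_clusters, "ligand"), cl_nodes(site_clusters, "site")),
    bind_rows(sim_edges(ligand_edges, "ligand"), sim_edges(site_edges, "site"))
  )
}

member_lookup <- function(net, partition) {
  nodes <- net$nodes[net$nodes$partition == partition, ]
  tibble(
    member_id = unlist(nodes$members),
    node_id = rep(nodes$id, lengths(nodes$members))
  )
}

#' Link observed ligand-site interactions into the network
#'
#' An interaction edge joins a ligand cluster and a site cluster when at
#' least one observed (ligand, site) member pair crosses them. Multiple
#' observations mapping to the same cluster pair collapse into one edge
#' whose evidence list keeps every supporting record. Interaction edges
#' carry distance 1 (an observed complex is a maximally reliable hop).
#'
#' @param net a `ppnet` from [assemble_network()].
#' @param observed tibble with columns `ligand_id`, `site_id`, `evidence`
#'   (complex identifier, e.g. a PDB code).
#' @return the network with interaction edges added; the number of
#'   observations whose ids did not resolve is attached as attribute
#'   `"n_skipped"` (also warned about).
#' @export
link_interactions <- function(net, observed) {
  stopifnot(all(c("ligand_id", "site_id") %in% names(observed)))
  if (!"evidence" %in% names(observed)) observed$evidence <- NA_character_
  lig <- member_lookup(net, "ligand")
  sit <- member_lookup(net, "site")
  ln <- lig$node_id[match(observed$ligand_id, lig$member_id)]
  sn <- sit$node_id[match(observed$site_id, sit$member_id)]
  ok <- !is.na(ln) & !is.na(sn)
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    warn(paste0("link_interactions: skipped ", n_skip,
                " observation(s) with unresolvable ids"))
  }
  if (any(ok)) {
    grouped <- tibble(a = ln[ok], b = sn[ok],
                      evidence = as.character(observed$evidence[ok])) |>
      group_by(.data$a, .data$b) |>
      summarise(evidence = list(.data$evidence), .groups = "drop")
    edges <- tibble(a = grouped$a, b = grouped$b, kind = "interaction",
                    similarity = 1, distance = 1,
                    evidence = grouped$evidence, identity = FALSE)
    net <- add_edges(net, edges)
  }
  net <- validate_network(net)
  attr(net, "n_skipped") <- n_skip
  net
}

#' Integrate modeled target binding sites
#'
#' Modeled pockets (e.g. from comparative models of a whole proteome) are
#' admitted through a fixed filter cascade, then attached to the site
#' partition by similarity edges. Stages, in order:
#'
#' 1. model quality: drop sites with `quality < quality_min` (default 1.1,
#'    a ModPipe-style composite score);
#' 2. transfer confidence: keep a modeled site only if some comparison row
#'    against a known site has both site sequence identity and site
#'    structure identity strictly above `id_min` (default 40; structure
#'    identity means Calpha atoms within 4 A after optimal superposition);
#' 3. size and redundancy: drop sites with fewer than `min_residues`
#'    (default 6) residues, then scan sites by descending residue count
#'    (ties: ascending id) and drop any site with more than
#'    `redundancy_pct` (default 80) sequence identity to an already-kept
#'    site;
#' 4. connection: rows with `z > z_min` (default 1.0, strict) become
#'    `site_model` similarity edges weighted by the normalized Z-score.
#'
#' Each surviving site becomes its own `site_model` node (modeled sites
#' are not condensed).
#'
#' @param net a `ppnet`.
#' @param model_sites tibble: `id`, `protein_id`, `n_residues`, `quality`.
#' @param comparisons tibble: `model_site`, `known_site`, `seq_id_site`,
#'   `struct_id_site`, `z` — one row per (modeled site, known site)
#'   structural comparison.
#' @param site_identity optional tibble `site_a`, `site_b`, `seq_id` of
#'   pairwise sequence identities among modeled sites, used by the
#'   redundancy scan (stage 3); omitted = no redundancy information, no
#'   drops.
#' @param quality_min,id_min,min_residues,redundancy_pct,z_min stage
#'   thresholds, see above.
#' @return the network with surviving model-site nodes and their edges;
#'   per-stage counts are attached as attribute `"filter_log"` and
#'   reported via [message()].
#' @export
integrate_target_sites <- function(net, model_sites, comparisons,
                                   site_identity = NULL,
                                   quality_min = 1.1, id_min = 40,
                                   min_residues = 6, redundancy_pct = 80,
                                   z_min = 1.0) {
  stopifnot(all(c("id", "protein_id", "n_residues", "quality") %in% names(model_sites)))
  stopifnot(all(c("model_site", "known_site", "seq_id_site", "struct_id_site", "z")
                %in% names(comparisons)))
  log <- c(input = nrow(model_sites))

  known <- member_lookup(net, "site")
  unknown_rows <- !(comparisons$known_site %in% known$member_id) |
    !(comparisons$model_site %in% model_sites$id)
  if (any(unknown_rows)) {
    warn(paste0("integrate_target_sites: skipped ", sum(unknown_rows),
                " comparison row(s) referencing unknown sites"))
    comparisons <- comparisons[!unknown_rows, , drop = FALSE]
  }

  # stage 1: model quality
  s1 <- model_sites[!is.na(model_sites$quality) &
                      model_sites$quality >= quality_min, , drop = FALSE]
  log["after_quality"] <- nrow(s1)

  # stage 2: accepted only with a confident site-level match (both > id_min)
  hit <- comparisons$seq_id_site > id_min & comparisons$struct_id_site > id_min
  accepted_ids <- unique(comparisons$model_site[hit])
  s2 <- s1[s1$id %in% accepted_ids, , drop = FALSE]
  log["after_identity"] <- nrow(s2)

  # stage 3a: size
  s3 <- s2[s2$n_residues >= min_residues, , drop = FALSE]
  log["after_size"] <- nrow(s3)

  # stage 3b: redundancy, deterministic first-seen-wins scan
  s3 <- s3[order(-s3$n_residues, s3$id), , drop = FALSE]
  kept <- character(0)
  if (!is.null(site_identity)) {
    stopifnot(all(c("site_a", "site_b", "seq_id") %in% names(site_identity)))
    idkey <- c(paste(site_identity$site_a, site_identity$site_b),
               paste(site_identity$site_b, site_identity$site_a))
    idval <- c(site_identity$seq_id, site_identity$seq_id)
    for (sid in s3$id) {
      pid <- idval[match(paste(sid, kept), idkey)]
      if (!any(!is.na(pid) & pid > redundancy_pct)) kept <- c(kept, sid)
    }
  } else {
    kept <- s3$id
  }
  s4 <- s3[s3$id %in% kept, , drop = FALSE]
  log["after_redundancy"] <- nrow(s4)

  # stage 4: similarity edges, strict z > z_min, weight = normalized Z
  cmp <- comparisons[comparisons$model_site %in% s4$id & comparisons$z > z_min, ,
                     drop = FALSE]
  cl <- known$node_id[match(cmp$known_site, known$member_id)]
  edges <- tibble(a = cmp$model_site, b = cl, kind = "site_model",
                  similarity = normalize_z(cmp$z, z_ref = z_min),
                  distance = NA_real_,
                  evidence = as.list(cmp$known_site), identity = FALSE) |>
    group_by(.data$a, .data$b) |>
    summarise(similarity = max(.data$similarity),
              evidence = list(unlist(.data$evidence)),
              kind = "site_model", identity = FALSE, .groups = "drop") |>
    mutate(distance = similarity_to_distance(.data$similarity))
  log["edges"] <- nrow(edges)

  nodes <- tibble(id = s4$id, partition = "site", role = "site_model",
                  protein_id = s4$protein_id, members = as.list(s4$id),
                  unreachable = FALSE)
  net <- add_nodes(net, nodes)
  if (nrow(edges) > 0) net <- add_edges(net, edges)
  net <- validate_network(net)
  inform(paste0("integrate_target_sites: ",
                paste(names(log), log, sep = "=", collapse = ", ")))
  attr(net, "filter_log") <- log
  net
}

#' Integrate query compounds into the ligand partition
#'
#' Each query becomes a `query` node in the ligand partition, linked to
#' ligand clusters whose member compounds the pair classifier calls
#' similar. When several members of one cluster match, only the
#' highest-probability link is retained. A query identical to a network
#' compound (canonical-structure equality, or probability exactly 1) gets
#' an identity edge with similarity exactly 1. Queries with no link are
#' kept as nodes but flagged unreachable.
#'
#' @param net a `ppnet`.
#' @param queries tibble of query compounds (`id`, optionally `cansmi`).
#' @param pair_probs tibble `query_id`, `compound_id`, `prob` of
#'   classifier probabilities against network member compounds. Supply
#'   either this (the precomputed bypass) or `pair_model` + `compounds`.
#' @param pair_model a trained [train_pair_classifier()] model.
#' @param compounds featurized network member compounds (needed with
#'   `pair_model`).
#' @param threshold minimum probability that creates an edge (default
#'   0.5).
#' @return the network with query nodes and their ligand edges.
#' @export
integrate_query_compounds <- function(net, queries, pair_probs = NULL,
                                      pair_model = NULL, compounds = NULL,
                                      threshold = 0.5) {
  stopifnot("id" %in% names(queries))
  lig <- member_lookup(net, "ligand")
  if (is.null(pair_probs)) {
    if (is.null(pair_model) || is.null(compounds)) {
      abort("supply pair_probs, or pair_model together with compounds")
    }
    pool <- compounds[compounds$id %in% lig$member_id, , drop = FALSE]
    pairs <- tidyr::expand_grid(id_a = queries$id, id_b = pool$id)
    feats <- compound_pair_features(bind_rows(queries, pool), pairs)
    prob <- predict_pair_probability(pair_model, feats)
    pair_probs <- tibble(query_id = pairs$id_a, compound_id = pairs$id_b,
                         prob = prob)
  }
  stopifnot(all(c("query_id", "compound_id", "prob") %in% names(pair_probs)))

  # exact-structure identity forces probability 1
  if ("cansmi" %in% names(queries) && !is.null(compounds) &&
      "cansmi" %in% names(compounds)) {
    qs <- queries$cansmi[match(pair_probs$query_id, queries$id)]
    cs <- compounds$cansmi[match(pair_probs$compound_id, compounds$id)]
    ident <- !is.na(qs) & !is.na(cs) & qs == cs
    pair_probs$prob[ident] <- 1
  }

  hits <- pair_probs |>
    filter(.data$prob >= threshold) |>
    mutate(node_id = lig$node_id[match(.data$compound_id, lig$member_id)]) |>
    filter(!is.na(.data$node_id))
  hits <- if (nrow(hits) == 0) {
    tibble(query_id = character(), node_id = character(), prob = numeric())
  } else {
    hits |>
      group_by(query_id = .data$query_id, node_id = .data$node_id) |>
      summarise(prob = max(.data$prob), .groups = "drop")
  }

  nodes <- tibble(id = queries$id, partition = "ligand", role = "query",
                  protein_id = NA_character_, members = as.list(queries$id),
                  unreachable = !(queries$id %in% hits$query_id))
  if (any(nodes$unreachable)) {
    inform(paste0("integrate_query_compounds: ", sum(nodes$unreachable),
                  " unreachable query node(s)"))
  }
  net <- add_nodes(net, nodes)
  if (nrow(hits) > 0) {
    edges <- tibble(a = hits$query_id, b = hits$node_id, kind = "ligand",
                    similarity = hits$prob,
                    distance = similarity_to_distance(hits$prob),
                    evidence = rep(list(character()), nrow(hits)),
                    identity = hits$prob == 1)
    net <- add_edges(net, edges)
  }
  validate_network(net)
}
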