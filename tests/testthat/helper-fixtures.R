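# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data files.

# A small hand-made network:
#   ligand partition: clusters LC1 {l1, l2}, LC2 {l3}; query q1
#   site partition:   clusters SC1 {s1, s2}, SC2 {s3}; model sites m1, m2
toy_network <- function() {
  nodes <- tibble::tibble(
    id = c("LC1", "LC2", "SC1", "SC2", "m1", "m2", "q1"),
    partition = c("ligand", "ligand", "site", "site", "site", "site", "ligand"),
    role = c("cluster", "cluster", "cluster", "cluster", "site_model",
             "site_model", "query"),
    protein_id = c(NA, NA, NA, NA, "prot1", "prot2", NA),
    members = list(c("l1", "l2"), "l3", c("s1", "s2"), "s3", "m1", "m2", "q1"),
    unreachable = FALSE
  )
  edges <- tibble::tibble(
    a = c("LC1", "SC1", "LC1", "SC1", "SC2", "q1"),
    b = c("LC2", "SC2", "SC1", "m1", "m2", "LC1"),
    kind = c("ligand", "site", "interaction", "site_model", "site_model",
             "ligand"),
    similarity = c(0.5, 0.8, 1, 0.8, 0.5, 0.8)
  )
  bipartite_network(nodes, edges)
}

# Random undirected weighted simple graph as an edge tibble.
random_edge_table <- function(n_nodes, p_edge = 0.4, seed = 1,
                              ids = sprintf("n%02d", seq_len(n_nodes))) {
  set.seed(seed)
  idx <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(idx)) < p_edge
  tibble::tibble(
    a = ids[idx[1, keep]],
    b = ids[idx[2, keep]],
    value = round(stats::runif(sum(keep), 0.2, 1), 3)
  )
}

# Exhaustive all-simple-paths shortest distance oracle (distances = 1/value).
brute_force_shortest <- function(edges, source, d_max = Inf) {
  ids <- sort(unique(c(edges$a, edges$b)))
  dist_of <- function(a, b) {
    hit <- (edges$a == a & edges$b == b) | (edges$a == b & edges$b == a)
    if (!any(hit)) return(NA_real_)
    1 / max(edges$value[hit])
  }
  best <- stats::setNames(rep(Inf, length(ids)), ids)
  best[source] <- 0
  walk <- function(node, d, visited) {
    for (nb in ids[!(ids %in% visited)]) {
      w <- dist_of(node, nb)
      if (is.na(w)) next
      nd <- d + w
      if (nd > d_max) next
      if (nd < best[[nb]]) best[[nb]] <<- nd
      walk(nb, nd, c(visited, nb))
    }
  }
  walk(source, 0, source)
  best[is.finite(best)]
}

# Iterative k-core peeling oracle: returns surviving node ids.
kcore_peel_oracle <- function(edges, ids, k) {
  repeat {
    deg <- stats::setNames(rep(0L, length(ids)), ids)
    e <- edges[edges$a %in% ids & edges$b %in% ids, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      deg[e$a[i]] <- deg[e$a[i]] + 1L
      deg[e$b[i]] <- deg[e$b[i]] + 1L
    }
    drop <- names(deg)[deg < k]
    if (length(drop) == 0) return(ids)
    ids <- setdiff(ids, drop)
    if (length(ids) == 0) return(character(0))
  }
}

# Rank-statistic (Mann-Whitney) AUC, independent of the package's ROC code.
auc_oracle <- function(labels, scores) {
  r <- rank(scores)
  p <- sum(labels)
  n <- sum(!labels)
  if (p == 0 || n == 0) return(NA_real_)
  (sum(r[labels]) - p * (p + 1) / 2) / (p * n)
}

# Population sd, for the Z-score contract.
sd_pop_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# Synthetic featurized compounds without any chemistry dependency.
fake_featurized_compounds <- function(n, seed = 1, fp_bits = 64) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("c%03d", seq_len(n)),
    smiles = NA_character_,
    wqed = stats::runif(n),
    fingerprint = lapply(seq_len(n),
                         function(i) as.integer(stats::runif(fp_bits) < 0.3)),
    mw = stats::runif(n, 100, 600),
    logp = stats::runif(n, -2, 6),
    tpsa = stats::runif(n, 10, 150),
    hba = sample(0:10, n, replace = TRUE),
    hbd = sample(0:5, n, replace = TRUE),
    rotb = sample(0:12, n, replace = TRUE),
    arom = sample(0:4, n, replace = TRUE)
  )
}

# A small synthetic universe (fast) for pipeline-level tests.
small_synth_config <- function(seed = 3) {
  synth_config(n_scaffolds = 4, ligands_per_scaffold = 4,
               n_pocket_classes = 4, sites_per_class = 3,
               n_queries = 6, seed = seed)
}

# Hand-built 10-site integration fixture for the filter cascade, used
# against toy_network() (site clusters SC1 {s1, s2}, SC2 {s3}).
# Hand derivation:
#   t02 (quality 1.0), t10 (0.9)      -> dropped at the quality stage
#   t03 (45/39: struct <= 40)         -> dropped at the identity stage
#   t05 (5 residues)                  -> dropped at the size stage
#   redundancy scan order (desc residues, asc id):
#     t08(13), t06(11), t01(10), t07(9), t04(8), t09(7)
#     t07 is 85% identical to kept t06 -> dropped
#     t04 is 82% identical to kept t08 -> dropped
#     t09 is exactly 80% identical to t01 -> kept (rule is strictly > 80)
#   survivors: t01, t06, t08, t09
model_site_fixture <- function() {
  list(
    model_sites = tibble::tibble(
      id = sprintf("t%02d", 1:10),
      protein_id = sprintf("hp%02d", 1:10),
      n_residues = c(10, 12, 9, 8, 5, 11, 9, 13, 7, 9),
      quality = c(1.5, 1.0, 1.1, 1.3, 2.0, 1.2, 1.4, 1.15, 1.1, 0.9)
    ),
    comparisons = tibble::tibble(
      model_site = c("t01", "t02", "t03", "t04", "t05", "t06", "t07",
                     "t08", "t08", "t09", "t10"),
      known_site = c("s1", "s1", "s1", "s2", "s1", "s3", "s3",
                     "s2", "s1", "s1", "s1"),
      seq_id_site = c(80, 70, 45, 41, 90, 50, 60, 55, 50, 40.5, 80),
      struct_id_site = c(80, 70, 39, 45, 90, 50, 70, 65, 60, 40.5, 80),
      z = c(5, 3, 2, 0.5, 6, 2, 3, 1.0, 2.5, 1.5, 4)
    ),
    site_identity = tibble::tibble(
      site_a = c("t06", "t08", "t01"),
      site_b = c("t07", "t04", "t09"),
      seq_id = c(85, 82, 80)
    ),
    expected_survivors = c("t01", "t06", "t08", "t09"),
    expected_log = c(input = 10, after_quality = 8, after_identity = 7,
                     after_size = 6, after_redundancy = 4, edges = 4)
  )
}
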