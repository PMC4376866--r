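chain_net <- function() {
  nodes <- tibble::tibble(
    id = c("q", "L", "S", "T"),
    partition = c("ligand", "ligand", "site", "site"),
    role = c("query", "cluster", "cluster", "site_model"),
    protein_id = c(NA, NA, NA, "protT"),
    members = list("q", "L", "S", "T"),
    unreachable = FALSE
  )
  edges <- tibble::tibble(
    a = c("q", "L", "S"), b = c("L", "S", "T"),
    kind = c("ligand", "interaction", "site_model"),
    similarity = c(1, 1, 1)
  )
  bipartite_network(nodes, edges)
}

test_that("a unit chain is traversed at distance 3 with full provenance", {
  hits <- bounded_dijkstra(chain_net(), "q", d_max = 10)
  t <- hits[hits$node == "T", ]
  expect_equal(t$distance, 3)
  expect_equal(t$path[[1]], c("q", "L", "S", "T"))
})

test_that("the distance bound excludes far nodes", {
  hits <- bounded_dijkstra(chain_net(), "q", d_max = 2.5)
  expect_false("T" %in% hits$node)
  expect_true("S" %in% hits$node)
  expect_error(bounded_dijkstra(chain_net(), "nope"), "unknown source")
})

test_that("shortest distances match exhaustive path enumeration on random graphs", {
  for (seed in 1:12) {
    e <- random_edge_table(8 + seed %% 5, p_edge = 0.35, seed = seed)
    if (nrow(e) == 0) next
    ids <- sort(unique(c(e$a, e$b)))
    nodes <- tibble::tibble(id = ids, partition = "ligand", role = "cluster",
                            protein_id = NA_character_, members = as.list(ids),
                            unreachable = FALSE)
    net <- bipartite_network(nodes, tibble::tibble(
      a = e$a, b = e$b, kind = "ligand", similarity = e$value))
    src <- ids[1]
    got <- bounded_dijkstra(net, src, d_max = 6)
    want <- brute_force_shortest(e, src, d_max = 6)
    expect_setequal(got$node, names(want))
    expect_equal(got$distance[match(names(want), got$node)], unname(want),
                 tolerance = 1e-12)
  }
})

test_that("returned paths are consistent with their distances", {
  e <- random_edge_table(10, p_edge = 0.5, seed = 99)
  ids <- sort(unique(c(e$a, e$b)))
  nodes <- tibble::tibble(id = ids, partition = "ligand", role = "cluster",
                          protein_id = NA_character_, members = as.list(ids),
                          unreachable = FALSE)
  net <- bipartite_network(nodes, tibble::tibble(
    a = e$a, b = e$b, kind = "ligand", similarity = e$value))
  got <- bounded_dijkstra(net, ids[1], d_max = 8)
  for (i in seq_len(nrow(got))) {
    p <- got$path[[i]]
    if (length(p) < 2) next
    d <- 0
    for (j in seq_len(length(p) - 1)) {
      hit <- net$edges[(net$edges$a == p[j] & net$edges$b == p[j + 1]) |
                         (net$edges$a == p[j + 1] & net$edges$b == p[j]), ]
      expect_equal(nrow(hit), 1)
      d <- d + hit$distance
    }
    expect_equal(d, got$distance[i], tolerance = 1e-12)
  }
})

test_that("adding an edge never increases a shortest distance", {
  e <- random_edge_table(9, p_edge = 0.3, seed = 5)
  ids <- sprintf("n%02d", 1:9)
  mk <- function(edges) {
    nodes <- tibble::tibble(id = ids, partition = "ligand", role = "cluster",
                            protein_id = NA_character_, members = as.list(ids),
                            unreachable = FALSE)
    bipartite_network(nodes, tibble::tibble(
      a = edges$a, b = edges$b, kind = "ligand", similarity = edges$value))
  }
  pairs <- utils::combn(ids, 2)
  present <- paste(e$a, e$b)
  free <- which(!(paste(pairs[1, ], pairs[2, ]) %in% present))[1:3]
  base <- bounded_dijkstra(mk(e), ids[1], d_max = 20)
  for (f in free) {
    e2 <- rbind(e, tibble::tibble(a = pairs[1, f], b = pairs[2, f], value = 0.9))
    more <- bounded_dijkstra(mk(e2), ids[1], d_max = 20)
    common <- intersect(base$node, more$node)
    expect_true(all(more$distance[match(common, more$node)] <=
                      base$distance[match(common, base$node)] + 1e-12))
    expect_true(all(base$node %in% more$node))
  }
})

test_that("path scores are inverse distances with the documented domain", {
  expect_equal(score_path(1), 1)
  expect_equal(score_path(4), 0.25)
  expect_true(score_path(2) > score_path(3))  # longer path scores lower
  expect_error(score_path(0), "positive")
  expect_error(score_path(-1), "positive")
})

test_that("global Z-scores standardize the population to mean 0, sd 1", {
  set.seed(11)
  pred <- tibble::tibble(
    query_id = rep(sprintf("q%d", 1:10), each = 8),
    site_id = rep(sprintf("t%d", 1:8), times = 10),
    protein_id = rep(sprintf("p%d", 1:8), times = 10),
    score = runif(80, 0.1, 1)
  )
  z <- zscore_predictions(pred)
  expect_lt(abs(mean(z$global_z)), 1e-9)
  expect_lt(abs(sd_pop_oracle(z$global_z) - 1), 1e-9)
  for (grp in split(z$local_z, z$site_id)) {
    expect_lt(abs(mean(grp)), 1e-9)
    expect_lt(abs(sd_pop_oracle(grp) - 1), 1e-9)
  }
  # a row scoring exactly the global mean has Gz 0
  pred2 <- pred
  pred2$score[1] <- mean(pred2$score[-1])  # not exact; use explicit case
  p3 <- tibble::tibble(query_id = c("a", "b", "c"), site_id = c("t", "t", "u"),
                       protein_id = c("t", "t", "u"), score = c(0.2, 0.4, 0.3))
  z3 <- suppressWarnings(zscore_predictions(p3, normalize = "none"))
  expect_equal(z3$global_z[3], 0)  # 0.3 is the mean of {0.2, 0.4, 0.3}
})

test_that("degenerate Z groups yield zero with a warning, empty input is fatal", {
  p <- tibble::tibble(query_id = c("a", "b"), site_id = c("t1", "t2"),
                      protein_id = c("p1", "p2"), score = c(0.5, 0.7))
  expect_warning(z <- zscore_predictions(p, normalize = "none"),
                 "zero score spread")
  expect_equal(z$local_z, c(0, 0))  # singleton target groups
  expect_error(zscore_predictions(p[0, ]), "empty")
  same <- tibble::tibble(query_id = c("a", "b"), site_id = "t",
                         protein_id = "p", score = c(0.4, 0.4))
  w <- testthat::capture_warnings(zs <- zscore_predictions(same, normalize = "none"))
  expect_true(any(grepl("standard deviation is 0", w)))
  expect_equal(zs$global_z, c(0, 0))
})

test_that("Z-scores are invariant to min-max normalization", {
  set.seed(3)
  pred <- tibble::tibble(query_id = rep("q", 20),
                         site_id = rep(c("t1", "t2"), 10),
                         protein_id = rep(c("p1", "p2"), 10),
                         score = runif(20))
  a <- zscore_predictions(pred, normalize = "minmax")
  b <- zscore_predictions(pred, normalize = "none")
  expect_equal(a$global_z, b$global_z, tolerance = 1e-12)
  expect_equal(a$local_z, b$local_z, tolerance = 1e-12)
})

test_that("per-protein aggregation reports the best pocket", {
  nodes <- tibble::tibble(
    id = c("q", "L", "S", "T1", "T2"),
    partition = c("ligand", "ligand", "site", "site", "site"),
    role = c("query", "cluster", "cluster", "site_model", "site_model"),
    protein_id = c(NA, NA, NA, "prot", "prot"),
    members = list("q", "L", "S", "T1", "T2"),
    unreachable = FALSE
  )
  edges <- tibble::tibble(
    a = c("q", "L", "S", "S"), b = c("L", "S", "T1", "T2"),
    kind = c("ligand", "interaction", "site_model", "site_model"),
    similarity = c(1, 1, 1, 0.25)
  )
  net <- bipartite_network(nodes, edges)
  pred <- suppressWarnings(predict_all(net, d_max = 10))
  expect_equal(nrow(pred), 2)
  expect_equal(unique(pred$protein_score),
               max(pred$score))
  expect_equal(sort(pred$score), sort(c(1 / 3, 1 / 6)))
})

test_that("removing the unique shortest-path edge weakens or removes the hit", {
  net <- chain_net()
  before <- suppressWarnings(predict_all(net, d_max = 10))
  expect_equal(nrow(before), 1)
  cut <- net
  cut$edges <- cut$edges[!(cut$edges$a == "S" & cut$edges$b == "T"), ]
  after <- suppressMessages(predict_all(cut, d_max = 10))
  expect_equal(nrow(after), 0)

  # weakening (not cutting) the edge strictly lowers the score
  weak <- net
  weak$edges$similarity[weak$edges$b == "T"] <- 0.5
  weak$edges$distance[weak$edges$b == "T"] <- 2
  after2 <- suppressWarnings(predict_all(weak, d_max = 10))
  expect_lt(after2$score, before$score)
})
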