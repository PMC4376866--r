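test_that("positive sets deduplicate and respect the whitelist", {
  rec <- tibble::tibble(drug_id = c("d1", "d1", "d2"),
                        protein_id = c("p1", "p1", "p2"),
                        evidence = c("a", "b", "c"))
  expect_equal(nrow(build_positive_set(rec, c("d1", "d2"))), 2)
  expect_equal(nrow(build_positive_set(rec, character(0))), 0)

  set.seed(1)
  rec10 <- tibble::tibble(
    drug_id = c("d1", "d1", "d1", "d2", "d2", "d3", "d3", "d4", "d4", "d4"),
    protein_id = c("p1", "p1", "p2", "p1", "p3", "p2", "p2", "p4", "p5", "p4"))
  expect_equal(nrow(build_positive_set(rec10, paste0("d", 1:4))), 7)
})

test_that("negative sampling avoids annotations and is seed-reproducible", {
  drugs <- paste0("d", 1:4)
  prots <- paste0("p", 1:4)
  pos <- tibble::tibble(drug_id = c("d1", "d1", "d2", "d2", "d3", "d4"),
                        protein_id = c("p1", "p2", "p1", "p3", "p4", "p2"))
  neg <- build_negative_set(drugs, prots, pos, 10, seed = 5)
  expect_equal(nrow(neg), 10)
  expect_equal(nrow(dplyr::distinct(neg)), 10)
  expect_equal(nrow(dplyr::inner_join(neg, pos, by = c("drug_id", "protein_id"))), 0)
  expect_identical(neg, build_negative_set(drugs, prots, pos, 10, seed = 5))
  expect_error(build_negative_set(drugs, prots, pos, 11, seed = 1), "cannot draw")

  for (s in 1:100) {
    n <- build_negative_set(drugs, prots, pos, 5, seed = s)
    expect_equal(nrow(dplyr::inner_join(n, pos, by = c("drug_id", "protein_id"))), 0)
  }
})

test_that("negative sampling leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(build_negative_set(paste0("d", 1:5), paste0("p", 1:5),
                               tibble::tibble(drug_id = character(),
                                              protein_id = character()),
                               3, seed = 9))
  expect_identical(runif(1), before)
})

test_that("miss-annotation screening flags exactly the planted pairs", {
  sim <- tibble::tibble(a = "d1", b = "d2", prob = 0.9)
  inter <- tibble::tibble(drug_id = "d2", protein_id = "t1")
  neg <- tibble::tibble(drug_id = c("d1", "d1", "d3"),
                        protein_id = c("t1", "t2", "t1"))
  out <- screen_negatives(neg, sim, inter)
  expect_equal(out$flagged, c(TRUE, FALSE, FALSE))

  # no similar compounds at all -> zero flags
  none <- screen_negatives(neg, sim[0, ], inter)
  expect_equal(sum(none$flagged), 0)

  # 3 plantable miss-annotations among 50 negatives
  set.seed(13)
  drugs <- sprintf("d%02d", 1:20)
  prots <- sprintf("t%02d", 1:20)
  neg50 <- tibble::tibble(drug_id = sample(drugs, 50, replace = TRUE),
                          protein_id = sample(prots, 50, replace = TRUE)) |>
    dplyr::distinct() |> utils::head(50)
  planted <- neg50[1:3, ]
  sims <- tibble::tibble(a = planted$drug_id,
                         b = paste0("buddy", 1:3), prob = 1)
  inters <- tibble::tibble(drug_id = paste0("buddy", 1:3),
                           protein_id = planted$protein_id)
  out50 <- screen_negatives(neg50, sims, inters)
  expect_equal(which(out50$flagged), 1:3)
  expect_equal(attr(out50, "n_flagged"), 3)
  removed <- screen_negatives(neg50, sims, inters, remove = TRUE)
  expect_equal(nrow(removed), nrow(neg50) - 3)
})

test_that("identity-edge exclusion removes exactly the planted links", {
  net <- toy_network()
  extra <- tibble::tibble(
    a = paste0("bq", 1:5), b = c("LC1", "LC2", "LC1", "LC2", "LC1"),
    kind = "ligand", similarity = 1, distance = 1,
    evidence = rep(list(character()), 5), identity = TRUE
  )
  nodes <- tibble::tibble(id = paste0("bq", 1:5), partition = "ligand",
                          role = "query", protein_id = NA_character_,
                          members = as.list(paste0("bq", 1:5)),
                          unreachable = FALSE)
  net2 <- pocketpath:::add_edges(pocketpath:::add_nodes(net, nodes), extra)
  net2 <- validate_network(net2)
  pruned <- suppressMessages(exclude_identity_links(net2, paste0("bq", 1:5)))
  expect_equal(attr(pruned, "n_removed"), 5)
  expect_equal(nrow(pruned$edges), nrow(net$edges))

  untouched <- suppressMessages(exclude_identity_links(net2, "unrelated"))
  expect_equal(attr(untouched, "n_removed"), 0)
  expect_equal(nrow(untouched$edges), nrow(net2$edges))
})

test_that("closed-form confusion metrics are reproduced", {
  truth <- tibble::tibble(
    query_id = paste0("q", 1:6),
    protein_id = paste0("p", 1:6),
    label = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  pred <- tibble::tibble(
    query_id = paste0("q", 1:6),
    site_id = paste0("s", 1:6),
    protein_id = paste0("p", 1:6),
    score = c(0.9, 0.8, 0.1, 0.2, 0.7, 0.6),
    classifier_prob = c(0.9, 0.8, 0.1, 0.2, 0.7, 0.6),
    classifier_label = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  ev <- evaluate_predictions(pred, truth)
  expect_equal(unname(ev$confusion), c(2, 2, 2, 0))
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
})

test_that("a perfect ranking yields AUC 1 and a one-class truth yields NA", {
  set.seed(14)
  truth <- tibble::tibble(query_id = paste0("q", 1:20),
                          protein_id = paste0("p", 1:20),
                          label = rep(c(TRUE, FALSE), each = 10))
  pred <- tibble::tibble(query_id = truth$query_id, site_id = paste0("s", 1:20),
                         protein_id = truth$protein_id,
                         score = ifelse(truth$label, runif(20, 0.6, 1),
                                        runif(20, 0, 0.4)))
  expect_equal(evaluate_predictions(pred, truth)$auc, 1)

  ones <- truth
  ones$label <- TRUE
  expect_true(is.na(evaluate_predictions(pred, ones)$auc))
})

test_that("evaluation agrees with an independent confusion/AUC oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    truth <- tibble::tibble(query_id = sprintf("q%02d", 1:n),
                            protein_id = sprintf("p%02d", 1:n),
                            label = runif(n) < 0.4)
    if (length(unique(truth$label)) < 2) next
    pred <- tibble::tibble(query_id = truth$query_id,
                           site_id = sprintf("s%02d", 1:n),
                           protein_id = truth$protein_id,
                           score = runif(n))
    ev <- evaluate_predictions(pred, truth, threshold = 0.5)
    # oracle: direct confusion counts and rank AUC
    call <- pred$score >= 0.5
    expect_equal(ev$confusion[["tp"]], sum(call & truth$label))
    expect_equal(ev$confusion[["fp"]], sum(call & !truth$label))
    expect_equal(ev$confusion[["fn"]], sum(!call & truth$label))
    expect_equal(ev$auc, auc_oracle(truth$label, pred$score), tolerance = 1e-12)
  }
})

test_that("evaluation matches pROC on a random fixture", {
  skip_if_not_installed("pROC")
  set.seed(15)
  n <- 120
  truth <- tibble::tibble(query_id = sprintf("q%03d", 1:n),
                          protein_id = sprintf("p%03d", 1:n),
                          label = runif(n) < 0.5)
  pred <- tibble::tibble(query_id = truth$query_id,
                         site_id = sprintf("s%03d", 1:n),
                         protein_id = truth$protein_id, score = runif(n))
  ev <- evaluate_predictions(pred, truth)
  proc <- suppressMessages(pROC::auc(pROC::roc(truth$label, pred$score,
                                               direction = "<", quiet = TRUE)))
  expect_equal(ev$auc, as.numeric(proc), tolerance = 1e-12)
})

test_that("enrichment curves are monotone and end at 1", {
  set.seed(16)
  n <- 80
  truth <- tibble::tibble(query_id = sprintf("q%02d", 1:n),
                          protein_id = sprintf("p%02d", 1:n),
                          label = runif(n) < 0.3)
  pred <- tibble::tibble(query_id = truth$query_id,
                         site_id = sprintf("s%02d", 1:n),
                         protein_id = truth$protein_id, score = runif(n))
  enr <- evaluate_predictions(pred, truth)$enrichment
  expect_true(all(diff(enr$frac_found) >= 0))
  expect_equal(enr$frac_found[nrow(enr)], 1)
  expect_equal(enr$frac_screened[nrow(enr)], 1)
})

test_that("unpredicted truth pairs count as false negatives", {
  truth <- tibble::tibble(query_id = c("q1", "q2"), protein_id = c("p1", "p2"),
                          label = c(TRUE, FALSE))
  pred <- tibble::tibble(query_id = "q1", site_id = "s1", protein_id = "p1",
                         score = 0.9, classifier_label = TRUE,
                         classifier_prob = 0.9)
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev$confusion[["tp"]], 1)
  expect_equal(ev$confusion[["tn"]], 1)
  expect_equal(ev$recall, 1)
  # flip: the positive pair is the unpredicted one
  truth2 <- tibble::tibble(query_id = c("q1", "q2"), protein_id = c("p1", "p2"),
                           label = c(FALSE, TRUE))
  ev2 <- evaluate_predictions(pred, truth2)
  expect_equal(ev2$confusion[["fn"]], 1)
  expect_equal(ev2$recall, 0)
})
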