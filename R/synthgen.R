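#' Configuration of the synthetic universe
#'
#' The generator plants the structure the method assumes: chemically
#' similar ligands (same scaffold) bind structurally similar pockets
#' (same pocket class). Compounds fall into `n_scaffolds` scaffold
#' families; pockets into `n_pocket_classes` classes; each class is bound
#' by one or two scaffolds, and every realized (ligand, site) complex in
#' that bipartite assignment is an observed interaction with probability
#' `p_interaction_within_class`. Pairwise similarities are drawn high
#' within a family and low across families; `cross_class_noise` is the
#' probability that a cross-family comparison is replaced by a spurious
#' borderline similarity (the knob that blurs the planted signal), and
#' `similarity_noise_sd` adds Gaussian jitter to every ligand similarity.
#' A fixed fraction of pocket classes is promiscuous: their modeled sites
#' attract spurious similarity from pockets of every class, which is
#' exactly the situation the local Z-score exists to flag.
#'
#' @param n_scaffolds,ligands_per_scaffold ligand partition size.
#' @param n_pocket_classes,sites_per_class known-site partition size.
#' @param cross_class_noise probability in `[0, 1)` of a spurious
#'   cross-family similarity.
#' @param similarity_noise_sd Gaussian jitter on ligand similarities.
#' @param p_interaction_within_class probability that a candidate
#'   (ligand, site) complex is observed.
#' @param n_queries number of query compounds (new members of existing
#'   scaffolds, never identical to a network ligand).
#' @param seed integer seed; generation is a pure function of the config.
#' @param promiscuous_frac fraction of pocket classes whose modeled sites
#'   are promiscuous.
#' @param model_sites_per_class modeled sites generated per class; the
#'   set deliberately includes low-quality, undersized and redundant
#'   sites so the integration filters have work to do.
#' @param model_quality_sd spread of the per-model base accuracy (the
#'   Z-score offset shared by all of one model's same-class comparisons);
#'   larger values give each target a stronger systematic score offset.
#' @return a `pp_synth_config` list.
#' @export
synth_config <- function(n_scaffolds = 8, ligands_per_scaffold = 6,
                         n_pocket_classes = 10, sites_per_class = 5,
                         cross_class_noise = 0.05, similarity_noise_sd = 0.05,
                         p_interaction_within_class = 0.9, n_queries = 30,
                         seed = 7, promiscuous_frac = 0.2,
                         model_sites_per_class = 3, model_quality_sd = 0.8) {
  cfg <- list(
    n_scaffolds = as.integer(n_scaffolds),
    ligands_per_scaffold = as.integer(ligands_per_scaffold),
    n_pocket_classes = as.integer(n_pocket_classes),
    sites_per_class = as.integer(sites_per_class),
    cross_class_noise = cross_class_noise,
    similarity_noise_sd = similarity_noise_sd,
    p_interaction_within_class = p_interaction_within_class,
    n_queries = as.integer(n_queries),
    seed = as.integer(seed),
    promiscuous_frac = promiscuous_frac,
    model_sites_per_class = as.integer(model_sites_per_class),
    model_quality_sd = model_quality_sd
  )
  counts <- c("n_scaffolds", "ligands_per_scaffold", "n_pocket_classes",
              "sites_per_class", "n_queries", "model_sites_per_class")
  if (any(unlist(cfg[counts]) < 1)) abort("all counts must be >= 1")
  if (cfg$cross_class_noise < 0 || cfg$cross_class_noise >= 1) {
    abort("cross_class_noise must lie in [0, 1)")
  }
  probs <- c(cfg$p_interaction_within_class, cfg$promiscuous_frac)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$similarity_noise_sd < 0) abort("similarity_noise_sd must be >= 0")
  if (cfg$n_scaffolds == 1 && cfg$n_pocket_classes == 1) {
    warn("degenerate config: one scaffold and one pocket class is unseparable")
  }
  structure(cfg, class = "pp_synth_config")
}

# Scaffold cores and substituents used to assemble simple but valid SMILES.
.pp_cores <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccc2ccccc2c1",
               "C1CCNCC1", "c1ccsc1", "c1ccc(cc1)O", "C1CCOC1",
               "c1cnc2[nH]ccc2c1", "C1CCC2CCCCC2C1")
.pp_subs <- c("C", "CC", "CCO", "CC(=O)O", "CN", "CCN", "COC", "CCl",
              "CC(C)C", "CCS", "C(=O)N", "CCCO")

synth_smiles <- function(scaffold, variant) {
  core <- .pp_cores[((scaffold - 1) %% length(.pp_cores)) + 1]
  sub <- .pp_subs[((variant - 1) %% length(.pp_subs)) + 1]
  paste0(core, sub)
}

# Similarity draw for a compound pair: high within a scaffold family,
# low across, borderline when the comparison is spurious.
draw_ligand_sim <- function(same, spurious, noise_sd) {
  n <- length(same)
  base <- numeric(n)
  base[same] <- rbeta(sum(same), 16, 4)
  cross <- !same & !spurious
  base[cross] <- rbeta(sum(cross), 4, 16)
  sp <- !same & spurious
  base[sp] <- rbeta(sum(sp), 6, 10)
  pmin(pmax(base + rnorm(n, 0, noise_sd), 0.01), 1)
}

#' Generate the full synthetic universe
#'
#' Draws every table the pipeline consumes: compounds (with generated
#' SMILES and wQED), all-against-all ligand similarities (emulating the
#' compound-pair classifier's probabilities), known binding sites and
#' their pairwise similarity Z-scores (emulating a structural pocket
#' comparison), observed interactions, query compounds with their
#' similarities to network ligands, modeled target sites with their
#' comparison and redundancy tables, and the planted truth over
#' (query, target protein) pairs. Truth is restricted to proteins whose
#' modeled site survives the integration filters, computed here by
#' independent arithmetic so the pipeline's filter cascade can be checked
#' against it.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, every table is also written
#'   as a TSV in the pipeline's input dialects.
#' @return named list of tibbles: `compounds`, `ligand_sim`, `sites`,
#'   `site_comparisons`, `interactions`, `queries`, `query_sim`,
#'   `model_sites`, `model_comparisons`, `model_identity`, `truth`,
#'   `class_scaffolds`.
#' @export
generate_universe <- function(config, dir = NULL) {
  stopifnot(inherits(config, "pp_synth_config"))
  with_seed(config$seed, generate_universe_impl(config, dir))
}

generate_universe_impl <- function(cfg, dir) {
  S <- cfg$n_scaffolds; L <- cfg$ligands_per_scaffold
  C <- cfg$n_pocket_classes; M <- cfg$sites_per_class

  # --- compounds -----------------------------------------------------------
  compounds <- tidyr::expand_grid(scaffold = seq_len(S), j = seq_len(L)) |>
    mutate(id = sprintf("L%02d_%d", .data$scaffold, .data$j),
           smiles = mapply(synth_smiles, .data$scaffold, .data$j),
           wqed = round(rbeta(S * L, 8, 2), 4)) |>
    select("id", "smiles", "wqed", "scaffold")

  pair_idx <- utils::combn(nrow(compounds), 2)
  same <- compounds$scaffold[pair_idx[1, ]] == compounds$scaffold[pair_idx[2, ]]
  spurious <- runif(ncol(pair_idx)) < cfg$cross_class_noise
  ligand_sim <- tibble(
    a = compounds$id[pair_idx[1, ]],
    b = compounds$id[pair_idx[2, ]],
    value = round(draw_ligand_sim(same, spurious, cfg$similarity_noise_sd), 6),
    kind = "ligand"
  )

  # --- known binding sites -------------------------------------------------
  sites <- tidyr::expand_grid(class = seq_len(C), j = seq_len(M)) |>
    mutate(id = sprintf("S%02d_%d", .data$class, .data$j),
           protein_id = sprintf("P%02d_%d", .data$class, .data$j),
           n_residues = sample(7:15, C * M, replace = TRUE)) |>
    select("id", "protein_id", "n_residues", "class")

  sp_idx <- utils::combn(nrow(sites), 2)
  s_same <- sites$class[sp_idx[1, ]] == sites$class[sp_idx[2, ]]
  s_spur <- !s_same & runif(ncol(sp_idx)) < cfg$cross_class_noise
  z <- numeric(ncol(sp_idx))
  z[s_same] <- rnorm(sum(s_same), 4, 1)
  z[s_spur] <- pmin(rnorm(sum(s_spur), 2.5, 1), 3.5)
  rest <- !s_same & !s_spur
  z[rest] <- rnorm(sum(rest), 0, 1)
  site_comparisons <- tibble(a = sites$id[sp_idx[1, ]],
                             b = sites$id[sp_idx[2, ]],
                             z = round(z, 6))

  # --- observed interactions (class bound by 1-2 scaffolds) ---------------
  class_scaffolds <- bind_rows(lapply(seq_len(C), function(c) {
    k <- sample(1:2, 1)
    tibble(class = c, scaffold = sample(seq_len(S), min(k, S)))
  }))
  cand <- class_scaffolds |>
    inner_join(compounds[, c("id", "scaffold")], by = "scaffold",
               relationship = "many-to-many") |>
    rename(ligand_id = "id") |>
    inner_join(sites[, c("id", "class")], by = "class",
               relationship = "many-to-many") |>
    rename(site_id = "id")
  realized <- runif(nrow(cand)) < cfg$p_interaction_within_class
  interactions <- cand[realized, ] |>
    mutate(evidence = sprintf("CPLX%05d", seq_len(sum(realized)))) |>
    select("ligand_id", "site_id", "evidence", "class", "scaffold")

  # --- query compounds -----------------------------------------------------
  # Each query carries a quality factor emulating how well its chemistry is
  # represented in the network: it scales every similarity of that query,
  # shifting all of the query's path scores together. Per-compound offsets
  # of this kind are what an identity-aware classifier can calibrate away.
  q_scaffold <- sample(seq_len(S), cfg$n_queries, replace = cfg$n_queries > S)
  q_quality <- runif(cfg$n_queries, 0.9, 1.05)
  queries <- tibble(
    id = sprintf("Q%02d", seq_len(cfg$n_queries)),
    smiles = mapply(synth_smiles, q_scaffold, L + seq_len(cfg$n_queries)),
    wqed = round(rbeta(cfg$n_queries, 8, 2), 4),
    scaffold = q_scaffold
  )
  qp <- tidyr::expand_grid(qi = seq_len(cfg$n_queries),
                           ci = seq_len(nrow(compounds)))
  q_same <- queries$scaffold[qp$qi] == compounds$scaffold[qp$ci]
  q_spur <- runif(nrow(qp)) < cfg$cross_class_noise
  query_sim <- tibble(
    query_id = queries$id[qp$qi],
    compound_id = compounds$id[qp$ci],
    prob = round(pmin(pmax(
      draw_ligand_sim(q_same, q_spur, cfg$similarity_noise_sd) *
        q_quality[qp$qi], 0.01), 1), 6)
  )

  # --- modeled target sites ------------------------------------------------
  n_prom <- floor(cfg$promiscuous_frac * C)
  promiscuous <- sort(sample(seq_len(C), n_prom))
  model_sites <- bind_rows(lapply(seq_len(C), function(c) {
    k <- cfg$model_sites_per_class
    tibble(
      id = sprintf("M%02d_%d", c, seq_len(k)),
      protein_id = sprintf("HP%02d_%d", c, seq_len(k)),
      # slot 1 always passes quality/size; later slots roll the dice so the
      # integration filters are exercised
      n_residues = c(sample(8:15, 1),
                     if (k > 1) sample(4:15, k - 1, replace = TRUE)),
      quality = round(c(runif(1, 1.2, 2),
                        if (k > 1) runif(k - 1, 0.8, 2)), 4),
      class = c
    )
  }))
  mp <- tidyr::expand_grid(mi = seq_len(nrow(model_sites)),
                           si = seq_len(nrow(sites)))
  m_same <- model_sites$class[mp$mi] == sites$class[mp$si]
  p_spur <- ifelse(model_sites$class[mp$mi] %in% promiscuous,
                   pmin(1, cfg$cross_class_noise + 0.4),
                   cfg$cross_class_noise)
  m_spur <- !m_same & runif(nrow(mp)) < p_spur
  mz <- numeric(nrow(mp))
  # modeled pockets vary widely in how well they match their own class:
  # one base accuracy per model shifts all of its comparisons jointly, so
  # each target carries a systematic score offset — exactly the situation
  # the local Z-score is meant to cancel
  m_base <- pmin(pmax(rnorm(nrow(model_sites), 4, cfg$model_quality_sd), 1.2), 7)
  mz[m_same] <- pmax(m_base[mp$mi[m_same]] + rnorm(sum(m_same), 0, 0.7), 1.1)
  mz[m_spur] <- pmin(rnorm(sum(m_spur), 2.5, 1), 3.5)
  m_rest <- !m_same & !m_spur
  mz[m_rest] <- rnorm(sum(m_rest), 0, 1)
  model_comparisons <- tibble(
    model_site = model_sites$id[mp$mi],
    known_site = sites$id[mp$si],
    seq_id_site = round(ifelse(m_same, runif(nrow(mp), 45, 95),
                               runif(nrow(mp), 5, 35)), 2),
    struct_id_site = round(ifelse(m_same, runif(nrow(mp), 45, 95),
                                  runif(nrow(mp), 5, 35)), 2),
    z = round(mz, 6)
  )

  # within-class model-model sequence identities; the last slot is a planted
  # redundant twin (> 80%) of slot 1
  model_identity <- bind_rows(lapply(seq_len(C), function(c) {
    ms <- model_sites$id[model_sites$class == c]
    if (length(ms) < 2) return(NULL)
    idx <- utils::combn(length(ms), 2)
    k <- length(ms)
    tibble(site_a = ms[idx[1, ]], site_b = ms[idx[2, ]]) |>
      mutate(seq_id = round(ifelse(
        .data$site_a == ms[1] & .data$site_b == ms[k] & k > 2,
        runif(ncol(idx), 85, 95), runif(ncol(idx), 20, 70)), 2))
  }))

  # --- planted truth -------------------------------------------------------
  survivors <- surviving_model_sites(model_sites, model_comparisons,
                                     model_identity)
  realized_links <- interactions |> distinct(.data$class, .data$scaffold)
  truth <- tidyr::expand_grid(
    query_id = queries$id,
    site = survivors
  ) |>
    mutate(
      protein_id = model_sites$protein_id[match(.data$site, model_sites$id)],
      class = model_sites$class[match(.data$site, model_sites$id)],
      scaffold = queries$scaffold[match(.data$query_id, queries$id)]
    ) |>
    mutate(label = paste(.data$class, .data$scaffold) %in%
             paste(realized_links$class, realized_links$scaffold)) |>
    select("query_id", "protein_id", "label")

  out <- list(
    compounds = compounds,
    ligand_sim = ligand_sim,
    sites = sites,
    site_comparisons = site_comparisons,
    interactions = interactions[, c("ligand_id", "site_id", "evidence")],
    queries = queries,
    query_sim = query_sim,
    model_sites = model_sites[, c("id", "protein_id", "n_residues", "quality")],
    model_comparisons = model_comparisons,
    model_identity = model_identity,
    truth = truth,
    class_scaffolds = class_scaffolds
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      readr::write_tsv(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  out
}

# Independent arithmetic replay of the integration filter cascade, used to
# decide which modeled sites the planted truth may reference.
surviving_model_sites <- function(model_sites, model_comparisons,
                                  model_identity,
                                  quality_min = 1.1, id_min = 40,
                                  min_residues = 6, redundancy_pct = 80) {
  ok_quality <- model_sites$quality >= quality_min
  hit <- model_comparisons$seq_id_site > id_min &
    model_comparisons$struct_id_site > id_min
  ok_match <- model_sites$id %in% model_comparisons$model_site[hit]
  ok_size <- model_sites$n_residues >= min_residues
  pool <- model_sites[ok_quality & ok_match & ok_size, , drop = FALSE]
  pool <- pool[order(-pool$n_residues, pool$id), , drop = FALSE]
  idkey <- c(paste(model_identity$site_a, model_identity$site_b),
             paste(model_identity$site_b, model_identity$site_a))
  idval <- c(model_identity$seq_id, model_identity$seq_id)
  kept <- character(0)
  for (sid in pool$id) {
    pid <- idval[match(paste(sid, kept), idkey)]
    if (!any(!is.na(pid) & pid > redundancy_pct)) kept <- c(kept, sid)
  }
  kept
}
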