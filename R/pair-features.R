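#' Feature vector for a pair of compounds
#'
#' Builds the fixed-order, symmetric feature set the compound-pair
#' classifier consumes: fingerprint Tanimoto, absolute descriptor
#' differences (molecular weight, logP, rotatable bonds, aromatic rings)
#' and bounded min/max descriptor ratios. A feature whose underlying
#' descriptor is missing on either side is set to the sentinel `-1` and
#' the row is flagged `incomplete`.
#'
#' @param compounds featurized compound tibble (see
#'   [featurize_compounds()]); descriptor columns may also come straight
#'   from a pre-featurized input table.
#' @param pairs tibble with columns `id_a`, `id_b` naming compounds to
#'   compare; defaults to all unordered pairs.
#' @return `pairs` with feature columns `tanimoto`, `d_mw`, `d_logp`,
#'   `d_rotb`, `d_arom`, `r_mw`, `r_logp`, `r_tpsa` and logical
#'   `incomplete`.
#' @export
compound_pair_features <- function(compounds, pairs = NULL) {
  validate_compounds(compounds)
  if (is.null(pairs)) {
    if (nrow(compounds) < 2) abort("need at least two compounds")
    idx <- utils::combn(compounds$id, 2)
    pairs <- tibble(id_a = idx[1, ], id_b = idx[2, ])
  }
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  miss <- setdiff(unique(c(pairs$id_a, pairs$id_b)), compounds$id)
  if (length(miss) > 0) {
    abort(paste0("pair ids not in compound table: ", paste(miss, collapse = ", ")))
  }
  ia <- match(pairs$id_a, compounds$id)
  ib <- match(pairs$id_b, compounds$id)

  tani <- mapply(tanimoto, compounds$fingerprint[ia], compounds$fingerprint[ib])
  col <- function(name) {
    if (name %in% names(compounds)) compounds[[name]] else rep(NA_real_, nrow(compounds))
  }
  adiff <- function(name) abs(col(name)[ia] - col(name)[ib])
  # min/max ratio is symmetric and lies in [0, 1] for same-sign values
  ratio <- function(name) {
    x <- col(name)[ia]; y <- col(name)[ib]
    lo <- pmin(abs(x), abs(y)); hi <- pmax(abs(x), abs(y))
    ifelse(hi == 0, 1, lo / hi)
  }
  out <- pairs
  out$tanimoto <- tani
  out$d_mw <- adiff("mw")
  out$d_logp <- adiff("logp")
  out$d_rotb <- adiff("rotb")
  out$d_arom <- adiff("arom")
  out$r_mw <- ratio("mw")
  out$r_logp <- ratio("logp")
  out$r_tpsa <- ratio("tpsa")
  featcols <- pair_feature_names()
  flag <- rep(FALSE, nrow(out))
  for (cn in featcols) {
    bad <- is.na(out[[cn]])
    flag <- flag | bad
    out[[cn]][bad] <- -1
  }
  out$incomplete <- flag
  out
}

pair_feature_names <- function() {
  c("tanimoto", "d_mw", "d_logp", "d_rotb", "d_arom", "r_mw", "r_logp", "r_tpsa")
}

#' Tanimoto coefficient of two bit fingerprints
#'
#' `|A & B| / |A | B|` over fingerprint bits; 0 when either fingerprint is
#' missing or the union is empty.
#'
#' @param fa,fb integer 0/1 vectors of equal length (or `NULL`).
#' @return a number in `[0, 1]` (`NA` when a fingerprint is missing).
#' @export
tanimoto <- function(fa, fb) {
  if (is.null(fa) || is.null(fb)) return(NA_real_)
  stopifnot(length(fa) == length(fb))
  both <- sum(fa & fb)
  either <- sum(fa | fb)
  if (either == 0) return(0)
  both / either
}
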