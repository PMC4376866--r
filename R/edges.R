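#' Read a pairwise edge list
#'
#' Reads a TSV with columns `a`, `b`, `value`, `kind` (tab-separated,
#' `#` comments, header required). `kind` distinguishes similarity edges
#' (`ligand`, `site`, `site_model`) from `interaction` edges. Similarity
#' edges are undirected: when both orientations of a pair are present the
#' maximum value is kept. Self-loop rows are dropped with one warning
#' (count attached as attribute `"n_self_loops"`). Non-numeric values are
#' fatal.
#'
#' @param path TSV file.
#' @return tibble with columns `a`, `b`, `value`, `kind`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(paste0("edge list not found: ", path))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("a", "b", "value", "kind")
  if (!all(need %in% names(tb))) {
    abort(paste0("edge list needs columns: ", paste(need, collapse = ", ")))
  }
  val <- suppressWarnings(as.numeric(tb$value))
  if (anyNA(val) & nrow(tb) > 0) {
    abort(paste0("non-numeric edge value at row(s): ",
                 paste(which(is.na(val)), collapse = ", ")))
  }
  tb <- tibble(a = tb$a, b = tb$b, value = val, kind = tb$kind)
  loops <- tb$a == tb$b
  if (any(loops)) {
    warn(paste0("dropped ", sum(loops), " self-loop row(s)"))
    tb <- tb[!loops, , drop = FALSE]
  }
  sim <- tb$kind != "interaction"
  out <- bind_rows(
    dedupe_symmetric(tb[sim, , drop = FALSE]),
    tb[!sim, , drop = FALSE]
  )
  attr(out, "n_self_loops") <- sum(loops)
  out
}

# Undirected dedup: canonicalize (a, b) order, keep the max value per pair.
dedupe_symmetric <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  edges$a <- lo
  edges$b <- hi
  edges |>
    group_by(.data$a, .data$b, .data$kind) |>
    summarise(value = max(.data$value), .groups = "drop") |>
    select("a", "b", "value", "kind")
}

#' Threshold binding-site similarity Z-scores into edges
#'
#' Structural comparison of two pockets yields a similarity Z-score; only
#' comparisons whose Z strictly exceeds `zmin` become network edges
#' (2.0 within the known-site sub-network, 1.0 when attaching modeled
#' sites). Retained edges carry similarity `normalize_z(z, zmin)`, a
#' bounded monotone map of the Z-score.
#'
#' @param comparisons tibble with columns `a`, `b`, `z` (one row per
#'   compared site pair).
#' @param zmin strict acceptance threshold.
#' @param kind edge kind for the retained edges (`"site"` or
#'   `"site_model"`).
#' @return tibble of edges `a`, `b`, `value` (normalized Z), `kind`;
#'   zero rows when nothing passes.
#' @export
site_similarity_edges <- function(comparisons, zmin = 2, kind = "site") {
  stopifnot(all(c("a", "b", "z") %in% names(comparisons)))
  stopifnot(all(is.finite(comparisons$z)))
  keep <- comparisons$z > zmin
  tibble(
    a = comparisons$a[keep],
    b = comparisons$b[keep],
    value = normalize_z(comparisons$z[keep], z_ref = zmin),
    kind = kind
  )
}

#' Write an edge list TSV
#'
#' @param edges tibble with columns `a`, `b`, `value`, `kind`.
#' @param path output file.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}
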