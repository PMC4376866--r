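#' Read a compound table
#'
#' Reads small-molecule records into the canonical compound tibble used by
#' the rest of the pipeline. Three input dialects are supported:
#'
#' * `tsv`: tab-separated with a header row and `#` comment lines; must
#'   carry an `id` column plus at least one of `smiles` or `fingerprint`
#'   (a `0/1` bit-string). Optional columns `wqed` and any numeric
#'   descriptor columns are carried through.
#' * `sdf`: an SD file; ids come from the molecule titles.
#' * `smiles`: one SMILES per line; ids are auto-generated (`cpd_001`, ...).
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"sdf"`, `"smiles"`.
#' @return a tibble with columns `id`, `smiles`, `wqed`, `fingerprint`
#'   (list-column of integer 0/1 vectors, `NULL` when absent) plus any
#'   descriptor columns present in the input.
#' @export
read_compound_table <- function(path, format = c("tsv", "sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("compound table not found: ", path))
  out <- switch(format,
    tsv = read_compounds_tsv(path),
    sdf = read_compounds_sdf(path),
    smiles = read_compounds_smiles(path)
  )
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate compound id(s): ", paste(unique(dup), collapse = ", ")))
  }
  validate_compounds(out)
  out
}

read_compounds_tsv <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!"id" %in% names(tb)) abort("compound TSV needs an `id` column")
  if (!any(c("smiles", "fingerprint") %in% names(tb))) {
    abort("compound TSV needs a `smiles` or `fingerprint` column")
  }
  tb$id <- as.character(tb$id)
  if (!"smiles" %in% names(tb)) tb$smiles <- NA_character_
  if ("wqed" %in% names(tb)) {
    tb$wqed <- as.numeric(tb$wqed)
  } else {
    tb$wqed <- NA_real_
  }
  fp <- if ("fingerprint" %in% names(tb)) {
    lapply(tb$fingerprint, parse_bitstring)
  } else {
    rep(list(NULL), nrow(tb))
  }
  tb$fingerprint <- fp
  as_tibble(tb)
}

read_compounds_sdf <- function(path) {
  require_chem()
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  smi <- tryCatch(
    as.character(ChemmineR::sdf2smiles(sdf)),
    error = function(e) rep(NA_character_, length(ids))
  )
  tibble(id = as.character(ids), smiles = smi, wqed = NA_real_,
         fingerprint = rep(list(NULL), length(ids)))
}

read_compounds_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tibble(
    id = sprintf("cpd_%03d", seq_along(lines)),
    smiles = lines,
    wqed = NA_real_,
    fingerprint = rep(list(NULL), length(lines))
  )
}

parse_bitstring <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  bits <- as.integer(strsplit(x, "")[[1]])
  if (anyNA(bits) || any(!bits %in% c(0L, 1L))) {
    abort("fingerprint columns must be 0/1 bit-strings")
  }
  bits
}

validate_compounds <- function(compounds) {
  stopifnot(is.data.frame(compounds), "id" %in% names(compounds))
  if (any(!nzchar(compounds$id)) || anyNA(compounds$id)) {
    abort("compound ids must be non-empty")
  }
  if (anyDuplicated(compounds$id)) abort("compound ids must be unique")
  if ("wqed" %in% names(compounds)) {
    w <- compounds$wqed[!is.na(compounds$wqed)]
    if (any(w < 0 | w > 1)) abort("wqed values must lie in [0, 1]")
  }
  if ("fingerprint" %in% names(compounds)) {
    lens <- setdiff(unique(lengths(compounds$fingerprint)), 0L)
    if (length(lens) > 1) {
      abort("all fingerprints in a collection must have the same length")
    }
  }
  invisible(compounds)
}

require_chem <- function() {
  ok <- requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
  if (!ok) abort("this operation needs the ChemmineR and ChemmineOB packages")
  invisible(TRUE)
}

#' Compute fingerprints and physicochemical descriptors from SMILES
#'
#' Fills the `fingerprint` list-column (hashed atom-pair fingerprint,
#' default 1024 bits) and descriptor columns `mw`, `logp`, `tpsa`, `hba`,
#' `hbd`, `rotb` (rotatable bonds), `arom` (aromatic ring count), plus a
#' `cansmi` canonical-SMILES column used for exact structure identity.
#' Rows whose SMILES cannot be parsed are reported together in a warning
#' and returned with `NULL` fingerprints; their ids are attached as the
#' `"failed_ids"` attribute.
#'
#' @param compounds compound tibble (see [read_compound_table()]).
#' @param fp_bits fingerprint length in bits.
#' @return the tibble with fingerprint/descriptor columns populated.
#' @export
featurize_compounds <- function(compounds, fp_bits = 1024) {
  validate_compounds(compounds)
  require_chem()
  n <- nrow(compounds)
  failed <- character(0)
  fps <- vector("list", n)
  desc <- matrix(NA_real_, n, 7,
                 dimnames = list(NULL, c("mw", "logp", "tpsa", "hba", "hbd",
                                         "rotb", "arom")))
  cansmi <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    smi <- compounds$smiles[i]
    if (is.na(smi) || !nzchar(smi)) {
      failed <- c(failed, compounds$id[i])
      next
    }
    feat <- tryCatch(featurize_one(smi, fp_bits), error = function(e) NULL)
    if (is.null(feat)) {
      failed <- c(failed, compounds$id[i])
      next
    }
    fps[[i]] <- feat$fp
    desc[i, ] <- feat$desc
    cansmi[i] <- feat$cansmi
  }
  if (length(failed) > 0) {
    warn(paste0("could not featurize ", length(failed), " compound(s): ",
                paste(failed, collapse = ", ")))
  }
  out <- compounds
  out$fingerprint <- fps
  for (col in colnames(desc)) out[[col]] <- desc[, col]
  out$cansmi <- cansmi
  attr(out, "failed_ids") <- failed
  out
}

.pp_chem_cache <- new.env(parent = emptyenv())

# The reference atom-pair vocabulary (most frequent atom pairs) used to
# hash a molecule's atom-pair set into a fixed-length bit vector.
ap_vocabulary <- function(fp_bits) {
  if (is.null(.pp_chem_cache$apfp)) {
    e <- new.env()
    utils::data("apfp", package = "ChemmineR", envir = e)
    .pp_chem_cache$apfp <- as.character(e$apfp$AP)
  }
  if (fp_bits > length(.pp_chem_cache$apfp)) {
    abort(paste0("fp_bits must be <= ", length(.pp_chem_cache$apfp)))
  }
  .pp_chem_cache$apfp[seq_len(fp_bits)]
}

featurize_one <- function(smiles, fp_bits) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  ap <- suppressWarnings(ChemmineR::sdf2ap(sdf[1]))
  pairs <- as.character(ChemmineR::ap(ap)[[1]])
  fp <- matrix(as.integer(ap_vocabulary(fp_bits) %in% pairs), nrow = 1)
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  pr <- ChemmineOB::prop_OB(mol)
  rotb <- ChemmineOB::smartsSearch_OB(
    mol, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE)
  rr <- ChemmineR::rings(sdf[1], type = "count", arom = TRUE)
  arom <- if (is.null(dim(rr))) rr[["AROMATIC"]] else rr[1, "AROMATIC"]
  list(
    fp = as.integer(fp[1, ]),
    desc = c(mw = pr$MW[1], logp = pr$logP[1], tpsa = pr$TPSA[1],
             hba = pr$HBA2[1], hbd = pr$HBD[1],
             rotb = as.numeric(rotb), arom = as.numeric(arom)),
    cansmi = trimws(pr$cansmi[1])
  )
}

#' Keep drug-like compounds
#'
#' Filters a compound collection on the weighted quantitative estimate of
#' drug-likeness (wQED), a `[0, 1]` desirability composite over molecular
#' descriptors. wQED is consumed as an input column (or supplied by
#' `scorer`); the composite itself is not computed here. The threshold is
#' inclusive: compounds with `wqed >= threshold` are kept, in input order.
#'
#' @param compounds compound tibble with a `wqed` column.
#' @param threshold minimum wQED kept (default 0.35).
#' @param scorer optional function `(compounds) -> numeric` used to fill in
#'   missing wQED values (a pluggable drug-likeness hook).
#' @return the drug-like subset; the number of removed compounds is
#'   attached as attribute `"n_removed"` and reported via [message()].
#' @export
filter_druglike <- function(compounds, threshold = 0.35, scorer = NULL) {
  validate_compounds(compounds)
  w <- if ("wqed" %in% names(compounds)) compounds$wqed else rep(NA_real_, nrow(compounds))
  if (anyNA(w)) {
    if (is.null(scorer)) {
      bad <- compounds$id[is.na(w)]
      abort(paste0("compounds missing wqed and no scorer hook configured: ",
                   paste(bad, collapse = ", ")))
    }
    w[is.na(w)] <- scorer(compounds[is.na(w), , drop = FALSE])
  }
  keep <- w >= threshold
  out <- compounds[keep, , drop = FALSE]
  out$wqed <- w[keep]
  attr(out, "n_removed") <- sum(!keep)
  inform(paste0("filter_druglike: kept ", sum(keep), "/", length(keep),
                " compounds (wQED >= ", threshold, ")"))
  out
}
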