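# Molecule tables, SDF I/O, standardization and deduplication.
#
# A molecule table is an ordinary data.frame with (at least) the columns
# `id`, `smiles` (as supplied) and `canonical` (OpenBabel canonical SMILES,
# stereo retained), plus optional `label` (binary activity) and `provenance`.
# Skip counts from lossy steps ride along as attributes so that
# records_in = records_out + skipped always holds.

#' Read a labelled SMILES table from CSV
#'
#' Parses a CSV of compounds, canonicalizes every SMILES and drops (with a
#' count) rows whose SMILES cannot be parsed. Salts and mixtures are reduced
#' to their largest organic component before canonicalization, since public
#' bioactivity databases routinely deposit counterions.
#'
#' @param path CSV file with a header.
#' @param smiles_col,id_col,label_col column names. `id_col` and `label_col`
#'   are optional: missing ids are synthesized as `row<N>`; labels, when
#'   present, must be 0/1.
#' @param strip_salts keep only the largest component of multi-component
#'   SMILES (default `TRUE`).
#' @return data.frame with columns `id`, `smiles`, `canonical`, `label`
#'   (NA when absent), `provenance`; attributes `skipped` (number of
#'   unparseable rows) and `salt_stripped` (number of rows reduced to their
#'   largest component).
#' @export
read_smiles_table <- function(path, smiles_col = "smiles", id_col = "id",
                              label_col = "label", strip_salts = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df)) {
    stop("configuration error: column '", smiles_col, "' not present in ",
         path, call. = FALSE)
  }
  smiles <- as.character(df[[smiles_col]])
  ids <- if (id_col %in% names(df)) as.character(df[[id_col]]) else
    paste0("row", seq_along(smiles))
  labels <- if (label_col %in% names(df)) df[[label_col]] else
    rep(NA_real_, length(smiles))
  if (!all(is.na(labels) | labels %in% c(0, 1))) {
    stop("labels must be 0 or 1 (or absent)", call. = FALSE)
  }
  build_molecule_table(ids, smiles, labels,
                       provenance = paste0("csv:", basename(path)),
                       strip_salts = strip_salts)
}

# Shared standardization path for SMILES coming from any source.
build_molecule_table <- function(ids, smiles, labels = NA_real_,
                                 provenance = "", strip_salts = TRUE) {
  n_strip <- 0L
  if (strip_salts) {
    stripped <- largest_component(smiles)
    n_strip <- sum(stripped != smiles, na.rm = TRUE)
    smiles <- stripped
  }
  can <- canonical_smiles(smiles)
  keep <- !is.na(can)
  if (!any(keep)) stop("input error: zero parseable SMILES", call. = FALSE)
  out <- data.frame(
    id = ids[keep], smiles = smiles[keep], canonical = can[keep],
    label = rep(labels, length.out = length(smiles))[keep],
    provenance = provenance, stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) stop("input error: zero parseable SMILES", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(!keep)
  attr(out, "salt_stripped") <- n_strip
  out
}

#' Largest organic component of multi-component SMILES
#'
#' Splits dot-disconnected SMILES and keeps the component with the most
#' heavy atoms, preferring carbon-containing components over purely
#' inorganic ones (so `[Na+].CC(=O)[O-]` keeps the acetate).
#'
#' @param smiles character vector.
#' @return character vector of single-component SMILES.
#' @export
largest_component <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    comps <- strsplit(s, ".", fixed = TRUE)[[1]]
    heavy <- vapply(comps, count_heavy_atoms_smiles, numeric(1))
    organic <- grepl("[cC]", comps)
    pool <- if (any(organic)) which(organic) else seq_along(comps)
    comps[pool[which.max(heavy[pool])]]
  }, character(1), USE.NAMES = FALSE)
}

# Rough heavy-atom count from a SMILES string: bracket atoms count once,
# two-letter organic-subset halogens count once, H never counts. Used only
# to rank components by size, not as a chemical descriptor.
count_heavy_atoms_smiles <- function(s) {
  n_br <- lengths(regmatches(s, gregexpr("\\[[^]]*\\]", s)))
  bare <- gsub("\\[[^]]*\\]", "", s)
  n_two <- lengths(regmatches(bare, gregexpr("Cl|Br", bare)))
  bare <- gsub("Cl|Br", "", bare)
  n_one <- lengths(regmatches(bare, gregexpr("[BCNOPSFIbcnops]", bare)))
  n_br + n_two + n_one
}

#' Read a V2000 SDF with conformers
#'
#' Each molblock becomes one record carrying its 3D coordinates unchanged —
#' no re-embedding and no alignment is performed. Corrupt molblocks are
#' skipped with a warning.
#'
#' @param path SDF file.
#' @return list with `sdfset` (a [ChemmineR::SDFset] of the valid
#'   molecules), `table` (molecule table as in [read_smiles_table()], with
#'   canonical SMILES derived from the 3D structures) and `skipped`.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfset)
  n_skipped <- sum(!valid)
  if (n_skipped > 0) {
    warning(n_skipped, " corrupt molblock(s) skipped in ", path)
    sdfset <- sdfset[valid]
  }
  if (length(sdfset) == 0) stop("input error: empty SDF ", path, call. = FALSE)
  ids <- vapply(ChemmineR::SDFset2SDF(sdfset),
                function(x) ChemmineR::header(x)[[1]], character(1))
  ids[!nzchar(trimws(ids))] <- paste0("mol", which(!nzchar(trimws(ids))))
  ChemmineR::cid(sdfset) <- make.unique(ids, sep = "_dup")
  blocks <- sdf_to_molblocks(sdfset)
  can <- molblocks_to_smiles(blocks)
  tab <- data.frame(id = ChemmineR::cid(sdfset), smiles = can,
                    canonical = can, label = NA_real_,
                    provenance = paste0("sdf:", basename(path)),
                    stringsAsFactors = FALSE)
  list(sdfset = sdfset, table = tab, skipped = n_skipped)
}

#' Write molecules to a V2000 SDF
#'
#' @param x an [ChemmineR::SDFset] or a character vector of V2000 molblocks.
#' @param path output file.
#' @export
write_sdf <- function(x, path) {
  if (methods::is(x, "SDFset")) {
    if (length(x) == 0) stop("input error: empty record list", call. = FALSE)
    ChemmineR::write.SDF(x, file = path)
  } else {
    x <- as.character(x)
    if (length(x) == 0) stop("input error: empty record list", call. = FALSE)
    writeLines(paste(x, collapse = "\n"), path)
  }
  invisible(path)
}

# Extract raw molblock text (without the trailing $$$$) for each molecule.
sdf_to_molblocks <- function(sdfset) {
  vapply(ChemmineR::SDFset2SDF(sdfset), function(m) {
    paste(ChemmineR::sdf2str(m), collapse = "\n")
  }, character(1))
}

#' Stable column order for screening output tables
#' @keywords internal
screening_columns <- function() {
  c("id", "smiles", "probability", "max_tanimoto", "qed", "sa",
    "pass_activity", "pass_ad", "pass_qed", "pass_sa", "final_pass")
}

#' Write a molecule or screening table to CSV
#'
#' Screening tables (output of [run_funnel()]) are written with the
#' documented stable column order `id, smiles, probability, max_tanimoto,
#' qed, sa, pass_activity, pass_ad, pass_qed, pass_sa, final_pass`.
#'
#' @param df data.frame of records.
#' @param path output CSV.
#' @export
write_table <- function(df, path) {
  if (!is.data.frame(df) || nrow(df) == 0) {
    stop("input error: empty record list", call. = FALSE)
  }
  sc <- screening_columns()
  if (all(sc %in% names(df))) df <- df[, c(sc, setdiff(names(df), sc))]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Deduplicate a molecule table by canonical structure
#'
#' One record per stereo-aware canonical SMILES; the first occurrence wins.
#' Idempotent. The removal count is attached as attribute `removed`.
#'
#' @param df molecule table with a `canonical` column.
#' @return deduplicated data.frame with attribute `removed`.
#' @export
deduplicate <- function(df) {
  stopifnot(is.data.frame(df), "canonical" %in% names(df))
  keep <- !duplicated(df$canonical)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}
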