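# Thin wrappers around the OpenBabel command line. All chemistry I/O in the
# package funnels through these so error handling (malformed molecules,
# missing binary) lives in one place. `obabel -e` continues past unparseable
# records; records are tagged with integer titles so survivors can be mapped
# back to their input rows.

ob_binary <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    stop("OpenBabel's 'obabel' executable was not found on the PATH; ",
         "it is required for SMILES/SDF handling and fingerprints.",
         call. = FALSE)
  }
  bin
}

ob_run <- function(args, stdin_lines = NULL) {
  infile <- NULL
  if (!is.null(stdin_lines)) {
    infile <- tempfile(fileext = ".obin")
    writeLines(stdin_lines, infile)
    on.exit(unlink(infile), add = TRUE)
    args <- c(infile, args)
  }
  out <- suppressWarnings(
    system2(ob_binary(), args = args, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0 && length(out) == 0) {
    stop("obabel failed (exit status ", status, ")", call. = FALSE)
  }
  as.character(out)
}

#' Canonical SMILES via OpenBabel
#'
#' Vectorized canonicalization. One canonical-SMILES dialect (OpenBabel's
#' `can` writer, stereo retained) is used everywhere in the package,
#' including deduplication keys, so that equality of canonical strings is
#' equality of structures.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of the same length; `NA` where the input could
#'   not be parsed.
#' @examples
#' \dontrun{canonical_smiles(c("OCC", "CCO"))  # both "CCO"}
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  smiles <- as.character(smiles)
  res <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(res)
  idx <- which(ok)
  lines <- paste(smiles[idx], seq_along(idx))
  out <- ob_run(c("-ismi", "-ocan", "-e"), stdin_lines = lines)
  out <- out[nzchar(out)]
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    can <- trimws(vapply(parts, `[`, character(1), 1L))
    ids <- suppressWarnings(
      as.integer(trimws(vapply(parts, function(p) {
        if (length(p) >= 2) p[2] else NA_character_
      }, character(1))))
    )
    keep <- !is.na(ids) & nzchar(can)
    res[idx[ids[keep]]] <- can[keep]
  }
  res
}

# Convert a character vector of V2000 molblocks to canonical SMILES.
# Returns NA for blocks OpenBabel rejects.
molblocks_to_smiles <- function(molblocks) {
  if (length(molblocks) == 0) return(character(0))
  tagged <- vapply(seq_along(molblocks), function(i) {
    set_molblock_title(molblocks[i], as.character(i))
  }, character(1))
  sdf_text <- paste(tagged, collapse = "\n")
  out <- ob_run(c("-isdf", "-ocan", "-e"),
                stdin_lines = strsplit(sdf_text, "\n", fixed = TRUE)[[1]])
  res <- rep(NA_character_, length(molblocks))
  out <- out[nzchar(out)]
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    can <- trimws(vapply(parts, `[`, character(1), 1L))
    ids <- suppressWarnings(as.integer(trimws(vapply(parts, function(p) {
      if (length(p) >= 2) p[2] else NA_character_
    }, character(1)))))
    keep <- !is.na(ids) & nzchar(can)
    res[ids[keep]] <- can[keep]
  }
  res
}

# Replace line 1 (title) of a V2000 molblock.
set_molblock_title <- function(molblock, title) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  lines[1] <- title
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  paste(lines, collapse = "\n")
}
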