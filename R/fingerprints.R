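# ECFP4 featurization and bit-vector similarity.
#
# Fingerprints are stored as dense 0/1 integer matrices (rows = molecules,
# columns = bits). At 2048 bits and the library sizes this package targets
# (1e3-1e4 molecules) dense storage keeps every similarity computation a
# single matrix product.

#' ECFP4 fingerprint parameterization
#'
#' Extended-connectivity (Morgan) fingerprint of radius 2, hashed to a
#' fixed-length bit vector. The OpenBabel ECFP4 implementation generates the
#' circular-environment identifiers; identifiers are folded to `n_bits`.
#' Counts and chirality flags are not used.
#'
#' @param n_bits fingerprint length; power of two, >= 256 (default 2048).
#' @return object of class `fingerprint_spec`.
#' @export
fingerprint_spec <- function(n_bits = 2048L) {
  n_bits <- as.integer(n_bits)
  if (n_bits < 256L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("n_bits must be a power of two >= 256", call. = FALSE)
  }
  structure(list(radius = 2L, n_bits = n_bits, counts = FALSE,
                 use_chirality = FALSE),
            class = "fingerprint_spec")
}

#' Compute ECFP4 bit fingerprints
#'
#' Deterministic for a fixed spec: the same SMILES always yields the same
#' bit vector. Unparseable molecules are skipped; their row indices are
#' reported in the `skipped` attribute and the corresponding rows are
#' all-zero (callers that need strict alignment keep the rows; callers that
#' need valid fingerprints drop them).
#'
#' @param smiles character vector of SMILES.
#' @param spec a [fingerprint_spec()].
#' @return integer 0/1 matrix of dimension `length(smiles) x n_bits` with
#'   `rownames = names(smiles)` when present; attribute `skipped` holds the
#'   indices of unparseable inputs.
#' @export
featurize <- function(smiles, spec = fingerprint_spec()) {
  stopifnot(inherits(spec, "fingerprint_spec"))
  n <- length(smiles)
  fp <- matrix(0L, nrow = n, ncol = spec$n_bits)
  if (!is.null(names(smiles))) rownames(fp) <- names(smiles)
  ok <- !is.na(smiles) & nzchar(trimws(as.character(smiles)))
  if (any(ok)) {
    idx <- which(ok)
    lines <- paste(as.character(smiles[idx]), seq_along(idx))
    out <- ob_run(c("-ismi", "-ofpt", "-xfECFP4",
                    paste0("-xN", spec$n_bits), "-xh", "-e"),
                  stdin_lines = lines)
    parsed <- parse_fpt_hex(out, spec$n_bits)
    if (length(parsed$rows)) {
      fp[idx[parsed$rows], ] <- parsed$bits
      ok[idx[-parsed$rows]] <- FALSE
    } else {
      ok[idx] <- FALSE
    }
  }
  attr(fp, "skipped") <- which(!ok)
  attr(fp, "n_bits") <- spec$n_bits
  fp
}

# Parse `obabel -ofpt -xh` output: per molecule a ">title   k bits set"
# header followed by hexadecimal 32-bit words, most of the time wrapped over
# several lines. Word w, bit b (LSB first) maps to column 32*w + b + 1.
parse_fpt_hex <- function(lines, n_bits) {
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  rows <- integer(0)
  bitlist <- list()
  for (k in seq_along(starts)) {
    hdr <- lines[starts[k]]
    id <- suppressWarnings(as.integer(sub("^>\\s*(\\S+).*$", "\\1", hdr)))
    if (is.na(id)) next
    end <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    body <- lines[setdiff(seq(starts[k], end), starts[k])]
    # keep pure-hex lines only; obabel intersperses commentary such as
    # "Possible superstructure of 1" whose digits must not be parsed
    body <- body[grepl("^[0-9a-fA-F]+( +[0-9a-fA-F]+)*$", trimws(body))]
    words <- unlist(strsplit(trimws(paste(body, collapse = " ")), "\\s+"))
    words <- words[grepl("^[0-9a-fA-F]{1,8}$", words)]
    vec <- integer(n_bits)
    if (length(words)) {
      for (w in seq_along(words)) {
        bits32 <- hex_word_bits(words[w])
        pos <- 32L * (w - 1L) + which(bits32 == 1L)
        pos <- pos[pos <= n_bits]
        vec[pos] <- 1L
      }
    }
    rows <- c(rows, id)
    bitlist[[length(bitlist) + 1L]] <- vec
  }
  list(rows = rows,
       bits = if (length(bitlist)) do.call(rbind, bitlist) else
         matrix(integer(0), 0, n_bits))
}

# 4-bit LSB-first patterns for each hex digit; avoids signed 32-bit
# overflow that bit-shifting the high word bits would hit in R.
.hex_nibble <- local({
  m <- sapply(0:15, function(v) as.integer(intToBits(v)[1:4]))
  colnames(m) <- c(0:9, letters[1:6])
  m
})

# One 32-bit hex word (<= 8 hex chars) -> 32 bits, LSB first.
hex_word_bits <- function(word) {
  word <- tolower(word)
  if (nchar(word) < 8) word <- paste0(strrep("0", 8 - nchar(word)), word)
  nibs <- rev(strsplit(word, "")[[1]])  # least significant nibble first
  as.integer(.hex_nibble[, nibs])
}

#' Tanimoto similarity between two bit fingerprints
#'
#' `|a AND b| / |a OR b|`, defined as 1 when both vectors are all-zero
#' (two empty molecules are identical).
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("input error: length mismatch", call. = FALSE)
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1.0)
  inter / uni
}

#' All-pairs Tanimoto similarity between two fingerprint matrices
#'
#' @param A,B 0/1 matrices with the same number of columns.
#' @return `nrow(A) x nrow(B)` similarity matrix.
#' @export
tanimoto_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("input error: length mismatch", call. = FALSE)
  inter <- A %*% t(B)
  pa <- rowSums(A); pb <- rowSums(B)
  uni <- outer(pa, pb, "+") - inter
  sim <- ifelse(uni == 0, 1.0, inter / pmax(uni, 1))
  dimnames(sim) <- list(rownames(A), rownames(B))
  sim
}

#' Maximum Tanimoto similarity of queries to a reference set
#'
#' Exact maximum by full linear scan (no approximate nearest neighbour).
#' This is the applicability-domain statistic: the model is trusted only on
#' compounds structurally close to what it was trained on.
#'
#' @param query 0/1 matrix (or single vector) of query fingerprints.
#' @param reference_set 0/1 matrix of reference fingerprints (the training
#'   set, actives and inactives alike).
#' @return data.frame with `max_tanimoto` and `nearest` (row name or index
#'   of the argmax reference).
#' @export
max_similarity_to_set <- function(query, reference_set) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  reference_set <- as.matrix(reference_set)
  if (nrow(reference_set) == 0) {
    stop("input error: empty reference set", call. = FALSE)
  }
  sim <- tanimoto_matrix(query, reference_set)
  j <- max.col(sim, ties.method = "first")
  refn <- rownames(reference_set)
  data.frame(
    max_tanimoto = sim[cbind(seq_len(nrow(sim)), j)],
    nearest = if (!is.null(refn)) refn[j] else as.character(j),
    stringsAsFactors = FALSE
  )
}
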