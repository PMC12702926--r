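# Independent oracles used by the tests. These re-derive expected results
# by brute force through their own code paths; they never call the
# operations they are checking.

# Pairwise-comparison ROC-AUC: P(score_active > score_inactive) + 0.5 ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Bit-loop Tanimoto on 0/1 vectors.
oracle_tanimoto <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

# ---- exhaustive hybridization enumerator ---------------------------------
# Works directly on ChemmineR atom/bond blocks with its own graph walks and
# its own molblock assembly; shares only the OpenBabel canonicalizer with
# the implementation.

oracle_hybridize <- function(sdfset, d_max = 1.0, theta_max = 15.0,
                             min_frag = 3L) {
  mols <- ChemmineR::SDFset2SDF(sdfset)
  parsed <- lapply(mols, function(m) {
    ab <- ChemmineR::atomblock(m)
    bb <- ChemmineR::bondblock(m)
    list(el = sub("_.*", "", rownames(ab)),
         xyz = unname(as.matrix(ab[, 1:3])),
         bd = cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                    as.integer(bb[, 3])))
  })
  reach <- function(bd, n, from, skip_a, skip_b) {
    # depth-first search avoiding one bond
    seen <- rep(FALSE, n); stack <- from; seen[from] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (r in seq_len(nrow(bd))) {
        a <- bd[r, 1]; b <- bd[r, 2]
        if ((a == skip_a && b == skip_b) || (a == skip_b && b == skip_a)) next
        w <- if (a == v) b else if (b == v) a else next
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    which(seen)
  }
  cut_bonds <- function(pm) {
    n <- length(pm$el)
    out <- list()
    for (r in seq_len(nrow(pm$bd))) {
      a <- pm$bd[r, 1]; b <- pm$bd[r, 2]
      if (pm$bd[r, 3] != 1) next
      if (pm$el[a] == "H" || pm$el[b] == "H") next
      side_a <- reach(pm$bd, n, a, a, b)
      if (b %in% side_a) next  # ring bond
      side_b <- setdiff(seq_len(n), side_a)
      ha <- sum(pm$el[side_a] != "H"); hb <- sum(pm$el[side_b] != "H")
      if (ha < min_frag || hb < min_frag) next
      out[[length(out) + 1]] <- list(a = a, b = b, side_a = side_a,
                                     side_b = side_b)
      out[[length(out) + 1]] <- list(a = b, b = a, side_a = side_b,
                                     side_b = side_a)
    }
    out
  }
  assemble <- function(pa, cut_a, pb, cut_b) {
    # head fragment of A (atoms around cut_a$a) + tail fragment of B
    ka <- sort(cut_a$side_a); kb <- sort(cut_b$side_b)
    el <- c(pa$el[ka], pb$el[kb])
    xyz <- rbind(pa$xyz[ka, , drop = FALSE], pb$xyz[kb, , drop = FALSE])
    mapa <- match(seq_along(pa$el), ka)
    mapb <- match(seq_along(pb$el), kb)
    bonds <- NULL
    for (r in seq_len(nrow(pa$bd))) {
      i <- mapa[pa$bd[r, 1]]; j <- mapa[pa$bd[r, 2]]
      if (!is.na(i) && !is.na(j)) bonds <- rbind(bonds, c(i, j, pa$bd[r, 3]))
    }
    off <- length(ka)
    for (r in seq_len(nrow(pb$bd))) {
      i <- mapb[pb$bd[r, 1]]; j <- mapb[pb$bd[r, 2]]
      if (!is.na(i) && !is.na(j))
        bonds <- rbind(bonds, c(i + off, j + off, pb$bd[r, 3]))
    }
    bonds <- rbind(bonds, c(mapa[cut_a$a], mapb[cut_b$b] + off, 1))
    lines <- c("oracle", "  oracle", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       length(el), nrow(bonds)),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], el),
               sprintf("%3d%3d%3d  0  0  0  0",
                       bonds[, 1], bonds[, 2], bonds[, 3]),
               "M  END")
    paste(lines, collapse = "\n")
  }
  geo_ok <- function(pa, ca, pb, cb) {
    A1 <- pa$xyz[ca$a, ]; A2 <- pa$xyz[ca$b, ]
    B1 <- pb$xyz[cb$a, ]; B2 <- pb$xyz[cb$b, ]
    d1 <- sqrt(sum((A1 - B1)^2)); d2 <- sqrt(sum((A2 - B2)^2))
    v1 <- A2 - A1; v2 <- B2 - B1
    ang <- acos(min(1, max(-1, sum(v1 * v2) /
                             (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
    d1 <= d_max && d2 <= d_max && ang <= theta_max
  }
  parents <- unlist(lapply(parsed, function(p) {
    lines <- c("p", "  p", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       length(p$el), nrow(p$bd)),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       p$xyz[, 1], p$xyz[, 2], p$xyz[, 3], p$el),
               sprintf("%3d%3d%3d  0  0  0  0", p$bd[, 1], p$bd[, 2],
                       p$bd[, 3]),
               "M  END")
    hybscreen:::molblocks_to_smiles(paste(lines, collapse = "\n"))
  }))
  hybrids <- character(0)
  n <- length(parsed)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    for (ca in cut_bonds(parsed[[i]])) for (cb in cut_bonds(parsed[[j]])) {
      if (!geo_ok(parsed[[i]], ca, parsed[[j]], cb)) next
      for (blk in list(assemble(parsed[[i]], ca, parsed[[j]], cb),
                       assemble(parsed[[j]], cb, parsed[[i]], ca))) {
        smi <- hybscreen:::molblocks_to_smiles(blk)
        if (!is.na(smi)) hybrids <- c(hybrids, smi)
      }
    }
  }
  sort(setdiff(unique(hybrids), parents))
}
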