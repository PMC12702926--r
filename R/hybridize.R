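# BREED-style fragment hybridization of pre-aligned 3D ligands.
#
# The algorithm: every acyclic single heavy-atom--heavy-atom bond of every
# ligand is a potential cut site. Two cut bonds from different ligands match
# when their endpoint atoms superimpose within `d_max` (both endpoints;
# the ligands share a binding-site frame, so no alignment happens here) and
# their bond vectors agree within `theta_max`. A matched pair is recombined
# into up to two hybrids by swapping the fragments on either side of the
# cut, keeping all original coordinates and joining with a new single bond.
# Hybrids failing valence sanitization are dropped and counted; survivors
# are deduplicated by canonical SMILES and parents are excluded.
#
# Everything in this module is deterministic: no randomness, output sorted
# by canonical SMILES.

#' Hybridization parameters
#'
#' Geometric and size tolerances for fragment recombination. The defaults
#' encode the classic criteria for chemically plausible joins: endpoint
#' displacement of at most 1.0 Angstrom so the new bond has a feasible
#' length, bond-vector deviation of at most 15 degrees so the junction is
#' not strained, and a minimum fragment size that keeps pharmacophore-sized
#' pieces rather than trivial substituents. Both tolerance tests are
#' boundary-inclusive (<=).
#'
#' @param d_max maximum endpoint displacement at the connection points
#'   (Angstrom, default 1.0).
#' @param theta_max maximum bond-vector angle deviation (degrees, default 15).
#' @param min_fragment_heavy_atoms minimum heavy atoms per fragment
#'   (default 3).
#' @param generations number of hybridization cycles; the output of cycle g
#'   joins the input pool of cycle g+1 (default 1).
#' @param untangle relax junction geometry with a short force-field
#'   minimization (default FALSE).
#' @param displacement_mode `"endpoint"` tests both endpoints against
#'   `d_max` (stricter, default); `"midpoint"` tests the bond midpoints.
#' @return object of class `hybridization_params`.
#' @export
hybridization_params <- function(d_max = 1.0, theta_max = 15.0,
                                 min_fragment_heavy_atoms = 3L,
                                 generations = 1L, untangle = FALSE,
                                 displacement_mode = c("endpoint", "midpoint")) {
  displacement_mode <- match.arg(displacement_mode)
  stopifnot(d_max > 0, theta_max >= 0, theta_max <= 180,
            min_fragment_heavy_atoms >= 1, generations >= 1)
  structure(list(d_max = d_max, theta_max = theta_max,
                 min_fragment_heavy_atoms = as.integer(min_fragment_heavy_atoms),
                 generations = as.integer(generations),
                 untangle = isTRUE(untangle),
                 displacement_mode = displacement_mode),
            class = "hybridization_params")
}

# ---- internal ligand graph representation --------------------------------

# Parse one ChemmineR SDF molecule into the light structure the hybridizer
# works on: element vector, coordinate matrix, bond table.
parse_ligand <- function(sdf, id = "ligand") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  if (all(coords[, 3] == 0) && nrow(coords) > 3 &&
      all(coords[, 1:2] == 0)) {
    stop("input error: ligand '", id, "' has no conformer", call. = FALSE)
  }
  bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  structure(list(id = id, elements = elements, coords = coords,
                 bonds = bonds, n_atoms = length(elements)),
            class = "hyb_ligand")
}

# Adjacency list from a bond table.
adjacency <- function(bonds, n_atoms) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Connected component of `start`, optionally with one bond removed.
component_of <- function(adj, start, skip = NULL) {
  seen <- logical(length(adj))
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.null(skip) &&
          ((v == skip[1] && w == skip[2]) || (v == skip[2] && w == skip[1]))) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

# A bond is in a ring iff its endpoints remain connected after removing it.
bond_in_ring <- function(adj, a, b) {
  b %in% component_of(adj, a, skip = c(a, b))
}

is_heavy <- function(el) toupper(el) != "H"

#' Enumerate cuttable bonds of an aligned ligand
#'
#' Every acyclic single bond between two heavy atoms whose cleavage leaves
#' at least `min_fragment_heavy_atoms` heavy atoms on each side. Each bond
#' is reported once per direction: the entry (a, b) means the fragment kept
#' from this ligand in a recombination is the one containing atom `a`.
#'
#' @param ligand a parsed ligand (internal class `hyb_ligand`) or a single
#'   [ChemmineR::SDF] molecule.
#' @param params a [hybridization_params()].
#' @return data.frame of directed cut-bond entries with endpoint
#'   coordinates (`ax..bz`) and heavy-atom counts of the retained fragment.
#' @export
enumerate_cuttable_bonds <- function(ligand, params = hybridization_params()) {
  if (methods::is(ligand, "SDF")) ligand <- parse_ligand(ligand)
  stopifnot(inherits(ligand, "hyb_ligand"))
  adj <- adjacency(ligand$bonds, ligand$n_atoms)
  heavy <- is_heavy(ligand$elements)
  out <- list()
  for (k in seq_len(nrow(ligand$bonds))) {
    bd <- ligand$bonds[k, ]
    if (bd$order != 1L) next
    if (!heavy[bd$a] || !heavy[bd$b]) next
    if (bond_in_ring(adj, bd$a, bd$b)) next
    comp_a <- component_of(adj, bd$a, skip = c(bd$a, bd$b))
    comp_b <- setdiff(seq_len(ligand$n_atoms), comp_a)
    na <- sum(heavy[comp_a]); nb <- sum(heavy[comp_b])
    if (na < params$min_fragment_heavy_atoms ||
        nb < params$min_fragment_heavy_atoms) next
    for (dir in 1:2) {
      aa <- if (dir == 1) bd$a else bd$b
      bb <- if (dir == 1) bd$b else bd$a
      out[[length(out) + 1L]] <- data.frame(
        parent_id = ligand$id, atom_a = aa, atom_b = bb,
        ax = ligand$coords[aa, 1], ay = ligand$coords[aa, 2],
        az = ligand$coords[aa, 3],
        bx = ligand$coords[bb, 1], by = ligand$coords[bb, 2],
        bz = ligand$coords[bb, 3],
        head_heavy = if (dir == 1) na else nb,
        tail_heavy = if (dir == 1) nb else na,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(parent_id = character(0), atom_a = integer(0),
                      atom_b = integer(0), ax = numeric(0), ay = numeric(0),
                      az = numeric(0), bx = numeric(0), by = numeric(0),
                      bz = numeric(0), head_heavy = integer(0),
                      tail_heavy = integer(0)))
  }
  do.call(rbind, out)
}

#' Test whether two cut bonds superimpose
#'
#' Endpoint pairing is directed: atom a of bond i is matched against atom a
#' of bond j, b against b. Acceptance requires both endpoint displacements
#' within `d_max` (or, in midpoint mode, the midpoint distance) and the
#' bond-vector angle within `theta_max`; both tests are inclusive.
#'
#' @param bond_i,bond_j one-row data.frames as produced by
#'   [enumerate_cuttable_bonds()], from two different ligands in a common
#'   binding-site frame.
#' @param params a [hybridization_params()].
#' @return list with `accept`, `displacement` (Angstrom; max of the two
#'   endpoint distances, or the midpoint distance) and `angle` (degrees).
#' @export
match_bond_vectors <- function(bond_i, bond_j,
                               params = hybridization_params()) {
  pa_i <- c(bond_i$ax, bond_i$ay, bond_i$az)
  pb_i <- c(bond_i$bx, bond_i$by, bond_i$bz)
  pa_j <- c(bond_j$ax, bond_j$ay, bond_j$az)
  pb_j <- c(bond_j$bx, bond_j$by, bond_j$bz)
  v_i <- pb_i - pa_i
  v_j <- pb_j - pa_j
  ni <- sqrt(sum(v_i^2)); nj <- sqrt(sum(v_j^2))
  if (ni == 0 || nj == 0) {
    stop("numerical degeneracy: zero-length bond vector", call. = FALSE)
  }
  cosang <- sum(v_i * v_j) / (ni * nj)
  angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (params$displacement_mode == "midpoint") {
    displacement <- sqrt(sum(((pa_i + pb_i) / 2 - (pa_j + pb_j) / 2)^2))
    disp_ok <- displacement <= params$d_max
  } else {
    d_a <- sqrt(sum((pa_i - pa_j)^2))
    d_b <- sqrt(sum((pb_i - pb_j)^2))
    displacement <- max(d_a, d_b)
    disp_ok <- d_a <= params$d_max && d_b <= params$d_max
  }
  list(accept = disp_ok && angle <= params$theta_max,
       displacement = displacement, angle = angle)
}

# Maximum plausible explicit valence per element; the sanitizer drops
# hybrids whose atoms exceed it. Order-4 (aromatic) bonds count 1.5.
.max_valence <- c(C = 4, N = 4, O = 2, S = 6, P = 5, F = 1, Cl = 1,
                  Br = 1, I = 1, B = 3, Si = 4)

valence_ok <- function(elements, bonds) {
  contrib <- ifelse(bonds$order == 4L, 1.5, bonds$order)
  val <- numeric(length(elements))
  for (k in seq_len(nrow(bonds))) {
    val[bonds$a[k]] <- val[bonds$a[k]] + contrib[k]
    val[bonds$b[k]] <- val[bonds$b[k]] + contrib[k]
  }
  lim <- .max_valence[elements]
  lim[is.na(lim)] <- 6  # unrecognized elements: permissive
  all(val <= lim + 1e-9)
}

# Assemble a V2000 molblock from elements, coordinates and bonds.
build_molblock <- function(title, elements, coords, bonds) {
  n_at <- length(elements); n_bd <- nrow(bonds)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        coords[, 1], coords[, 2], coords[, 3], elements)
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0", bonds$a, bonds$b, bonds$order)
  paste(c(title, "  hybscreen 3D", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd),
          atom_lines, bond_lines, "M  END"), collapse = "\n")
}

# Extract the fragment of `lig` containing `keep_atom` once the bond
# (cut_a, cut_b) is removed. Returns remapped atoms/bonds plus the new
# index of the junction atom.
extract_fragment <- function(lig, cut_a, cut_b, keep_atom) {
  adj <- adjacency(lig$bonds, lig$n_atoms)
  comp <- sort(component_of(adj, keep_atom, skip = c(cut_a, cut_b)))
  remap <- integer(lig$n_atoms)
  remap[comp] <- seq_along(comp)
  keep_bond <- lig$bonds$a %in% comp & lig$bonds$b %in% comp
  bonds <- lig$bonds[keep_bond, , drop = FALSE]
  bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
  list(elements = lig$elements[comp],
       coords = lig$coords[comp, , drop = FALSE],
       bonds = bonds, junction = remap[keep_atom])
}

#' Recombine two matched cut bonds into hybrid molecules
#'
#' Produces up to two hybrids: the fragment of ligand A containing atom a of
#' bond i joined to the fragment of ligand B containing atom b of bond j,
#' and the complementary pairing (B-head + A-tail). Atoms keep their
#' original coordinates; the junction is a new single bond. Hybrids whose
#' atoms would exceed standard valences, or that OpenBabel cannot
#' sanitize into a SMILES, are dropped and counted.
#'
#' @param bond_i,bond_j matched one-row cut-bond entries.
#' @param ligand_A,ligand_B the parsed parent ligands.
#' @param params a [hybridization_params()].
#' @return list with `hybrids` (list of hybrid records: `molblock`,
#'   `smiles`, `parent_head_id`, `parent_tail_id`, `displacement`, `angle`)
#'   and `dropped` (count of sanitization failures).
#' @export
recombine <- function(bond_i, bond_j, ligand_A, ligand_B,
                      params = hybridization_params()) {
  m <- match_bond_vectors(bond_i, bond_j, params)
  hybrids <- list()
  dropped <- 0L
  pairings <- list(
    list(head = ligand_A, hb = bond_i, tail = ligand_B, tb = bond_j),
    list(head = ligand_B, hb = bond_j, tail = ligand_A, tb = bond_i)
  )
  for (p in pairings) {
    if (p$head$id == p$tail$id) next
    head_fr <- extract_fragment(p$head, p$hb$atom_a, p$hb$atom_b, p$hb$atom_a)
    tail_fr <- extract_fragment(p$tail, p$tb$atom_a, p$tb$atom_b, p$tb$atom_b)
    n_head <- length(head_fr$elements)
    elements <- c(head_fr$elements, tail_fr$elements)
    coords <- rbind(head_fr$coords, tail_fr$coords)
    tb <- tail_fr$bonds
    tb$a <- tb$a + n_head; tb$b <- tb$b + n_head
    bonds <- rbind(head_fr$bonds, tb,
                   data.frame(a = head_fr$junction,
                              b = tail_fr$junction + n_head, order = 1L))
    if (!valence_ok(elements, bonds)) { dropped <- dropped + 1L; next }
    mb <- build_molblock("hybrid", elements, coords, bonds)
    smi <- molblocks_to_smiles(mb)
    if (is.na(smi)) { dropped <- dropped + 1L; next }
    hybrids[[length(hybrids) + 1L]] <- list(
      molblock = mb, smiles = smi,
      parent_head_id = p$head$id, parent_tail_id = p$tail$id,
      junction = c(p$hb$atom_a, p$tb$atom_b),
      displacement = m$displacement, angle = m$angle,
      n_heavy = sum(is_heavy(elements)))
  }
  list(hybrids = hybrids, dropped = dropped)
}

#' Generate a hybrid library from a set of aligned ligands
#'
#' Tests all cross-ligand pairings of directed cut bonds under the geometric
#' tolerances, recombines accepted pairs, drops sanitization failures,
#' deduplicates by stereo-aware canonical SMILES and removes any hybrid
#' identical to an input (or pool) structure. With `generations > 1` the
#' novel hybrids of each cycle join the ligand pool of the next. Output is
#' sorted by canonical SMILES, so the library is reproducible structure for
#' structure.
#'
#' @param ligands a [ChemmineR::SDFset] of pre-aligned 3D ligands (at least
#'   two), or a list of parsed ligands.
#' @param params a [hybridization_params()].
#' @return list with `hybrids` (data.frame: `id`, `smiles`,
#'   `parent_head_id`, `parent_tail_id`, `displacement`, `angle`,
#'   `n_heavy`, `generation`), `molblocks` (named character vector) and
#'   `report` (per-generation and total counts: pairs tested, matches,
#'   valence drops, duplicates removed, novel kept).
#' @export
generate_library <- function(ligands, params = hybridization_params()) {
  pool <- as_ligand_list(ligands)
  if (length(pool) < 2) {
    stop("input error: need at least 2 ligands with conformers", call. = FALSE)
  }
  pool_smiles <- vapply(pool, function(l) {
    molblocks_to_smiles(build_molblock(l$id, l$elements, l$coords, l$bonds))
  }, character(1))
  seen <- unique(pool_smiles[!is.na(pool_smiles)])
  all_hyb <- list()
  gen_reports <- list()
  for (g in seq_len(params$generations)) {
    cuts <- lapply(pool, enumerate_cuttable_bonds, params = params)
    pairs_tested <- 0L; matches <- 0L; drops <- 0L; dup <- 0L
    novel <- list()
    n <- length(pool)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        ci <- cuts[[i]]; cj <- cuts[[j]]
        if (nrow(ci) == 0 || nrow(cj) == 0) next
        for (bi in seq_len(nrow(ci))) {
          for (bj in seq_len(nrow(cj))) {
            pairs_tested <- pairs_tested + 1L
            m <- match_bond_vectors(ci[bi, ], cj[bj, ], params)
            if (!m$accept) next
            matches <- matches + 1L
            rec <- recombine(ci[bi, ], cj[bj, ], pool[[i]], pool[[j]], params)
            drops <- drops + rec$dropped
            for (h in rec$hybrids) {
              if (h$smiles %in% seen) { dup <- dup + 1L; next }
              seen <- c(seen, h$smiles)
              h$generation <- g
              novel[[length(novel) + 1L]] <- h
            }
          }
        }
      }
    }
    gen_reports[[g]] <- list(generation = g, pairs_tested = pairs_tested,
                             matches = matches, valence_drops = drops,
                             duplicates_removed = dup,
                             novel_kept = length(novel))
    all_hyb <- c(all_hyb, novel)
    if (g < params$generations && length(novel)) {
      new_ligs <- lapply(seq_along(novel), function(k) {
        h <- novel[[k]]
        lig <- parse_molblock_ligand(h$molblock, sprintf("gen%d_h%d", g, k))
        lig
      })
      pool <- c(pool, new_ligs)
    }
    if (length(novel) == 0 && g < params$generations) break
  }
  if (length(all_hyb)) {
    df <- data.frame(
      smiles = vapply(all_hyb, `[[`, character(1), "smiles"),
      parent_head_id = vapply(all_hyb, `[[`, character(1), "parent_head_id"),
      parent_tail_id = vapply(all_hyb, `[[`, character(1), "parent_tail_id"),
      displacement = vapply(all_hyb, `[[`, numeric(1), "displacement"),
      angle = vapply(all_hyb, `[[`, numeric(1), "angle"),
      n_heavy = vapply(all_hyb, function(h) as.numeric(h$n_heavy), numeric(1)),
      generation = vapply(all_hyb, function(h) as.numeric(h$generation),
                          numeric(1)),
      stringsAsFactors = FALSE)
    ord <- order(df$smiles)
    df <- df[ord, , drop = FALSE]
    molblocks <- vapply(all_hyb, `[[`, character(1), "molblock")[ord]
    if (params$untangle) {
      relaxed <- vapply(molblocks, function(mb) untangle_hybrid(mb)$molblock,
                        character(1), USE.NAMES = FALSE)
      molblocks <- relaxed
    }
    df$id <- sprintf("HYB%05d", seq_len(nrow(df)))
    df <- df[, c("id", setdiff(names(df), "id"))]
    rownames(df) <- NULL
    molblocks <- vapply(seq_along(molblocks), function(k) {
      set_molblock_title(molblocks[k], df$id[k])
    }, character(1))
    names(molblocks) <- df$id
  } else {
    df <- data.frame(id = character(0), smiles = character(0),
                     parent_head_id = character(0),
                     parent_tail_id = character(0), displacement = numeric(0),
                     angle = numeric(0), n_heavy = numeric(0),
                     generation = numeric(0), stringsAsFactors = FALSE)
    molblocks <- character(0)
  }
  totals <- list(
    pairs_tested = sum(vapply(gen_reports, `[[`, numeric(1), "pairs_tested")),
    matches = sum(vapply(gen_reports, `[[`, numeric(1), "matches")),
    valence_drops = sum(vapply(gen_reports, `[[`, numeric(1), "valence_drops")),
    duplicates_removed = sum(vapply(gen_reports, `[[`, numeric(1),
                                    "duplicates_removed")),
    novel_kept = nrow(df))
  list(hybrids = df, molblocks = molblocks,
       report = list(generations = gen_reports, totals = totals,
                     n_input_ligands = length(as_ligand_list(ligands))))
}

as_ligand_list <- function(ligands) {
  if (methods::is(ligands, "SDFset")) {
    ids <- ChemmineR::cid(ligands)
    mols <- ChemmineR::SDFset2SDF(ligands)
    return(lapply(seq_along(mols), function(i) parse_ligand(mols[[i]], ids[i])))
  }
  if (is.list(ligands) && all(vapply(ligands, inherits, logical(1),
                                     "hyb_ligand"))) {
    return(ligands)
  }
  stop("ligands must be an SDFset or a list of parsed ligands", call. = FALSE)
}

parse_molblock_ligand <- function(molblock, id) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_at <- as.integer(substr(counts, 1, 3))
  n_bd <- as.integer(substr(counts, 4, 6))
  at <- lines[5:(4 + n_at)]
  coords <- cbind(as.numeric(substr(at, 1, 10)),
                  as.numeric(substr(at, 11, 20)),
                  as.numeric(substr(at, 21, 30)))
  elements <- trimws(substr(at, 32, 34))
  bd <- lines[(5 + n_at):(4 + n_at + n_bd)]
  bonds <- data.frame(a = as.integer(substr(bd, 1, 3)),
                      b = as.integer(substr(bd, 4, 6)),
                      order = as.integer(substr(bd, 7, 9)))
  structure(list(id = id, elements = elements, coords = coords,
                 bonds = bonds, n_atoms = n_at), class = "hyb_ligand")
}

#' Relax the geometry of a hybrid molecule
#'
#' Short force-field minimization (MMFF94, steepest descent) to resolve
#' junction strain such as an over-long new bond. The molecular topology is
#' required to be invariant: if the relaxed structure canonicalizes to a
#' different SMILES, or the force-field setup fails, the original geometry
#' is returned with `relaxed = FALSE`.
#'
#' @param molblock V2000 molblock text of the hybrid.
#' @param steps minimization steps (default 200).
#' @return list with `molblock` (possibly relaxed) and `relaxed` flag.
#' @export
untangle_hybrid <- function(molblock, steps = 200L) {
  before <- molblocks_to_smiles(molblock)
  out <- tryCatch({
    lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
    if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
    res <- ob_run(c("-isdf", "-osdf", "--minimize", "--ff", "MMFF94",
                    "--steps", as.character(steps), "--sd"),
                  stdin_lines = lines)
    res
  }, error = function(e) NULL)
  if (is.null(out) || !length(out)) {
    return(list(molblock = molblock, relaxed = FALSE))
  }
  relaxed_block <- paste(out[!grepl("^\\$\\$\\$\\$", out)], collapse = "\n")
  after <- tryCatch(molblocks_to_smiles(relaxed_block),
                    error = function(e) NA_character_)
  if (is.na(after) || is.na(before) || after != before) {
    return(list(molblock = molblock, relaxed = FALSE))
  }
  list(molblock = relaxed_block, relaxed = TRUE)
}

#' Rigidly superimpose one ligand onto a reference (convenience)
#'
#' Least-squares (Kabsch) superposition using an explicit atom
#' correspondence. Provided as a convenience for preparing inputs; the
#' hybridizer itself never re-aligns — it assumes a common binding-site
#' frame, because geometric bond matching is meaningless across frames.
#'
#' @param lig parsed ligand to move.
#' @param ref parsed reference ligand.
#' @param pairs two-column integer matrix: atom index in `lig`, matching
#'   atom index in `ref` (at least 3 rows).
#' @return `lig` with transformed coordinates.
#' @export
align_ligand <- function(lig, ref, pairs) {
  stopifnot(inherits(lig, "hyb_ligand"), inherits(ref, "hyb_ligand"),
            is.matrix(pairs), nrow(pairs) >= 3)
  X <- lig$coords[pairs[, 1], , drop = FALSE]
  Y <- ref$coords[pairs[, 2], , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  lig$coords <- sweep(sweep(lig$coords, 2, cx) %*% t(R), 2, cy, "+")
  lig
}
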