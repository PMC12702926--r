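# Deterministic synthetic-data generators. Every stage of the pipeline is
# testable offline against these: aligned ligand sets whose hybridization
# outcome is enumerable by hand, planted-motif activity datasets that are
# separable in fingerprint space by construction, screening libraries with
# planted per-stage funnel survival, and ranked screens with analytically
# known enrichment statistics.
#
# Every generator is a pure function of its seed (where it is random at
# all); manifests of expected outcomes are produced by direct construction,
# never by running the code under test.

# ---- aligned 3D ligand sets ----------------------------------------------

# Shared scaffold geometry: a benzene ring (Kekule) in the z = 0 plane with
# an optional para substituent, and a three-heavy-atom tail attached at C1.
# All coordinates are fixed literals so geometric tests are exact.
.aligned_ring <- matrix(c(
   1.390,  0.0000, 0,
   0.695,  1.2038, 0,
  -0.695,  1.2038, 0,
  -1.390,  0.0000, 0,
  -0.695, -1.2038, 0,
   0.695, -1.2038, 0), ncol = 3, byrow = TRUE)
.aligned_sub_pos <- c(-2.790, 0, 0)
.aligned_tail_pos <- matrix(c(
  2.890, 0.000, 0,
  3.645, 1.307, 0,
  5.155, 1.307, 0), ncol = 3, byrow = TRUE)

.aligned_heads <- list(
  list(sub = NA_character_, smi_open = "c1ccc(cc1)"),
  list(sub = "F",  smi_open = "Fc1ccc(cc1)"),
  list(sub = "Cl", smi_open = "Clc1ccc(cc1)"),
  list(sub = "C",  smi_open = "Cc1ccc(cc1)"))
.aligned_tails <- list(
  list(elements = c("C", "C", "O"), smi = "CCO"),
  list(elements = c("C", "C", "N"), smi = "CCN"),
  list(elements = c("C", "C", "C"), smi = "CCC"),
  list(elements = c("C", "C", "F"), smi = "CCF"))

#' Generate an aligned ligand set with known hybridization outcome
#'
#' Builds `k` ligands (2-4) that share an exactly superimposed aromatic
#' scaffold and cut-bond geometry but differ in both a ring decoration
#' (head) and a three-atom tail, so every cross-ligand head/tail swap is a
#' novel structure. With the default minimum fragment size of 3 heavy
#' atoms, each ligand has exactly one cuttable bond (ring-to-tail) whose
#' endpoints coincide across ligands (displacement 0, angle 0), so the
#' expected hybrid set is every head_i + tail_j with i != j:
#' `k * (k - 1)` novel structures, enumerated in the manifest by direct
#' SMILES assembly.
#'
#' @param k number of ligands (2-4).
#' @param perturb indices of ligands whose tail-attachment atom (the cut
#'   bond's far endpoint) is displaced 1.5 Angstrom out of plane; such a
#'   ligand matches nothing at the default 1.0 Angstrom tolerance.
#' @return list: `sdfset`, `molblocks`, `table` (id + canonical SMILES),
#'   `manifest_novel` (sorted canonical SMILES of all expected hybrids) and
#'   `manifest_parents`.
#' @export
make_aligned_set <- function(k = 4, perturb = integer(0)) {
  stopifnot(k >= 2, k <= 4)
  molblocks <- character(k)
  parent_smi <- character(k)
  for (i in seq_len(k)) {
    head <- .aligned_heads[[i]]
    tail <- .aligned_tails[[i]]
    elements <- c(rep("C", 6),
                  if (!is.na(head$sub)) head$sub else character(0),
                  tail$elements)
    sub_present <- !is.na(head$sub)
    n_ring <- 6L
    sub_idx <- if (sub_present) 7L else NA_integer_
    tail_base <- n_ring + as.integer(sub_present)
    coords <- rbind(.aligned_ring,
                    if (sub_present) matrix(.aligned_sub_pos, 1) else NULL,
                    .aligned_tail_pos)
    if (i %in% perturb) coords[tail_base + 1L, 3] <- coords[tail_base + 1L, 3] + 1.5
    bonds <- data.frame(
      a = c(1L, 2L, 3L, 4L, 5L, 6L), b = c(2L, 3L, 4L, 5L, 6L, 1L),
      order = c(1L, 2L, 1L, 2L, 1L, 2L))
    if (sub_present) {
      bonds <- rbind(bonds, data.frame(a = 4L, b = sub_idx, order = 1L))
    }
    bonds <- rbind(bonds,
                   data.frame(a = c(1L, tail_base + 1L, tail_base + 2L),
                              b = c(tail_base + 1L, tail_base + 2L,
                                    tail_base + 3L),
                              order = 1L))
    molblocks[i] <- paste0(
      build_molblock(paste0("L", i), elements, coords, bonds), "\n$$$$")
    parent_smi[i] <- paste0(head$smi_open, tail$smi)
  }
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(paste(molblocks, collapse = "\n"), "\n")[[1]]))
  ChemmineR::cid(sdfset) <- paste0("L", seq_len(k))
  # manifest by direct assembly: head_i + tail_j, i != j
  combos <- expand.grid(i = seq_len(k), j = seq_len(k))
  combos <- combos[combos$i != combos$j, ]
  novel <- canonical_smiles(vapply(seq_len(nrow(combos)), function(r) {
    paste0(.aligned_heads[[combos$i[r]]]$smi_open,
           .aligned_tails[[combos$j[r]]]$smi)
  }, character(1)))
  parents <- canonical_smiles(parent_smi)
  novel <- sort(unique(setdiff(novel, parents)))
  list(sdfset = sdfset, molblocks = molblocks,
       table = data.frame(id = paste0("L", seq_len(k)), smiles = parents,
                          stringsAsFactors = FALSE),
       manifest_novel = novel, manifest_parents = parents)
}

# ---- planted-motif activity datasets -------------------------------------

.motif_smarts <- "Nc1ncccn1"  # 2-aminopyrimidine core, kinase-hinge-like

.substituent_pool <- c("C", "CC", "CCC", "CC(C)C", "CCO", "CO", "OC",
                       "OCC", "N", "NC", "N(C)C", "F", "Cl", "Br",
                       "c2ccccc2", "c2ccc(F)cc2", "c2ccc(C)cc2",
                       "C(F)(F)F", "C(=O)N", "C(=O)NC", "S(=O)(=O)C",
                       "CC(C)O")

.inactive_templates <- c("%sC1CCC(%s)CC1", "%sC1CCN(%s)CC1",
                         "%sc1ccc(%s)cc1", "%sC1CCC(%s)C1",
                         "%sC1CCOC1%s", "%sCCOCC%s")

#' Generate a planted-motif activity dataset
#'
#' Actives are decorated 2-aminopyrimidines (every active carries the motif
#' `Nc1ncccn1`); inactives are decoy structures grown from aliphatic and
#' plain-aromatic templates and rejection-sampled so none contains the
#' motif. With `noise_rate = 0` the classes are therefore separable in
#' ECFP4 space by construction. Reproducible for a fixed seed.
#'
#' @param seed integer seed.
#' @param n_active,n_inactive class sizes (defaults 614/614, a balanced
#'   curated-kinase-set scale).
#' @param noise_rate fraction of labels flipped after construction
#'   (in \[0, 0.5)).
#' @return data.frame `id, smiles, label` with attributes `motif_smarts`
#'   and `flipped` (ids whose labels were flipped).
#' @export
make_activity_dataset <- function(seed = 1L, n_active = 614L,
                                  n_inactive = 614L, noise_rate = 0) {
  stopifnot(n_active >= 1, n_inactive >= 1, noise_rate >= 0, noise_rate < 0.5)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  actives <- grow_unique(n_active, function(m) {
    r <- sample(.substituent_pool, 3, replace = TRUE)
    sprintf("Nc1nc(%s)c(%s)c(%s)n1", r[1], r[2], r[3])
  })
  inactives <- grow_unique(n_inactive, function(m) {
    tpl <- sample(.inactive_templates, 1)
    r <- sample(.substituent_pool, 2, replace = TRUE)
    sprintf(tpl, r[1], r[2])
  }, reject_motif = TRUE)
  df <- data.frame(
    id = c(sprintf("ACT%04d", seq_len(n_active)),
           sprintf("DEC%04d", seq_len(n_inactive))),
    smiles = c(actives, inactives),
    label = c(rep(1, n_active), rep(0, n_inactive)),
    stringsAsFactors = FALSE)
  flipped <- character(0)
  n_flip <- round(noise_rate * nrow(df))
  if (n_flip > 0) {
    fi <- sample(nrow(df), n_flip)
    df$label[fi] <- 1 - df$label[fi]
    flipped <- df$id[fi]
  }
  attr(df, "motif_smarts") <- .motif_smarts
  attr(df, "flipped") <- flipped
  df
}

# Sample canonical structures from a template sampler until n unique ones
# accumulate; optionally reject any that contain the planted motif.
grow_unique <- function(n, sampler, reject_motif = FALSE, max_rounds = 60) {
  acc <- character(0)
  for (round in seq_len(max_rounds)) {
    need <- n - length(acc)
    if (need <= 0) break
    raw <- vapply(seq_len(max(2 * need, 50)), function(m) sampler(m),
                  character(1))
    can <- canonical_smiles(raw)
    can <- can[!is.na(can)]
    if (reject_motif && length(can)) {
      can <- can[!smarts_any_match(can, .motif_smarts)]
    }
    acc <- unique(c(acc, can))
  }
  if (length(acc) < n) {
    stop("fixture generator could not reach ", n, " unique structures",
         call. = FALSE)
  }
  acc[seq_len(n)]
}

# ---- funnel libraries with planted stage survival -------------------------

# Structure templates with known filter behaviour (verified at generation
# time; generation fails loudly if a template stops satisfying its role).
.funnel_templates <- list(
  pass    = c("Cc1ccc(NC(=O)C2CC2)cc1", "CC(C)c1ccc(NC(=O)C2CC2)cc1",
              "Cc1ccc(NC(=O)C2CCC2)cc1"),
  failqed = c("CCCCCCCCCCCCCCCCCCCC", "CCCCCCCCCCCCCCCCCCCCCC"),
  failsa  = c("C[C@H]1C[C@@H](O)[C@H](Nc2ccc(C)cc2)[C@@H](C)O1",
              "C[C@H]1[C@@H](C)[C@H](C)OC(=O)[C@@H]1Nc1ccc(C)cc1"),
  failad  = c("FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
              "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"))

#' Generate a screening library with planted funnel survival
#'
#' Constructs a library in which exactly the planted number of compounds
#' survives each funnel stage under the default thresholds: activity is
#' controlled by the assigned probability, the applicability domain by
#' structural families (the AD reference fingerprints returned with the
#' library cover every family except the out-of-domain one), and QED / SA by
#' structure templates with verified filter behaviour.
#'
#' @param seed integer seed (drives probabilities and row order).
#' @param counts non-increasing integer vector
#'   `(input, after_activity, after_AD, after_QED, after_SA)`.
#' @return list: `table` (id, canonical), `probabilities`, `training_fps`
#'   (AD reference), `expected` (planted survivor counts) and `templates`.
#' @export
make_funnel_library <- function(seed = 1L,
                                counts = c(1000L, 800L, 600L, 300L, 150L)) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 5, all(diff(counts) <= 0), all(counts >= 0))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  tpl <- lapply(.funnel_templates, function(x) canonical_smiles(x)[1])
  # verify template roles under the default thresholds
  th <- triage_thresholds()
  qv <- qed(unlist(tpl[c("pass", "failqed", "failsa")]))
  sv <- sa_score(unlist(tpl[c("pass", "failqed", "failsa")]))
  ok <- qv[1] >= th$qed_min && sv[1] <= th$sa_max &&   # pass template
    qv[2] < th$qed_min &&                              # fail-QED template
    qv[3] >= th$qed_min && sv[3] > th$sa_max           # fail-SA template
  fam_fps <- featurize(unlist(tpl))
  ad_gap <- max(tanimoto_matrix(fam_fps["failad", , drop = FALSE],
                                fam_fps[c("pass", "failqed", "failsa"), ,
                                        drop = FALSE]))
  if (!ok || ad_gap >= th$tanimoto_min) {
    stop("infeasible plant: funnel templates violate their roles",
         call. = FALSE)
  }
  n <- counts[1]
  n_group <- c(fail_act = counts[1] - counts[2],
               fail_ad = counts[2] - counts[3],
               fail_qed = counts[3] - counts[4],
               fail_sa = counts[4] - counts[5],
               pass = counts[5])
  group <- rep(names(n_group), n_group)
  smiles <- character(n); probs <- numeric(n)
  role_of <- c(fail_act = "pass", fail_ad = "failad", fail_qed = "failqed",
               fail_sa = "failsa", pass = "pass")
  for (g in names(n_group)) {
    idx <- which(group == g)
    smiles[idx] <- tpl[[role_of[[g]]]]
    probs[idx] <- if (g == "fail_act") stats::runif(length(idx), 0.01, 0.45)
      else stats::runif(length(idx), 0.55, 0.99)
  }
  ord <- sample.int(n)
  training_fps <- fam_fps[c("pass", "failqed", "failsa"), , drop = FALSE]
  list(table = data.frame(id = sprintf("LIB%05d", seq_len(n)),
                          canonical = smiles[ord],
                          stringsAsFactors = FALSE),
       probabilities = probs[ord],
       training_fps = training_fps,
       expected = stats::setNames(counts,
                                  c("input", "activity", "ad", "qed", "sa")),
       templates = tpl)
}

# ---- ranked screens with known statistics --------------------------------

#' Generate a ranked screen with analytically known behaviour
#'
#' Score generator for enrichment-statistic validation. Scores follow the
#' docking convention (lower = better). Qualities: `perfect` (every active
#' outranks every decoy; BEDROC -> 1, EF at fraction f -> min(1/f, N/n)),
#' `worst` (all actives last; BEDROC -> 0), `random` (expected RIE and EF
#' of 1) and `exponential` (active ranks concentrated early with the given
#' `rate`).
#'
#' @param seed integer seed.
#' @param N total compounds; `n` actives.
#' @param quality one of `perfect`, `random`, `worst`, `exponential`.
#' @param rate early-concentration parameter for `exponential`.
#' @return a [ranked_screen()] with attribute `quality`.
#' @export
make_ranked_screen <- function(seed = 1L, N = 1130L, n = 130L,
                               quality = c("perfect", "random", "worst",
                                           "exponential"),
                               rate = 20) {
  quality <- match.arg(quality)
  stopifnot(n >= 1, N > n)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  labels <- c(rep(1L, n), rep(0L, N - n))
  pos <- switch(quality,
    perfect = seq_len(N),
    worst = c(seq(N - n + 1, N), seq_len(N - n)),
    random = sample.int(N),
    exponential = {
      p <- exp(-rate * seq_len(N) / N)
      act_pos <- sample(N, n, prob = p)
      rest <- sample(setdiff(seq_len(N), act_pos))
      out <- integer(N); out[seq_len(n)] <- act_pos
      out[(n + 1):N] <- rest
      out
    })
  # position 1 = best; docking convention: lower score = better
  scores <- pos + stats::runif(N, 0, 0.1)  # strictly increasing with position
  scr <- ranked_screen(scores, labels, lower_is_better = TRUE,
                       ids = sprintf("CMP%05d", seq_len(N)))
  attr(scr, "quality") <- quality
  scr
}
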