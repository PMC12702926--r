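# Screening-library triage: applicability domain (max Tanimoto to the
# training set), drug-likeness (QED) and synthetic accessibility (Ertl-style
# SA score), combined into the sequential screening funnel
# activity -> AD -> QED -> SA.

#' Triage thresholds
#'
#' The funnel's four cut-offs: minimum predicted activity probability,
#' minimum applicability-domain similarity, minimum drug-likeness and
#' maximum synthetic-accessibility score.
#'
#' @param prob_min activity probability threshold (default 0.5).
#' @param tanimoto_min applicability-domain threshold (default 0.4).
#' @param qed_min drug-likeness threshold (default 0.7).
#' @param sa_max synthetic-accessibility ceiling (default 3; SA lives in
#'   \[1, 10\], 1 = easiest).
#' @return object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(prob_min = 0.5, tanimoto_min = 0.4,
                              qed_min = 0.7, sa_max = 3.0) {
  stopifnot(prob_min >= 0, prob_min <= 1, tanimoto_min >= 0,
            tanimoto_min <= 1, qed_min >= 0, qed_min <= 1,
            sa_max >= 1, sa_max <= 10)
  structure(list(prob_min = prob_min, tanimoto_min = tanimoto_min,
                 qed_min = qed_min, sa_max = sa_max),
            class = "triage_thresholds")
}

# ---- QED ------------------------------------------------------------------

# Published desirability-function parameters of the QED method (asymmetric
# double sigmoid per property) and the canonical property weights.
.qed_ads <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764,
             d = 2.419764353, e = 49.22325677, f = 65.37051707,
             dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431,
             d = 4.581497897, e = 0.822739154, f = 0.576295591,
             dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657,
             d = 4.435986202, e = 0.290141953, f = 1.300669958,
             dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388,
             d = 1e-09, e = 0.713820843, f = 0.920922555,
             dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554,
             d = 87.83366614, e = 12.01999824, f = 28.51324732,
             dmax = 104.5686167),
  ROTB   = c(a = 0.01, b = 272.4121427, c = 2.55837997,
             d = 1.565547684, e = 1.271567166, f = 2.758063707,
             dmax = 105.4420403),
  AROM   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939,
             d = 1e-09, e = 1.317690384, f = 0.375760881,
             dmax = 312.337261),
  ALERTS = c(a = 0.01, b = 1199.094025, c = -0.09002883,
             d = 1e-09, e = 0.185904477, f = 0.875193782,
             dmax = 417.725314))

.qed_weights_mean <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                       PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads_value <- function(x, p) {
  (p["a"] + p["b"] / (1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])) *
     (1 - 1 / (1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])))) / p["dmax"]
}

#' QED from a table of the eight molecular properties
#'
#' The weighted-geometric-mean drug-likeness score: each property (molecular
#' weight, logP, H-bond acceptors/donors, polar surface area, rotatable
#' bonds, aromatic rings, structural alerts) is mapped through its published
#' asymmetric-double-sigmoid desirability function and the desirabilities
#' are combined as `exp(sum(w log d) / sum(w))`. Exposed separately from
#' [qed()] so the scoring arithmetic can be driven by property values from
#' any descriptor engine.
#'
#' @param props data.frame (or named vector) with columns
#'   `MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS`.
#' @param weights named property weights; the canonical weighted form by
#'   default, `rep(1, 8)` gives the unweighted mean.
#' @return numeric QED values in \[0, 1\].
#' @export
qed_score <- function(props, weights = .qed_weights_mean) {
  if (is.null(dim(props))) props <- as.data.frame(as.list(props))
  keys <- names(.qed_ads)
  stopifnot(all(keys %in% names(props)))
  d <- vapply(keys, function(k) {
    pmax(qed_ads_value(as.numeric(props[[k]]), .qed_ads[[k]]), 1e-10)
  }, numeric(nrow(props)))
  d <- matrix(d, nrow = nrow(props))
  w <- weights[keys]
  exp(as.numeric(log(d) %*% w) / sum(w))
}

#' Compute the eight QED properties for a set of molecules
#'
#' Property engines: OpenBabel for molecular weight, Wildman-Crippen logP,
#' topological polar surface area, H-bond acceptor/donor counts and
#' rotatable bonds; aromatic-ring counts from ring perception; structural
#' alerts from the package's curated SMARTS list
#' (`inst/extdata/structural_alerts.tsv`, a Brenk-style set).
#'
#' @param smiles character vector of SMILES.
#' @param alerts data.frame with `name` and `smarts` columns; the packaged
#'   list by default.
#' @return data.frame with one row per molecule: `MW`, `ALOGP`, `HBA`,
#'   `HBD`, `PSA`, `ROTB`, `AROM`, `ALERTS`; `NA` rows for molecules whose
#'   descriptors fail.
#' @export
qed_properties <- function(smiles, alerts = default_alerts()) {
  n <- length(smiles)
  out <- data.frame(MW = rep(NA_real_, n), ALOGP = NA_real_, HBA = NA_real_,
                    HBD = NA_real_, PSA = NA_real_, ROTB = NA_real_,
                    AROM = NA_real_, ALERTS = NA_real_)
  ok <- !is.na(smiles) & nzchar(as.character(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(as.character(smiles[idx]), seq_along(idx))
  res <- ob_run(c("-ismi", "-osmi", "--append",
                  "MW logP TPSA HBA2 HBD rotors", "-e"),
                stdin_lines = lines)
  res <- res[nzchar(res)]
  for (line in res) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    fields <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(fields) < 7) next
    i <- suppressWarnings(as.integer(fields[1]))
    if (is.na(i)) next
    vals <- suppressWarnings(as.numeric(fields[2:7]))
    out$MW[idx[i]] <- vals[1]; out$ALOGP[idx[i]] <- vals[2]
    out$PSA[idx[i]] <- vals[3]; out$HBA[idx[i]] <- vals[4]
    out$HBD[idx[i]] <- vals[5]; out$ROTB[idx[i]] <- vals[6]
  }
  out$AROM[idx] <- aromatic_ring_count(smiles[idx])
  out$ALERTS[idx] <- alert_count(smiles[idx], alerts)
  out
}

#' @rdname qed_properties
#' @export
default_alerts <- function() {
  path <- system.file("extdata", "structural_alerts.tsv",
                      package = "hybscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Number of SSSR aromatic rings per molecule (ring perception over small
# rings, size <= 7; large aromatic macrocycles are out of scope).
aromatic_ring_count <- function(smiles) {
  sdf <- smiles_to_sdfset(smiles)
  vapply(seq_along(smiles), function(i) {
    k <- match(i, sdf$index)
    if (is.na(k)) return(NA_real_)
    m <- sdf$mols[[k]]
    r <- tryCatch(
      suppressWarnings(ChemmineR::rings(m, upper = 7, type = "count",
                                        arom = TRUE)),
      error = function(e) NULL)
    if (is.null(r)) return(NA_real_)
    as.numeric(r[["AROMATIC"]])
  }, numeric(1))
}

# Which molecules match a SMARTS pattern (OpenBabel filter, batch).
smarts_any_match <- function(smiles, smarts) {
  n <- length(smiles)
  hit <- logical(n)
  lines <- paste(as.character(smiles), seq_len(n))
  filt <- paste0("s='", smarts, "'")
  out <- tryCatch(
    ob_run(c("-ismi", "-osmi", "--filter", shQuote(filt), "-e"),
           stdin_lines = lines),
    error = function(e) character(0))
  out <- out[nzchar(out)]
  ids <- suppressWarnings(as.integer(vapply(strsplit(out, "\t", fixed = TRUE),
                                            function(p) trimws(p[length(p)]),
                                            character(1))))
  hit[ids[!is.na(ids)]] <- TRUE
  hit
}

# Number of distinct alert names matched per molecule.
alert_count <- function(smiles, alerts = default_alerts()) {
  counts <- numeric(length(smiles))
  for (nm in unique(alerts$name)) {
    pats <- alerts$smarts[alerts$name == nm]
    hit <- Reduce(`|`, lapply(pats, function(p) smarts_any_match(smiles, p)))
    counts <- counts + as.numeric(hit)
  }
  counts
}

#' Quantitative estimate of drug-likeness
#'
#' Full pipeline: computes the eight properties with [qed_properties()] and
#' scores them with [qed_score()]. Molecules whose descriptors fail get
#' `NA` (treated as failing the drug-likeness filter downstream).
#'
#' @param smiles character vector of SMILES.
#' @param weights see [qed_score()].
#' @return numeric vector in \[0, 1\].
#' @export
qed <- function(smiles, weights = .qed_weights_mean) {
  props <- qed_properties(smiles)
  res <- rep(NA_real_, length(smiles))
  ok <- stats::complete.cases(props)
  if (any(ok)) res[ok] <- qed_score(props[ok, , drop = FALSE], weights)
  res
}

# ---- SA score -------------------------------------------------------------

# Convert SMILES to an SDFset, keeping the mapping of surviving molecules.
smiles_to_sdfset <- function(smiles) {
  named <- stats::setNames(as.character(smiles), seq_along(smiles))
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(named)),
    error = function(e) NULL)
  if (is.null(sdfset)) {
    # fall back to per-molecule conversion so one bad SMILES cannot sink
    # the whole batch
    mols <- list(); index <- integer(0)
    for (i in seq_along(smiles)) {
      one <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(named[i])),
        error = function(e) NULL)
      if (!is.null(one) && length(one) == 1) {
        mols[[length(mols) + 1L]] <- one[[1]]
        index <- c(index, i)
      }
    }
    return(list(mols = mols, index = index))
  }
  list(mols = ChemmineR::SDFset2SDF(sdfset),
       index = as.integer(ChemmineR::cid(sdfset)))
}

# Radius-1 atom-environment signature for every heavy atom of a molecule.
# Aromatic bonds are coded "a" so the signature is independent of the
# Kekule form the SMILES writer happened to choose.
atom_signatures <- function(sdf_mol) {
  lig <- parse_ligand(sdf_mol, id = "sig")
  heavy <- is_heavy(lig$elements)
  arom_atoms <- aromatic_atoms(sdf_mol, lig)
  bonds <- lig$bonds
  arom_bond <- arom_atoms[bonds$a] & arom_atoms[bonds$b] & bonds$order %in% c(1L, 2L, 4L)
  ring_atom <- two_core(bonds, lig$n_atoms)
  deg <- tabulate(c(bonds$a[heavy[bonds$b]], bonds$b[heavy[bonds$a]]),
                  nbins = lig$n_atoms)
  std_val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
               I = 1, B = 3, Si = 4)
  bond_contrib <- ifelse(arom_bond, 1.5, ifelse(bonds$order == 4L, 1.5,
                                                bonds$order))
  val <- numeric(lig$n_atoms)
  for (k in seq_len(nrow(bonds))) {
    val[bonds$a[k]] <- val[bonds$a[k]] + bond_contrib[k]
    val[bonds$b[k]] <- val[bonds$b[k]] + bond_contrib[k]
  }
  vapply(which(heavy), function(i) {
    nb_tokens <- character(0)
    for (k in seq_len(nrow(bonds))) {
      j <- if (bonds$a[k] == i) bonds$b[k] else if (bonds$b[k] == i)
        bonds$a[k] else NA_integer_
      if (is.na(j) || !heavy[j]) next
      code <- if (arom_bond[k]) "a" else as.character(bonds$order[k])
      nb_tokens <- c(nb_tokens,
                     paste0(code, lig$elements[j],
                            if (arom_atoms[j]) "*" else ""))
    }
    sv <- std_val[lig$elements[i]]
    nh <- if (is.na(sv)) 0 else max(0, round(sv - val[i]))
    paste0(lig$elements[i], if (arom_atoms[i]) "*" else "",
           if (ring_atom[i]) "R" else "", "/d", deg[i], "h", nh, "|",
           paste(sort(nb_tokens), collapse = ","))
  }, character(1))
}

# Atoms that are part of some aromatic ring (size <= 7).
aromatic_atoms <- function(sdf_mol, lig) {
  arom <- logical(lig$n_atoms)
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf_mol, upper = 7, type = "all",
                                      arom = TRUE)),
    error = function(e) NULL)
  if (is.null(r) || !length(r$RINGS)) return(arom)
  for (k in seq_along(r$RINGS)) {
    if (isTRUE(r$AROMATIC[[k]])) {
      idx <- as.integer(sub(".*_", "", r$RINGS[[k]]))
      arom[idx] <- TRUE
    }
  }
  arom
}

# Ring membership: the 2-core of the molecular graph (iteratively strip
# degree-1 atoms; whatever survives lies on a cycle).
two_core <- function(bonds, n_atoms) {
  alive_bond <- rep(TRUE, nrow(bonds))
  repeat {
    deg <- tabulate(c(bonds$a[alive_bond], bonds$b[alive_bond]),
                    nbins = n_atoms)
    leaf <- which(deg == 1)
    if (!length(leaf)) break
    drop <- alive_bond & (bonds$a %in% leaf | bonds$b %in% leaf)
    if (!any(drop)) break
    alive_bond[drop] <- FALSE
  }
  deg <- tabulate(c(bonds$a[alive_bond], bonds$b[alive_bond]),
                  nbins = n_atoms)
  deg > 0
}

# Greedy small-ring set (approximate SSSR): candidate rings up to size 12,
# accepted smallest-first while contributing an uncovered bond, capped at
# the cyclomatic number.
sssr_rings <- function(sdf_mol, lig) {
  mu <- nrow(lig$bonds) - lig$n_atoms +
    length(unique_components(lig$bonds, lig$n_atoms))
  if (mu <= 0) return(list())
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf_mol, upper = 12, type = "all",
                                      arom = FALSE)),
    error = function(e) NULL)
  if (is.null(r) || !length(r)) return(list())
  ring_atoms <- lapply(r, function(v) as.integer(sub(".*_", "", v)))
  ring_atoms <- ring_atoms[order(lengths(ring_atoms))]
  chosen <- list(); covered <- character(0)
  for (ring in ring_atoms) {
    m <- length(ring)
    eb <- paste(pmin(ring, c(ring[-1], ring[1])),
                pmax(ring, c(ring[-1], ring[1])), sep = "-")
    if (any(!eb %in% covered)) {
      chosen[[length(chosen) + 1L]] <- ring
      covered <- union(covered, eb)
      if (length(chosen) >= mu) break
    }
  }
  chosen
}

unique_components <- function(bonds, n_atoms) {
  adj <- adjacency(bonds, n_atoms)
  seen <- logical(n_atoms); comps <- integer(0)
  for (s in seq_len(n_atoms)) {
    if (seen[s]) next
    comp <- component_of(adj, s)
    seen[comp] <- TRUE
    comps <- c(comps, s)
  }
  comps
}

.hybscreen_env <- new.env(parent = emptyenv())

#' The packaged SA fragment-contribution scorer
#'
#' Builds (once per session) the fragment-frequency contribution table from
#' the package's built-in reference corpus of common drug-like structures
#' (`inst/extdata/sa_corpus.smi`). Contributions are log10 frequencies
#' centred on the corpus's upper-quartile fragment, clipped to
#' \[-4, 0.5\]; fragments never seen in the corpus score -2. The corpus is
#' a package artifact: it stands in for the large purchasable-compound
#' collections the original fragment-score idea was trained on, and is
#' deliberately small, so absolute values are calibrated, not identical, to
#' other SA implementations.
#'
#' @return list with `table` (named contributions) and `unknown` (score for
#'   unseen fragments), usable as the `scorer` argument of [sa_score()].
#' @export
default_sa_scorer <- function() {
  if (!is.null(.hybscreen_env$sa_scorer)) return(.hybscreen_env$sa_scorer)
  path <- system.file("extdata", "sa_corpus.smi", package = "hybscreen",
                      mustWork = TRUE)
  lines <- readLines(path)
  smiles <- sub("\\s.*$", "", lines[nzchar(trimws(lines))])
  sdf <- smiles_to_sdfset(smiles)
  sigs <- unlist(lapply(sdf$mols, function(m) {
    tryCatch(atom_signatures(m), error = function(e) character(0))
  }))
  counts <- table(sigs)
  ref <- stats::quantile(as.numeric(counts), 0.75)
  contrib <- pmin(pmax(log10(as.numeric(counts) / ref), -4), 0.5)
  names(contrib) <- names(counts)
  scorer <- list(table = contrib, unknown = -2)
  .hybscreen_env$sa_scorer <- scorer
  scorer
}

#' Synthetic accessibility score
#'
#' Ertl-style estimate in \[1, 10\] (1 = easy to make): a fragment-frequency
#' term (mean contribution of every heavy atom's circular environment,
#' common environments scoring high) minus complexity penalties for
#' molecular size, stereocentres, macrocycles, spiro and bridged ring
#' systems, mapped onto the conventional 1-10 scale. The scorer is
#' pluggable: any list with `table`/`unknown` in the shape of
#' [default_sa_scorer()] can be supplied.
#'
#' @param smiles character vector of SMILES.
#' @param scorer fragment-contribution scorer (default: packaged corpus).
#' @return numeric vector in \[1, 10\]; `NA` where the molecule cannot be
#'   processed.
#' @export
sa_score <- function(smiles, scorer = default_sa_scorer()) {
  if (is.null(scorer$table)) stop("configuration error: missing SA ",
                                  "contribution table", call. = FALSE)
  sdf <- smiles_to_sdfset(smiles)
  res <- rep(NA_real_, length(smiles))
  for (k in seq_along(sdf$index)) {
    i <- sdf$index[k]
    m <- sdf$mols[[k]]
    raw <- tryCatch({
      lig <- parse_ligand(m, id = "sa")
      sigs <- atom_signatures(m)
      contrib <- scorer$table[sigs]
      contrib[is.na(contrib)] <- scorer$unknown
      frag <- mean(contrib)
      n_heavy <- sum(is_heavy(lig$elements))
      size_pen <- n_heavy^1.005 - n_heavy
      n_stereo <- length(gregexpr("@@|@", smiles[i])[[1]])
      if (identical(gregexpr("@@|@", smiles[i])[[1]][1], -1L)) n_stereo <- 0
      rings <- sssr_rings(m, lig)
      n_macro <- sum(lengths(rings) > 8)
      n_spiro <- 0L; n_bridge <- 0L
      if (length(rings) > 1) {
        for (p in seq_len(length(rings) - 1)) {
          for (q in seq((p + 1), length(rings))) {
            shared <- length(intersect(rings[[p]], rings[[q]]))
            if (shared == 1) n_spiro <- n_spiro + 1L
            if (shared >= 3) n_bridge <- n_bridge + 1L
          }
        }
      }
      frag - size_pen - log10(n_stereo + 1) - log10(n_macro + 1) -
        log10(n_spiro + 1) - log10(n_bridge + 1)
    }, error = function(e) NA_real_)
    if (is.na(raw)) next
    # map raw score onto the 1 (easy) .. 10 (hard) scale
    rmin <- -3.5; rmax <- 0.3
    sa <- 11 - (raw - rmin) / (rmax - rmin) * 9
    if (sa > 8) sa <- 8 + log(sa - 7)
    res[i] <- min(10, max(1, sa))
  }
  res
}

# ---- funnel ---------------------------------------------------------------

#' Run the screening funnel
#'
#' Applies the four filters in the fixed order activity -> applicability
#' domain -> QED -> SA. Flags are computed for every record; the funnel
#' report counts sequential survivors (a record excluded at one stage is
#' not reconsidered later) and each stage's exclusion percentage relative
#' to the records entering it. Survivors are ranked by probability
#' (descending), ties broken by id.
#'
#' @param records molecule table with `id` and `canonical` columns.
#' @param probabilities predicted activity probability per record.
#' @param training_fps 0/1 fingerprint matrix of the full training set
#'   (actives and inactives) — the applicability-domain reference.
#' @param thresholds a [triage_thresholds()].
#' @param fp_spec fingerprint parameterization for the AD comparison.
#' @param qed_values,sa_values optional precomputed per-record values
#'   (computed from the structures when omitted).
#' @return list with `records` (ScreeningRecord data.frame in the stable
#'   column order) and `report` (stage survivor counts and exclusion
#'   percentages).
#' @export
run_funnel <- function(records, probabilities, training_fps,
                       thresholds = triage_thresholds(),
                       fp_spec = fingerprint_spec(),
                       qed_values = NULL, sa_values = NULL) {
  stopifnot(is.data.frame(records), nrow(records) == length(probabilities))
  smiles <- records$canonical
  fps <- featurize(stats::setNames(smiles, records$id), fp_spec)
  ad <- max_similarity_to_set(fps, training_fps)
  if (is.null(qed_values)) qed_values <- qed(smiles)
  if (is.null(sa_values)) sa_values <- sa_score(smiles)
  pass_activity <- probabilities >= thresholds$prob_min
  pass_ad <- !is.na(ad$max_tanimoto) & ad$max_tanimoto >= thresholds$tanimoto_min
  pass_qed <- !is.na(qed_values) & qed_values >= thresholds$qed_min
  pass_sa <- !is.na(sa_values) & sa_values <= thresholds$sa_max
  df <- data.frame(
    id = records$id, smiles = smiles, probability = probabilities,
    max_tanimoto = ad$max_tanimoto, qed = qed_values, sa = sa_values,
    pass_activity = pass_activity, pass_ad = pass_ad, pass_qed = pass_qed,
    pass_sa = pass_sa,
    final_pass = pass_activity & pass_ad & pass_qed & pass_sa,
    stringsAsFactors = FALSE)
  ord <- order(-df$probability, df$id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  report <- funnel_report(df)
  list(records = df, report = report)
}

#' Stage accounting for a screening table
#'
#' @param df ScreeningRecord data.frame (as from [run_funnel()]).
#' @return list with the stage order, sequential survivor counts, per-stage
#'   exclusion counts and percentages (relative to the records entering the
#'   stage), and the final survivor count.
#' @export
funnel_report <- function(df) {
  s0 <- nrow(df)
  s1 <- sum(df$pass_activity)
  s2 <- sum(df$pass_activity & df$pass_ad)
  s3 <- sum(df$pass_activity & df$pass_ad & df$pass_qed)
  s4 <- sum(df$final_pass)
  surv <- c(input = s0, activity = s1, ad = s2, qed = s3, sa = s4)
  entering <- c(s0, s1, s2, s3)
  excluded <- entering - surv[-1]
  pct <- ifelse(entering > 0, 100 * excluded / entering, 0)
  list(stage_order = c("activity", "ad", "qed", "sa"),
       survivors = surv,
       excluded = stats::setNames(excluded, names(surv)[-1]),
       exclusion_pct = stats::setNames(pct, names(surv)[-1]),
       final = s4)
}
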