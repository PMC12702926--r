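# Early-recognition statistics for screen validation, docking-selectivity
# arithmetic and MM/GBSA energy aggregation.
#
# Ranking convention: docking scores are negative-better, so the default is
# `lower_is_better = TRUE`; internal ranks are always "best first". Ties are
# broken by a stable (score, id) sort for the exponentially weighted
# statistics (deterministic BEDROC/RIE) and by midranks inside the AUC.

#' Bundle scores and labels into a ranked screen
#'
#' @param scores numeric score per compound.
#' @param labels binary activity (1 = active).
#' @param lower_is_better direction flag (default TRUE, the docking
#'   convention in kcal/mol).
#' @param ids optional compound ids used for deterministic tie-breaks.
#' @return object of class `ranked_screen` with ranks (1 = best), `N`, `n`
#'   and the active fraction `Ra`.
#' @export
ranked_screen <- function(scores, labels, lower_is_better = TRUE,
                          ids = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("input error: labels must be binary", call. = FALSE)
  }
  n <- sum(labels)
  N <- length(labels)
  if (n < 1) stop("input error: no actives in screen", call. = FALSE)
  if (N <= n) stop("input error: no inactives in screen", call. = FALSE)
  if (is.null(ids)) ids <- seq_along(scores)
  key <- if (lower_is_better) scores else -scores
  ord <- order(key, ids)
  ranks <- integer(N)
  ranks[ord] <- seq_len(N)
  structure(list(scores = scores, labels = labels, ranks = ranks,
                 lower_is_better = lower_is_better,
                 N = N, n = n, Ra = n / N),
            class = "ranked_screen")
}

#' Robust initial enhancement (RIE)
#'
#' Exponentially weighted early-recognition score: the mean of
#' `exp(-alpha * r_i / N)` over active ranks, normalized by its value for a
#' uniformly random ranking, so RIE = 1 means no enrichment and larger
#' values mean actives concentrate early. `alpha` sets how early: the top
#' `1/alpha` fraction of the list carries most of the weight.
#'
#' @param screen a [ranked_screen()].
#' @param alpha exponential weighting parameter (> 0).
#' @return RIE value.
#' @export
rie <- function(screen, alpha) {
  stopifnot(inherits(screen, "ranked_screen"), alpha > 0)
  r <- screen$ranks[screen$labels == 1]
  N <- screen$N; n <- screen$n
  s <- sum(exp(-alpha * r / N)) / n
  denom <- (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  s / denom
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' The min-max rescaling of RIE onto \[0, 1\]: 0 for all actives ranked
#' last, 1 for all ranked first.
#'
#' @inheritParams rie
#' @return BEDROC value in \[0, 1\].
#' @export
bedroc <- function(screen, alpha) {
  stopifnot(inherits(screen, "ranked_screen"), alpha > 0)
  Ra <- screen$Ra
  r <- rie(screen, alpha)
  r * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Enrichment factor at a screening fraction
#'
#' Active rate in the top `ceiling(fraction * N)` compounds divided by the
#' overall active rate. EF = 1 is random; the maximum is
#' `min(1/fraction, N/n)`.
#'
#' @param screen a [ranked_screen()].
#' @param fraction screened fraction in (0, 1\].
#' @param top_k_rule how to round `fraction * N` to a compound count:
#'   `ceiling` (default), `floor` or `round`.
#' @return EF value.
#' @export
enrichment_factor <- function(screen, fraction,
                              top_k_rule = c("ceiling", "floor", "round")) {
  stopifnot(inherits(screen, "ranked_screen"),
            fraction > 0, fraction <= 1)
  top_k_rule <- match.arg(top_k_rule)
  k <- switch(top_k_rule,
              ceiling = ceiling(fraction * screen$N),
              floor = max(1, floor(fraction * screen$N)),
              round = max(1, round(fraction * screen$N)))
  hits <- sum(screen$labels[screen$ranks <= k])
  (hits / k) / (screen$n / screen$N)
}

#' ROC-AUC of a ranked screen
#'
#' Identical rank statistic (midrank ties) as [roc_auc()], applied with the
#' screen's direction flag.
#'
#' @param screen a [ranked_screen()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc_screen <- function(screen) {
  stopifnot(inherits(screen, "ranked_screen"))
  s <- if (screen$lower_is_better) -screen$scores else screen$scores
  roc_auc(s, screen$labels)
}

#' Domain-selectivity gaps from paired docking scores
#'
#' For each compound docked against both the allosteric (target) and the
#' catalytic (off-target) domain, the gap `score_offtarget - score_target`
#' (scores negative-better, so a positive gap means the compound prefers
#' the target domain). Rows with a missing score are flagged, not dropped.
#'
#' @param pairs data.frame with columns `id`, `score_target`,
#'   `score_offtarget` (kcal/mol XP-style scores).
#' @return data.frame sorted by decreasing gap with a `flagged` column for
#'   incomplete rows.
#' @export
selectivity_gap <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("id", "score_target", "score_offtarget") %in% names(pairs)))
  gap <- pairs$score_offtarget - pairs$score_target
  out <- data.frame(id = pairs$id, score_target = pairs$score_target,
                    score_offtarget = pairs$score_offtarget, gap = gap,
                    flagged = is.na(gap), stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$gap), -Inf, out$gap)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-frame MM/GBSA energy decompositions
#'
#' Per frame the binding energy is `dE = EC - (ER + EL)` — complex energy
#' minus the sum of isolated receptor and ligand energies (kcal/mol, more
#' negative = stronger binding). Returns the ensemble mean and sample
#' standard deviation (n - 1 denominator) over frames.
#'
#' @param frames data.frame with columns `EC`, `ER`, `EL` (one row per
#'   trajectory frame).
#' @return list with `mean_dE`, `sd_dE`, `n_frames` and the per-frame `dE`.
#' @export
mmgbsa_aggregate <- function(frames) {
  stopifnot(is.data.frame(frames),
            all(c("EC", "ER", "EL") %in% names(frames)))
  if (nrow(frames) == 0) stop("input error: no frames", call. = FALSE)
  dE <- frames$EC - (frames$ER + frames$EL)
  list(mean_dE = mean(dE),
       sd_dE = if (nrow(frames) >= 2) stats::sd(dE) else NA_real_,
       n_frames = nrow(frames), dE = dE)
}
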