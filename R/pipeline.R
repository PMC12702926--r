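# End-to-end pipeline: hybridize -> train (or load) -> predict -> triage ->
# report. One config object drives everything; every artifact directory is
# stamped with the effective config and its hash plus the seed, and
# re-running with the same config reproduces identical outputs.

#' Pipeline configuration
#'
#' Collects paths and stage parameterizations. Unknown fields are rejected
#' (a typo in a config must not silently fall back to a default).
#'
#' @param aligned_sdf SDF of pre-aligned 3D ligands to hybridize.
#' @param training_csv labelled SMILES table (id, smiles, label).
#' @param seed master seed; drives the split and model training.
#' @param hybridization a [hybridization_params()].
#' @param fingerprint a [fingerprint_spec()].
#' @param model a [model_spec()] (its seed is overridden by `seed`).
#' @param thresholds a [triage_thresholds()].
#' @param enrichment list with `alpha` and `ef_fractions` for the
#'   enrichment report on the held-out test set.
#' @param test_fraction held-out fraction of the training table.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(aligned_sdf, training_csv, seed = 42L,
                            hybridization = hybridization_params(),
                            fingerprint = fingerprint_spec(),
                            model = model_spec(),
                            thresholds = triage_thresholds(),
                            enrichment = list(alpha = 160.9,
                                              ef_fractions = c(0.02, 0.05)),
                            test_fraction = 0.2) {
  stopifnot(is.character(aligned_sdf), is.character(training_csv))
  if (!all(c("alpha", "ef_fractions") %in% names(enrichment)) ||
      length(setdiff(names(enrichment), c("alpha", "ef_fractions")))) {
    stop("config error: enrichment must have exactly alpha and ef_fractions",
         call. = FALSE)
  }
  model$seed <- as.integer(seed)
  structure(list(aligned_sdf = aligned_sdf, training_csv = training_csv,
                 seed = as.integer(seed), hybridization = hybridization,
                 fingerprint = fingerprint, model = model,
                 thresholds = thresholds, enrichment = enrichment,
                 test_fraction = test_fraction),
            class = "pipeline_config")
}

config_json <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

#' Run the full screening pipeline
#'
#' Stages, in order: hybridize the aligned ligands; train the classifier on
#' the labelled table (stratified split); predict activity for every
#' hybrid; run the triage funnel; write the enrichment report for the
#' held-out test set. Every artifact lands in `out_dir`:
#' `hybrids.sdf`, `generation_report.json`, `model/`, `test_metrics.json`,
#' `screening.csv`, `funnel.json`, `enrich.json`, `config.json` and
#' `pipeline.log`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list with the in-memory results of each stage, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    cat(line, "\n", file = logfile, append = TRUE)
    message(line)
  }
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(config_json(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  logmsg("config hash ", cfg_hash, " seed ", config$seed)

  logmsg("stage hybridize: reading ", config$aligned_sdf)
  aligned <- read_sdf(config$aligned_sdf)
  lib <- generate_library(aligned$sdfset, config$hybridization)
  write_sdf(lib$molblocks, file.path(out_dir, "hybrids.sdf"))
  jsonlite::write_json(c(lib$report, list(config_hash = cfg_hash,
                                          seed = config$seed)),
                       file.path(out_dir, "generation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("stage hybridize: ", nrow(lib$hybrids), " novel hybrids from ",
         length(aligned$sdfset), " ligands")
  if (nrow(lib$hybrids) == 0) {
    stop("stage hybridize produced no hybrids", call. = FALSE)
  }

  logmsg("stage train: reading ", config$training_csv)
  train_tab <- deduplicate(read_smiles_table(config$training_csv))
  fps <- featurize(stats::setNames(train_tab$canonical, train_tab$id),
                   config$fingerprint)
  split <- split_stratified(train_tab$label, config$test_fraction,
                            config$seed)
  clf <- train_mlp(fps[split$train, , drop = FALSE],
                   train_tab$label[split$train], config$model)
  save_classifier(clf, file.path(out_dir, "model"))
  p_test <- predict_proba(clf, fps[split$test, , drop = FALSE])
  panel <- evaluate(p_test, train_tab$label[split$test],
                    config$thresholds$prob_min)
  jsonlite::write_json(
    list(accuracy = panel$accuracy, roc_auc = panel$roc_auc,
         confusion = as.list(panel$confusion),
         per_class = panel$per_class, config_hash = cfg_hash,
         seed = config$seed),
    file.path(out_dir, "test_metrics.json"), auto_unbox = TRUE, digits = NA)
  logmsg("stage train: n=", clf$n_train, " test accuracy ",
         round3(panel$accuracy), " AUC ", round3(panel$roc_auc))

  logmsg("stage predict: scoring ", nrow(lib$hybrids), " hybrids")
  hyb_fps <- featurize(stats::setNames(lib$hybrids$smiles, lib$hybrids$id),
                       config$fingerprint)
  probs <- predict_proba(clf, hyb_fps)

  logmsg("stage triage: funnel")
  records <- data.frame(id = lib$hybrids$id, canonical = lib$hybrids$smiles,
                        stringsAsFactors = FALSE)
  funnel <- run_funnel(records, probs, clf$training_fingerprints,
                       config$thresholds, config$fingerprint)
  write_table(funnel$records, file.path(out_dir, "screening.csv"))
  jsonlite::write_json(c(funnel$report, list(config_hash = cfg_hash,
                                             seed = config$seed)),
                       file.path(out_dir, "funnel.json"), auto_unbox = TRUE,
                       digits = NA)
  logmsg("stage triage: ", funnel$report$final, " of ",
         nrow(funnel$records), " pass")

  logmsg("stage enrich: held-out test set")
  scr <- ranked_screen(p_test, train_tab$label[split$test],
                       lower_is_better = FALSE,
                       ids = train_tab$id[split$test])
  enr <- list(
    roc_auc = roc_auc_screen(scr),
    bedroc = bedroc(scr, config$enrichment$alpha),
    rie = rie(scr, config$enrichment$alpha),
    alpha = config$enrichment$alpha,
    ef = as.list(stats::setNames(
      vapply(config$enrichment$ef_fractions,
             function(f) enrichment_factor(scr, f), numeric(1)),
      paste0("ef_", config$enrichment$ef_fractions))),
    config_hash = cfg_hash, seed = config$seed)
  jsonlite::write_json(enr, file.path(out_dir, "enrich.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("pipeline complete")
  invisible(list(library = lib, classifier = clf, test_metrics = panel,
                 probabilities = probs, funnel = funnel, enrichment = enr,
                 config_hash = cfg_hash))
}
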