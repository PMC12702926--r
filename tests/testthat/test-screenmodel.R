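# ECFP4 featurization, the MLP classifier and the metric panel.

test_that("featurization is deterministic and order-preserving", {
  smis <- c(a = "CCO", b = "c1ccccc1", c = "CCO", d = "CC(=O)Nc1ccc(O)cc1")
  fp <- featurize(smis)
  expect_equal(dim(fp), c(4, 2048))
  expect_identical(fp["a", ], fp["c", ])       # same SMILES, same bits
  expect_identical(fp, featurize(smis))        # deterministic
  expect_true(all(rowSums(fp) >= 1))
  expect_false(identical(fp["a", ], fp["b", ]))
  expect_equal(tanimoto(fp["a", ], fp["a", ]), 1.0)
})

test_that("unparseable molecules are skipped with their indices reported", {
  fp <- featurize(c("CCO", "xyz((", "CCN"))
  expect_equal(attr(fp, "skipped"), 2L)
  expect_equal(sum(fp[2, ]), 0)
  expect_gt(sum(fp[1, ]), 0)
})

test_that("fingerprint spec validates its invariants", {
  expect_error(fingerprint_spec(100), "power of two")
  expect_error(fingerprint_spec(1000), "power of two")
  expect_equal(fingerprint_spec(512)$n_bits, 512L)
  fp <- featurize(c(m = "c1ccncc1CCO"), fingerprint_spec(512))
  expect_equal(ncol(fp), 512)
})

test_that("stratified split keeps class balance, disjointness and seed", {
  labels <- c(rep(1, 614), rep(0, 614))
  sp <- split_stratified(labels, 0.2, seed = 42)
  expect_equal(length(sp$test), 246)
  expect_equal(sum(labels[sp$test] == 1), 123, tolerance = 1)
  expect_equal(sum(labels[sp$test] == 0), 123, tolerance = 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, split_stratified(labels, 0.2, seed = 42))
  expect_false(identical(sp$test,
                         split_stratified(labels, 0.2, seed = 43)$test))
  expect_error(split_stratified(rep(1, 10)), "both classes")
})

test_that("training learns a separable fixture and is seed-reproducible", {
  ds <- make_activity_dataset(seed = 8, n_active = 120, n_inactive = 120)
  fp <- featurize(stats::setNames(ds$smiles, ds$id))
  sp <- split_stratified(ds$label, 0.2, seed = 8)
  clf <- train_mlp(fp[sp$train, ], ds$label[sp$train], model_spec(seed = 8))
  # loss decreases on the fixtures; training set is fit essentially exactly
  expect_lt(tail(clf$loss_trace, 1), clf$loss_trace[1])
  p_train <- predict_proba(clf, fp[sp$train, ])
  expect_gt(mean(p_train[ds$label[sp$train] == 1] > 0.9), 0.95)
  expect_equal(mean((p_train >= 0.5) == ds$label[sp$train]), 1.0)
  expect_true(all(p_train >= 0 & p_train <= 1))
  # identical seed, identical model and predictions
  clf2 <- train_mlp(fp[sp$train, ], ds$label[sp$train], model_spec(seed = 8))
  expect_identical(clf$layers, clf2$layers)
  expect_identical(predict_proba(clf, fp[sp$test, ]),
                   predict_proba(clf2, fp[sp$test, ]))
  expect_error(train_mlp(fp[1:10, ], rep(1, 10)), "degenerate")
})

test_that("shuffled labels give chance-level held-out AUC", {
  ds <- make_activity_dataset(seed = 9, n_active = 120, n_inactive = 120)
  fp <- featurize(stats::setNames(ds$smiles, ds$id))
  sp <- split_stratified(ds$label, 0.2, seed = 9)
  set.seed(901)
  y_shuf <- sample(ds$label[sp$train])
  clf <- train_mlp(fp[sp$train, ], y_shuf, model_spec(seed = 9))
  auc <- evaluate(predict_proba(clf, fp[sp$test, ]),
                  ds$label[sp$test])$roc_auc
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})

test_that("serialization round-trips to identical predictions", {
  ds <- make_activity_dataset(seed = 10, n_active = 40, n_inactive = 40)
  fp <- featurize(stats::setNames(ds$smiles, ds$id))
  clf <- train_mlp(fp, ds$label, model_spec(seed = 10, epochs = 5))
  dir <- tempfile()
  save_classifier(clf, dir)
  clf2 <- load_classifier(dir)
  expect_identical(predict_proba(clf, fp), predict_proba(clf2, fp))
  expect_identical(clf2$training_fingerprints, clf$training_fingerprints)
  expect_equal(clf2$spec$hidden, clf$spec$hidden)
})

test_that("metric panel reproduces exact confusion arithmetic", {
  panel <- metrics_from_confusion(tp = 88, fp = 0, tn = 154, fn = 8)
  expect_equal(round3(panel$accuracy), 0.968)
  pc <- panel$per_class
  expect_equal(round3(pc$recall[pc$class == 1]), 0.917)
  expect_equal(round3(pc$precision[pc$class == 1]), 1.0)
  expect_equal(round3(pc$precision[pc$class == 0]), 0.951)
  expect_equal(round3(unname(panel$macro["recall"])), 0.958)
  # F1 from precision 1.0 and recall 11/12 is 22/23, not anything larger
  expect_equal(pc$f1[pc$class == 1], 2 * (1 * 88 / 96) / (1 + 88 / 96))
  expect_equal(round3(pc$f1[pc$class == 1]), 0.957)
  expect_equal(panel$support, 250)
})

test_that("degenerate confusion inputs are handled explicitly", {
  p <- metrics_from_confusion(0, 0, 50, 0)
  expect_equal(p$accuracy, 1.0)
  expect_true("recall1" %in% p$undefined)
  expect_true(is.nan(p$per_class$recall[p$per_class$class == 1]))
  expect_error(metrics_from_confusion(0, 0, 0, 0), "empty")
  expect_error(metrics_from_confusion(-1, 0, 1, 0), "non-negative")
})

test_that("evaluate agrees with metrics_from_confusion on hard calls", {
  set.seed(31)
  prob <- runif(200)
  labels <- rbinom(200, 1, plogis(6 * (prob - 0.5)))
  ev <- evaluate(prob, labels, threshold = 0.5)
  pred <- as.integer(prob >= 0.5)
  direct <- metrics_from_confusion(sum(pred & labels),
                                   sum(pred & !labels),
                                   sum(!pred & !labels),
                                   sum(!pred & labels))
  expect_equal(ev$accuracy, direct$accuracy)
  expect_equal(ev$per_class, direct$per_class)
  # perfect predictions: everything 1
  evp <- evaluate(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(evp$accuracy, 1)
  expect_equal(evp$roc_auc, 1)
  # single-class labels: threshold metrics remain, AUC undefined
  ev1 <- evaluate(c(0.9, 0.8), c(1, 1))
  expect_true(is.na(ev1$roc_auc))
  expect_equal(ev1$accuracy, 1)
})

test_that("rank AUC equals the pairwise-comparison oracle, with ties", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("probability histogram reports confident and ambiguous fractions", {
  h <- probability_histogram(c(0.95, 0.95, 0.5, 0.1))
  expect_equal(sum(h$counts), 4)
  expect_equal(h$fraction_high_confidence, 0.5)
  expect_equal(h$fraction_ambiguous, 0.25)
  h2 <- probability_histogram(rep(0.55, 10))
  expect_equal(max(h2$counts), 10)
  expect_equal(h2$fraction_ambiguous, 1)
  expect_error(probability_histogram(c(0.5, 1.2)), "outside")
})
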