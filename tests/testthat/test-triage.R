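# Applicability domain, drug-likeness, synthetic accessibility and the
# screening funnel.

test_that("tanimoto matches the bit-loop oracle and its edge cases", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1.0)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0.0)
  expect_equal(tanimoto(integer(8), integer(8)), 1.0)  # both empty
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
  set.seed(5)
  for (k in 1:200) {
    a <- rbinom(64, 1, 0.2); b <- rbinom(64, 1, 0.2)
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
  # matrix form agrees with scalar form
  A <- matrix(rbinom(10 * 64, 1, 0.3), 10)
  B <- matrix(rbinom(7 * 64, 1, 0.3), 7)
  tm <- tanimoto_matrix(A, B)
  for (i in 1:10) for (j in 1:7) {
    expect_equal(tm[i, j], tanimoto(A[i, ], B[j, ]))
  }
})

test_that("max similarity to a set is the exact linear-scan maximum", {
  set.seed(6)
  refs <- matrix(rbinom(100 * 256, 1, 0.1), 100)
  rownames(refs) <- paste0("r", 1:100)
  q <- refs[37, , drop = FALSE]
  res <- max_similarity_to_set(q, refs)
  expect_equal(res$max_tanimoto, 1.0)
  q2 <- matrix(rbinom(256, 1, 0.1), 1)
  res2 <- max_similarity_to_set(q2, refs)
  brute <- max(vapply(1:100, function(i) oracle_tanimoto(q2[1, ], refs[i, ]),
                      numeric(1)))
  expect_equal(res2$max_tanimoto, brute)
  res3 <- max_similarity_to_set(q2, refs[5, , drop = FALSE])
  expect_equal(res3$max_tanimoto, oracle_tanimoto(q2[1, ], refs[5, ]))
  expect_equal(res3$nearest, "r5")
  expect_error(max_similarity_to_set(q2, refs[0, , drop = FALSE]), "empty")
})

test_that("the QED desirability arithmetic reproduces the reference values", {
  # property values computed with RDKit 2024.09 for aspirin; the weighted
  # geometric mean of the published desirability functions must match the
  # reference implementation's score to full precision
  props <- data.frame(MW = 180.159, ALOGP = 1.3101, HBA = 4, HBD = 1,
                      PSA = 63.6, ROTB = 2, AROM = 1, ALERTS = 2)
  expect_equal(qed_score(props), 0.5501217966938848, tolerance = 1e-9)
  # ibuprofen, same source
  props2 <- data.frame(MW = 206.285, ALOGP = 3.0732, HBA = 2, HBD = 1,
                       PSA = 37.3, ROTB = 4, AROM = 1, ALERTS = 0)
  expect_equal(qed_score(props2), 0.8215995487, tolerance = 1e-6)
})

test_that("full QED pipeline lands near the reference implementation", {
  # descriptor engines differ slightly (rotatable-bond and alert
  # definitions), so the full pipeline is checked against RDKit values
  # within a coarser band than the shared arithmetic
  v <- qed(c("CC(C)Cc1ccc(cc1)C(C)C(=O)O",                      # 0.822
             "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                      # 0.538
             "CC(C)CCCC(C)C1CCC2C3CCC4CC(O)CCC4(C)C3CCC12C"))   # 0.518
  expect_equal(v[1], 0.822, tolerance = 0.05)
  expect_equal(v[2], 0.538, tolerance = 0.05)
  expect_equal(v[3], 0.518, tolerance = 0.05)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("QED penalizes structural alerts and extreme size", {
  # the ALERTS desirability is monotone: all else equal, more alerts never
  # raise the score
  base <- data.frame(MW = 250, ALOGP = 2.5, HBA = 3, HBD = 1, PSA = 60,
                     ROTB = 3, AROM = 1, ALERTS = 0:4)
  q_alert <- qed_score(base)
  expect_true(all(diff(q_alert) < 0))
  # and the alert matcher does see a planted nitro group
  clean <- "Cc1ccc(NC(=O)C2CC2)cc1"
  with_nitro <- "Cc1ccc(NC(=O)C2CC2)cc1N(=O)=O"
  counts <- qed_properties(c(clean, with_nitro))$ALERTS
  expect_equal(counts[2], counts[1] + 1)
  # a near-5-kDa peptide-like chain collapses the size desirability
  big <- paste0("NC(C)C(=O)", paste(rep("NC(C)C(=O)", 40), collapse = ""),
                "O")
  expect_lt(qed(big), 0.3)
})

test_that("qed handles unparseable molecules as flagged NA", {
  v <- qed(c("CCO", "zzz(("))
  expect_false(is.na(v[1]))
  expect_true(is.na(v[2]))
})

test_that("SA score is bounded, easy for simple and high for complex", {
  v <- sa_score(c("CCO", "c1ccccc1", "CCN"))
  expect_true(all(v >= 1 & v <= 10))
  expect_lt(v[1], 2)
  # a stereocentre-dense fused bicyclic scores clearly harder
  complexed <- sa_score("C[C@H]1C[C@@H](O)[C@H](Nc2ccc(C)cc2)[C@@H](C)O1")
  expect_gt(complexed, 4)
  expect_gt(complexed, max(v))
  # degenerate scorer config
  expect_error(sa_score("CCO", scorer = list(unknown = -2)),
               "configuration error")
})

test_that("SA scorer interface is pluggable", {
  # an everything-is-common table must score easier than an
  # everything-is-rare table for the same molecule
  easy <- list(table = c(dummy = 0), unknown = 0.5)
  hard <- list(table = c(dummy = 0), unknown = -4)
  s_easy <- sa_score("CCOC(=O)c1ccccc1", scorer = easy)
  s_hard <- sa_score("CCOC(=O)c1ccccc1", scorer = hard)
  expect_lt(s_easy, s_hard)
})

test_that("triage thresholds validate their ranges", {
  expect_error(triage_thresholds(prob_min = 1.2))
  expect_error(triage_thresholds(tanimoto_min = -0.1))
  expect_error(triage_thresholds(sa_max = 11))
  th <- triage_thresholds()
  expect_equal(th$prob_min, 0.5)
  expect_equal(th$tanimoto_min, 0.4)
  expect_equal(th$qed_min, 0.7)
  expect_equal(th$sa_max, 3.0)
})

test_that("the funnel reproduces planted stage survival exactly", {
  fl <- make_funnel_library(seed = 7, counts = c(200L, 160L, 120L, 60L, 30L))
  res <- run_funnel(fl$table, fl$probabilities, fl$training_fps)
  expect_equal(unname(res$report$survivors), unname(as.integer(fl$expected)))
  expect_equal(unname(res$report$exclusion_pct),
               100 * c(40 / 200, 40 / 160, 60 / 120, 30 / 60))
  expect_equal(res$report$final, 30L)
  # flags consistent with thresholds and with final_pass
  th <- triage_thresholds()
  r <- res$records
  expect_equal(r$final_pass,
               r$pass_activity & r$pass_ad & r$pass_qed & r$pass_sa)
  expect_equal(r$pass_activity, r$probability >= th$prob_min)
  expect_equal(r$pass_ad, r$max_tanimoto >= th$tanimoto_min)
  # ranked by probability descending, ties by id
  expect_true(all(diff(r$probability) <= 0))
})

test_that("funnel counts are conserved and order-independent", {
  fl <- make_funnel_library(seed = 13, counts = c(60L, 50L, 35L, 20L, 10L))
  res <- run_funnel(fl$table, fl$probabilities, fl$training_fps)
  surv <- res$report$survivors
  expect_true(all(diff(surv) <= 0))
  expect_equal(sum(res$report$excluded) + res$report$final, nrow(fl$table))
  # permuting the input permutes the output identically
  set.seed(3)
  perm <- sample(nrow(fl$table))
  res2 <- run_funnel(fl$table[perm, ], fl$probabilities[perm],
                     fl$training_fps)
  expect_equal(res2$report$survivors, res$report$survivors)
  r1 <- res$records[order(res$records$id), ]
  r2 <- res2$records[order(res2$records$id), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("loosest thresholds pass everything", {
  fl <- make_funnel_library(seed = 5, counts = c(40L, 30L, 20L, 10L, 5L))
  res <- run_funnel(fl$table, fl$probabilities, fl$training_fps,
                    triage_thresholds(prob_min = 0, tanimoto_min = 0,
                                      qed_min = 0, sa_max = 10))
  expect_equal(res$report$final, 40L)
  expect_true(all(res$records$final_pass))
})

test_that("funnel exclusion percentages follow the stage arithmetic", {
  # the published-style accounting: percentages are relative to the
  # records entering each stage
  df <- data.frame(
    id = sprintf("c%d", 1:10), smiles = "x", probability = 1,
    max_tanimoto = 1, qed = 1, sa = 1,
    pass_activity = rep(c(TRUE, FALSE), c(8, 2)),
    pass_ad = rep(c(TRUE, FALSE), c(6, 4)),
    pass_qed = rep(c(TRUE, FALSE), c(5, 5)),
    pass_sa = rep(c(TRUE, FALSE), c(4, 6)))
  df$final_pass <- df$pass_activity & df$pass_ad & df$pass_qed & df$pass_sa
  rep_ <- funnel_report(df)
  expect_equal(unname(rep_$survivors), c(10, 8, 6, 5, 4))
  expect_equal(unname(rep_$exclusion_pct),
               100 * c(2 / 10, 2 / 8, 1 / 6, 1 / 5))
})
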