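test_that("stratified folds deal classes proportionally and reproducibly", {
  labels <- rep(0:2, c(50, 30, 20))
  folds <- stratified_folds(labels, 5, seed = 9)
  for (f in folds) {
    expect_equal(as.integer(table(factor(labels[f], levels = 0:2))),
                 c(10L, 6L, 4L))
  }
  expect_equal(sort(unlist(folds)), seq_along(labels))  # partition
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
  expect_identical(stratified_folds(labels, 5, seed = 9), folds)
  expect_false(identical(stratified_folds(labels, 5, seed = 10), folds))
  expect_error(stratified_folds(c(rep(0, 10), rep(1, 3)), 5), "fewer than")
})

test_that("the all-majority predictor reproduces the degenerate baseline row", {
  # 69 validation cases, 49 in the dominant class; constant predictor and
  # constant scores
  true <- rep(c(0L, 1L, 2L), c(49L, 12L, 8L))
  pred <- rep(0L, 69L)
  scores <- matrix(1 / 3, 69, 3)
  rep_ <- evaluate_predictions(true, pred, scores)
  expect_equal(rep_$accuracy, 71.01, tolerance = 0.005)
  expect_equal(rep_$precision, 23.67, tolerance = 0.005)
  expect_equal(rep_$recall, 33.33, tolerance = 0.005)
  expect_equal(rep_$f1, 27.68, tolerance = 0.005)
  expect_equal(rep_$auc, 0.5, tolerance = 1e-12)
})

test_that("perfect predictions score 100 percent everywhere with AUC 1", {
  true <- rep(0:2, each = 5)
  scores <- matrix(0.01, 15, 3)
  scores[cbind(1:15, true + 1)] <- 0.98
  rep_ <- evaluate_predictions(true, true, scores)
  expect_equal(rep_$accuracy, 100)
  expect_equal(rep_$precision, 100)
  expect_equal(rep_$recall, 100)
  expect_equal(rep_$f1, 100)
  expect_equal(rep_$auc, 1)
})

test_that("accuracy equals the confusion-matrix trace over the total", {
  set.seed(5)
  true <- sample(0:2, 60, replace = TRUE)
  pred <- sample(0:2, 60, replace = TRUE)
  rep_ <- evaluate_predictions(true, pred)
  expect_equal(rep_$accuracy,
               100 * sum(diag(rep_$confusion)) / sum(rep_$confusion))
  expect_equal(sum(rep_$confusion), 60)
  expect_error(evaluate_predictions(c(0, 5), c(0, 1), n_classes = 3),
               "label")
})

test_that("one-vs-rest AUC handles ties and separable scores correctly", {
  true <- c(0, 0, 1, 1)
  # constant scores: 0.5 per class by the midrank convention
  expect_equal(evaluate_predictions(true, c(0, 0, 1, 1),
                                    matrix(1 / 3, 4, 3),
                                    n_classes = 3)$auc, 0.5)
  # perfectly ranked binary scores inside a 3-class frame
  sc <- cbind(c(0.8, 0.7, 0.2, 0.1), c(0.1, 0.2, 0.7, 0.8), 0.1)
  sc <- sc / rowSums(sc)
  r <- evaluate_predictions(true, c(0, 0, 1, 1), sc, n_classes = 3)
  expect_equal(r$per_class$auc[1:2], c(1, 1))
})

test_that("paired t-test matches the closed form and the stats oracle", {
  # symmetric differences: t = 0, p = 1
  r0 <- paired_ttest(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  # differences (1, 2, 3): t = 2 * sqrt(3), p ~ 0.0742
  a <- c(3, 5, 7); b <- c(2, 3, 4)
  r <- paired_ttest(a, b)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$p_value, 0.0742, tolerance = 5e-4)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(paired_ttest(1, 2), "at least 2")
})

test_that("class-count merging reproduces printed cohort proportions", {
  luna <- c(AAH = 63, AIS = 299, MIA = 389, IA = 863)
  merged <- merge_class_counts(luna, list(AIS = c("AAH", "AIS")))
  expect_equal(merged$count, c(362, 389, 863))
  expect_equal(sum(merged$count), 1614)
  expect_equal(100 * merged$prop, c(22.4, 24.1, 53.5), tolerance = 0.05)
  expect_error(merge_class_counts(luna, list(x = "nope")), "unknown")
})

test_that("parameter counts are exact, itemized and respond to sharing", {
  cfg <- tiny_config(ehr_len = 4L)
  m <- cmmf_model(cfg, seed = 1)
  cp <- count_parameters(m)
  expect_equal(unname(cp$total), unname(sum(cp$by_group)))
  # the bounding-box embedding is a 6 -> D linear map
  expect_equal(length(m$params$cte_small$bbox$W) +
                 length(m$params$cte_small$bbox$b), 6 * 16 + 16)
  # with equal crop shapes, two independent CT encoders hold exactly twice
  # the parameters of one
  cfg_eq <- tiny_config(ehr_len = 4L, crop_large = c(16L, 16L, 16L))
  m_eq <- cmmf_model(cfg_eq, seed = 1)
  cp_eq <- count_parameters(m_eq)
  expect_equal(cp_eq$by_group[["cte_large"]], cp_eq$by_group[["cte_small"]])
  # sharing keeps only the positional table of the second scale
  cfg_sh <- tiny_config(ehr_len = 4L, crop_large = c(16L, 16L, 16L),
                        share_cte = TRUE)
  m_sh <- cmmf_model(cfg_sh, seed = 1)
  cp_sh <- count_parameters(m_sh)
  expect_equal(cp_sh$by_group[["cte_large"]],
               length(m_sh$params$cte_large$pos))
  expect_equal(cp_eq$total - cp_sh$total,
               cp_eq$by_group[["cte_large"]] -
                 length(m_sh$params$cte_large$pos))
  # a frozen temperature is not learnable
  cfg_fr <- tiny_config(ehr_len = 4L, freeze_temperature = TRUE)
  expect_false("clip" %in% names(count_parameters(cmmf_model(cfg_fr, 1))$by_group))
})
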