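test_that("the printed study confusion matrix yields its printed metrics", {
  cm <- studyConfusion()
  met <- confusionMetrics(cm)
  expect_equal(roundHalfUp(met$sensitivity), c(0.83, 0.84, 0.86))
  expect_equal(roundHalfUp(met$specificity), c(0.93, 0.96, 0.88))
  expect_equal(roundHalfUp(met$class_error), c(0.12, 0.10, 0.13))
  expect_equal(met$class_error, 1 - (met$sensitivity + met$specificity) / 2)
  expect_identical(sum(cm), 1878L)
})

test_that("metric formulas check out on hand-enumerated toys", {
  ident <- diag(c(10L, 10L, 10L))
  dimnames(ident) <- list(predicted = c("HC", "RD", "SjD"),
                          actual = c("HC", "RD", "SjD"))
  met <- confusionMetrics(ident)
  expect_equal(met$sensitivity, rep(1, 3))
  expect_equal(met$specificity, rep(1, 3))
  expect_equal(met$class_error, rep(0, 3))

  ## 2x2: TP=3 FN=1 FP=2 TN=4 for the SjD column
  cm2 <- matrix(c(4L, 2L, 1L, 3L), 2, 2,
                dimnames = list(predicted = c("HC", "SjD"),
                                actual = c("HC", "SjD")))
  met2 <- confusionMetrics(cm2)
  i <- met2$class == "SjD"
  expect_equal(met2$sensitivity[i], 0.75)
  expect_equal(met2$specificity[i], 2 / 3)
  expect_equal(met2$class_error[i], 1 - (0.75 + 2 / 3) / 2)

  empty_col <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
                      dimnames = list(predicted = c("HC", "SjD"),
                                      actual = c("HC", "SjD")))
  expect_true(is.na(confusionMetrics(empty_col)$sensitivity[2]))
})

test_that("cross-validation pools a conserving confusion matrix", {
  ds <- separableSet(n_per_class = 8, noise = 0.05)
  cvr <- crossValidate(ds, NULL,
                       classifierConfig(compress_ncomp = 2, svm_cost = 10,
                                        rbf_gamma = 1),
                       cvScheme(n_splits = 6, seed = 2))
  expect_identical(sum(cvr$confusion), nrow(cvr$predictions))
  expect_identical(sum(cvr$confusion), ncol(ds))
  ## separable data: near-diagonal
  expect_gte(sum(diag(cvr$confusion)) / sum(cvr$confusion), 0.9)
  ## donor-grouped splitting also conserves
  cvd <- crossValidate(ds, NULL,
                       classifierConfig(compress_ncomp = 2, svm_cost = 10,
                                        rbf_gamma = 1),
                       cvScheme(n_splits = 4, split_unit = "donor",
                                seed = 2))
  expect_identical(sum(cvd$confusion), ncol(ds))
})

test_that("n-fold CV with one spectrum per fold equals a direct LOO oracle", {
  ds <- separableSet(n_per_class = 10, noise = 0.3, seed = 7)
  cfg <- classifierConfig(compress_ncomp = 2, svm_cost = 10, rbf_gamma = 1)
  cvr <- crossValidate(ds, NULL, cfg, cvScheme(n_splits = 30, seed = 5))
  loo <- character(ncol(ds))
  for (i in seq_len(ncol(ds))) {
    clf <- trainClassifier(ds[, -i], NULL, cfg)
    loo[i] <- predictClasses(clf, ds[, i])$predicted
  }
  key <- paste(donorIds(ds), spotIndices(ds))
  got <- cvr$predictions$predicted[
    match(key, paste(cvr$predictions$donor_id,
                     cvr$predictions$spot_index))]
  expect_identical(got, loo)
})

test_that("donor votes follow the threshold-and-tie rules", {
  pred <- data.frame(
    donor_id = c(rep("a", 36), rep("b", 4), rep("c", 36)),
    predicted = c(rep("SjD", 20), rep("HC", 10), rep("RD", 6),
                  "HC", "HC", "RD", "RD",
                  rep("HC", 36)),
    actual = c(rep("SjD", 36), rep("HC", 4), rep("HC", 36)))
  v <- voteDonors(pred, threshold = 0.5)
  votes <- v$votes
  expect_equal(votes$call[votes$donor_id == "a"], "SjD")   # 20/36 >= 0.5
  expect_equal(votes$call[votes$donor_id == "b"], "INDETERMINATE")
  expect_equal(votes$frac_HC[votes$donor_id == "c"], 1.0)
  expect_equal(votes$call[votes$donor_id == "c"], "HC")
  fr <- as.matrix(votes[, grep("^frac_", names(votes))])
  expect_equal(unname(rowSums(fr)), rep(1, 3))
  expect_equal(v$accuracy, 2 / 3)
})

test_that("lowering the vote threshold never un-calls a donor", {
  set.seed(12)
  for (rep_i in 1:5) {
    pred <- data.frame(
      donor_id = rep(sprintf("d%02d", 1:8), each = 12),
      predicted = sample(c("HC", "RD", "SjD"), 96, TRUE),
      actual = rep("HC", 96))
    v_hi <- voteDonors(pred, threshold = 0.6)$votes
    v_lo <- voteDonors(pred, threshold = 0.4)$votes
    called_hi <- v_hi$donor_id[v_hi$call != "INDETERMINATE"]
    called_lo <- v_lo$donor_id[v_lo$call != "INDETERMINATE"]
    expect_true(all(called_hi %in% called_lo))
  }
})

test_that("external validation guards contamination and handles UNKNOWN", {
  ds <- separableSet(n_per_class = 6)
  clf <- trainClassifier(ds, NULL,
                         classifierConfig(compress_ncomp = 2, svm_cost = 10,
                                          rbf_gamma = 1))
  expect_error(externalValidate(clf, ds), "overlap")

  ext0 <- separableSet(n_per_class = 2, seed = 99)
  ext <- RamanSet(t(spectraMatrix(ext0)), wavenumbers(ext0),
                  donor_id = paste0("X", donorIds(ext0)),
                  class_label = classLabels(ext0),
                  spot_index = spotIndices(ext0))
  res <- externalValidate(clf, ext)
  expect_equal(res$donor_accuracy, 1)
  expect_gte(res$spectral_accuracy, 0.9)

  unk <- RamanSet(t(spectraMatrix(ext0)), wavenumbers(ext0),
                  donor_id = paste0("X", donorIds(ext0)),
                  class_label = rep("UNKNOWN", ncol(ext0)),
                  spot_index = spotIndices(ext0))
  res_u <- externalValidate(clf, unk)
  expect_true(is.na(res_u$spectral_accuracy))
  expect_true(all(res_u$votes$call %in% c(clf@classes, "INDETERMINATE")))
  expect_true(is.na(res_u$donor_accuracy))
})
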