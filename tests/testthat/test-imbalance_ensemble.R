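test_that("undersampled subsets follow the round(|neg|/|pos|) rule and partition negatives", {
  s11 <- make_undersampled_subsets(paste0("p", 1:410), paste0("n", 1:4464), seed = 1)
  expect_length(s11, 11L)

  s1 <- make_undersampled_subsets(paste0("p", 1:10), paste0("n", 1:10), seed = 1)
  expect_length(s1, 1L)
  expect_setequal(s1[[1]], c(paste0("p", 1:10), paste0("n", 1:10)))

  s5 <- make_undersampled_subsets(paste0("p", 1:5), paste0("n", 1:23), seed = 1)
  expect_length(s5, 5L)
  expect_equal(sort(lengths(s5) - 5, decreasing = TRUE), c(5, 5, 5, 4, 4))

  # every negative in exactly one subset; all positives in every subset
  negs <- unlist(lapply(s5, setdiff, y = paste0("p", 1:5)))
  expect_setequal(negs, paste0("n", 1:23))
  expect_length(negs, 23L)
  for (sub in s5) expect_true(all(paste0("p", 1:5) %in% sub))

  # reproducible under seed
  expect_identical(s5, make_undersampled_subsets(paste0("p", 1:5), paste0("n", 1:23), seed = 1))
  expect_error(make_undersampled_subsets(character(0), "n1"), "non-empty")
})

test_that("metrics identities hold to 1e-12 on random confusion counts", {
  for (s in 1:6) {
    cnt <- withr_seed(s, sample(0:200, 4))
    if (cnt[1] + cnt[4] == 0 || cnt[2] + cnt[3] == 0) next
    m <- metrics_from_counts(tp = cnt[1], tn = cnt[2], fp = cnt[3], fn = cnt[4])
    expect_equal(m$sn, cnt[1] / (cnt[1] + cnt[4]), tolerance = 1e-12)
    expect_equal(m$sp, cnt[2] / (cnt[2] + cnt[3]), tolerance = 1e-12)
    expect_equal(m$acc, (cnt[1] + cnt[2]) / sum(cnt), tolerance = 1e-12)
    expect_equal(m$bacc, (m$sn + m$sp) / 2, tolerance = 1e-12)
  }
  perfect <- compute_metrics(rep(c("positive", "negative"), 5),
                             rep(c("positive", "negative"), 5))
  expect_equal(c(perfect$sn, perfect$sp, perfect$acc, perfect$bacc), rep(1, 4))
  # degenerate truth is an explicit NA, not a silent zero
  onesided <- compute_metrics(rep("negative", 4), rep("negative", 4))
  expect_true(is.na(onesided$sn) && is.na(onesided$bacc))
  expect_error(compute_metrics("positive", c("positive", "negative")), "length")
})

test_that("majority vote follows counts and even ties go to the positive class", {
  fm <- planted_matrix(n_pos = 20, n_neg = 20, seed = 12)
  model <- train_ensemble(fm, seed = 3)
  pred <- predict_vote(model, fm)
  expect_equal(nrow(pred), 40L)
  expect_true(all(pred$votes_positive + pred$votes_negative == length(model$members)))
  expect_true(all(as.character(pred$label) ==
                    ifelse(pred$votes_positive >= pred$votes_negative,
                           "positive", "negative")))
  expect_error(predict_vote(model, feature_matrix(
    matrix(0, 2, 2, dimnames = list(c("a", "b"), c("zz1", "zz2"))))),
    "missing model feature")
})

test_that("training is deterministic under seed and balanced K=1 equals a single forest", {
  fm <- planted_matrix(n_pos = 20, n_neg = 20, seed = 9)
  m1 <- train_ensemble(fm, seed = 5)
  m2 <- train_ensemble(fm, seed = 5)
  expect_length(m1$members, 1L)
  expect_equal(predict_vote(m1, fm), predict_vote(m2, fm))
  ms <- single_forest(fm, seed = 5)
  expect_equal(predict_vote(m1, fm), predict_vote(ms, fm))

  imb <- planted_matrix(n_pos = 10, n_neg = 52, seed = 9)
  m5 <- train_ensemble(imb, seed = 5)
  expect_length(m5$members, 5L)  # round(52/10)
})

test_that("stratified CV tests every sample exactly once and recovers planted signal", {
  fm <- planted_matrix(n_pos = 30, n_neg = 30, seed = 2)
  m <- stratified_cv(fm, folds = 5, seed = 4)
  expect_equal(m$tp + m$tn + m$fp + m$fn, 60L)
  expect_equal(m$tp + m$fn, 30L)  # all positives tested once
  expect_gte(m$bacc, 0.9)

  shuffled <- feature_matrix(fm$x, withr_seed(10, sample(as.character(fm$labels))))
  m0 <- stratified_cv(shuffled, folds = 5, seed = 4)
  expect_true(abs(m0$bacc - 0.5) <= 0.15)

  expect_error(stratified_cv(fm, folds = 40, seed = 1), "at least 40")
})

test_that("ratio sweep shows the imbalance pathology on a small planted matrix", {
  fm <- planted_matrix(n_pos = 12, n_neg = 60, d_noise = 6, seed = 21)
  sw <- ratio_sweep(fm, ratios = c(1, 3, 5), repeats = 2, seed = 2, folds = 3)
  expect_equal(sw$ratio, c(1, 3, 5))
  expect_equal(sw$repeats, rep(2, 3))
  expect_true(all(sw$bacc >= 0 & sw$bacc <= 1))
  # balanced training keeps Sn and Sp close
  expect_lte(abs(sw$sn[1] - sw$sp[1]), 0.2)
  expect_error(ratio_sweep(fm, ratios = 1:10, repeats = 1, seed = 1), "negatives")
})
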