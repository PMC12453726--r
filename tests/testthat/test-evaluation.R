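# Ensemble algebra, rank AUC against the exhaustive pair-counting oracle,
# thresholding, and support-weighted aggregation.

test_that("ensemble averaging: mean, idempotence, single member, bounds", {
  a <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  b <- matrix(c(0.8, 0.6, 0.4, 0.2), 2, 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  ens <- ensemble_scores(list(a, b))
  expect_equal(ens$scores[1, 1], 0.5)
  expect_equal(ens$m, 2L)
  expect_equal(ensemble_scores(list(a, a))$scores, a)
  expect_equal(ensemble_scores(list(a))$scores, a)
  # elementwise bounds
  set.seed(6)
  mats <- lapply(1:4, function(i) matrix(runif(20), 5, 4))
  e <- ensemble_scores(mats)$scores
  lo <- Reduce(pmin, mats); hi <- Reduce(pmax, mats)
  expect_true(all(e >= lo - 1e-15 & e <= hi + 1e-15))
  bad <- matrix(0.5, 3, 2)
  expect_error(ensemble_scores(list(a, bad)), class = "alignment_error")
  expect_error(ensemble_scores(list()), class = "alignment_error")
})

test_that("binarize uses >= and is monotone in the threshold", {
  s <- matrix(c(0.49, 0.50, 0.51), 1)
  expect_equal(as.vector(binarize(s, 0.5)), c(0L, 1L, 1L))
  all_half <- matrix(0.5, 2, 2)
  expect_true(all(binarize(all_half, 0.5) == 1L))
  set.seed(8)
  sc <- matrix(runif(100), 10)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                   function(th) sum(binarize(sc, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # complementary scores give complementary predictions off ties
  p1 <- binarize(sc, 0.5); p2 <- binarize(1 - sc, 0.5)
  off_tie <- sc != 0.5
  expect_true(all((p1 + p2)[off_tie] == 1L))
})

test_that("rank AUC equals the exhaustive concordant-pair oracle (500 random instances)", {
  set.seed(13)
  for (i in 1:500) {
    n <- sample(4:12, 1)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) y[sample(n, 2)] <- c(0, 1)
    s <- sample(round(runif(n), 2))          # coarse grid to provoke ties
    expect_equal(auc_rank(y, s), auc_pair_oracle(y, s))
  }
})

test_that("AUC hand cases: separation, the 0.75 pair count, ties, undefined", {
  expect_equal(auc_rank(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_rank(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc_rank(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_true(is.na(auc_rank(c(1, 1), c(0.2, 0.3))))
})

test_that("per-class metrics: perfect classifier, undefined AUC, zero denominators", {
  truth <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  scores <- cbind(a = c(0.9, 0.8, 0.1, 0.2), b = c(0.7, 0.2, 0.9, 0.1))
  m <- per_class_metrics(truth, scores, 0.5)
  expect_equal(m$auc, c(1, 1))
  expect_equal(m$sensitivity, c(1, 1))
  expect_equal(m$precision, c(1, 1))
  expect_equal(m$f1, c(1, 1))
  expect_equal(m$support, c(2L, 2L))
  # class with no negatives: AUC reported NA, not dropped
  t2 <- cbind(a = c(1, 1), b = c(1, 0))
  s2 <- cbind(a = c(0.9, 0.9), b = c(0.9, 0.1))
  m2 <- per_class_metrics(t2, s2)
  expect_true(is.na(m2$auc[1]))
  expect_equal(nrow(m2), 2L)
  # nothing predicted positive: precision 0 with the degenerate flag
  t3 <- cbind(a = c(1, 0, 0, 1))
  s3 <- cbind(a = c(0.1, 0.2, 0.1, 0.3))
  expect_warning(m3 <- per_class_metrics(t3, s3, 0.5))
  expect_equal(m3$precision, 0)
  expect_true(m3$degenerate)
})

test_that("weighted average: hand value, normalization, selection, convexity", {
  expect_equal(weighted_average(c(0.8, 0.6), c(3, 1)), 0.75)
  expect_equal(weighted_average(rep(0.4, 5), runif(5) + 0.1), 0.4)
  expect_equal(weighted_average(c(0.2, 0.9, 0.5), c(0, 1, 0)), 0.9)
  set.seed(17)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    v <- runif(k); w <- runif(k)
    wa <- weighted_average(v, w)
    expect_gte(wa, min(v) - 1e-12)
    expect_lte(wa, max(v) + 1e-12)
  }
  expect_error(weighted_average(c(0.5), c(-1)), class = "weight_error")
  expect_error(weighted_average(c(0.5, 0.5), c(0.5)), class = "weight_error")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.4)
    if (sum(y) %in% c(0, 40)) y[1:2] <- c(0, 1)
    s <- runif(40)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(auc_rank(y, s), ref)
  }
})

test_that("evaluate_ensemble wires members, ensemble and weighted metrics together", {
  set.seed(23)
  classes <- c("no finding", "bronchitis", "broncho-pneumonia",
               "bronchiolitis", "pneumonia", "other diseases")
  y <- matrix(rbinom(10 * 6, 1, 0.4), 10, 6, dimnames = list(NULL, classes))
  y[1, ] <- c(1L, rep(0L, 5))              # ensure positives exist
  tab <- label_table(sprintf("e%02d", 1:10), y, "test")
  imgs <- render_cxr_images(y, 64, noise_sd = 0.02)
  model <- init_mae(toy_mae_config(), seed = 31)
  fcfg <- finetune_config(epochs = 2L, warmup_epochs = 1L, base_lr = 1e-3,
                          batch_size = 8L, n_classes = 6L, seeds = 0L)
  tr_tab <- label_table(tab$ids, y, "train")
  clf <- finetune(model, tr_tab, imgs, fcfg, seed = 0L)
  rep4 <- evaluate_ensemble(list(clf, clf, clf, clf), tab, imgs)
  expect_length(rep4$members, 4L)
  expect_equal(rep4$m, 4L)
  # identical members: ensemble equals the single-model report
  rep1 <- evaluate_ensemble(list(clf), tab, imgs)
  expect_equal(rep4$ensemble, rep1$ensemble)
  expect_equal(rep4$weighted, rep1$weighted)
  # weighted metrics lie within the per-class range
  for (mname in c("auc", "sensitivity", "precision", "f1")) {
    v <- rep4$per_class[[mname]]
    expect_gte(rep4$weighted[[mname]], min(v, na.rm = TRUE) - 1e-12)
    expect_lte(rep4$weighted[[mname]], max(v, na.rm = TRUE) + 1e-12)
  }
  # report writing produces the CSV/JSON artifacts
  dir <- withr::local_tempdir()
  write_metrics_report(rep4, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "scores_member4.csv")))
})
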