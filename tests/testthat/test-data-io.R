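# Manifest filtering, label restructuring, splits, and augmentation.

fake_manifest <- function(n_frontal, n_lateral, origin, prefix) {
  n <- n_frontal + n_lateral
  data.frame(
    sample_id = sprintf("%s%06d", prefix, seq_len(n)),
    path = sprintf("%s/%06d.png", origin, seq_len(n)),
    origin = origin,
    view = c(rep("frontal", n_frontal), rep("lateral", n_lateral)),
    stringsAsFactors = FALSE
  )
}

test_that("frontal filter reproduces the adult pretraining image accounting", {
  chexpert <- fake_manifest(191229L, 33087L, "chexpert", "cx")
  cxr14 <- fake_manifest(112120L, 0L, "chestxray14", "nx")
  man <- build_pretrain_manifest(list(chexpert, cxr14))
  expect_equal(nrow(man), 303349L)
  expect_true(all(man$view == "frontal"))
})

test_that("frontal filter edge cases: identity, empty result, duplicates", {
  src <- fake_manifest(10L, 0L, "a", "a")
  expect_identical(build_pretrain_manifest(list(src)), src)
  lat <- fake_manifest(0L, 5L, "b", "b")
  expect_warning(out <- build_pretrain_manifest(list(lat)), "no frontal")
  expect_equal(nrow(out), 0L)
  dup <- rbind(src, src[1, ])
  expect_error(build_pretrain_manifest(list(dup)), class = "duplication_error")
})

test_that("label restructuring yields the six named classes and conserves positives", {
  tabs <- generate_pedicxr_raw_labels(500L, 200L, seed = 3)
  res <- restructure_pedicxr_labels(tabs$train, tabs$test)
  final <- c("no finding", "bronchitis", "broncho-pneumonia",
             "bronchiolitis", "pneumonia", "other diseases")
  expect_identical(res$train$classes, final)
  expect_identical(res$test$classes, final)
  expect_setequal(res$merged_classes,
                  c(pedicxr_schema()$absent_in_test, pedicxr_schema()$rare_in_train))
  # per-row label conservation: any original positive row stays positive
  expect_identical(rowSums(res$train$labels) > 0, rowSums(tabs$train$labels) > 0)
  # retained base-class columns are unchanged
  for (cl in setdiff(final, "other diseases"))
    expect_identical(res$train$labels[, cl], tabs$train$labels[, cl])
})

test_that("restructuring applies the merge rules row-wise", {
  sch <- pedicxr_schema()$all
  mk_row <- function(pos) { y <- rep(0L, 15); y[match(pos, sch)] <- 1L; y }
  y_tr <- rbind(mk_row("tuberculosis"),
                mk_row(c("bronchitis", "lung tumor")),
                matrix(rep(mk_row("bronchitis"), 30), 30, byrow = TRUE),
                matrix(rep(mk_row(c("pneumonia", "broncho-pneumonia",
                                    "bronchiolitis", "other diseases",
                                    "no finding")), 30), 30, byrow = TRUE))
  colnames(y_tr) <- sch
  y_te <- y_tr[3:62, ]
  train <- label_table(sprintf("tr%02d", 1:62), y_tr, "train")
  test <- label_table(sprintf("te%02d", 1:60), y_te, "test")
  res <- restructure_pedicxr_labels(train, test)
  # tuberculosis-only row becomes other-diseases-only
  r1 <- res$train$labels[1, ]
  expect_equal(unname(r1["other diseases"]), 1L)
  expect_equal(sum(r1), 1L)
  # bronchitis + merged class keeps bronchitis and gains other diseases
  r2 <- res$train$labels[2, ]
  expect_equal(unname(r2[c("bronchitis", "other diseases")]), c(1L, 1L))
  # schema error when the catch-all class is missing
  bad <- label_table(train$ids, y_tr[, -match("other diseases", sch)], "train")
  expect_error(restructure_pedicxr_labels(bad, bad), class = "schema_error")
})

test_that("train/val split sizes, determinism, and rounding", {
  tab <- label_table(sprintf("s%03d", 1:100),
                     matrix(0L, 100, 2, dimnames = list(NULL, c("a", "b"))))
  sp <- split_train_val(tab, 0.8, seed = 4)
  expect_equal(sum(sp$split == "train"), 80L)
  expect_equal(sum(sp$split == "val"), 20L)
  expect_identical(split_train_val(tab, 0.8, seed = 4)$split, sp$split)
  expect_false(identical(split_train_val(tab, 0.8, seed = 5)$split, sp$split))
  tiny <- label_table(sprintf("s%d", 1:5),
                      matrix(0L, 5, 1, dimnames = list(NULL, "a")))
  sp5 <- split_train_val(tiny, 0.8, seed = 1)
  expect_equal(sum(sp5$split == "train"), 4L)
  one <- label_table("s1", matrix(0L, 1, 1, dimnames = list(NULL, "a")))
  expect_error(split_train_val(one, 0.8, 1), class = "cannot_split_error")
})

test_that("augmentation: output geometry, standardization closed form, flip involution", {
  img <- matrix(runif(512 * 512), 512)
  cfg <- augmentation_config(resize_to = 256L, crop_to = 224L, phase = "eval")
  out <- load_and_augment(img, cfg)
  expect_equal(dim(out), c(3L, 224L, 224L))
  # constant image: channel c is exactly (v - mean_c)/sd_c everywhere
  v <- 0.3
  const <- matrix(v, 64, 64)
  cfge <- augmentation_config(resize_to = 64L, crop_to = 64L, phase = "eval")
  oc <- load_and_augment(const, cfge)
  for (ch in 1:3)
    expect_equal(unique(as.vector(oc[ch, , ])),
                 (v - cfge$normalize_mean[ch]) / cfge$normalize_sd[ch])
  # flip twice restores the original
  x <- array(runif(3 * 8 * 8), c(3, 8, 8))
  expect_identical(currimae:::hflip_chw(currimae:::hflip_chw(x)), x)
  # eval phase is a pure function of content
  expect_identical(load_and_augment(img, cfg), load_and_augment(img, cfg))
  # config invariants
  expect_error(augmentation_config(resize_to = 128L, crop_to = 256L),
               class = "invalid_spec_error")
  expect_error(load_and_augment("no/such/file.png", cfg), class = "io_error")
})
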