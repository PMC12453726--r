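# Training loops: snapshot bookkeeping, schedule logging, learning, resume
# equivalence, and the layer-wise learning-rate rule.

small_pretrain_cfg <- function(seed = 0L) {
  pretrain_config(
    plan = fixed_stage_plan(4L, c(0.6, 0.7, 0.8, 0.9)),
    model = toy_mae_config(),
    augment = augmentation_config(resize_to = 64L, crop_to = 64L, phase = "pretrain"),
    alpha0 = 1e-3, batch_size = 16L, seed = seed
  )
}

test_that("layer-wise learning-rate decay follows the geometric rule", {
  expect_equal(layerwise_lr(1, 0.55, 12, 12), 1)
  expect_equal(layerwise_lr(2e-3, 1, 3, 12), 2e-3)
  expect_equal(layerwise_lr(1, 0.55, 10, 12), 0.55^2)
  expect_equal(layerwise_lr(1, 0.55, 0, 4), 0.55^4)   # embedding gets the deepest discount
  expect_error(layerwise_lr(1, 0, 1, 4), class = "config_error")
  expect_error(layerwise_lr(1, 0.5, 7, 4), class = "range_error")
})

test_that("warmup then cosine: linear ramp, peak, decay to zero", {
  lr <- warmup_cosine_lr(1:100, 100, 10, 2.5e-3)
  expect_equal(lr[1:10], 2.5e-3 * (1:10) / 10)
  expect_equal(lr[10], 2.5e-3)
  expect_true(all(diff(lr[10:100]) <= 0))
  expect_equal(lr[100], 2.5e-3 * 0.5 * (1 + cos(pi)), tolerance = 1e-12)
})

test_that("curriculum pretraining saves one snapshot per stage with correct metadata and logs", {
  set.seed(1)
  imgs <- generate_cxr_like(synthetic_spec(32, 64, seed = 5))$images
  out <- withr::local_tempdir()
  cfg <- small_pretrain_cfg()
  snaps <- pretrain_curriculum(cfg, imgs, out_dir = out)
  expect_length(snaps$dirs, 4L)
  expect_equal(vapply(snaps$meta, `[[`, 1L, "epoch"), snapshot_epochs(cfg$plan))
  expect_equal(vapply(snaps$meta, `[[`, 1, "masking_ratio"), c(0.6, 0.7, 0.8, 0.9))
  # logged ratio per epoch equals the plan's step function
  for (ep in unique(snaps$log$epoch))
    expect_equal(unique(snaps$log$masking_ratio[snaps$log$epoch == ep]),
                 masking_ratio_at(cfg$plan, ep))
  # logged lr at each cycle start is exactly alpha0
  ipe <- nrow(snaps$log) / cfg$plan$total_epochs
  starts <- (c(0L, utils::head(cfg$plan$boundaries, -1L)) * ipe) + 1
  expect_equal(snaps$log$lr[starts], rep(cfg$alpha0, 4))
  # snapshots reload with matching metadata
  s2 <- load_snapshot(snaps$dirs[2])
  expect_equal(s2$meta$stage, 2L)
  expect_equal(s2$meta$masking_ratio, 0.7)
  expect_error(pretrain_curriculum(cfg, array(0, c(0, 64, 64))), class = "data_error")
})

test_that("pretraining lowers held-out masked loss below fresh initialization", {
  imgs <- generate_cxr_like(synthetic_spec(32, 64, seed = 5))$images
  hold <- generate_cxr_like(synthetic_spec(12, 64, seed = 99))$images
  cfg <- small_pretrain_cfg()
  snaps <- pretrain_curriculum(cfg, imgs, out_dir = withr::local_tempdir())
  trained <- masked_eval_loss(snaps$model, hold, 0.9, seed = 1)
  fresh <- masked_eval_loss(init_mae(cfg$model, seed = 123), hold, 0.9, seed = 1)
  expect_lt(trained, fresh)
})

test_that("resuming from a snapshot reproduces the uninterrupted run exactly", {
  imgs <- generate_cxr_like(synthetic_spec(16, 64, seed = 2))$images
  cfg <- small_pretrain_cfg()
  full <- pretrain_curriculum(cfg, imgs, out_dir = withr::local_tempdir())
  half_dir <- withr::local_tempdir()
  # stop after stage 2, then resume for stages 3-4
  cfg2 <- cfg
  cfg2$plan <- fixed_stage_plan(4L, c(0.6, 0.7, 0.8, 0.9))
  half <- pretrain_curriculum(cfg, imgs, out_dir = half_dir)
  resumed <- pretrain_curriculum(cfg, imgs, out_dir = withr::local_tempdir(),
                                 resume_from = file.path(half_dir, "snapshot-2"))
  expect_equal(vapply(resumed$meta, `[[`, 1L, "epoch"), c(3L, 4L))
  expect_equal(vapply(resumed$meta, `[[`, 1, "masking_ratio"), c(0.8, 0.9))
  # deterministic replay: identical final weights to the uninterrupted run
  expect_equal(resumed$model$params, full$model$params, tolerance = 1e-12)
})

test_that("fine-tuning: sigmoid head width, score range, and decreasing loss", {
  set.seed(3)
  cfg_m <- toy_mae_config()
  model <- init_mae(cfg_m, seed = 3)
  classes <- c("no finding", "bronchitis", "broncho-pneumonia",
               "bronchiolitis", "pneumonia", "other diseases")
  y <- matrix(rbinom(16 * 6, 1, 0.3), 16, 6, dimnames = list(NULL, classes))
  tab <- label_table(sprintf("s%02d", 1:16), y, "train")
  set.seed(4)
  imgs <- render_cxr_images(y, 64, noise_sd = 0.02)
  fcfg <- toy_finetune_config(n_classes = 6L, seeds = 0L)
  clf <- finetune(model, tab, imgs, fcfg, seed = 0L)
  scores <- predict_scores(clf, imgs, tab$ids)
  expect_equal(dim(scores), c(16L, 6L))
  expect_true(all(scores > 0 & scores < 1))
  expect_identical(colnames(scores), classes)
  # the seeded overfit run ends below its starting loss
  expect_lt(clf$log$loss[nrow(clf$log)], clf$log$loss[1])
  # repeatability under the same seed
  clf2 <- finetune(model, tab, imgs, fcfg, seed = 0L)
  expect_identical(predict_scores(clf2, imgs, tab$ids), scores)
  # class-count mismatch is rejected
  bad <- toy_finetune_config(n_classes = 4L)
  expect_error(finetune(model, tab, imgs, bad), class = "schema_error")
})
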