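# Patch grid operations, random masking, the masked reconstruction loss,
# and the encoder/decoder forward and backward contracts.

test_that("patchify counts and exact round-trip across sizes and channels", {
  g <- patchify(array(0, c(3, 224, 224)), 16)
  expect_equal(dim(g$patches), c(196L, 768L))
  expect_equal(dim(patchify(array(0, c(1, 32, 32)), 16)$patches)[1], 4L)
  set.seed(11)
  for (case in list(c(1, 16, 8), c(3, 32, 8), c(2, 24, 12))) {
    x <- array(runif(case[1] * case[2]^2), c(case[1], case[2], case[2]))
    g <- patchify(x, case[3])
    expect_identical(unpatchify(g), x)
    # replacement matrix path
    expect_identical(unpatchify(g, g$patches), x)
  }
  expect_error(patchify(array(0, c(1, 30, 30)), 16), class = "shape_error")
})

test_that("mask cardinality follows round-half-up over a grid of (n, ratio)", {
  expect_length(sample_mask(196, 0.60)$masked, 118L)
  expect_length(sample_mask(196, 0.90)$masked, 176L)
  set.seed(2)
  for (n in c(16, 49, 196, 256)) {
    for (r in c(0.1, 0.25, 0.5, 0.6, 0.75, 0.9)) {
      plan <- sample_mask(n, r)
      expect_length(plan$masked, floor(r * n + 0.5))
      expect_identical(sort(c(plan$masked, plan$visible)), seq_len(n))
      expect_length(intersect(plan$masked, plan$visible), 0L)
    }
  }
  set.seed(5); a <- sample_mask(196, 0.6)
  set.seed(5); b <- sample_mask(196, 0.6)
  expect_identical(a, b)
  expect_error(sample_mask(10, 0.01), class = "degenerate_ratio_error")
  expect_error(sample_mask(10, 0.99), class = "degenerate_ratio_error")
})

test_that("masked loss: exact hand values and invariance to visible-index changes", {
  # one masked 2x2 single-channel patch with constant error 0.5 per pixel
  x <- array(0.25, c(1, 2, 4))
  g <- patchify(x, 2)
  plan <- manual_plan(1L, 2L)
  pred <- g$patches
  pred[1, ] <- pred[1, ] + 0.5
  expect_equal(masked_mse_loss(g, pred, plan), 1.0)
  # perfect reconstruction
  expect_equal(masked_mse_loss(g, g$patches, plan), 0)
  # changing only visible patches leaves the loss at zero ...
  pv <- g$patches
  pv[2, ] <- pv[2, ] + rnorm(4)
  expect_equal(masked_mse_loss(g, pv, plan), 0)
  # ... and, property-style, never changes the loss at all
  set.seed(21)
  for (i in 1:20) {
    gg <- patchify(rand_image(1, 16), 8)
    pl <- sample_mask(4, 0.5)
    pr <- matrix(rnorm(4 * 64), 4, 64)
    base <- masked_mse_loss(gg, pr, pl)
    pr2 <- pr
    pr2[pl$visible, ] <- pr2[pl$visible, ] + matrix(rnorm(length(pl$visible) * 64), ncol = 64)
    expect_equal(masked_mse_loss(gg, pr2, pl), base)
  }
  expect_error(masked_mse_loss(g, g$patches, manual_plan(integer(0), 2L)),
               class = "degenerate_plan_error")
})

test_that("reconstruction contract: shapes, determinism, and encoder blindness", {
  cfg <- tiny_mae_config()
  model <- init_mae(cfg, seed = 4)
  set.seed(8)
  img <- rand_image(3, 16)
  grid <- patchify(img, 8)
  plan <- manual_plan(c(1L, 3L), 4L)
  f1 <- mae_reconstruct(model, grid, plan)
  f2 <- mae_reconstruct(model, grid, plan)
  expect_identical(f1$pred, f2$pred)                 # eval-mode determinism
  expect_equal(dim(f1$pred), dim(grid$patches))      # predicts every patch
  # perturbing a masked patch leaves the encoder latent unchanged
  img2 <- img
  img2[, 1:8, 1:8] <- runif(192)                     # patch 1 is masked
  f3 <- mae_reconstruct(model, patchify(img2, 8), plan)
  expect_identical(f1$latent, f3$latent)
  # mismatched plan is rejected
  expect_error(mae_reconstruct(model, grid, manual_plan(5L, 6L)),
               class = "shape_error")
})

test_that("encoder latents depend only on visible patches (random trials)", {
  cfg <- tiny_mae_config()
  model <- init_mae(cfg, seed = 10)
  set.seed(31)
  for (i in 1:100) {
    img <- rand_image(3, 16)
    plan <- sample_mask(4, runif(1, 0.3, 0.7))
    base <- mae_reconstruct(model, patchify(img, 8), plan)$latent
    img2 <- img
    for (b in plan$masked) {
      ys <- ((b - 1) %/% 2) * 8 + 1:8
      xs <- ((b - 1) %% 2) * 8 + 1:8
      img2[, ys, xs] <- runif(192)
    }
    expect_identical(mae_reconstruct(model, patchify(img2, 8), plan)$latent, base)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_mae_config()
  model <- init_mae(cfg, seed = 1)
  set.seed(42)
  grid <- patchify(rand_image(3, 16), 8)
  plan <- manual_plan(c(2L, 4L), 4L)
  loss_of <- function(m) {
    fwd <- mae_reconstruct(m, grid, plan)
    masked_mse_loss(grid, fwd$pred, plan)
  }
  fwd <- mae_reconstruct(model, grid, plan, keep_cache = TRUE)
  gr <- mae_backward(model, fwd, currimae:::masked_mse_grad(grid, fwd$pred, plan))
  leaves_p <- currimae:::tree_leaves(model$params)
  leaves_g <- currimae:::tree_leaves(gr)
  eps <- 1e-5
  set.seed(7)
  for (nm in names(leaves_p)) {
    p <- leaves_p[[nm]]
    for (id in sample(length(p), min(2, length(p)))) {
      perturbed <- function(d) {
        m <- model
        eval(parse(text = paste0("m$params", nm, "[", id, "] <- p[id] + d")))
        loss_of(m)
      }
      num <- (perturbed(eps) - perturbed(-eps)) / (2 * eps)
      ana <- leaves_g[[nm]][id]
      expect_lt(abs(num - ana), 1e-5 + 1e-3 * (abs(num) + abs(ana)))
    }
  }
})
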