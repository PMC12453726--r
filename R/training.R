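# Training loops: curriculum MAE pretraining (per-sample random masking,
# stage-wise masking ratios, cyclic cosine warm restarts, snapshots at
# stage ends) and multi-label fine-tuning of the pretrained encoder
# (sigmoid head, mean binary cross-entropy, warmup + cosine decay,
# layer-wise learning-rate decay, DropPath, RandAugment).

#' Pretraining configuration
#'
#' Defaults follow the reference recipe: 800 epochs in four 200-epoch
#' stages at masking ratios 60/70/80/90\%, AdamW
#' (\eqn{\beta_1 = 0.9, \beta_2 = 0.99}, weight decay 0.05), peak learning
#' rate \eqn{\alpha_0 = 1.5 \times 10^{-4}} under a cyclic cosine schedule
#' with one cycle per stage, batch size 256.
#'
#' @param plan a \code{\link{stage_plan}}; its last boundary is the epoch
#'   count.
#' @param model an \code{\link{mae_config}}.
#' @param augment an \code{\link{augmentation_config}} (pretrain phase).
#' @param alpha0 peak learning rate.
#' @param batch_size minibatch size.
#' @param beta1,beta2,weight_decay AdamW hyperparameters.
#' @param seed integer seed controlling init, masking and augmentation.
#' @return object of class \code{pretrain_config}.
#' @export
pretrain_config <- function(plan = fixed_stage_plan(),
                            model = mae_config(),
                            augment = augmentation_config(phase = "pretrain"),
                            alpha0 = 1.5e-4, batch_size = 256L,
                            beta1 = 0.9, beta2 = 0.99, weight_decay = 0.05,
                            seed = 0L) {
  if (alpha0 <= 0 || batch_size < 1L)
    stop_currimae("alpha0 and batch_size must be positive", "config_error")
  structure(list(plan = plan, model = model, augment = augment,
                 alpha0 = alpha0, batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

#' CPU-scale pretraining preset
#'
#' Tiny model (\code{\link{toy_mae_config}}), an 8-epoch four-stage
#' curriculum (boundaries 2/4/6/8), batch 16, and a larger peak rate
#' (1e-3) appropriate for the tiny model and short horizon.
#' @param seed integer seed.
#' @export
toy_pretrain_config <- function(seed = 0L) {
  pretrain_config(
    plan = fixed_stage_plan(8L, c(0.6, 0.7, 0.8, 0.9)),
    model = toy_mae_config(),
    augment = augmentation_config(resize_to = 64L, crop_to = 64L, phase = "pretrain"),
    alpha0 = 1e-3, batch_size = 16L, seed = seed
  )
}

# Materialize images as a list of [0,1] grayscale matrices from either an
# n x s x s array or a manifest data.frame with a `path` column.
as_image_list <- function(data) {
  if (is.array(data) && length(dim(data)) == 3L)
    return(lapply(seq_len(dim(data)[1]), function(i) data[i, , ]))
  if (is.data.frame(data)) {
    if (nrow(data) == 0L) stop_currimae("empty manifest", "data_error")
    return(lapply(data$path, read_gray_image))
  }
  if (is.list(data)) return(data)
  stop_currimae("data must be an image array, list, or manifest", "data_error")
}

prepare_batch <- function(images, idx, aug) {
  lapply(idx, function(i) load_and_augment(images[[i]], aug))
}

#' Curriculum MAE pretraining
#'
#' Runs the full curriculum: every epoch uses the stage plan's masking
#' ratio, each sample draws its own random mask, optimizer steps minimize
#' the masked MSE under the stage-aligned cyclic cosine learning rate, and
#' a snapshot (weights, optimizer state, RNG state, stage metadata) is
#' written at the end of every stage. Training is resumable from any
#' snapshot.
#'
#' @param cfg a \code{\link{pretrain_config}}.
#' @param data image array (\code{n x s x s}), list of matrices, or
#'   manifest data.frame with a \code{path} column.
#' @param out_dir directory for snapshots and the training log.
#' @param resume_from optional snapshot directory to continue from.
#' @return object of class \code{snapshot_set}: list with \code{dirs},
#'   \code{meta} (stage/ratio/epoch per snapshot), \code{log}
#'   (per-iteration data.frame), \code{model} (final weights).
#' @export
pretrain_curriculum <- function(cfg, data, out_dir = tempfile("pretrain-"),
                                resume_from = NULL) {
  images <- as_image_list(data)
  n <- length(images)
  if (n == 0L) stop_currimae("empty pretraining data", "data_error")
  plan <- cfg$plan
  ipe <- ceiling(n / cfg$batch_size)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  start_epoch <- 1L
  if (is.null(resume_from)) {
    set.seed(cfg$seed)
    model <- init_mae(cfg$model)
    opt <- adamw_init(model$params)
    global_t <- 0L
    log_rows <- list()
  } else {
    snap <- load_snapshot(resume_from)
    model <- snap$model
    opt <- attr(model, "opt_state")
    rng <- attr(model, "rng_state")
    if (is.null(opt) || is.null(rng))
      stop_currimae("snapshot lacks optimizer/RNG state; cannot resume", "io_error")
    assign(".Random.seed", rng, envir = globalenv())
    start_epoch <- snap$meta$epoch + 1L
    global_t <- snap$meta$epoch * ipe
    log_rows <- list()
  }

  snap_eps <- snapshot_epochs(plan)
  snap_dirs <- character(0)
  snap_meta <- list()
  for (epoch in start_epoch:plan$total_epochs) {
    ratio <- masking_ratio_at(plan, epoch)
    ord <- sample.int(n)
    for (b in seq_len(ipe)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      batch <- prepare_batch(images, idx, cfg$augment)
      global_t <- global_t + 1L
      lr <- stage_cosine_lr(plan, global_t, ipe, cfg$alpha0)
      grads <- NULL
      loss <- 0
      for (x in batch) {
        grid <- patchify(x, cfg$model$patch_size)
        mask <- sample_mask(nrow(grid$patches), ratio)
        fwd <- mae_reconstruct(model, grid, mask, keep_cache = TRUE)
        loss <- loss + masked_mse_loss(grid, fwd$pred, mask, cfg$model$norm_pix_loss)
        dpred <- masked_mse_grad(grid, fwd$pred, mask, cfg$model$norm_pix_loss)
        g <- mae_backward(model, fwd, dpred)
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      grads <- tree_scale(grads, 1 / length(batch))
      loss <- loss / length(batch)
      st <- adamw_step(model$params, grads, opt, lr,
                       beta1 = cfg$beta1, beta2 = cfg$beta2,
                       weight_decay = cfg$weight_decay)
      model$params <- st$params
      opt <- st$state
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(epoch = epoch, iteration = global_t, lr = lr,
                   masking_ratio = ratio, loss = loss)
    }
    if (epoch %in% snap_eps) {
      stage <- which(snap_eps == epoch)
      attr(model, "opt_state") <- opt
      attr(model, "rng_state") <- get(".Random.seed", envir = globalenv())
      dir <- file.path(out_dir, sprintf("snapshot-%d", stage))
      save_snapshot(model, dir, stage = stage, masking_ratio = ratio,
                    epoch = epoch)
      snap_dirs <- c(snap_dirs, dir)
      snap_meta[[length(snap_meta) + 1L]] <-
        list(stage = stage, masking_ratio = ratio, epoch = epoch)
    }
  }
  log <- do.call(rbind, log_rows)
  utils::write.csv(log, file.path(out_dir, "pretrain_log.csv"), row.names = FALSE)
  attr(model, "opt_state") <- NULL
  attr(model, "rng_state") <- NULL
  structure(list(dirs = snap_dirs, meta = snap_meta, log = log, model = model),
            class = "snapshot_set")
}

#' Masked reconstruction loss on held-out data
#'
#' Evaluates the mean masked MSE of a model over a set of images at a given
#' masking ratio, using eval-phase preprocessing and seeded masks.
#'
#' @param model an \code{mae_model}.
#' @param data image array/list/manifest.
#' @param ratio masking ratio.
#' @param augment eval-phase \code{\link{augmentation_config}}.
#' @param seed seed for the mask draws.
#' @return mean loss over samples.
#' @export
masked_eval_loss <- function(model, data, ratio,
                             augment = augmentation_config(
                               resize_to = model$cfg$image_size,
                               crop_to = model$cfg$image_size, phase = "eval"),
                             seed = 0L) {
  images <- as_image_list(data)
  set.seed(seed)
  losses <- vapply(images, function(im) {
    x <- load_and_augment(im, augment)
    grid <- patchify(x, model$cfg$patch_size)
    mask <- sample_mask(nrow(grid$patches), ratio)
    fwd <- mae_reconstruct(model, grid, mask)
    masked_mse_loss(grid, fwd$pred, mask, model$cfg$norm_pix_loss)
  }, numeric(1))
  mean(losses)
}

# ---- fine-tuning ------------------------------------------------------------

#' Fine-tuning configuration
#'
#' Defaults follow the reference recipe: 75 epochs with a 5-epoch linear
#' warmup then cosine decay from a base rate of 2.5e-3, batch 128, AdamW
#' (\eqn{\beta_1=0.9,\beta_2=0.99}, weight decay 0.05), layer-wise
#' learning-rate decay 0.55, RandAugment magnitude 6, DropPath 0.2, and
#' three repeats with seeds 0, 1, 2.
#'
#' @param epochs,warmup_epochs training and warmup epochs.
#' @param base_lr peak learning rate after warmup.
#' @param batch_size minibatch size.
#' @param layerwise_decay geometric per-block learning-rate decay in (0, 1].
#' @param randaug_magnitude RandAugment magnitude (0--10).
#' @param droppath stochastic-depth rate.
#' @param beta1,beta2,weight_decay AdamW hyperparameters.
#' @param n_classes classifier output width.
#' @param seeds integer seeds, one fine-tuning repeat each.
#' @return object of class \code{finetune_config}.
#' @export
finetune_config <- function(epochs = 75L, warmup_epochs = 5L, base_lr = 2.5e-3,
                            batch_size = 128L, layerwise_decay = 0.55,
                            randaug_magnitude = 6, droppath = 0.2,
                            beta1 = 0.9, beta2 = 0.99, weight_decay = 0.05,
                            n_classes = 6L, seeds = c(0L, 1L, 2L)) {
  if (warmup_epochs >= epochs)
    stop_currimae("warmup_epochs must be smaller than epochs", "config_error")
  if (layerwise_decay <= 0 || layerwise_decay > 1)
    stop_currimae("layerwise_decay must lie in (0, 1]", "config_error")
  structure(list(epochs = as.integer(epochs), warmup_epochs = as.integer(warmup_epochs),
                 base_lr = base_lr, batch_size = as.integer(batch_size),
                 layerwise_decay = layerwise_decay,
                 randaug_magnitude = randaug_magnitude, droppath = droppath,
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
                 n_classes = as.integer(n_classes), seeds = as.integer(seeds)),
            class = "finetune_config")
}

#' CPU-scale fine-tuning preset
#' @param n_classes classifier output width.
#' @param seeds fine-tuning seeds (a single repeat by default at toy scale).
#' @export
toy_finetune_config <- function(n_classes = 6L, seeds = 0L) {
  finetune_config(epochs = 6L, warmup_epochs = 1L, base_lr = 1e-3,
                  batch_size = 16L, n_classes = n_classes, seeds = seeds)
}

#' Layer-wise learning-rate factor
#'
#' \code{base_lr * decay^(depth - block_index)}: the head and topmost
#' block train at the base rate, the patch embedding (block index 0) gets
#' the deepest discount.
#'
#' @param base_lr base learning rate.
#' @param decay decay factor, > 0.
#' @param block_index 0 (embedding) through \code{depth} (head).
#' @param depth number of transformer blocks.
#' @return scaled learning rate.
#' @examples
#' layerwise_lr(1, 0.55, 10, 12)  # 0.55^2
#' @export
layerwise_lr <- function(base_lr, decay, block_index, depth) {
  if (decay <= 0) stop_currimae("decay must be positive", "config_error")
  if (block_index < 0 || block_index > depth)
    stop_currimae("block_index must lie in [0, depth]", "range_error")
  base_lr * decay^(depth - block_index)
}

#' Warmup + cosine learning rate
#'
#' Linear warmup from 0 to \code{base_lr} over the warmup iterations,
#' then cosine decay to 0 at the final iteration.
#'
#' @param t iteration (1-based), vectorized.
#' @param total_iters,warmup_iters horizon and warmup length.
#' @param base_lr peak rate.
#' @return learning rate(s).
#' @export
warmup_cosine_lr <- function(t, total_iters, warmup_iters, base_lr) {
  ifelse(t <= warmup_iters,
         base_lr * t / max(1, warmup_iters),
         base_lr * 0.5 * (1 + cos(pi * (t - warmup_iters) /
                                    max(1, total_iters - warmup_iters))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Mean binary cross-entropy over classes and samples
#' @param scores matrix of sigmoid scores in (0, 1).
#' @param truth binary matrix of the same shape.
#' @param eps numeric floor for the logs.
#' @return scalar loss.
#' @export
mean_bce <- function(scores, truth, eps = 1e-12) {
  s <- pmin(1 - eps, pmax(eps, scores))
  -mean(truth * log(s) + (1 - truth) * log(1 - s))
}

# layer-wise lr multiplier tree matching the encoder parameter shape
encoder_lr_scales <- function(enc, decay) {
  depth <- length(enc$blocks)
  list(
    patch_embed = layerwise_lr(1, decay, 0L, depth),
    cls = layerwise_lr(1, decay, 0L, depth),
    blocks = lapply(seq_len(depth), function(k) layerwise_lr(1, decay, k, depth)),
    norm = 1
  )
}

#' Fine-tune a pretrained encoder for multi-label classification
#'
#' Attaches a linear head to the class-token output, keeps all patches
#' (no masking), and trains end-to-end with the mean of per-class binary
#' cross-entropies, warmup + cosine learning rate, layer-wise decay,
#' DropPath and RandAugment.
#'
#' @param snapshot an \code{mae_model}, a \code{snapshot_set} element
#'   directory, or a checkpoint directory path.
#' @param table a \code{\link{label_table}} with train (and optionally
#'   val) split tags.
#' @param images image array/list aligned with \code{table$ids}.
#' @param cfg a \code{\link{finetune_config}}.
#' @param augment training-phase \code{\link{augmentation_config}}
#'   (finetune phase; RandAugment strength taken from \code{cfg}).
#' @param seed seed for this repeat (head init, shuffling, augmentation).
#' @return object of class \code{vit_classifier}: encoder + head weights,
#'   class names, and the per-iteration training \code{log}.
#' @export
finetune <- function(snapshot, table, images, cfg,
                     augment = NULL, seed = cfg$seeds[1]) {
  model <- if (is.character(snapshot)) load_snapshot(snapshot)$model else snapshot
  if (!inherits(model, "mae_model"))
    stop_currimae("snapshot must be an mae_model or checkpoint path", "config_error")
  if (length(table$classes) != cfg$n_classes)
    stop_currimae(sprintf("table has %d classes but config expects %d",
                          length(table$classes), cfg$n_classes), "schema_error")
  mcfg <- model$cfg
  augment <- augment %||% augmentation_config(
    resize_to = mcfg$image_size, crop_to = mcfg$image_size,
    phase = "finetune", randaug_magnitude = cfg$randaug_magnitude)
  images <- as_image_list(images)
  tr <- which(table$split == "train")
  if (length(tr) == 0L) stop_currimae("no training rows", "data_error")
  set.seed(seed)
  head <- list(W = matrix(trunc_normal(mcfg$enc_width * cfg$n_classes),
                          mcfg$enc_width, cfg$n_classes),
               b = rep(0, cfg$n_classes))
  params <- list(enc = model$params$enc, head = head)
  lr_scales <- list(enc = encoder_lr_scales(params$enc, cfg$layerwise_decay),
                    head = 1)
  opt <- adamw_init(params)
  ipe <- ceiling(length(tr) / cfg$batch_size)
  total_iters <- cfg$epochs * ipe
  warmup_iters <- cfg$warmup_epochs * ipe
  it <- 0L
  log_rows <- list()
  enc_model <- model
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    for (b in seq_len(ipe)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, length(tr))]
      it <- it + 1L
      lr <- warmup_cosine_lr(it, total_iters, warmup_iters, cfg$base_lr)
      grads <- NULL
      loss <- 0
      for (i in idx) {
        x <- load_and_augment(images[[i]], augment)
        grid <- patchify(x, mcfg$patch_size)
        enc_model$params$enc <- params$enc
        ef <- mae_encode_full(enc_model, grid, droppath = cfg$droppath,
                              training = TRUE, keep_cache = TRUE)
        cls <- ef$latent[1, , drop = FALSE]
        logits <- cls %*% params$head$W + params$head$b
        s <- sigmoid(logits)
        y <- table$labels[i, , drop = FALSE]
        loss <- loss + mean_bce(s, y)
        dlogits <- (s - y) / cfg$n_classes
        gh <- list(W = t(cls) %*% dlogits, b = as.numeric(dlogits))
        dlatent <- matrix(0, nrow(ef$latent), ncol(ef$latent))
        dlatent[1, ] <- dlogits %*% t(params$head$W)
        eb <- encoder_bwd(dlatent, params$enc, ef$cache, mcfg$enc_heads)
        g <- list(enc = eb$grads, head = gh)
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      grads <- tree_scale(grads, 1 / length(idx))
      loss <- loss / length(idx)
      st <- adamw_step(params, grads, opt, lr,
                       beta1 = cfg$beta1, beta2 = cfg$beta2,
                       weight_decay = cfg$weight_decay, lr_scale = lr_scales)
      params <- st$params
      opt <- st$state
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(epoch = epoch, iteration = it, lr = lr, loss = loss)
    }
  }
  structure(list(cfg = mcfg, enc = params$enc, head = params$head,
                 const = model$const, classes = table$classes,
                 log = do.call(rbind, log_rows), seed = seed),
            class = "vit_classifier")
}

#' Sigmoid class scores for a set of images
#'
#' Eval-phase preprocessing (center crop, no flip, no RandAugment), all
#' patches kept, class-token head; deterministic.
#'
#' @param classifier a \code{vit_classifier}.
#' @param images image array/list.
#' @param ids sample ids for the score matrix rows.
#' @return numeric matrix (samples x classes) of scores in (0, 1).
#' @export
predict_scores <- function(classifier, images, ids = NULL) {
  mcfg <- classifier$cfg
  augment <- augmentation_config(resize_to = mcfg$image_size,
                                 crop_to = mcfg$image_size, phase = "eval")
  images <- as_image_list(images)
  model <- structure(list(cfg = mcfg, params = list(enc = classifier$enc),
                          const = classifier$const), class = "mae_model")
  out <- t(vapply(images, function(im) {
    x <- load_and_augment(im, augment)
    grid <- patchify(x, mcfg$patch_size)
    ef <- mae_encode_full(model, grid)
    as.numeric(sigmoid(ef$latent[1, , drop = FALSE] %*% classifier$head$W +
                         classifier$head$b))
  }, numeric(length(classifier$classes))))
  rownames(out) <- ids %||% sprintf("s%05d", seq_len(nrow(out)))
  colnames(out) <- classifier$classes
  out
}
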