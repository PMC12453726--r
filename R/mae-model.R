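# The masked-autoencoder model: a ViT encoder that sees only visible
# patches (plus a class token), and a lighter ViT decoder that receives the
# encoded visible tokens, a shared learnable mask token at every masked
# position, and restored positional embeddings, then predicts the pixel
# content of all patches.

#' MAE / ViT model configuration
#'
#' @param image_size square input edge in pixels, divisible by
#'   \code{patch_size}.
#' @param patch_size patch edge in pixels.
#' @param channels input channels (radiographs are replicated to 3).
#' @param enc_width,enc_depth,enc_heads encoder embedding width, number of
#'   transformer blocks, attention heads. Defaults give a ViT-S-shaped
#'   encoder (384/12/6).
#' @param dec_width,dec_depth,dec_heads decoder geometry; deliberately small
#'   (the reconstruction head is discarded after pretraining).
#' @param norm_pix_loss standardize each target patch inside the loss
#'   (off by default; the plain masked MSE is the objective).
#' @return object of class \code{mae_config}.
#' @export
mae_config <- function(image_size = 224L, patch_size = 16L, channels = 3L,
                       enc_width = 384L, enc_depth = 12L, enc_heads = 6L,
                       dec_width = 256L, dec_depth = 4L, dec_heads = 8L,
                       norm_pix_loss = FALSE) {
  if (image_size %% patch_size != 0L)
    stop_currimae("image_size must be divisible by patch_size", "config_error")
  if (enc_width %% enc_heads != 0L || dec_width %% dec_heads != 0L)
    stop_currimae("widths must be divisible by head counts", "config_error")
  structure(list(image_size = image_size, patch_size = patch_size,
                 channels = channels,
                 enc_width = enc_width, enc_depth = enc_depth, enc_heads = enc_heads,
                 dec_width = dec_width, dec_depth = dec_depth, dec_heads = dec_heads,
                 norm_pix_loss = norm_pix_loss),
            class = "mae_config")
}

#' Tiny CPU-scale model configuration
#'
#' 64-pixel images, 8-pixel patches, a 64-wide/2-deep encoder and a
#' 32-wide/1-deep decoder: small enough that pretraining, fine-tuning and
#' ensembling run in seconds on one CPU while exercising every code path.
#' @export
toy_mae_config <- function() {
  mae_config(image_size = 64L, patch_size = 8L,
             enc_width = 64L, enc_depth = 2L, enc_heads = 4L,
             dec_width = 32L, dec_depth = 1L, dec_heads = 4L)
}

n_patches_of <- function(cfg) (cfg$image_size %/% cfg$patch_size)^2
patch_dim_of <- function(cfg) cfg$channels * cfg$patch_size^2

#' Initialize MAE weights
#'
#' Transformer block weights use Xavier-uniform initialization; the class
#' and mask tokens and the patch embedding use a truncated normal
#' (sd 0.02, clipped at 2 sd). Positional embeddings are fixed 2-D
#' sinusoidal tables (class-token position is all zeros).
#'
#' @param cfg an \code{\link{mae_config}}.
#' @param seed optional integer seed for reproducible initialization.
#' @return object of class \code{mae_model}: \code{cfg}, learnable
#'   \code{params}, fixed \code{const} (positional tables).
#' @export
init_mae <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- cfg$image_size %/% cfg$patch_size
  pd <- patch_dim_of(cfg)
  params <- list(
    enc = list(
      patch_embed = list(W = matrix(trunc_normal(pd * cfg$enc_width), pd, cfg$enc_width),
                         b = rep(0, cfg$enc_width)),
      cls = matrix(trunc_normal(cfg$enc_width), 1, cfg$enc_width),
      blocks = lapply(seq_len(cfg$enc_depth), function(i) init_block(cfg$enc_width)),
      norm = list(g = rep(1, cfg$enc_width), b = rep(0, cfg$enc_width))
    ),
    dec = list(
      embed = list(W = xavier_uniform(cfg$enc_width, cfg$dec_width),
                   b = rep(0, cfg$dec_width)),
      mask_token = matrix(trunc_normal(cfg$dec_width), 1, cfg$dec_width),
      blocks = lapply(seq_len(cfg$dec_depth), function(i) init_block(cfg$dec_width)),
      norm = list(g = rep(1, cfg$dec_width), b = rep(0, cfg$dec_width)),
      pred = list(W = xavier_uniform(cfg$dec_width, pd), b = rep(0, pd))
    )
  )
  const <- list(
    enc_pos = pos_embed_2d(cfg$enc_width, g, g),
    dec_pos = pos_embed_2d(cfg$dec_width, g, g)
  )
  structure(list(cfg = cfg, params = params, const = const), class = "mae_model")
}

#' Encode and reconstruct under a masking plan
#'
#' The encoder consumes only the visible patches (plus the class token);
#' the decoder sees the encoded visible tokens scattered back to their grid
#' positions, the shared mask token at each masked position, and decoder
#' positional embeddings, and predicts every patch's pixels.
#'
#' @param model an \code{mae_model}.
#' @param grid a \code{\link{patchify}} result for one image.
#' @param plan a \code{\link{sample_mask}} plan over the same patch count.
#' @param keep_cache keep intermediate activations for backprop (internal).
#' @return list with \code{pred} (n_patches x patch_dim prediction matrix),
#'   \code{latent} (encoder output, class token in row 1), and, when
#'   requested, \code{cache}.
#' @export
mae_reconstruct <- function(model, grid, plan, keep_cache = FALSE) {
  cfg <- model$cfg
  n <- n_patches_of(cfg)
  if (nrow(grid$patches) != n)
    stop_currimae("patch grid does not match model configuration", "shape_error")
  if (max(plan$masked) > n || length(plan$masked) + length(plan$visible) != n)
    stop_currimae("masking plan inconsistent with patch count", "shape_error")
  p <- model$params
  vis <- plan$visible
  ef <- encoder_fwd(p$enc, model$const$enc_pos,
                    grid$patches[vis, , drop = FALSE], vis, cfg$enc_heads)
  # project all encoder outputs (cls + visible) into the decoder width
  z <- add_row_bias(ef$latent %*% p$dec$embed$W, p$dec$embed$b)
  seq_full <- matrix(rep(p$dec$mask_token, each = n), n, cfg$dec_width)
  seq_full[vis, ] <- z[-1, , drop = FALSE]
  x <- rbind(z[1, , drop = FALSE], seq_full + model$const$dec_pos)
  caches <- vector("list", cfg$dec_depth)
  for (i in seq_along(p$dec$blocks)) {
    st <- block_fwd(x, p$dec$blocks[[i]], cfg$dec_heads)
    x <- st$y
    caches[[i]] <- st$cache
  }
  ln <- layernorm_fwd(x, p$dec$norm)
  pred_all <- add_row_bias(ln$y %*% p$dec$pred$W, p$dec$pred$b)
  pred <- pred_all[-1, , drop = FALSE]
  out <- list(pred = pred, latent = ef$latent)
  if (keep_cache)
    out$cache <- list(enc = ef$cache, enc_latent = ef$latent, z = z,
                      dec_blocks = caches, dec_norm = ln$cache,
                      dec_in_rows = ln, ln_y = ln$y, vis = vis, n = n)
  out
}

# Backward pass: dpred is the gradient of the loss w.r.t. the prediction
# matrix (n_patches x patch_dim). Returns gradients in the params shape.
mae_backward <- function(model, fwd, dpred) {
  cfg <- model$cfg
  p <- model$params
  ca <- fwd$cache
  n <- ca$n
  vis <- ca$vis
  dy <- rbind(0, dpred)                                   # cls row got no loss
  dpredW <- t(ca$ln_y) %*% dy
  dpredb <- colSums(dy)
  dx <- dy %*% t(p$dec$pred$W)
  ln <- layernorm_bwd(dx, ca$dec_norm)
  dnorm <- ln$grads
  dx <- ln$dx
  dec_blocks <- vector("list", cfg$dec_depth)
  for (i in rev(seq_along(p$dec$blocks))) {
    bb <- block_bwd(dx, p$dec$blocks[[i]], ca$dec_blocks[[i]])
    dx <- bb$dx
    dec_blocks[[i]] <- bb$grads
  }
  dcls_dec <- dx[1, , drop = FALSE]
  dseq <- dx[-1, , drop = FALSE]
  dmask_token <- matrix(colSums(dseq[setdiff(seq_len(n), vis), , drop = FALSE]),
                        1, cfg$dec_width)
  dz <- rbind(dcls_dec, dseq[vis, , drop = FALSE])        # grads w.r.t. z rows
  dembed <- list(W = t(ca$enc_latent) %*% dz, b = colSums(dz))
  dlatent <- dz %*% t(p$dec$embed$W)
  eb <- encoder_bwd(dlatent, p$enc, ca$enc, cfg$enc_heads)
  list(enc = eb$grads,
       dec = list(embed = dembed, mask_token = dmask_token,
                  blocks = dec_blocks, norm = dnorm,
                  pred = list(W = dpredW, b = dpredb)))
}

#' Encoder latent for a full (unmasked) image
#'
#' Used at fine-tune/evaluation time: all patches are kept, and the class
#' token's output row summarizes the image.
#'
#' @inheritParams mae_reconstruct
#' @param droppath stochastic-depth rate (training only).
#' @param training enable stochastic depth.
#' @keywords internal
mae_encode_full <- function(model, grid, droppath = 0, training = FALSE,
                            keep_cache = FALSE) {
  cfg <- model$cfg
  ef <- encoder_fwd(model$params$enc, model$const$enc_pos, grid$patches,
                    seq_len(nrow(grid$patches)), cfg$enc_heads,
                    droppath = droppath, training = training)
  out <- list(latent = ef$latent)
  if (keep_cache) out$cache <- ef$cache
  out
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model snapshot
#'
#' Writes a checkpoint directory holding the weights (\code{weights.rds})
#' and a plain-text \code{meta.json} echoing the configuration, the
#' curriculum stage, the masking ratio in force, the epoch saved, and the
#' RNG state (for exact resumption).
#'
#' @param model an \code{mae_model} (optionally with optimizer state
#'   attached for resumption).
#' @param dir output directory (created).
#' @param stage,masking_ratio,epoch curriculum metadata.
#' @param extra optional named list merged into the metadata.
#' @return \code{dir}, invisibly.
#' @export
save_snapshot <- function(model, dir, stage = NA, masking_ratio = NA,
                          epoch = NA, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    saveRDS(model, file.path(dir, "weights.rds"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_currimae(sprintf("failed to write snapshot at %s", dir), "io_error")
  meta <- c(list(stage = stage, masking_ratio = masking_ratio, epoch = epoch,
                 config = unclass(model$cfg)), extra)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model snapshot
#' @param dir checkpoint directory written by \code{\link{save_snapshot}}.
#' @return list with \code{model} and \code{meta}.
#' @export
load_snapshot <- function(dir) {
  wf <- file.path(dir, "weights.rds")
  mf <- file.path(dir, "meta.json")
  if (!file.exists(wf) || !file.exists(mf))
    stop_currimae(sprintf("no snapshot at %s", dir), "io_error")
  list(model = readRDS(wf), meta = jsonlite::read_json(mf))
}
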