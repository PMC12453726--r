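# Patch grid operations: images are cut into non-overlapping square patches
# in row-major grid order; each patch is flattened with the pixel raster
# fastest and the channel slowest, so a C x H x W image becomes an
# (n_patches x C*p^2) matrix. patchify/unpatchify are exact inverses.

#' Cut an image into non-overlapping square patches
#'
#' @param image numeric array \code{C x H x W} (channels first).
#' @param patch_size patch edge length in pixels; must divide both H and W.
#' @return An object of class \code{patch_grid}: list with \code{patches}
#'   (matrix \code{n_patches x C*patch_size^2}, row-major grid order),
#'   \code{patch_size}, \code{grid_h}, \code{grid_w}, \code{channels},
#'   \code{image_size = c(H, W)}.
#' @examples
#' x <- array(runif(3 * 32 * 32), c(3, 32, 32))
#' g <- patchify(x, 16)          # 4 patches of dimension 768
#' all.equal(unpatchify(g), x)
#' @export
patchify <- function(image, patch_size) {
  d <- dim(image)
  if (length(d) != 3L)
    stop_currimae("image must be a C x H x W array", "shape_error")
  C <- d[1]; H <- d[2]; W <- d[3]
  if (H %% patch_size != 0L || W %% patch_size != 0L)
    stop_currimae(sprintf("image %dx%d not divisible by patch size %d", H, W, patch_size),
                  "shape_error")
  gh <- H %/% patch_size; gw <- W %/% patch_size
  n <- gh * gw
  out <- matrix(0, n, C * patch_size^2)
  idx <- 1L
  for (i in seq_len(gh)) {
    ys <- ((i - 1L) * patch_size + 1L):(i * patch_size)
    for (j in seq_len(gw)) {
      xs <- ((j - 1L) * patch_size + 1L):(j * patch_size)
      blk <- image[, ys, xs, drop = FALSE]           # C x p x p
      out[idx, ] <- as.vector(aperm(blk, c(2, 3, 1)))  # y fastest, channel slowest
      idx <- idx + 1L
    }
  }
  structure(list(patches = out, patch_size = patch_size, grid_h = gh,
                 grid_w = gw, channels = C, image_size = c(H, W)),
            class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' Exact inverse of \code{\link{patchify}}; also accepts a plain prediction
#' matrix via \code{patches}, reassembled against the grid's geometry.
#'
#' @param grid a \code{patch_grid}.
#' @param patches optional replacement patch matrix of the same shape.
#' @return numeric array \code{C x H x W}.
#' @export
unpatchify <- function(grid, patches = NULL) {
  p <- grid$patch_size; C <- grid$channels
  pm <- patches %||% grid$patches
  if (!all(dim(pm) == dim(grid$patches)))
    stop_currimae("patch matrix shape does not match grid", "shape_error")
  img <- array(0, c(C, grid$image_size[1], grid$image_size[2]))
  idx <- 1L
  for (i in seq_len(grid$grid_h)) {
    ys <- ((i - 1L) * p + 1L):(i * p)
    for (j in seq_len(grid$grid_w)) {
      xs <- ((j - 1L) * p + 1L):(j * p)
      img[, ys, xs] <- aperm(array(pm[idx, ], c(p, p, C)), c(3, 1, 2))
      idx <- idx + 1L
    }
  }
  img
}

#' Sample a random masking plan
#'
#' Draws \code{round(ratio * n_patches)} patch indices uniformly without
#' replacement (rounding half up, so the realized ratio is nearest the
#' nominal one). Deterministic given the R RNG state.
#'
#' @param n_patches number of patches in the grid.
#' @param ratio nominal masking ratio in (0, 1); must leave at least one
#'   masked and one visible patch.
#' @return An object of class \code{masking_plan}: list with sorted integer
#'   vectors \code{masked} and \code{visible} partitioning
#'   \code{1:n_patches}, and \code{ratio}.
#' @export
sample_mask <- function(n_patches, ratio) {
  if (ratio <= 0 || ratio >= 1)
    stop_currimae("masking ratio must lie strictly in (0, 1)", "degenerate_ratio_error")
  k <- round_half_up(ratio * n_patches)
  if (k < 1 || k > n_patches - 1)
    stop_currimae(sprintf("ratio %.3f leaves an empty masked or visible set for %d patches",
                          ratio, n_patches), "degenerate_ratio_error")
  masked <- sort(sample.int(n_patches, k))
  structure(list(masked = masked,
                 visible = setdiff(seq_len(n_patches), masked),
                 ratio = ratio),
            class = "masking_plan")
}

#' Masked-patch mean squared error
#'
#' The reconstruction objective: with masked index set \eqn{B},
#' \deqn{\mathrm{loss} = \frac{1}{|B|}\sum_{i \in B}\lVert X_i - Y_i\rVert_2^2,}
#' i.e. the per-patch squared L2 error summed over masked patches only and
#' averaged over \eqn{|B|}. Visible patches contribute exactly zero.
#' With \code{norm_pix_loss = TRUE} each target patch is standardized to
#' zero mean and unit variance before the difference (off by default).
#'
#' @param target a \code{patch_grid} (or patch matrix) of ground-truth patches.
#' @param pred predicted patch matrix of identical shape.
#' @param plan a \code{masking_plan}.
#' @param norm_pix_loss standardize target patches first.
#' @return nonnegative scalar.
#' @export
masked_mse_loss <- function(target, pred, plan, norm_pix_loss = FALSE) {
  X <- if (inherits(target, "patch_grid")) target$patches else target
  Y <- if (inherits(pred, "patch_grid")) pred$patches else pred
  if (!all(dim(X) == dim(Y)))
    stop_currimae("target and prediction shapes differ", "shape_error")
  B <- plan$masked
  if (length(B) < 1L) stop_currimae("empty masked set", "degenerate_plan_error")
  if (max(B) > nrow(X)) stop_currimae("plan indexes beyond patch count", "shape_error")
  Xb <- X[B, , drop = FALSE]
  if (norm_pix_loss) {
    mu <- rowMeans(Xb)
    sd_ <- sqrt(rowMeans((Xb - mu)^2) + 1e-6)
    Xb <- (Xb - mu) / sd_
  }
  sum((Xb - Y[B, , drop = FALSE])^2) / length(B)
}

# Gradient of masked_mse_loss w.r.t. the prediction matrix (norm_pix_loss
# affects only the target, so the gradient form is unchanged).
masked_mse_grad <- function(target, pred, plan, norm_pix_loss = FALSE) {
  X <- if (inherits(target, "patch_grid")) target$patches else target
  Y <- if (inherits(pred, "patch_grid")) pred$patches else pred
  B <- plan$masked
  Xb <- X[B, , drop = FALSE]
  if (norm_pix_loss) {
    mu <- rowMeans(Xb)
    sd_ <- sqrt(rowMeans((Xb - mu)^2) + 1e-6)
    Xb <- (Xb - mu) / sd_
  }
  g <- matrix(0, nrow(Y), ncol(Y))
  g[B, ] <- 2 * (Y[B, , drop = FALSE] - Xb) / length(B)
  g
}
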