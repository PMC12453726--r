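# Vision-transformer primitives with explicit forward/backward passes.
# Everything operates on one sample at a time: a token matrix (n_tokens x
# width). Batching is a loop with gradient accumulation in the training
# module. Pre-norm blocks: x + Attn(LN(x)), then x + MLP(LN(x)).
# Backward passes are verified against central finite differences in the
# test suite.

add_row_bias <- function(M, b) M + rep(b, each = nrow(M))

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# ---- layer norm -------------------------------------------------------------

layernorm_fwd <- function(x, p, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv                      # length-n 'inv' recycles over rows
  y <- add_row_bias(xhat * rep(p$g, each = nrow(x)), p$b)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = p$g))
}

layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(cache$g, each = nrow(dy))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, grads = list(g = dg, b = db))
}

# ---- multi-head self-attention ---------------------------------------------

attention_fwd <- function(x, p, n_heads) {
  d <- ncol(x)
  dh <- d %/% n_heads
  qkv <- add_row_bias(x %*% p$Wqkv, p$bqkv)     # n x 3d, layout [Q | K | V]
  scale <- 1 / sqrt(dh)
  O <- matrix(0, nrow(x), d)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Q <- qkv[, cols, drop = FALSE]
    K <- qkv[, d + cols, drop = FALSE]
    V <- qkv[, 2L * d + cols, drop = FALSE]
    A <- softmax_rows((Q %*% t(K)) * scale)
    O[, cols] <- A %*% V
    heads[[h]] <- list(Q = Q, K = K, V = V, A = A, cols = cols)
  }
  y <- add_row_bias(O %*% p$Wproj, p$bproj)
  list(y = y, cache = list(x = x, qkv = qkv, O = O, heads = heads,
                           scale = scale, d = d))
}

attention_bwd <- function(dy, p, cache) {
  d <- cache$d
  dWproj <- t(cache$O) %*% dy
  dbproj <- colSums(dy)
  dO <- dy %*% t(p$Wproj)
  dqkv <- matrix(0, nrow(dy), 3L * d)
  for (hd in cache$heads) {
    cols <- hd$cols
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(hd$V)
    dV <- t(hd$A) %*% dOh
    dS <- (dA - rowSums(dA * hd$A)) * hd$A        # softmax backward, row-wise
    dQ <- (dS %*% hd$K) * cache$scale
    dK <- (t(dS) %*% hd$Q) * cache$scale
    dqkv[, cols] <- dQ
    dqkv[, d + cols] <- dK
    dqkv[, 2L * d + cols] <- dV
  }
  dWqkv <- t(cache$x) %*% dqkv
  dbqkv <- colSums(dqkv)
  dx <- dqkv %*% t(p$Wqkv)
  list(dx = dx, grads = list(Wqkv = dWqkv, bqkv = dbqkv,
                             Wproj = dWproj, bproj = dbproj))
}

# ---- MLP (two-layer GELU) ---------------------------------------------------

mlp_fwd <- function(x, p) {
  h <- add_row_bias(x %*% p$W1, p$b1)
  a <- gelu(h)
  y <- add_row_bias(a %*% p$W2, p$b2)
  list(y = y, cache = list(x = x, h = h, a = a))
}

mlp_bwd <- function(dy, p, cache) {
  dW2 <- t(cache$a) %*% dy
  db2 <- colSums(dy)
  da <- dy %*% t(p$W2)
  dh <- da * gelu_grad(cache$h)
  dW1 <- t(cache$x) %*% dh
  db1 <- colSums(dh)
  dx <- dh %*% t(p$W1)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- transformer block ------------------------------------------------------
# DropPath (stochastic depth): during training each residual branch is
# dropped for the whole sample with probability `droppath`, otherwise scaled
# by 1/(1-p); at evaluation the branch passes through unscaled.

droppath_scale <- function(droppath, training) {
  if (!training || droppath <= 0) return(1)
  if (stats::runif(1) < droppath) 0 else 1 / (1 - droppath)
}

block_fwd <- function(x, p, n_heads, droppath = 0, training = FALSE) {
  s1 <- droppath_scale(droppath, training)
  ln1 <- layernorm_fwd(x, p$ln1)
  at <- attention_fwd(ln1$y, p$attn, n_heads)
  x1 <- x + s1 * at$y
  s2 <- droppath_scale(droppath, training)
  ln2 <- layernorm_fwd(x1, p$ln2)
  ml <- mlp_fwd(ln2$y, p$mlp)
  y <- x1 + s2 * ml$y
  list(y = y, cache = list(ln1 = ln1$cache, at = at$cache, ln2 = ln2$cache,
                           ml = ml$cache, s1 = s1, s2 = s2))
}

block_bwd <- function(dy, p, cache) {
  ml <- mlp_bwd(cache$s2 * dy, p$mlp, cache$ml)
  ln2 <- layernorm_bwd(ml$dx, cache$ln2)
  dx1 <- dy + ln2$dx
  at <- attention_bwd(cache$s1 * dx1, p$attn, cache$at)
  ln1 <- layernorm_bwd(at$dx, cache$ln1)
  dx <- dx1 + ln1$dx
  list(dx = dx, grads = list(ln1 = ln1$grads, attn = at$grads,
                             ln2 = ln2$grads, mlp = ml$grads))
}

# ---- initialization ---------------------------------------------------------

xavier_uniform <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

init_block <- function(d, mlp_ratio = 4L) {
  dm <- d * mlp_ratio
  list(
    ln1 = list(g = rep(1, d), b = rep(0, d)),
    attn = list(Wqkv = xavier_uniform(d, 3L * d), bqkv = rep(0, 3L * d),
                Wproj = xavier_uniform(d, d), bproj = rep(0, d)),
    ln2 = list(g = rep(1, d), b = rep(0, d)),
    mlp = list(W1 = xavier_uniform(d, dm), b1 = rep(0, dm),
               W2 = xavier_uniform(dm, d), b2 = rep(0, d))
  )
}

# ---- 2-D sinusoidal positional embeddings ----------------------------------
# Fixed (non-learned): half the width encodes the patch row, half the column,
# each half split sin/cos over a geometric frequency ladder. Row 0 is used
# for the class token (all zeros by construction at position 0? no: a zero
# vector is prepended explicitly by callers).

sincos_1d <- function(d_half, pos) {
  stopifnot(d_half %% 2 == 0)
  omega <- 1 / 10000^((seq_len(d_half / 2) - 1) / (d_half / 2))
  ang <- outer(pos, omega)
  cbind(sin(ang), cos(ang))
}

pos_embed_2d <- function(d, grid_h, grid_w) {
  if (d %% 4 != 0) stop_currimae("embedding width must be divisible by 4", "config_error")
  y <- rep(0:(grid_h - 1L), each = grid_w)   # row-major, matching patchify
  x <- rep(0:(grid_w - 1L), grid_h)
  cbind(sincos_1d(d / 2, y), sincos_1d(d / 2, x))
}

# ---- encoder ----------------------------------------------------------------
# `patches`: (k x patch_dim) matrix of the patches actually given to the
# encoder (the visible subset during pretraining, all patches at fine-tune).
# `positions`: their 1-based indices into the full grid, used to pick
# positional embeddings. The class token always rides in row 1 with a zero
# positional embedding.

encoder_fwd <- function(enc, pos_table, patches, positions, n_heads,
                        droppath = 0, training = FALSE) {
  tok <- add_row_bias(patches %*% enc$patch_embed$W, enc$patch_embed$b)
  x <- rbind(enc$cls, tok + pos_table[positions, , drop = FALSE])
  caches <- vector("list", length(enc$blocks))
  for (i in seq_along(enc$blocks)) {
    st <- block_fwd(x, enc$blocks[[i]], n_heads, droppath, training)
    x <- st$y
    caches[[i]] <- st$cache
  }
  ln <- layernorm_fwd(x, enc$norm)
  list(latent = ln$y,
       cache = list(blocks = caches, norm = ln$cache, patches = patches))
}

encoder_bwd <- function(dlatent, enc, cache, n_heads) {
  grads <- list(patch_embed = NULL, cls = NULL, blocks = vector("list", length(enc$blocks)),
                norm = NULL)
  ln <- layernorm_bwd(dlatent, cache$norm)
  grads$norm <- ln$grads
  dx <- ln$dx
  for (i in rev(seq_along(enc$blocks))) {
    bb <- block_bwd(dx, enc$blocks[[i]], cache$blocks[[i]])
    dx <- bb$dx
    grads$blocks[[i]] <- bb$grads
  }
  grads$cls <- dx[1, , drop = FALSE]
  dtok <- dx[-1, , drop = FALSE]
  grads$patch_embed <- list(W = t(cache$patches) %*% dtok, b = colSums(dtok))
  list(grads = grads, dpatches = dtok %*% t(enc$patch_embed$W))
}
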