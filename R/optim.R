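# AdamW over nested parameter lists. Decoupled weight decay is applied only
# to genuine weight matrices (both dimensions > 1); biases, layer-norm
# gains/offsets and the class/mask tokens are exempt, the standard practice
# for transformer training. An optional multiplier tree of the same shape
# scales the learning rate per parameter group (layer-wise decay).

adamw_init <- function(params) {
  list(m = tree_zero_like(params), v = tree_zero_like(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.99, eps = 1e-8,
                       weight_decay = 0.05, lr_scale = NULL) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  step_leaf <- function(p, g, m, v, s) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    decay <- if (is.matrix(p) && all(dim(p) > 1L)) weight_decay else 0
    p <- p - lr * s * (upd + decay * p)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v, s) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        si <- if (is.list(s)) s[[i]] else s
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]], si)
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      step_leaf(p, g, m, v, s)
    }
  }
  r <- walk(params, grads, state$m, state$v, lr_scale %||% 1)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
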