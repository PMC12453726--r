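# Internal helpers shared across modules.

# Round half away from zero. Used for mask cardinality and split sizes so the
# realized fraction is the nearest integer to the nominal one (base round()
# is round-half-even, which would give e.g. round(0.5*2)=1 but round(2.5)=2).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_currimae <- function(msg, class) {
  stop(structure(
    class = c(class, "currimae_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# ---- recursive operations over nested parameter lists ----------------------
# Model parameters, gradients and optimizer moments all share one nested-list
# shape; these walk that shape.

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zero_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

# Flatten leaves into a named list of numeric arrays (for gradient checking).
tree_leaves <- function(tree, prefix = "") {
  if (!is.list(tree)) {
    out <- list(tree)
    names(out) <- prefix
    return(out)
  }
  nm <- names(tree)
  out <- list()
  for (i in seq_along(tree)) {
    part <- if (!is.null(nm) && nzchar(nm[i])) paste0("$", nm[i])
            else paste0("[[", i, "]]")
    key <- paste0(prefix, part)
    out <- c(out, tree_leaves(tree[[i]], key))
  }
  out
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
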