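# Shared fixtures: a minimal transformer geometry for fast exact checks and
# small random inputs. Everything is generated in code; no stored data.

tiny_mae_config <- function() {
  mae_config(image_size = 16L, patch_size = 8L,
             enc_width = 8L, enc_depth = 1L, enc_heads = 2L,
             dec_width = 8L, dec_depth = 1L, dec_heads = 2L)
}

rand_image <- function(channels = 3L, size = 16L) {
  array(stats::runif(channels * size * size), c(channels, size, size))
}

# Independent AUC oracle: exhaustive concordant-pair fraction with ties
# counted one half. Used only to check the rank-based implementation.
auc_pair_oracle <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Manual masking plan for exact-loss constructions.
manual_plan <- function(masked, n) {
  structure(list(masked = as.integer(masked),
                 visible = setdiff(seq_len(n), masked),
                 ratio = length(masked) / n),
            class = "masking_plan")
}
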