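# Curriculum stage plans and the cyclic cosine (warm-restart) learning-rate
# schedule. A stage plan partitions the pretraining epochs into contiguous
# stages of increasing masking ratio; the scheduler restarts at each cycle
# start; snapshots are taken at stage ends.

#' Construct a curriculum stage plan
#'
#' A stage plan pairs cumulative epoch boundaries with masking ratios. Stage
#' \eqn{k} covers the 1-based epoch interval \eqn{(b_{k-1}, b_k]}, so a plan
#' with boundaries \code{c(200, 400, 600, 800)} assigns its first ratio to
#' epochs 1--200 exactly.
#'
#' @param boundaries strictly increasing integer vector of cumulative epoch
#'   boundaries (inclusive stage ends); the last entry is the total number of
#'   pretraining epochs.
#' @param ratios masking ratio per stage, strictly increasing in (0, 1).
#' @return An object of class \code{stage_plan} with elements
#'   \code{boundaries}, \code{ratios}, \code{total_epochs}.
#' @examples
#' stage_plan(c(200, 400, 600, 800), c(0.6, 0.7, 0.8, 0.9))
#' @export
stage_plan <- function(boundaries, ratios) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries) != length(ratios))
    stop_currimae("boundaries and ratios must have equal length", "plan_error")
  if (length(boundaries) < 1L || any(boundaries < 1L) || any(diff(boundaries) <= 0L))
    stop_currimae("boundaries must be strictly increasing positive epochs", "plan_error")
  if (any(ratios <= 0) || any(ratios >= 1) || any(diff(ratios) <= 0))
    stop_currimae("masking ratios must be strictly increasing within (0, 1)", "plan_error")
  structure(
    list(boundaries = boundaries, ratios = as.numeric(ratios),
         total_epochs = boundaries[length(boundaries)]),
    class = "stage_plan"
  )
}

#' @export
print.stage_plan <- function(x, ...) {
  starts <- c(1L, utils::head(x$boundaries, -1L) + 1L)
  cat(sprintf("<stage_plan: %d stages, %d epochs>\n",
              length(x$ratios), x$total_epochs))
  for (k in seq_along(x$ratios))
    cat(sprintf("  stage %d: epochs %d-%d, masking ratio %.0f%%\n",
                k, starts[k], x$boundaries[k], 100 * x$ratios[k]))
  invisible(x)
}

#' Fixed-epoch curriculum plan
#'
#' Divides \code{total_epochs} into equal-length stages, one per masking
#' ratio. The default reproduces the reference pretraining curriculum:
#' 800 epochs with ratios 60/70/80/90\% over 200-epoch stages.
#'
#' @param total_epochs total pretraining epochs; must be divisible by the
#'   number of ratios.
#' @param ratios strictly increasing masking ratios.
#' @return A \code{\link{stage_plan}}.
#' @export
fixed_stage_plan <- function(total_epochs = 800L, ratios = c(0.6, 0.7, 0.8, 0.9)) {
  k <- length(ratios)
  if (total_epochs %% k != 0L)
    stop_currimae("total_epochs must be divisible by the number of stages", "plan_error")
  stage_plan(seq_len(k) * (total_epochs %/% k), ratios)
}

#' Adaptive-epoch curriculum plan
#'
#' Stage boundaries are supplied directly, so harder (higher-ratio) stages
#' may receive more epochs. The default is the incremental schedule in which
#' each stage runs 50 epochs longer than the previous one: boundaries
#' 125/300/525/800, i.e. stage lengths 125, 175, 225, 275.
#'
#' @param boundaries strictly increasing cumulative epoch boundaries.
#' @param ratios strictly increasing masking ratios, one per stage.
#' @return A \code{\link{stage_plan}}.
#' @export
adaptive_stage_plan <- function(boundaries = c(125L, 300L, 525L, 800L),
                                ratios = c(0.6, 0.7, 0.8, 0.9)) {
  stage_plan(boundaries, ratios)
}

#' Stage lengths of a plan
#' @param plan a \code{\link{stage_plan}}.
#' @return integer vector of epochs per stage.
#' @export
stage_lengths <- function(plan) diff(c(0L, plan$boundaries))

stage_index_at <- function(plan, epoch) {
  if (epoch < 1L || epoch > plan$total_epochs)
    stop_currimae(sprintf("epoch %d outside [1, %d]", epoch, plan$total_epochs),
                  "range_error")
  # first boundary >= epoch; intervals are (b_{k-1}, b_k]
  which(plan$boundaries >= epoch)[1L]
}

#' Masking ratio in force at an epoch
#'
#' @param plan a \code{\link{stage_plan}}.
#' @param epoch 1-based epoch within \code{[1, total_epochs]}.
#' @return the stage's masking ratio.
#' @export
masking_ratio_at <- function(plan, epoch) plan$ratios[stage_index_at(plan, epoch)]

#' Snapshot epochs of a plan
#'
#' Snapshots are saved at the end of every stage, which coincides with the
#' end of every learning-rate cycle when cycles are stage-aligned; the count
#' equals the number of stages.
#'
#' @param plan a \code{\link{stage_plan}}.
#' @return integer vector of epochs at which snapshots are written.
#' @export
snapshot_epochs <- function(plan) plan$boundaries

#' Cyclic cosine learning rate with warm restarts
#'
#' Computes
#' \deqn{\alpha(t) = \frac{\alpha_0}{2}\left(\cos\!\left(\frac{\pi\,
#'   \mathrm{mod}(t-1, \lceil T/M\rceil)}{\lceil T/M\rceil}\right)+1\right)}
#' with cycle length \eqn{c = \lceil T/M\rceil}: the rate starts at
#' \eqn{\alpha_0}, decays along a half-cosine within each cycle, and resets
#' to \eqn{\alpha_0} at \eqn{t = kc + 1}.
#'
#' @param t current iteration, 1-based; vectorized.
#' @param total_iters total number of iterations \eqn{T}.
#' @param n_cycles number of cycles \eqn{M}, with \eqn{1 \le M \le T}.
#' @param alpha0 initial (peak) learning rate \eqn{\alpha_0 > 0}.
#' @return learning rate(s) in \eqn{(0, \alpha_0]}.
#' @examples
#' cyclic_cosine_lr(1, 800, 4, 1.5e-4)    # alpha0
#' cyclic_cosine_lr(401, 800, 4, 1.5e-4)  # restart: alpha0 again
#' @export
cyclic_cosine_lr <- function(t, total_iters, n_cycles, alpha0) {
  if (alpha0 <= 0) stop_currimae("alpha0 must be positive", "config_error")
  if (n_cycles < 1 || n_cycles > total_iters)
    stop_currimae("need 1 <= n_cycles <= total_iters", "config_error")
  if (any(t < 1) || any(t > total_iters))
    stop_currimae("iteration t outside [1, total_iters]", "range_error")
  cyc <- ceiling(total_iters / n_cycles)
  (alpha0 / 2) * (cos(pi * ((t - 1) %% cyc) / cyc) + 1)
}

# Stage-aligned generalization used for adaptive plans: each stage is one
# warm-restart cycle of its own (possibly unequal) length, restarting at
# alpha0. For equal-length stages this reduces exactly to cyclic_cosine_lr
# with M = number of stages.
stage_cosine_lr <- function(plan, t, iters_per_epoch, alpha0) {
  total <- plan$total_epochs * iters_per_epoch
  if (any(t < 1) || any(t > total))
    stop_currimae("iteration t outside the plan's horizon", "range_error")
  starts <- c(0L, utils::head(plan$boundaries, -1L)) * iters_per_epoch
  ends <- plan$boundaries * iters_per_epoch
  vapply(t, function(ti) {
    k <- which(ends >= ti)[1L]
    len <- ends[k] - starts[k]
    loc <- ti - starts[k]              # 1-based within the cycle
    (alpha0 / 2) * (cos(pi * (loc - 1) / len) + 1)
  }, numeric(1))
}

#' Export a schedule trace
#'
#' Tabulates iteration, learning rate and masking ratio over a whole
#' pretraining run, for plotting and audit.
#'
#' @param plan a \code{\link{stage_plan}}.
#' @param alpha0 peak learning rate.
#' @param iters_per_epoch optimizer iterations per epoch.
#' @return data.frame with columns \code{iteration}, \code{epoch},
#'   \code{lr}, \code{masking_ratio}.
#' @export
schedule_trace <- function(plan, alpha0, iters_per_epoch = 1L) {
  total <- plan$total_epochs * iters_per_epoch
  it <- seq_len(total)
  ep <- ceiling(it / iters_per_epoch)
  data.frame(
    iteration = it,
    epoch = ep,
    lr = stage_cosine_lr(plan, it, iters_per_epoch, alpha0),
    masking_ratio = plan$ratios[vapply(ep, function(e) stage_index_at(plan, e), 1L)]
  )
}
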