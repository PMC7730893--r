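#' Cyclic learning rate
#'
#' Within each cycle of `c` steps the rate descends linearly from `alpha1`
#' toward `alpha2` and then restarts: with `t(i) = (mod(i - 1, c) + 1) / c`,
#' the rate is `alpha(i) = (1 - t(i)) * alpha1 + t(i) * alpha2`. The rate
#' therefore always lies in `[alpha2, alpha1)`, reaches `alpha2` exactly at
#' the end of every cycle, and is periodic: `alpha(i + c) = alpha(i)`.
#'
#' @param i 1-based step index (vectorized).
#' @param alpha1 Upper learning rate at the start of a cycle (default 0.1).
#' @param alpha2 Lower rate reached at the cycle end; this is the rate at
#'   which weight snapshots are taken (default 0.05).
#' @param c Cycle length in steps (default 1).
#' @return Numeric vector of learning rates, one per entry of `i`.
#' @export
#' @examples
#' cyclic_lr(1:10, alpha1 = 0.1, alpha2 = 0.05, c = 5)
cyclic_lr <- function(i, alpha1 = 0.1, alpha2 = 0.05, c = 1) {
  if (any(i < 1)) stop("step index i must be >= 1")
  if (c < 1) stop("cycle length c must be >= 1")
  if (alpha1 < alpha2 || alpha2 <= 0) {
    stop("need alpha1 >= alpha2 > 0")
  }
  t <- ((i - 1) %% c + 1) / c
  (1 - t) * alpha1 + t * alpha2
}

#' Create an empty stochastic-weight-averaging state
#'
#' The state holds the running average of model weights and the number of
#' snapshots averaged so far. Together with the live model this is the
#' only weight set retained during training (two models in memory).
#'
#' @return Object of class `swa_state` with fields `avg` (`NULL` until the
#'   first update) and `n_models` (0).
#' @export
swa_state <- function() {
  structure(list(avg = NULL, n_models = 0L), class = "swa_state")
}

# elementwise running mean over arbitrarily nested lists of numerics
running_mean <- function(avg, w, n) {
  if (is.list(w)) {
    if (!is.list(avg) || length(avg) != length(w)) {
      stop("snapshot structure does not match the running average")
    }
    out <- mapply(running_mean, avg, w, MoreArgs = list(n = n),
                  SIMPLIFY = FALSE)
    names(out) <- names(w)
    return(out)
  }
  if (length(avg) != length(w)) stop("snapshot shape mismatch")
  (avg * n + w) / (n + 1)
}

#' Fold a weight snapshot into the running average
#'
#' Implements the running-mean update
#' `w_swa <- (w_swa * n_models + w) / (n_models + 1)`, so after `k` updates
#' the state holds the exact arithmetic mean of all `k` snapshots.
#'
#' @param state An [swa_state()].
#' @param w A weight snapshot: a numeric vector/array or a (nested) list of
#'   them, shape-compatible with previous snapshots.
#' @return The updated `swa_state`.
#' @export
swa_update <- function(state, w) {
  if (!inherits(state, "swa_state")) stop("state must be an swa_state")
  if (state$n_models == 0L) {
    state$avg <- w
  } else {
    state$avg <- running_mean(state$avg, w, state$n_models)
  }
  state$n_models <- state$n_models + 1L
  state
}

#' @export
print.swa_state <- function(x, ...) {
  cat("<swa_state> snapshots averaged:", x$n_models, "\n")
  invisible(x)
}
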