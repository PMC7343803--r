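#' Enumerate the reachable stimulus orientations
#'
#' Memory stimuli take one of three base orientations (15, 75, 135 degrees),
#' jittered by an integer number of degrees. With the default jitter range
#' of -10..+10 degrees this yields 63 distinct orientations, because the
#' bases are 60 degrees apart and the jitter windows never collide.
#'
#' @param bases base orientations in degrees.
#' @param jitter integer jitter values in degrees added to a base.
#' @return sorted integer vector of distinct orientations in `[0, 180)`.
#' @examples
#' length(enumerate_orientations()) # 63
#' @export
enumerate_orientations <- function(bases = c(15, 75, 135), jitter = -10:10) {
  stopifnot(all(jitter == round(jitter)))
  sort(unique(as.integer(outer(bases, jitter, `+`) %% 180)))
}

#' Generate a counterbalanced trial table
#'
#' Each run holds 24 trials forming the full factorial of condition
#' (remember-both `RB` vs remember-single `RS`), cued side (left/right),
#' and ordered base-orientation pair (6 ordered pairs from \{15, 75, 135\},
#' never the same base on both sides). Trial order is shuffled within run;
#' per-side jitters are drawn uniformly from `jitter`.
#'
#' @param n_runs number of runs (the study design uses 18).
#' @param seed integer seed; the same `(n_runs, seed)` always reproduces
#'   the same table.
#' @param bases base orientations in degrees.
#' @param jitter integer jitter values in degrees.
#' @return a `data.frame` of class `trial_table` with columns `run_id`,
#'   `trial_id`, `condition`, `cued_side`, `base_left`, `base_right`,
#'   `jitter_left`, `jitter_right`, `orient_left`, `orient_right`, `iti_ms`.
#' @export
generate_trial_table <- function(n_runs, seed, bases = c(15, 75, 135),
                                 jitter = -10:10) {
  if (length(n_runs) != 1L || !is.finite(n_runs) || n_runs < 1) {
    stop("`n_runs` must be a positive integer")
  }
  n_runs <- as.integer(n_runs)
  set.seed(as.integer(seed))
  pairs <- expand.grid(base_left = bases, base_right = bases)
  pairs <- pairs[pairs$base_left != pairs$base_right, , drop = FALSE]
  cells <- expand.grid(
    condition = c("RB", "RS"),
    cued_side = c("left", "right"),
    pair = seq_len(nrow(pairs)),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  n_tr <- nrow(cells) # 24
  runs <- lapply(seq_len(n_runs), function(r) {
    idx <- sample.int(n_tr)
    tab <- cells[idx, , drop = FALSE]
    data.frame(
      run_id = r,
      trial_id = (r - 1L) * n_tr + seq_len(n_tr),
      condition = tab$condition,
      cued_side = tab$cued_side,
      base_left = pairs$base_left[tab$pair],
      base_right = pairs$base_right[tab$pair],
      jitter_left = sample(jitter, n_tr, replace = TRUE),
      jitter_right = sample(jitter, n_tr, replace = TRUE),
      iti_ms = sample(c(1500, 4000, 6500), n_tr, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, runs)
  out$orient_left <- (out$base_left + out$jitter_left) %% 180
  out$orient_right <- (out$base_right + out$jitter_right) %% 180
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Trial epochs and the TR windows they average over
#'
#' BOLD responses are averaged over a few TRs per trial epoch. The second
#' delay and second test exist only on remember-both (RB) trials.
#'
#' @return `data.frame` with columns `name`, `tr_start`, `tr_end`,
#'   `applies_to`.
#' @export
epoch_spec <- function() {
  data.frame(
    name = c("stimulus", "delay1", "test1", "delay2", "test2"),
    tr_start = c(1L, 3L, 6L, 9L, 12L),
    tr_end = c(2L, 5L, 7L, 11L, 13L),
    applies_to = c("both", "both", "both", "RB", "RB"),
    stringsAsFactors = FALSE
  )
}

#' Label each item's working-memory state per trial and epoch
#'
#' Maps (condition, epoch, side) to the phenomenological state of the item
#' represented on that side:
#' \itemize{
#'   \item stimulus epoch: both items are perceived stimuli (`stim`).
#'   \item delay 1, RB: the first-cued item is `cued`, the other item is
#'     un-cued but needed later (`fut_rel`).
#'   \item delay 1, RS: the cued item is `cued`, the other may be dropped
#'     (`fut_irr`).
#'   \item delay 2 (RB only): the second-cued item is now `cued` and the
#'     already-tested first item is `fut_irr`.
#' }
#'
#' @param table a `trial_table`.
#' @param epochs epochs to label; subset of `c("stimulus","delay1","delay2")`.
#' @return long `data.frame` with one row per (trial, epoch, side):
#'   `trial_id`, `run_id`, `condition`, `epoch`, `side`, `item`
#'   (`RB-1`, `RB-2`, `RS-1`, `RS-0`), `state`, `orientation`, `base`.
#' @export
label_states <- function(table,
                         epochs = c("stimulus", "delay1", "delay2")) {
  stopifnot(inherits(table, "data.frame"))
  bad <- setdiff(unique(table$condition), c("RB", "RS"))
  if (length(bad)) {
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  }
  other <- function(s) ifelse(s == "left", "right", "left")
  rows <- list()
  for (ep in epochs) {
    for (side in c("left", "right")) {
      cued_here <- table$cued_side == side
      item <- ifelse(table$condition == "RB",
        ifelse(cued_here, "RB-1", "RB-2"),
        ifelse(cued_here, "RS-1", "RS-0")
      )
      state <- switch(ep,
        stimulus = rep("stim", nrow(table)),
        delay1 = ifelse(cued_here, "cued",
          ifelse(table$condition == "RB", "fut_rel", "fut_irr")
        ),
        delay2 = ifelse(table$condition == "RB",
          ifelse(cued_here, "fut_irr", "cued"), NA_character_
        ),
        stop("unknown epoch: ", ep)
      )
      keep <- !is.na(state)
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = table$trial_id[keep],
        run_id = table$run_id[keep],
        condition = table$condition[keep],
        epoch = ep,
        side = side,
        item = item[keep],
        state = state[keep],
        orientation = if (side == "left") table$orient_left[keep] else table$orient_right[keep],
        base = if (side == "left") table$base_left[keep] else table$base_right[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$trial_id, out$epoch, out$side), ]
  rownames(out) <- NULL
  out
}
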