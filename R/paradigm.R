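#' Construct a trial table
#'
#' A trial table is an ordered set of non-overlapping annotations describing a
#' block-design recording: task and rest trials plus optional fixation
#' periods. Onsets are seconds from the start of the block's recording.
#'
#' @param onset_s Numeric vector of trial onsets (seconds).
#' @param duration_s Numeric vector of trial durations (seconds, > 0).
#' @param condition Character vector; each entry one of `"task"`, `"rest"`,
#'   `"fixation"`.
#' @param block Character scalar or vector labelling the block (e.g.
#'   `"restricted"`, `"unrestricted"`, `"realistic"`).
#' @return A `data.frame` of class `trial_table`, sorted by onset.
#' @export
trial_table <- function(onset_s, duration_s, condition, block = "block") {
  tt <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   condition = as.character(condition),
                   block = as.character(block),
                   stringsAsFactors = FALSE)
  tt <- tt[order(tt$onset_s), , drop = FALSE]
  rownames(tt) <- NULL
  class(tt) <- c("trial_table", "data.frame")
  validate_trial_table(tt)
  tt
}

#' Validate trial table invariants
#'
#' Checks ordering, non-overlap, positive durations and known condition
#' labels; called by all consumers of trial tables.
#'
#' @param tt A `trial_table`.
#' @return `tt`, invisibly.
#' @export
validate_trial_table <- function(tt) {
  required <- c("onset_s", "duration_s", "condition", "block")
  missing <- setdiff(required, names(tt))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tt$condition), c("task", "rest", "fixation"))
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(tt$duration_s <= 0)) {
    stop("all trial durations must be > 0", call. = FALSE)
  }
  if (is.unsorted(tt$onset_s)) {
    stop("trial table entries must be sorted by onset", call. = FALSE)
  }
  if (nrow(tt) > 1) {
    ends <- tt$onset_s + tt$duration_s
    if (any(tt$onset_s[-1] < ends[-nrow(tt)] - 1e-9)) {
      stop("trial table entries must not overlap", call. = FALSE)
    }
  }
  invisible(tt)
}

#' Generate a block-design trial paradigm
#'
#' Two paradigm kinds are supported. `"training_block"` interleaves `n_task`
#' task trials and `n_rest` rest trials in seeded-shuffled order, each trial
#' lasting `trial_dur` seconds and consecutive trials separated by a
#' `fixation_dur`-second fixation cross (no trailing fixation).
#' `"realistic"` emulates continuous monitoring: three 210 s segments (3.5 min
#' rest, 3.5 min task, 3.5 min post-task rest) with no fixation.
#'
#' @param kind `"training_block"` or `"realistic"`.
#' @param n_task,n_rest Trial counts for a training block (>= 0, at least one
#'   trial in total); ignored for the realistic paradigm.
#' @param trial_dur Trial duration in seconds (> 0).
#' @param fixation_dur Fixation duration in seconds (>= 0; 0 disables
#'   fixation insertion).
#' @param seed Integer seed for the trial-order shuffle.
#' @param block Block label written into the table; defaults to `kind`.
#' @param segment_dur Segment duration (seconds) for the realistic paradigm.
#' @return A [trial_table()].
#' @examples
#' tt <- generate_paradigm("training_block", seed = 1)
#' table(tt$condition)
#' generate_paradigm("realistic")
#' @export
generate_paradigm <- function(kind = c("training_block", "realistic"),
                              n_task = 9, n_rest = 9, trial_dur = 30,
                              fixation_dur = 30, seed = 1L, block = NULL,
                              segment_dur = 210) {
  kind <- match.arg(kind)
  block <- block %||% kind
  if (kind == "realistic") {
    stop_if_not_scalar_number(segment_dur, "segment_dur", positive = TRUE)
    return(trial_table(onset_s = c(0, segment_dur, 2 * segment_dur),
                       duration_s = rep(segment_dur, 3),
                       condition = c("rest", "task", "rest"),
                       block = block))
  }
  if (!is_scalar_count(n_task) || !is_scalar_count(n_rest)) {
    stop("`n_task` and `n_rest` must be non-negative integers", call. = FALSE)
  }
  if (n_task + n_rest < 1) {
    stop("a training block needs at least one trial", call. = FALSE)
  }
  stop_if_not_scalar_number(trial_dur, "trial_dur", positive = TRUE)
  stop_if_not_scalar_number(fixation_dur, "fixation_dur")
  if (fixation_dur < 0) stop("`fixation_dur` must be >= 0", call. = FALSE)

  conditions <- c(rep("task", n_task), rep("rest", n_rest))
  if (length(conditions) > 1) {
    conditions <- with_seed(seed, sample(conditions))
  }
  n <- length(conditions)
  onset <- numeric(n)
  t0 <- 0
  rows <- vector("list", 2L * n - 1L)
  j <- 0L
  for (i in seq_len(n)) {
    j <- j + 1L
    rows[[j]] <- data.frame(onset_s = t0, duration_s = trial_dur,
                            condition = conditions[i], block = block,
                            stringsAsFactors = FALSE)
    t0 <- t0 + trial_dur
    if (i < n && fixation_dur > 0) {
      j <- j + 1L
      rows[[j]] <- data.frame(onset_s = t0, duration_s = fixation_dur,
                              condition = "fixation", block = block,
                              stringsAsFactors = FALSE)
      t0 <- t0 + fixation_dur
    }
  }
  tab <- do.call(rbind, rows[seq_len(j)])
  trial_table(tab$onset_s, tab$duration_s, tab$condition, tab$block)
}

#' Total span of a trial table in seconds
#' @param tt A `trial_table`.
#' @return Last trial end time (seconds from block start).
#' @export
trial_span <- function(tt) {
  validate_trial_table(tt)
  max(tt$onset_s + tt$duration_s)
}

#' Subset the task/rest trials of a trial table
#' @noRd
nonfixation_trials <- function(tt) {
  out <- tt[tt$condition %in% c("task", "rest"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
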