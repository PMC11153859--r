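#' @useDynLib valuelink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate approx coef cor density dnorm integrate pnorm
#'   pt qlogis plogis quantile rbinom rlnorm rnorm runif sd setNames simulate
#' @importFrom graphics arrows legend points
#' @importFrom utils modifyList read.csv write.csv
NULL

LEARN_CONDITIONS <- c("reward", "punishment", "zero")
SEARCH_CONDITIONS <- c("reward", "punishment", "zero", "absent")

#' Map condition labels to the integer coding used by the likelihood kernels
#'
#' Learning coding: reward = 1, punishment = 2, zero = 0 (zero-outcome trials
#' carry no feedback and are excluded from the learning likelihood). Search
#' coding: reward = 1, punishment = 2, zero = 3 (target-present conditions).
#'
#' @param condition character vector of condition labels.
#' @param model `"rl"` or `"ddm"`.
#' @return integer vector.
#' @keywords internal
condition_code <- function(condition, model = c("rl", "ddm")) {
  model <- match.arg(model)
  allowed <- if (model == "rl") LEARN_CONDITIONS else LEARN_CONDITIONS
  bad <- setdiff(unique(condition), allowed)
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  if (model == "rl") {
    c(reward = 1L, punishment = 2L, zero = 0L)[condition]
  } else {
    c(reward = 1L, punishment = 2L, zero = 3L)[condition]
  }
}

# Shuffle a vector of trial slots until no two consecutive entries share the
# same key, also respecting the key of the trial immediately before the block.
# Rejection resampling, capped.
resample_block <- function(keys, prev_key = NA_character_, max_tries = 10000L) {
  n <- length(keys)
  for (i in seq_len(max_tries)) {
    ord <- sample.int(n)
    k <- keys[ord]
    if (!is.na(prev_key) && k[1L] == prev_key) next
    if (n > 1L && any(k[-1L] == k[-n])) next
    return(ord)
  }
  stop("could not satisfy the no-consecutive-repeat constraint in ",
       max_tries, " attempts")
}

#' Generate the associative learning task schedule
#'
#' Builds the 300-trial main schedule: 10 blocks, each presenting each of the
#' 3 face pairs 10 times in pseudo-random order. The two faces of a pair sit
#' above/below fixation; `arrangement` flags which of the two layouts is shown
#' (1 = target above, 0 = target below). Ordering is rejection-resampled so no
#' two consecutive trials (including across block boundaries) show the same
#' pair in the same arrangement.
#'
#' @param seed non-negative integer seed; equal seeds give identical schedules.
#' @param condition_assignment named integer vector mapping each condition to
#'   a pair id; the default is one fixed counterbalancing assignment.
#' @param n_blocks,presentations_per_block design constants; defaults are the
#'   main-experiment values (10 blocks x 10 presentations per pair).
#' @param practice if `TRUE`, 30 practice trials (flagged `practice = TRUE`)
#'   are prepended; practice trials are excluded from analysis.
#' @return data.frame with columns `block`, `trial`, `pair_id`, `condition`,
#'   `arrangement`, `practice`.
#' @export
#' @examples
#' sched <- build_learning_schedule(seed = 1)
#' table(sched$condition, sched$block)
build_learning_schedule <- function(seed,
                                    condition_assignment = c(reward = 1L,
                                                             punishment = 2L,
                                                             zero = 3L),
                                    n_blocks = 10L,
                                    presentations_per_block = 10L,
                                    practice = FALSE) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0)
  stopifnot(setequal(names(condition_assignment), LEARN_CONDITIONS))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  pair_of <- condition_assignment
  cond_of_pair <- setNames(names(pair_of), as.character(pair_of))

  make_block <- function(block, prev_key) {
    pairs <- rep(unname(pair_of), each = presentations_per_block)
    for (redraw in 1:50) {
      # arrangements are balanced within block (each pair appears equally
      # often in both layouts), which also keeps the no-repeat constraint
      # easily satisfiable
      arr <- unlist(lapply(seq_along(pair_of), function(p) {
        sample(rep(c(0L, 1L), length.out = presentations_per_block))
      }))
      keys <- paste(pairs, arr)
      ord <- tryCatch(resample_block(keys, prev_key, max_tries = 2000L),
                      error = function(e) NULL)
      if (!is.null(ord)) {
        return(data.frame(block = block,
                          pair_id = pairs[ord],
                          condition = unname(
                            cond_of_pair[as.character(pairs[ord])]),
                          arrangement = arr[ord],
                          stringsAsFactors = FALSE))
      }
    }
    stop("could not satisfy the no-consecutive-repeat constraint")
  }

  blocks <- vector("list", n_blocks)
  prev_key <- NA_character_
  for (b in seq_len(n_blocks)) {
    blocks[[b]] <- make_block(b, prev_key)
    last <- blocks[[b]][nrow(blocks[[b]]), ]
    prev_key <- paste(last$pair_id, last$arrangement)
  }
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out))
  out$practice <- FALSE
  if (practice) {
    pr <- make_block(0L, NA_character_)
    pr <- pr[rep(seq_len(nrow(pr)), length.out = 30L), ]
    pr$trial <- -rev(seq_len(nrow(pr)))
    pr$practice <- TRUE
    out <- rbind(pr, out)
  }
  rownames(out) <- NULL
  out[, c("block", "trial", "pair_id", "condition", "arrangement", "practice")]
}

#' Generate the visual search task schedule
#'
#' Builds the 192-trial main schedule: 4 blocks of 48 trials, each with 24
#' target-present trials (8 per learning condition) and 24 target-absent
#' trials. Within each block every target appears exactly twice at each of the
#' four display positions, so over the experiment each target is presented 32
#' times, 8 per position. Ordering is rejection-resampled so no two
#' consecutive trials show the same target in the same position.
#'
#' @inheritParams build_learning_schedule
#' @param practice if `TRUE`, 24 practice trials are prepended.
#' @return data.frame with columns `block`, `trial`, `condition`
#'   (`"reward"`, `"punishment"`, `"zero"`, or `"absent"`), `target_id`
#'   (1..3, `NA` on absent trials), `target_position` (1..4, `NA` on absent
#'   trials), `practice`.
#' @export
build_search_schedule <- function(seed, n_blocks = 4L, practice = FALSE) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # target_id i is the target learned under condition LEARN_CONDITIONS[i]
  make_block <- function(block, prev_key) {
    present <- expand.grid(target_id = 1:3, target_position = 1:4,
                           dup = 1:2, KEEP.OUT.ATTRS = FALSE)
    present$condition <- LEARN_CONDITIONS[present$target_id]
    absent <- data.frame(target_id = NA_integer_, target_position = NA_integer_,
                         dup = NA_integer_, condition = "absent",
                         stringsAsFactors = FALSE)
    absent <- absent[rep(1L, 24L), ]
    blk <- rbind(present[, c("target_id", "target_position", "condition")],
                 absent[, c("target_id", "target_position", "condition")])
    keys <- ifelse(blk$condition == "absent", "absent",
                   paste(blk$target_id, blk$target_position))
    # absent trials never repeat a target/position pair; exclude them from the
    # adjacency key by making each unique
    keys[blk$condition == "absent"] <-
      paste0("absent", seq_len(sum(blk$condition == "absent")))
    ord <- resample_block(keys, prev_key)
    blk <- blk[ord, ]
    blk$block <- block
    blk
  }

  blocks <- vector("list", n_blocks)
  prev_key <- NA_character_
  for (b in seq_len(n_blocks)) {
    blocks[[b]] <- make_block(b, prev_key)
    last <- blocks[[b]][nrow(blocks[[b]]), ]
    prev_key <- if (last$condition == "absent") NA_character_ else
      paste(last$target_id, last$target_position)
  }
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out))
  out$practice <- FALSE
  if (practice) {
    pr <- make_block(0L, NA_character_)
    pr <- pr[seq_len(24L), ]
    pr$trial <- -rev(seq_len(nrow(pr)))
    pr$practice <- TRUE
    out <- rbind(pr, out)
  }
  rownames(out) <- NULL
  out[, c("block", "trial", "condition", "target_id", "target_position",
          "practice")]
}

#' Validate trial records against the task-design invariants
#'
#' Checks a data.frame of learning trials (columns `condition`,
#' `chose_target`, `outcome`) or search trials (columns `condition`,
#' `target_present`, `response`, `rt_sec`) and reports every violation:
#' outcome codes outside the condition's support, non-positive RTs,
#' inconsistent target-present flags. An unknown condition label is a hard
#' error naming the offending row.
#'
#' @param records data.frame of trial records.
#' @return data.frame with columns `row`, `field`, `problem`; zero rows means
#'   the records are valid.
#' @export
validate_trials <- function(records) {
  stopifnot(is.data.frame(records))
  kind <- if ("outcome" %in% names(records)) "learning"
          else if ("rt_sec" %in% names(records)) "search"
          else stop("records are neither learning trials (need 'outcome') ",
                    "nor search trials (need 'rt_sec')")
  allowed <- if (kind == "learning") LEARN_CONDITIONS else SEARCH_CONDITIONS
  bad <- which(!records$condition %in% allowed)
  if (length(bad)) {
    stop("unknown condition label '", records$condition[bad[1L]],
         "' in row ", bad[1L])
  }
  viol <- list()
  flag <- function(rows, field, problem) {
    if (length(rows)) {
      viol[[length(viol) + 1L]] <<- data.frame(row = rows, field = field,
                                               problem = problem)
    }
  }
  if (kind == "learning") {
    flag(which(!records$outcome %in% c(-1, 0, 1)), "outcome",
         "outcome not in {-1, 0, +1}")
    flag(which(records$condition == "zero" & records$outcome != 0), "outcome",
         "nonzero outcome in zero condition")
    flag(which(records$condition == "reward" & records$outcome == -1),
         "outcome", "punishment outcome in reward condition")
    flag(which(records$condition == "punishment" & records$outcome == 1),
         "outcome", "reward outcome in punishment condition")
    flag(which(!records$chose_target %in% c(0, 1, TRUE, FALSE)),
         "chose_target", "chose_target not boolean")
  } else {
    flag(which(!(records$rt_sec > 0)), "rt_sec", "rt <= 0")
    flag(which(!records$response %in% c("present", "absent")), "response",
         "response not present/absent")
    present <- records$condition != "absent"
    if ("target_present" %in% names(records)) {
      flag(which(present != (records$target_present %in% c(1, TRUE))),
           "target_present", "target_present inconsistent with condition")
    }
  }
  if (!length(viol)) {
    return(data.frame(row = integer(), field = character(),
                      problem = character()))
  }
  out <- do.call(rbind, viol)
  out[order(out$row), , drop = FALSE]
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
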