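#' Canonical stimulus interval sets
#'
#' The experiment uses two fixed sets of four intervals with identical first and
#' second moments (mean 700 ms, sample SD 294.39 ms), so that sequence
#' conditions differ only in temporal order, never in ensemble statistics.
#'
#' @param set_id 1 or 2.
#' @return Numeric vector of four durations in ms, ascending order.
#' @examples
#' interval_set(1)   # 400 500 900 1000
#' sd(interval_set(2))
#' @export
interval_set <- function(set_id) {
  sets <- list(c(400, 500, 900, 1000), c(400, 600, 700, 1100))
  if (length(set_id) != 1L || !set_id %in% c(1, 2)) {
    stop("`set_id` must be 1 or 2", call. = FALSE)
  }
  sets[[set_id]]
}

#' @rdname interval_set
#' @export
interval_sets <- function() list(`1` = interval_set(1), `2` = interval_set(2))

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. A NULL seed uses (and advances) the global
## stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`rng_seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## The 22 admissible random orders: all permutations of 4 positions except the
## fully ascending and fully descending ones.
rs_permutations <- function() {
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == 4L), , drop = FALSE]
  keep <- apply(perms, 1L, function(p) !(all(p == 1:4) || all(p == 4:1)))
  unname(perms[keep, , drop = FALSE])
}

#' Construct one presented sequence
#'
#' Orders a canonical interval set according to the sequence condition:
#' decelerating (`"DS"`) sequences run short to long, accelerating (`"AS"`)
#' sequences long to short, and random (`"RS"`) sequences take a uniformly
#' sampled permutation excluding both monotone orders (so they are never
#' confusable with the structured conditions).
#'
#' @param set_id 1 or 2, or a numeric vector of four positive durations (ms).
#' @param condition One of `"AS"`, `"DS"`, `"RS"`.
#' @param rng_seed Optional integer; when given, the RS draw is a pure function
#'   of the seed and the caller's RNG stream is left untouched.
#' @return Numeric vector of four durations in presented order.
#' @examples
#' build_sequence(1, "DS")            # 400 500 900 1000
#' build_sequence(1, "AS")            # 1000 900 500 400
#' build_sequence(2, "RS", rng_seed = 7)
#' @export
build_sequence <- function(set_id, condition, rng_seed = NULL) {
  intervals <- if (length(set_id) == 4L && is.numeric(set_id)) {
    if (any(set_id <= 0)) stop("intervals must be positive", call. = FALSE)
    sort(set_id)
  } else {
    interval_set(set_id)
  }
  if (length(condition) != 1L || !condition %in% CONDITIONS) {
    stop("unknown sequence condition: ", deparse(condition),
         " (expected one of \"AS\", \"DS\", \"RS\")", call. = FALSE)
  }
  switch(condition,
    DS = intervals,
    AS = rev(intervals),
    RS = with_local_seed(rng_seed, {
      perms <- rs_permutations()
      intervals[perms[sample.int(nrow(perms), 1L), ]]
    })
  )
}

#' Generate one participant's session of trials
#'
#' Builds the full 6-block session: 44 trials per block, 264 trials in total,
#' split into equal thirds per sequence condition (88 trials each) with the two
#' interval sets balanced 44/44 within condition, and the trial order shuffled.
#' Random-order trials draw their permutation uniformly from the 22 admissible
#' orders. The result is deterministic given the seed.
#'
#' @param participant_id Participant label.
#' @param rng_seed Integer seed for this participant's stream.
#' @param n_trials Total trial count; must be divisible by 6 (blocks) and 264
#'   by default.
#' @return Long-format data frame, one row per (trial, position):
#'   `participant_id`, `block`, `trial`, `condition`, `set_id`, `position`,
#'   `sample_ms`.
#' @examples
#' ses <- generate_session("s01", rng_seed = 11)
#' nrow(ses) / 4                      # 264 trials
#' @export
generate_session <- function(participant_id, rng_seed, n_trials = 264L) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 6L || n_trials %% 6L != 0L) {
    stop("`n_trials` must be a positive multiple of 6", call. = FALSE)
  }
  with_local_seed(rng_seed, {
    # As-balanced-as-possible allocation: conditions in (near-)equal thirds,
    # sets alternated within condition, then the whole order shuffled.
    cond <- rep(CONDITIONS, length.out = 3L * ceiling(n_trials / 3))[seq_len(n_trials)]
    cond <- sort(cond)
    sets <- unlist(lapply(CONDITIONS, function(cc) {
      m <- sum(cond == cc)
      rep(c(1L, 2L), length.out = m)
    }))
    ord <- sample.int(n_trials)
    cond <- cond[ord]
    sets <- sets[ord]
    perms <- rs_permutations()
    samples <- vapply(seq_len(n_trials), function(i) {
      iv <- interval_set(sets[i])
      switch(cond[i],
        DS = iv,
        AS = rev(iv),
        RS = iv[perms[sample.int(nrow(perms), 1L), ]]
      )
    }, numeric(4))                     # 4 x n_trials
    data.frame(
      participant_id = as.character(participant_id),
      block = rep(rep(seq_len(6L), each = n_trials / 6L), each = 4L),
      trial = rep(seq_len(n_trials), each = 4L),
      condition = rep(cond, each = 4L),
      set_id = rep(sets, each = 4L),
      position = rep(1:4, times = n_trials),
      sample_ms = as.vector(samples),
      stringsAsFactors = FALSE
    )
  })
}

#' Categorize reproduction accuracy for trial feedback
#'
#' Reproduces the three-band feedback rule: relative error
#' `e = (reproduced - sample) / sample` within \eqn{\pm}15% is `"accurate"`
#' (gray disk), between 15% and 50% in magnitude is `"moderate"` (yellow), and
#' beyond 50% is `"poor"` (red). Band edges belong to the inner band.
#'
#' @param sample_ms Positive sample duration(s), ms.
#' @param reproduced_ms Reproduced duration(s), ms.
#' @return Character vector in `{"accurate", "moderate", "poor"}`.
#' @examples
#' feedback_category(700, 700)    # accurate
#' feedback_category(1000, 1200)  # moderate
#' feedback_category(400, 640)    # poor
#' @export
feedback_category <- function(sample_ms, reproduced_ms) {
  if (any(!is.finite(sample_ms)) || any(sample_ms <= 0)) {
    stop("`sample_ms` must be positive", call. = FALSE)
  }
  e <- abs((reproduced_ms - sample_ms) / sample_ms)
  ifelse(e <= 0.15, "accurate", ifelse(e <= 0.50, "moderate", "poor"))
}
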