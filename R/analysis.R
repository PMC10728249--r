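## Per-trial reproduced-sequence means: one row per trial with its cell labels.
trial_means <- function(trials) {
  key <- paste(trials$participant_id, trials$trial, sep = "\r")
  first <- !duplicated(key)
  data.frame(
    participant_id = trials$participant_id[first],
    trial = trials$trial[first],
    condition = trials$condition[first],
    mean_ms = as.numeric(tapply(trials$reproduced_ms, factor(key, levels = key[first]),
                                mean)),
    stringsAsFactors = FALSE
  )
}

#' Exclude outlier trials
#'
#' Flags trials whose reproduced-sequence mean (the mean of the trial's four
#' reproduced intervals) deviates from its participant-by-condition cell by at
#' least twice the cell's standard deviation of those per-trial means
#' (population SD, single pass). Degenerate cells with zero spread exclude
#' nothing; empty cells pass through with a warning.
#'
#' @param trials Long-format trial table with `reproduced_ms`.
#' @param sd_mult Exclusion threshold in SD units (2 in the original analysis).
#' @return List with `trials` (kept rows), `n_excluded` (trial count) and
#'   `excluded` (the flagged trials' per-trial means).
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 2, master_seed = 1))
#' exclude_outliers(d)$n_excluded
#' @export
exclude_outliers <- function(trials, sd_mult = 2) {
  check_trials(trials)
  tm <- trial_means(trials)
  cell <- paste(tm$participant_id, tm$condition, sep = "\r")
  n_cell <- table(cell)
  if (any(n_cell < 2L)) {
    warning("cell(s) with fewer than 2 trials passed through untouched")
  }
  center <- stats::ave(tm$mean_ms, cell, FUN = mean)
  # population SD (1/n): the denominator used by the original Python pipeline
  spread <- stats::ave(tm$mean_ms, cell,
                       FUN = function(x) sqrt(mean((x - mean(x))^2)))
  out <- spread > 0 & abs(tm$mean_ms - center) >= sd_mult * spread &
    as.vector(n_cell[cell]) >= 2L
  bad_key <- paste(tm$participant_id[out], tm$trial[out], sep = "\r")
  row_key <- paste(trials$participant_id, trials$trial, sep = "\r")
  list(trials = trials[!row_key %in% bad_key, , drop = FALSE],
       n_excluded = sum(out),
       excluded = tm[out, , drop = FALSE])
}

## OLS of y on x, slope/intercept via lm.fit (exact OLS, no formula overhead).
ols_fit <- function(x, y) {
  fit <- stats::lm.fit(cbind(intercept = 1, slope = x), y)
  fit$coefficients
}

#' Central-tendency slopes
#'
#' For each participant and condition, regresses reproduced on sample intervals
#' (ordinary least squares, pooled over the four positions). Slopes below 1
#' quantify the central tendency bias; 1 means veridical reproduction. The
#' headline estimate (`group = "set_mean"`) fits one regression per interval
#' set and averages the two slopes, matching a design that treats interval set
#' as a factor; `"pooled"` fits a single regression across sets, and
#' `"per_set"` returns the set-level fits themselves.
#'
#' @param trials Post-exclusion trial table.
#' @param group `"set_mean"`, `"pooled"` or `"per_set"`.
#' @return Data frame with `participant_id`, `condition` (and `set_id` for
#'   `"per_set"`), `slope`, `intercept`, `n_points`.
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 2, master_seed = 1))
#' head(central_tendency_slope(d))
#' @export
central_tendency_slope <- function(trials,
                                   group = c("set_mean", "pooled", "per_set")) {
  check_trials(trials)
  group <- match.arg(group)
  by_set <- group != "pooled"
  keys <- if (by_set) {
    list(participant_id = trials$participant_id, condition = trials$condition,
         set_id = trials$set_id)
  } else {
    list(participant_id = trials$participant_id, condition = trials$condition)
  }
  idx <- split(seq_len(nrow(trials)), keys, drop = TRUE)
  rows <- lapply(idx, function(i) {
    x <- trials$sample_ms[i]
    y <- trials$reproduced_ms[i]
    if (length(unique(x)) < 2L) {
      stop("cannot fit a slope: fewer than 2 distinct sample intervals in a group",
           call. = FALSE)
    }
    cf <- ols_fit(x, y)
    data.frame(participant_id = trials$participant_id[i[1L]],
               condition = trials$condition[i[1L]],
               set_id = if (by_set) trials$set_id[i[1L]] else NA_integer_,
               slope = unname(cf["slope"]), intercept = unname(cf["intercept"]),
               n_points = length(i), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (group == "per_set") return(res)
  if (group == "pooled") { res$set_id <- NULL; return(res) }
  agg <- stats::aggregate(cbind(slope, intercept, n_points) ~ participant_id + condition,
                          data = res, FUN = mean)
  agg$n_points <- as.integer(round(agg$n_points * 2))  # total points across sets
  agg[order(agg$participant_id, agg$condition), , drop = FALSE]
}

#' Condition-level reproduction summaries
#'
#' Per participant and condition: the mean reproduced interval (pooling all
#' rows, i.e. trials then positions, across both interval sets) and, for the
#' variability analysis, the SD of reproductions per distinct sample interval
#' (sets pooled, giving the seven durations 400-1100 ms).
#'
#' @param trials Post-exclusion trial table.
#' @return List of two data frames: `means` (`participant_id`, `condition`,
#'   `mean_ms`, `sd_ms`) and `by_interval` (`participant_id`, `condition`,
#'   `sample_ms`, `mean_ms`, `sd_ms`).
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 2, master_seed = 1))
#' condition_means(d)$means
#' @export
condition_means <- function(trials) {
  check_trials(trials)
  means <- stats::aggregate(reproduced_ms ~ participant_id + condition,
                            data = trials,
                            FUN = mean)
  names(means)[names(means) == "reproduced_ms"] <- "mean_ms"
  sds <- stats::aggregate(reproduced_ms ~ participant_id + condition,
                          data = trials, FUN = stats::sd)
  means$sd_ms <- sds$reproduced_ms[match(
    paste(means$participant_id, means$condition),
    paste(sds$participant_id, sds$condition))]
  by_int <- stats::aggregate(reproduced_ms ~ participant_id + condition + sample_ms,
                             data = trials, FUN = mean)
  names(by_int)[names(by_int) == "reproduced_ms"] <- "mean_ms"
  by_int_sd <- stats::aggregate(reproduced_ms ~ participant_id + condition + sample_ms,
                                data = trials, FUN = stats::sd)
  by_int$sd_ms <- by_int_sd$reproduced_ms[match(
    paste(by_int$participant_id, by_int$condition, by_int$sample_ms),
    paste(by_int_sd$participant_id, by_int_sd$condition, by_int_sd$sample_ms))]
  list(means = means[order(means$participant_id, means$condition), ],
       by_interval = by_int[order(by_int$participant_id, by_int$condition,
                                  by_int$sample_ms), ])
}

#' Tag random sequences by their first or last interval
#'
#' Splits RS trials into `short` (< 700 ms), `middle` (= 700 ms; only interval
#' set 2 contains the 700-ms interval) and `long` (> 700 ms) according to the
#' interval at the chosen endpoint, so that downstream means and slopes can be
#' computed per tag (primacy analysis for the first interval, recency for the
#' last).
#'
#' @param trials Trial table containing only RS rows.
#' @param endpoint `"first"` or `"last"`.
#' @return `trials` with an added `endpoint_tag` column.
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 2, master_seed = 1))
#' rs <- d[d$condition == "RS", ]
#' table(categorize_rs_by_endpoint(rs, "last")$endpoint_tag)
#' @export
categorize_rs_by_endpoint <- function(trials, endpoint = c("first", "last")) {
  endpoint <- match.arg(endpoint)
  check_trials(trials, need_reproduced = FALSE)
  if (any(trials$condition != "RS")) {
    stop("endpoint categorization applies to RS trials only", call. = FALSE)
  }
  pos <- if (endpoint == "first") 1L else 4L
  key <- paste(trials$participant_id, trials$trial, sep = "\r")
  at <- trials$position == pos
  ep <- stats::setNames(trials$sample_ms[at], key[at])[key]
  trials$endpoint_tag <- ifelse(abs(ep - DESIGN_MEAN_MS) <= 1e-6, "middle",
                                ifelse(ep < DESIGN_MEAN_MS, "short", "long"))
  trials
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject F test with `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom, computed via [stats::aov()] with an `Error(participant)` stratum.
#' A descriptive utility for the behavioral summaries; it requires a balanced
#' participant-by-level table.
#'
#' @param data Data frame with columns `participant_id`, `level`, `value`, or
#'   a numeric matrix (participants in rows, factor levels in columns).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(2, 3, 5), c = c(4, 4, 6))
#' rm_anova_oneway(m)
#' @export
rm_anova_oneway <- function(data) {
  if (is.matrix(data)) {
    if (is.null(colnames(data))) colnames(data) <- paste0("l", seq_len(ncol(data)))
    data <- data.frame(
      participant_id = rep(seq_len(nrow(data)), times = ncol(data)),
      level = rep(colnames(data), each = nrow(data)),
      value = as.vector(data), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("participant_id", "level", "value") %in% names(data)))
  tab <- table(data$participant_id, data$level)
  if (any(tab != 1L)) {
    stop("design must be balanced: exactly one value per participant x level",
         call. = FALSE)
  }
  data$participant_id <- factor(data$participant_id)
  data$level <- factor(data$level)
  fit <- stats::aov(value ~ level + Error(participant_id), data = data)
  within <- summary(fit)[["Error: Within"]][[1L]]
  if (within["level", "Sum Sq"] <= .Machine$double.eps * sum(data$value^2)) {
    # no effect at all (possibly with zero residual too): report F = 0, p = 1
    return(list(F = 0, df1 = within["level", "Df"],
                df2 = within["Residuals", "Df"], p = 1))
  }
  list(F = within["level", "F value"],
       df1 = within["level", "Df"],
       df2 = within["Residuals", "Df"],
       p = within["level", "Pr(>F)"])
}

#' Run the full behavioral summary pipeline
#'
#' Convenience wrapper: outlier exclusion, headline central-tendency slopes,
#' condition means/SDs, and the first/last-interval analyses of the random
#' sequences (per-tag means and slopes).
#'
#' @param trials Long-format trial table.
#' @param exclude Apply the 2-SD outlier rule first?
#' @return List with `slopes`, `means` ([condition_means()] output), `endpoint`
#'   (per-tag RS summaries for both endpoints) and `n_excluded`.
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 3, master_seed = 1))
#' s <- analyze_reproduction(d)
#' aggregate(slope ~ condition, s$slopes, mean)
#' @export
analyze_reproduction <- function(trials, exclude = TRUE) {
  check_trials(trials)
  n_excluded <- 0L
  if (exclude) {
    ex <- exclude_outliers(trials)
    trials <- ex$trials
    n_excluded <- ex$n_excluded
  }
  rs <- trials[trials$condition == "RS", , drop = FALSE]
  endpoint <- lapply(c(first = "first", last = "last"), function(ep) {
    tagged <- categorize_rs_by_endpoint(rs, ep)
    idx <- split(seq_len(nrow(tagged)),
                 list(participant_id = tagged$participant_id,
                      tag = tagged$endpoint_tag), drop = TRUE)
    rows <- lapply(idx, function(i) {
      cf <- ols_fit(tagged$sample_ms[i], tagged$reproduced_ms[i])
      data.frame(participant_id = tagged$participant_id[i[1L]],
                 endpoint_tag = tagged$endpoint_tag[i[1L]],
                 mean_ms = mean(tagged$reproduced_ms[i]),
                 slope = unname(cf["slope"]),
                 n_points = length(i), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$participant_id, out$endpoint_tag), ]
  })
  list(slopes = central_tendency_slope(trials),
       means = condition_means(trials),
       endpoint = endpoint,
       n_excluded = n_excluded)
}
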