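#' @export
print.observer_fit <- function(x, digits = 3, ...) {
  ids <- names(x$params)
  cat("Two-stage Bayesian observer fit (", x$estimator, ")\n", sep = "")
  cat("  participants:", length(ids),
      " trials (post-exclusion):", length(unique(paste(x$data$participant_id,
                                                       x$data$trial))), "\n")
  cat("  group-mean parameters:\n")
  print(round(coef(x), digits))
  cat("  R^2 by condition:",
      paste(names(x$r2), format(unname(x$r2), digits = digits),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Extract fitted observer parameters
#'
#' @param object An `"observer_fit"`.
#' @param by_participant Return the participant-by-parameter matrix instead of
#'   group means?
#' @param ... Unused.
#' @return Named vector of group-mean estimates, or a matrix with one row per
#'   participant.
#' @export
coef.observer_fit <- function(object, by_participant = FALSE, ...) {
  est <- object$estimates
  pars <- unique(est$parameter)
  mat <- vapply(pars, function(p) {
    v <- est$estimate[est$parameter == p]
    stats::setNames(v, est$participant_id[est$parameter == p])
  }, numeric(length(unique(est$participant_id))))
  if (by_participant) return(mat)
  colMeans(mat)
}

#' Summarize a fitted observer model
#'
#' Group means with between-subject SDs for every parameter, per-condition
#' R-squared between predicted and observed interval-level means, exclusion
#' counts and convergence flags.
#'
#' @param object An `"observer_fit"`.
#' @param ... Unused.
#' @return An object of class `"summary.observer_fit"`.
#' @export
summary.observer_fit <- function(object, ...) {
  mat <- coef(object, by_participant = TRUE)
  tab <- data.frame(parameter = colnames(mat),
                    mean = colMeans(mat),
                    sd = apply(mat, 2L, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  conv1 <- vapply(object$stage1, `[[`, logical(1), "converged")
  conv2 <- vapply(object$stage2,
                  function(s) is.null(s) || isTRUE(s$converged), logical(1))
  structure(list(parameters = tab, r2 = object$r2,
                 n_participants = nrow(mat),
                 n_excluded = object$n_excluded,
                 estimator = object$estimator,
                 nonconverged = names(conv1)[!(conv1 & conv2)]),
            class = "summary.observer_fit")
}

#' @export
print.summary.observer_fit <- function(x, digits = 3, ...) {
  cat("Bayesian observer model, two-stage fit (", x$estimator, ")\n", sep = "")
  cat("Participants:", x$n_participants,
      "  outlier trials excluded:", x$n_excluded, "\n\n")
  cat("Group parameters (mean +/- between-subject SD):\n")
  tab <- x$parameters
  cat(paste0("  ", format(tab$parameter, width = 6), " ",
             format(round(tab$mean, digits)), " +/- ",
             format(round(tab$sd, digits)), collapse = "\n"), "\n\n")
  cat("R^2 (predicted vs observed interval means):\n")
  cat(paste0("  ", names(x$r2), " = ", format(round(x$r2, digits)),
             collapse = "\n"), "\n")
  if (length(x$nonconverged)) {
    cat("\nNon-converged participant(s):",
        paste(x$nonconverged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Model predictions for trial data
#'
#' Applies each participant's fitted parameters to `newdata` (default: the data
#' the model was fitted to), returning the table with the forward-model columns
#' `mu_e`, `w`, `R_pred` and `sigma_r` appended.
#'
#' @param object An `"observer_fit"`.
#' @param newdata Optional trial table; participants must have been fitted.
#' @param ... Unused.
#' @return Data frame.
#' @export
predict.observer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  predict_trials(object$params, newdata)
}

#' @export
residuals.observer_fit <- function(object, ...) {
  object$predictions$reproduced_ms - object$predictions$R_pred
}

#' @export
logLik.observer_fit <- function(object, ...) {
  ll <- sum(vapply(names(object$params), function(id) {
    observer_loglik(object$params[[id]],
                    object$data[object$data$participant_id == id, , drop = FALSE])
  }, numeric(1)))
  n_par <- nrow(object$estimates)
  structure(ll, df = n_par, nobs = nrow(object$data), class = "logLik")
}

#' Simulate reproduction data from a fitted model
#'
#' Parametric bootstrap: regenerates full sessions for the fitted participants
#' from their estimated parameters, using the same generative scheme as
#' [simulate_dataset()].
#'
#' @param object An `"observer_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer master seed.
#' @param n_trials Trials per participant in each replicate.
#' @param ... Unused.
#' @return A list of `nsim` trial tables.
#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = 1L,
                                  n_trials = 264L, ...) {
  ids <- names(object$params)
  lapply(seq_len(nsim), function(s) {
    tabs <- lapply(seq_along(ids), function(i) {
      cfg <- simulation_config(n_participants = 1L,
                               master_seed = (seed + s * 1000L + i) %% .Machine$integer.max,
                               truth = object$params[[ids[i]]],
                               n_trials = n_trials)
      d <- simulate_dataset(cfg)
      d$participant_id <- ids[i]
      d
    })
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  })
}

#' Plot observed versus predicted reproductions
#'
#' One panel per condition: mean observed (points, dashed line) and mean
#' predicted (solid line) reproduced duration per sample interval, averaged
#' across participants, with the identity line for reference.
#'
#' @param x An `"observer_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted means.
#' @export
plot.observer_fit <- function(x, ...) {
  pred <- x$predictions
  agg <- stats::aggregate(cbind(reproduced_ms, R_pred) ~ condition + sample_ms,
                          data = pred, FUN = mean)
  conds <- sort(unique(agg$condition))
  old <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(old))
  rng <- range(agg$sample_ms, agg$reproduced_ms, agg$R_pred)
  for (cc in conds) {
    a <- agg[agg$condition == cc, ]
    graphics::plot(a$sample_ms, a$reproduced_ms, xlim = rng, ylim = rng,
                   xlab = "sample interval (ms)",
                   ylab = "reproduced interval (ms)", main = cc, pch = 19, ...)
    graphics::lines(a$sample_ms, a$reproduced_ms, lty = 2)
    graphics::lines(a$sample_ms, a$R_pred, col = "steelblue", lwd = 2)
    graphics::abline(0, 1, col = "gray", lty = 3)
  }
  invisible(agg)
}
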