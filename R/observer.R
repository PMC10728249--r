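#' Observer model parameters
#'
#' Bundles the four quantities that define the Bayesian observer: the sensory
#' Weber fraction `wf_s` (scalar variability of interval measurement), the
#' prior Weber fraction `wf_p` (uncertainty of the ensemble prior, proportional
#' to its mean), the first-interval weight `alpha` (how strongly the first
#' interval pulls the ensemble mean away from the 700-ms design mean), and the
#' per-condition volatility factors `k` that inflate sensory variance for
#' sequences perceived as more irregular.
#'
#' Defaults are the group-level estimates reported for this paradigm
#' (`wf_s = 0.18`, `wf_p = 0.35`, `alpha = 0.195`,
#' `k = c(AS = 2, DS = 2.4, RS = 2.13)`), which also serve as the simulator's
#' default ground truth.
#'
#' @param wf_s Sensory Weber fraction, > 0.
#' @param wf_p Prior Weber fraction, > 0.
#' @param alpha First-interval weight in `[0, 1]`.
#' @param k Named numeric vector of volatility factors (> 0), one entry per
#'   modeled condition.
#' @return An object of class `"observer_params"`.
#' @examples
#' observer_params()
#' observer_params(wf_s = 0.1, alpha = 0)
#' @export
observer_params <- function(wf_s = 0.18, wf_p = 0.35, alpha = 0.195,
                            k = c(AS = 2, DS = 2.4, RS = 2.13)) {
  stopifnot(is.numeric(wf_s), length(wf_s) == 1L,
            is.numeric(wf_p), length(wf_p) == 1L,
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(k), length(k) >= 1L)
  if (!is.finite(wf_s) || wf_s <= 0) stop("`wf_s` must be > 0", call. = FALSE)
  if (!is.finite(wf_p) || wf_p <= 0) stop("`wf_p` must be > 0", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(k)) || any(!nzchar(names(k)))) {
    stop("`k` must be a named vector (names are condition codes)", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) stop("all `k` must be > 0", call. = FALSE)
  structure(list(wf_s = wf_s, wf_p = wf_p, alpha = alpha, k = k),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, digits = 3, ...) {
  cat("Observer parameters\n")
  cat("  wf_s (sensory Weber fraction):", format(x$wf_s, digits = digits), "\n")
  cat("  wf_p (prior Weber fraction):  ", format(x$wf_p, digits = digits), "\n")
  cat("  alpha (first-interval weight):", format(x$alpha, digits = digits), "\n")
  cat("  k (volatility):", paste(names(x$k), format(unname(x$k), digits = digits),
                                 sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Ensemble prior mean of a sequence
#'
#' The observer's internal summary of a sequence is a weighted average of its
#' first interval and the fixed design mean of the stimulus distribution:
#' `mu_e = alpha * D1 + anchor * (1 - alpha)`. The anchor is the 700-ms mean
#' shared by both canonical interval sets and is part of the design, not a free
#' parameter.
#'
#' @param alpha First-interval weight in `[0, 1]`.
#' @param d1 First presented interval, ms (> 0).
#' @param anchor Design mean, ms.
#' @return Prior mean in ms.
#' @examples
#' ensemble_prior(0.195, 400)   # 641.5
#' @export
ensemble_prior <- function(alpha, d1, anchor = DESIGN_MEAN_MS) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(d1)) || any(d1 <= 0)) stop("`d1` must be > 0", call. = FALSE)
  alpha * d1 + anchor * (1 - alpha)
}

#' Volatility-scaled sensory variance of an interval
#'
#' Scalar (Weber) variability inflated by the sequence's volatility factor:
#' `sigma_i^2 = k_j * (wf_s * D_i)^2`.
#'
#' @param wf_s Sensory Weber fraction (> 0).
#' @param k_j Volatility factor of the sequence type (> 0).
#' @param d_i Interval duration, ms (> 0).
#' @return Sensory variance in ms^2.
#' @examples
#' sensory_variance(0.1, 1, 1000)   # 10000
#' @export
sensory_variance <- function(wf_s, k_j, d_i) {
  if (any(!is.finite(wf_s)) || any(wf_s <= 0)) stop("`wf_s` must be > 0", call. = FALSE)
  if (any(!is.finite(k_j)) || any(k_j <= 0)) stop("`k_j` must be > 0", call. = FALSE)
  if (any(!is.finite(d_i)) || any(d_i <= 0)) stop("`d_i` must be > 0", call. = FALSE)
  k_j * (wf_s * d_i)^2
}

#' Reliability weight of the sensory measurement
#'
#' Precision-weighted fusion weight `w = sigma_e^2 / (sigma_e^2 + sigma_i^2)`,
#' the normalization of "w proportional to 1/sigma_i^2" that is consistent with
#' the posterior variance formula of the model: the sensory estimate dominates
#' (`w -> 1`) as its variance vanishes and is ignored (`w -> 0`) as it blows up.
#'
#' @param sigma_i2 Sensory variance (> 0), ms^2.
#' @param sigma_e2 Prior variance (> 0), ms^2.
#' @return Weight in (0, 1).
#' @examples
#' integration_weight(64800, 70490.25)   # ~0.521
#' @export
integration_weight <- function(sigma_i2, sigma_e2) {
  if (any(!is.finite(sigma_i2)) || any(sigma_i2 <= 0)) {
    stop("`sigma_i2` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(sigma_e2)) || any(sigma_e2 <= 0)) {
    stop("`sigma_e2` must be > 0", call. = FALSE)
  }
  sigma_e2 / (sigma_e2 + sigma_i2)
}

#' Expected reproduction of one interval
#'
#' Bayesian integration of ensemble mean and individual duration:
#' `R_i = (1 - w) * mu_e + w * D_i`. This convex combination is the source of
#' the central tendency bias: intervals shorter than the ensemble mean are
#' overestimated and longer ones underestimated.
#'
#' @param mu_e Prior mean, ms.
#' @param w Sensory weight in `[0, 1]`.
#' @param d_i Interval duration, ms.
#' @return Expected reproduced duration, ms.
#' @examples
#' reproduce_expected(641.5, 0.872, 400)   # ~430.9
#' @export
reproduce_expected <- function(mu_e, w, d_i) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  (1 - w) * mu_e + w * d_i
}

#' Reproduction standard deviation
#'
#' Posterior SD of the fusion, `sigma_r^2 = sigma_i^2 sigma_e^2 /
#' (sigma_i^2 + sigma_e^2)`; never larger than either source alone.
#'
#' @param sigma_i Sensory SD (> 0), ms.
#' @param sigma_e Prior SD (> 0), ms.
#' @return Reproduction SD, ms.
#' @examples
#' reproduction_sd(100, 100)   # 100 / sqrt(2)
#' @export
reproduction_sd <- function(sigma_i, sigma_e) {
  if (any(!is.finite(sigma_i)) || any(sigma_i <= 0)) stop("`sigma_i` must be > 0", call. = FALSE)
  if (any(!is.finite(sigma_e)) || any(sigma_e <= 0)) stop("`sigma_e` must be > 0", call. = FALSE)
  sqrt(sigma_i^2 * sigma_e^2 / (sigma_i^2 + sigma_e^2))
}

#' Forward model for one presented sequence
#'
#' Composes the model for a whole trial: the ensemble prior is formed from the
#' first presented interval (`mu_e`, with SD `sigma_e = wf_p * mu_e`), each
#' interval gets its volatility-scaled sensory variance, and every position is
#' reproduced as the precision-weighted fusion of prior and sensory estimate.
#' Pure function of its inputs.
#'
#' @param params An [observer_params()] object whose `k` has an entry for
#'   `condition`.
#' @param sample_ms Numeric vector of the presented intervals, in order.
#' @param condition Sequence condition code, e.g. `"AS"`.
#' @return A data frame with one row per position: `position`, `sample_ms`,
#'   `mu_e`, `sigma_e`, `sigma_i`, `w`, `R`, `sigma_r`.
#' @examples
#' predict_sequence(observer_params(), build_sequence(1, "AS"), "AS")
#' @export
predict_sequence <- function(params, sample_ms, condition) {
  stopifnot(inherits(params, "observer_params"))
  if (length(condition) != 1L || !condition %in% names(params$k)) {
    stop("no volatility factor for condition ", deparse(condition), call. = FALSE)
  }
  if (any(!is.finite(sample_ms)) || any(sample_ms <= 0)) {
    stop("all intervals must be positive (Weber scaling is undefined at 0)",
         call. = FALSE)
  }
  mu_e <- ensemble_prior(params$alpha, sample_ms[1L])
  sigma_e <- params$wf_p * mu_e
  sigma_i2 <- sensory_variance(params$wf_s, params$k[[condition]], sample_ms)
  w <- integration_weight(sigma_i2, sigma_e^2)
  data.frame(
    position = seq_along(sample_ms),
    sample_ms = sample_ms,
    mu_e = mu_e,
    sigma_e = sigma_e,
    sigma_i = sqrt(sigma_i2),
    w = w,
    R = reproduce_expected(mu_e, w, sample_ms),
    sigma_r = reproduction_sd(sqrt(sigma_i2), sigma_e)
  )
}

## Vectorized forward model over a long trial table. Requires columns
## condition, position, sample_ms and a trial key (participant_id + trial).
## Returns the table with mu_e, w, R_pred, sigma_r columns appended.
## `params` may be a single observer_params or a named list keyed by
## participant_id.
predict_trials <- function(params, trials) {
  check_trials(trials, need_reproduced = FALSE)
  key <- paste(trials$participant_id, trials$trial, sep = "\r")
  first <- trials$position == 1L
  d1 <- unname(stats::setNames(trials$sample_ms[first], key[first])[key])
  if (inherits(params, "observer_params")) {
    wf_s <- params$wf_s; wf_p <- params$wf_p; alpha <- params$alpha
    kvec <- params$k[trials$condition]
    if (anyNA(kvec)) stop("missing volatility factor for some condition", call. = FALSE)
  } else {
    stopifnot(is.list(params), !is.null(names(params)))
    pid <- as.character(trials$participant_id)
    missing_p <- setdiff(unique(pid), names(params))
    if (length(missing_p)) {
      stop("no parameters for participant(s): ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
    wf_s <- vapply(params, `[[`, numeric(1), "wf_s")[pid]
    wf_p <- vapply(params, `[[`, numeric(1), "wf_p")[pid]
    alpha <- vapply(params, `[[`, numeric(1), "alpha")[pid]
    kvec <- mapply(function(p, cc) p$k[[cc]], params[pid], trials$condition)
  }
  mu_e <- alpha * d1 + DESIGN_MEAN_MS * (1 - alpha)
  sigma_e2 <- (wf_p * mu_e)^2
  sigma_i2 <- kvec * (wf_s * trials$sample_ms)^2
  w <- sigma_e2 / (sigma_e2 + sigma_i2)
  trials$mu_e <- mu_e
  trials$w <- unname(w)
  trials$R_pred <- unname((1 - w) * mu_e + w * trials$sample_ms)
  trials$sigma_r <- unname(sqrt(sigma_i2 * sigma_e2 / (sigma_i2 + sigma_e2)))
  trials
}
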