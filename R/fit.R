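#' Trial-level log-likelihood of the observer model
#'
#' Sum over all (trial, position) rows of the Normal log-density of the
#' reproduced interval, with mean `R_i` and SD `sigma_r_i` from the forward
#' model. The likelihood is exchangeable over trials.
#'
#' @param params An [observer_params()] with `k` entries covering every
#'   condition present.
#' @param trials Long-format trial table with `reproduced_ms`.
#' @return Log-likelihood (scalar).
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 1))
#' observer_loglik(observer_params(), d)
#' @export
observer_loglik <- function(params, trials) {
  check_trials(trials)
  pred <- predict_trials(params, trials)
  if (any(pred$sigma_r <= 0) || any(!is.finite(pred$sigma_r))) {
    stop("non-finite likelihood: sigma_r must be strictly positive", call. = FALSE)
  }
  sum(stats::dnorm(trials$reproduced_ms, pred$R_pred, pred$sigma_r, log = TRUE))
}

#' Prior scales for model fitting
#'
#' Weakly informative, support-respecting priors: half-normal on the Weber
#' fractions and volatility factors, uniform(0, 1) on `alpha`. The sensory
#' Weber fraction's scale (0.15) encodes the 0.05-0.2 range typical of auditory
#' interval timing; this matters because the likelihood identifies `wf_s` and
#' the volatility factors only through the products `k_j * wf_s^2`, so the
#' `wf_s` prior fixes the overall scale (see the package vignette).
#'
#' @param wf_s_scale,wf_p_scale,k_scale Half-normal scale parameters.
#' @return Named list of scales.
#' @export
observer_priors <- function(wf_s_scale = 0.15, wf_p_scale = 0.5, k_scale = 3) {
  stopifnot(wf_s_scale > 0, wf_p_scale > 0, k_scale > 0)
  list(wf_s_scale = wf_s_scale, wf_p_scale = wf_p_scale, k_scale = k_scale)
}

## log prior density (unnormalized); alpha's uniform(0,1) contributes 0 inside
## its support, which the optimizer's box constraints enforce.
log_prior <- function(wf_s, wf_p, k, priors) {
  -wf_s^2 / (2 * priors$wf_s_scale^2) -
    wf_p^2 / (2 * priors$wf_p_scale^2) -
    sum(k^2) / (2 * priors$k_scale^2)
}

## MAP fit of (wf_s, wf_p, alpha, k[conds]) on one participant's trials.
## `fixed` optionally pins wf_s/wf_p/alpha (stage 2).
map_fit <- function(trials, conds, priors, fixed = NULL,
                    start = c(wf_s = 0.15, wf_p = 0.3, alpha = 0.2, k = 1.5)) {
  free_shared <- is.null(fixed)
  theta0 <- if (free_shared) {
    c(start[["wf_s"]], start[["wf_p"]], start[["alpha"]],
      rep(start[["k"]], length(conds)))
  } else {
    rep(start[["k"]], length(conds))
  }
  lower <- if (free_shared) c(1e-4, 1e-4, 0, rep(1e-4, length(conds)))
           else rep(1e-4, length(conds))
  upper <- if (free_shared) c(3, 3, 1, rep(30, length(conds)))
           else rep(30, length(conds))
  unpack <- function(theta) {
    if (free_shared) {
      observer_params(wf_s = theta[1L], wf_p = theta[2L], alpha = theta[3L],
                      k = stats::setNames(theta[-(1:3)], conds))
    } else {
      observer_params(wf_s = fixed$wf_s, wf_p = fixed$wf_p, alpha = fixed$alpha,
                      k = stats::setNames(theta, conds))
    }
  }
  negpost <- function(theta) {
    p <- unpack(theta)
    -(observer_loglik(p, trials) +
        log_prior(p$wf_s, p$wf_p, p$k[conds], priors))
  }
  opt <- stats::optim(theta0, negpost, method = "L-BFGS-B",
                      lower = lower, upper = upper, hessian = TRUE,
                      control = list(maxit = 500L))
  se <- rep(NA_real_, length(theta0))
  h <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(h, "try-error")) {
    v <- diag(h)
    se[v > 0] <- sqrt(v[v > 0])
  }
  pnames <- if (free_shared) c("wf_s", "wf_p", "alpha", paste0("k_", conds))
            else paste0("k_", conds)
  list(params = unpack(opt$par),
       estimate = stats::setNames(opt$par, pnames),
       se = stats::setNames(se, pnames),
       loglik = observer_loglik(unpack(opt$par), trials),
       converged = opt$convergence == 0L,
       diagnostics = list(optim_convergence = opt$convergence,
                          message = opt$message))
}

## MCMC fit via JAGS. Same model and priors; returns posterior means/SDs and
## the Gelman-Rubin R-hat per parameter.
jags_fit <- function(trials, conds, priors, fixed = NULL, seed = 1L,
                     draws = 1000L, chains = 2L, burnin = 500L) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("estimator = \"mcmc\" requires the rjags package; use \"map\" instead",
         call. = FALSE)
  }
  free_shared <- is.null(fixed)
  model_str <- paste0(
    "model {\n",
    "  for (n in 1:N) {\n",
    "    mu_e[n] <- alpha * d1[n] + 700 * (1 - alpha)\n",
    "    s2e[n] <- pow(wfp * mu_e[n], 2)\n",
    "    s2i[n] <- k[cond[n]] * pow(wfs * d[n], 2)\n",
    "    r[n] <- (s2i[n] * mu_e[n] + s2e[n] * d[n]) / (s2e[n] + s2i[n])\n",
    "    tau[n] <- (s2e[n] + s2i[n]) / (s2e[n] * s2i[n])\n",
    "    y[n] ~ dnorm(r[n], tau[n])\n",
    "  }\n",
    if (free_shared) paste0(
      "  wfs ~ dnorm(0, ", 1 / priors$wf_s_scale^2, ") T(1e-4,)\n",
      "  wfp ~ dnorm(0, ", 1 / priors$wf_p_scale^2, ") T(1e-4,)\n",
      "  alpha ~ dunif(0, 1)\n") else "",
    "  for (j in 1:J) { k[j] ~ dnorm(0, ", 1 / priors$k_scale^2, ") T(1e-4,) }\n",
    "}\n")
  key <- paste(trials$participant_id, trials$trial, sep = "\r")
  first <- trials$position == 1L
  d1 <- unname(stats::setNames(trials$sample_ms[first], key[first])[key])
  dat <- list(N = nrow(trials), J = length(conds),
              d = trials$sample_ms, d1 = d1,
              cond = match(trials$condition, conds),
              y = trials$reproduced_ms)
  if (!free_shared) {
    dat$wfs <- fixed$wf_s; dat$wfp <- fixed$wf_p; dat$alpha <- fixed$alpha
  }
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(k = rep(1 + 0.5 * ch, length(conds)),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed) + ch)
    if (free_shared) {
      ini$wfs <- 0.1 + 0.05 * ch; ini$wfp <- 0.3; ini$alpha <- 0.2
    }
    ini
  })
  monitor <- if (free_shared) c("wfs", "wfp", "alpha", "k") else "k"
  jm <- rjags::jags.model(textConnection(model_str), data = dat, inits = inits,
                          n.chains = chains, quiet = TRUE)
  stats::update(jm, burnin, progress.bar = "none")
  post <- rjags::coda.samples(jm, monitor, n.iter = draws, progress.bar = "none")
  mat <- do.call(rbind, lapply(post, as.matrix))
  nm <- colnames(mat)
  nm <- sub("^wfs$", "wf_s", nm)
  nm <- sub("^wfp$", "wf_p", nm)
  for (j in seq_along(conds)) nm <- sub(paste0("^k\\[", j, "\\]$"),
                                        paste0("k_", conds[j]), nm)
  colnames(mat) <- nm
  est <- colMeans(mat)
  se <- apply(mat, 2L, stats::sd)
  rhat <- rep(NA_real_, ncol(mat))
  if (chains > 1L && requireNamespace("coda", quietly = TRUE)) {
    gd <- try(coda::gelman.diag(post, autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1L]
  }
  ord <- if (free_shared) c("wf_s", "wf_p", "alpha", paste0("k_", conds))
         else paste0("k_", conds)
  est <- est[ord]; se <- se[ord]
  params <- if (free_shared) {
    observer_params(wf_s = est[["wf_s"]], wf_p = est[["wf_p"]],
                    alpha = est[["alpha"]],
                    k = stats::setNames(est[paste0("k_", conds)], conds))
  } else {
    observer_params(wf_s = fixed$wf_s, wf_p = fixed$wf_p, alpha = fixed$alpha,
                    k = stats::setNames(est[paste0("k_", conds)], conds))
  }
  converged <- all(is.na(rhat) | rhat < 1.05)
  list(params = params, estimate = est, se = se,
       loglik = observer_loglik(params, trials),
       converged = converged,
       diagnostics = list(rhat = stats::setNames(rhat, names(est)),
                          draws = draws, chains = chains))
}

#' Stage 1: fit the observer to the structured sequences
#'
#' Estimates `wf_s`, `wf_p`, `alpha`, `k_AS` and `k_DS` from one participant's
#' accelerating and decelerating trials. The default estimator is the maximum
#' a posteriori point (penalized likelihood, with a Laplace standard error);
#' `estimator = "mcmc"` samples the same posterior with JAGS and reports
#' posterior means, SDs and split-chain R-hat (fits with any R-hat > 1.05 are
#' flagged as non-converged, not silently accepted).
#'
#' @param trials One participant's trials; both AS and DS must be present.
#' @param estimator `"map"` or `"mcmc"`.
#' @param priors [observer_priors()].
#' @param seed Integer seed (MCMC chains; the MAP path is deterministic).
#' @param draws,chains,burnin MCMC settings.
#' @return List of class `"observer_stage_fit"`: `params`, `estimate`, `se`,
#'   `loglik`, `converged`, `diagnostics`, `stage`.
#' @export
fit_structured <- function(trials, estimator = c("map", "mcmc"),
                           priors = observer_priors(), seed = 1L,
                           draws = 1000L, chains = 2L, burnin = 500L) {
  estimator <- match.arg(estimator)
  check_trials(trials)
  trials <- trials[trials$condition %in% c("AS", "DS"), , drop = FALSE]
  if (!all(c("AS", "DS") %in% trials$condition)) {
    stop("stage 1 needs both AS and DS trials", call. = FALSE)
  }
  res <- if (estimator == "map") {
    map_fit(trials, conds = c("AS", "DS"), priors = priors)
  } else {
    jags_fit(trials, conds = c("AS", "DS"), priors = priors, seed = seed,
             draws = draws, chains = chains, burnin = burnin)
  }
  res$stage <- "structured"
  class(res) <- "observer_stage_fit"
  res
}

#' Stage 2: fit the random-sequence volatility factor
#'
#' Freezes `wf_s`, `wf_p` and `alpha` at their stage-1 point estimates and
#' estimates only `k_RS` from the participant's random-order trials.
#'
#' @param trials One participant's RS trials.
#' @param frozen The participant's stage-1 fit ([fit_structured()]).
#' @inheritParams fit_structured
#' @return List of class `"observer_stage_fit"` (stage `"rs"`); its `params`
#'   carry the frozen shared values plus all three `k` entries.
#' @export
fit_rs <- function(trials, frozen, estimator = c("map", "mcmc"),
                   priors = observer_priors(), seed = 1L,
                   draws = 1000L, chains = 2L, burnin = 500L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(frozen, "observer_stage_fit"))
  check_trials(trials)
  trials <- trials[trials$condition == "RS", , drop = FALSE]
  if (!nrow(trials)) stop("stage 2 needs RS trials", call. = FALSE)
  fixed <- list(wf_s = frozen$params$wf_s, wf_p = frozen$params$wf_p,
                alpha = frozen$params$alpha)
  res <- if (estimator == "map") {
    map_fit(trials, conds = "RS", priors = priors, fixed = fixed)
  } else {
    jags_fit(trials, conds = "RS", priors = priors, fixed = fixed, seed = seed,
             draws = draws, chains = chains, burnin = burnin)
  }
  res$params$k <- c(frozen$params$k[c("AS", "DS")], res$params$k)
  res$stage <- "rs"
  class(res) <- "observer_stage_fit"
  res
}

#' Coefficient of determination between predicted and observed reproductions
#'
#' Per participant and condition, the predicted and observed reproductions are
#' averaged per distinct sample interval (sets pooled); R-squared is the
#' squared Pearson correlation of those interval-level means, averaged across
#' participants within each condition.
#'
#' @param trials Trial table that already carries model predictions in
#'   `predicted_col` (e.g. the output of [predict.observer_fit()]).
#' @param predicted_col,observed_col Column names.
#' @return Named numeric vector, one R-squared per condition.
#' @export
goodness_r2 <- function(trials, predicted_col = "R_pred",
                        observed_col = "reproduced_ms") {
  stopifnot(predicted_col %in% names(trials), observed_col %in% names(trials))
  agg <- stats::aggregate(trials[, c(predicted_col, observed_col)],
                          by = list(participant_id = trials$participant_id,
                                    condition = trials$condition,
                                    sample_ms = trials$sample_ms),
                          FUN = mean)
  idx <- split(seq_len(nrow(agg)),
               list(agg$participant_id, agg$condition), drop = TRUE)
  r2 <- vapply(idx, function(i) {
    p <- agg[[predicted_col]][i]; o <- agg[[observed_col]][i]
    if (stats::sd(p) == 0 || stats::sd(o) == 0) {
      stop("R^2 undefined for constant predicted or observed means", call. = FALSE)
    }
    stats::cor(p, o)^2
  }, numeric(1))
  cond <- vapply(idx, function(i) agg$condition[i[1L]], character(1))
  out <- tapply(r2, cond, mean)
  out[sort(unique(cond))]
}

#' Fit the Bayesian observer model
#'
#' The package's main fitting function. Runs the two-stage protocol
#' independently for every participant in the data: stage 1 estimates the
#' shared parameters (`wf_s`, `wf_p`, `alpha`) together with the structured
#' sequences' volatility factors (`k_AS`, `k_DS`); stage 2 freezes the shared
#' parameters at their stage-1 point estimates and fits `k_RS` to the
#' random-order trials. Outlier trials are removed with the 2-SD rule first
#' (disable with `exclude = FALSE`).
#'
#' @param data Long-format trial table (see [read_trials()]) or the output of
#'   [simulate_dataset()].
#' @param estimator `"map"` (default; deterministic penalized-likelihood point
#'   estimates with Laplace SEs) or `"mcmc"` (JAGS posterior means).
#' @param priors [observer_priors()].
#' @param seed Integer seed used for the MCMC chains.
#' @param draws,chains,burnin MCMC settings, ignored for `"map"`.
#' @param exclude Apply outlier exclusion before fitting?
#' @return An object of class `"observer_fit"`; see [summary.observer_fit()],
#'   [coef.observer_fit()], [predict.observer_fit()],
#'   [simulate.observer_fit()], [plot.observer_fit()].
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 2, master_seed = 1,
#'                                         n_trials = 66))
#' fit <- fit_observer(d)
#' coef(fit)
#' @export
fit_observer <- function(data, estimator = c("map", "mcmc"),
                         priors = observer_priors(), seed = 1L,
                         draws = 1000L, chains = 2L, burnin = 500L,
                         exclude = TRUE) {
  estimator <- match.arg(estimator)
  check_trials(data)
  n_excluded <- 0L
  if (exclude) {
    ex <- exclude_outliers(data)
    data <- ex$trials
    n_excluded <- ex$n_excluded
  }
  ids <- unique(as.character(data$participant_id))
  stage1 <- list(); stage2 <- list(); params <- list()
  for (id in ids) {
    tr <- data[data$participant_id == id, , drop = FALSE]
    s1 <- fit_structured(tr, estimator = estimator, priors = priors,
                         seed = seed, draws = draws, chains = chains,
                         burnin = burnin)
    s2 <- if (any(tr$condition == "RS")) {
      fit_rs(tr, s1, estimator = estimator, priors = priors, seed = seed + 1L,
             draws = draws, chains = chains, burnin = burnin)
    } else NULL
    stage1[[id]] <- s1
    stage2[[id]] <- s2
    params[[id]] <- if (is.null(s2)) s1$params else s2$params
  }
  est_rows <- do.call(rbind, lapply(ids, function(id) {
    e1 <- stage1[[id]]$estimate; se1 <- stage1[[id]]$se
    rows <- data.frame(participant_id = id, stage = "structured",
                       parameter = names(e1), estimate = unname(e1),
                       se = unname(se1), stringsAsFactors = FALSE)
    if (!is.null(stage2[[id]])) {
      e2 <- stage2[[id]]$estimate; se2 <- stage2[[id]]$se
      rows <- rbind(rows, data.frame(participant_id = id, stage = "rs",
                                     parameter = names(e2),
                                     estimate = unname(e2), se = unname(se2),
                                     stringsAsFactors = FALSE))
    }
    rows
  }))
  pred <- predict_trials(params, data)
  r2 <- goodness_r2(pred)
  structure(list(estimates = est_rows, params = params,
                 stage1 = stage1, stage2 = stage2,
                 r2 = r2, data = data, predictions = pred,
                 n_excluded = n_excluded,
                 estimator = estimator, priors = priors, seed = seed,
                 call = match.call()),
            class = "observer_fit")
}

#' Parameter-recovery study
#'
#' Simulates replicate datasets at known ground truth, refits each with the
#' two-stage procedure, and reports the recovered group-mean parameters and
#' their relative errors — the standard check that the estimation pipeline can
#' recover the generating process at the study's scale.
#'
#' @param truth Generating [observer_params()].
#' @param n_replicates Number of replicate datasets.
#' @param n_participants,n_trials Study size per replicate.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param estimator Passed to [fit_observer()].
#' @param ... Passed to [fit_observer()].
#' @return Data frame, one row per replicate x parameter: `replicate`,
#'   `parameter`, `truth`, `recovered` (group mean), `rel_error`.
#' @examples
#' rec <- parameter_recovery(n_replicates = 1, n_participants = 2,
#'                           n_trials = 66, seed = 3)
#' rec
#' @export
parameter_recovery <- function(truth = observer_params(), n_replicates = 20L,
                               n_participants = 15L, n_trials = 264L,
                               seed = 1L, estimator = "map", ...) {
  true_vec <- c(wf_s = truth$wf_s, wf_p = truth$wf_p, alpha = truth$alpha,
                stats::setNames(unname(truth$k), paste0("k_", names(truth$k))))
  out <- lapply(seq_len(n_replicates), function(r) {
    d <- simulate_dataset(simulation_config(n_participants = n_participants,
                                            master_seed = seed + r,
                                            truth = truth,
                                            n_trials = n_trials))
    fit <- fit_observer(d, estimator = estimator, seed = seed + r, ...)
    grp <- stats::aggregate(estimate ~ parameter, data = fit$estimates,
                            FUN = mean)
    keep <- intersect(names(true_vec), grp$parameter)
    data.frame(replicate = r, parameter = keep,
               truth = unname(true_vec[keep]),
               recovered = grp$estimate[match(keep, grp$parameter)],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$rel_error <- (res$recovered - res$truth) / res$truth
  rownames(res) <- NULL
  res
}
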