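#' Configuration for the synthetic-data generator
#'
#' Describes one simulated study: number of participants (15, the scale of the
#' original experiment), trials per participant (264), a master seed from which
#' per-participant streams are spawned, and the generating ("truth")
#' parameters — either one [observer_params()] shared by all participants, or a
#' population mean plus between-subject SDs from which per-participant
#' parameters are drawn (truncated to each parameter's support).
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param master_seed Integer master seed.
#' @param truth [observer_params()] ground truth (population mean when
#'   `truth_sd` is given).
#' @param truth_sd Optional [observer_params()]-shaped list of between-subject
#'   SDs (`wf_s`, `wf_p`, `alpha`, `k`); `NULL` fixes all participants at
#'   `truth`. SDs of 0 are allowed.
#' @param n_trials Trials per participant (multiple of 6).
#' @return An object of class `"simulation_config"`.
#' @examples
#' simulation_config(n_participants = 3, master_seed = 1)
#' @export
simulation_config <- function(n_participants = 15L, master_seed = 1L,
                              truth = observer_params(), truth_sd = NULL,
                              n_trials = 264L) {
  stopifnot(inherits(truth, "observer_params"))
  n_participants <- as.integer(n_participants)
  if (n_participants < 1L) stop("`n_participants` must be >= 1", call. = FALSE)
  if (!is.null(truth_sd)) {
    stopifnot(is.list(truth_sd),
              all(c("wf_s", "wf_p", "alpha", "k") %in% names(truth_sd)))
    sds <- c(truth_sd$wf_s, truth_sd$wf_p, truth_sd$alpha, truth_sd$k)
    if (any(!is.finite(sds)) || any(sds < 0)) {
      stop("population SDs must be >= 0", call. = FALSE)
    }
  }
  structure(list(n_participants = n_participants,
                 master_seed = as.integer(master_seed),
                 truth = truth, truth_sd = truth_sd,
                 n_trials = as.integer(n_trials)),
            class = "simulation_config")
}

## Exact truncated-normal draw via inverse-CDF; lower/upper may be infinite.
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  q <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)
}

#' Draw one participant's parameters from a population
#'
#' Independent truncated-normal draws around the population mean, respecting
#' each parameter's support: Weber fractions and volatility factors are
#' truncated below at 0 (exclusive in practice: the inverse-CDF draw never
#' returns the bound for positive SD), and `alpha` at `[0, 1]`. Zero SDs return
#' the mean exactly.
#'
#' @param pop_mean Population mean, an [observer_params()].
#' @param pop_sd List of SDs with entries `wf_s`, `wf_p`, `alpha`, `k` (the `k`
#'   entry may be a single SD or one per condition).
#' @param seed Optional integer seed (local; does not disturb the caller's RNG
#'   stream).
#' @return An [observer_params()].
#' @examples
#' population_draw(observer_params(),
#'                 list(wf_s = 0.09, wf_p = 0.03, alpha = 0.07,
#'                      k = c(AS = 1.2, DS = 1.4, RS = 0.17)),
#'                 seed = 42)
#' @export
population_draw <- function(pop_mean, pop_sd, seed = NULL) {
  stopifnot(inherits(pop_mean, "observer_params"))
  k_sd <- rep(unlist(pop_sd$k), length.out = length(pop_mean$k))
  with_local_seed(seed, {
    wf_s <- rtruncnorm1(1L, pop_mean$wf_s, pop_sd$wf_s, lower = 1e-6)
    wf_p <- rtruncnorm1(1L, pop_mean$wf_p, pop_sd$wf_p, lower = 1e-6)
    alpha <- rtruncnorm1(1L, pop_mean$alpha, pop_sd$alpha, lower = 0, upper = 1)
    k <- vapply(seq_along(pop_mean$k), function(i) {
      rtruncnorm1(1L, pop_mean$k[[i]], k_sd[[i]], lower = 1e-6)
    }, numeric(1))
    names(k) <- names(pop_mean$k)
    observer_params(wf_s = wf_s, wf_p = wf_p, alpha = alpha, k = k)
  })
}

#' Simulate a trial-level reproduction dataset
#'
#' Generates each participant's session with [generate_session()], runs the
#' forward observer model, and draws every reproduced interval independently
#' from `Normal(R_i, sigma_r_i)` — the model's posterior mean and SD for that
#' position. Draws are truncated at 0 by resampling (no point mass at zero).
#' The master seed deterministically spawns one stream per participant, so the
#' whole table is a pure function of the configuration.
#'
#' @param cfg A [simulation_config()].
#' @return Long-format data frame (schema of [generate_session()] plus
#'   `reproduced_ms`), with attributes `truth` (per-participant
#'   [observer_params()]) and `seeds` (per-participant seeds).
#' @examples
#' d <- simulate_dataset(simulation_config(n_participants = 2, master_seed = 7))
#' head(d)
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_local_seed(cfg$master_seed, {
    seeds <- sample.int(.Machine$integer.max, cfg$n_participants * 2L)
    session_seeds <- seeds[seq_len(cfg$n_participants)]
    noise_seeds <- seeds[cfg$n_participants + seq_len(cfg$n_participants)]
    ids <- sprintf("p%02d", seq_len(cfg$n_participants))
    truth <- vector("list", cfg$n_participants)
    names(truth) <- ids
    out <- vector("list", cfg$n_participants)
    for (i in seq_len(cfg$n_participants)) {
      truth[[i]] <- if (is.null(cfg$truth_sd)) cfg$truth else {
        population_draw(cfg$truth, cfg$truth_sd, seed = session_seeds[i] %% 1000003L)
      }
      ses <- generate_session(ids[i], rng_seed = session_seeds[i],
                              n_trials = cfg$n_trials)
      ses <- predict_trials(truth[[i]], ses)
      ses$reproduced_ms <- with_local_seed(noise_seeds[i], {
        r <- stats::rnorm(nrow(ses), ses$R_pred, ses$sigma_r)
        bad <- which(r <= 0)
        while (length(bad)) {       # resample, never clip: keeps density smooth
          r[bad] <- stats::rnorm(length(bad), ses$R_pred[bad], ses$sigma_r[bad])
          bad <- bad[r[bad] <= 0]
        }
        r
      })
      out[[i]] <- ses[, c("participant_id", "block", "trial", "condition",
                          "set_id", "position", "sample_ms", "reproduced_ms")]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "truth") <- truth
    attr(res, "seeds") <- list(master = cfg$master_seed,
                               session = session_seeds, noise = noise_seeds)
    res
  })
}
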