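test_that("log-likelihood equals hand-summed normal densities", {
  p <- truth_params()
  d <- toy_trials(1, condition = "AS", sample = c(1000, 900, 500, 400))
  d$reproduced_ms <- c(850, 820, 560, 470)
  # oracle: explicit normal log-densities from the worked forward pass
  pred <- predict_sequence(p, c(1000, 900, 500, 400), "AS")
  manual <- sum(-0.5 * log(2 * pi * pred$sigma_r^2) -
                  (d$reproduced_ms - pred$R)^2 / (2 * pred$sigma_r^2))
  expect_equal(observer_loglik(p, d), manual, tolerance = 1e-9)
})

test_that("log-likelihood is additive and exchangeable over trials", {
  p <- truth_params()
  d <- small_sim()
  one <- d[d$participant_id == "p01", ]
  ll <- observer_loglik(p, one)
  doubled <- rbind(one, transform(one, trial = trial + 1000L))
  expect_equal(observer_loglik(p, doubled), 2 * ll, tolerance = 1e-9)
  shuffled <- one[sample(nrow(one)), ]
  expect_equal(observer_loglik(p, shuffled), ll, tolerance = 1e-9)
})

test_that("likelihood peaks at the generating parameters", {
  d <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 11))
  truth <- truth_params()
  ll_true <- observer_loglik(truth, d)
  for (fac in c(0.5, 1.5)) {
    pert <- observer_params(wf_s = truth$wf_s * fac, wf_p = truth$wf_p * fac,
                            alpha = min(1, truth$alpha * fac),
                            k = truth$k * fac)
    expect_gt(ll_true, observer_loglik(pert, d))
  }
})

test_that("stage 1 recovers the identified parameter combinations", {
  d <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 21))
  one <- d[d$participant_id == "p01", ]
  fit <- fit_structured(one)
  expect_s3_class(fit, "observer_stage_fit")
  expect_true(fit$converged)
  truth <- truth_params()
  # the likelihood identifies k_j * wf_s^2, wf_p and alpha
  expect_equal(fit$params$k[["AS"]] * fit$params$wf_s^2,
               truth$k[["AS"]] * truth$wf_s^2, tolerance = 0.2)
  expect_equal(fit$params$k[["DS"]] * fit$params$wf_s^2,
               truth$k[["DS"]] * truth$wf_s^2, tolerance = 0.2)
  expect_equal(fit$params$wf_p, truth$wf_p, tolerance = 0.2)
  expect_equal(fit$params$alpha, truth$alpha, tolerance = 0.35)
  expect_error(fit_structured(one[one$condition == "AS", ]), "both AS and DS")
})

test_that("stage 2 freezes the shared parameters bit-for-bit", {
  d <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 22))
  one <- d[d$participant_id == "p01", ]
  s1 <- fit_structured(one)
  before <- unlist(s1$params[c("wf_s", "wf_p", "alpha")])
  s2 <- fit_rs(one, s1)
  expect_identical(unlist(s2$params[c("wf_s", "wf_p", "alpha")]), before)
  expect_identical(unlist(s1$params[c("wf_s", "wf_p", "alpha")]), before)
  expect_named(s2$estimate, "k_RS")
  truth <- truth_params()
  expect_equal(s2$params$k[["RS"]] * s2$params$wf_s^2,
               truth$k[["RS"]] * truth$wf_s^2, tolerance = 0.25)
})

test_that("the RS likelihood profile over k is unimodal", {
  d <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 23))
  rs <- d[d$condition == "RS", ]
  truth <- truth_params()
  grid <- seq(0.3, 8, by = 0.1)
  prof <- vapply(grid, function(k) {
    observer_loglik(observer_params(wf_s = truth$wf_s, wf_p = truth$wf_p,
                                    alpha = truth$alpha, k = c(RS = k)), rs)
  }, numeric(1))
  signs <- sign(diff(prof))
  expect_equal(sum(diff(signs) != 0), 1)   # rises once, falls once
})

test_that("a zero first-interval weight is recovered as (near) zero", {
  null_truth <- observer_params(wf_s = 0.18, wf_p = 0.35, alpha = 0,
                                k = c(AS = 2, DS = 2.4, RS = 2.13))
  d <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 31,
                                          truth = null_truth))
  fit <- fit_structured(d[d$participant_id == "p01", ])
  a <- fit$estimate[["alpha"]]
  se <- fit$se[["alpha"]]
  expect_lt(a - 2 * max(se, 0.02, na.rm = TRUE), 0)
  expect_lt(a, 0.1)
})

test_that("R^2 scoring matches hand-computed correlations", {
  d <- toy_trials(rep(1, 1))
  d$reproduced_ms <- d$sample_ms
  d$R_pred <- d$sample_ms
  expect_equal(unname(goodness_r2(d)), 1, tolerance = 1e-12)
  o <- c(450, 540, 820, 880)
  p <- c(470, 520, 790, 900)
  d$reproduced_ms <- o
  d$R_pred <- p
  num <- sum((o - mean(o)) * (p - mean(p)))
  r2_manual <- num^2 / (sum((o - mean(o))^2) * sum((p - mean(p))^2))
  expect_equal(unname(goodness_r2(d)), r2_manual, tolerance = 1e-9)
  d$R_pred <- 700
  expect_error(goodness_r2(d), "constant")
})

test_that("fit_observer assembles the two-stage fit across participants", {
  d <- simulate_dataset(simulation_config(n_participants = 2, master_seed = 41,
                                          n_trials = 132))
  fit <- fit_observer(d)
  expect_s3_class(fit, "observer_fit")
  expect_setequal(unique(fit$estimates$parameter),
                  c("wf_s", "wf_p", "alpha", "k_AS", "k_DS", "k_RS"))
  expect_equal(sort(names(fit$params)), c("p01", "p02"))
  expect_named(fit$r2, c("AS", "DS", "RS"))
  expect_true(all(fit$r2 <= 1))
  # restricted model (k frozen at 1) fits simulated volatile data worse
  restr <- observer_params(wf_s = coef(fit)[["wf_s"]],
                           wf_p = coef(fit)[["wf_p"]],
                           alpha = coef(fit)[["alpha"]],
                           k = c(AS = 1, DS = 1, RS = 1))
  one <- fit$data[fit$data$participant_id == "p01", ]
  expect_gt(observer_loglik(fit$params$p01, one), observer_loglik(restr, one))
})

test_that("MCMC estimation agrees with the MAP point on the same data", {
  d <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 51,
                                          n_trials = 66))
  one <- d[d$participant_id == "p01", ]
  map <- fit_structured(one, estimator = "map")
  mc <- fit_structured(one, estimator = "mcmc", seed = 2, draws = 400L,
                       chains = 2L, burnin = 300L)
  expect_true(all(is.finite(mc$estimate)))
  expect_true(all(is.finite(mc$diagnostics$rhat)))
  # identified combinations agree across estimators
  expect_equal(mc$params$k[["AS"]] * mc$params$wf_s^2,
               map$params$k[["AS"]] * map$params$wf_s^2, tolerance = 0.25)
  expect_lt(abs(mc$params$alpha - map$params$alpha), 0.08)
})
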