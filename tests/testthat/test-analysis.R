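test_that("the 2-SD rule excludes exactly the far-out trial in the toy cell", {
  d <- toy_trials(c(700, 700, 700, 700, 1500))
  res <- exclude_outliers(d)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$excluded$trial, 5L)
  expect_equal(nrow(res$trials), 4L * 4L)
  # untouched cells: identical reproductions have zero spread, exclude nothing
  same <- toy_trials(rep(700, 6))
  expect_equal(exclude_outliers(same)$n_excluded, 0L)
})

test_that("outlier exclusion removes a few percent of model-scale data", {
  d <- simulate_dataset(simulation_config(n_participants = 5, master_seed = 61))
  res <- exclude_outliers(d)
  frac <- res$n_excluded / (nrow(d) / 4)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.08)
  # single pass: kept table is returned as-is, with complete trials only
  expect_equal(nrow(res$trials) %% 4, 0)
})

test_that("central tendency slopes are plain OLS on reproduced vs sample", {
  d <- toy_trials(rep(1, 4))
  d$reproduced_ms <- d$sample_ms             # identity reproduction
  s <- central_tendency_slope(d)
  expect_equal(s$slope, 1, tolerance = 1e-12)
  expect_equal(s$intercept, 0, tolerance = 1e-9)
  d$reproduced_ms <- 700                     # constant reproduction
  s <- central_tendency_slope(d)
  expect_equal(s$slope, 0, tolerance = 1e-12)
  expect_equal(s$intercept, 700, tolerance = 1e-9)
})

test_that("pipeline slope on noiseless forward predictions matches lm exactly", {
  p <- truth_params()
  pred <- predict_sequence(p, interval_set(1), "DS")
  d <- toy_trials(rep(1, 3))
  d$reproduced_ms <- rep(pred$R, times = 3)
  s <- central_tendency_slope(d, group = "per_set")
  oracle <- lm(R ~ sample_ms, data = pred)
  expect_equal(s$slope, unname(coef(oracle)[2]), tolerance = 1e-9)
  expect_equal(s$intercept, unname(coef(oracle)[1]), tolerance = 1e-9)
  expect_lt(s$slope, 1)
})

test_that("slope estimation is scale-equivariant and rejects degenerate groups", {
  d <- small_sim()
  s1 <- central_tendency_slope(d)
  d2 <- d
  d2$sample_ms <- d2$sample_ms * 3.7
  d2$reproduced_ms <- d2$reproduced_ms * 3.7
  s2 <- central_tendency_slope(d2)
  expect_equal(s1$slope, s2$slope, tolerance = 1e-9)
  bad <- toy_trials(c(700, 710), sample = rep(700, 4))
  expect_error(central_tendency_slope(bad), "distinct sample")
})

test_that("headline slopes average the two interval-set regressions", {
  d <- small_sim()
  per_set <- central_tendency_slope(d, group = "per_set")
  avg <- central_tendency_slope(d, group = "set_mean")
  chk <- aggregate(slope ~ participant_id + condition, per_set, mean)
  m <- merge(avg, chk, by = c("participant_id", "condition"))
  expect_equal(m$slope.x, m$slope.y, tolerance = 1e-12)
  pooled <- central_tendency_slope(d, group = "pooled")
  expect_false("set_id" %in% names(pooled))
})

test_that("condition means pool rows within participant", {
  d <- toy_trials(rep(1, 1), sample = c(500, 600, 800, 900))
  d$reproduced_ms <- d$sample_ms
  cm <- condition_means(d)
  expect_equal(cm$means$mean_ms, 700)
  # two trials: grand mean of all 8 values
  d2 <- toy_trials(c(1, 1), sample = c(500, 600, 800, 900))
  d2$reproduced_ms <- c(d2$sample_ms[1:4], d2$sample_ms[1:4] + 100)
  cm2 <- condition_means(d2)
  expect_equal(cm2$means$mean_ms, mean(d2$reproduced_ms))
  # per-interval SDs are computed with sets pooled
  d3 <- small_sim()
  bi <- condition_means(d3)$by_interval
  expect_setequal(unique(bi$sample_ms), c(400, 500, 600, 700, 900, 1000, 1100))
})

test_that("RS trials are tagged by their first or last interval", {
  d <- toy_trials(rep(700, 3), condition = "RS", set_id = 2)
  d$sample_ms <- c(c(400, 700, 1100, 600),   # first short, last middle-ish
                   c(700, 400, 1100, 600),
                   c(1100, 600, 400, 700))
  first <- categorize_rs_by_endpoint(d, "first")
  expect_equal(first$endpoint_tag[first$position == 1],
               c("short", "middle", "long"))
  last <- categorize_rs_by_endpoint(d, "last")
  expect_equal(unique(last$endpoint_tag[last$trial == 3]), "middle")
  expect_error(categorize_rs_by_endpoint(toy_trials(700), "first"), "RS")
})

test_that("repeated-measures ANOVA matches the sum-of-squares decomposition", {
  # 3 participants x 5 levels worked example, SS computed from first principles
  m <- matrix(c(8, 7, 9, 5, 6,
                6, 6, 8, 4, 5,
                7, 5, 8, 5, 6), nrow = 3, byrow = TRUE)
  colnames(m) <- paste0("c", 1:5)
  res <- rm_anova_oneway(m)
  grand <- mean(m)
  ss_level <- nrow(m) * sum((colMeans(m) - grand)^2)
  ss_subj <- ncol(m) * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  df1 <- ncol(m) - 1
  df2 <- (ncol(m) - 1) * (nrow(m) - 1)
  f_manual <- (ss_level / df1) / (ss_err / df2)
  expect_equal(res$F, f_manual, tolerance = 1e-9)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_equal(res$p, pf(f_manual, df1, df2, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("two-level repeated-measures F equals the squared paired t", {
  set.seed(8)
  a <- rnorm(10, 5)
  b <- a + rnorm(10, 0.5)
  res <- rm_anova_oneway(cbind(a = a, b = b))
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  # no effect at all -> F = 0
  zero <- rm_anova_oneway(cbind(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(zero$F, 0)
  expect_error(rm_anova_oneway(data.frame(participant_id = c(1, 1),
                                          level = c("a", "a"),
                                          value = c(1, 2))), "balanced")
})

test_that("the full behavioral pipeline returns coherent summaries", {
  d <- small_sim()
  a <- analyze_reproduction(d)
  expect_named(a, c("slopes", "means", "endpoint", "n_excluded"))
  expect_setequal(unique(a$endpoint$last$endpoint_tag),
                  c("short", "middle", "long"))
  expect_true(all(a$means$means$mean_ms > 0 & a$means$means$mean_ms < 2800))
  # slopes on noiseless data equal the closed-form prediction slope
  nl <- observer_params(wf_s = 0.18e-6, wf_p = 0.35e-6, alpha = 0.195,
                        k = c(AS = 2, DS = 2.4, RS = 2.13))
  dn <- simulate_dataset(simulation_config(n_participants = 1, master_seed = 3,
                                           truth = nl, n_trials = 66))
  sn <- central_tendency_slope(dn, group = "per_set")
  pred <- predict_sequence(truth_params(), interval_set(1), "DS")
  oracle <- unname(coef(lm(pred$R ~ pred$sample_ms))[2])
  got <- sn$slope[sn$condition == "DS" & sn$set_id == 1]
  expect_equal(got, oracle, tolerance = 1e-6)
})
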