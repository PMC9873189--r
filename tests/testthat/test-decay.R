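# Broken-line decay model: exact recovery, brute-force oracle equivalence,
# nested-model tests and half-life arithmetic.

# independent oracle: straight lm() on the broken-line basis, exhaustive
# fine-grid changepoint enumeration
oracle_rss <- function(tt, y, t0) {
  X <- cbind(pmin(tt - t0, 0), pmax(tt - t0, 0))
  sum(resid(lm(y ~ X))^2)
}
oracle_min_rss <- function(tt, y, step = 0.1) {
  grid <- seq(min(tt), max(tt), by = step)
  min(vapply(grid, function(t0) oracle_rss(tt, y, t0), numeric(1)),
      na.rm = TRUE)
}

test_that("log transform matches its definition", {
  m <- matrix(c(exp(1) - 1, 0, 10), 1, 3)
  y <- log_transform(m, pseudocount = 1)
  expect_equal(y[1, 1], 1)
  expect_equal(y[1, 2], 0)
  expect_true(all(diff(order(m)) > 0) == all(diff(order(y)) > 0))
  expect_error(log_transform(matrix(-1, 1, 1)), "negative")
  expect_error(log_transform(matrix(1, 1, 1), pseudocount = -1),
               "nonnegative")
})

test_that("noiseless kinked data are recovered exactly", {
  tt <- c(0, 5, 10, 20, 30, 60)
  y <- ifelse(tt <= 20, 10 - 0.1 * tt, 8)
  fit <- fit_broken_line(tt, y)
  expect_equal(fit$B, -0.1, tolerance = 1e-8)
  expect_equal(fit$Bp, 0, tolerance = 1e-8)
  expect_equal(fit$t0, 20, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-16)
  expect_equal(fit$alpha, 8, tolerance = 1e-8)
})

test_that("pure linear data reduce to simple regression", {
  tt <- rep(c(0, 10, 20, 40, 60), 2)
  y <- 5 - 0.05 * tt        # no kink at all
  fit <- fit_broken_line(tt, y)
  expect_equal(fit$B, -0.05, tolerance = 1e-6)
  expect_equal(fit$Bp, -0.05, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # with noise the changepoint model can only do at least as well
  set.seed(8)
  yn <- y + rnorm(10, 0, 0.1)
  expect_lte(fit_broken_line(tt, yn)$rss, sum(resid(lm(yn ~ tt))^2) + 1e-9)
})

test_that("profiled search matches exhaustive enumeration on random data", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(8:14, 1)
    tt <- sort(sample(0:60, n, replace = TRUE))
    while (length(unique(tt)) < 4)
      tt <- sort(sample(0:60, n, replace = TRUE))
    t0 <- runif(1, 10, 50)
    y <- 5 - 0.08 * pmin(tt - t0, 0) * -1 + rnorm(n, 0, 0.2)
    fit <- fit_broken_line(tt, y)
    expect_lte(fit$rss, oracle_min_rss(tt, y) * (1 + 1e-8))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_broken_line(c(0, 1, 2), c(1, 2, 3)), ">= 4")
  expect_error(fit_broken_line(c(0, 0, 1, 1), c(1, 1, 2, 2)),
               ">= 3 distinct")
})

test_that("the multi-treatment fit recovers distinct slopes exactly", {
  tt <- rep(c(0, 5, 10, 15, 30, 45, 60, 120), each = 2)
  times <- c(tt, tt)
  trt <- rep(c("rec", "actd"), each = length(tt))
  t0 <- c(rec = 30, actd = 45)
  mu <- ifelse(trt == "rec", 8 - 0.10 * pmin(times, 30),
               7 - 0.02 * pmin(times, 45))
  fit <- fit_multi_treatment(mu, times, trt, t0)
  expect_equal(unname(fit$beta1["rec"]), -0.10, tolerance = 1e-10)
  expect_equal(unname(fit$beta1["actd"]), -0.02, tolerance = 1e-10)
  expect_equal(unname(fit$beta0["rec"]), 8, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
})

test_that("one-treatment multi fit equals the broken-line fit at fixed t0", {
  set.seed(4)
  tt <- rep(c(0, 5, 10, 15, 30, 60), 2)
  y <- 9 - 0.07 * pmin(tt, 25) + rnorm(length(tt), 0, 0.1)
  single <- fit_broken_line(tt, y, t0_candidates = 25)
  multi <- fit_multi_treatment(y, tt, rep("actd", length(tt)),
                               c(actd = 25))
  expect_equal(multi$rss, single$rss, tolerance = 1e-8)
  expect_equal(unname(multi$beta1["actd"]), single$B, tolerance = 1e-8)
  expect_equal(unname(multi$beta2["actd"]), single$Bp, tolerance = 1e-8)
  # the two intercept parameterizations are related through the changepoint
  expect_equal(unname(multi$beta0["actd"]) + 25 * single$B, single$alpha,
               tolerance = 1e-8)
})

test_that("tying identical slopes costs nothing; nesting always holds", {
  set.seed(9)
  tt <- rep(c(0, 5, 10, 15, 30, 45, 60), 3)
  times <- c(tt, tt)
  trt <- rep(c("actd", "actd_fe"), each = length(tt))
  t0 <- c(actd = 30, actd_fe = 30)
  for (i in 1:10) {
    y <- 8 - 0.08 * pmin(times, 30) + rnorm(length(times), 0, 0.15)
    free <- fit_multi_treatment(y, times, trt, t0)
    tied <- fit_multi_treatment(y, times, trt, t0, tie_beta1 = c("actd",
                                                                 "actd_fe"))
    expect_gte(tied$rss, free$rss - 1e-10)
    lrt <- lrt_equal_decay(free, tied)
    expect_gte(lrt$statistic, 0)
    expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  }
})

test_that("identical fits give statistic zero and p one", {
  set.seed(77)
  tt <- rep(c(0, 10, 20, 40, 60), 2)
  times <- c(tt, tt)
  trt <- rep(c("rec", "actd"), each = length(tt))
  # both arms see identical data, so the slope tie costs nothing
  ya <- 6 - 0.05 * pmin(tt, 30) + rnorm(length(tt), 0, 0.1)
  y <- c(ya, ya)
  free <- fit_multi_treatment(y, times, trt, c(rec = 30, actd = 30))
  tied <- fit_multi_treatment(y, times, trt, c(rec = 30, actd = 30),
                              tie_beta1 = c("rec", "actd"))
  lrt <- lrt_equal_decay(free, tied)
  expect_equal(lrt$statistic, 0, tolerance = 1e-6)
  expect_equal(lrt$p_value, 1, tolerance = 1e-6)
})

test_that("a large slope difference at low noise is decisively detected", {
  set.seed(33)
  tt <- rep(c(0, 5, 10, 15, 30, 45, 60), 2)
  times <- c(tt, tt)
  trt <- rep(c("rec", "actd"), each = length(tt))
  y <- ifelse(trt == "rec", 8 - 0.10 * pmin(times, 30),
              8 - 0.02 * pmin(times, 30)) + rnorm(length(times), 0, 0.05)
  t0 <- c(rec = 30, actd = 30)
  free <- fit_multi_treatment(y, times, trt, t0)
  tied <- fit_multi_treatment(y, times, trt, t0,
                              tie_beta1 = c("rec", "actd"))
  expect_lt(lrt_equal_decay(free, tied)$p_value, 1e-3)
})

test_that("half-life arithmetic follows t1/2 = ln2 / k", {
  expect_equal(half_life(-log(2))$half_life_min, 1)
  # a ~90-min transcript decays at about 0.0077 per minute
  expect_equal(half_life(-0.0077)$half_life_min, 90, tolerance = 0.01)
  flat <- half_life(0.01)   # rising transcript: no half-life
  expect_true(is.na(flat$half_life_min))
  expect_false(flat$reliable)
  # strictly decreasing in k
  ks <- c(0.01, 0.05, 0.1, 0.5)
  hls <- vapply(ks, function(k) half_life(-k)$half_life_min, numeric(1))
  expect_true(all(diff(hls) < 0))
  # half-lives beyond the observed span are flagged
  expect_false(half_life(-0.001, time_span_min = 360)$reliable)
})

test_that("slope-change test separates kinks from lines", {
  tt <- rep(c(0, 5, 10, 20, 30, 60), 2)
  y <- ifelse(tt <= 20, 10 - 0.1 * tt, 8) + 0  # noiseless kink
  fit <- fit_broken_line(tt, y)
  expect_lt(slope_change_test(fit)$p_value, 1e-12)

  # symmetric V: contrast equals 2|B|
  yv <- abs(tt - 20) * 0.1 + rnorm(length(tt), 0, 1e-6)
  fitv <- fit_broken_line(tt, yv, t0_candidates = 20)
  sc <- slope_change_test(fitv)
  expect_equal(sc$estimate, 2 * abs(fitv$B), tolerance = 1e-3)
  expect_lt(sc$p_value, 1e-6)
})

test_that("slope-change test keeps its size on straight-line nulls", {
  set.seed(71)
  tt <- rep(c(0, 5, 10, 15, 30, 45, 60, 120), 2)
  rej <- 0; reps <- 500
  for (i in seq_len(reps)) {
    y <- 5 - 0.03 * tt + rnorm(length(tt), 0, 0.2)
    fit <- fit_broken_line(tt, y, t0_candidates = 30)
    if (slope_change_test(fit)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.03)
  expect_lt(rej / reps, 0.07)
})

test_that("half-life summaries exclude unreliable and listed genes", {
  est <- data.frame(gene = c("A", "B", "C"), treatment = "actd",
                    changepoint_min = 30, k_per_min = log(2) / c(6, 8, 10),
                    half_life_min = c(6, 8, 10),
                    reliable = TRUE, slope_change_p = 0.001, n_obs = 20)
  s <- summarize_half_lives(est)
  expect_equal(s$average, 8)

  est$reliable[3] <- FALSE
  s <- summarize_half_lives(est)
  expect_equal(s$average, 7)
  expect_identical(s$excluded, "C")

  est$reliable <- FALSE
  expect_error(summarize_half_lives(est), "no genes")
})

test_that("a mixed panel averages to the fast half-life after exclusion", {
  # panel like the study: most genes ~8 min, four long-lived 50-90 min
  des <- design_spec(st_treatments = "actd",
                     lt_treatments = character(0))
  sim <- simulate_experiment(des, seed = 14)
  norm <- suppressWarnings(
    normalize_pipeline(sim$counts, hk_probe = "NUCL_HK",
                       titration = sim$titration))
  hl <- fit_decay_table(norm$matrix, treatments = "actd")
  long_lived <- c("MNSOD", "PETE", "PETF", "CREGX2")
  s <- summarize_half_lives(hl, exclude = long_lived)
  expect_equal(s$average, 8, tolerance = 0.15)
  expect_true(all(hl$half_life_min[hl$gene %in% long_lived] > 45))
})
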