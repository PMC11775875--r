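test_that("partial eta-squared reproduces the worked value and edge cases", {
  expect_equal(round(partial_eta_squared(6.09, 1, 225), 3), 0.026)
  expect_equal(partial_eta_squared(0, 1, 100), 0)
  expect_equal(partial_eta_squared(1, 1, 1), 0.5)
  expect_error(partial_eta_squared(1, 0, 10), "positive")
  expect_error(partial_eta_squared(-1, 1, 10))
  # strictly increasing in F for fixed dfs
  Fs <- seq(0, 50, by = 0.5)
  vals <- vapply(Fs, partial_eta_squared, numeric(1), df_num = 2,
                 df_den = 100)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("trend contrasts are orthogonal and zero-sum", {
  C <- trend_contrasts()
  expect_equal(unname(rowSums(C)), c(0, 0, 0))
  expect_equal(sum(C["linear", ] * C["quadratic", ]), 0)
  expect_equal(sum(C["linear", ] * C["cubic", ]), 0)
  expect_equal(sum(C["quadratic", ] * C["cubic", ]), 0)
})

test_that("polynomial trends isolate the generating shape", {
  # exactly linear means: quadratic and cubic vanish
  tr <- polynomial_trends(c(1, 2, 3, 4, 5))
  expect_gt(abs(tr$estimate[tr$trend == "linear"]), 0)
  expect_lt(abs(tr$estimate[tr$trend == "quadratic"]), 1e-10)
  expect_lt(abs(tr$estimate[tr$trend == "cubic"]), 1e-10)
  # tent shape: quadratic dominates (brute-force contrast products)
  means <- c(1, 2, 3, 2, 1)
  C <- trend_contrasts()
  brute <- as.numeric(C %*% means)
  tr2 <- polynomial_trends(means)
  expect_equal(tr2$estimate, brute)
  expect_gt(abs(tr2$estimate[2]), max(abs(tr2$estimate[c(1, 3)])))
  expect_error(polynomial_trends(c(1, 2, 3)), "5 intensity levels")
  # data-frame mode: within-participant t-test recovers a linear trend
  set.seed(21)
  d <- expand.grid(participant = paste0("p", 1:15),
                   intensity = c(20, 40, 60, 80, 100))
  d$value <- d$intensity / 100 + rnorm(nrow(d), 0, 0.1)
  tr3 <- polynomial_trends(d)
  expect_lt(tr3$p[tr3$trend == "linear"], 0.001)
  expect_gt(min(tr3$p[tr3$trend != "linear"]), 0.05)
})

test_that("the mixed model detects a true emotion effect and reports it", {
  set.seed(22)
  d <- expand.grid(participant = paste0("p", 1:25),
                   emotion = c("happy", "angry"),
                   roi = c("left", "right", "medial"))
  pid <- rnorm(25, 0, 0.3)[as.integer(factor(d$participant))]
  d$value <- 0.5 * (d$emotion == "happy") + pid + rnorm(nrow(d), 0, 0.3)
  fit <- fit_lmm(d, "value", c("emotion", "roi"))
  eff <- fit$effects
  expect_setequal(eff$term, c("emotion", "roi", "emotion:roi"))
  expect_lt(eff$p[eff$term == "emotion"], 0.001)
  expect_true(all(is.finite(eff$F)))
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
  expect_equal(eff$partial_eta_sq,
               mapply(partial_eta_squared, eff$F, eff$df_num, eff$df_den))
  expect_error(fit_lmm(d[d$participant == "p1", ], "value",
                       c("emotion", "roi")), "at least 2 participants")
})

test_that("a singular fit falls back to fixed-effects ANOVA with a warning", {
  set.seed(1)  # this draw yields a zero random-intercept variance
  d <- expand.grid(participant = paste0("p", 1:6),
                   emotion = c("happy", "angry"))
  d$value <- rnorm(nrow(d))          # no participant variance to estimate
  expect_warning(fit <- fit_lmm(d, "value", "emotion"), "singular")
  expect_true(fit$singular)
  expect_true(is.finite(fit$effects$F[1]))
})

test_that("pairwise comparisons carry Tukey adjustment", {
  set.seed(24)
  d <- expand.grid(participant = paste0("p", 1:20),
                   emotion = c("happy", "angry"),
                   roi = c("left", "right", "medial"))
  d$value <- 0.4 * (d$roi == "right") +
    rnorm(20, 0, 0.2)[as.integer(factor(d$participant))] +
    rnorm(nrow(d), 0, 0.25)
  fit <- fit_lmm(d, "value", c("emotion", "roi"))
  ph <- posthoc_pairwise(fit, "roi")
  expect_equal(nrow(ph), 3)          # k (k - 1) / 2 for k = 3
  unadj <- 2 * stats::pt(abs(ph$t), ph$df, lower.tail = FALSE)
  expect_true(all(ph$p_tukey >= unadj - 1e-12))
  # 2-level factor: single comparison, Tukey equals the unadjusted p
  ph2 <- posthoc_pairwise(fit, "emotion")
  expect_equal(nrow(ph2), 1)
  expect_equal(ph2$p_tukey,
               2 * stats::pt(abs(ph2$t), ph2$df, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("ERT summaries compute cell accuracy and RT on correct trials", {
  trials <- data.frame(
    emotion = "happy", intensity = rep(c(0, 100), c(30, 30)),
    correct = rep(c(TRUE, FALSE), c(45, 15))[sample(60)],
    rt_s = runif(60, 0.5, 2), timeout = FALSE)
  s <- ert_summarize(trials)
  expect_equal(sum(s$n * s$accuracy) / sum(s$n), 0.75)
  # all timeouts: accuracy still defined, RT missing
  trials2 <- transform(trials, timeout = TRUE, rt_s = NA_real_,
                       correct = FALSE)
  s2 <- ert_summarize(trials2)
  expect_true(all(is.na(s2$mean_rt)))
  expect_true(all(s2$accuracy == 0))
})

test_that("simulated ERT curves recover the psychometric threshold", {
  # pool many blocks, fit the known-form model by maximum likelihood and
  # check the generating threshold is inside a basic Wald interval
  des <- ert_design(threshold = 55, slope = 0.09, lapse = 0.02)
  tt <- do.call(rbind, lapply(1:60, function(s)
    simulate_ert(des, emotions = "happy", seed = 100 + s)))
  tt <- tt[tt$trial_type == "expressive", ]
  nll <- function(par) {
    p <- des$guess + (1 - des$guess - des$lapse) *
      stats::plogis(par[2] * (tt$intensity - par[1]))
    -sum(log(ifelse(tt$correct, p, 1 - p)))
  }
  fit <- stats::optim(c(40, 0.05), nll, hessian = TRUE)
  se <- sqrt(diag(solve(fit$hessian)))[1]
  expect_lt(abs(fit$par[1] - 55), 3 * se + 5)
})
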