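test_that("Kaplan-Meier matches hand product-limit values", {
  # all events: 1 -> 2/3 -> 1/3 -> 0
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))$all
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring pattern 1, 2+, 3, 4+, 5
  times <- c(1, 2, 3, 4, 5)
  events <- c(1, 0, 1, 0, 1)
  km2 <- kaplan_meier(times, events)$all
  hand <- bf_km(times, events)
  expect_equal(km2$surv[km2$n_event > 0], hand$surv)
  expect_equal(hand$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 0))
  # no events: survival stays at 1
  km3 <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))$all
  expect_true(all(km3$surv == 1))
  expect_error(kaplan_meier(numeric(0), numeric(0)))
})

test_that("log-rank matches the hand observed-minus-expected oracle", {
  # duplicated groups are perfectly balanced
  t0 <- c(3, 5, 8, 11)
  e0 <- c(1, 1, 0, 1)
  bal <- logrank_test(rep(t0, 2), rep(e0, 2), rep(c("a", "b"), each = 4))
  expect_equal(bal$statistic, 0, tolerance = 1e-12)
  expect_equal(bal$p_value, 1)
  # toy two-group data against the hand statistic
  times <- c(1, 3, 4, 6, 8, 9, 11, 13)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), 4)
  lr <- logrank_test(times, events, group)
  expect_equal(lr$statistic, bf_logrank(times, events, group),
               tolerance = 1e-8)
  expect_equal(lr$df, 1L)
  expect_error(logrank_test(times, events, rep("a", 8)), "two groups")
  expect_error(logrank_test(times, rep(0, 8), group), "one event")
})

test_that("a strong protective five-marker effect separates survival", {
  cfg <- sim_config()
  pat <- simulate_patient_profiles(cfg, 600, seed = 2)
  score <- five_marker_score(pat)
  keep <- score <= 1 | score >= 4
  lr <- logrank_test(pat$time_months[keep], pat$event[keep],
                     ifelse(score[keep] >= 4, "high", "low"))
  expect_lt(lr$p_value, 1e-4)
})

test_that("Cox estimates match the two-sample exponential closed form", {
  set.seed(4)
  n <- 2000
  grp <- rep(0:1, each = n / 2)
  times <- rexp(n, 0.02 * exp(log(0.5) * grp))
  events <- rep(1, n)
  fit <- cox_ph(times, events, data.frame(group = grp))
  # exponential MLE: rate ratio = (d1 / T1) / (d0 / T0)
  rr <- (sum(grp == 1) / sum(times[grp == 1])) /
    (sum(grp == 0) / sum(times[grp == 0]))
  expect_lt(abs(fit$coefficients$hr - rr), 0.05)
  expect_lt(abs(fit$coefficients$hr - 0.5), 0.1)
  # null covariate recovers HR 1 within simulation error
  z <- rnorm(n)
  fit0 <- cox_ph(rexp(n, 0.02), rep(1, n), data.frame(z = z))
  expect_gt(fit0$coefficients$hr, 0.85)
  expect_lt(fit0$coefficients$hr, 1.18)
  expect_error(cox_ph(times, events, data.frame(k = rep(1, n))),
               "constant")
})

test_that("time-dependent AUC covers perfect, null and brute-force cases", {
  # perfect ordering, no censoring
  n <- 40
  times <- sort(rexp(n, 0.1))
  score <- -times        # higher score = earlier event
  auc <- time_dependent_auc(score, times, rep(1, n),
                            horizon = stats::median(times))
  expect_equal(auc$auc, 1)
  # n = 6 hand enumeration, no censoring
  t6 <- c(1, 2, 3, 4, 5, 6)
  s6 <- c(5, 1, 4, 2, 6, 3)
  hz <- 3.5
  cases <- which(t6 <= hz)
  ctrls <- which(t6 > hz)
  hand <- mean(outer(s6[cases], s6[ctrls], ">") +
                 0.5 * outer(s6[cases], s6[ctrls], "=="))
  expect_equal(time_dependent_auc(s6, t6, rep(1, 6), hz)$auc, hand)
  # independent score: AUC near 1/2 (with censoring, IPCW weights active)
  set.seed(9)
  n <- 1000
  tt <- rexp(n, 0.05)
  cc <- rexp(n, 0.02)
  obs <- pmin(tt, cc)
  ev <- as.integer(tt <= cc)
  a <- time_dependent_auc(rnorm(n), obs, ev, horizon = 10)
  expect_lt(abs(a$auc - 0.5), 0.05)
  expect_error(time_dependent_auc(rnorm(5), c(9, 9, 9, 9, 9),
                                  rep(1, 5), 1), "no cases")
})

test_that("highest-slope dichotomization is overridable and reproducible", {
  set.seed(21)
  scores <- c(rnorm(120, 10, 3), rnorm(80, 40, 3))
  cp <- highest_slope_threshold(scores)
  expect_identical(cp$method, "highest_slope_auto")
  expect_identical(cp$cutpoint, highest_slope_threshold(scores)$cutpoint)
  # the cut sits in the steep region between/around the two modes and
  # orders the groups correctly
  expect_gt(cp$cutpoint, stats::quantile(scores, 0.1))
  expect_lt(cp$cutpoint, stats::quantile(scores, 0.9))
  expect_gt(mean(scores[cp$high]), mean(scores[!cp$high]))
  man <- highest_slope_threshold(scores, override = 15)
  expect_identical(man$method, "manual")
  expect_identical(man$cutpoint, 15)
  expect_identical(man$high, scores > 15)
  expect_error(highest_slope_threshold(rep(3, 50)), "constant")
  expect_error(highest_slope_threshold(1:5), "10 patients")
})

test_that("five-marker score counts high flags and is strictly monotone", {
  fl <- data.frame(PR_high = TRUE, ER_high = TRUE, AR_high = TRUE,
                   GATA3_high = TRUE, PDL1_high = TRUE)
  expect_identical(five_marker_score(fl), 5L)
  fl0 <- as.data.frame(lapply(fl, function(x) FALSE))
  expect_identical(five_marker_score(fl0), 0L)
  fl1 <- fl0
  fl1$PR_high <- TRUE
  expect_identical(five_marker_score(fl1), 1L)
  expect_error(five_marker_score(fl0[-1]), "PR")
  set.seed(3)
  base <- as.data.frame(matrix(runif(50) < 0.5, 10, 5))
  names(base) <- paste0(SCORE_MARKERS, "_high")
  s0 <- five_marker_score(base)
  for (m in names(base)) {
    flipped <- base
    low <- which(!flipped[[m]])
    if (length(low)) {
      flipped[[m]][low] <- TRUE
      expect_identical(five_marker_score(flipped)[low], s0[low] + 1L)
    }
  }
})

test_that("association tests match closed forms and report descriptives", {
  # perfectly proportional 2x3 table
  status <- rep(c("high", "low"), times = c(30, 30))
  category <- rep(c("1", "2", "3"), times = c(10, 10, 10))
  a <- association_test(status, rep(category, 2))
  expect_equal(a$chisq$statistic, 0)
  expect_equal(a$chisq$p_value, 1)
  # 2x2 table (20,10; 10,20) against the hand chi-square
  st <- rep(c("h", "h", "l", "l"), times = c(20, 10, 10, 20))
  ct <- rep(c("a", "b", "a", "b"), times = c(20, 10, 10, 20))
  b <- association_test(st, ct)
  hand <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  expect_equal(b$chisq$statistic, hand)
  # degenerate category level
  expect_error(association_test(c("h", "l"), c("a", "a")), "2x2")
  # descriptives carry mean +/- SD per category
  sc <- c(rnorm(30, 50, 5), rnorm(30, 20, 5))
  d <- association_test(status, rep(c("G1", "G2"), 30), score = sc)
  expect_identical(nrow(d$descriptives), 2L)
  expect_true(all(c("mean", "sd") %in% names(d$descriptives)))
  expect_true(d$kruskal$p_value >= 0 && d$kruskal$p_value <= 1)
})

test_that("grade-linked marker status is detected in most cohorts", {
  cfg <- sim_config()
  hits <- vapply(1:60, function(i) {
    pat <- simulate_patient_profiles(cfg, 600, seed = 5000 + i)
    association_test(ifelse(pat$PR_high, "high", "low"),
                     pat$grade)$chisq$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("log-rank is invariant under common time rescaling", {
  set.seed(10)
  times <- rexp(60, 0.05)
  events <- rbinom(60, 1, 0.7)
  group <- rep(c("a", "b"), 30)
  a <- logrank_test(times, events, group)
  b <- logrank_test(times * 12, events, group)
  expect_equal(a$statistic, b$statistic)
})
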