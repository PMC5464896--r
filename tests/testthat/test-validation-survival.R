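# Holdout validation, fold splitting, cross-validation, ROC cutoff,
# Kaplan-Meier and log-rank — against brute-force / hand oracles.

test_that("holdout validation is perfect on noiseless equation data", {
  sim <- simulate_cohort(n = 15, seed = 8, group = "validation",
                         growth_noise_sd = 0, curves = FALSE)
  hv <- holdout_validate(hnscc_growth_equation(), sim$cohort)
  expect_equal(hv$r, 1, tolerance = 1e-9)
  expect_equal(hv$icc, 1, tolerance = 1e-9)
  expect_equal(hv$n, 15)
})

test_that("holdout r lands near the calibration target across seeds", {
  rs <- vapply(1:12, function(s) {
    sim <- simulate_cohort(n = 15, seed = s, group = "validation",
                           target_r = 0.66, curves = FALSE)
    holdout_validate(hnscc_growth_equation(), sim$cohort)$r
  }, numeric(1))
  expect_equal(mean(rs), 0.66, tolerance = 0.15)
})

test_that("constant predictions give an undefined correlation, not an error", {
  val <- data.frame(d2 = rep(0.9, 5), d3 = rep(0.6, 5),
                    growth_rate = c(120, 130, 140, 125, 135))
  hv <- holdout_validate(hnscc_growth_equation(), val)
  expect_true(is.na(hv$r))
  expect_error(holdout_validate(hnscc_growth_equation(),
                                val[1:2, ]), "n >= 3")
})

test_that("k-fold split partitions 55 ids into 11/44 folds deterministically", {
  ids <- sprintf("P%02d", 1:55)
  fa <- kfold_split(ids, k = 5, seed = 42)
  expect_equal(lengths(fa$folds), setNames(rep(11L, 5), 1:5))
  expect_setequal(unlist(fa$folds), ids)
  expect_equal(sum(duplicated(unlist(fa$folds))), 0L)
  # training complements have 44 patients each
  expect_true(all(55L - lengths(fa$folds) == 44L))
  # determinism and seed sensitivity
  expect_identical(fa, kfold_split(ids, k = 5, seed = 42))
  expect_false(identical(fa$fold, kfold_split(ids, k = 5, seed = 43)$fold))
  expect_error(kfold_split(ids, k = 60, seed = 1), "k <= n")
  expect_error(kfold_split(c("a", "a", "b"), k = 2, seed = 1), "unique")
})

test_that("cross-validation is perfect on a noiseless cohort and k metrics come back", {
  sim <- simulate_cohort(n = 30, seed = 17, growth_noise_sd = 0,
                         curves = FALSE)
  co <- encode_predictors(sim$cohort)
  cv <- crossvalidate(co, c("d2", "d3"), k = 5, seed = 4)
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(cv$folds$r, rep(1, 5), tolerance = 1e-6)
  expect_equal(cv$mean_icc, 1, tolerance = 1e-6)
})

test_that("cross-validated r on calibrated-noise cohorts sits in the expected band", {
  rs <- vapply(c(5, 6, 7), function(s) {
    sim <- simulate_cohort(n = 55, seed = s, curves = FALSE)
    co <- encode_predictors(sim$cohort)
    crossvalidate(co, c("d2", "d3"), k = 5, seed = s)$mean_r
  }, numeric(1))
  expect_gt(mean(rs), 0.5)
  expect_lt(mean(rs), 0.9)
})

test_that("leave-one-out cross-validation is well defined", {
  sim <- simulate_cohort(n = 12, seed = 19, growth_noise_sd = 0,
                         curves = FALSE)
  co <- encode_predictors(sim$cohort)
  # k = n: every test fold is a single patient; per-fold r/ICC cannot be
  # computed on one point, but the pipeline must run and record it
  expect_error(cv <- crossvalidate(co, c("d2", "d3"), k = 12, seed = 2),
               NA)
  expect_equal(nrow(cv$folds), 12L)
  expect_true(all(cv$folds$n_test == 1L))
  expect_true(all(cv$folds$n_predictors >= 1L))
})

test_that("ROC cutoff equals brute force over all thresholds", {
  # worked example: perfect separation at the midpoint
  rc <- roc_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(rc$cutoff, 2.5)
  expect_equal(rc$sensitivity, 1)
  expect_equal(rc$specificity, 1)

  brute <- function(scores, labels) {
    su <- sort(unique(scores))
    thr <- (su[-1] + su[-length(su)]) / 2
    best <- NULL
    for (t in thr) {
      se <- mean(scores[labels == 1] >= t)
      sp <- mean(scores[labels == 0] < t)
      d <- sqrt((1 - se)^2 + (1 - sp)^2)
      if (is.null(best) || d < best$d - 1e-12 ||
          (d < best$d + 1e-12 && se > best$se)) {
        best <- list(t = t, se = se, sp = sp, d = d)
      }
    }
    best
  }
  set.seed(55)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- rnorm(n) + labels
    rc <- roc_cutoff(scores, labels)
    bf <- brute(scores, labels)
    expect_equal(rc$cutoff, bf$t)
    expect_equal(rc$sensitivity, bf$se)
    expect_equal(rc$specificity, bf$sp)
  }
  expect_error(roc_cutoff(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("ROC cutoff agrees with pROC closest.topleft on a reference instance", {
  skip_if_not_installed("pROC")
  set.seed(66)
  labels <- rbinom(60, 1, 0.5)
  scores <- rnorm(60) + 1.2 * labels
  rc <- roc_cutoff(scores, labels)
  pr <- pROC::coords(pROC::roc(labels, scores, quiet = TRUE),
                     "best", best.method = "closest.topleft")
  expect_equal(rc$cutoff, pr$threshold, tolerance = 1e-9)
})

test_that("Kaplan-Meier matches the hand product-limit on small cases", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$survival, c(2 / 3, 1 / 3, 0))

  # censoring between events: hand product-limit
  km2 <- kaplan_meier(c(1, 1.5, 2, 3), c(1, 0, 1, 1))
  # events at 1 (4 at risk), 2 (2 at risk), 3 (1 at risk)
  expect_equal(km2$table$survival[km2$table$n_event > 0],
               c(3 / 4, 3 / 4 * 1 / 2, 0))

  # no events: survival 1 everywhere
  km3 <- kaplan_meier(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(km3$table$survival == 1))
  expect_equal(km_survival(km3, c(1, 10)), c(1, 1))
  # survival is 1 before the first event, flat after the last
  expect_equal(km_survival(km, c(0.5, 2.5, 10)), c(1, 2 / 3 * 1 / 2, 0))

  # exhaustive n <= 5 check against an explicit product-limit oracle
  pl_oracle <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- 1
    out <- numeric(length(ts))
    for (i in seq_along(ts)) {
      at_risk <- sum(time >= ts[i])
      d <- sum(time == ts[i] & event == 1)
      s <- s * (1 - d / at_risk)
      out[i] <- s
    }
    list(time = ts, surv = out)
  }
  set.seed(91)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    time <- sample(1:4, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    km <- kaplan_meier(time, event)
    or <- pl_oracle(time, event)
    expect_equal(km_survival(km, or$time), or$surv)
  }
})

test_that("log-rank matches the hand observed-minus-expected oracle", {
  # a: events at 1, 2; b: events at 3, 4
  hand_logrank <- function(time, event, grp) {
    ts <- sort(unique(time[event == 1]))
    o_minus_e <- 0; v <- 0
    for (t in ts) {
      n_all <- sum(time >= t); n_a <- sum(time >= t & grp == "a")
      d <- sum(time == t & event == 1)
      d_a <- sum(time == t & event == 1 & grp == "a")
      o_minus_e <- o_minus_e + d_a - d * n_a / n_all
      if (n_all > 1) {
        v <- v + d * (n_a / n_all) * (1 - n_a / n_all) *
          (n_all - d) / (n_all - 1)
      }
    }
    (o_minus_e)^2 / v
  }
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  grp <- c("a", "a", "b", "b")
  lr <- logrank(time, event, grp)
  expect_equal(lr$chi2, hand_logrank(time, event, grp), tolerance = 1e-9)

  set.seed(13)
  for (i in 1:10) {
    n <- 12
    time <- round(rexp(n, 0.1) + 0.5, 1)
    event <- rbinom(n, 1, 0.8)
    grp <- rep(c("a", "b"), each = 6)
    if (sum(event) == 0) next
    expect_equal(logrank(time, event, grp)$chi2,
                 hand_logrank(time, event, grp), tolerance = 1e-9)
  }

  # identical groups: chi2 0, p 1
  lr0 <- logrank(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-9)
  # label swap invariance
  expect_equal(logrank(time, event, grp)$chi2,
               logrank(time, event, rev(grp))$chi2, tolerance = 1e-9)
  # no events: undefined with a warning
  expect_warning(lr_na <- logrank(c(1, 2), c(0, 0), c("a", "b")),
                 "undefined")
  expect_true(is.na(lr_na$chi2))
})

test_that("survival split by growth rate behaves as the hazard link implies", {
  sim <- simulate_cohort(n = 55, seed = 23, curves = FALSE)
  co <- sim$cohort
  sv <- simulate_survival(co$growth_rate, seed = 29, link = 0.9)
  co$os_months <- sv$months; co$os_event <- sv$event
  res <- survival_by_growth(co, "growth_rate", "os")
  # low-rate group should sit above the high-rate group mid-follow-up
  expect_gte(km_survival(res$km_low, 18), km_survival(res$km_high, 18))
  expect_true(res$cutoff$sensitivity >= 0 && res$cutoff$sensitivity <= 1)

  # all-censored cohort: undefined log-rank, reported not thrown
  co$os_event <- 0
  expect_warning(res0 <- survival_by_growth(co, "growth_rate", "os"),
                 "undefined|both outcome classes|censored")
})
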