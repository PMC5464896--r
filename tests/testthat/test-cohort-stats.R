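# Encoding, univariate screen, VIF exclusion, multivariate regression,
# ICC, Mann-Whitney and correlation bands — each against an independent
# oracle where the computation is non-trivial.

test_that("categorical predictors are encoded to the documented codes", {
  tab <- data.frame(
    sex = c("male", "female", "Male"),
    site = c("oropharynx", "nasal cavity", "paranasal sinus"),
    t_stage = c("T4a", "T4b", "T2"),
    n_stage = c("N0", "N2", "N1"),
    smoking = c("smoker", "non-smoker", "smoker"),
    alcohol = c("heavy", "moderate", "occasional or non-drinker"),
    age = c(60, 60, 60))
  enc <- encode_predictors(tab)
  expect_equal(enc$sex, c(0, 1, 0))
  expect_equal(enc$site, c(1, 0, 0))
  expect_equal(enc$t_stage, c(4, 4, 2))  # T4a and T4b share level 4
  expect_equal(enc$n_stage, c(0, 2, 1))
  expect_equal(enc$smoking, c(1, 0, 1))
  expect_equal(enc$alcohol, c(2, 1, 0))
  expect_true("age" %in% attr(enc, "zero_variance"))
  expect_error(encode_predictors(data.frame(site = "nasopharynx")),
               "nasopharynx")
})

test_that("univariate screen returns exact r and slope-t p-values", {
  x <- c(1, 2, 3, 4, 5, 6)
  tab <- data.frame(x = x, y_exact = 2 * x, noise = c(2, 1, 3, 1, 2, 3),
                    const = 1, growth_rate = 2 * x)
  scr <- univariate_screen(tab, c("x", "noise", "const"),
                           outcome = "growth_rate")
  expect_equal(scr$r[scr$predictor == "x"], 1)
  expect_lt(scr$p[scr$predictor == "x"], 1e-12)
  expect_true(is.na(scr$r[scr$predictor == "const"]))
  # oracle: cor.test gives the identical p for the noisy predictor
  ct <- cor.test(tab$noise, tab$growth_rate)
  expect_equal(scr$p[scr$predictor == "noise"], unname(ct$p.value),
               tolerance = 1e-12)
  expect_equal(scr$r[scr$predictor == "noise"], unname(ct$estimate),
               tolerance = 1e-12)
})

test_that("screen flags the generating D2/D3 link on synthetic cohorts", {
  for (seed in c(2, 3)) {
    sim <- simulate_cohort(n = 40, seed = seed, curves = FALSE)
    co <- encode_predictors(sim$cohort)
    scr <- univariate_screen(co, c("d2", "d3", "age", "f1", "k"))
    expect_true(scr$significant[scr$predictor == "d2"])
    expect_true(scr$significant[scr$predictor == "d3"])
    expect_lt(scr$r[scr$predictor == "d2"], 0)
    expect_lt(scr$r[scr$predictor == "d3"], 0)
  }
})

test_that("VIF values match the closed form and the screen is idempotent", {
  # two predictors with correlation 0.9: VIF = 1 / (1 - 0.81) = 5.263...
  n <- 2000
  set.seed(77)
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  # force the empirical correlation to exactly 0.9
  x2 <- stats::residuals(lm(x2 ~ x1)) /
    sd(stats::residuals(lm(x2 ~ x1))) * sqrt(1 - 0.81) + 0.9 * x1 / sd(x1)
  x1 <- x1 / sd(x1)
  tab <- data.frame(a = x1, b = x2, growth_rate = rnorm(n))
  r <- cor(tab$a, tab$b)
  vs <- vif_screen(tab, c("a", "b"))
  expect_equal(unname(vs$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-9)
  expect_equal(round(unname(vs$vif)[1], 3), 5.263)
  expect_equal(vs$retained, c("a", "b"))  # below threshold 10

  # orthogonal (and mean-centered) predictors: all VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(30), 10))))[, 2:4]
  tab2 <- data.frame(q, growth_rate = rnorm(10))
  names(tab2)[1:3] <- c("p1", "p2", "p3")
  vs2 <- vif_screen(tab2, c("p1", "p2", "p3"))
  expect_equal(unname(vs2$vif), rep(1, 3), tolerance = 1e-9)

  # duplicated column: infinite VIF, one copy removed, never a crash
  tab3 <- data.frame(a = x1, b = x1, c = rnorm(n), growth_rate = x1 + rnorm(n))
  vs3 <- vif_screen(tab3, c("a", "b", "c"))
  expect_length(vs3$retained, 2L)
  expect_equal(nrow(vs3$removed), 1L)
  expect_true(vs3$removed$predictor %in% c("a", "b"))

  # idempotence
  vs4 <- vif_screen(tab3, vs3$retained)
  expect_equal(vs4$retained, vs3$retained)
  expect_equal(nrow(vs4$removed), 0L)
})

test_that("multivariate regression recovers a noiseless affine outcome exactly", {
  sim <- simulate_cohort(n = 40, seed = 13, growth_noise_sd = 0,
                         curves = FALSE)
  co <- sim$cohort
  reg <- multivariate_regress(co, c("d2", "d3"))
  expect_equal(unname(reg$coefficients), c(-43.3, -91.2), tolerance = 1e-6)
  expect_equal(reg$intercept, 227.5, tolerance = 1e-6)
  expect_equal(reg$multiple_r, 1, tolerance = 1e-9)
  eq <- as_growth_equation(reg)
  expect_equal(predict_growth(eq, 0, 0), 227.5, tolerance = 1e-6)

  # standardized coefficient identity and OLS properties on noisy data
  sim2 <- simulate_cohort(n = 40, seed = 14, curves = FALSE)
  co2 <- sim2$cohort
  reg2 <- multivariate_regress(co2, c("d2", "d3"), alpha = 1)
  sd_y <- sd(co2$growth_rate)
  expect_equal(unname(reg2$std_coef),
               unname(reg2$coefficients) * c(sd(co2$d2), sd(co2$d3)) / sd_y)
  # residuals orthogonal to retained predictors
  res <- residuals(reg2$model)
  expect_lt(abs(sum(res * scale(co2$d2))), 1e-8)
  expect_lt(abs(sum(res * scale(co2$d3))), 1e-8)
  # multiple r equals |cor(fitted, observed)|
  expect_equal(reg2$multiple_r, abs(cor(reg2$fitted, co2$growth_rate)))
  # standardized coefficients invariant to predictor rescaling
  co3 <- co2
  co3$d2 <- co3$d2 * 1000 + 5
  reg3 <- multivariate_regress(co3, c("d2", "d3"), alpha = 1)
  expect_equal(unname(reg3$std_coef), unname(reg2$std_coef),
               tolerance = 1e-9)

  # single predictor reduces to the univariate fit
  reg1 <- multivariate_regress(co2, "d3", alpha = 1)
  uni <- lm(growth_rate ~ d3, data = co2)
  expect_equal(unname(reg1$coefficients), unname(coef(uni)[2]))
})

test_that("ICC(2,1) matches an explicit ANOVA-sums oracle", {
  x <- cbind(r1 = c(1, 2, 3, 4), r2 = c(2, 3, 4, 5))
  # oracle: hand ANOVA
  n <- 4; k <- 2
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  mse <- (sum((x - grand)^2) - k * sum((rowMeans(x) - grand)^2) -
            n * sum((colMeans(x) - grand)^2)) / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc(x)$icc, oracle, tolerance = 1e-12)

  # identical columns agree perfectly
  expect_equal(icc(cbind(1:5, 1:5))$icc, 1)
  # constant matrix is undefined
  expect_true(is.na(icc(matrix(3, 4, 2))$icc))
  # independent random columns: near zero in expectation
  set.seed(21)
  vals <- replicate(200, icc(cbind(rnorm(20), rnorm(20)))$icc)
  expect_lt(abs(mean(vals)), 0.06)
})

test_that("ICC of simulated rater pairs matches the variance-components formula", {
  set.seed(31)
  truth <- rnorm(300, 1, 1)
  expect_equal(icc(simulate_rater_pair(truth, 0, seed = 1))$icc, 1)
  # var(true) = rater_sd^2 gives expected ICC 0.5
  vals <- vapply(1:40, function(s) {
    icc(simulate_rater_pair(truth, 1, seed = s))$icc
  }, numeric(1))
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
  # determinism
  expect_identical(simulate_rater_pair(truth, 1, seed = 3),
                   simulate_rater_pair(truth, 1, seed = 3))
})

test_that("Mann-Whitney exact p matches full enumeration and wilcox.test", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)  # 2 * 1 / choose(6, 3)
  wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(mw$p, wt$p.value)

  # label swap leaves p unchanged
  mw2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw2$p, mw$p)
  expect_equal(mw2$u, 9)

  # random tie-free instances: agreement with wilcox.test exact p
  set.seed(41)
  for (i in 1:10) {
    a <- sample(100, 5); b <- sample(200:300, 6)
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # identical groups under midrank ties
  mw3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw3$u, 3 * 3 / 2)
  expect_gt(mw3$p, 0.9)

  # large samples use the tie-corrected normal approximation
  a <- rep(1:10, 3); b <- rep(2:11, 3)
  mw4 <- mann_whitney(a, b)
  expect_equal(mw4$method, "normal approximation with tie correction")
  wt4 <- suppressWarnings(wilcox.test(a, b, correct = FALSE))
  expect_equal(mw4$p, wt4$p.value, tolerance = 1e-9)
})

test_that("correlation bands follow the half-open boundaries", {
  expect_equal(classify_correlation(c(0, 0.19, 0.2, 0.4, 0.41, 0.6,
                                      0.61, 0.74, 0.8, 0.81, 1)),
               c("poor", "poor", "fair", "fair", "moderate", "moderate",
                 "good", "good", "good", "excellent", "excellent"))
  expect_equal(classify_correlation(0.66), "good")
  expect_equal(classify_correlation(-0.65), "good")  # classified on |r|
  expect_error(classify_correlation(1.2), "<= 1")
})
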