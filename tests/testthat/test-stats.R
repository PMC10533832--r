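test_that("mixed_anova agrees with stats::aov on a split-plot design", {
  df <- anova_fixture_mixed()
  res <- mixed_anova(df, dv = "y", subject = "subject", between = "delay",
                     within = c("emotion", "lure"))
  df2 <- df
  for (cl in c("subject", "delay", "emotion", "lure"))
    df2[[cl]] <- factor(df2[[cl]])
  ao <- summary(stats::aov(
    y ~ delay * emotion * lure + Error(subject / (emotion * lure)),
    data = df2))
  pick <- function(stratum, term) {
    tab <- ao[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)
    unlist(tab[i[1], c("F value", "Pr(>F)", "Df")])
  }
  cases <- list(
    c("delay", "Error: subject", "delay"),
    c("emotion", "Error: subject:emotion", "emotion"),
    c("delay:emotion", "Error: subject:emotion", "delay:emotion"),
    c("lure", "Error: subject:lure", "lure"),
    c("delay:lure", "Error: subject:lure", "delay:lure"),
    c("emotion:lure", "Error: subject:emotion:lure", "emotion:lure"),
    c("delay:emotion:lure", "Error: subject:emotion:lure",
      "delay:emotion:lure"))
  for (cs in cases) {
    mine <- res[res$effect == cs[1], ]
    ref <- pick(cs[2], cs[3])
    expect_equal(mine$F, unname(ref["F value"]), tolerance = 1e-6,
                 label = paste("F for", cs[1]))
    expect_equal(mine$p_uncorrected, unname(ref["Pr(>F)"]),
                 tolerance = 1e-6, label = paste("p for", cs[1]))
    expect_equal(mine$df1, unname(ref["Df"]), label = paste("df1", cs[1]))
  }
})

test_that("GG epsilon, Mauchly and eta_p2 match frozen reference values", {
  # Frozen from an independent reference implementation (pingouin 0.6.1,
  # rm_anova/sphericity) run on the identical seeded fixture.
  df <- anova_fixture_within()
  res <- mixed_anova(df, dv = "y", subject = "subject", within = "lure")
  expect_equal(res$F, 1.200627, tolerance = 1e-6)
  expect_equal(res$p_uncorrected, 0.319975, tolerance = 1e-5)
  expect_equal(res$epsilon, 0.789268, tolerance = 1e-6)
  expect_equal(res$p_gg, 0.314076, tolerance = 1e-5)
  expect_equal(res$mauchly_p, 0.2116064337, tolerance = 1e-8)
  # eta_p2 for the between effect of the mixed fixture (pingouin np2)
  dfm <- anova_fixture_mixed()
  resm <- mixed_anova(dfm, dv = "y", subject = "subject", between = "delay",
                      within = c("emotion", "lure"))
  expect_equal(resm$eta_p2[resm$effect == "delay"], 0.236641,
               tolerance = 1e-5)   # reference printed to 6 decimals
  # two-level within factor: epsilon exactly 1, no correction applied
  expect_equal(resm$epsilon[resm$effect == "emotion"], 1)
  expect_false(resm$gg_applied[resm$effect == "emotion"])
  # eta CI sanity: contains the point estimate, within [0, 1]
  expect_true(all(resm$eta_p2_lo <= resm$eta_p2 + 1e-12))
  expect_true(all(resm$eta_p2 <= resm$eta_p2_hi + 1e-12))
  expect_true(all(resm$eta_p2_lo >= 0 & resm$eta_p2_hi <= 1))
})

test_that("one-between-factor ANOVA reduces to the two-sample t-test", {
  set.seed(51)
  df <- data.frame(subject = sprintf("s%02d", 1:24),
                   grp = rep(c("a", "b"), each = 12),
                   cell = "c1",
                   y = rnorm(24) + rep(c(0, 0.8), each = 12))
  res <- mixed_anova(df, dv = "y", subject = "subject", between = "grp",
                     within = "cell")
  tt <- t.test(y ~ grp, df, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_uncorrected, tt$p.value, tolerance = 1e-10)
})

test_that("mixed_anova rejects malformed input", {
  df <- anova_fixture_within()
  expect_error(mixed_anova(df[-1, ], dv = "y", subject = "subject",
                           within = "lure"), "missing cell for subject s01")
  dup <- rbind(df, df[1, ])
  expect_error(mixed_anova(dup, dv = "y", subject = "subject",
                           within = "lure"), "more than one value")
  # constant dv -> zero error variance, F flagged undefined with a warning
  dfc <- df; dfc$y <- 5
  expect_warning(
    resc <- mixed_anova(dfc, dv = "y", subject = "subject", within = "lure"),
    "zero error variance")
  expect_true(is.nan(resc$F))
})

test_that("Sidak adjustment is exact and monotone", {
  expect_equal(sidak_adjust(0.02, 3), 1 - 0.98^3)      # 0.058808
  expect_equal(sidak_adjust(0.02, 3), 0.058808)
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0, 7), 0)
  expect_error(sidak_adjust(0.05, 0), "m must be")
  # monotone in m and in p
  p <- seq(0, 1, 0.05)
  expect_true(all(diff(sidak_adjust(p, 4)) >= 0))
  for (pp in c(0.001, 0.04, 0.3))
    expect_true(all(diff(sapply(1:6, function(m) sidak_adjust(pp, m))) >= 0))
})

test_that("sidak_posthoc contrasts match direct t-tests", {
  set.seed(61)
  df <- expand.grid(subject = sprintf("s%02d", 1:20),
                    emotion = c("neu", "neg"), stringsAsFactors = FALSE)
  df$delay <- ifelse(as.integer(sub("s", "", df$subject)) <= 10, "1d", "28d")
  df$y <- rnorm(40) + 0.6 * (df$emotion == "neg") * (df$delay == "28d")
  ph <- sidak_posthoc(
    df, "y", "subject", within = "emotion", between = "delay",
    contrasts = list(
      list(name = "paired", type = "paired", cells = c("neg", "neu"),
           groups = "28d"),
      list(name = "group", type = "two_sample", cells = NULL,
           groups = c("28d", "1d")),
      list(name = "ixn", type = "interaction", cells = c("neg", "neu"),
           groups = c("28d", "1d"))))
  # oracle: direct t-tests
  w <- reshape(df, idvar = c("subject", "delay"), timevar = "emotion",
               direction = "wide")
  d28 <- w[w$delay == "28d", ]
  tp <- t.test(d28$y.neg, d28$y.neu, paired = TRUE)
  expect_equal(ph$t[1], unname(tp$statistic), tolerance = 1e-10)
  expect_equal(ph$p[1], tp$p.value, tolerance = 1e-10)
  m <- (w$y.neg + w$y.neu) / 2
  tg <- t.test(m[w$delay == "28d"], m[w$delay == "1d"], var.equal = TRUE)
  expect_equal(ph$t[2], unname(tg$statistic), tolerance = 1e-10)
  dd <- w$y.neg - w$y.neu
  ti <- t.test(dd[w$delay == "28d"], dd[w$delay == "1d"], var.equal = TRUE)
  expect_equal(ph$t[3], unname(ti$statistic), tolerance = 1e-10)
  expect_equal(ph$p_sidak, sidak_adjust(ph$p, 3))
  expect_true(all(ph$p_sidak >= ph$p))
})

test_that("fit_mixed_model reports boundary fits and recovers parameters", {
  set.seed(71)
  # zero between-cluster variance -> near-zero random-intercept estimate
  d <- expand.grid(subject = sprintf("s%02d", 1:12),
                   item = sprintf("i%02d", 1:10))
  d$y <- rnorm(nrow(d))
  fit <- fit_mixed_model(
    mixed_model_spec("y", "1", c("subject", "item"), "gaussian"), d)
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  expect_lt(max(vc$vcov[vc$grp != "Residual"]), 0.05)
  expect_true(fit$converged)
  # gaussian LMM: t statistics and residual-df p-values present
  expect_true(all(is.finite(fit$coefficients$df)))
  # binomial GLMM with a strong fixed effect: sign recovered, Wald z used
  d$x <- rnorm(nrow(d))
  d$fa <- rbinom(nrow(d), 1, plogis(-0.5 + 1.2 * d$x))
  gfit <- fit_mixed_model(
    mixed_model_spec("fa", "x", c("subject", "item"), "binomial"), d)
  cf <- gfit$coefficients
  expect_gt(cf$estimate[cf$term == "x"], 0)
  expect_true(all(is.na(cf$df)))
  expect_error(fit_mixed_model(
    mixed_model_spec("fa", "x", "nosuchcol", "binomial"), d),
    "grouping factor")
})

test_that("exclude_outliers implements the mean +- 3 SD rule", {
  expect_true(all(exclude_outliers(rep(5, 10))))
  # {0,0,0,0,100}: mean 20, SD 44.72 -> 100 is within 3 SD, not excluded
  x <- c(0, 0, 0, 0, 100)
  expect_true(all(exclude_outliers(x)))
  expect_equal(abs(100 - mean(x)) / sd(x) < 3, TRUE)
  # a genuinely extreme point is excluded
  y <- c(rnorm(50), 1000)
  expect_false(exclude_outliers(y)[51])
  expect_true(all(exclude_outliers(y, k = Inf)))
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})
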