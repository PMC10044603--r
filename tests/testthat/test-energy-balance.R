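test_that("metabolic weight is the 0.75 power of mean live weight", {
  expect_equal(metabolic_weight(1, 1), 1)
  expect_equal(metabolic_weight(16, 16), 8)
  # independent evaluation through logs
  expect_equal(metabolic_weight(0.135, 0.135), exp(0.75 * log(0.135)),
               tolerance = 1e-12)
  expect_equal(metabolic_weight(0.135, 0.135), 0.2227, tolerance = 5e-4)
  # period means of unequal weights
  expect_equal(metabolic_weight(0.1, 0.3), 0.2^0.75)
  expect_error(metabolic_weight(0, 1), "positive")
  expect_error(metabolic_weight(1, -2), "positive")
})

test_that("AME follows gross energy in minus excreta energy out", {
  expect_equal(compute_ame(1.0, 16.21, 0.0), 16.21)
  expect_equal(compute_ame(0.70, 16.0, 2.24), 12.80)
  expect_equal(compute_ame(1.0, 16.0, 16.0), 0.0)
  expect_error(compute_ame(0, 16, 1), "positive")
  expect_error(compute_ame(1.0, 16.0, 17.0), "mass-balance")
  # scale equivariance: doubling intake and excreta leaves AME unchanged
  expect_equal(compute_ame(1.4, 16.0, 4.48), compute_ame(0.7, 16.0, 2.24))
})

test_that("compute_balance recovers engineered MEI/RE/HP and conserves energy", {
  # record engineered to the printed restricted-15% level means
  rec <- make_record(mei = 1.94, re = 0.51)
  bal <- compute_balance(rec)
  expect_equal(bal$mei, 1.94, tolerance = 1e-12)
  expect_equal(bal$re, 0.51, tolerance = 1e-12)
  expect_equal(bal$hp, 1.43, tolerance = 1e-12)

  # zero retention: all metabolizable intake leaves as heat
  bal0 <- compute_balance(make_record(mei = 1.5, re = 0))
  expect_equal(bal0$hp, bal0$mei)

  # conservation MEI = HP + RE to machine precision on a noisy trial
  trial <- generate_feeding_trial(trial_design(hp_sigma = 0.05), seed = 9)
  b <- compute_balance(trial)
  expect_equal(b$mei, b$hp + b$re, tolerance = 1e-14)

  # generator round trip at zero noise
  trial0 <- generate_feeding_trial(trial_design(hp_sigma = 0), seed = 2)
  b0 <- compute_balance(trial0)
  expect_equal(b0$mei, trial0$true_mei, tolerance = 1e-12)
  expect_equal(b0$re, trial0$true_re, tolerance = 1e-12)
  expect_equal(b0$hp, trial0$true_hp, tolerance = 1e-12)
})

test_that("daily rates scale with the period and negative HP is flagged", {
  rec <- make_record(mei = 1.5, re = 0.4, period = 7)
  rec14 <- rec
  rec14$period_d <- 14  # same totals over twice the time
  b7 <- compute_balance(rec)
  b14 <- compute_balance(rec14)
  expect_equal(b14$mei, b7$mei / 2)
  expect_equal(b14$re, b7$re / 2)

  neg <- make_record(mei = 1.0, re = 1.2)  # RE above intake: HP < 0
  bn <- compute_balance(neg)
  expect_true(bn$hp_negative)
  expect_equal(nrow(bn), 1L)  # flagged, not dropped

  expect_error(
    compute_balance(rec[, setdiff(names(rec), "feed_intake_kg")]),
    "lack columns")
})

test_that("difference method inverts the mixture for any inclusion", {
  expect_equal(ame_by_difference(13.0, 13.0, 0.2), 13.0)
  expect_equal(ame_by_difference(12.90, 12.80, 0.2), 13.30)
  expect_equal(ame_by_difference(12.34, 99.0, 1.0), 12.34)
  set.seed(1)
  for (i in 1:20) {
    inc <- runif(1, 0.05, 1)
    basal <- runif(1, 10, 14)
    ingredient <- runif(1, 8, 16)
    mixed <- (1 - inc) * basal + inc * ingredient
    expect_equal(ame_by_difference(mixed, basal, inc), ingredient,
                 tolerance = 1e-10)
  }
  expect_error(ame_by_difference(13, 13, 0), "\\(0, 1\\]")
  expect_error(ame_by_difference(13, 13, 1.01), "\\(0, 1\\]")
})

test_that("level summary reproduces hand-computed and lm-based ANOVA", {
  # two levels {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5
  bal <- data.frame(level = rep(c("a", "b"), each = 3), mei = c(1:3, 4:6),
                    re = 0, hp = c(1:3, 4:6))
  s <- summarize_by_level(bal, quantities = "mei")
  expect_equal(s$anova$F, 13.5)
  expect_equal(s$anova$p,
               pf(13.5, 1, 4, lower.tail = FALSE))
  # two-group identity: F equals the squared pooled-variance t statistic
  tt <- t.test(mei ~ level, data = bal, var.equal = TRUE)
  expect_equal(s$anova$F, unname(tt$statistic)^2, tolerance = 1e-12)

  # oracle on an unbalanced random layout: anova(lm(...))
  set.seed(4)
  bal2 <- data.frame(level = rep(c("a", "b", "c"), times = c(4, 5, 7)),
                     mei = rnorm(16), re = 0, hp = rnorm(16))
  s2 <- summarize_by_level(bal2, quantities = c("mei", "hp"))
  for (q in c("mei", "hp")) {
    ref <- anova(lm(bal2[[q]] ~ factor(bal2$level)))
    row <- s2$anova[s2$anova$quantity == q, ]
    expect_equal(row$F, ref$`F value`[1], tolerance = 1e-12)
    expect_equal(row$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  }

  # degenerate case: identical observations define F = 0, p = 1
  flat <- data.frame(level = rep(c("a", "b"), each = 3), mei = 1, re = 1,
                     hp = 1)
  sf <- summarize_by_level(flat, quantities = "mei")
  expect_equal(sf$anova$F, 0)
  expect_equal(sf$anova$p, 1)

  # single-replicate levels: SD undefined, excluded from ANOVA with warning
  one <- rbind(bal, data.frame(level = "c", mei = 9, re = 0, hp = 9))
  expect_warning(s3 <- summarize_by_level(one, quantities = "mei"),
                 "single replicate")
  expect_true(is.na(s3$summary$sd[s3$summary$level == "c"]))
  expect_equal(s3$anova$df_between, 1L)  # only the two full levels
})

test_that("synthetic trial at the reference design reproduces the level means", {
  trial <- generate_feeding_trial(trial_design(), seed = 6)
  bal <- compute_balance(trial)
  s <- summarize_by_level(bal)
  lv <- reference_feeding_levels()
  got <- s$summary[s$summary$quantity == "mei", ]
  got <- got[match(lv$level, got$level), ]
  # each level mean within 3 SE of its target
  expect_true(all(abs(got$mean - lv$mei_mean) <
                    3 * lv$mei_sd / sqrt(lv$mei_sd * 0 + 5)))
  # restriction is detected: MEI differs strongly across levels
  expect_lt(s$anova$p[s$anova$quantity == "mei"], 1e-6)
})
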