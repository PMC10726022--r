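test_that("filter_farms applies the per-trait minimum-records rule", {
  d <- data.frame(farm = rep(c("F1", "F2", "F3"), c(5, 4, 3)),
                  BW = rnorm(12))
  out <- suppressMessages(filter_farms(d, "BW", 4))
  expect_setequal(unique(out$farm), c("F1", "F2"))
  expect_equal(attr(out, "dropped_farms"), "F3")

  expect_equal(nrow(filter_farms(d, "BW", 1)), 12)

  # a missing trait value makes a borderline farm fall below threshold
  d$BW[6] <- NA
  out <- suppressMessages(filter_farms(d, "BW", 4))
  expect_equal(unique(out$farm), "F1")

  expect_error(suppressMessages(filter_farms(d, "BW", 50)), "lower")
})

test_that("balanced one-way fit recovers means, effects and the t^2 identity", {
  d <- data.frame(g = rep(c("lo", "hi"), each = 6),
                  y = c(10, 11, 9, 10.5, 9.5, 10, 20, 21, 19, 20.5, 19.5, 20))
  fit <- fit_fixed_model(d, "y", "g")
  expect_equal(fit$mu, 15)
  expect_equal(sort(unname(fit$effects$g)), c(-5, 5))
  lsm <- ls_means(fit, "g")
  expect_equal(sort(lsm$estimate), c(10, 20))
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(fit$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$anova$p, tt$p.value, tolerance = 1e-10)
})

test_that("constant response yields zero effects and undefined F with warning", {
  d <- data.frame(g = rep(c("a", "b"), 4), y = rep(3, 8))
  expect_warning(fit <- fit_fixed_model(d, "y", "g"), "zero")
  expect_equal(unname(fit$effects$g), c(0, 0))
  expect_true(is.nan(fit$anova$F) || !is.finite(fit$anova$F))
})

test_that("unbalanced two-factor coefficients match the pseudoinverse oracle", {
  d <- two_factor_data()
  fit <- fit_fixed_model(d, "y", c("f1", "f2"))
  # brute-force normal equations with explicit sum-to-zero design matrix
  M <- cbind(1,
             ifelse(d$f1 == "a", 1, -1),
             ifelse(d$f2 == "x", 1, -1))
  beta <- MASS::ginv(M) %*% d$y
  expect_equal(fit$mu, beta[1], tolerance = 1e-10)
  expect_equal(unname(fit$effects$f1[c("a", "b")]),
               c(beta[2], -beta[2]), tolerance = 1e-10)
  expect_equal(unname(fit$effects$f2[c("x", "y")]),
               c(beta[3], -beta[3]), tolerance = 1e-10)
})

test_that("ls_means equal raw group means in one-way designs and the
           cell-prediction average in two-factor designs", {
  set.seed(31)
  d1 <- data.frame(g = rep(c("a", "b", "c"), c(3, 5, 4)), y = rnorm(12))
  fit1 <- fit_fixed_model(d1, "y", "g")
  lsm1 <- ls_means(fit1, "g")
  expect_equal(lsm1$estimate,
               as.vector(tapply(d1$y, d1$g, mean))[match(lsm1$level,
                                                         c("a", "b", "c"))])

  d2 <- two_factor_data(seed = 33)
  fit2 <- fit_fixed_model(d2, "y", c("f1", "f2"))
  for (f in c("f1", "f2")) {
    lsm <- ls_means(fit2, f)
    oracle <- lsmeans_oracle(fit2, f)
    expect_equal(lsm$estimate, unname(oracle[lsm$level]), tolerance = 1e-10)
  }
  expect_true(all(ls_means(fit2, "f1")$SE > 0))
})

test_that("F statistics are invariant to level relabeling and response shifts", {
  d <- two_factor_data(seed = 40)
  f0 <- fit_fixed_model(d, "y", c("f1", "f2"))$anova$F
  d2 <- d
  levels(d2$f1) <- c("zzz", "aaa")
  d2$y <- d2$y + 100
  f1 <- fit_fixed_model(d2, "y", c("f1", "f2"))$anova$F
  expect_equal(f0, f1, tolerance = 1e-10)
})

test_that("tukey_groups letters separate means as the studentized range dictates", {
  set.seed(52)
  # two far-separated groups
  d <- data.frame(g = rep(c("hi", "lo"), each = 6),
                  y = c(rnorm(6, 50, 1), rnorm(6, 10, 1)))
  tg <- tukey_groups(fit_fixed_model(d, "y", "g"), "g")
  expect_equal(tg$letters, c("a", "b"))
  expect_equal(tg$level, c("hi", "lo"))    # highest mean first, letter "a"

  # indistinguishable groups share the letter
  d2 <- data.frame(g = rep(c("p", "q"), each = 6),
                   y = c(rnorm(6, 10, 5), rnorm(6, 10.2, 5)))
  tg2 <- tukey_groups(fit_fixed_model(d2, "y", "g"), "g")
  expect_equal(tg2$letters, c("a", "a"))

  # three groups with only the extremes differing -> a / ab / b
  found <- FALSE
  for (seed in 1:50) {
    set.seed(seed)
    d3 <- data.frame(g = rep(c("A", "B", "C"), each = 5),
                     y = c(rnorm(5, 0, 1.1), rnorm(5, 1.4, 1.1), rnorm(5, 2.8, 1.1)))
    fit3 <- fit_fixed_model(d3, "y", "g")
    emm <- emmeans::emmeans(fit3$lm, "g", data = fit3$data)
    pv <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))$p.value
    # contrasts ordered A-B, A-C, B-C; want only A vs C significant
    if (pv[2] < 0.05 && pv[1] > 0.05 && pv[3] > 0.05) {
      tg3 <- tukey_groups(fit3, "g")
      expect_equal(tg3$letters[order(tg3$level)], c("b", "ab", "a"))
      found <- TRUE
      break
    }
  }
  expect_true(found)

  dd <- data.frame(g = rep(c("a", "b"), 3), y = rep(1, 6))
  fitd <- suppressWarnings(fit_fixed_model(dd, "y", "g"))
  expect_error(tukey_groups(fitd, "g"), "MS_error")
})

test_that("adjust_phenotypes removes significant effects and keeps the grand mean", {
  set.seed(61)
  # strong two-level effect: groups equalized after adjustment
  d <- data.frame(g = rep(c("a", "b"), c(7, 5)))
  d$y <- 10 + ifelse(d$g == "a", 5, -5) + rnorm(12, 0, 0.5)
  fit <- fit_fixed_model(d, "y", "g")
  adj <- adjust_phenotypes(fit)
  expect_equal(attr(adj, "adjusted_for"), "g")
  gm <- tapply(adj$y_adj, adj$g, mean)
  expect_lt(abs(gm[["a"]] - gm[["b"]]), 1)
  expect_equal(mean(adj$y_adj), mean(d$y), tolerance = 1e-9)

  # non-significant factors leave data untouched
  set.seed(62)
  d2 <- data.frame(g = rep(c("a", "b"), 10), y = rnorm(20))
  fit2 <- fit_fixed_model(d2, "y", "g")
  if (fit2$anova$p > 0.05) {
    adj2 <- adjust_phenotypes(fit2)
    expect_equal(adj2$y_adj, d2$y)
  }
  adj2a <- adjust_phenotypes(fit2, which = "all")
  expect_equal(attr(adj2a, "adjusted_for"), "g")
})

test_that("adjusted values are decorrelated from simulated farm effects", {
  set.seed(71)
  n <- 1000
  farms <- sprintf("F%02d", 1:25)
  farm_eff <- setNames(rnorm(25, 0, 4), farms)
  d <- data.frame(farm = sample(farms, n, replace = TRUE))
  d$y <- 50 + farm_eff[d$farm] + rnorm(n, 0, 2)
  fit <- fit_fixed_model(d, "y", "farm")
  adj <- adjust_phenotypes(fit)
  expect_lt(abs(cor(adj$y_adj, farm_eff[adj$farm])), 0.05)
})

test_that("aliased factors are reported as a singular design", {
  d <- data.frame(f1 = rep(c("a", "b"), each = 4),
                  f2 = rep(c("x", "y"), each = 4), y = rnorm(8))
  expect_error(fit_fixed_model(d, "y", c("f1", "f2")), "singular|aliased")
})
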