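test_that("nested ANOVA with one culture equals classical one-way ANOVA", {
  d <- data.frame(value = c(1, 2, 3, 4, 5, 6),
                  group = rep(c("a", "b"), each = 3),
                  culture = "c1")
  res <- nested_anova(d)
  # closed-form oracle: SSB = 3*(1.5^2+1.5^2) = 13.5, MSW = 4/4 = 1
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # equality with R's own one-way ANOVA on a larger sample
  set.seed(2)
  d2 <- data.frame(value = rnorm(40), group = rep(c("a", "b", "c", "d"), 10),
                   culture = "c1")
  res2 <- nested_anova(d2)
  oracle <- anova(lm(value ~ group, d2))
  expect_equal(res2$F, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(res2$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("culture variance is absorbed before testing the group effect", {
  # big culture offsets, no group effect: p stays large even though a
  # culture-blind ANOVA would not change (offsets balanced across groups)
  d <- simulate_grouped_measurements(c(a = 0, b = 0), c(-50, 0, 50), 1, 6,
                                     seed = 4)
  res <- nested_anova(d)
  expect_gt(res$p, 0.01)
  # residual df: 36 obs - 1 - (2-1) - (3-1) = 32
  expect_equal(res$df2, 32)

  # group effect on top of culture structure is found
  d2 <- simulate_grouped_measurements(c(a = 0, b = 10), c(-50, 0, 50), 1, 6,
                                      seed = 4)
  expect_lt(nested_anova(d2)$p, 1e-6)
})

test_that("degenerate and aliased designs are handled explicitly", {
  # identical group means, zero noise: F = 0, p = 1
  d <- simulate_grouped_measurements(c(a = 5, b = 5), c(0, 2), 0, 3, seed = 1)
  res <- nested_anova(d)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # culture perfectly aliased with group
  d2 <- data.frame(value = rnorm(12), group = rep(c("a", "b"), each = 6),
                   culture = rep(c("c1", "c2"), each = 6))
  expect_error(nested_anova(d2), "aliased")

  expect_error(nested_anova(data.frame(value = 1:5, group = "a",
                                       culture = "c1")), "2 groups")
})

test_that("null simulations give uniform p-values and nominal type-I error", {
  ps <- vapply(1:400, function(s) {
    d <- simulate_grouped_measurements(c(a = 0, b = 0), c(-1, 0, 1), 1, 5,
                                       seed = s)
    nested_anova(d)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.07)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("Tukey contrasts match the studentized-range oracle", {
  set.seed(6)
  d <- data.frame(
    value = rnorm(30) + rep(c(0, 0.5, 2), each = 10),
    group = rep(c("a", "b", "c"), each = 10),
    culture = "c1"
  )
  out <- pairwise_contrasts(d)
  expect_equal(nrow(out), 3)

  # brute-force oracle for balanced one-way data: q = |diff| / SE,
  # p = ptukey(q * sqrt(2), nmeans, df)
  fit <- lm(value ~ group, d)
  mse <- sum(resid(fit)^2) / fit$df.residual
  se <- sqrt(mse * (1 / 10 + 1 / 10))
  means <- tapply(d$value, d$group, mean)
  pair <- function(g1, g2) {
    ptukey(abs(means[g1] - means[g2]) / se * sqrt(2), 3, fit$df.residual,
           lower.tail = FALSE)
  }
  oracle <- c(pair("a", "b"), pair("a", "c"), pair("b", "c"))
  expect_equal(out$p.value, unname(oracle), tolerance = 1e-6)

  # three identical groups, tiny noise: all p ~ 1
  d0 <- data.frame(value = rep(c(1, 1.0001, 0.9999), 9),
                   group = rep(c("a", "b", "c"), each = 9), culture = "c1")
  expect_true(all(pairwise_contrasts(d0)$p.value > 0.95))

  expect_error(pairwise_contrasts(d[d$group != "c", ]), "nested_anova")
})

test_that("one-sample t matches the closed form", {
  x <- c(90, 95, 100, 105)
  res <- one_sample_t(x, 100)
  t_oracle <- (mean(x) - 100) / (sd(x) / sqrt(4))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)       # -0.7746
  expect_equal(res$p, 2 * pt(t_oracle, 3), tolerance = 1e-12)  # 0.4950

  # symmetric sample: t = 0, p = 1
  res0 <- one_sample_t(c(99, 101, 98, 102), 100)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  expect_error(one_sample_t(5, 0), "at least 2")
  expect_error(one_sample_t(c(3, 3, 3), 0), "variance")
})

test_that("outlier flags catch gross outliers and stay quiet under the null", {
  # a 10 MAD outlier in n = 20 is flagged
  set.seed(11)
  x <- rnorm(19)
  x20 <- c(x, median(x) + 10 * mad(x))
  flags <- flag_outliers(x20)
  expect_true(flags[20])
  expect_equal(sum(flags), 1)

  # identical values: nothing flagged
  expect_true(all(!flag_outliers(rep(2, 10))))

  # homogeneous Gaussian samples: flag rate stays at or below ~q
  rate <- mean(vapply(1:200, function(s) {
    set.seed(s)
    mean(flag_outliers(rnorm(25)))
  }, numeric(1)))
  expect_lt(rate, 0.02)
})

test_that("the DE filter applies strict two-sided thresholds", {
  tab <- data.frame(
    protein = paste0("p", 1:5),
    log2fc = c(0.60, -0.70, 0.50, 1.0, 0.56),
    qvalue = c(0.005, 0.001, 0.001, 0.02, 0.005)
  )
  res <- filter_de_table(tab)
  expect_equal(nrow(res$significant), 2)
  expect_equal(res$n_up, 1)
  expect_equal(res$n_down, 1)
  expect_equal(res$pct_up, 50)
  expect_equal(res$pct_down, 50)
  expect_equal(res$pct_of_total, 40)
  # the boundary protein (log2fc exactly 0.56) is excluded
  expect_false("p5" %in% res$significant$protein)

  # all q = 1: empty; zero thresholds: everything with nonzero fc kept
  expect_equal(nrow(filter_de_table(transform(tab, qvalue = 1))$significant), 0)
  expect_equal(nrow(filter_de_table(tab, 0, 1.01)$significant), 5)
})

test_that("the DE filter is order-invariant and monotone in its thresholds", {
  set.seed(21)
  tab <- data.frame(
    protein = paste0("p", 1:300),
    log2fc = rnorm(300, 0, 1),
    qvalue = runif(300)
  )
  res <- filter_de_table(tab)
  shuf <- tab[sample(nrow(tab)), ]
  res2 <- filter_de_table(shuf)
  expect_setequal(res$significant$protein, res2$significant$protein)
  expect_equal(res$n_up, res2$n_up)

  n_at <- function(fc, q) nrow(filter_de_table(tab, fc, q)$significant)
  expect_true(all(diff(vapply(c(0, 0.3, 0.56, 1, 2), n_at, numeric(1),
                              q = 0.5)) <= 0))
  expect_true(all(diff(vapply(c(0.9, 0.5, 0.1, 0.01), n_at, numeric(1),
                              fc = 0.56)) <= 0))
})
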