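test_that("crosstab reproduces published within-column percentages", {
  # anxiety low-flat row of the depression baseline table: counts over
  # column totals (3641, 205, 33, 104)
  labels <- factor(rep(c("lf", "ltm", "lth", "hs"), c(3641, 205, 33, 104)),
                   levels = c("lf", "ltm", "lth", "hs"))
  anx_lf <- c(rep(c(1, 0), c(3519, 3641 - 3519)),
              rep(c(1, 0), c(162, 205 - 162)),
              rep(c(1, 0), c(28, 33 - 28)),
              rep(c(1, 0), c(76, 104 - 76)))
  ct <- crosstab(labels, factor(anx_lf, levels = c(1, 0)))
  expect_equal(unname(ct$col_pct["1", c("ltm", "hs")]), c(79.0, 73.1))
  # the published table prints 96.7 although 3519/3641 rounds to 96.6; its
  # own rounding is inconsistent, so this cell is held to +/- 0.1
  expect_equal(unname(ct$col_pct["1", "lf"]), 96.7, tolerance = 0.00105)
  expect_equal(unname(ct$counts["1", ]), c(3519, 162, 28, 76),
               ignore_attr = TRUE)
})

test_that("crosstab degenerate layouts give exact percentages", {
  ct <- crosstab(c("a", "a", "b", "b"), rep("only", 4))
  expect_equal(unname(ct$col_pct[1, ]), c(100, 100))
  ct2 <- crosstab(c("a", "a", "b", "b"), c("x", "y", "x", "y"))
  expect_true(all(ct2$col_pct == 50))
  expect_error(crosstab(character(0), character(0)), "empty")
})

test_that("missing covariates are excluded and counted per group", {
  labels <- c("g1", "g1", "g2", "g2", "g2")
  cov <- c("a", NA, "b", "a", NA)
  ct <- crosstab(labels, cov)
  expect_equal(unname(ct$n_excluded), c(1L, 1L))
  expect_equal(unname(ct$col_n), c(1, 2))
})

test_that("chisq_test reproduces the Pearson statistic", {
  r <- chisq_test(rbind(c(10, 20), c(20, 10)))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-4)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, 0.009823, tolerance = 1e-3)

  # a table equal to its independence expectation has statistic 0
  r0 <- chisq_test(rbind(c(10, 20), c(20, 40)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  # homogeneity: scaling counts by 10 scales the statistic by 10
  r10 <- chisq_test(rbind(c(100, 200), c(200, 100)))
  expect_equal(r10$statistic, 10 * r$statistic, tolerance = 1e-10)

  expect_error(chisq_test(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_gt(chisq_test(rbind(c(2, 1), c(1, 2)))$n_expected_lt_5, 0)
})

test_that("2x2 multinomial logit equals the cross-product odds ratio", {
  labels <- rep(c("ref", "alt"), c(30, 30))
  cov <- c(rep(c("x0", "x1"), c(20, 10)), rep(c("x0", "x1"), c(10, 20)))
  t <- multinomial_logit(labels, data.frame(v = cov), reference_group = "ref")
  expect_equal(t$or, 4, tolerance = 1e-8)
  expect_true(t$ci_low < 4 && 4 < t$ci_high)
})

test_that("two-group multinomial logit matches binary logistic regression", {
  set.seed(51)
  n <- 300
  x <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  z <- factor(sample(c("m", "f"), n, replace = TRUE))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * (x == "b") + 0.4 * (z == "m")))
  labels <- factor(ifelse(y == 1, "g2", "g1"))
  t <- multinomial_logit(labels, data.frame(x = x, z = z),
                         reference_group = "g1")
  ref <- glm(y ~ x + z, family = binomial())
  expect_equal(unname(attr(t, "coef")[1, ]), unname(coef(ref)),
               tolerance = 1e-8)
})

test_that("multinomial logit agrees with an independent implementation", {
  skip_if_not_installed("nnet")
  set.seed(52)
  n <- 400
  x <- factor(sample(c("lo", "hi"), n, replace = TRUE))
  g <- factor(sample(c("r", "s", "t"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)))
  t <- multinomial_logit(g, data.frame(x = x), reference_group = "r")
  ref <- nnet::multinom(g ~ x, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(attr(t, "coef")), unname(coef(ref)), tolerance = 1e-4)
})

test_that("a covariate independent of the label gives OR near 1 at N=1e4", {
  set.seed(53)
  n <- 10000
  labels <- factor(sample(c("g1", "g2"), n, replace = TRUE))
  cov <- factor(sample(c("a", "b"), n, replace = TRUE))
  t <- multinomial_logit(labels, data.frame(v = cov))
  expect_lt(abs(log(t$or)), 0.1)
})

test_that("quasi-complete separation is flagged, not reported as a finite OR", {
  labels <- rep(c("g1", "g2"), c(20, 20))
  cov <- rep(c("a", "b"), c(20, 20))  # perfectly separates the groups
  t <- suppressWarnings(multinomial_logit(labels, data.frame(v = cov)))
  expect_true(t$flagged)
  expect_true(is.na(t$or))
})

test_that("singular designs fail naming the aliased column", {
  labels <- factor(rep(c("g1", "g2"), 25))
  v <- factor(rep(c("a", "b"), each = 25))
  w <- v  # perfectly aliased
  expect_error(multinomial_logit(labels, data.frame(v = v, w = w)),
               "aliased.*w")
})

test_that("swapping the reference level reciprocates the odds ratio", {
  set.seed(54)
  n <- 500
  cov <- factor(sample(c("a", "b"), n, replace = TRUE))
  labels <- factor(rbinom(n, 1, plogis(-0.3 + 0.9 * (cov == "b"))),
                   labels = c("g1", "g2"))
  t_ab <- multinomial_logit(labels, data.frame(v = cov))
  t_ba <- multinomial_logit(labels, data.frame(v = relevel(cov, "b")))
  expect_equal(t_ba$or, 1 / t_ab$or, tolerance = 1e-6)
  expect_equal(t_ba$ci_low, 1 / t_ab$ci_high, tolerance = 1e-6)
  expect_equal(t_ba$ci_high, 1 / t_ab$ci_low, tolerance = 1e-6)
})

test_that("univariate screen reduces to multinomial_logit per covariate", {
  set.seed(55)
  n <- 300
  x <- factor(sample(c("a", "b"), n, replace = TRUE))
  z <- factor(sample(c("u", "v"), n, replace = TRUE))
  g <- factor(sample(c("g1", "g2"), n, replace = TRUE))
  sc <- univariate_screen(g, data.frame(x = x, z = z))
  expect_named(sc, c("x", "z"))
  single <- multinomial_logit(g, data.frame(x = x))
  expect_equal(sc$x$or, single$or)
})

test_that("univariate screen recovers a simulated doubled odds at N=5000", {
  set.seed(56)
  n <- 5000
  female <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 1, plogis(-2 + log(2) * female))
  labels <- factor(ifelse(g == 1, "g2", "g1"))
  sc <- univariate_screen(labels, data.frame(
    sex = factor(ifelse(female == 1, "female", "male"), c("male", "female"))))
  expect_lt(abs(sc$sex$or - 2) / 2, 0.25)
})

test_that("baseline_table conserves column counts and isolates exclusions", {
  cfg <- khps_preset(N = 500)
  sim <- generate_dual_panel(cfg, seed = 57)
  labels <- factor(sim$labels$group1)
  bt <- baseline_table(sim$panel, labels)
  for (g in levels(labels)) {
    sex_rows <- bt$table$covariate == "sex"
    expect_equal(sum(bt$table[sex_rows, paste0("n_", g)]),
                 unname(as.integer(bt$col_n[g])))
  }
  expect_true(all(c("sex", "chronic3", "econ_activity") %in%
                    bt$tests$covariate))

  # a missing covariate category is excluded and reported
  p2 <- sim$panel
  p2$covariates$sex[1:5] <- NA
  bt2 <- baseline_table(p2, labels, "sex")
  expect_equal(sum(bt2$excluded["sex", ]), 5)
  expect_equal(sum(bt2$table[, grep("^n_", names(bt2$table))]),
               n_subjects(p2) - 5)
})
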