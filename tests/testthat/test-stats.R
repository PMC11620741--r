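test_that("one-sample Wilcoxon: exact small-n behavior and flags", {
  # six values all above mu: exact two-sided p = 2/2^6
  r <- wilcoxon_one_sample(c(1.2, 1.4, 1.1, 1.3, 1.25, 1.5), mu = 1)
  expect_equal(r$p_value, 2 / 64)
  expect_equal(r$n, 6)

  # exact enumeration oracle for n <= 10: p = 2 P(V >= v) via full
  # enumeration of sign patterns
  enum_p <- function(x, mu) {
    d <- x - mu
    rk <- rank(abs(d))
    v_obs <- sum(rk[d > 0])
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% rk
    min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
  }
  set.seed(51)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    x <- round(1 + rnorm(n, 0.2, 0.5), 3)
    x <- x[x != 1]
    if (any(duplicated(abs(x - 1))) || length(x) < 6) next
    r <- wilcoxon_one_sample(x, mu = 1)
    expect_equal(r$p_value, enum_p(x, 1), tolerance = 1e-12)
  }

  # a sample whose signed-rank statistic sits exactly at its null mean: p = 1
  sym <- wilcoxon_one_sample(1 + c(0.1, -0.2, -0.3, -0.4, -0.5, 0.6, 0.7),
                             mu = 1)
  expect_equal(sym$p_value, 1)
  expect_warning(wilcoxon_one_sample(c(1.1, 1.2, 1.3, 1.4), mu = 1),
                 "cannot reach 0.05")
  # values equal to mu are dropped; all equal -> undefined
  expect_true(wilcoxon_one_sample(rep(1, 8), mu = 1)$undefined)
})

test_that("Kruskal-Wallis: hand-computed H, degeneracy and symmetry", {
  r <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-9)  # 3.857 with df 1
  expect_equal(r$df, 1)

  same <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(same$undefined)

  set.seed(52)
  g <- list(rnorm(6), rnorm(5), rnorm(7))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(rev(g))$statistic, tolerance = 1e-12)
})

test_that("linear-model ANOVA F matches the closed form", {
  # 5-point hand-computable fixture
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  r <- linear_model_anova(y, x)
  fit <- stats::lm(y ~ x)
  ssr <- sum((stats::fitted(fit) - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  expect_equal(r$statistic, (ssr / 1) / (sse / 3), tolerance = 1e-9)
  expect_equal(r$df, c(1, 3))

  perfect <- linear_model_anova(2 * x + 1, x)
  expect_equal(perfect$statistic, Inf)
  expect_equal(perfect$p_value, 0)
  expect_equal(perfect$slope, 2, tolerance = 1e-12)

  expect_error(linear_model_anova(y, rep(3, 5)), "variance")

  # under the null the F statistic's mean ~ df2/(df2 - 2)
  set.seed(53)
  n <- 30
  fs <- replicate(1000, linear_model_anova(rnorm(n), rnorm(n))$statistic)
  expect_equal(mean(fs), (n - 2) / (n - 4), tolerance = 0.15)
})

test_that("paired t: identity, degeneracy and closed-form oracle", {
  a <- c(1, 2, 3)
  same <- paired_t(a, a)
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)

  shifted <- paired_t(a + 1, a)
  expect_true(shifted$undefined)

  set.seed(54)
  x <- rnorm(9, 0.3); y <- rnorm(9)
  r <- paired_t(x, y)
  d <- x - y
  t_closed <- mean(d) / (stats::sd(d) / sqrt(9))
  expect_equal(r$statistic, t_closed, tolerance = 1e-12)
  expect_equal(r$df, 8)
  expect_equal(r$p_value, 2 * stats::pt(-abs(t_closed), 8), tolerance = 1e-12)
})

test_that("firing incidence rounds percentages to one decimal", {
  tab <- data.frame(cell = rep(sprintf("c%02d", 1:60), times = 2),
                    modality = rep(c("auditory", "tectal"), each = 60),
                    fired = c(rep(c(TRUE, FALSE), c(3, 57)),
                              rep(c(TRUE, FALSE), c(4, 56))))
  out <- firing_incidence(tab)
  expect_equal(out$percent[out$modality == "auditory"], 5.0)
  expect_equal(out$percent[out$modality == "tectal"], 6.7)
  none <- firing_incidence(data.frame(cell = "c1", modality = "m",
                                      fired = FALSE))
  expect_equal(none$percent, 0)
  expect_error(firing_incidence(tab[0, ]), "empty")
})
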