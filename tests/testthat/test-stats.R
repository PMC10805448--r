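test_that("normality screening passes normal and rejects uniform samples", {
  pass <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    ks_normality(rnorm(200))$p > 0.05
  })
  expect_gte(mean(pass), 0.9)
  rej <- sapply(1:20, function(s) {
    set.seed(2000 + s)
    ks_normality(runif(200))$p < 0.05
  })
  expect_gte(mean(rej), 0.9)
  expect_error(ks_normality(rep(1, 50)), "constant")
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("adjusted comparison reduces to the pooled two-sample t test", {
  set.seed(3)
  y <- rnorm(30)
  group <- rep(c("patient", "control"), each = 15)
  # constant covariates carry no information and are dropped
  cmp <- adjusted_group_compare(y, group, age = rep(35, 30),
                                gender = rep("male", 30))
  tt <- t.test(y[group == "control"], y[group == "patient"],
               var.equal = TRUE)
  expect_equal(abs(cmp$t), abs(unname(tt$statistic)), tolerance = 1e-12)
  expect_equal(cmp$p, tt$p.value, tolerance = 1e-12)
  expect_equal(cmp$df, 28)
  expect_setequal(cmp$dropped_covariates, c("age", "gender"))
  # perfect group separation (lm warns about the perfect fit; expected)
  sep <- suppressWarnings(
    adjusted_group_compare(as.numeric(group == "patient"), group,
                           age = rnorm(30), gender = rep(0:1, 15))
  )
  expect_lt(sep$p, 1e-12)
})

test_that("adjusted comparison removes covariate confounding", {
  set.seed(4)
  n <- 60
  group <- rep(c("patient", "control"), each = n / 2)
  age <- rnorm(n, ifelse(group == "patient", 45, 30), 5)
  y <- 0.5 * age + rnorm(n, sd = 0.5)  # age effect only, no group effect
  naive <- t.test(y ~ group, var.equal = TRUE)$p.value
  adj <- adjusted_group_compare(y, group, age = age,
                                gender = rep(0:1, n / 2))
  expect_lt(naive, 0.01)  # confounded test finds a spurious difference
  expect_gt(adj$p, 0.05)  # adjustment removes it
  # adjusted means are evaluated at grand-mean covariates
  expect_lt(abs(diff(adj$adjusted_means)), abs(diff(tapply(y, group, mean))))
})

test_that("adjusted comparison attains nominal type-I error", {
  set.seed(5)
  n_sim <- 400
  hits <- 0
  group <- rep(c("patient", "control"), c(18, 29))
  for (s in seq_len(n_sim)) {
    age <- rnorm(47, 29, 7)
    gender <- rbinom(47, 1, 0.6)
    y <- rnorm(47)
    if (adjusted_group_compare(y, group, age, gender)$p < 0.05) {
      hits <- hits + 1
    }
  }
  # 3 binomial SDs around 5% at 400 simulations
  expect_lt(abs(hits / n_sim - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("rank-deficient designs raise an explicit error", {
  group <- rep(c("patient", "control"), each = 10)
  y <- rnorm(20)
  expect_error(
    adjusted_group_compare(y, group, age = rnorm(20),
                           gender = as.numeric(group == "patient")),
    "confounded"
  )
  expect_error(adjusted_group_compare(y, rep("patient", 20)), "two levels")
})

test_that("BH adjustment follows the step-up rule", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$q, rep(0.04, 4))
  expect_true(all(out$reject))
  expect_equal(fdr_bh(0.031)$q, 0.031)       # m = 1: adjusted equals raw
  expect_false(any(fdr_bh(rep(1, 10))$reject))
  p <- c(0.001, 0.02, 0.3, 0.9)
  out2 <- fdr_bh(p)
  expect_true(all(out2$q >= p))
  expect_true(all(diff(out2$q[order(p)]) >= 0))  # monotone in order stats
  expect_true(all(out2$q <= 1))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial correlation matches its closed-form oracle", {
  set.seed(6)
  n <- 1e5
  z <- rnorm(n)
  x <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  y_t <- 0.4 * z + sqrt(1 - 0.16) * rnorm(n)
  pc <- partial_correlation(x, y_t, cbind(z = z))
  # closed form from the same sample's pairwise correlations
  rxy <- cor(x, y_t); rxz <- cor(x, z); rzy <- cor(z, y_t)
  closed <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  expect_equal(pc$r, closed, tolerance = 1e-3)
  expect_equal(pc$df, n - 3L)
  # and the population value for this construction is ~0 (x,y only share z)
  expect_lt(abs(pc$r), 0.02)
})

test_that("partial correlation handles edge cases and invariances", {
  set.seed(7)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  # constant covariate is a no-op: plain Pearson correlation
  pc <- partial_correlation(x, y, cbind(rep(1, 50)))
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, x, NULL)$r, 1)
  # affine rescaling of x, y and covariates leaves r unchanged
  z <- rnorm(50)
  a <- partial_correlation(x, y, cbind(z))
  b <- partial_correlation(3 * x - 1, -2 * y + 5, cbind(10 * z + 2))
  expect_equal(abs(a$r), abs(b$r), tolerance = 1e-12)
  expect_error(partial_correlation(rnorm(5), rnorm(5),
                                   matrix(rnorm(15), 5, 3)), "degrees")
  expect_error(partial_correlation(x, 2 * x, cbind(x)), "residual variance")
})
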