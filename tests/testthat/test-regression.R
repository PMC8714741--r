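test_that("a noiseless line is recovered exactly", {
  d <- tibble::tibble(x = seq(-3, 3, length.out = 30), y = 2 * x)
  fit <- suppressWarnings(fit_ols(d, "y", "x")) # lm warns on a perfect fit
  expect_equal(fit$coefficients$B[2], 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$beta[2], 1, tolerance = 1e-12)
})

test_that("fit_ols matches the normal-equations oracle to 1e-10", {
  withr::local_seed(44)
  for (rep in 1:10) {
    d <- tibble::tibble(
      x1 = rnorm(50), x2 = rnorm(50), x3 = rnorm(50),
      y = 1 + 0.5 * x1 - 0.3 * x2 + rnorm(50)
    )
    fit <- fit_ols(d, "y", c("x1", "x2", "x3"))
    o <- ols_oracle(d[c("x1", "x2", "x3")], d$y)
    expect_equal(fit$coefficients$B, unname(o$b), tolerance = 1e-10)
    expect_equal(fit$coefficients$se_B, unname(o$se), tolerance = 1e-10)
    expect_equal(fit$r2, o$r2, tolerance = 1e-10)
    # standardized coefficients follow B * sd(x) / sd(y)
    expect_equal(
      fit$coefficients$beta[-1],
      unname(o$b[-1] * sapply(d[c("x1", "x2", "x3")], sd)) / sd(d$y),
      tolerance = 1e-10
    )
  }
  expect_error(fit_ols(tibble::tibble(y = rnorm(3), x = rnorm(3), z = rnorm(3)),
                       "y", c("x", "z")), "too few")
  d <- tibble::tibble(x = rnorm(20))
  d$z <- 2 * d$x
  d$y <- rnorm(20)
  expect_error(fit_ols(d, "y", c("x", "z")), "rank")
})

test_that("hierarchical block statistics match the direct nested F test", {
  withr::local_seed(7)
  d <- tibble::tibble(
    age = rnorm(90, 38, 11),
    gender = sample(c("female", "male"), 90, replace = TRUE),
    m1 = rnorm(90), m2 = rnorm(90),
    y = 8 - 0.1 * age + 1.5 * m1 + rnorm(90, 0, 5)
  )
  hf <- hierarchical_fit(d, "y", list(c("age", "gender"), c("m1", "m2")))
  gl <- glance(hf)

  # oracle: residual-sum-of-squares nested F via anova()
  d2 <- d
  d2$gender <- as.numeric(d2$gender == "male")
  lm0 <- lm(y ~ age + gender, data = d2)
  lm1 <- lm(y ~ age + gender + m1 + m2, data = d2)
  an <- anova(lm0, lm1)
  expect_equal(gl$delta_f[2], an$F[2], tolerance = 1e-8)
  expect_equal(gl$p_change[2], an$`Pr(>F)`[2], tolerance = 1e-8)
  expect_equal(gl$r2, c(summary(lm0)$r.squared, summary(lm1)$r.squared),
               tolerance = 1e-10)
  expect_equal(gl$delta_r2[2], gl$r2[2] - gl$r2[1], tolerance = 1e-12)
  expect_true(all(gl$delta_r2 >= 0))
  expect_error(
    hierarchical_fit(d, "y", list(c("age"), c("age", "m1"))),
    "more than one block"
  )
})

test_that("adding pure noise never lowers R2 and gives F-change near 1", {
  withr::local_seed(12)
  delta_f <- replicate(200, {
    d <- tibble::tibble(x = rnorm(50), y = rnorm(50), z = rnorm(50))
    gl <- glance(hierarchical_fit(d, "y", list("x", "z")))
    stopifnot(gl$delta_r2[2] >= 0)
    gl$delta_f[2]
  })
  # E[F(1, 46)] = 46/44 ~ 1.05
  expect_equal(mean(delta_f), 1.05, tolerance = 0.35)
})

test_that("published fit statistics are reproduced from printed R2 values", {
  # combined model: R2 .344, dR2 .261, n 90, 3 added predictors over 5
  expect_equal(fchange_from_r2(0.344, 0.261, 90, 3, 5), 11.119,
               tolerance = 0.05 / 11.119)
  # demographics-only model: R2 .083 with 2 predictors
  expect_equal(model_f_from_r2(0.083, 2, 90), 3.944, tolerance = 0.05 / 3.944)
})

test_that("VIFs equal the closed form and an independent implementation", {
  withr::local_seed(3)
  # exactly correlated pair: VIF = 1 / (1 - r^2), r = 0.5 -> 4/3
  n <- 40
  z1 <- scale(rnorm(n))[, 1]
  z2 <- scale(resid(lm(rnorm(n) ~ z1)))[, 1]
  r <- 0.5
  d <- tibble::tibble(a = z1, b = r * z1 + sqrt(1 - r^2) * z2)
  v <- vif(d, c("a", "b"))
  expect_equal(unname(v), rep(4 / 3, 2), tolerance = 1e-10)

  # exactly uncorrelated (centered, orthogonal) predictors: all VIFs are 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20))))[, 2:4]
  dq <- tibble::as_tibble(as.data.frame(q))
  expect_equal(unname(vif(dq, names(dq))), rep(1, 3), tolerance = 1e-10)

  # cross-check against car::vif on a random design
  d3 <- tibble::tibble(
    x1 = rnorm(80), x2 = rnorm(80) + 0.6 * x1, x3 = rnorm(80),
    y = rnorm(80)
  )
  ours <- vif(d3, c("x1", "x2", "x3"))
  theirs <- car::vif(lm(y ~ x1 + x2 + x3, data = d3))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("effect sizes expose both f-squared conventions", {
  f2 <- effect_size_f2(0.261, 0.344)
  expect_equal(f2$f2_cohen, 0.261 / (1 - 0.344), tolerance = 1e-12)
  expect_equal(f2$f2_variant, 0.261 / (1 - 0.261), tolerance = 1e-12)
  expect_equal(round(f2$f2_cohen, 3), 0.398)
  expect_equal(round(f2$f2_variant, 3), 0.353)
  expect_equal(effect_size_f2(0, 0.3)$f2_cohen, 0)
  expect_error(effect_size_f2(0.4, 0.3), "delta_r2")
  expect_error(effect_size_f2(0.5, 1), "r2_full")
})

test_that("coefficients recover from simulated data with shrinking error", {
  withr::local_seed(91)
  coefs <- c(`(Intercept)` = 14, age = -0.18, gender = -0.5)
  mom <- tibble::tibble(
    variable = c("age", "gender"), dist = c("normal", "bernoulli"),
    mean = c(38, 0.63), sd = c(11, NA)
  )
  fit_n <- function(n) {
    d <- simulate_from_fitted_model(coefs, mom, residual_sd = 6.6, n = n)
    fit_ols(d, "phq9", c("age", "gender"))
  }
  f500 <- fit_n(500)
  f20k <- fit_n(20000)
  for (f in list(f500, f20k)) {
    co <- f$coefficients
    expect_lt(abs(co$B[co$term == "age"] - (-0.18)),
              3 * co$se_B[co$term == "age"])
  }
  # standard errors shrink like 1/sqrt(n): factor sqrt(40) ~ 6.3
  expect_lt(
    f20k$coefficients$se_B[2] / f500$coefficients$se_B[2], 1 / 4
  )
})
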