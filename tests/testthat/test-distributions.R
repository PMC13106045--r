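test_that("mean/CV parameterisation maps to the correct native parameters", {
  g <- dist_from_mean_cv("gamma", mean = 2, cv = 0.5)
  expect_equal(g$param1, 4)   # shape = 1/cv^2
  expect_equal(g$param2, 0.5) # scale = mean * cv^2
  ln <- dist_from_mean_cv("lognormal", mean = 300, cv = 0.4)
  s2 <- log(1 + 0.4^2)
  expect_equal(ln$param2, sqrt(s2))
  expect_equal(ln$param1, log(300) - s2 / 2)
  expect_error(dist_from_mean_cv("lognormal", -1, 0.5), "mean")
  expect_error(dist_from_mean_cv("gamma", 2, 0), "cv")
  expect_error(dist_from_mean_cv("weibull", 2, 0.5), "family")
})

test_that("native-parameter moments follow the closed forms", {
  ln <- dist_from_native("lognormal", 0, 1)
  expect_equal(ln$mean, exp(0.5))
  g <- dist_from_native("gamma", 4, 0.5)
  expect_equal(g$mean, 2)
  expect_equal(dist_moments(g$family, g$mean, g$cv)$sd, 1)
  expect_equal(g$cv, 0.5)
  expect_error(dist_from_native("gamma", -1, 1), "shape")
  expect_error(dist_from_native("lognormal", 0, 0), "param2")
})

test_that("analytic moments agree with quadrature over the density", {
  cases <- expand.grid(family = c("lognormal", "gamma"),
                       mean = c(0.9, 12, 300), cv = c(0.2, 0.5, 0.8),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    q <- quadrature_moments(cases$family[i], cases$mean[i], cases$cv[i])
    expect_equal(q[["mean"]], cases$mean[i], tolerance = 1e-6)
    expect_equal(q[["sd"]], cases$mean[i] * cases$cv[i], tolerance = 1e-6)
  }
})

test_that("moments match Monte-Carlo sampling within 3 standard errors", {
  withr::with_seed(11, {
    for (fam in c("lognormal", "gamma")) {
      x <- rintake(2e5, fam, mean = 50, cv = 0.5)
      se <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - 50), 3 * se)
    }
  })
})

test_that("shifting adds exactly the contribution and preserves variability", {
  # identity at zero shift
  s0 <- shift_dist("gamma", 2, 0.5, 0)
  expect_identical(s0$mean, 2)
  expect_identical(s0$cv, 0.5)
  # the worked large shift: a 433.2 mg calcium contribution
  s <- shift_dist("lognormal", 612, 0.35, 433.2)
  expect_equal(s$mean - 612, 433.2)
  expect_equal(s$cv, 0.35)
  # gamma under the CV convention re-derives shape/scale from new moments
  g <- shift_dist("gamma", 2, 0.5, 1)
  p <- dist_from_mean_cv(g$family, g$mean, g$cv)
  expect_equal(p$param1, 4)
  expect_equal(p$param2, 0.75)
  # SD convention: absolute spread fixed, CV shrinks
  sd_conv <- shift_dist("gamma", 2, 0.5, 2, convention = "sd")
  expect_equal(sd_conv$mean * sd_conv$cv, 1)  # sd stays 2 * 0.5
  expect_error(shift_dist("gamma", 2, 0.5, -1), "delta")
})

test_that("shift contract holds for random distributions and composes", {
  withr::with_seed(21, {
    n <- 100
    fam <- sample(c("lognormal", "gamma"), n, TRUE)
    mean <- exp(runif(n, -1, 6))
    cv <- runif(n, 0.2, 0.8)
    delta <- runif(n, 0, 10) * mean
    s <- shift_dist(fam, mean, cv, delta)
    expect_equal(s$mean - mean, delta, tolerance = 1e-9)
    expect_equal(s$cv, cv, tolerance = 1e-9)
    # composition: shifting by a then b lands on the a + b mean
    a <- delta / 3; b <- delta - a
    s2 <- shift_dist(fam, shift_dist(fam, mean, cv, a)$mean, cv, b)
    expect_equal(s2$mean, shift_dist(fam, mean, cv, delta)$mean,
                 tolerance = 1e-12)
  })
})

test_that("cdf and quantile are consistent and handle degenerate spread", {
  expect_equal(pintake(exp(1.3), "lognormal",
                       dist_from_native("lognormal", 1.3, 0.6)$mean,
                       dist_from_native("lognormal", 1.3, 0.6)$cv), 0.5)
  expect_equal(pintake(1, "gamma", 1, 1), 1 - exp(-1))  # shape 1, scale 1
  for (fam in c("lognormal", "gamma")) {
    for (p in c(0.1, 0.5, 0.9)) {
      expect_equal(pintake(qintake(p, fam, 25, 0.45), fam, 25, 0.45), p,
                   tolerance = 1e-8)
    }
  }
  # point mass: step cdf at the mean, constant quantile
  expect_identical(pintake(c(0.99, 1, 1.01), "lognormal", 1, 1e-9),
                   c(0, 1, 1))
  expect_identical(qintake(c(0.1, 0.9), "gamma", 3, 1e-9), c(3, 3))
})
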