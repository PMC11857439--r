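sim_fixture <- function(n = 120, seed = 21) {
  withr::with_seed(seed, {
    ages <- runif(n, 20, 81)
    y <- 1.1 - 0.004 * (ages - 50) + rnorm(n, sd = 0.05)
  })
  list(ages = ages, y = y)
}

test_that("identity-warp posterior equals the ridge-regression oracle", {
  fx <- sim_fixture()
  al <- 0.7; be <- 45
  fit <- fit_normative(fx$ages, fx$y, warp_params = c(0, 1), alpha = al,
                       beta = be, standardize = FALSE)
  Phi <- design_matrix(fx$ages, fit$basis)
  ridge <- solve(crossprod(Phi) + (al / be) * diag(ncol(Phi)),
                 crossprod(Phi, fx$y))
  expect_equal(unname(fit$m_w), unname(drop(ridge)), tolerance = 1e-8)
  expect_equal(unname(fit$S_w),
               unname(solve(al * diag(ncol(Phi)) + be * crossprod(Phi))),
               tolerance = 1e-10)
})

test_that("the alpha -> 0 limit reproduces least-squares fitted values", {
  fx <- sim_fixture(n = 80, seed = 3)
  fit <- fit_normative(fx$ages, fx$y, warp_params = c(0, 1), alpha = 1e-12,
                       beta = 100, standardize = FALSE)
  Phi <- design_matrix(fx$ages, fit$basis)
  # the basis plus intercept is rank deficient (partition of unity), so
  # compare fitted values, which least squares determines uniquely
  ols_fitted <- fitted(lm(fx$y ~ Phi - 1))
  expect_equal(unname(drop(Phi %*% fit$m_w)), unname(ols_fitted),
               tolerance = 1e-6)
})

test_that("noiseless linear data are interpolated under the identity warp", {
  ages <- seq(20, 80, length.out = 40)
  y <- 2 - 0.01 * ages
  fit <- fit_normative(ages, y, warp_params = c(0, 1), alpha = 1e-10,
                       beta = 1e8, standardize = FALSE)
  pr <- predict(fit, ages)
  expect_equal(pr$median_pred, y, tolerance = 1e-6)
})

test_that("predictive variance is floored by the noise variance", {
  fx <- sim_fixture()
  fit <- fit_normative(fx$ages, fx$y)
  pr <- predict(fit, seq(25, 75, by = 5))
  expect_true(all(pr$latent_sd^2 >= 1 / fit$beta))
})

test_that("optimized evidence never exceeds the identity-warp start", {
  fx <- sim_fixture()
  fit <- fit_normative(fx$ages, fx$y)
  expect_lte(fit$nlml, fit$nlml_init)
})

test_that("warp parameters are recovered from SHASH-generated data", {
  a_true <- 0.8; b_true <- 1.3
  n <- 4000
  withr::with_seed(31, {
    ages <- runif(n, 20, 81)
    f <- 0.06 * (ages - 50)
    z <- f + rnorm(n, sd = 1)
  })
  y <- warp_inverse(z, a_true, b_true)
  fit <- fit_normative(ages, y, standardize = FALSE)
  expect_equal(fit$warp[["a"]], a_true, tolerance = 0.1)
  expect_equal(fit$warp[["b"]], b_true, tolerance = 0.1)
})

test_that("training Z-scores are standard normal for well-specified data", {
  withr::with_seed(41, {
    ages <- runif(1000, 20, 81)
    y <- 1.2 - 0.005 * (ages - 50) + rnorm(1000, sd = 0.07)
  })
  fit <- fit_normative(ages, y)
  zz <- zscores(fit, ages, y)
  expect_equal(mean(zz$z), 0, tolerance = 0.1)
  expect_equal(var(zz$z), 1, tolerance = 0.1)
})

test_that("Z-scores flag extremes by strict inequality", {
  fx <- sim_fixture()
  fit <- fit_normative(fx$ages, fx$y)
  pr <- predict(fit, c(40, 55))
  # a point on the median curve scores zero
  z0 <- zscores(fit, 40, pr$median_pred[1])
  expect_equal(z0$z, 0, tolerance = 1e-10)
  expect_equal(z0$extreme, "none")
  # a point two predictive SDs up scores Z = 2
  lat <- pr$latent_mean[2] + 2 * pr$latent_sd[2]
  y2 <- fit$y_center + fit$y_scale *
    warp_inverse(lat, fit$warp[["a"]], fit$warp[["b"]])
  z2 <- zscores(fit, 55, y2)
  expect_equal(z2$z, 2, tolerance = 1e-10)

  # exact-boundary semantics, checked on a unit model where the Z-score
  # equals the observation itself: Z = 2 is NOT flagged (strict), the
  # next representable value up is
  unit <- fit
  unit$m_w[] <- 0; unit$S_w[] <- 0; unit$beta <- 1
  unit$warp <- c(a = 0, b = 1); unit$y_center <- 0; unit$y_scale <- 1
  zz <- zscores(unit, rep(50, 4), c(2, 2 + 1e-12, -2, -2 - 1e-12))
  expect_equal(zz$z, c(2, 2 + 1e-12, -2, -2 - 1e-12))
  expect_equal(zz$extreme, c("none", "positive", "none", "negative"))
})

test_that("centiles are monotone in the level and symmetric when identity", {
  fx <- sim_fixture()
  fit <- fit_normative(fx$ages, fx$y)
  grid <- seq(25, 75, by = 2.5)
  cc <- centiles(fit, grid)
  by_age <- split(cc, cc$age)
  for (d in by_age) {
    expect_true(all(diff(d$value[order(d$quantile)]) > 0))
  }
  # median curve equals the back-transformed latent mean
  med <- dplyr::filter(cc, quantile == 0.5)
  expect_equal(med$value, predict(fit, grid)$median_pred)
  # identity warp: q and 1-q symmetric about the latent mean
  fit_id <- fit_normative(fx$ages, fx$y, warp_params = c(0, 1),
                          standardize = FALSE)
  cid <- centiles(fit_id, grid, quantiles = c(0.05, 0.5, 0.95))
  lo <- dplyr::filter(cid, quantile == 0.05)$value
  hi <- dplyr::filter(cid, quantile == 0.95)$value
  mid <- dplyr::filter(cid, quantile == 0.5)$value
  expect_equal(hi - mid, mid - lo, tolerance = 1e-10)
  expect_error(centiles(fit, grid, quantiles = c(0, 0.5)), "strictly")
})

test_that("centile coverage matches its level on a large test sample", {
  # well-specified case: the latent variable is Gaussian around a linear
  # age trend and the observation is its back-transformed SHASH warp
  withr::with_seed(51, {
    ages <- runif(4000, 20, 81)
    lat <- 1.1 - 0.03 * (ages - 50) + rnorm(4000, sd = 0.5)
  })
  y <- warp_inverse(lat, 0.4, 1.1)
  tr <- 1:2000; te <- 2001:4000
  fit <- fit_normative(ages[tr], y[tr], standardize = FALSE)
  cc <- centiles(fit, ages[te], quantiles = 0.75)
  frac <- mean(y[te] < cc$value)
  # binomial noise at n = 2000 plus evidence-optimization error
  expect_lt(abs(frac - 0.75), 0.03)
})

test_that("explained variance behaves at its anchor points", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, rep(7, 5)), 0)   # any constant
  expect_lt(explained_variance(y, -y), 0)             # anti-correlated
  expect_error(explained_variance(rep(1, 5), y), "zero variance")
  expect_error(explained_variance(1, 1), ">= 2")
})

test_that("tidy and glance summarize the fitted model", {
  fx <- sim_fixture()
  fit <- fit_normative(fx$ages, fx$y)
  td <- tidy(fit)
  expect_equal(nrow(td), fit$df)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(fit)
  expect_equal(gl$n, length(fx$ages))
  expect_true(all(c("alpha", "beta", "warp_a", "warp_b", "nlml") %in%
                    names(gl)))
})
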