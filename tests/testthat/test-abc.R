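test_that("rejection accepts the nearest simulations with Epanechnikov weights", {
  set.seed(1)
  tab <- toy_linear_table(10, sd = 0.5)
  fit <- abc_reject(tab$stats[3, 1] + 1e-4, tab, tolerance = 0.1)
  expect_length(fit$accepted_idx, 1)
  d <- abs(tab$stats[, 1] - (tab$stats[3, 1] + 1e-4))
  expect_equal(fit$accepted_idx, which.min(d))

  # obs equal to a table row: that row is accepted with the maximal weight
  tab2 <- toy_linear_table(500, sd = 0.5, seed = 2)
  fit2 <- abc_reject(tab2$stats[17, 1], tab2, tolerance = 0.1)
  expect_true(17 %in% fit2$accepted_idx)
  expect_equal(fit2$accepted_idx[which.max(fit2$weights)], 17L)
  expect_equal(sum(fit2$weights), 1)
  expect_true(all(fit2$weights >= 0))
  expect_length(fit2$accepted_idx, 50)
})

test_that("tolerance 1 reproduces the prior and constant columns are dropped", {
  set.seed(3)
  n <- 4000
  theta <- rnorm(n)
  stats_m <- cbind(theta + rnorm(n, 0, 0.5), rep(1, n))
  tab <- reference_table(data.frame(theta = theta), stats_m)
  expect_warning(fit <- abc_reject(c(0, 1), tab, tolerance = 1), "zero-MAD")
  expect_length(fit$accepted_idx, n)
  set.seed(4)
  expect_gt(stats::ks.test(fit$adjusted$theta, rnorm(n))$p.value, 0.001)
})

test_that("regression adjustment matches the conjugate closed form", {
  tab <- toy_linear_table(50000, sd = 0.1, seed = 11)
  y_obs <- 0.8
  post_mean <- y_obs / (1 + 0.1^2)
  post_sd <- sqrt(0.1^2 / (1 + 0.1^2))
  fit <- abc_fit(y_obs, tab, tolerance = 0.1)
  est <- fit$summary$estimate[fit$summary$term == "theta"]
  expect_lt(abs(est - post_mean), 0.05 * post_sd)
  wm <- sum(fit$weights * fit$adjusted$theta)
  wsd <- sqrt(sum(fit$weights * (fit$adjusted$theta - wm)^2))
  expect_lt(abs(wsd - post_sd) / post_sd, 0.15)
  # interval narrows relative to rejection alone
  rej <- abc_fit(y_obs, tab, tolerance = 0.1, method = "rejection")
  width <- function(f) diff(c(f$summary$conf.low, f$summary$conf.high))
  expect_lt(width(fit), width(rej))
})

test_that("uninformative statistics leave the rejection posterior unadjusted", {
  set.seed(12)
  n <- 5000
  theta <- rnorm(n)
  tab <- reference_table(data.frame(theta = theta),
                         matrix(rnorm(n), ncol = 1))
  rej <- abc_fit(0, tab, tolerance = 0.2, method = "rejection")
  rdg <- abc_fit(0, tab, tolerance = 0.2, method = "ridge")
  # both should look like the prior: mean ~ 0, sd ~ 1
  expect_lt(abs(rdg$summary$estimate), 0.1)
  expect_equal(rdg$summary$conf.high - rdg$summary$conf.low,
               rej$summary$conf.high - rej$summary$conf.low,
               tolerance = 0.15)
})

test_that("with equal weights and a vanishing penalty ridge matches WLS", {
  set.seed(13)
  n <- 50
  X <- matrix(rnorm(n * 2), ncol = 2)
  y <- 1 + X %*% c(2, -1) + rnorm(n, 0, 0.3)
  w <- rep(1 / n, n)
  eng <- enclosabc:::ridge_engine(X, w, penalty_grid = 1e-10)
  sol <- enclosabc:::ridge_solve(eng, as.numeric(y), w)
  ls <- stats::lm.fit(cbind(1, X), as.numeric(y))
  expect_equal(sol$b, unname(ls$coefficients[-1]), tolerance = 1e-4)
  expect_equal(sol$pred_obs, unname(ls$coefficients[1]), tolerance = 1e-4)
  expect_equal(sol$fitted, unname(ls$fitted.values), tolerance = 1e-4)
})

test_that("adjusted draws respect parameter supports", {
  ctx <- make_fit_context(toy_design(s = 0.5), n_sims = 1500, seed = 31)
  fit <- abc_fit(ctx$obs, ctx$table, tolerance = 0.1)
  expect_true(all(fit$adjusted$s > -1))
  expect_true(all(fit$adjusted$h >= 0 & fit$adjusted$h <= 1))
  expect_true(all(fit$summary$conf.low <= fit$summary$conf.high))
  g <- glance(fit)
  expect_equal(g$n_accepted, 150)
  expect_equal(g$method, "ridge")
})

test_that("estimates are stable across tolerances on the same table", {
  tab <- toy_linear_table(20000, sd = 0.3, seed = 41)
  y_obs <- 0.5
  post_mean <- y_obs / (1 + 0.3^2)
  ests <- vapply(c(0.01, 0.1, 0.2), function(tol) {
    abc_fit(y_obs, tab, tolerance = tol)$summary$estimate
  }, numeric(1))
  expect_true(all(abs(ests - post_mean) < 0.05))
  expect_lt(max(ests) - min(ests), 0.05)
})
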