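test_that("conjugate posterior arithmetic is exact", {
  expect_equal(conjugate_posterior_single_area(0, 1, 1, 1),
               c(shape = 1, rate = 2))
  post <- conjugate_posterior_single_area(10, 10, 0.001, 0.001)
  expect_equal(unname(post[1] / post[2]), 1.0, tolerance = 1e-3)
  expect_error(conjugate_posterior_single_area(1.5, 1, 1, 1))
  expect_error(conjugate_posterior_single_area(1, 0, 1, 1))
})

test_that("exceedance probability is the strict exceedance fraction", {
  expect_equal(exceedance_probability(c(0.5, 1.5), 1), 0.5)
  expect_equal(exceedance_probability(c(0.2, 0.9), 1), 0)
  # draws exactly at the threshold do not exceed
  expect_equal(exceedance_probability(c(1, 1, 2), 1), 1 / 3)
  # complement identity Pr(RR<1) = 1 - Pr(RR>1) for continuous draws
  set.seed(1); d <- rlnorm(1000)
  expect_equal(mean(d < 1), 1 - exceedance_probability(d, 1))
  expect_error(exceedance_probability(numeric(0)), "no draws")
})

test_that("sampler matches the single-area conjugate oracle", {
  # one isolated area, unstructured term disabled, near-flat intercept prior:
  # the posterior of theta is approximately Gamma(O, E)
  g1 <- adjacency_graph("a")
  fit <- fit_bym(data.frame(area_id = "a", observed = 20, expected = 20), g1,
                 n_iter = 6000, n_burnin = 2000, n_chains = 2,
                 fix_tau_v = 1e8, intercept_prior_sd = 25, seed = 3)
  th <- theta_draws(fit)[, "a"]
  post <- conjugate_posterior_single_area(20, 20, 1e-9, 1e-9)
  mc_se <- sd(th) / sqrt(fit$estimates$ess)
  expect_lt(abs(mean(th) - post[["shape"]] / post[["rate"]]), 3 * mc_se)
  expect_lt(abs(exceedance_probability(th) -
                  pgamma(1, post[["shape"]], post[["rate"]], lower.tail = FALSE)),
            0.03)
  # quantiles track the closed form too
  expect_equal(unname(quantile(th, c(0.025, 0.975))),
               qgamma(c(0.025, 0.975), post[["shape"]], post[["rate"]]),
               tolerance = 0.03)
  # a vague fit at these counts leaves the exceedance near one half
  expect_gt(fit$estimates$pr_exceed, 0.35)
  expect_lt(fit$estimates$pr_exceed, 0.65)
})

test_that("flat data leave no area evidentially extreme", {
  g <- grid_geography(3, 3)$graph
  oe <- data.frame(area_id = g$area_ids, observed = 50, expected = 50)
  fit <- fit_bym(oe, g, n_iter = 3000, n_burnin = 1500, n_chains = 2, seed = 4)
  expect_true(all(fit$estimates$smrr > 0.85 & fit$estimates$smrr < 1.15))
  expect_true(all(fit$estimates$pr_exceed > 0.2 & fit$estimates$pr_exceed < 0.8))
  expect_true(all(fit$estimates$ci_low <= fit$estimates$ci_high))
  expect_true(all(fit$estimates$smrr > 0))
})

test_that("a three-fold excess among flat neighbors is decisively flagged", {
  g <- grid_geography(3, 3)$graph
  oe <- data.frame(area_id = g$area_ids, observed = 20, expected = 20)
  oe$observed[oe$area_id == "r2c2"] <- 60
  fit <- fast_fit(oe, g, seed = 6)
  est <- fit$estimates
  expect_equal(est$area_id[which.max(est$pr_exceed)], "r2c2")
  expect_gt(est$pr_exceed[est$area_id == "r2c2"], 0.95)
})

test_that("chains are bit-reproducible under a fixed seed", {
  g <- grid_geography(2, 3)$graph
  oe <- data.frame(area_id = g$area_ids, observed = c(5, 9, 12, 7, 20, 8),
                   expected = rep(10, 6))
  f1 <- fast_fit(oe, g, seed = 12)
  f2 <- fast_fit(oe, g, seed = 12)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$draws, f2$draws)
})

test_that("smoothing shrinks the raw observed-to-expected ratios", {
  g <- halland_sized_graph()
  sim <- simulate_two_waves(g, sim_config(seed = 31))
  s <- area_summary(sim$wave1)
  fit <- fast_fit(s, g, seed = 2)
  est <- fit$estimates
  keep <- est$observed > 0
  expect_lt(var(log(est$smrr[keep])), var(log(est$rr_raw[keep])))
})

test_that("posterior recovers a known risk surface", {
  g <- halland_sized_graph()
  cfg <- sim_config(mean_children_per_area = 300, sigma_u = 0, sigma_v = 0.4,
                    seed = 8)
  surf <- simulate_risk_surface(g, 0, 0.4, seed = 8)
  tab <- simulate_cases(simulate_population(g, cfg), surf, cfg)
  fit <- fast_fit(area_summary(tab), g, seed = 3)
  expect_gt(cor(unclass(surf)[fit$estimates$area_id], log(fit$estimates$smrr)),
            0.7)
})

test_that("convergence diagnostics behave on a well-sized flat run", {
  g <- grid_geography(3, 3)$graph
  oe <- data.frame(area_id = g$area_ids, observed = 50, expected = 50)
  fit <- fit_bym(oe, g, n_iter = 5000, n_burnin = 2000, n_chains = 2, seed = 10)
  expect_true(all(fit$estimates$rhat < 1.1))
  expect_true(all(fit$estimates$ess > 100))
})

test_that("degenerate inputs are rejected with clear messages", {
  g <- grid_geography(2, 2)$graph
  oe <- data.frame(area_id = g$area_ids, observed = 0, expected = 0)
  expect_error(fit_bym(oe, g), "all expected counts are zero")
  oe2 <- data.frame(area_id = g$area_ids, observed = c(3, 0, 0, 0),
                    expected = c(0, 5, 5, 5))
  expect_error(fit_bym(oe2, g), "zero expected")
  oe3 <- data.frame(area_id = c("x", "y", "z", "w"), observed = 1, expected = 1)
  expect_error(fit_bym(oe3, g), "different area sets")
})

test_that("areas with E = 0 are carried prior-only and islands are allowed", {
  g <- adjacency_graph(c("a", "b", "c", "island"),
                       list(a = c("b", "c"), b = c("a", "c"), c = c("a", "b")))
  oe <- data.frame(area_id = g$area_ids, observed = c(12, 9, 11, 0),
                   expected = c(10, 10, 10, 0))
  fit <- fast_fit(oe, g, seed = 5)
  est <- fit$estimates
  expect_true(is.na(est$rr_raw[est$area_id == "island"]))
  expect_true(est$smrr[est$area_id == "island"] > 0)
  expect_true(all(est$pr_exceed >= 0 & est$pr_exceed <= 1))
})

test_that("model methods expose the fit the standard way", {
  g <- grid_geography(2, 3)$graph
  oe <- data.frame(area_id = g$area_ids, observed = c(5, 9, 12, 7, 20, 8),
                   expected = rep(10, 6))
  fit <- fast_fit(oe, g, seed = 12)
  expect_named(coef(fit), g$area_ids)
  expect_true(all(coef(fit, type = "mean") >= 0))
  expect_equal(unname(fitted(fit)), fit$estimates$expected * fit$estimates$smrr)
  r <- residuals(fit)
  expect_equal(unname(r),
               (oe$observed - unname(fitted(fit))) / sqrt(unname(fitted(fit))))
  s <- summary(fit)
  expect_s3_class(s, "summary.bym")
  expect_lt(s$shrinkage, 1)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(6L, 4L))
  expect_true(all(sim$sim_1 >= 0))
  expect_identical(as.data.frame(fit), fit$estimates)
  expect_output(print(fit), "Besag-York-Mollie")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
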