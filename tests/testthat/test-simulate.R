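test_that("population skeleton honors the zero-dispersion limit and determinism", {
  g <- grid_geography(2, 2)$graph
  cfg <- sim_config(mean_children_per_area = 100, children_dispersion = 0, seed = 1)
  skel <- simulate_population(g, cfg)
  expect_equal(nrow(skel), 8L)
  expect_true(all(skel$n_examined == 50L))
  expect_setequal(unique(skel$sex), c("M", "F"))

  cfg2 <- sim_config(seed = 11)
  expect_identical(simulate_population(g, cfg2), simulate_population(g, cfg2))
})

test_that("a Halland-scale configuration yields roughly 10,000 children", {
  g <- halland_sized_graph()
  totals <- vapply(1:10, function(s) {
    sum(simulate_population(g, sim_config(seed = s))$n_examined)
  }, numeric(1))
  # lognormal cells: mean total = 66 * 151 * exp(0.35^2 / 2) ~ 10,600
  expect_true(all(totals > 8000 & totals < 14000))
  expect_gt(mean(totals), 9000)
  expect_lt(mean(totals), 12000)
})

test_that("risk surface degenerates to flat when both sigmas are zero", {
  g <- grid_geography(3, 3)$graph
  s <- simulate_risk_surface(g, 0, 0, seed = 5)
  expect_true(all(s == 0))
})

test_that("risk surface is centered per component and reproducible", {
  g <- halland_sized_graph()
  s1 <- simulate_risk_surface(g, 0.4, 0.3, seed = 7)
  s2 <- simulate_risk_surface(g, 0.4, 0.3, seed = 7)
  expect_identical(s1, s2)
  expect_equal(mean(s1), 0, tolerance = 1e-12)
})

test_that("structured surfaces carry positive spatial autocorrelation", {
  g <- grid_geography(10, 10)$graph
  i_structured <- vapply(1:40, function(s) {
    morans_i(unclass(simulate_risk_surface(g, 0.5, 0, seed = s)), g)
  }, numeric(1))
  i_noise <- vapply(1:40, function(s) {
    morans_i(unclass(simulate_risk_surface(g, 0, 0.5, seed = s)), g)
  }, numeric(1))
  expect_gt(mean(i_structured), 0.2)
  # pure noise: E[I] = -1/(N-1)
  expect_equal(mean(i_noise), -1 / 99, tolerance = 0.05)
})

test_that("morans_i agrees with the ape implementation", {
  skip_if_not_installed("ape")
  g <- grid_geography(5, 5)$graph
  set.seed(42)
  x <- stats::setNames(rnorm(25), g$area_ids)
  w <- matrix(0, 25, 25, dimnames = list(g$area_ids, g$area_ids))
  for (id in g$area_ids) w[id, g$neighbors[[id]]] <- 1
  expect_equal(morans_i(x, g),
               ape::Moran.I(as.numeric(x), w, scaled = FALSE)$observed,
               tolerance = 1e-10)
})

test_that("an unstructured surface at sigma 0.45 spans the oracle RR spread", {
  # independent oracle: range of 66 iid N(0, 0.45) draws; exp(range) has
  # 10-90% interval ~ (5.9, 12.4), median ~ 8.1 (4000-draw reference run)
  g <- halland_sized_graph()
  ratios <- vapply(1:60, function(s) {
    x <- simulate_risk_surface(g, 0, 0.45, seed = s)
    exp(max(x) - min(x))
  }, numeric(1))
  expect_gt(median(ratios), 5.5)
  expect_lt(median(ratios), 12.5)
})

test_that("case counts follow the planted risks", {
  g <- halland_sized_graph()
  cfg <- sim_config(mean_children_per_area = 151, sigma_u = 0, sigma_v = 0, seed = 3)
  skel <- simulate_population(g, cfg)
  flat <- simulate_risk_surface(g, 0, 0, seed = 3)
  tab <- simulate_cases(skel, flat, cfg)
  prev <- sum(tab$n_cases) / sum(tab$n_examined)
  expect_equal(prev, 0.16, tolerance = 0.02)

  # zero baseline rate: no cases at all
  cfg0 <- sim_config(baseline_rate_by_sex = c(M = 0, F = 0), seed = 3)
  expect_true(all(simulate_cases(skel, flat, cfg0)$n_cases == 0))

  # a doubled-risk area shows an empirical RR near 2 at large n
  cfg_big <- sim_config(mean_children_per_area = 20000, children_dispersion = 0,
                        baseline_rate_by_sex = c(M = 0.1, F = 0.1), seed = 4)
  g2 <- adjacency_graph(c("a", "b", "c"))
  surf <- structure(c(a = log(2), b = 0, c = 0), class = "risk_surface")
  tab2 <- simulate_cases(simulate_population(g2, cfg_big), surf, cfg_big)
  s <- area_summary(tab2, rates = c(M = 0.1, F = 0.1))
  expect_equal(s$rr_raw[s$area_id == "a"], 2, tolerance = 0.05)
})

test_that("two-wave simulation plants changes and stays reproducible", {
  g <- grid_geography(3, 3)$graph
  cfg <- sim_config(seed = 9)
  sim <- simulate_two_waves(g, cfg)
  expect_identical(unclass(sim$surface1), unclass(sim$surface2))
  expect_identical(sim, simulate_two_waves(g, cfg))
  # populations are re-drawn per wave
  expect_false(identical(sim$wave1$n_examined, sim$wave2$n_examined))

  cfg2 <- sim_config(seed = 9, changed_areas = c(r2c2 = 3))
  sim2 <- simulate_two_waves(g, cfg2)
  r1 <- rank(unclass(sim2$surface1))[["r2c2"]]
  r2 <- rank(unclass(sim2$surface2))[["r2c2"]]
  expect_gt(r2, r1)
  expect_equal(r2, 9)  # a 3-fold boost dominates a 9-area surface
  # centering is preserved after planting
  expect_equal(mean(unclass(sim2$surface2)), 0, tolerance = 1e-12)

  expect_error(simulate_two_waves(g, sim_config(changed_areas = c(zz = 2))),
               "unknown area")
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(baseline_rate_by_sex = c(M = 1.2, F = 0.1)), "probabilities")
  expect_error(sim_config(changed_areas = c(a = -1)), "multipliers")
  expect_error(sim_config(changed_areas = 2), "named")
  expect_error(sim_config(sigma_u = -0.1))
})
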