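#' Simulation settings for two-wave area-level surveillance data
#'
#' Bundles the generative parameters for the synthetic datasets the package
#' uses to exercise the full pipeline. The defaults emulate a Halland-scale
#' survey: 66 areas of ~151 children each (~10,000 children per wave), an
#' outcome prevalence of 16% in wave 1 improving to 11.4% in wave 2, and a
#' spatially correlated true risk surface whose max/min relative-risk spread
#' is of the same order as published smoothed-risk maps (~4-7).
#'
#' @param mean_children_per_area Mean number of examined children per area
#'   (both sexes combined).
#' @param children_dispersion Lognormal sigma of area population sizes; 0
#'   gives identical areas.
#' @param baseline_rate_by_sex Named probabilities (`M`, `F`): outcome
#'   prevalence in the reference population, wave 1.
#' @param baseline_rate_by_sex_wave2 Same for wave 2 (secular trend); defaults
#'   emulate a prevalence drop from 16% to 11.4%.
#' @param sigma_u Marginal s.d. of the spatially structured log relative risk.
#' @param sigma_v S.d. of the unstructured log relative risk.
#' @param changed_areas Named numeric: multiplicative relative-risk change
#'   applied to selected areas in wave 2 (names are area ids).
#' @param seed Master integer seed; every stage derives a sub-seed from it via
#'   [substream_seed()].
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, changed_areas = c(r1c1 = 3))
sim_config <- function(mean_children_per_area = 151,
                       children_dispersion = 0.35,
                       baseline_rate_by_sex = c(M = 0.16, F = 0.16),
                       baseline_rate_by_sex_wave2 = c(M = 0.114, F = 0.114),
                       sigma_u = 0.3,
                       sigma_v = 0.3,
                       changed_areas = NULL,
                       seed = 1L) {
  stopifnot(mean_children_per_area > 0, children_dispersion >= 0,
            sigma_u >= 0, sigma_v >= 0)
  for (r in list(baseline_rate_by_sex, baseline_rate_by_sex_wave2)) {
    if (!all(c("M", "F") %in% names(r)) || any(r < 0) || any(r >= 1)) {
      stop_fmt("baseline rates must be named (M, F) probabilities in [0, 1)")
    }
  }
  if (!is.null(changed_areas)) {
    if (is.null(names(changed_areas)) || any(!nzchar(names(changed_areas)))) {
      stop_fmt("changed_areas must be a named numeric vector")
    }
    if (any(changed_areas <= 0)) stop_fmt("risk multipliers must be > 0")
  }
  structure(list(mean_children_per_area = mean_children_per_area,
                 children_dispersion = children_dispersion,
                 baseline_rate_by_sex = baseline_rate_by_sex,
                 baseline_rate_by_sex_wave2 = baseline_rate_by_sex_wave2,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 changed_areas = changed_areas, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate examined-children counts per area and sex
#'
#' Draws each (area, sex) denominator as `max(1, round(L))` where `L` is
#' lognormal with log-mean `log(mean_children_per_area / 2)` and log-s.d.
#' `children_dispersion`; with dispersion 0 every cell has exactly half the
#' per-area mean.
#'
#' @param graph An [adjacency_graph()].
#' @param config A [sim_config()].
#' @param wave Wave index (used for sub-seeding and the `wave` column).
#' @return An area table: data frame with columns `area_id`, `sex`,
#'   `n_examined`, `n_cases` (`NA` until [simulate_cases()]), `wave`.
#' @export
simulate_population <- function(graph, config, wave = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"), inherits(config, "sim_config"))
  ids <- graph$area_ids
  set.seed(substream_seed(config$seed, "population", wave))
  n_cells <- 2L * length(ids)
  sizes <- if (config$children_dispersion == 0) {
    rep(config$mean_children_per_area / 2, n_cells)
  } else {
    stats::rlnorm(n_cells, meanlog = log(config$mean_children_per_area / 2),
                  sdlog = config$children_dispersion)
  }
  data.frame(area_id = rep(ids, each = 2L),
             sex = rep(c("M", "F"), times = length(ids)),
             n_examined = pmax(1L, as.integer(round(sizes))),
             n_cases = NA_integer_,
             wave = as.character(wave),
             stringsAsFactors = FALSE)
}

# Draw a spatially structured field on the graph: proper CAR surrogate with
# autocorrelation 0.99 (the intrinsic prior is improper), centered per
# component, then rescaled so the empirical s.d. equals sigma_u. Areas in
# singleton components carry no spatial signal and stay at 0.
draw_car_field <- function(graph, sigma_u) {
  ids <- graph$area_ids
  u <- stats::setNames(numeric(length(ids)), ids)
  if (sigma_u == 0) return(u)
  comps <- graph_components(graph)
  active <- unlist(comps[lengths(comps) > 1L], use.names = FALSE)
  if (!length(active)) return(u)
  w <- adjacency_matrix(graph)[active, active, drop = FALSE]
  q <- diag(rowSums(w), nrow(w)) - 0.99 * w
  # x ~ N(0, Q^{-1}): solve R x = z with Q = R'R
  r <- chol(q)
  x <- backsolve(r, stats::rnorm(length(active)))
  u[active] <- x
  for (comp in comps) {
    if (length(comp) > 1L) u[comp] <- u[comp] - mean(u[comp])
  }
  s <- stats::sd(u[active])
  if (s > 0) u[active] <- u[active] * sigma_u / s
  u
}

adjacency_matrix <- function(graph) {
  ids <- graph$area_ids
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (id in ids) w[id, graph$neighbors[[id]]] <- 1
  w
}

#' Simulate a true area-level risk surface
#'
#' Generates centered true log relative risks `log_rr = u + v`: `u` is a
#' spatially structured draw (proper CAR with autocorrelation 0.99, centered
#' per graph component, scaled to marginal s.d. `sigma_u`) and `v` is iid
#' Normal(0, `sigma_v`^2). The sum is re-centered per component so the surface
#' is a pure relative-risk contrast.
#'
#' @param graph An [adjacency_graph()].
#' @param sigma_u,sigma_v Non-negative s.d. of the structured / unstructured
#'   components on the log scale.
#' @param seed Integer seed.
#' @return An object of class `risk_surface`: named numeric vector of true
#'   log relative risks, one per area.
#' @export
#' @examples
#' g <- grid_geography(3, 3)$graph
#' s <- simulate_risk_surface(g, sigma_u = 0.3, sigma_v = 0.2, seed = 1)
simulate_risk_surface <- function(graph, sigma_u, sigma_v, seed = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"), sigma_u >= 0, sigma_v >= 0)
  set.seed(as.integer(seed))
  u <- draw_car_field(graph, sigma_u)
  v <- stats::rnorm(length(u), 0, sigma_v)
  log_rr <- u + v
  for (comp in graph_components(graph)) {
    log_rr[comp] <- log_rr[comp] - mean(log_rr[comp])
  }
  structure(log_rr, class = "risk_surface")
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf("True risk surface: %d areas, log RR range [%.3f, %.3f], RR spread %.2f\n",
              length(x), min(x), max(x), exp(max(x) - min(x))))
  invisible(x)
}

#' Simulate outcome counts given a population skeleton and risk surface
#'
#' Each (area, sex) cell's case count is Binomial(`n_examined`, `p`) with
#' `p = rate_sex * exp(log_rr_area)` truncated at 1 — child-level binary
#' outcomes, deliberately not the Poisson likelihood the smoothing model uses.
#'
#' @param skeleton Area table from [simulate_population()].
#' @param surface A `risk_surface` covering the skeleton's areas.
#' @param config A [sim_config()].
#' @param wave Wave index; selects the wave-specific baseline rates and
#'   sub-seed.
#' @return The skeleton with `n_cases` filled in.
#' @export
simulate_cases <- function(skeleton, surface, config, wave = 1L) {
  stopifnot(inherits(config, "sim_config"))
  missing_ids <- setdiff(skeleton$area_id, names(surface))
  if (length(missing_ids)) {
    stop_fmt("surface missing area(s): %s", paste(missing_ids, collapse = ", "))
  }
  rates <- if (wave >= 2) config$baseline_rate_by_sex_wave2 else config$baseline_rate_by_sex
  p <- pmin(1, rates[skeleton$sex] * exp(unclass(surface)[skeleton$area_id]))
  set.seed(substream_seed(config$seed, "cases", wave))
  skeleton$n_cases <- stats::rbinom(nrow(skeleton), skeleton$n_examined, p)
  skeleton
}

#' Simulate a full two-wave dataset with planted risk changes
#'
#' Wave 1 draws a risk surface and population; wave 2 reuses the same surface
#' with `log(multiplier)` added for each area in `config$changed_areas`
#' (re-centered per component), an independently re-drawn population, and the
#' wave-2 baseline rates (secular trend). All randomness derives from
#' `config$seed` through named sub-streams.
#'
#' @param graph An [adjacency_graph()].
#' @param config A [sim_config()].
#' @return A list with `wave1`, `wave2` (area tables), `surface1`, `surface2`
#'   (risk surfaces).
#' @export
#' @examples
#' g <- grid_geography(3, 3)$graph
#' sim <- simulate_two_waves(g, sim_config(seed = 3, changed_areas = c(r2c2 = 3)))
simulate_two_waves <- function(graph, config) {
  stopifnot(inherits(graph, "adjacency_graph"), inherits(config, "sim_config"))
  unknown <- setdiff(names(config$changed_areas), graph$area_ids)
  if (length(unknown)) {
    stop_fmt("changed_areas refer to unknown area(s): %s", paste(unknown, collapse = ", "))
  }
  surface1 <- simulate_risk_surface(graph, config$sigma_u, config$sigma_v,
                                    seed = substream_seed(config$seed, "surface", 1L))
  log_rr2 <- unclass(surface1)
  for (id in names(config$changed_areas)) {
    log_rr2[id] <- log_rr2[id] + log(config$changed_areas[[id]])
  }
  if (length(config$changed_areas)) {
    for (comp in graph_components(graph)) {
      log_rr2[comp] <- log_rr2[comp] - mean(log_rr2[comp])
    }
  }
  surface2 <- structure(log_rr2, class = "risk_surface")
  wave1 <- simulate_cases(simulate_population(graph, config, wave = 1L),
                          surface1, config, wave = 1L)
  wave2 <- simulate_cases(simulate_population(graph, config, wave = 2L),
                          surface2, config, wave = 2L)
  list(wave1 = wave1, wave2 = wave2, surface1 = surface1, surface2 = surface2)
}

#' Moran's I of an area-level variable
#'
#' Spatial autocorrelation with row-standardized adjacency weights (each
#' area's neighbors share unit total weight — the common W-coding), used to
#' check that simulated risk surfaces carry the intended spatial structure.
#' Areas without neighbors are excluded. Under no spatial structure the
#' expectation is `-1/(N - 1)`.
#'
#' @param values Named numeric vector (names are area ids).
#' @param graph An [adjacency_graph()].
#' @return Moran's I (numeric scalar); `NA` if fewer than 2 connected areas.
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  ids <- graph$area_ids[lengths(graph$neighbors[graph$area_ids]) > 0L]
  if (length(ids) < 2L) return(NA_real_)
  x <- values[ids]
  w <- adjacency_matrix(graph)[ids, ids]
  w <- w / rowSums(w)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  (length(ids) / sum(w)) * as.numeric(t(z) %*% w %*% z) / denom
}
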