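#' Fit the Besag-York-Mollie spatial smoothing model by MCMC
#'
#' Fits the Bayesian hierarchical disease-mapping model
#' \deqn{O_a \sim \mathrm{Poisson}(E_a \theta_a), \quad
#'       \log \theta_a = \alpha + u_a + v_a,}
#' where `u` follows an intrinsic CAR prior on the adjacency graph (density
#' proportional to `exp(-tau_u/2 * sum_{a~b} (u_a - u_b)^2)`, sum-to-zero per
#' connected component), `v_a ~ Normal(0, 1/tau_v)` is unstructured
#' heterogeneity, `alpha ~ Normal(0, intercept_prior_sd^2)`, and the
#' precisions carry Gamma hyperpriors. Each area's relative risk is thereby
#' smoothed towards both the global level (through `alpha` and `v`) and the
#' local average of its neighbors (through `u`).
#'
#' The sampler is Metropolis-within-Gibbs: random-walk Metropolis updates for
#' `alpha`, each `u_a` and each `v_a` (u-updates are performed jointly over
#' color classes of the graph, which is exact because non-adjacent areas are
#' conditionally independent), with conjugate Gibbs draws for `tau_u` (shape
#' `+ (N - C)/2`, rate `+ sum_{a~b}(u_a - u_b)^2 / 2`, for `N` areas and `C`
#' components) and `tau_v` (shape `+ N/2`, rate `+ sum v_a^2 / 2`). Proposal
#' scales are adapted towards 30-50% acceptance during burn-in only. `u` is
#' re-centered per component after every sweep; with a single component the
#' removed level is folded into `alpha` so fitted risks are unchanged.
#' Isolated areas have `u_a` fixed at 0 (no local information); areas with
#' `E_a = 0` contribute no likelihood and are summarized from the prior.
#'
#' @param x Per-area data: a data frame with columns `area_id`, `observed`,
#'   `expected` (as from [area_summary()]), or a raw area table with `sex`,
#'   `n_examined`, `n_cases` columns, which is indirectly standardized first.
#' @param graph An [adjacency_graph()] covering exactly the areas of `x`.
#' @param n_iter Kept post-burn-in iterations per chain.
#' @param n_burnin Burn-in sweeps per chain (discarded; adaptation happens here).
#' @param thin Thinning interval applied after burn-in.
#' @param n_chains Number of independent chains.
#' @param prior_tau_u,prior_tau_v Length-2 `(shape, rate)` of the Gamma
#'   hyperpriors on the structured / unstructured precisions. The default
#'   `Gamma(0.5, 0.0005)` is a widespread disease-mapping convention.
#' @param intercept_prior_sd Prior s.d. of the intercept (log baseline risk).
#' @param proposal_sd Initial random-walk proposal s.d. (adapted in burn-in).
#' @param fix_tau_u,fix_tau_v Optional positive values freezing a precision
#'   instead of sampling it (e.g. a very large `fix_tau_v` disables the
#'   unstructured term — useful for degenerate-case validation).
#' @param seed Integer seed; chain `k` uses a sub-seed derived from it.
#' @param verbose Print per-chain progress.
#' @return An object of class `bym`; see [summary.bym()]. Its `estimates`
#'   element is a data frame with per-area `observed`, `expected`, `rr_raw`,
#'   `smrr` (posterior median relative risk), `smrr_mean`, `pr_exceed`
#'   (`Pr(RR > 1 | data)`), `ci_low`, `ci_high` (95% equal-tailed credible
#'   interval), `ess` and `rhat` (split-chain potential scale reduction).
#' @references Besag, J., York, J. and Mollie, A. (1991) Bayesian image
#'   restoration, with two applications in spatial statistics.
#'   *Ann Inst Stat Math* 43, 1-20.
#' @export
#' @examples
#' g <- grid_geography(3, 3)$graph
#' oe <- data.frame(area_id = g$area_ids, observed = 20, expected = 20)
#' fit <- fit_bym(oe, g, n_iter = 500, n_burnin = 200, n_chains = 1, seed = 1)
#' coef(fit)[1:3]
fit_bym <- function(x, graph,
                    n_iter = 10000L, n_burnin = 5000L, thin = 1L,
                    n_chains = 2L,
                    prior_tau_u = c(0.5, 0.0005),
                    prior_tau_v = c(0.5, 0.0005),
                    intercept_prior_sd = 10,
                    proposal_sd = 0.1,
                    fix_tau_u = NULL, fix_tau_v = NULL,
                    seed = 1L, verbose = FALSE) {
  stopifnot(inherits(graph, "adjacency_graph"),
            n_iter >= 1, n_burnin >= 1, thin >= 1, n_chains >= 1,
            all(prior_tau_u > 0), all(prior_tau_v > 0),
            intercept_prior_sd > 0, proposal_sd > 0)
  if (all(c("sex", "n_examined", "n_cases") %in% names(x))) x <- area_summary(x)
  stopifnot(all(c("area_id", "observed", "expected") %in% names(x)))
  if (!setequal(x$area_id, graph$area_ids)) {
    stop_fmt("data and graph cover different area sets")
  }
  x <- x[match(graph$area_ids, x$area_id), , drop = FALSE]
  o <- as.numeric(x$observed); e <- as.numeric(x$expected)
  if (any(!is.finite(o)) || any(!is.finite(e)) || any(o < 0) || any(e < 0)) {
    stop_fmt("observed/expected must be finite and non-negative")
  }
  if (all(e == 0)) stop_fmt("all expected counts are zero; nothing to fit")
  if (any(o > 0 & e == 0)) {
    stop_fmt("area '%s' has observed cases but zero expected count",
             graph$area_ids[which(o > 0 & e == 0)[1L]])
  }
  n <- length(o)
  ids <- graph$area_ids

  w <- adjacency_matrix(graph)
  deg <- rowSums(w)
  comps <- graph_components(graph)
  comp_idx <- lapply(comps, function(cc) match(cc, ids))
  n_comp <- length(comps)
  edges <- graph_edges(graph)
  ei <- match(edges[, 1L], ids); ej <- match(edges[, 2L], ids)
  classes <- color_classes(graph)       # indices, non-isolated only
  w_by_class <- lapply(classes, function(idx) w[idx, , drop = FALSE])

  kept_total <- as.integer(n_iter)
  chains <- vector("list", n_chains)
  accept <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- run_bym_chain(
      o = o, e = e, deg = deg, comp_idx = comp_idx,
      n_comp = n_comp, ei = ei, ej = ej, classes = classes,
      w_by_class = w_by_class,
      n_iter = kept_total, n_burnin = as.integer(n_burnin), thin = as.integer(thin),
      prior_tau_u = prior_tau_u, prior_tau_v = prior_tau_v,
      intercept_prior_sd = intercept_prior_sd, proposal_sd = proposal_sd,
      fix_tau_u = fix_tau_u, fix_tau_v = fix_tau_v,
      chain_seed = substream_seed(seed, "bym-chain", ch))
    accept[[ch]] <- chains[[ch]]$acceptance
    if (verbose) {
      message(sprintf("chain %d/%d done (mean acceptance %.2f)",
                      ch, n_chains, mean(unlist(accept[[ch]]))))
    }
  }

  theta_chains <- lapply(chains, `[[`, "theta")   # kept x n matrices
  theta <- do.call(rbind, theta_chains)
  smrr <- apply(theta, 2L, stats::median)
  smrr_mean <- colMeans(theta)
  pr_exceed <- colMeans(theta > 1)
  ci <- apply(theta, 2L, stats::quantile, probs = c(0.025, 0.975))
  ess <- vapply(seq_len(n), function(j) {
    sum(vapply(theta_chains, function(m) ess_autocorr(m[, j]), numeric(1)))
  }, numeric(1))
  rhat <- vapply(seq_len(n), function(j) {
    split_rhat(lapply(theta_chains, function(m) log(m[, j])))
  }, numeric(1))

  estimates <- data.frame(
    area_id = ids, observed = o, expected = e,
    rr_raw = as.numeric(raw_rr(stats::setNames(o, ids), stats::setNames(e, ids))),
    smrr = smrr, smrr_mean = smrr_mean, pr_exceed = pr_exceed,
    ci_low = ci[1L, ], ci_high = ci[2L, ], ess = ess, rhat = rhat,
    row.names = NULL, stringsAsFactors = FALSE)

  globals <- data.frame(
    parameter = c("alpha", "tau_u", "tau_v", "sd_u", "sd_v"),
    mean = c(mean(unlist(lapply(chains, `[[`, "alpha"))),
             mean(unlist(lapply(chains, `[[`, "tau_u"))),
             mean(unlist(lapply(chains, `[[`, "tau_v"))),
             mean(unlist(lapply(chains, `[[`, "sd_u"))),
             mean(unlist(lapply(chains, `[[`, "sd_v")))),
    median = c(stats::median(unlist(lapply(chains, `[[`, "alpha"))),
               stats::median(unlist(lapply(chains, `[[`, "tau_u"))),
               stats::median(unlist(lapply(chains, `[[`, "tau_v"))),
               stats::median(unlist(lapply(chains, `[[`, "sd_u"))),
               stats::median(unlist(lapply(chains, `[[`, "sd_v")))),
    stringsAsFactors = FALSE)

  structure(list(estimates = estimates, globals = globals,
                 draws = list(theta = theta_chains,
                              alpha = lapply(chains, `[[`, "alpha"),
                              tau_u = lapply(chains, `[[`, "tau_u"),
                              tau_v = lapply(chains, `[[`, "tau_v")),
                 acceptance = accept, graph = graph,
                 settings = list(n_iter = n_iter, n_burnin = n_burnin,
                                 thin = thin, n_chains = n_chains,
                                 prior_tau_u = prior_tau_u,
                                 prior_tau_v = prior_tau_v,
                                 intercept_prior_sd = intercept_prior_sd,
                                 fix_tau_u = fix_tau_u, fix_tau_v = fix_tau_v,
                                 seed = seed),
                 call = match.call()),
            class = "bym")
}

# Greedy graph coloring; returns a list of integer index vectors such that no
# two areas in the same class are adjacent (so their full conditionals are
# independent and can be Metropolis-updated jointly). Isolated areas are
# excluded (their u is pinned at 0).
color_classes <- function(graph) {
  ids <- graph$area_ids
  deg <- lengths(graph$neighbors)
  ord <- order(-deg)
  col <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (k in ord) {
    id <- ids[[k]]
    if (deg[[k]] == 0L) next
    used <- col[graph$neighbors[[id]]]
    col[[id]] <- min(setdiff(seq_len(length(ids)), used[!is.na(used)]))
  }
  lapply(split(seq_along(ids), col), as.integer)
}

run_bym_chain <- function(o, e, deg, comp_idx, n_comp, ei, ej,
                          classes, w_by_class, n_iter, n_burnin, thin,
                          prior_tau_u, prior_tau_v, intercept_prior_sd,
                          proposal_sd, fix_tau_u, fix_tau_v, chain_seed) {
  set.seed(chain_seed)
  n <- length(o)
  alpha <- log(sum(o[e > 0]) / sum(e[e > 0]))
  if (!is.finite(alpha)) alpha <- 0
  u <- numeric(n); v <- numeric(n)
  tau_u <- fix_tau_u %||% 10
  tau_v <- fix_tau_v %||% 10
  sd_alpha <- proposal_sd
  sd_u <- rep(proposal_sd, n)
  sd_v <- rep(proposal_sd, n)

  total <- n_burnin + n_iter * thin
  theta_kept <- matrix(NA_real_, n_iter, n)
  alpha_kept <- numeric(n_iter)
  tau_u_kept <- numeric(n_iter)
  tau_v_kept <- numeric(n_iter)
  sdu_kept <- numeric(n_iter)
  sdv_kept <- numeric(n_iter)

  batch <- 50L
  acc_alpha <- 0L; acc_u <- numeric(n); acc_v <- numeric(n)
  try_alpha <- 0L; try_u <- numeric(n); try_v <- 0L

  for (it in seq_len(total)) {
    # -- intercept: random-walk Metropolis
    prop <- alpha + stats::rnorm(1L, 0, sd_alpha)
    ll <- sum(o * (prop - alpha)) -
      sum(e * exp(u + v) * (exp(prop) - exp(alpha)))
    lp <- (alpha^2 - prop^2) / (2 * intercept_prior_sd^2)
    try_alpha <- try_alpha + 1L
    if (log(stats::runif(1L)) < ll + lp) {
      alpha <- prop
      acc_alpha <- acc_alpha + 1L
    }

    # -- structured effects, jointly over independent color classes
    for (k in seq_along(classes)) {
      idx <- classes[[k]]
      s_nb <- as.numeric(w_by_class[[k]] %*% u)
      cur <- u[idx]
      prop <- cur + stats::rnorm(length(idx), 0, sd_u[idx])
      ll <- o[idx] * (prop - cur) -
        e[idx] * exp(alpha + v[idx]) * (exp(prop) - exp(cur))
      lp <- -tau_u / 2 * (deg[idx] * (prop^2 - cur^2) - 2 * s_nb * (prop - cur))
      acc <- log(stats::runif(length(idx))) < ll + lp
      u[idx[acc]] <- prop[acc]
      try_u[idx] <- try_u[idx] + 1L
      acc_u[idx] <- acc_u[idx] + acc
    }
    # re-center per component; with one component the level moves into alpha
    for (ci in comp_idx) {
      if (length(ci) > 1L) {
        m <- mean(u[ci])
        u[ci] <- u[ci] - m
        if (n_comp == 1L) alpha <- alpha + m
      }
    }

    # -- unstructured effects, elementwise (conditionally independent)
    prop <- v + stats::rnorm(n, 0, sd_v)
    ll <- o * (prop - v) - e * exp(alpha + u) * (exp(prop) - exp(v))
    lp <- -tau_v / 2 * (prop^2 - v^2)
    acc <- log(stats::runif(n)) < ll + lp
    v[acc] <- prop[acc]
    try_v <- try_v + 1L
    acc_v <- acc_v + acc

    # -- precisions: conjugate Gibbs (unless fixed)
    if (is.null(fix_tau_u)) {
      ssq_u <- if (length(ei)) sum((u[ei] - u[ej])^2) else 0
      tau_u <- stats::rgamma(1L, shape = prior_tau_u[1L] + (n - n_comp) / 2,
                             rate = prior_tau_u[2L] + ssq_u / 2)
    }
    if (is.null(fix_tau_v)) {
      tau_v <- stats::rgamma(1L, shape = prior_tau_v[1L] + n / 2,
                             rate = prior_tau_v[2L] + sum(v^2) / 2)
    }

    # -- proposal adaptation, burn-in only, frozen afterwards
    if (it <= n_burnin && it %% batch == 0L) {
      sd_alpha <- adapt_sd(sd_alpha, acc_alpha / try_alpha)
      rate_u <- ifelse(try_u > 0, acc_u / pmax(try_u, 1L), 0.4)
      sd_u <- adapt_sd(sd_u, rate_u)
      sd_v <- adapt_sd(sd_v, acc_v / try_v)
      acc_alpha <- 0L; try_alpha <- 0L
      acc_u[] <- 0; try_u[] <- 0
      acc_v[] <- 0; try_v <- 0L
    }
    if (it == n_burnin) {
      # acceptance reported over the kept phase only
      acc_alpha <- 0L; try_alpha <- 0L; acc_u[] <- 0; try_u[] <- 0
      acc_v[] <- 0; try_v <- 0L
    }

    if (it > n_burnin && (it - n_burnin) %% thin == 0L) {
      j <- (it - n_burnin) %/% thin
      theta_kept[j, ] <- exp(alpha + u + v)
      alpha_kept[j] <- alpha
      tau_u_kept[j] <- tau_u
      tau_v_kept[j] <- tau_v
      sdu_kept[j] <- stats::sd(u)
      sdv_kept[j] <- stats::sd(v)
    }
  }

  list(theta = theta_kept, alpha = alpha_kept, tau_u = tau_u_kept,
       tau_v = tau_v_kept, sd_u = sdu_kept, sd_v = sdv_kept,
       acceptance = list(alpha = if (try_alpha > 0) acc_alpha / try_alpha else NA_real_,
                         u = if (any(try_u > 0)) sum(acc_u) / sum(try_u) else NA_real_,
                         v = if (try_v > 0) mean(acc_v / try_v) else NA_real_))
}

adapt_sd <- function(sd, rate, target = 0.4) {
  pmin(5, pmax(1e-4, sd * exp(pmin(0.5, pmax(-0.5, rate - target)))))
}

# Effective sample size from the empirical autocorrelation function,
# truncated at the first negative pair sum (Geyer's initial positive
# sequence).
ess_autocorr <- function(x) {
  m <- length(x)
  if (m < 4L || stats::sd(x) == 0) return(as.numeric(m))
  rho <- as.numeric(stats::acf(x, lag.max = min(200L, m - 2L), plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, m / (1 + 2 * s))
}

# Split-chain potential scale reduction factor (each chain halved).
split_rhat <- function(chain_list) {
  seqs <- list()
  for (x in chain_list) {
    m <- floor(length(x) / 2)
    if (m < 2L) return(NA_real_)
    seqs <- c(seqs, list(x[seq_len(m)], x[m + seq_len(m)]))
  }
  mns <- vapply(seqs, mean, numeric(1))
  vrs <- vapply(seqs, stats::var, numeric(1))
  n <- length(seqs[[1L]])
  w <- mean(vrs)
  if (w == 0) return(1)
  b <- n * stats::var(mns)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Conjugate posterior for a single area under a Gamma prior
#'
#' Analytic oracle for the degenerate no-spatial case: with
#' `O ~ Poisson(E * theta)` and `theta ~ Gamma(shape, rate)`, the posterior is
#' `Gamma(shape + O, rate + E)`. Used to validate the MCMC sampler.
#'
#' @param observed Non-negative count `O`.
#' @param expected Positive expected count `E`.
#' @param shape,rate Positive Gamma prior parameters.
#' @return Named numeric `c(shape =, rate =)` of the posterior.
#' @export
#' @examples
#' conjugate_posterior_single_area(0, 1, 1, 1)  # Gamma(1, 2), mean 0.5
conjugate_posterior_single_area <- function(observed, expected, shape, rate) {
  stopifnot(is_count(observed), expected > 0, shape > 0, rate > 0)
  c(shape = shape + observed, rate = rate + expected)
}

#' Posterior exceedance probability from MCMC draws
#'
#' Fraction of draws strictly greater than the threshold — the
#' `Pr(RR > 1 | data)` summary when applied to relative-risk draws with
#' threshold 1. Draws exactly at the threshold (measure zero for a continuous
#' posterior) count as not exceeding.
#'
#' @param draws Numeric vector of posterior draws (at least one).
#' @param threshold Positive threshold, default 1.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' exceedance_probability(c(0.5, 1.5), 1)  # 0.5
exceedance_probability <- function(draws, threshold = 1) {
  if (!length(draws)) stop_fmt("no draws supplied")
  stopifnot(is.numeric(draws), threshold > 0)
  mean(draws > threshold)
}

#' Pooled posterior draws of the per-area relative risks
#'
#' @param object A fitted [fit_bym()] model.
#' @return Matrix (total kept draws x areas) of relative-risk draws, columns
#'   named by area id.
#' @export
theta_draws <- function(object) {
  stopifnot(inherits(object, "bym"))
  m <- do.call(rbind, object$draws$theta)
  colnames(m) <- object$estimates$area_id
  m
}
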