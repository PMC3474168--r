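#' @export
print.bym <- function(x, ...) {
  s <- x$settings
  est <- x$estimates
  cat("Besag-York-Mollie spatial smoothing model\n")
  cat(sprintf("  %d areas, %d chain(s) x %d kept draws (burn-in %d, thin %d)\n",
              nrow(est), s$n_chains, s$n_iter, s$n_burnin, s$thin))
  a <- x$globals$median[x$globals$parameter == "alpha"]
  cat(sprintf("  baseline relative risk exp(alpha): %.3f\n", exp(a)))
  cat(sprintf("  smoothed RR range: %.2f - %.2f (raw %.2f - %.2f)\n",
              min(est$smrr), max(est$smrr),
              min(est$rr_raw, na.rm = TRUE), max(est$rr_raw, na.rm = TRUE)))
  cat(sprintf("  areas with Pr(RR>1|data) > 0.95: %d; < 0.05: %d\n",
              sum(est$pr_exceed > 0.95), sum(est$pr_exceed < 0.05)))
  invisible(x)
}

#' Summarize a fitted BYM model
#'
#' @param object A [fit_bym()] object.
#' @param ... Unused.
#' @return A `summary.bym` list: per-area `estimates`, `globals` (posterior
#'   summaries of the intercept, both precisions, and the realized s.d. of the
#'   structured/unstructured effects), the empirical `shrinkage` factor
#'   `var(log smrr) / var(log rr_raw)` over areas with observed cases, and the
#'   worst convergence diagnostics.
#' @export
summary.bym <- function(object, ...) {
  est <- object$estimates
  with_cases <- est$observed > 0 & est$expected > 0
  shrinkage <- if (sum(with_cases) >= 2) {
    stats::var(log(est$smrr[with_cases])) /
      stats::var(log(est$rr_raw[with_cases]))
  } else NA_real_
  structure(list(estimates = est, globals = object$globals,
                 shrinkage = shrinkage,
                 max_rhat = max(est$rhat, na.rm = TRUE),
                 min_ess = min(est$ess),
                 acceptance = object$acceptance,
                 settings = object$settings),
            class = "summary.bym")
}

#' @export
print.summary.bym <- function(x, ...) {
  cat("BYM model summary\n\nGlobal parameters (posterior):\n")
  print(x$globals, row.names = FALSE, digits = 4)
  cat(sprintf("\nShrinkage var(log SmRR)/var(log raw RR): %.3f\n", x$shrinkage))
  cat(sprintf("Diagnostics: max split-Rhat %.3f, min ESS %.0f\n",
              x$max_rhat, x$min_ess))
  cat("\nPer-area estimates (first rows):\n")
  print(utils::head(x$estimates, 8), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract smoothed relative risks
#'
#' @param object A [fit_bym()] object.
#' @param type `"median"` (the SmRR reported throughout, default) or
#'   `"mean"`.
#' @param ... Unused.
#' @return Named numeric vector of per-area smoothed relative risks.
#' @export
coef.bym <- function(object, type = c("median", "mean"), ...) {
  type <- match.arg(type)
  est <- object$estimates
  stats::setNames(if (type == "median") est$smrr else est$smrr_mean, est$area_id)
}

#' @export
fitted.bym <- function(object, ...) {
  est <- object$estimates
  stats::setNames(est$expected * est$smrr, est$area_id)
}

#' Residuals of a fitted BYM model
#'
#' @param object A [fit_bym()] object.
#' @param type `"pearson"` (default; `(O - E*SmRR)/sqrt(E*SmRR)` under the
#'   Poisson likelihood) or `"response"` (`O - E*SmRR`).
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.bym <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  est <- object$estimates
  mu <- est$expected * est$smrr
  r <- est$observed - mu
  if (type == "pearson") r <- ifelse(mu > 0, r / sqrt(mu), NA_real_)
  stats::setNames(r, est$area_id)
}

#' @export
as.data.frame.bym <- function(x, ...) x$estimates

#' Posterior-predictive simulation of observed counts
#'
#' Draws replicate observed counts `O* ~ Poisson(E * theta)` using relative
#' risks sampled from the kept posterior draws.
#'
#' @param object A [fit_bym()] object.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame, one row per area, columns `sim_1 ... sim_nsim`.
#' @export
simulate.bym <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  theta <- theta_draws(object)
  est <- object$estimates
  rows <- sample.int(nrow(theta), nsim, replace = TRUE)
  out <- vapply(rows, function(r) {
    stats::rpois(nrow(est), est$expected * theta[r, ])
  }, numeric(nrow(est)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(area_id = est$area_id, stringsAsFactors = FALSE), out)
}

#' Caterpillar plot of smoothed relative risks
#'
#' Areas ordered by SmRR, with 95% credible intervals, colored by the
#' certainty classification at the given threshold; the dashed line marks
#' RR = 1 and open circles show the raw observed-to-expected ratios.
#'
#' @param x A [fit_bym()] object.
#' @param threshold Certainty threshold for the red/yellow/green coloring.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bym <- function(x, threshold = 0.95, ...) {
  est <- x$estimates[order(x$estimates$smrr), ]
  cols <- c(red = "#c23b22", yellow = "#e0b020", green = "#2e8540")
  cls <- as.character(classify_certainty(est$pr_exceed, threshold))
  idx <- seq_len(nrow(est))
  graphics::plot(idx, est$smrr, log = "y",
                 ylim = range(c(est$ci_low, est$ci_high, est$rr_raw), na.rm = TRUE),
                 pch = 19, col = cols[cls],
                 xlab = "areas (ordered by SmRR)", ylab = "relative risk", ...)
  graphics::segments(idx, est$ci_low, idx, est$ci_high, col = cols[cls])
  graphics::points(idx, est$rr_raw, pch = 1, col = "grey40", cex = 0.7)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
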