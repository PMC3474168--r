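#' Red/yellow/green certainty classification
#'
#' Classifies each area's posterior exceedance probability: *red* when
#' `Pr(RR > 1 | data) > threshold` (strong evidence of elevated risk),
#' *green* when `Pr(RR < 1 | data) = 1 - Pr(RR > 1 | data) > threshold`
#' (strong evidence of lowered risk), *yellow* otherwise. Inequalities are
#' strict, so a probability exactly at the threshold is yellow.
#'
#' @param pr_exceed Numeric vector of probabilities in `[0, 1]`.
#' @param threshold Certainty threshold in `(0.5, 1)`; default 0.95.
#' @return Factor with levels `red`, `yellow`, `green`.
#' @export
#' @examples
#' classify_certainty(c(0.96, 0.5, 0.04, 0.95))
classify_certainty <- function(pr_exceed, threshold = 0.95) {
  if (any(!is.finite(pr_exceed)) || any(pr_exceed < 0) || any(pr_exceed > 1)) {
    stop_fmt("pr_exceed values must lie in [0, 1]")
  }
  if (!is.finite(threshold) || threshold <= 0.5 || threshold >= 1) {
    stop_fmt("threshold must lie in (0.5, 1)")
  }
  # strict inequalities with a representation-noise guard so that, e.g.,
  # pr = 0.05 at threshold 0.95 sits exactly on the boundary (yellow) even
  # though 1 - 0.95 > 0.05 in floating point
  eps <- 1e-9
  factor(ifelse(pr_exceed - threshold > eps, "red",
                ifelse((1 - threshold) - pr_exceed > eps, "green", "yellow")),
         levels = c("red", "yellow", "green"))
}

#' Certainty ranks from exceedance probabilities
#'
#' Orders areas by ascending `Pr(RR > 1 | data)`: rank 1 is the most certainly
#' lowered relative risk and rank N the most certainly elevated. Ties are
#' broken by ascending SmRR, then lexicographic area id, so the ranks are a
#' deterministic permutation of `1..N`.
#'
#' @param pr_by_area Named numeric vector of exceedance probabilities.
#' @param smrr Optional named numeric vector of smoothed relative risks used
#'   for tie-breaking.
#' @return Named integer vector of ranks in the input order.
#' @export
#' @examples
#' certainty_rank(c(A = 0.01, B = 0.99, C = 0.5))
certainty_rank <- function(pr_by_area, smrr = NULL) {
  if (!length(pr_by_area)) stop_fmt("empty probability map")
  ids <- names(pr_by_area)
  if (is.null(ids)) stop_fmt("pr_by_area must be named by area id")
  tie <- if (is.null(smrr)) rep(0, length(ids)) else as.numeric(smrr[ids])
  ord <- order(as.numeric(pr_by_area), tie, ids)
  rank <- integer(length(ids))
  rank[ord] <- seq_along(ids)
  stats::setNames(rank, ids)
}

#' Build the per-wave certainty map
#'
#' Combines the color classification and certainty rank for every area of a
#' fitted model into the table behind a statistical certainty geo-map.
#'
#' @param estimates A [fit_bym()] object or its `estimates` data frame (needs
#'   `area_id`, `pr_exceed`, `smrr`).
#' @param threshold Certainty threshold; default 0.95.
#' @param wave_label Label attached to the map (e.g. the survey year).
#' @return A data frame of class `certainty_map` with columns `area_id`,
#'   `color`, `pr_exceed`, `smrr`, `certainty_rank`; attributes `wave_label`
#'   and `threshold`.
#' @export
#' @examples
#' est <- data.frame(area_id = c("a", "b"), pr_exceed = c(0.98, 0.4),
#'                   smrr = c(1.6, 0.9))
#' build_certainty_map(est, wave_label = "2006")
build_certainty_map <- function(estimates, threshold = 0.95, wave_label = "") {
  if (inherits(estimates, "bym")) estimates <- estimates$estimates
  req <- c("area_id", "pr_exceed", "smrr")
  if (!is.data.frame(estimates) || !all(req %in% names(estimates)) ||
      !nrow(estimates)) {
    stop_fmt("estimates must be a non-empty data frame with columns %s",
             paste(req, collapse = ", "))
  }
  pr <- stats::setNames(estimates$pr_exceed, estimates$area_id)
  smrr <- stats::setNames(estimates$smrr, estimates$area_id)
  out <- data.frame(area_id = estimates$area_id,
                    color = classify_certainty(estimates$pr_exceed, threshold),
                    pr_exceed = estimates$pr_exceed,
                    smrr = estimates$smrr,
                    certainty_rank = as.integer(certainty_rank(pr, smrr)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("certainty_map", "data.frame"),
            wave_label = wave_label, threshold = threshold)
}

#' @export
print.certainty_map <- function(x, ...) {
  counts <- table(x$color)
  cat(sprintf("Certainty map%s: %d areas (red %d, yellow %d, green %d; threshold %.2f)\n",
              if (nzchar(attr(x, "wave_label"))) paste0(" [", attr(x, "wave_label"), "]") else "",
              nrow(x), counts[["red"]], counts[["yellow"]], counts[["green"]],
              attr(x, "threshold")))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE, digits = 3)
  if (nrow(x) > 6) cat(sprintf("... %d more areas\n", nrow(x) - 6))
  invisible(x)
}
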