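#' Detect evidential positional changes between two survey waves
#'
#' Compares two certainty maps area by area. A positional change is
#' *evidential* when both conditions hold: the certainty color changed
#' between waves, and `Pr(RR > 1 | data)` differed by at least `delta`
#' (absolute difference in probability; the boundary `delta` itself counts).
#' An area can thus change color without an evidential change when its
#' exceedance probability moved less than `delta`, and a large probability
#' shift within the same color is never evidential on its own.
#'
#' @param map1,map2 [build_certainty_map()] objects over the identical area
#'   set (wave 1 and wave 2).
#' @param delta Minimum absolute shift in exceedance probability; default
#'   0.25 (i.e. 25 percentage points).
#' @return An object of class `change_report`: list with `areas` (data frame
#'   with per-area colors, probabilities, SmRRs, ranks, `color_changed`,
#'   `pr_abs_diff` and `evidential`), `transitions` (the
#'   [transition_table()]), and `evidential_ids`.
#' @export
detect_positional_changes <- function(map1, map2, delta = 0.25) {
  stopifnot(inherits(map1, "certainty_map"), inherits(map2, "certainty_map"))
  if (!is.finite(delta) || delta < 0 || delta > 1) {
    stop_fmt("delta must be a probability difference in [0, 1]")
  }
  if (!setequal(map1$area_id, map2$area_id)) {
    stop_fmt("the two certainty maps cover different area sets")
  }
  m2 <- map2[match(map1$area_id, map2$area_id), , drop = FALSE]
  pr_abs_diff <- abs(m2$pr_exceed - map1$pr_exceed)
  color_changed <- as.character(map1$color) != as.character(m2$color)
  evidential <- color_changed & pr_abs_diff >= delta
  areas <- data.frame(area_id = map1$area_id,
                      color_1 = as.character(map1$color),
                      color_2 = as.character(m2$color),
                      pr_1 = map1$pr_exceed, pr_2 = m2$pr_exceed,
                      smrr_1 = map1$smrr, smrr_2 = m2$smrr,
                      rank_1 = map1$certainty_rank, rank_2 = m2$certainty_rank,
                      color_changed = color_changed,
                      pr_abs_diff = pr_abs_diff,
                      evidential = evidential,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(areas = areas,
                 transitions = transition_table(map1, map2),
                 evidential_ids = areas$area_id[evidential],
                 delta = delta,
                 wave_labels = c(attr(map1, "wave_label"), attr(map2, "wave_label"))),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  wl <- x$wave_labels
  cat(sprintf("Two-wave change report%s\n",
              if (all(nzchar(wl))) sprintf(" (%s vs %s)", wl[1L], wl[2L]) else ""))
  cat(sprintf("  %d areas; %d changed color; %d evidential positional change(s) (delta = %.2f)\n",
              nrow(x$areas), sum(x$areas$color_changed),
              length(x$evidential_ids), x$delta))
  if (length(x$evidential_ids)) {
    cat("  evidential areas:", paste(x$evidential_ids, collapse = ", "), "\n")
  }
  cat("  color transitions (rows wave 1, cols wave 2):\n")
  print(x$transitions)
  invisible(x)
}

#' Color transition table between two waves
#'
#' @param map1,map2 [build_certainty_map()] objects over the same areas.
#' @return A 3 x 3 contingency table of (wave-1 color, wave-2 color); the
#'   diagonal holds the stable areas.
#' @export
transition_table <- function(map1, map2) {
  stopifnot(inherits(map1, "certainty_map"), inherits(map2, "certainty_map"))
  if (!setequal(map1$area_id, map2$area_id)) {
    stop_fmt("the two certainty maps cover different area sets")
  }
  m2 <- map2[match(map1$area_id, map2$area_id), , drop = FALSE]
  lv <- c("red", "yellow", "green")
  table(wave1 = factor(map1$color, levels = lv),
        wave2 = factor(m2$color, levels = lv))
}

#' Polarization ratio of smoothed relative risks
#'
#' `max(SmRR) / min(SmRR)` over all areas of one wave — a one-number summary
#' of the geographic inequality in risk; 1 means a perfectly even map.
#' Summaries conventionally report it to one decimal.
#'
#' @param smrr_by_area Numeric vector of positive per-area SmRRs.
#' @return The ratio (numeric scalar, `>= 1`).
#' @export
#' @examples
#' polarization_ratio(c(0.44, 1.0, 1.76))  # 4.0
polarization_ratio <- function(smrr_by_area) {
  if (!length(smrr_by_area)) stop_fmt("empty SmRR vector")
  if (any(!is.finite(smrr_by_area)) || any(smrr_by_area <= 0)) {
    stop_fmt("SmRR values must be positive and finite")
  }
  max(smrr_by_area) / min(smrr_by_area)
}

#' Descriptive rank of an area-level covariate
#'
#' Ranks areas by a covariate value (e.g. a parish-level socio-economic
#' proportion), rank 1 = smallest; ties are broken by area id so the result
#' is always a permutation of `1..N`.
#'
#' @param values_by_area Named numeric vector.
#' @return Named integer ranks in the input order.
#' @export
#' @examples
#' covariate_rank(c(A = 10.0, B = 48.4))
covariate_rank <- function(values_by_area) {
  if (!length(values_by_area)) stop_fmt("empty covariate vector")
  ids <- names(values_by_area)
  if (is.null(ids)) stop_fmt("values_by_area must be named by area id")
  ord <- order(as.numeric(values_by_area), ids)
  rank <- integer(length(ids))
  rank[ord] <- seq_along(ids)
  stats::setNames(rank, ids)
}
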