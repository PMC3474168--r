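#' Validate an area table
#'
#' An area table holds one survey wave of area-level counts: one row per
#' (area, sex) with the number of children examined and the number with the
#' outcome. Checks the schema, count sanity (`0 <= n_cases <= n_examined`)
#' and uniqueness of (area, sex) rows; extra columns (e.g. an age stratum)
#' are permitted and ignored.
#'
#' @param table Data frame with columns `area_id`, `sex` (`"M"`/`"F"`),
#'   `n_examined`, `n_cases`, and optionally `wave`.
#' @param graph Optional [adjacency_graph()]; if given, every `area_id` must
#'   be a graph area.
#' @return The validated table (invisibly usable), with `area_id` and `sex`
#'   as character.
#' @export
as_area_table <- function(table, graph = NULL) {
  req <- c("area_id", "sex", "n_examined", "n_cases")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop_fmt("area table missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  table$area_id <- as.character(table$area_id)
  table$sex <- as.character(table$sex)
  bad_sex <- which(!table$sex %in% c("M", "F"))
  if (length(bad_sex)) {
    stop_fmt("row %d: sex must be 'M' or 'F' (got '%s')", bad_sex[[1L]], table$sex[bad_sex[[1L]]])
  }
  for (col in c("n_examined", "n_cases")) {
    bad <- which(!is.finite(table[[col]]) | table[[col]] < 0 |
                   table[[col]] != floor(table[[col]]))
    if (length(bad)) {
      stop_fmt("row %d: %s must be a non-negative integer", bad[[1L]], col)
    }
  }
  over <- which(table$n_cases > table$n_examined)
  if (length(over)) {
    stop_fmt("row %d: n_cases (%d) exceeds n_examined (%d)", over[[1L]],
             table$n_cases[over[[1L]]], table$n_examined[over[[1L]]])
  }
  key <- paste(table$area_id, table$sex,
               if ("wave" %in% names(table)) table$wave else "")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_fmt("row %d: duplicate (area_id, sex) = (%s, %s)", dup[[1L]],
             table$area_id[dup[[1L]]], table$sex[dup[[1L]]])
  }
  if (!is.null(graph)) {
    unknown <- setdiff(table$area_id, graph$area_ids)
    if (length(unknown)) {
      stop_fmt("area table contains area(s) absent from the graph: %s",
               paste(unknown, collapse = ", "))
    }
  }
  table
}

#' Sex-specific reference rates for the whole study population
#'
#' Pools all areas: `rate_s = sum_a n_cases(a, s) / sum_a n_examined(a, s)` —
#' the outcome rates of the total study population used as the reference for
#' indirect standardization.
#'
#' @param table An area table (see [as_area_table()]).
#' @return Named numeric vector of per-sex rates, class `reference_rates`.
#' @export
#' @examples
#' tab <- data.frame(area_id = "a", sex = c("M", "F"),
#'                   n_examined = c(100, 100), n_cases = c(10, 20))
#' reference_rates(tab)
reference_rates <- function(table) {
  table <- as_area_table(table)
  cases <- tapply(table$n_cases, table$sex, sum)
  denom <- tapply(table$n_examined, table$sex, sum)
  zero <- names(denom)[denom == 0]
  if (length(zero)) {
    stop_fmt("sex stratum '%s' has zero examined children", zero[[1L]])
  }
  structure(as.numeric(cases / denom), names = names(denom), class = "reference_rates")
}

#' Indirectly standardized expected counts per area
#'
#' `E_a = sum_s n_examined(a, s) * rate_s`: the cases each area would see if
#' its children experienced the reference (whole-population, sex-specific)
#' rates. Areas with zero examined children get `E = 0` and are carried
#' through (not dropped), so downstream maps stay complete.
#'
#' @param table An area table.
#' @param rates A [reference_rates()] vector (or any named per-sex rates).
#' @return Named numeric vector of expected counts, one per area, in order of
#'   first appearance.
#' @export
expected_counts <- function(table, rates) {
  table <- as_area_table(table)
  missing_sex <- setdiff(unique(table$sex), names(rates))
  if (length(missing_sex)) {
    stop_fmt("no reference rate for sex stratum '%s'", missing_sex[[1L]])
  }
  e_row <- table$n_examined * as.numeric(rates[table$sex])
  ids <- unique(table$area_id)
  e <- vapply(split(e_row, factor(table$area_id, levels = ids)), sum, numeric(1))
  e[ids]
}

#' Raw observed-to-expected relative risks
#'
#' `RR_a = O_a / E_a`. Areas with `O = 0` and `E = 0` get `NA` (flagged
#' undefined; excluded from smoothing but kept in output). `O > 0` with
#' `E = 0` is impossible under internal standardization and raises an error.
#'
#' @param observed,expected Named numeric vectors over the same areas.
#' @return Named numeric vector of raw relative risks.
#' @export
raw_rr <- function(observed, expected) {
  if (!setequal(names(observed), names(expected))) {
    stop_fmt("observed and expected cover different area sets")
  }
  expected <- expected[names(observed)]
  bad <- names(observed)[observed > 0 & expected == 0]
  if (length(bad)) {
    stop_fmt("area '%s' has observed cases but zero expected count; inputs inconsistent",
             bad[[1L]])
  }
  rr <- ifelse(expected > 0, observed / expected, NA_real_)
  stats::setNames(rr, names(observed))
}

#' Per-area observed, expected and raw relative risk
#'
#' Convenience wrapper combining [reference_rates()] (computed internally from
#' the same wave unless supplied), [expected_counts()] and [raw_rr()]. With
#' internal rates, indirect standardization guarantees `sum(E) == sum(O)`.
#'
#' @param table An area table for one wave.
#' @param rates Optional externally supplied per-sex rates; defaults to the
#'   table's own pooled rates.
#' @return Data frame with columns `area_id`, `observed`, `expected`, `rr_raw`.
#' @export
#' @examples
#' g <- grid_geography(2, 2)$graph
#' sim <- simulate_two_waves(g, sim_config(seed = 1))
#' head(area_summary(sim$wave1))
area_summary <- function(table, rates = NULL) {
  table <- as_area_table(table)
  if (is.null(rates)) rates <- reference_rates(table)
  e <- expected_counts(table, rates)
  ids <- names(e)
  o <- vapply(split(table$n_cases, factor(table$area_id, levels = ids)), sum, numeric(1))[ids]
  data.frame(area_id = ids, observed = as.numeric(o), expected = as.numeric(e),
             rr_raw = as.numeric(raw_rr(o, e)), row.names = NULL,
             stringsAsFactors = FALSE)
}
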