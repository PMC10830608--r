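#' Can a patch produce offspring next year?
#'
#' An occupied patch counts as "breeding" when it holds a population
#' capable of producing offspring: at least one female in female-only
#' mode, at least one individual of each sex in two-sex mode. Juveniles
#' count by default (a juvenile pair this year breeds next year).
#'
#' @param n_f,n_m female and male counts in the patch (vectorised); pass
#'   adult-only counts to get the adults-only criterion.
#' @param mode `"female_only"` or `"two_sex"`.
#' @return logical.
#' @export
breeding_patch <- function(n_f, n_m = 0L, mode = c("two_sex", "female_only")) {
  mode <- match.arg(mode)
  if (mode == "female_only") n_f >= 1 else n_f >= 1 & n_m >= 1
}

#' Range edge of a set of breeding patches
#'
#' The furthest-forward (maximum-row) habitat patch with a breeding
#' population. Returns `NA` when no breeding patch exists (extinct or
#' all patches single-sex).
#'
#' @param rows patch row indices.
#' @param breeding logical from [breeding_patch].
#' @return edge row index, or `NA`.
#' @export
range_edge <- function(rows, breeding = TRUE) {
  rows <- rows[breeding]
  if (length(rows) == 0L) NA_integer_ else max(rows)
}

#' Overall spread rate from a yearly edge series
#'
#' The number of extra rows colonised in every consecutive
#' non-overlapping `window`-year interval, divided by `window`; the
#' overall rate is the mean of these window rates. The series is indexed
#' from year 0 (initial state); windows containing a missing edge are
#' dropped. Units: rows per generation (one generation = one year).
#'
#' @param edge edge-row series at years `0, 1, ..., length(edge) - 1`;
#'   truncate the series to restrict the horizon.
#' @param window window length in years (default 5).
#' @return mean window rate, or `NA` if no complete window exists.
#' @examples
#' spread_rate(c(500, NA, NA, NA, NA, 520, NA, NA, NA, NA, 555, NA, NA, NA, NA, 555))
#' # windows (520-500)/5, (555-520)/5, (555-555)/5 -> mean(4, 7, 0)
#' @export
spread_rate <- function(edge, window = 5L) {
  n_win <- (length(edge) - 1L) %/% window
  if (n_win < 1L) return(NA_real_)
  starts <- (seq_len(n_win) - 1L) * window + 1L
  rates <- (edge[starts + window] - edge[starts]) / window
  rates <- rates[!is.na(rates)]
  if (length(rates) == 0L) NA_real_ else mean(rates)
}

#' Quasi-equilibrium test on core occupancy
#'
#' A non-extinct run maintains quasi-equilibrium occupancy when the mean
#' yearly change in core proportional occupancy over the assessment
#' window, plus one standard error, exceeds zero (strictly):
#' mean(dp) + sd(dp)/sqrt(n) > 0 for dp_t = p_{t+1} - p_t,
#' t = y_from .. y_to - 1.
#'
#' @param p core-occupancy series.
#' @param years year index of each element (default `0, 1, ...`).
#' @param y_from,y_to assessment window (default years 20 to the end).
#' @return logical.
#' @export
quasi_equilibrium <- function(p, years = seq_along(p) - 1L, y_from = 20L,
                              y_to = max(years)) {
  keep <- years >= y_from & years <= y_to
  p <- p[keep][order(years[keep])]
  dp <- diff(p)
  if (length(dp) < 2L || anyNA(dp)) return(FALSE)
  se <- stats::sd(dp) / sqrt(length(dp))
  (mean(dp) + se) > 0
}

#' Neighbourhood occupancy and mating failure along the occupied range
#'
#' Splits the occupied range into 10-row sections starting from the
#' range edge and working backwards, so that each section keeps a fixed
#' relative location in the occupied range as it moves. Per section it
#' reports the proportion of habitat patches holding a breeding
#' population (occupancy P) and the proportion of unmated females among
#' the section's reproductive-age females (missing when the section held
#' no such females). Occupancy uses end-of-year patch states; unmated
#' counts come from that year's mating step.
#'
#' @param patches one year of the `patches` table from
#'   [run_simulation] (run with `record_patches = TRUE`).
#' @param landscape the `grid_landscape` of the run.
#' @param edge_row that year's range-edge row.
#' @param mode `"female_only"` or `"two_sex"`.
#' @param section_rows section depth in rows (default 10).
#' @param breeding_includes_juveniles as in [sim_config].
#' @return data.frame: `section` (0 at the edge), `row_hi`, `row_lo`,
#'   `n_patches`, `n_breeding`, `occupancy`, `females`, `unmated`,
#'   `prop_unmated`.
#' @export
neighbourhood_stats <- function(patches, landscape, edge_row,
                                mode = c("two_sex", "female_only"),
                                section_rows = 10L,
                                breeding_includes_juveniles = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(landscape, "grid_landscape"))
  if (is.na(edge_row)) stop("`edge_row` is missing: no occupied range to section")
  hab_rows <- ((which(landscape$habitat) - 1L) %% landscape$n_rows) + 1L
  n_sections <- ceiling(edge_row / section_rows)
  out <- vector("list", n_sections)
  nf_end <- patches$end_adult_f +
    if (breeding_includes_juveniles) patches$end_juv_f else 0L
  nm_end <- patches$end_adult_m +
    if (breeding_includes_juveniles) patches$end_juv_m else 0L
  breeding <- breeding_patch(nf_end, nm_end, mode)
  for (s in seq_len(n_sections) - 1L) {
    hi <- edge_row - s * section_rows
    lo <- max(1L, hi - section_rows + 1L)
    n_hab <- sum(hab_rows >= lo & hab_rows <= hi)
    in_sec <- patches$row >= lo & patches$row <= hi
    fem <- sum(patches$n_adult_f[in_sec])
    unm <- sum(patches$n_unmated_f[in_sec])
    out[[s + 1L]] <- data.frame(
      section = s, row_hi = hi, row_lo = lo,
      n_patches = n_hab, n_breeding = sum(breeding & in_sec),
      occupancy = if (n_hab > 0) sum(breeding & in_sec) / n_hab else NA_real_,
      females = fem, unmated = unm,
      prop_unmated = if (fem > 0) unm / fem else NA_real_)
  }
  do.call(rbind, out)
}

#' Extinction proportions by mating system
#'
#' @param table experiment table from [run_experiment].
#' @return data.frame: `mating_system`, `n_runs`, `n_extinct`,
#'   `prop_extinct`.
#' @export
extinction_stats <- function(table) {
  agg <- stats::aggregate(extinct ~ mating_system, data = table,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  data.frame(mating_system = agg$mating_system,
             n_runs = agg$extinct[, "n"],
             n_extinct = agg$extinct[, "k"],
             prop_extinct = agg$extinct[, "k"] / agg$extinct[, "n"])
}
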