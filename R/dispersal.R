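#' Directional-persistence weight for a turn
#'
#' A disperser with directional persistence DP is DP^k times less likely
#' to turn by k x 45 degrees than to continue straight ahead: the weight
#' of a candidate heading is DP^(-turn). With DP = 3 a 90-degree turn
#' (turn = 2) has weight 1/9 and a reversal (turn = 4) 1/81.
#'
#' @param turn turn size in multiples of 45 degrees, 0..4 (vectorised).
#' @param dp directional persistence, >= 1.
#' @return relative weight, 1 for straight ahead.
#' @export
directional_weight <- function(turn, dp = 3) {
  if (any(!turn %in% 0:4)) stop("`turn` must be in 0..4 (multiples of 45 degrees)")
  if (dp < 1) stop("`dp` must be >= 1")
  dp^(-turn)
}

#' Per-heading effective movement costs
#'
#' For each cell and each of the 8 compass headings, the effective cost
#' a disperser standing in that cell perceives for a step toward the
#' heading: the arithmetic mean of per-cell movement costs within its
#' perceptual range in that direction, truncated at the grid border.
#' Moving toward habitat within perceptual range is cheaper than moving
#' into open matrix. Two aggregations are available: `"sector"` (every
#' cell within Euclidean distance `pr` whose bearing lies within 22.5
#' degrees of the heading — the stochastic movement simulator's wedge;
#' default) and `"line"` (the `pr` cells along the heading's straight
#' line, starting at the adjacent candidate cell).
#'
#' Headings are numbered 1..8 clockwise from "north" (decreasing row):
#' N, NE, E, SE, S, SW, W, NW, with S pointing up-range.
#'
#' @param landscape a `grid_landscape`.
#' @param cost_habitat,cost_matrix per-cell movement costs (>= 1).
#' @param pr perceptual range in cells, >= 1.
#' @param aggregation `"sector"` or `"line"`.
#' @return numeric matrix, `n_rows * n_cols` rows (row-major cell order:
#'   cell = (row - 1) * n_cols + col) by 8 headings.
#' @export
sms_effective_costs <- function(landscape, cost_habitat = 1, cost_matrix = 10,
                                pr = 5, aggregation = c("sector", "line")) {
  stopifnot(inherits(landscape, "grid_landscape"))
  aggregation <- match.arg(aggregation)
  if (pr < 1) stop("`pr` must be >= 1")
  if (cost_habitat < 1 || cost_matrix < 1) stop("costs must be >= 1")
  sms_effective_cost_cpp(as.integer(t(landscape$habitat)),
                         landscape$n_cols, landscape$n_rows,
                         cost_habitat, cost_matrix, as.integer(pr),
                         as.integer(aggregation == "sector"))
}

#' Step-choice probabilities from one cell
#'
#' Reference implementation of the SMS step kernel: the probability of
#' moving into each on-grid neighbouring cell is proportional to
#' directional_weight(turn) / effective_cost(current cell, heading); with
#' no previous heading the directional weight is 1 for all headings.
#'
#' @param eff effective-cost matrix from [sms_effective_costs].
#' @param landscape the `grid_landscape` the costs were computed on.
#' @param row,col current cell (1-based).
#' @param heading previous heading 1..8, or `NA` for the first step.
#' @param dp directional persistence.
#' @return data.frame with `heading`, `row`, `col`, `prob` over on-grid
#'   neighbours (probabilities sum to 1).
#' @export
step_probs <- function(eff, landscape, row, col, heading = NA, dp = 3) {
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  out <- data.frame(heading = 1:8, row = row + dr, col = col + dc, w = 0)
  for (d in 1:8) {
    rr <- out$row[d]; cc <- out$col[d]
    if (rr < 1 || rr > landscape$n_rows || cc < 1 || cc > landscape$n_cols) {
      out$w[d] <- NA
      next
    }
    cur <- (row - 1) * landscape$n_cols + col
    w <- 1 / eff[cur, d]
    if (!is.na(heading)) {
      turn <- abs(heading - d)
      turn <- min(turn, 8 - turn)
      w <- w * directional_weight(turn, dp)
    }
    out$w[d] <- w
  }
  out <- out[!is.na(out$w), , drop = FALSE]
  out$prob <- out$w / sum(out$w)
  out$w <- NULL
  rownames(out) <- NULL
  out
}

#' Density-dependent settlement probability
#'
#' Probability that a disperser entering a patch with N_f resident
#' females settles there, under negative density-dependent settlement:
#' \deqn{P_s = \frac{1}{1 + e^{-(b N_f - \beta_s)\alpha_s}}}
#' With slope alpha_s < 0 the probability decreases with female density
#' and equals 0.5 at the inflection b N_f = beta_s.
#'
#' @param n_f number of females in the candidate patch (vectorised).
#' @param b strength of density dependence.
#' @param beta_s inflection point (default 0.75).
#' @param alpha_s slope (default -10; negative = avoid crowded patches).
#' @return settlement probability.
#' @examples
#' settlement_prob_dd(7.5, b = 0.1)   # 0.5 at the inflection
#' @export
settlement_prob_dd <- function(n_f, b, beta_s = 0.75, alpha_s = -10) {
  if (any(n_f < 0)) stop("`n_f` must be non-negative")
  1 / (1 + exp(-(b * n_f - beta_s) * alpha_s))
}

#' Juvenile emigration decision
#'
#' Each age-0 individual emigrates from its natal patch with a fixed
#' probability (0.5 in all the shipped experiment designs); adults never
#' disperse.
#'
#' @param age ages of the candidates (all must be 0).
#' @param prob emigration probability.
#' @return logical vector: `TRUE` = disperse.
#' @export
emigrate <- function(age, prob = 0.5) {
  if (any(age != 0)) stop("only juveniles (age 0) can emigrate")
  if (prob < 0 || prob > 1) stop("`prob` must be a probability")
  stats::runif(length(age)) < prob
}

#' Run one cohort of dispersers through the landscape
#'
#' Standalone harness around the synchronous dispersal scheduler: all
#' dispersers advance one SMS step per global tick (randomised order
#' within a tick), settlement is checked on every entry into a non-natal
#' habitat cell against up-to-the-moment occupancy, and under mate-search
#' rules a patch holding unsettled dispersers of both sexes at the end of
#' a tick settles them together (simultaneous arrival). The loop runs
#' until every disperser has settled or died in transit.
#'
#' @param landscape a `grid_landscape`.
#' @param dispersers data.frame with columns `row`, `col` (natal cell,
#'   1-based) and `sex` (`"F"`/`"M"`).
#' @param residents optional data.frame of resident individuals with
#'   columns `row`, `col`, `sex`; these provide the occupancy dispersers
#'   see (mate presence, settlement density).
#' @param config a [sim_config] (movement + settlement parameters are
#'   taken from it).
#' @return data.frame per disperser: `sex`, `natal_row`, `fate`
#'   (`"settled"`/`"died_transit"`), `settle_row`, `settle_col`, `steps`,
#'   `rows_displaced`.
#' @export
disperse_cohort <- function(landscape, dispersers, residents = NULL, config) {
  stopifnot(inherits(landscape, "grid_landscape"), inherits(config, "sim_config"))
  hab <- as.integer(t(landscape$habitat))
  ncells <- landscape$n_cols * landscape$n_rows
  cell0 <- function(row, col) (row - 1L) * landscape$n_cols + (col - 1L)
  res_f <- integer(ncells); res_m <- integer(ncells)
  if (!is.null(residents) && nrow(residents)) {
    rc <- cell0(residents$row, residents$col) + 1L
    for (i in seq_along(rc)) {
      if (residents$sex[i] == "F") res_f[rc[i]] <- res_f[rc[i]] + 1L
      else res_m[rc[i]] <- res_m[rc[i]] + 1L
    }
  }
  natal <- cell0(dispersers$row, dispersers$col)
  out <- disperse_cohort_cpp(hab, landscape$n_cols, landscape$n_rows,
                             engine_par(config),
                             as.integer(natal), # start in natal cell
                             as.integer(dispersers$sex == "M"),
                             as.integer(natal), res_f, res_m)
  settled <- out$status == 1L
  srow <- ifelse(settled, out$cell %/% landscape$n_cols + 1L, NA_integer_)
  scol <- ifelse(settled, out$cell %% landscape$n_cols + 1L, NA_integer_)
  data.frame(sex = dispersers$sex,
             natal_row = dispersers$row,
             fate = ifelse(settled, "settled", "died_transit"),
             settle_row = srow, settle_col = scol,
             steps = out$steps,
             rows_displaced = ifelse(settled, abs(srow - dispersers$row), NA_integer_))
}
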