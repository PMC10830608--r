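test_that("directional persistence weights penalise turns geometrically", {
  expect_equal(directional_weight(0, 3), 1)
  expect_equal(directional_weight(2, 3), 1 / 9)
  expect_equal(directional_weight(4, 3), 1 / 81)
  expect_equal(directional_weight(0, 7.5), 1)
  expect_error(directional_weight(5, 3), "0..4")
  expect_error(directional_weight(1, 0.5), ">= 1")
})

test_that("effective costs reduce to the plain cost on homogeneous ground", {
  # interior cells: every heading's view is on-grid and homogeneous
  interior <- as.vector(outer(6:6, 6:6, function(r, c) (r - 1) * 11 + c))
  for (agg in c("line", "sector")) {
    Lm <- matrix_landscape()
    eff <- sms_effective_costs(Lm, pr = 5, aggregation = agg)
    expect_true(all(eff[interior, ] == 10))
    Lh <- all_habitat_landscape()
    eff <- sms_effective_costs(Lh, pr = 5, aggregation = agg)
    expect_true(all(eff[interior, ] == 1))
    expect_true(all(eff >= 1 & eff <= 10))
  }
})

test_that("line aggregation matches a hand-computed cost strip", {
  # 1 x 12 strip, habitat at rows 1 and 6; heading 5 ("S") points down-strip
  fx <- make_fixture("strip_costs")
  eff <- sms_effective_costs(fx$landscape, pr = 5, aggregation = "line")
  # standing at row 1, looking down-strip: cells 2..6 cost (10,10,10,10,1)
  expect_equal(eff[1, 5], mean(c(10, 10, 10, 10, 1)))
  # standing at row 5: cells 6..10 cost (1,10,10,10,10) -> 8.2
  expect_equal(eff[5, 5], 8.2)
  # standing at row 7: cells 8..12 all matrix
  expect_equal(eff[7, 5], 10)
  # truncation at the border: from row 10 only cells 11, 12 exist
  expect_equal(eff[10, 5], 10)
  # looking back up-strip (heading 1, "N") from row 7: cells 6..2
  expect_equal(eff[7, 1], 8.2)
  # independent R oracle for an interior line with mixed costs
  costs <- ifelse(fx$landscape$habitat[, 1], 1, 10)
  expect_equal(eff[2, 5], mean(costs[3:7]))
})

test_that("step probabilities are symmetric, normalised and DP-ratioed", {
  L <- matrix_landscape(11, 11)
  eff <- sms_effective_costs(L, pr = 5)
  # no previous heading, interior cell: all 8 neighbours equiprobable
  p <- step_probs(eff, L, 6, 6, heading = NA)
  expect_equal(nrow(p), 8)
  expect_equal(sum(p$prob), 1)
  expect_true(all(abs(p$prob - 1 / 8) < 1e-12))
  # corner cell: uniform over the 3 on-grid neighbours
  p <- step_probs(eff, L, 1, 1, heading = NA)
  expect_equal(nrow(p), 3)
  expect_true(all(abs(p$prob - 1 / 3) < 1e-12))
  # previous heading north: P(straight)/P(90) = DP^2, /P(180) = DP^4
  p <- step_probs(eff, L, 6, 6, heading = 1, dp = 3)
  expect_equal(p$prob[p$heading == 1] / p$prob[p$heading == 3], 9)
  expect_equal(p$prob[p$heading == 1] / p$prob[p$heading == 5], 81)
  expect_equal(sum(p$prob), 1)
})

test_that("density-dependent settlement has its logistic closed form", {
  expect_equal(settlement_prob_dd(7.5, b = 0.1), 0.5)  # inflection b N = beta_s
  expect_equal(settlement_prob_dd(0, b = 0.1), 1 / (1 + exp(-7.5)))
  expect_equal(settlement_prob_dd(15, b = 0.1), 1 / (1 + exp(7.5)))
  nf <- seq(0, 30, by = 0.5)
  expect_true(all(diff(settlement_prob_dd(nf, b = 0.1)) < 0))
  expect_error(settlement_prob_dd(-2, 0.1), "non-negative")
})

test_that("emigration is a Bernoulli filter on juveniles only", {
  expect_true(all(!emigrate(rep(0, 50), prob = 0)))
  expect_true(all(emigrate(rep(0, 50), prob = 1)))
  set.seed(2)
  n <- sum(emigrate(rep(0, 1e4), prob = 0.5))
  expect_lt(abs(n - 5000), 3 * sqrt(1e4 * 0.25))
  expect_error(emigrate(c(0, 1), 0.5), "juveniles")
})

test_that("transit survival without settlement is geometric in steps", {
  # all-matrix world: nobody can ever settle; death is by step mortality
  L <- matrix_landscape(41, 41)
  cfg <- std_config(n_cols = 41, n_rows = 41, core_rows = 20,
                    step_mortality = 0.02)
  d <- data.frame(row = rep(21L, 4000), col = rep(21L, 4000),
                  sex = rep(c("F", "M"), 2000))
  set.seed(31)
  out <- disperse_cohort(L, d, config = cfg)
  expect_true(all(out$fate == "died_transit"))
  # steps-to-death ~ Geometric(0.02) counting the killing step:
  # mortality precedes each move, so steps taken = failures before death
  ks <- suppressWarnings(stats::ks.test(out$steps + 1, function(q)
    stats::pgeom(q - 1, 0.02)))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(out$steps + 1) - 1 / 0.02), 3 * sqrt(0.98 / 0.02^2 / 4000))
})

test_that("settlement rules gate who may stop where", {
  fx <- make_fixture("two_patch_pair")
  L <- fx$landscape
  cfg <- std_config(n_cols = 5, n_rows = 20, core_rows = 10)
  # habitat-only: a female settles in the empty far patch
  set.seed(5)
  out <- disperse_cohort(L, data.frame(row = 3L, col = 3L, sex = "F"),
                         config = cfg)
  if (out$fate == "settled") expect_equal(out$settle_row, 8L)

  # mate-search: male disperser may join the patch holding a female
  cfg_ms <- std_config(n_cols = 5, n_rows = 20, core_rows = 10,
                       settlement = "mate_search")
  set.seed(6)
  res <- fx$occupants[fx$occupants$sex == "F", ]
  out <- replicate(60, {
    o <- disperse_cohort(L, data.frame(row = 8L, col = 3L, sex = "M"),
                         residents = res, config = cfg_ms)
    if (o$fate == "settled") o$settle_row else NA_integer_
  })
  expect_true(all(out == 3L, na.rm = TRUE))  # only the female's patch accepts
  expect_true(any(!is.na(out)))

  # mate-search: a lone female can never settle anywhere (empty world)
  set.seed(7)
  o <- disperse_cohort(L, data.frame(row = 3L, col = 3L, sex = "F"),
                       config = cfg_ms)
  expect_equal(o$fate, "died_transit")

  # simultaneous arrival: opposite-sex dispersers can found an empty patch
  set.seed(8)
  d2 <- data.frame(row = c(3L, 3L), col = c(3L, 3L), sex = c("F", "M"))
  outs <- replicate(120, {
    o <- disperse_cohort(L, d2, config = cfg_ms)
    sum(o$fate == "settled")
  })
  expect_gt(sum(outs), 0)  # some pairs do co-settle
  # and whenever anyone settled, both did, in the same patch
  set.seed(8)
  for (i in 1:120) {
    o <- disperse_cohort(L, d2, config = cfg_ms)
    if (any(o$fate == "settled")) {
      expect_equal(o$fate, c("settled", "settled"))
      expect_equal(o$settle_row[1], o$settle_row[2])
    }
  }
})

test_that("no disperser settles in its natal patch; settlers sit on habitat", {
  L <- generate_landscape(20, 120, 0.07, seed = 77)
  cfg <- std_config(n_cols = 20, n_rows = 120, core_rows = 60)
  hab_cells <- which(L$habitat)
  rows <- ((hab_cells - 1) %% L$n_rows) + 1
  cols <- ((hab_cells - 1) %/% L$n_rows) + 1
  pick <- sample(seq_along(hab_cells), 500, replace = TRUE)
  d <- data.frame(row = rows[pick], col = cols[pick],
                  sex = sample(c("F", "M"), 500, TRUE))
  set.seed(9)
  out <- disperse_cohort(L, d, config = cfg)
  s <- out[out$fate == "settled", ]
  expect_gt(nrow(s), 0)
  expect_true(all(L$habitat[cbind(s$settle_row, s$settle_col)]))
  natal_col <- d$col[out$fate == "settled"]
  expect_true(all(s$settle_row != s$natal_row | s$settle_col != natal_col))
})

test_that("dispersal kernels under density dependence dominate habitat-only", {
  L <- generate_landscape(20, 400, 0.07, seed = 13)
  hab_cells <- which(L$habitat)
  rows <- ((hab_cells - 1) %% L$n_rows) + 1
  cols <- ((hab_cells - 1) %/% L$n_rows) + 1
  core <- rows <= 200
  set.seed(14)
  pick <- sample(which(core), 3000, replace = TRUE)
  d <- data.frame(row = rows[pick], col = cols[pick],
                  sex = sample(c("F", "M"), 3000, TRUE))
  # residents: 12 females on every core habitat patch (quasi-equilibrium-like)
  res <- data.frame(row = rep(rows[core], 12), col = rep(cols[core], 12),
                    sex = "F")
  cfg_ho <- std_config(n_cols = 20, n_rows = 400, core_rows = 200)
  cfg_dd <- std_config(n_cols = 20, n_rows = 400, core_rows = 200,
                       settlement = "density_dependent")
  set.seed(15)
  ho <- disperse_cohort(L, d, residents = res, config = cfg_ho)
  set.seed(16)
  dd <- disperse_cohort(L, d, residents = res, config = cfg_dd)
  ho_d <- ho$rows_displaced[ho$fate == "settled"]
  dd_d <- dd$rows_displaced[dd$fate == "settled"]
  expect_gt(mean(dd_d), mean(ho_d))
  expect_gt(quantile(dd_d, 0.75), quantile(ho_d, 0.75))
})
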