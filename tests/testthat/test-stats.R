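# brute-force LMG: average R^2 increments over all orderings of term groups
lmg_by_orderings <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(mf), "term.labels")
  p <- length(labels)
  tss <- sum((y - mean(y))^2)
  r2 <- function(members) {
    cols <- assign == 0L | assign %in% members
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    1 - sum(fit$residuals^2) / tss
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  shares <- numeric(p)
  all_p <- perms(seq_len(p))
  for (ord in all_p) {
    prev <- 0
    for (k in seq_along(ord)) {
      cur <- r2(ord[1:k])
      shares[ord[k]] <- shares[ord[k]] + (cur - prev)
      prev <- cur
    }
  }
  stats::setNames(shares / length(all_p), labels)
}

test_that("LMG shares equal the ordering-enumeration oracle", {
  set.seed(5)
  n <- 120
  d <- data.frame(a = rnorm(n), b = rnorm(n), g = factor(sample(1:3, n, TRUE)))
  d$y <- 0.8 * d$a + 0.5 * d$b + as.numeric(d$g) + rnorm(n)
  # 3 groups, continuous + categorical
  fit <- lmg_importance(y ~ a + b + g, d)
  oracle <- lmg_by_orderings(y ~ a + b + g, d)
  expect_equal(fit$shares, oracle, tolerance = 1e-10)
  expect_equal(sum(fit$shares), fit$r_squared, tolerance = 1e-10)
  expect_true(all(fit$shares >= 0))
  # 4 groups with an interaction block
  d$h <- factor(sample(c("u", "v"), n, TRUE))
  d$y2 <- d$a + (d$g == "2") * (d$h == "v") * 2 + rnorm(n)
  fit4 <- lmg_importance(y2 ~ a + g + h + g:h, d)
  oracle4 <- lmg_by_orderings(y2 ~ a + g + h + g:h, d)
  expect_equal(fit4$shares, oracle4, tolerance = 1e-10)
})

test_that("orthogonal regressors get their marginal R-squared as share", {
  # balanced 2x2 design: factors are exactly orthogonal
  d <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), rep = 1:25)
  set.seed(9)
  d$y <- 1.5 * d$x1 + 0.5 * d$x2 + rnorm(100)
  fit <- lmg_importance(y ~ x1 + x2, d)
  r2_marg <- function(v) summary(stats::lm(d$y ~ v))$r.squared
  expect_equal(unname(fit$shares["x1"]), r2_marg(d$x1), tolerance = 1e-10)
  expect_equal(unname(fit$shares["x2"]), r2_marg(d$x2), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the term named", {
  d <- data.frame(x = rnorm(20))
  d$z <- d$x  # aliased
  d$y <- d$x + rnorm(20)
  expect_error(lmg_importance(y ~ x + z, d), "rank-deficient.*z")
})

test_that("factorial LMG fit reports Table-style output", {
  # synthetic factorial with known dominant factor
  des <- expand.grid(habitat_quality = c(8, 10, 12, 14), fecundity = c(3, 4),
                     mating_system = c("female_only", "polygynous",
                                       "monogamous"), replicate = 1:4)
  set.seed(11)
  des$final_occupancy <- 0.05 * des$habitat_quality +
    0.01 * des$fecundity + 0.02 * (des$mating_system == "female_only") +
    rnorm(nrow(des), sd = 0.02)
  fit <- fit_lm_with_lmg(des, "final_occupancy")
  expect_named(fit$shares, c("HQ", "F", "M", "HQ:F", "HQ:M", "F:M"))
  expect_equal(which.max(fit$pct), c(HQ = 1))
  expect_equal(sum(fit$shares), fit$r_squared, tolerance = 1e-12)
  expect_equal(fit$anova$Df, c(3, 1, 2, 3, 6, 2))
})

test_that("binomial GLM recovers known mating-failure coefficients", {
  set.seed(23)
  n <- 5000
  d <- data.frame(
    mating_system = factor(sample(c("monogamous", "polygynous"), n, TRUE)),
    pop_size = sample(1:30, n, TRUE),
    fecundity = 3)
  b0 <- 1.2; b_sys <- -1.5; b_size <- -0.15; b_int <- 0.08
  eta <- b0 + b_sys * (d$mating_system == "polygynous") +
    b_size * d$pop_size + b_int * d$pop_size * (d$mating_system == "polygynous")
  pr <- 1 / (1 + exp(-eta))
  d$n_adult_f <- pmax(1L, rpois(n, 4))
  d$n_adult_m <- pmax(0L, d$pop_size - d$n_adult_f)
  d$pop_size <- d$n_adult_f + d$n_adult_m
  eta <- b0 + b_sys * (d$mating_system == "polygynous") +
    b_size * d$pop_size + b_int * d$pop_size * (d$mating_system == "polygynous")
  pr <- 1 / (1 + exp(-eta))
  d$n_unmated_f <- rbinom(n, d$n_adult_f, pr)
  fit <- fit_unmated_glm(d)
  est <- fit$coefficients
  truth <- c("(Intercept)" = b0, "mating_systempolygynous" = b_sys,
             "pop_size" = b_size, "mating_systempolygynous:pop_size" = b_int)
  for (nm in names(truth)) {
    expect_lt(abs(est[nm, "Estimate"] - truth[nm]) / est[nm, "Std. Error"], 2.5)
  }
  # female-only rows are excluded by construction
  d2 <- rbind(d, within(d[1:50, ], mating_system <- "female_only"))
  fit2 <- fit_unmated_glm(d2)
  expect_equal(fit2$n_patches, n)
  # degenerate all-unmated input flags separation
  d3 <- d[1:200, ]
  d3$n_unmated_f <- d3$n_adult_f
  expect_warning(try(fit_unmated_glm(d3), silent = TRUE), "separation")
})

test_that("experiment-1 summary ratios and lags match hand arithmetic", {
  tab <- data.frame(
    mating_system = rep(c("female_only", "polygynous", "monogamous"), 2),
    habitat_quality = rep(c(10, 14), each = 3),
    fecundity = 3,
    extinct = FALSE,
    spread_rate = c(7, 3.5, 2.8, 7.4, 3.7, 3))
  s <- summarize_experiment1(tab, lmg = FALSE)
  sp <- s$spread[match(c("female_only", "polygynous", "monogamous"),
                       s$spread$mating_system), ]
  expect_equal(sp$mean_spread, c(7.2, 3.6, 2.9))
  expect_equal(sp$ratio_pct, c(100, 50, 2.9 / 7.2 * 100))
  expect_equal(sp$lag, c(0, 3.6, 4.3))
  # identical systems: ratios 100, lags 0
  tab$spread_rate <- 5
  s2 <- summarize_experiment1(tab, lmg = FALSE)
  expect_true(all(s2$spread$ratio_pct == 100))
  expect_true(all(s2$spread$lag == 0))
})
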