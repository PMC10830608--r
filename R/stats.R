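#' LMG relative importance of regressor groups
#'
#' Decomposes the R-squared of a linear model over groups of regressors
#' (here: each factor's dummy-column block and each interaction block is
#' one group). A group's LMG share is the increase in R-squared when the
#' group enters the model, averaged over all orders in which the groups
#' can enter. Computed by subset enumeration with the combinatorial
#' weights |S|! (p - |S| - 1)! / p!, equivalent to the full
#' average-over-orderings but needing 2^p fits instead of p! orderings.
#' Shares are non-negative for nested OLS fits and sum to the full-model
#' R-squared.
#'
#' @param formula model formula; every term (main effect or interaction)
#'   is one group.
#' @param data data.frame.
#' @return object of class `lmg_fit`: list with `shares` (named, on the
#'   R-squared scale), `pct` (shares x 100, the "variance explained"
#'   scale), `r_squared`, `anova` (per-term df and sums of squares from
#'   the sequential fit), and `n`.
#' @examples
#' d <- data.frame(x = rnorm(50), z = rnorm(50))
#' d$y <- d$x + rnorm(50)
#' lmg_importance(y ~ x + z, d)
#' @export
lmg_importance <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(mf), "term.labels")
  p <- length(labels)
  if (p > 12L) stop("subset enumeration over ", p, " groups is not sensible")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    offending <- unique(labels[assign[dropped]])
    stop("rank-deficient design; aliased term(s): ",
         paste(offending[!is.na(offending)], collapse = ", "))
  }
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  r2_subset <- function(members) {
    if (length(members) == 0L) return(0)
    cols <- assign == 0L | assign %in% members
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    1 - sum(fit$residuals^2) / tss
  }
  # R^2 of every subset of groups, indexed by bitmask
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1L)) {
    r2[mask + 1L] <- r2_subset(which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) > 0L))
  }
  lfac <- lfactorial(0:p)
  shares <- numeric(p)
  for (g in seq_len(p)) {
    gbit <- bitwShiftL(1L, g - 1L)
    others <- setdiff(seq_len(p), g)
    acc <- 0
    n_sub <- 2^(p - 1L)
    for (smask in 0:(n_sub - 1L)) {
      mask <- 0L
      sz <- 0L
      for (j in seq_along(others)) {
        if (bitwAnd(smask, bitwShiftL(1L, j - 1L)) > 0L) {
          mask <- bitwOr(mask, bitwShiftL(1L, others[j] - 1L))
          sz <- sz + 1L
        }
      }
      w <- exp(lfac[sz + 1L] + lfac[p - sz] - lfac[p + 1L])
      acc <- acc + w * (r2[bitwOr(mask, gbit) + 1L] - r2[mask + 1L])
    }
    shares[g] <- acc
  }
  names(shares) <- labels
  full <- stats::lm(formula, data)
  an <- stats::anova(full)
  structure(list(shares = shares, pct = 100 * shares,
                 r_squared = r2[2^p], n = n,
                 anova = an[seq_len(p), c("Df", "Sum Sq", "Mean Sq")]),
            class = "lmg_fit")
}

#' @export
print.lmg_fit <- function(x, ...) {
  cat(sprintf("<lmg_fit> n = %d, R-squared = %.3f\n", x$n, x$r_squared))
  tab <- data.frame(Df = x$anova$Df,
                    `Sum Sq` = round(x$anova$`Sum Sq`, 2),
                    `Variance explained (%)` = round(x$pct, 1),
                    check.names = FALSE, row.names = names(x$shares))
  print(tab)
  invisible(x)
}

#' Linear model with LMG decomposition for a factorial response
#'
#' Fits the factorial linear model of one experiment response on habitat
#' quality, fecundity and mating system (all coded categorical, matching
#' the discrete factor levels of the design) plus all two-way
#' interactions, and decomposes the variance explained by each term with
#' [lmg_importance]. For the spread-rate response, restrict the input to
#' scenarios where spread occurred for all mating systems (habitat
#' quality > 6 and fecundity > 2) before calling, to avoid singular fits.
#'
#' @param table experiment table from [run_experiment] (scenario x
#'   replicate rows).
#' @param response column name, e.g. `"final_occupancy"` or
#'   `"spread_rate"` (rows with a missing response are dropped).
#' @return an `lmg_fit`.
#' @export
fit_lm_with_lmg <- function(table, response = "final_occupancy") {
  d <- data.frame(y = table[[response]],
                  HQ = factor(table$habitat_quality),
                  F_ = factor(table$fecundity),
                  M = factor(table$mating_system))
  d <- d[!is.na(d$y), , drop = FALSE]
  fit <- lmg_importance(y ~ HQ + F_ + M + HQ:F_ + HQ:M + F_:M, d)
  names(fit$shares) <- names(fit$pct) <-
    c("HQ", "F", "M", "HQ:F", "HQ:M", "F:M")
  rownames(fit$anova) <- names(fit$shares)
  fit
}

#' Binomial GLM of female mating failure
#'
#' Fits patch-level proportions of unmated females (successes = unmated,
#' trials = reproductive-age females) on the interaction between mating
#' system and patch-level population size (adults in the patch at mating,
#' continuous), controlling for fecundity as a categorical main effect.
#' Logit link, fitted by iteratively reweighted least squares via
#' [stats::glm]. Female-only runs are excluded by design (no female
#' remains unmated there). Complete separation is flagged with a warning
#' and the coefficients are still returned.
#'
#' @param patch_table pooled per-patch mating records with columns
#'   `n_adult_f`, `n_adult_m`, `n_unmated_f`, `mating_system`, and
#'   `fecundity`; rows with no adult females are dropped.
#' @return object of class `unmated_glm`: the `glm` fit plus the data
#'   dimensions.
#' @export
fit_unmated_glm <- function(patch_table) {
  d <- patch_table[patch_table$n_adult_f >= 1 &
                     patch_table$mating_system != "female_only", , drop = FALSE]
  if (nrow(d) == 0L) stop("no two-sex patches with females to fit")
  d$pop_size <- d$n_adult_f + d$n_adult_m
  d$mating_system <- factor(d$mating_system)
  d$fecundity <- factor(d$fecundity)
  has_fec <- nlevels(d$fecundity) > 1L
  form <- if (has_fec)
    cbind(n_unmated_f, n_adult_f - n_unmated_f) ~ mating_system * pop_size + fecundity
  else
    cbind(n_unmated_f, n_adult_f - n_unmated_f) ~ mating_system * pop_size
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = d))
  if (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8) ||
      !fit$converged)
    warning("possible complete separation in the mating-failure GLM",
            call. = FALSE)
  structure(list(fit = fit, n_patches = nrow(d),
                 coefficients = stats::coef(summary(fit))),
            class = "unmated_glm")
}

#' @export
print.unmated_glm <- function(x, ...) {
  cat(sprintf("<unmated_glm> binomial logit fit over %d patch-years\n",
              x$n_patches))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Headline summary of the mating-system factorial
#'
#' From an experiment table (optionally restricted to the spread
#' inclusion rule habitat quality > 6, fecundity > 2), computes the
#' per-mating-system mean spread rates over runs that maintained
#' quasi-equilibrium, their ratios to the female-only (not mate-limited)
#' mean, the absolute lags in rows/generation, extinction proportions
#' over the unrestricted table, and the LMG decompositions for occupancy
#' and spread.
#'
#' @param table experiment table from [run_experiment].
#' @param spread_filter apply the inclusion rule `habitat_quality > 6 &
#'   fecundity > 2` to the spread analyses (default TRUE)?
#' @param lmg also fit the LMG decompositions (needs >= 2 levels per
#'   factor after filtering)?
#' @return list: `spread` (per-system mean rate, ratio_pct, lag),
#'   `extinction` (from [extinction_stats]), and optionally
#'   `lmg_occupancy`, `lmg_spread`.
#' @export
summarize_experiment1 <- function(table, spread_filter = TRUE, lmg = TRUE) {
  sub <- if (spread_filter)
    table[table$habitat_quality > 6 & table$fecundity > 2, , drop = FALSE]
  else table
  means <- tapply(sub$spread_rate, sub$mating_system,
                  function(x) mean(x, na.rm = TRUE))
  fo <- means[["female_only"]]
  spread <- data.frame(mating_system = names(means),
                       mean_spread = as.numeric(means),
                       ratio_pct = 100 * as.numeric(means) / fo,
                       lag = fo - as.numeric(means))
  out <- list(spread = spread, extinction = extinction_stats(table))
  if (lmg) {
    out$lmg_occupancy <- fit_lm_with_lmg(table, "final_occupancy")
    out$lmg_spread <- fit_lm_with_lmg(sub, "spread_rate")
  }
  out
}
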