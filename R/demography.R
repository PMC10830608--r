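#' Expected number of matings in a patch (harmonic-mean mating function)
#'
#' The expected number of mated females c among f potentially
#' reproductive females and m males when each male can fertilise at most
#' h females ("harem size"):
#' \deqn{c = \min(1, 2hm / (f + hm)) \, f}
#' h = 1 gives obligate monogamy, large h polygyny. c is bounded by
#' 0 <= c <= f and c <= 2hm, and is non-decreasing in m and h.
#'
#' @param f,m non-negative counts of reproductive females and males
#'   (vectorised).
#' @param h harem size, >= 1.
#' @return expected matings c.
#' @examples
#' expected_matings(4, 2, 1)    # 8/3
#' expected_matings(10, 1, 100) # 10: one polygynous male serves all
#' @export
expected_matings <- function(f, m, h = 1) {
  if (any(f < 0) || any(m < 0)) stop("`f` and `m` must be non-negative")
  if (any(h < 1)) stop("harem size `h` must be >= 1")
  hm <- h * m
  c_ <- ifelse(f + hm == 0, 0, pmin(1, 2 * hm / (f + hm)) * f)
  c_
}

#' Per-female probability of reproducing
#'
#' Given the expected number of matings c among f females, each female
#' independently reproduces with probability Pr = c / f.
#'
#' @param c expected matings (from [expected_matings]).
#' @param f number of reproductive females, >= 1.
#' @return probability in [0, 1].
#' @export
female_reproduction_prob <- function(c, f) {
  if (any(f < 1)) stop("`f` must be >= 1 (no females, no probability)")
  if (any(c < 0) || any(c > f + 1e-9)) stop("`c` must lie in [0, f]")
  pmin(1, c / f)
}

#' Assign this year's reproduction among a patch's adults
#'
#' Applies the mating system: in female-only mode every adult female
#' reproduces (males are not modelled and never limiting); in two-sex
#' mode each adult female reproduces independently with probability
#' Pr = c/f from the harmonic-mean mating function, and the remainder
#' are recorded as unmated.
#'
#' @param f,m adult female and male counts in the patch.
#' @param mode `"female_only"` or `"two_sex"`.
#' @param h harem size (two-sex mode).
#' @return list with `reproducing` and `unmated` counts.
#' @export
assign_reproduction <- function(f, m, mode = c("two_sex", "female_only"), h = 1) {
  mode <- match.arg(mode)
  stopifnot(length(f) == 1L, length(m) == 1L, f >= 0, m >= 0)
  if (f == 0) return(list(reproducing = 0L, unmated = 0L))
  if (mode == "female_only")
    return(list(reproducing = as.integer(f), unmated = 0L))
  pr <- female_reproduction_prob(expected_matings(f, m, h), f)
  rep_n <- stats::rbinom(1L, as.integer(f), pr)
  list(reproducing = rep_n, unmated = as.integer(f) - rep_n)
}

#' Offspring of one reproducing female
#'
#' Litter size is Poisson with mean equal to the effective fecundity:
#' the female-only fecundity phi, or 2*phi in two-sex mode when fecundity
#' doubling is on (each offspring is then female with probability
#' `sex_ratio_f`, so the expected number of daughters matches the
#' female-only model). Offspring are age-0 juveniles in the natal patch.
#'
#' @param phi mean offspring per female (female-only scale).
#' @param two_sex two-sex mode?
#' @param fecundity_doubling double phi in two-sex mode (default TRUE)?
#' @param sex_ratio_f probability an offspring is female in two-sex mode.
#' @return character vector of offspring sexes (`"F"`/`"M"`), possibly
#'   length zero.
#' @export
produce_offspring <- function(phi, two_sex = FALSE, fecundity_doubling = TRUE,
                              sex_ratio_f = 0.5) {
  stopifnot(phi >= 0)
  phi_eff <- if (two_sex && fecundity_doubling) 2 * phi else phi
  n <- stats::rpois(1L, phi_eff)
  if (!two_sex) return(rep("F", n))
  ifelse(stats::runif(n) < sex_ratio_f, "F", "M")
}

#' Density-dependent survival probability
#'
#' Stage-specific survival declines exponentially with the number of
#' females in the patch:
#' \deqn{\sigma = \sigma_0 e^{-b N_f}}
#' Only females contribute to density, so female-only and two-sex models
#' are directly comparable; 1/b (females/patch) is the habitat quality
#' of a patch. At N_f = 0 survival equals the low-density maximum
#' sigma_0 (0.3 for adults by default).
#'
#' @param n_f number of females in the patch (vectorised).
#' @param sigma0 maximum survival at low density for the stage.
#' @param b strength of density dependence (> 0; habitat quality = 1/b).
#' @return survival probability.
#' @examples
#' survival_prob(10, 0.3, b = 1/10)  # 0.3 * exp(-1)
#' @export
survival_prob <- function(n_f, sigma0 = 0.3, b) {
  if (any(n_f < 0)) stop("`n_f` must be non-negative")
  if (sigma0 < 0 || sigma0 > 1) stop("`sigma0` must be a probability")
  if (b < 0) stop("`b` must be non-negative")
  sigma0 * exp(-b * n_f)
}

#' Apply survival and aging to a patch's occupants
#'
#' Reference (single-patch) implementation of the end-of-year step:
#' every individual survives independently with the stage-specific
#' density-dependent probability, survivors age by one year, and
#' individuals that would exceed the maximum age (3 years) are removed.
#' Density N_f counts all females present after dispersal (juvenile
#' settlers included) unless `females = "adults"`.
#'
#' @param occupants data.frame with columns `sex` (`"F"`/`"M"`) and
#'   `age` (integer years, 0 = juvenile).
#' @param b strength of density dependence.
#' @param sigma0_juv,sigma0_adult stage maxima.
#' @param max_age maximum age in years.
#' @param females `"all"` or `"adults"`: which females count toward N_f.
#' @return the surviving occupants, aged.
#' @export
apply_survival_and_aging <- function(occupants, b, sigma0_juv = 1,
                                     sigma0_adult = 0.3, max_age = 3L,
                                     females = c("all", "adults")) {
  females <- match.arg(females)
  stopifnot(is.data.frame(occupants), all(c("sex", "age") %in% names(occupants)))
  if (nrow(occupants) == 0L) return(occupants)
  n_f <- if (females == "all") sum(occupants$sex == "F")
         else sum(occupants$sex == "F" & occupants$age >= 1)
  s0 <- ifelse(occupants$age == 0, sigma0_juv, sigma0_adult)
  keep <- stats::runif(nrow(occupants)) < s0 * exp(-b * n_f)
  out <- occupants[keep, , drop = FALSE]
  out$age <- out$age + 1L
  out <- out[out$age <= max_age, , drop = FALSE]
  rownames(out) <- NULL
  out
}
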