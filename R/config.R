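settlement_rules <- function() {
  c(habitat_only = 0L, mate_search = 1L, density_dependent = 2L,
    mate_search_dd = 3L)
}

#' Build a full simulation configuration
#'
#' Collects every parameter of one scenario. Defaults are the constants
#' held fixed across all shipped experiments (adult survival 0.3,
#' emigration 0.5, perceptual range 5 cells, directional persistence 3.0,
#' per-step mortality 0.005, movement costs 1 habitat / 10 matrix,
#' settlement parameters beta_s = 0.75, alpha_s = -10). `habitat_quality`
#' (1/b, in females/patch) has no default and must always be supplied.
#'
#' @param habitat_quality habitat quality 1/b in females per patch (> 0);
#'   b = 1/habitat_quality is the strength of density dependence.
#' @param fecundity mean offspring per female phi, on the female-only
#'   scale (doubled internally in two-sex mode when
#'   `fecundity_doubling = TRUE`).
#' @param mating `"female_only"` or `"two_sex"`.
#' @param harem harem size h: 1 = obligate monogamy, 100 = polygyny.
#' @param settlement one of `"habitat_only"`, `"mate_search"`,
#'   `"density_dependent"`, `"mate_search_dd"`. Mate-search rules require
#'   two-sex mode.
#' @param n_cols,n_rows,habitat_fraction,cell_size landscape geometry.
#' @param core_rows rows forming the initially populated core.
#' @param init_fraction,lambda_init founder sampling (see
#'   [sample_initial_population]).
#' @param sigma0_adult,sigma0_juv stage maxima of density-dependent
#'   survival.
#' @param fecundity_doubling,sex_ratio_f two-sex fecundity convention.
#' @param emigration_prob,perceptual_range,directional_persistence,
#'   step_mortality,cost_habitat,cost_matrix movement parameters.
#' @param cost_aggregation how per-cell costs within perceptual range are
#'   aggregated into the effective cost of a heading: `"sector"` (45-degree
#'   wedge, the stochastic movement simulator's convention; default) or
#'   `"line"` (straight line of cells).
#' @param beta_s,alpha_s density-dependent settlement parameters.
#' @param years simulated years per run.
#' @param max_age maximum age in years.
#' @param survival_females `"all"` (juvenile settlers count toward the
#'   density in the survival step) or `"adults"`.
#' @param breeding_includes_juveniles count juveniles when deciding
#'   whether a patch can produce offspring next year?
#' @param max_ticks dispersal-scheduler safety valve.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(habitat_quality,
                       fecundity = 3,
                       mating = c("two_sex", "female_only"),
                       harem = 100,
                       settlement = c("habitat_only", "mate_search",
                                      "density_dependent", "mate_search_dd"),
                       n_cols = 20L, n_rows = 1000L, habitat_fraction = 0.07,
                       cell_size = 100, core_rows = 500L,
                       init_fraction = 0.5, lambda_init = 2,
                       sigma0_adult = 0.3, sigma0_juv = 1,
                       fecundity_doubling = TRUE, sex_ratio_f = 0.5,
                       emigration_prob = 0.5, perceptual_range = 5L,
                       directional_persistence = 3, step_mortality = 0.005,
                       cost_habitat = 1, cost_matrix = 10,
                       cost_aggregation = c("sector", "line"),
                       beta_s = 0.75, alpha_s = -10,
                       years = 50L, max_age = 3L,
                       survival_females = c("all", "adults"),
                       breeding_includes_juveniles = TRUE,
                       max_ticks = 1e6) {
  mating <- match.arg(mating)
  settlement <- match.arg(settlement)
  survival_females <- match.arg(survival_females)
  cost_aggregation <- match.arg(cost_aggregation)
  cfg <- structure(mget(setdiff(names(formals(sim_config)), "...")),
                   class = "sim_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$habitat_quality) && cfg$habitat_quality > 0,
      "`habitat_quality` (1/b) must be supplied and positive")
  chk(cfg$fecundity >= 0, "`fecundity` must be non-negative")
  chk(cfg$harem >= 1, "`harem` must be >= 1")
  for (p in c("habitat_fraction", "init_fraction", "sigma0_adult", "sigma0_juv",
              "emigration_prob", "step_mortality", "sex_ratio_f")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1,
        sprintf("`%s` must be a probability in [0, 1]", p))
  }
  chk(cfg$habitat_fraction > 0 && cfg$habitat_fraction < 1,
      "`habitat_fraction` must lie strictly between 0 and 1")
  chk(cfg$step_mortality < 1, "`step_mortality` must be < 1")
  chk(cfg$perceptual_range >= 1, "`perceptual_range` must be >= 1")
  chk(cfg$directional_persistence >= 1, "`directional_persistence` must be >= 1")
  chk(cfg$cost_habitat >= 1 && cfg$cost_matrix >= 1, "movement costs must be >= 1")
  chk(cfg$lambda_init > 0, "`lambda_init` must be positive")
  chk(cfg$core_rows >= 1 && cfg$core_rows <= cfg$n_rows,
      "`core_rows` must lie within the landscape rows")
  chk(cfg$years >= 1, "`years` must be >= 1")
  chk(cfg$max_age >= 1, "`max_age` must be >= 1")
  if (cfg$mating == "female_only" &&
      cfg$settlement %in% c("mate_search", "mate_search_dd"))
    stop("mate-search settlement requires a two-sex model", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %s%s, 1/b = %g females/patch, phi = %g, settlement = %s\n",
    "  landscape %d x %d (%.0f%% habitat), core %d rows, %d years\n"),
    x$mating,
    if (x$mating == "two_sex") sprintf(" (h = %g)", x$harem) else "",
    x$habitat_quality, x$fecundity, x$settlement,
    x$n_cols, x$n_rows, 100 * x$habitat_fraction, x$core_rows, x$years))
  invisible(x)
}

# parameter list handed to the C++ engine
engine_par <- function(cfg) {
  two_sex <- cfg$mating == "two_sex"
  list(b = 1 / cfg$habitat_quality,
       phi_eff = if (two_sex && cfg$fecundity_doubling) 2 * cfg$fecundity
                 else cfg$fecundity,
       sex_ratio_f = if (two_sex) cfg$sex_ratio_f else 1,
       harem = cfg$harem,
       female_only = !two_sex,
       sigma0_juv = cfg$sigma0_juv,
       sigma0_adult = cfg$sigma0_adult,
       emigration_prob = cfg$emigration_prob,
       step_mortality = cfg$step_mortality,
       perceptual_range = as.integer(cfg$perceptual_range),
       directional_persistence = cfg$directional_persistence,
       cost_habitat = cfg$cost_habitat,
       cost_matrix = cfg$cost_matrix,
       cost_sector = as.integer(cfg$cost_aggregation == "sector"),
       settlement_code = unname(settlement_rules()[cfg$settlement]),
       beta_s = cfg$beta_s,
       alpha_s = cfg$alpha_s,
       max_age = as.integer(cfg$max_age),
       survival_all_females = cfg$survival_females == "all",
       breeding_includes_juveniles = cfg$breeding_includes_juveniles,
       max_ticks = cfg$max_ticks)
}

#' Read a simulation configuration from a plain-text file
#'
#' The native format is one `key = value` pair per line; `#` starts a
#' comment; keys are the argument names of [sim_config]. Any key absent
#' from the file takes its default; unknown keys are an error (no silent
#' typos). `habitat_quality` must be present.
#'
#' @param path file path.
#' @return a validated `sim_config`.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% setdiff(names(formals(sim_config)), ""))
      stop(sprintf("unknown config key: '%s'", key), call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (!is.na(num)) num
                   else if (val %in% c("TRUE", "FALSE")) as.logical(val)
                   else val
  }
  do.call(sim_config, args)
}

#' Write a simulation configuration to a plain-text file
#'
#' Writes every resolved parameter exactly once in `key = value` form;
#' [load_config] of the result reproduces the configuration.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  keys <- names(formals(sim_config))
  vals <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.character(v)) v else format(v, scientific = FALSE)
  }, character(1))
  writeLines(paste(keys, vals, sep = " = "), path)
  invisible(path)
}
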