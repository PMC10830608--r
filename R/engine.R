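#' Derive a reproducible substream seed
#'
#' Hashes a master seed with scenario and replicate indices (and a stream
#' tag) into an integer below 2^31, so that every stochastic stream of an
#' experiment is a deterministic function of the master seed. Plain
#' modular arithmetic on doubles; identical across platforms.
#'
#' @param master master integer seed.
#' @param scenario scenario index (0 reserved for the shared landscape
#'   stream).
#' @param replicate replicate index.
#' @param stream small integer tag separating streams within a run.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, scenario = 0L, replicate = 1L, stream = 0L) {
  m <- 2147483647
  x <- as.numeric(master) %% m
  for (k in c(scenario, replicate, stream)) {
    x <- (x * 48271 + as.numeric(k) * 16807 + 12345) %% m
  }
  as.integer(x)
}

#' Run one replicate simulation
#'
#' Executes the annual cycle for `config$years` years (or until
#' metapopulation extinction): (1) mating and reproduction in every
#' patch, (2) juvenile emigration, stepwise dispersal and settlement,
#' (3) density-dependent survival and aging in the end-of-dispersal
#' patch, then the yearly census. Deterministic given `(config, seed)`.
#'
#' @param config a [sim_config].
#' @param seed integer seed for this run (all demographic and movement
#'   randomness).
#' @param landscape optional pre-built `grid_landscape` (shared across
#'   scenarios for paired contrasts); generated from `landscape_seed`
#'   when `NULL`.
#' @param landscape_seed seed for landscape generation and founder
#'   sampling when `landscape` is not supplied (defaults to `seed`).
#' @param founders optional founder data.frame (from
#'   [sample_initial_population]); sampled when `NULL`.
#' @param record_patches,record_dispersal emit per-patch / per-disperser
#'   tables (memory-heavy on large runs; off by default).
#' @return list of class `sim_result`: `yearly` (year, n_individuals,
#'   edge_row with `NA` when no breeding patch exists, n_breeding_patches,
#'   core_occupancy, year 0 = initial state), `extinct`,
#'   `extinction_year`, optionally `patches` and `dispersal` (rows/cols
#'   1-based, `natal_row`/`settle_row`/`rows_displaced` in rows), plus the
#'   `landscape` and `config` used.
#' @export
run_simulation <- function(config, seed = 1L, landscape = NULL,
                           landscape_seed = NULL, founders = NULL,
                           record_patches = FALSE, record_dispersal = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  validate_config(config)
  if (is.null(landscape_seed)) landscape_seed <- seed
  if (is.null(landscape)) {
    landscape <- generate_landscape(config$n_cols, config$n_rows,
                                    config$habitat_fraction,
                                    seed = landscape_seed,
                                    cell_size = config$cell_size)
  }
  if (is.null(founders)) {
    founders <- sample_initial_population(
      landscape, core_rows = config$core_rows,
      init_fraction = config$init_fraction, lambda_init = config$lambda_init,
      two_sex = config$mating == "two_sex",
      seed = derive_seed(landscape_seed, 0L, 0L, 1L))
  }
  idx <- rep(seq_len(nrow(founders)), founders$count)
  cell0 <- (founders$row[idx] - 1L) * landscape$n_cols + (founders$col[idx] - 1L)
  set.seed(seed)
  raw <- sim_run_cpp(as.integer(t(landscape$habitat)),
                     landscape$n_cols, landscape$n_rows,
                     as.integer(cell0),
                     as.integer(founders$sex[idx] == "M"),
                     as.integer(founders$age[idx]),
                     engine_par(config), as.integer(config$years),
                     as.integer(config$core_rows),
                     record_patches, record_dispersal)
  yearly <- raw$yearly
  yearly$edge_row[yearly$edge_row < 0] <- NA_integer_
  yearly$edge_row <- yearly$edge_row + 1L   # 1-based rows
  out <- list(yearly = yearly, extinct = raw$extinct,
              extinction_year = raw$extinction_year,
              landscape = landscape, config = config, seed = seed)
  ncols <- landscape$n_cols
  if (record_patches) {
    p <- raw$patches
    p$row <- p$cell %/% ncols + 1L
    p$col <- p$cell %% ncols + 1L
    p$patch_id <- landscape$patch_id[cbind(p$row, p$col)]
    out$patches <- p
  }
  if (record_dispersal) {
    d <- raw$dispersal
    d$sex <- ifelse(d$sex == 1L, "M", "F")
    d$natal_row <- d$natal_cell %/% ncols + 1L
    d$fate <- ifelse(d$settled == 1L, "settled", "died_transit")
    d$settle_row <- ifelse(d$settled == 1L, d$settle_cell %/% ncols + 1L,
                           NA_integer_)
    d$rows_displaced <- abs(d$settle_row - d$natal_row)
    d$natal_cell <- d$settle_cell <- d$settled <- NULL
    out$dispersal <- d
  }
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  yr <- x$yearly
  last <- yr[nrow(yr), ]
  cat(sprintf(paste0(
    "<sim_result> %d years simulated; %s\n",
    "  final: %d individuals, %d breeding patches, edge row %s, core occupancy %.3f\n"),
    max(yr$year),
    if (x$extinct) sprintf("extinct in year %d", x$extinction_year)
    else "metapopulation persisted",
    last$n_individuals, last$n_breeding_patches,
    ifelse(is.na(last$edge_row), "-", as.character(last$edge_row)),
    last$core_occupancy))
  invisible(x)
}

#' Factorial experiment designs
#'
#' Builds the scenario table of the two shipped factorial experiments.
#' Experiment 1 crosses three mating systems (female-only; two-sex
#' polygynous h = 100; two-sex monogamous h = 1) with habitat quality
#' 1/b in {2, 4, 6, 8, 10, 12, 14} females/patch and fecundity in
#' {2, 3, 4} offspring/female, under habitat-only settlement. Experiment
#' 2 crosses the two two-sex mating systems with all four settlement
#' strategies and 1/b in {8, 10, 12, 14} at fecundity 3.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param habitat_quality,fecundity optional overrides of the factor
#'   levels (used for scaled-down runs).
#' @return data.frame with one row per scenario: `scenario` (id),
#'   `mating_system` (`"female_only"`, `"polygynous"`, `"monogamous"`),
#'   `mating`, `harem`, `settlement`, `habitat_quality`, `fecundity`.
#' @export
experiment_design <- function(design = c("exp1", "exp2"),
                              habitat_quality = NULL, fecundity = NULL) {
  design <- match.arg(design)
  systems <- data.frame(
    mating_system = c("female_only", "polygynous", "monogamous"),
    mating = c("female_only", "two_sex", "two_sex"),
    harem = c(1, 100, 1))
  if (design == "exp1") {
    hq <- if (is.null(habitat_quality)) c(2, 4, 6, 8, 10, 12, 14) else habitat_quality
    fec <- if (is.null(fecundity)) c(2, 3, 4) else fecundity
    grid <- expand.grid(i = 1:3, habitat_quality = hq, fecundity = fec,
                        settlement = "habitat_only", stringsAsFactors = FALSE)
  } else {
    hq <- if (is.null(habitat_quality)) c(8, 10, 12, 14) else habitat_quality
    fec <- if (is.null(fecundity)) 3 else fecundity
    grid <- expand.grid(i = 2:3, habitat_quality = hq, fecundity = fec,
                        settlement = c("habitat_only", "mate_search",
                                       "density_dependent", "mate_search_dd"),
                        stringsAsFactors = FALSE)
  }
  out <- cbind(systems[grid$i, ], grid[setdiff(names(grid), "i")])
  out <- out[order(out$settlement, out$habitat_quality, out$fecundity,
                   out$mating_system), ]
  rownames(out) <- NULL
  out$scenario <- seq_len(nrow(out))
  out[c("scenario", "mating_system", "mating", "harem", "settlement",
        "habitat_quality", "fecundity")]
}

#' Run a factorial simulation experiment
#'
#' Runs every scenario x replicate cell of a design and collects the
#' per-run responses: extinction flag and year, core occupancy in the
#' final year, quasi-equilibrium flag, and overall spread rate (mean
#' 5-year edge advance / 5; `NA` for runs that went extinct or failed
#' quasi-equilibrium, which the spread analyses exclude). One landscape
#' realization is drawn per replicate and shared across scenarios, so
#' scenario contrasts are paired.
#'
#' When `out_dir` is given, each completed scenario x replicate row is
#' saved as a small CSV and re-runs resume from what is on disk.
#'
#' @param design scenario table from [experiment_design].
#' @param replicates replicates per scenario.
#' @param years simulated years per run.
#' @param master_seed master seed; all landscape and run seeds derive
#'   from it via [derive_seed].
#' @param spread_horizon years of the edge series used for the spread
#'   rate (default all); quasi-equilibrium is always assessed from year
#'   20 to the end of the series.
#' @param config_args named list of [sim_config] overrides applied to
#'   every scenario (e.g. a smaller landscape for scaled runs).
#' @param out_dir optional checkpoint directory.
#' @param verbose print one line per run.
#' @return data.frame: design columns plus `replicate`, `extinct`,
#'   `extinction_year`, `final_occupancy`, `quasi_equilibrium`,
#'   `spread_rate`.
#' @export
run_experiment <- function(design, replicates = 5L, years = 50L,
                           master_seed = 1L, spread_horizon = NULL,
                           config_args = list(), out_dir = NULL,
                           verbose = FALSE) {
  if (nrow(design) == 0L) return(cbind(design[0, ], replicate = integer(),
                                       extinct = logical(),
                                       extinction_year = integer(),
                                       final_occupancy = numeric(),
                                       quasi_equilibrium = logical(),
                                       spread_rate = numeric()))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", nrow(design) * replicates)
  k <- 0L
  for (rep_i in seq_len(replicates)) {
    land_seed <- derive_seed(master_seed, 0L, rep_i, 0L)
    landscape <- NULL
    for (s in seq_len(nrow(design))) {
      k <- k + 1L
      sc <- design[s, ]
      ckpt <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("run_s%03d_r%02d.csv", sc$scenario, rep_i))
      if (!is.null(out_dir) && file.exists(ckpt)) {
        prev <- try(utils::read.csv(ckpt), silent = TRUE)
        if (!inherits(prev, "try-error") && nrow(prev) == 1L) {
          # fix types that all-NA CSV columns lose on re-read
          prev$extinction_year <- as.integer(prev$extinction_year)
          prev$spread_rate <- as.numeric(prev$spread_rate)
          prev$final_occupancy <- as.numeric(prev$final_occupancy)
          rows[[k]] <- prev
          next
        }
        warning(sprintf("corrupt checkpoint %s; re-running", ckpt))
      }
      if (is.null(landscape)) {
        # built lazily so fully checkpointed replicates cost nothing
        geom <- config_args[intersect(names(config_args),
                                      c("n_cols", "n_rows", "habitat_fraction",
                                        "cell_size"))]
        landscape <- do.call(generate_landscape, c(geom, list(seed = land_seed)))
      }
      args <- c(list(habitat_quality = sc$habitat_quality,
                     fecundity = sc$fecundity, mating = sc$mating,
                     harem = sc$harem, settlement = sc$settlement,
                     years = years),
                config_args[setdiff(names(config_args), "years")])
      cfg <- do.call(sim_config, args)
      res <- run_simulation(cfg, seed = derive_seed(master_seed, sc$scenario,
                                                    rep_i, 2L),
                            landscape = landscape,
                            landscape_seed = land_seed)
      row <- cbind(sc, replicate = rep_i,
                   run_responses(res, spread_horizon = spread_horizon),
                   row.names = NULL)
      rows[[k]] <- row
      if (!is.null(out_dir)) utils::write.csv(row, ckpt, row.names = FALSE)
      if (verbose)
        message(sprintf("scenario %d (%s, 1/b=%g, phi=%g, %s) rep %d: %s",
                        sc$scenario, sc$mating_system, sc$habitat_quality,
                        sc$fecundity, sc$settlement, rep_i,
                        if (row$extinct) "extinct" else
                          sprintf("occ %.2f, spread %s", row$final_occupancy,
                                  format(row$spread_rate, digits = 3))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-run response summary used by run_experiment
run_responses <- function(res, spread_horizon = NULL) {
  yr <- res$yearly
  horizon <- if (is.null(spread_horizon)) max(yr$year) else spread_horizon
  qe <- if (res$extinct) FALSE else
    quasi_equilibrium(yr$core_occupancy, years = yr$year, y_from = 20,
                      y_to = max(yr$year))
  sr <- if (res$extinct || !qe) NA_real_ else
    spread_rate(yr$edge_row[yr$year <= horizon])
  data.frame(extinct = res$extinct,
             extinction_year = if (res$extinct) res$extinction_year else NA_integer_,
             final_occupancy = if (res$extinct) 0 else
               yr$core_occupancy[nrow(yr)],
             quasi_equilibrium = qe,
             spread_rate = sr)
}
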