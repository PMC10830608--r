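#' Generate a corridor landscape of single-cell habitat patches
#'
#' Builds the gridded corridor landscape in which all simulations take
#' place: `n_cols` x `n_rows` cells of `cell_size` metres, of which an
#' exact count `round(habitat_fraction * n_cols * n_rows)` are suitable
#' breeding habitat, placed uniformly at random without replacement.
#' Every habitat cell is its own one-cell patch (patches are never
#' merged); the remaining cells are unsuitable matrix through which
#' dispersal can occur. Borders are hard: there is no wraparound.
#'
#' Rows are indexed `1..n_rows` with the populated core at the low-row
#' end, so range expansion proceeds toward increasing row index. One row
#' equals `cell_size` metres (100 m by default).
#'
#' @param n_cols,n_rows grid dimensions (default 20 x 1000).
#' @param habitat_fraction proportion of cells that are habitat, in (0, 1).
#' @param seed optional integer seed; when supplied the landscape is
#'   reproducible.
#' @param cell_size cell side length in metres.
#' @return An object of class `grid_landscape`: a list with `n_cols`,
#'   `n_rows`, `cell_size`, a logical `habitat` matrix (`n_rows` x
#'   `n_cols`), and an integer `patch_id` matrix (`NA` on matrix cells;
#'   each habitat cell carries a distinct id).
#' @examples
#' L <- generate_landscape(20, 100, 0.07, seed = 1)
#' sum(L$habitat)  # exactly round(0.07 * 2000) = 140
#' @export
generate_landscape <- function(n_cols = 20L, n_rows = 1000L,
                               habitat_fraction = 0.07, seed = NULL,
                               cell_size = 100) {
  if (length(n_cols) != 1L || length(n_rows) != 1L ||
      n_cols < 1 || n_rows < 1 || n_cols != round(n_cols) || n_rows != round(n_rows))
    stop("`n_cols` and `n_rows` must be positive integers")
  if (!is.numeric(habitat_fraction) || habitat_fraction <= 0 || habitat_fraction >= 1)
    stop("`habitat_fraction` must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  n_cells <- as.integer(n_cols) * as.integer(n_rows)
  n_hab <- round(habitat_fraction * n_cells)
  if (n_hab < 1) stop("`habitat_fraction` too small: no habitat cells on this grid")
  cells <- sample.int(n_cells, n_hab)
  habitat <- matrix(FALSE, nrow = n_rows, ncol = n_cols)
  habitat[cells] <- TRUE
  patch_id <- matrix(NA_integer_, nrow = n_rows, ncol = n_cols)
  patch_id[habitat] <- seq_len(n_hab)
  structure(
    list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         cell_size = cell_size, habitat = habitat, patch_id = patch_id),
    class = "grid_landscape")
}

#' @export
print.grid_landscape <- function(x, ...) {
  cat(sprintf("<grid_landscape> %d cols x %d rows (%g m cells), %d habitat patches (%.1f%%)\n",
              x$n_cols, x$n_rows, x$cell_size, sum(x$habitat),
              100 * mean(x$habitat)))
  invisible(x)
}

#' Zero-truncated Poisson random draws
#'
#' Samples from the zero-truncated Poisson distribution with
#' P(k) = lambda^k exp(-lambda) / (k! (1 - exp(-lambda))) on k = 1, 2, ...
#' Used for founder numbers per populated patch. `mean_is` controls the
#' reading of `lambda`: `"rate"` (default) takes it as the rate parameter
#' of the underlying Poisson before truncation, so the realized mean is
#' lambda / (1 - exp(-lambda)); `"realized"` solves for the rate whose
#' truncated distribution has mean `lambda`.
#'
#' @param n number of draws.
#' @param lambda positive rate (or target mean, see `mean_is`).
#' @param mean_is `"rate"` or `"realized"`.
#' @return integer vector of draws, all >= 1.
#' @examples
#' mean(rztpois(1e4, 2))        # ~ 2 / (1 - exp(-2)) = 2.313
#' @export
rztpois <- function(n, lambda, mean_is = c("rate", "realized")) {
  mean_is <- match.arg(mean_is)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number")
  if (mean_is == "realized") {
    if (lambda <= 1) stop("a zero-truncated Poisson mean must exceed 1")
    f <- function(r) r / (1 - exp(-r)) - lambda
    lambda <- stats::uniroot(f, c(1e-8, lambda))$root
  }
  # inverse-CDF on the truncated scale: F(k) = (ppois(k) - ppois(0)) / (1 - ppois(0))
  p0 <- exp(-lambda)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}

#' Probability mass of the zero-truncated Poisson
#'
#' @param k integer quantiles (>= 1; mass is 0 elsewhere).
#' @param lambda positive rate parameter.
#' @return P(K = k).
#' @export
dztpois <- function(k, lambda) {
  ifelse(k >= 1, stats::dpois(k, lambda) / (1 - exp(-lambda)), 0)
}

#' Sample founder populations in the landscape core
#'
#' Populates exactly `floor(init_fraction * n)` of the `n` habitat cells
#' lying within the first `core_rows` rows (a uniform random subset).
#' Each populated patch receives a zero-truncated Poisson number of
#' founding adults; in two-sex mode the two sexes are drawn
#' independently, so every populated patch starts with at least one
#' female and one male. Founders are adults (age 1): they breed in the
#' first simulated year.
#'
#' @param landscape a `grid_landscape`.
#' @param core_rows number of rows from the low-row end that form the
#'   core (default 500).
#' @param init_fraction proportion of core habitat cells populated.
#' @param lambda_init zero-truncated Poisson parameter (see [rztpois]).
#' @param two_sex draw males as well as females?
#' @param seed optional integer seed.
#' @param mean_is passed to [rztpois].
#' @return data.frame with columns `patch_id`, `row`, `col`, `sex`
#'   (`"F"`/`"M"`), `age`, `count` — one row per populated patch and sex.
#' @export
sample_initial_population <- function(landscape, core_rows = 500L,
                                      init_fraction = 0.5, lambda_init = 2,
                                      two_sex = TRUE, seed = NULL,
                                      mean_is = "rate") {
  stopifnot(inherits(landscape, "grid_landscape"))
  if (core_rows > landscape$n_rows)
    stop("`core_rows` exceeds the number of rows in the landscape")
  if (!is.null(seed)) set.seed(seed)
  idx <- which(landscape$habitat)               # column-major cell indices
  rows <- ((idx - 1L) %% landscape$n_rows) + 1L
  core <- idx[rows <= core_rows]
  n_pop <- floor(init_fraction * length(core))
  if (n_pop < 1) stop("no core habitat cells to populate")
  pop <- sort(sample(core, n_pop))
  prow <- ((pop - 1L) %% landscape$n_rows) + 1L
  pcol <- ((pop - 1L) %/% landscape$n_rows) + 1L
  pid <- landscape$patch_id[pop]
  out <- data.frame(patch_id = pid, row = prow, col = pcol, sex = "F",
                    age = 1L, count = rztpois(n_pop, lambda_init, mean_is))
  if (two_sex) {
    out <- rbind(out,
                 data.frame(patch_id = pid, row = prow, col = pcol, sex = "M",
                            age = 1L, count = rztpois(n_pop, lambda_init, mean_is)))
  }
  rownames(out) <- NULL
  out
}
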