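# Small worlds and shared scenario runs used across test files.

std_config <- function(...) {
  args <- list(habitat_quality = 10, fecundity = 3, mating = "two_sex",
               harem = 100, years = 10)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a homogeneous all-matrix landscape (no habitat anywhere except one far
# corner cell so generate_landscape constraints are respected by hand)
matrix_landscape <- function(n_cols = 11, n_rows = 11) {
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 cell_size = 100,
                 habitat = matrix(FALSE, n_rows, n_cols),
                 patch_id = matrix(NA_integer_, n_rows, n_cols)),
            class = "grid_landscape")
}

all_habitat_landscape <- function(n_cols = 11, n_rows = 11) {
  L <- matrix_landscape(n_cols, n_rows)
  L$habitat[] <- TRUE
  L$patch_id[] <- seq_len(n_cols * n_rows)
  L
}
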