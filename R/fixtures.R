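#' Deterministic miniature worlds for tests and examples
#'
#' Hand-built landscapes and occupant states small enough to reason
#' about by eye. Available fixtures:
#' \describe{
#'   \item{`two_patch_pair`}{5 x 20 grid with habitat at rows 3 and 8 of
#'     column 3; one adult female on the row-3 patch, one adult male on
#'     the row-8 patch. Isolates mate-search settlement.}
#'   \item{`edge_ladder`}{3 x 30 grid with habitat (and a breeding pair)
#'     at rows 5, 12 and 25 of column 2, plus an empty habitat cell at
#'     row 28: the range edge is exactly row 25.}
#'   \item{`strip_costs`}{1 x 12 strip, habitat at cells 1 and 6:
#'     effective-cost hand-checks along a line.}
#' }
#'
#' @param name fixture name.
#' @return list with `landscape` (a `grid_landscape`) and `occupants`
#'   (data.frame `row`, `col`, `sex`, `age`; possibly empty).
#' @export
make_fixture <- function(name = c("two_patch_pair", "edge_ladder",
                                  "strip_costs")) {
  name <- match.arg(name)
  blank <- function(n_cols, n_rows) {
    structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                   cell_size = 100,
                   habitat = matrix(FALSE, n_rows, n_cols),
                   patch_id = matrix(NA_integer_, n_rows, n_cols)),
              class = "grid_landscape")
  }
  finalize <- function(L) {
    L$patch_id[L$habitat] <- seq_len(sum(L$habitat))
    L
  }
  switch(name,
    two_patch_pair = {
      L <- blank(5, 20)
      L$habitat[3, 3] <- TRUE
      L$habitat[8, 3] <- TRUE
      occ <- data.frame(row = c(3L, 8L), col = c(3L, 3L),
                        sex = c("F", "M"), age = c(1L, 1L))
      list(landscape = finalize(L), occupants = occ)
    },
    edge_ladder = {
      L <- blank(3, 30)
      rows <- c(5L, 12L, 25L)
      L$habitat[cbind(c(rows, 28L), 2L)] <- TRUE
      occ <- data.frame(row = rep(rows, each = 2L), col = 2L,
                        sex = rep(c("F", "M"), times = 3L), age = 1L)
      list(landscape = finalize(L), occupants = occ)
    },
    strip_costs = {
      L <- blank(1, 12)
      L$habitat[c(1L, 6L), 1L] <- TRUE
      list(landscape = finalize(L),
           occupants = data.frame(row = integer(), col = integer(),
                                  sex = character(), age = integer()))
    })
}
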