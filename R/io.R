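#' Write a landscape as ESRI-ASCII-style rasters
#'
#' Serialises a `grid_landscape` to `landscape.asc` (0 = matrix, 1 =
#' habitat) and `patches.asc` (patch ids; NODATA on matrix cells) in the
#' ESRI ASCII raster dialect (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header, then the integer grid, one raster row per line,
#' top row first). The grid's highest row index is written first so
#' row 1 sits at the raster's lower edge.
#'
#' @param landscape a `grid_landscape`.
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
write_landscape_asc <- function(landscape, dir = ".") {
  stopifnot(inherits(landscape, "grid_landscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(mat, path, nodata = -9999L) {
    header <- c(paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
                "xllcorner 0", "yllcorner 0",
                paste("cellsize", landscape$cell_size),
                paste("NODATA_value", nodata))
    mat[is.na(mat)] <- nodata
    body <- apply(mat[rev(seq_len(nrow(mat))), , drop = FALSE], 1, paste,
                  collapse = " ")
    writeLines(c(header, body), path)
    path
  }
  p1 <- write_one(matrix(as.integer(landscape$habitat),
                         nrow = landscape$n_rows),
                  file.path(dir, "landscape.asc"))
  p2 <- write_one(landscape$patch_id, file.path(dir, "patches.asc"))
  invisible(c(landscape = p1, patches = p2))
}

#' Read a landscape back from ESRI-ASCII-style rasters
#'
#' Inverse of [write_landscape_asc].
#'
#' @param dir directory holding `landscape.asc` and `patches.asc`.
#' @return a `grid_landscape`.
#' @export
read_landscape_asc <- function(dir = ".") {
  read_one <- function(path) {
    lines <- readLines(path)
    header <- lines[1:6]
    kv <- do.call(rbind, strsplit(trimws(header), "\\s+"))
    h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
    body <- lines[-(1:6)]
    vals <- as.integer(unlist(strsplit(trimws(body), "\\s+")))
    mat <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
    mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
    mat[mat == h[["nodata_value"]]] <- NA_integer_
    list(mat = mat, cellsize = h[["cellsize"]])
  }
  hab <- read_one(file.path(dir, "landscape.asc"))
  pat <- read_one(file.path(dir, "patches.asc"))
  structure(list(n_cols = ncol(hab$mat), n_rows = nrow(hab$mat),
                 cell_size = hab$cellsize,
                 habitat = hab$mat == 1L, patch_id = pat$mat),
            class = "grid_landscape")
}

#' Write a founder table as CSV
#'
#' @param founders data.frame from [sample_initial_population].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_founders_csv <- function(founders, path) {
  utils::write.csv(founders, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
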