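#' Read and write single-band ESRI ASCII grids
#'
#' Plain-text grid exchange for gradient and land-cover layers. The ASCII
#' grid stores rows north-to-south; [simple_raster()] stores them
#' south-to-north, so the row order is flipped on the way in and out.
#'
#' @param r A [simple_raster()].
#' @param path File path.
#' @param nodata NODATA sentinel written for `NA` (default -9999).
#' @return `read_ascii_grid()` returns a [simple_raster()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "simple_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)),
               paste("nrows", nrow(v)),
               paste("xllcorner", format(r$xmin, digits = 15)),
               paste("yllcorner", format(r$ymin, digits = 15)),
               paste("cellsize", format(r$res, digits = 15)),
               paste("NODATA_value", nodata)), con)
  utils::write.table(v[rev(seq_len(nrow(v))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  if (!is.na(vals["nodata_value"])) v[v == vals["nodata_value"]] <- NA
  simple_raster(v[rev(seq_len(nrow(v))), , drop = FALSE],
                xmin = vals["xllcorner"], ymin = vals["yllcorner"],
                res = vals["cellsize"])
}
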