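#' Gridded raster layers as plain-text ESRI ASCII grids
#'
#' The upscaling stage works on modest regular grids (soil property means
#' and percentile bands, baseline respiration). Layers are held in memory
#' as numeric matrices (row 1 = northernmost row, matching the on-disk
#' order) inside a light container that carries the shared geometry, and
#' are exchanged on disk as ESRI ASCII grids (`.asc`) -- a standard,
#' diff-friendly plain-text raster format.
#'
#' @name tundresp-grids
NULL

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m numeric matrix; `NA` cells are written as the nodata value.
#' @param path output file path.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (map units, e.g. m).
#' @param nodata value used to encode missing cells.
#' @export
write_asc <- function(m, path, xll = 0, yll = 0, cellsize = 1000,
                      nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  m[is.na(m)] <- nodata
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return a numeric matrix with attributes `xll`, `yll`, `cellsize`;
#'   nodata cells are `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (l in lines) {
    parts <- strsplit(trimws(l), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing header fields): ", path)
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid body has ", length(vals), " values; header promises ",
         hdr$ncols * hdr$nrows, ": ", path)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  attr(m, "xll") <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  attr(m, "yll") <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  attr(m, "cellsize") <- hdr$cellsize
  m
}

#' Assemble aligned soil layers into a grid stack
#'
#' @param layers named list of numeric matrices. Soil layers follow the
#'   naming convention `<variable>_<statistic>_<top>_<bottom>` with
#'   variable in `TN`, `SOC`, `BD` (units: % by mass for TN/SOC, g/cm^3
#'   for BD), statistic in `mean`, `q05`, `q95` and the depth interval in
#'   cm (e.g. `TN_mean_0_30`); a `baseline_er` layer (gC m^-2 yr^-1) may
#'   be included.
#' @param cellsize cell edge length in m (cell area = `cellsize^2`).
#' @param xll,yll lower-left corner coordinates.
#' @return an object of class `"soil_stack"`: the layers, the parsed depth
#'   intervals, the geometry, and a logical `valid` matrix which masks
#'   cells missing any mandatory layer value or with an inverted
#'   percentile pair (`q05 > q95`, counted in attribute
#'   `"n_inverted_percentiles"`).
#' @export
soil_stack <- function(layers, cellsize = 1000, xll = 0, yll = 0) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), all(nzchar(names(layers))))
  dims <- vapply(layers, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    off <- names(layers)[which(dims[1L, ] != dims[1L, 1L] |
                               dims[2L, ] != dims[2L, 1L])]
    stop("grid mismatch: layer(s) ", paste(off, collapse = ", "),
         " differ in dimension from ", names(layers)[1L])
  }
  soil_names <- grep("^(TN|SOC|BD)_(mean|q05|q95)_\\d+_\\d+$",
                     names(layers), value = TRUE)
  if (!length(soil_names)) stop("no soil layers found in 'layers'")
  parts <- strsplit(soil_names, "_")
  depths <- unique(data.frame(
    top = as.numeric(vapply(parts, `[`, "", 3L)),
    bottom = as.numeric(vapply(parts, `[`, "", 4L))
  ))
  depths <- depths[order(depths$top), , drop = FALSE]
  if (any(depths$bottom <= depths$top)) stop("depth interval with bottom <= top")
  if (nrow(depths) > 1L &&
      any(abs(depths$top[-1L] - depths$bottom[-nrow(depths)]) > 1e-9)) {
    stop("depth intervals must tile the profile without gaps or overlaps")
  }

  valid <- matrix(TRUE, nrow = dims[1L, 1L], ncol = dims[2L, 1L])
  mandatory <- expand.grid(v = c("TN", "SOC", "BD"),
                           s = c("mean", "q05", "q95"),
                           d = seq_len(nrow(depths)))
  for (i in seq_len(nrow(mandatory))) {
    nm <- sprintf("%s_%s_%s_%s", mandatory$v[i], mandatory$s[i],
                  depths$top[mandatory$d[i]], depths$bottom[mandatory$d[i]])
    if (!nm %in% names(layers)) {
      stop("missing mandatory soil layer: ", nm)
    }
    valid <- valid & !is.na(layers[[nm]])
  }
  n_inv <- 0L
  for (v in c("TN", "SOC", "BD")) {
    for (d in seq_len(nrow(depths))) {
      lo <- layers[[sprintf("%s_q05_%s_%s", v, depths$top[d], depths$bottom[d])]]
      hi <- layers[[sprintf("%s_q95_%s_%s", v, depths$top[d], depths$bottom[d])]]
      inv <- !is.na(lo) & !is.na(hi) & lo > hi
      n_inv <- n_inv + sum(inv & valid)
      valid <- valid & !inv
    }
  }
  if (n_inv) warning(n_inv, " cell(s) masked: q05 > q95")
  structure(list(layers = layers, depths = depths, valid = valid,
                 cellsize = cellsize, xll = xll, yll = yll),
            class = "soil_stack",
            n_inverted_percentiles = n_inv)
}

#' Read aligned soil rasters from disk
#'
#' @param paths named character vector of `.asc` file paths; names follow
#'   the layer convention of [soil_stack()].
#' @return a `"soil_stack"`.
#' @export
read_soil_rasters <- function(paths) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  mats <- lapply(paths, read_asc)
  cs <- vapply(mats, attr, numeric(1L), "cellsize")
  if (any(cs != cs[1L])) {
    stop("grid mismatch: cellsize differs for layer(s) ",
         paste(names(paths)[cs != cs[1L]], collapse = ", "))
  }
  soil_stack(lapply(mats, function(m) { attributes(m) <- list(dim = dim(m)); m }),
             cellsize = unname(cs[1L]),
             xll = attr(mats[[1L]], "xll"), yll = attr(mats[[1L]], "yll"))
}

#' Block-mean aggregation of a grid to a coarser resolution
#'
#' Means are taken over `factor x factor` blocks ignoring missing cells;
#' blocks with no valid cell become `NA`. Trailing rows/columns that do
#' not fill a block are dropped.
#'
#' @param m numeric matrix.
#' @param factor integer aggregation factor (>= 1).
#' @return aggregated matrix.
#' @export
aggregate_grid <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(is.matrix(m), factor >= 1L)
  if (factor == 1L) return(m)
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  if (nr < 1L || nc < 1L) stop("aggregation factor exceeds grid size")
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1L) * factor + 1L):(i * factor)
    for (j in seq_len(nc)) {
      cols <- ((j - 1L) * factor + 1L):(j * factor)
      block <- m[rows, cols]
      if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

#' @export
print.soil_stack <- function(x, ...) {
  d <- dim(x$layers[[1L]])
  cat("<soil_stack> ", d[1L], "x", d[2L], " cells, cellsize ", x$cellsize,
      " m\n", sep = "")
  cat("  depth intervals (cm): ",
      paste(sprintf("%g-%g", x$depths$top, x$depths$bottom), collapse = ", "),
      "\n  layers: ", length(x$layers),
      " | valid cells: ", sum(x$valid), "/", length(x$valid), "\n", sep = "")
  invisible(x)
}
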