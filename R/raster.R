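# Minimal in-memory raster stack: a named list of equally shaped matrices with
# a shared geotransform. Row 1 is the north edge; cells are half-open intervals
# [xll + (c-1)*cs, xll + c*cs) x [yll + (nr-r)*cs, yll + (nr-r+1)*cs).

#' Build an environmental raster stack
#'
#' An `env_stack` bundles one grid per environmental variable with a shared
#' geotransform, coordinate-reference tag and epoch tag. All layers must share
#' the same dimensions; cells that are nodata in *any* layer are masked in all
#' of them (the shared mask is the union of per-layer nodata).
#'
#' @param layers Named list of numeric matrices (rows x cols), `NA` = nodata.
#'   Row 1 is the northern edge of the grid.
#' @param xll,yll Coordinates of the lower-left corner of the grid (degrees).
#' @param cellsize Cell size in degrees (square cells).
#' @param crs Free-text CRS tag, default `"WGS84"`.
#' @param epoch Epoch tag, e.g. `"current"` or `"SSP585_2041_2060"`.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, xll, yll, cellsize, crs = "WGS84",
                      epoch = "current") {
  stopifnot(is.list(layers), length(layers) >= 1L, !is.null(names(layers)))
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- names(layers)[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]]
    stop("layer '", bad, "' does not match the shape of the other layers")
  }
  mask <- Reduce(`|`, lapply(layers, is.na))
  layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
  structure(
    list(layers = layers, xll = xll, yll = yll, cellsize = cellsize,
         nrow = dims[1, 1], ncol = dims[2, 1], mask = mask,
         crs = crs, epoch = epoch),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> ", x$nrow, "x", x$ncol, " cells, ",
      length(x$layers), " layer(s), epoch '", x$epoch, "'\n", sep = "")
  cat("  variables: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  cat("  origin (", x$xll, ", ", x$yll, "), cellsize ", x$cellsize,
      ", ", sum(x$mask), " masked cell(s)\n", sep = "")
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

stack_dim <- function(stack) c(stack$nrow, stack$ncol)

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return List with `values` (matrix, `NA` for nodata), `xll`, `yll`,
#'   `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- list()
  lines <- readLines(path, n = 6L)
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  n_hdr <- sum(vapply(lines, function(ln)
    grepl("^[a-zA-Z]", trimws(ln)), logical(1)))
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body of ", path, " has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param values Numeric matrix (row 1 = north edge); `NA` written as nodata.
#' @param path Output path.
#' @param xll,yll,cellsize Geotransform.
#' @param nodata Nodata sentinel written to file, default -9999.
#' @export
write_ascii_grid <- function(values, path, xll, yll, cellsize,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", nodata)), con)
  vals <- values
  vals[is.na(vals)] <- nodata
  for (r in seq_len(nrow(vals)))
    writeLines(paste(format(vals[r, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Read a set of ASCII grids into an `env_stack`
#'
#' @param paths Named character vector of `.asc` paths; names become variable
#'   names (defaults to file base names).
#' @param epoch Epoch tag for the stack.
#' @param crs CRS tag.
#' @return An [env_stack()].
#' @export
read_raster_stack <- function(paths, epoch = "current", crs = "WGS84") {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.asc$", "", basename(paths))
  grids <- lapply(paths, read_ascii_grid)
  ref <- grids[[1]]
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    if (!identical(dim(g$values), dim(ref$values)) ||
        abs(g$xll - ref$xll) > 1e-9 || abs(g$yll - ref$yll) > 1e-9 ||
        abs(g$cellsize - ref$cellsize) > 1e-12)
      stop("layer '", names(paths)[i],
           "' does not share the grid of the first layer")
  }
  env_stack(lapply(grids, `[[`, "values"),
            xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
            crs = crs, epoch = epoch)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack An [env_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix Optional filename prefix.
#' @return Named vector of written paths.
#' @export
write_raster_stack <- function(stack, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(v) {
    p <- file.path(dir, paste0(prefix, v, ".asc"))
    write_ascii_grid(stack$layers[[v]], p, stack$xll, stack$yll,
                     stack$cellsize)
    p
  }, character(1))
  paths
}

# (lon, lat) -> (row, col) under the half-open cell convention; 0 row means
# north of the grid / out of range.
point_to_cell <- function(stack, lon, lat) {
  col <- floor((lon - stack$xll) / stack$cellsize) + 1L
  row <- stack$nrow - floor((lat - stack$yll) / stack$cellsize)
  ok <- col >= 1L & col <= stack$ncol & row >= 1L & row <= stack$nrow
  cbind(row = ifelse(ok, row, NA_integer_), col = ifelse(ok, col, NA_integer_))
}

# Centre coordinates of every cell, as vectors aligned with column-major
# cell indexing (cell id = (col-1)*nrow + row).
cell_centres <- function(stack) {
  r <- rep(seq_len(stack$nrow), times = stack$ncol)
  c <- rep(seq_len(stack$ncol), each = stack$nrow)
  lon <- stack$xll + (c - 0.5) * stack$cellsize
  lat <- stack$yll + (stack$nrow - r + 0.5) * stack$cellsize
  tibble::tibble(cell = seq_along(r), row = r, col = c, lon = lon, lat = lat)
}

#' Extract environmental values at population locations
#'
#' Looks up, for every population, the raster cell containing its coordinates
#' (no interpolation) and returns a per-population environmental table.
#'
#' @param stack An [env_stack()].
#' @param pops Tibble with columns `pop`, `lon`, `lat`.
#' @return Tibble with `pop` plus one column per stack variable.
#' @export
extract_env_at_points <- function(stack, pops) {
  rc <- point_to_cell(stack, pops$lon, pops$lat)
  if (anyNA(rc))
    stop("population(s) outside the grid extent: ",
         paste(pops$pop[is.na(rc[, 1])], collapse = ", "))
  vals <- lapply(stack$layers, function(m) m[rc])
  out <- tibble::as_tibble(c(list(pop = pops$pop), vals))
  bad <- !complete.cases(out)
  if (any(bad))
    stop("population(s) fall on nodata cells: ",
         paste(pops$pop[bad], collapse = ", "))
  out
}

#' Crop a stack to a row/column window
#'
#' @param stack An [env_stack()].
#' @param rows,cols Contiguous integer ranges of rows / columns to keep.
#' @return The cropped [env_stack()] with an adjusted geotransform.
#' @export
crop_stack <- function(stack, rows, cols) {
  stopifnot(all(diff(rows) == 1), all(diff(cols) == 1),
            min(rows) >= 1, max(rows) <= stack$nrow,
            min(cols) >= 1, max(cols) <= stack$ncol)
  layers <- lapply(stack$layers, function(m) m[rows, cols, drop = FALSE])
  env_stack(layers,
            xll = stack$xll + (min(cols) - 1) * stack$cellsize,
            yll = stack$yll + (stack$nrow - max(rows)) * stack$cellsize,
            cellsize = stack$cellsize, crs = stack$crs, epoch = stack$epoch)
}

#' Convert a stack to a long tibble of cell values
#'
#' @param stack An [env_stack()].
#' @return Tibble with `cell`, `row`, `col`, `lon`, `lat` and one column per
#'   variable; masked cells carry `NA`.
#' @export
stack_to_tibble <- function(stack) {
  cc <- cell_centres(stack)
  for (v in names(stack$layers)) cc[[v]] <- as.vector(stack$layers[[v]])
  cc
}

#' Plot a raster layer
#'
#' @param stack An [env_stack()].
#' @param variable Layer to draw (default first).
#' @return A ggplot object.
#' @export
plot_stack_layer <- function(stack, variable = names(stack$layers)[1]) {
  df <- stack_to_tibble(stack)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data[[variable]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(variable, " (", stack$epoch, ")"),
                  x = "longitude", y = "latitude")
}
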