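#' Environmental raster stacks
#'
#' An `env_raster_stack` holds one gridded layer per environmental variable on
#' a shared extent and square cell size. Layers are stored as matrices whose
#' first row is the northernmost row (the ESRI ASCII grid convention). Cells
#' that are nodata in *any* layer are masked (`NA`) in *all* layers, so the
#' background environment is defined consistently across variables.
#'
#' @param layers named list of numeric matrices, identical dimensions.
#' @param xmin,xmax,ymin,ymax extent in decimal degrees (cell edges).
#' @return an object of class `env_raster_stack`.
#' @export
env_raster_stack <- function(layers, xmin, xmax, ymin, ymax) {
  if (!is.list(layers) || length(layers) < 1L)
    abort("`layers` must be a non-empty named list of matrices.")
  if (is.null(names(layers)) || any(!nzchar(names(layers))) ||
      anyDuplicated(names(layers)))
    abort("`layers` must have unique, non-empty names.")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("All layers must share identical dimensions.")
  nr <- dims[1, 1]; nc <- dims[2, 1]
  csx <- (xmax - xmin) / nc
  csy <- (ymax - ymin) / nr
  if (abs(csx - csy) > 1e-8 * max(abs(csx), abs(csy)))
    abort("Cells must be square: (xmax-xmin)/ncol must equal (ymax-ymin)/nrow.")
  # unify the nodata mask across layers
  mask <- Reduce(`|`, lapply(layers, is.na))
  layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
  structure(
    list(layers = layers, xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         nrow = nr, ncol = nc, cellsize = csx),
    class = "env_raster_stack"
  )
}

#' @export
print.env_raster_stack <- function(x, ...) {
  cat("<env_raster_stack> ", length(x$layers), " layer(s), ",
      x$nrow, " x ", x$ncol, " cells of ", signif(x$cellsize, 4),
      " deg\n", sep = "")
  cat("  extent: lon [", x$xmin, ", ", x$xmax, "], lat [",
      x$ymin, ", ", x$ymax, "]\n", sep = "")
  cat("  variables: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a stack of ESRI ASCII grids
#'
#' Reads one `.asc` grid per environmental variable. All grids must share the
#' same extent, dimensions and cell size. GeoTIFF input is not supported;
#' convert to ASCII grid (e.g. `gdal_translate -of AAIGrid`) upstream.
#'
#' @param paths character vector of file paths.
#' @param names variable names; defaults to file base names.
#' @return an [env_raster_stack()].
#' @export
read_env_rasters <- function(paths, names = NULL) {
  if (any(grepl("\\.tiff?$", paths, ignore.case = TRUE)))
    abort("GeoTIFF input is not supported; supply ESRI ASCII grids (.asc).")
  names <- names %||% sub("\\.[^.]*$", "", basename(paths))
  grids <- lapply(paths, read_ascii_grid)
  hdr <- grids[[1]]
  for (g in grids[-1]) {
    same <- isTRUE(all.equal(hdr[c("xmin", "ymin", "cellsize")],
                             g[c("xmin", "ymin", "cellsize")])) &&
      identical(dim(hdr$values), dim(g$values))
    if (!same) abort("All raster layers must share extent and resolution.")
  }
  layers <- setNames(lapply(grids, `[[`, "values"), names)
  env_raster_stack(layers,
                   xmin = hdr$xmin, xmax = hdr$xmin + hdr$cellsize * ncol(hdr$values),
                   ymin = hdr$ymin, ymax = hdr$ymin + hdr$cellsize * nrow(hdr$values))
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    abort(paste0("Not an ESRI ASCII grid (missing header): ", path))
  if (is.null(hdr$xllcorner) && !is.null(hdr$xllcenter))
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (is.null(hdr$yllcorner) && !is.null(hdr$yllcenter))
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    abort(paste0("Grid body has ", length(vals), " values, expected ",
                 hdr$ncols * hdr$nrows, ": ", path))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(values = m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param mat matrix, row 1 = northernmost row; `NA` written as nodata.
#' @param path output file.
#' @param xmin,ymin lower-left corner; @param cellsize cell size in degrees.
#' @param nodata nodata sentinel value.
#' @export
write_ascii_grid <- function(mat, path, xmin, ymin, cellsize, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", format(xmin, digits = 12)),
    paste("yllcorner", format(ymin, digits = 12)),
    paste("cellsize", format(cellsize, digits = 12)),
    paste("NODATA_value", nodata)
  ), con)
  m <- mat
  m[is.na(m)] <- nodata
  writeLines(apply(m, 1L, function(r) paste(format(r, digits = 8), collapse = " ")),
             con)
  invisible(path)
}

#' Write all layers of a stack as ASCII grids
#'
#' @param stack an [env_raster_stack()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_env_rasters <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], p, stack$xmin, stack$ymin,
                     stack$cellsize)
    p
  }, character(1))
  invisible(paths)
}

# Cell membership: half-open [west, east) x [south, north); points on the
# extreme east/north boundary belong to the last cell. Row 1 is the north row.
cell_index <- function(stack, lon, lat) {
  col <- floor((lon - stack$xmin) / stack$cellsize) + 1L
  col[lon == stack$xmax] <- stack$ncol
  row_from_s <- floor((lat - stack$ymin) / stack$cellsize) + 1L
  row_from_s[lat == stack$ymax] <- stack$nrow
  row <- stack$nrow - row_from_s + 1L
  inside <- lon >= stack$xmin & lon <= stack$xmax &
    lat >= stack$ymin & lat <= stack$ymax
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Tabulate the background environment of a raster stack
#'
#' Returns one row per cell with complete (non-nodata) values in every layer,
#' with cell-center coordinates — the "whole environmental space of the study
#' area" on which the ordination is calibrated.
#'
#' @param stack an [env_raster_stack()].
#' @return a tibble with `lon`, `lat` and one column per variable.
#' @export
env_background <- function(stack) {
  nr <- stack$nrow; nc <- stack$ncol
  lon <- stack$xmin + (seq_len(nc) - 0.5) * stack$cellsize
  lat <- stack$ymax - (seq_len(nr) - 0.5) * stack$cellsize
  out <- tibble(
    lon = rep(lon, each = nr),
    lat = rep(lat, times = nc)
  )
  for (nm in names(stack$layers)) out[[nm]] <- as.vector(stack$layers[[nm]])
  out[stats::complete.cases(out), ]
}
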