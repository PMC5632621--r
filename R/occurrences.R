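#' Read lineage occurrence records
#'
#' Reads a UTF-8 CSV with header `lineage,lon,lat[,year]` into a tibble of
#' georeferenced records. Rows with unparseable or out-of-range coordinates
#' are rejected with their row numbers; a missing `year` column yields `NA`
#' years (such records survive the year filter, see [filter_by_year()]).
#'
#' @param path path to the CSV file.
#' @return a tibble with columns `lineage`, `lon`, `lat`, `year`.
#' @export
read_occurrences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("lineage", "lon", "lat")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) {
    warn("Occurrence file is empty; returning an empty table.")
    return(tibble(lineage = character(), lon = double(), lat = double(),
                  year = integer()))
  }
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- which(is.na(lon) | is.na(lat) |
                 lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (length(bad))
    abort(paste0("Malformed or out-of-range coordinates in row(s): ",
                 paste(bad, collapse = ", ")))
  year <- if ("year" %in% names(df)) {
    suppressWarnings(as.integer(df$year))
  } else rep(NA_integer_, nrow(df))
  tibble(lineage = as.character(df$lineage), lon = lon, lat = lat, year = year)
}

#' Drop records collected before a cutoff year
#'
#' Records whose collection year is strictly earlier than `min_year` are
#' removed; records with missing year are retained (the cutoff targets the
#' identification reliability of databased records, and discarding undated
#' herbarium material would silently bias the sample). The number of
#' year-less records kept is reported.
#'
#' @param records occurrence tibble (see [read_occurrences()]).
#' @param min_year earliest collection year kept (default 1990).
#' @return the filtered tibble.
#' @export
filter_by_year <- function(records, min_year = 1990) {
  n_missing <- sum(is.na(records$year))
  if (n_missing > 0L)
    inform(paste0(n_missing, " record(s) without a collection year retained."))
  dplyr::filter(records, is.na(.data$year) | .data$year >= min_year)
}

#' Attach environmental values to occurrence records
#'
#' Looks up, for every record, the raster cell containing its coordinate
#' (half-open cell intervals; points on the extreme east/north edge belong to
#' the last cell) and appends one column per raster variable. Records falling
#' on nodata cells (e.g. sea) are dropped and counted; coordinates outside
#' the raster extent are an error.
#'
#' @param records occurrence tibble.
#' @param rasters an [env_raster_stack()].
#' @return the tibble with environmental columns appended, plus attribute
#'   `n_dropped_nodata`.
#' @export
extract_env <- function(records, rasters) {
  idx <- cell_index(rasters, records$lon, records$lat)
  if (any(!idx$inside))
    abort(paste0("Record(s) outside the raster extent: row(s) ",
                 paste(which(!idx$inside), collapse = ", ")))
  flat <- (idx$col - 1L) * rasters$nrow + idx$row
  out <- records
  for (nm in names(rasters$layers))
    out[[nm]] <- rasters$layers[[nm]][flat]
  env <- as.matrix(out[names(rasters$layers)])
  keep <- stats::complete.cases(env)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    inform(paste0(n_drop, " record(s) on nodata cells dropped."))
  out <- out[keep, ]
  attr(out, "n_dropped_nodata") <- n_drop
  out
}

#' Collapse duplicate records to one occurrence per raster cell
#'
#' Kernel density estimation over-weights localities reported many times;
#' standard practice on gridded environments keeps one record per lineage per
#' cell. Toggleable from the pipeline configuration.
#'
#' @param records occurrence tibble.
#' @param rasters the [env_raster_stack()] defining the cells.
#' @return the thinned tibble (first record per lineage x cell kept).
#' @export
thin_per_cell <- function(records, rasters) {
  idx <- cell_index(rasters, records$lon, records$lat)
  records |>
    mutate(.cell = paste(idx$row, idx$col)) |>
    group_by(.data$lineage, .data$.cell) |>
    dplyr::slice(1L) |>
    ungroup() |>
    select(-".cell")
}

#' Screen environmental variables for collinearity
#'
#' Greedy elimination until all pairwise Pearson correlations among retained
#' variables satisfy |r| <= `threshold`: at each step, among variables
#' involved in an offending pair, the one with the largest mean |r| over the
#' currently offending pairs is dropped (ties broken by input column order,
#' keeping the earlier variable).
#'
#' @param env_matrix records x variables data frame or matrix of
#'   environmental values.
#' @param threshold maximum allowed pairwise |r| (default 0.70).
#' @return character vector of retained variable names, with attribute
#'   `dropped`.
#' @export
screen_collinearity <- function(env_matrix, threshold = 0.70) {
  m <- as.matrix(env_matrix)
  if (ncol(m) < 2L) abort("Need at least 2 variables to screen.")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) abort("Need at least 3 complete records.")
  vars <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  colnames(m) <- vars
  keep <- vars
  dropped <- character()
  repeat {
    r <- abs(cor(m[, keep, drop = FALSE]))
    diag(r) <- 0
    offending <- which(r > threshold, arr.ind = TRUE)
    if (nrow(offending) == 0L) break
    involved <- sort(unique(as.vector(offending)))
    # mean |r| over offending pairs only, per involved variable
    score <- vapply(involved, function(i) {
      rows <- offending[offending[, 1] == i, , drop = FALSE]
      mean(r[rows])
    }, numeric(1))
    worst <- involved[score == max(score)]
    drop_i <- max(worst)   # later column dropped on ties
    dropped <- c(dropped, keep[drop_i])
    keep <- keep[-drop_i]
    if (length(keep) < 2L) break
  }
  structure(keep, dropped = dropped)
}
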