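#' Read and write landscape rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of integer
#' codes from north to south.  Coordinates in the file are kilometres and
#' the cell size metres, matching the package's projected-km convention.
#'
#' @param path File path.
#' @param catalog Catalog to attach on read.
#' @return `read_ascii_grid()` returns a `landscape_grid`.
#' @export
read_ascii_grid <- function(path, catalog = default_catalog()) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(text = lines[-(1:6)], what = integer(), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m_topdown <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m_topdown[nr:1, , drop = FALSE]  # store south-to-north
  m[m == vals[["nodata_value"]]] <- CODE_NODATA
  landscape_grid(m, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                 res_m = vals[["cellsize"]], catalog = catalog)
}

#' @rdname read_ascii_grid
#' @param grid A `landscape_grid` to write.
#' @export
write_ascii_grid <- function(grid, path) {
  m <- grid$codes[nrow(grid$codes):1, , drop = FALSE]  # north first on disk
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$origin[1], digits = 12)),
    paste("yllcorner", format(grid$origin[2], digits = 12)),
    paste("cellsize", format(grid$res_m, digits = 12)),
    paste("NODATA_value", CODE_NODATA)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read ownership polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (or single-ring MultiPolygon)
#' features whose properties carry an `owner` field.  Coordinates must be in
#' the projected km system shared by all package inputs; only the outer ring
#' of each polygon is used.
#'
#' @param path GeoJSON file path.
#' @return A list of `list(owner, x, y)` polygons for [reclassify()].
#' @export
read_ownership_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  lapply(feats, function(f) {
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported geometry type: ", geom$type)
    )
    xy <- do.call(rbind, lapply(ring, function(pt) unlist(pt[1:2])))
    list(owner = f$properties$owner, x = xy[, 1], y = xy[, 2])
  })
}

#' Read or write GPS fixes
#'
#' The fix interchange format is CSV with columns `animal_id`, `timestamp`
#' (ISO 8601, UTC), `easting_km`, `northing_km`.
#'
#' @param path CSV path.
#' @return A data frame sorted by animal and time, with POSIXct timestamps.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("animal_id", "timestamp", "easting_km", "northing_km")
  if (!all(needed %in% names(df))) {
    stop("fix CSV must have columns: ", paste(needed, collapse = ", "))
  }
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                            "%Y-%m-%d %H:%M:%OS"))
  validate_fixes(df)
}

#' @rdname read_fixes
#' @param fixes Fix data frame to write.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_fixes <- function(fixes) {
  if (!all(is.finite(fixes$easting_km)) || !all(is.finite(fixes$northing_km))) {
    stop("fix coordinates must be finite")
  }
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
  dup <- unlist(tapply(as.numeric(fixes$timestamp), fixes$animal_id,
                       function(t) c(FALSE, diff(t) <= 0)), use.names = FALSE)
  if (any(dup)) stop("timestamps must be strictly increasing within an animal")
  rownames(fixes) <- NULL
  fixes
}

#' Read feed-site coordinates
#'
#' @param path CSV with columns `easting_km`, `northing_km`.
#' @return Data frame of feed sites.
#' @export
read_feed_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("easting_km", "northing_km") %in% names(df)))
  df
}
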