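#' Landscape grid of resource-by-ownership codes
#'
#' A `landscape_grid` is a regular raster in a projected coordinate system
#' (km): an integer code matrix plus an origin (lower-left corner, km) and a
#' cell resolution in metres.  Row 1 is the southernmost row; row indices
#' increase northwards, column indices eastwards.  Codes are catalog variable
#' codes, `0` for unclassified ("other") cells or `-1` for missing data.
#'
#' @param codes Integer matrix (rows = south to north).
#' @param origin Numeric length-2, lower-left corner easting/northing in km.
#' @param res_m Cell edge length in metres (default 38.7).
#' @param catalog Variable catalog the codes refer to.
#' @return An object of class `landscape_grid`.
#' @export
landscape_grid <- function(codes, origin = c(0, 0), res_m = 38.7,
                           catalog = default_catalog()) {
  stopifnot(is.matrix(codes), res_m > 0, length(origin) == 2)
  if (length(codes) == 0) stop("empty raster")
  validate_catalog(catalog)
  codes <- matrix(as.integer(codes), nrow(codes), ncol(codes))
  known <- c(catalog$code, CODE_OTHER, CODE_NODATA)
  bad <- setdiff(unique(as.vector(codes)), known)
  if (length(bad)) {
    stop("unregistered cell code(s): ", paste(sort(bad), collapse = ", "))
  }
  structure(
    list(codes = codes, origin = as.numeric(origin), res_m = res_m,
         catalog = catalog),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "<landscape_grid> %d x %d cells at %.1f m (%.2f x %.2f km), origin (%.2f, %.2f) km\n",
    nrow(x$codes), ncol(x$codes), x$res_m,
    ncol(x$codes) * x$res_m / 1000, nrow(x$codes) * x$res_m / 1000,
    x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' Cell area of a landscape grid in hectares
#' @param grid A `landscape_grid`.
#' @export
cell_area_ha <- function(grid) grid$res_m^2 / 1e4

#' @keywords internal
res_km <- function(grid) grid$res_m / 1000

# cell-centre coordinate vectors (km)
#' @keywords internal
cell_centers_x <- function(grid) {
  grid$origin[1] + (seq_len(ncol(grid$codes)) - 0.5) * res_km(grid)
}
#' @keywords internal
cell_centers_y <- function(grid) {
  grid$origin[2] + (seq_len(nrow(grid$codes)) - 0.5) * res_km(grid)
}

#' Spatial extent of a grid
#' @param grid A `landscape_grid`.
#' @return Numeric `c(xmin, xmax, ymin, ymax)` in km.
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + ncol(grid$codes) * res_km(grid),
    ymin = grid$origin[2],
    ymax = grid$origin[2] + nrow(grid$codes) * res_km(grid))
}

#' Reclassify a base land-class raster into resource-by-ownership codes
#'
#' Applies, in order: (1) grouping of base land classes into the five
#' foraging resource classes (agriculture, water, marsh, plus "other");
#' (2) recoding of agriculture cells inside intentionally flooded parcels to
#' flooded agriculture; (3) crossing of resource class with ownership to a
#' catalog variable code (MICH-DNR ownership is kept as an ownership-only
#' stratum); (4) recoding of every cell whose centre lies within the
#' no-hunting buffer (default 400 m) of a supplemental feed site to the
#' feed-refuge variable of its ownership, when the catalog defines one.
#' Ownership never changes in step (4) — only the resource component.
#'
#' @param base_classes A `landscape_grid`-shaped object or plain integer
#'   matrix of base class codes, with `origin`/`res_m` attributes taken from
#'   `grid_template` when a bare matrix is given.
#' @param ownership Either a character/integer matrix of ownership labels
#'   aligned with the raster, or a list of polygons (each
#'   `list(owner =, x =, y =)` with ring coordinates in km).  Cells covered
#'   by no polygon become `NODATA`.  Overlaps are resolved by the priority
#'   order CWS > Walpole > MICH-DNR > Michigan > private > public.
#' @param feed_sites Data frame with columns `easting_km`, `northing_km`
#'   (possibly empty).
#' @param flooded_parcels Optional list of polygons (`list(x =, y =)`, km)
#'   whose agriculture cells become flooded agriculture.
#' @param catalog Variable catalog.
#' @param class_map Named integer vector mapping base class codes to the
#'   names `agriculture`, `water`, `marsh`, `other`.
#' @param buffer_m Feed-refuge buffer radius in metres (default 400).
#' @param grid_template Optional `landscape_grid` supplying geometry when
#'   `base_classes` is a bare matrix.
#' @param codes_are Either `"base"` (codes are source land classes to be
#'   grouped via `class_map`) or `"catalog"` (codes are already crossed
#'   catalog variables, e.g. re-running the rules on a finished grid, which
#'   is then a no-op under the same inputs).
#' @return A `landscape_grid` of catalog codes.
#' @export
reclassify <- function(base_classes, ownership, feed_sites = NULL,
                       flooded_parcels = NULL, catalog = default_catalog(),
                       class_map = c(agriculture = 1L, water = 2L,
                                     marsh = 3L, other = 4L),
                       buffer_m = 400, grid_template = NULL,
                       codes_are = c("base", "catalog")) {
  codes_are <- match.arg(codes_are)
  if (inherits(base_classes, "landscape_grid")) {
    geom <- base_classes
    base <- base_classes$codes
  } else {
    if (is.null(grid_template)) {
      stop("a bare base-class matrix needs a grid_template for geometry")
    }
    geom <- grid_template
    base <- base_classes
  }
  if (length(base) == 0) stop("empty raster")
  validate_catalog(catalog)

  # 1. cell codes -> resource class names
  if (codes_are == "catalog") {
    cls_idx <- match(as.vector(base), catalog$code)
    unknown <- setdiff(unique(as.vector(base)),
                       c(catalog$code, CODE_OTHER, CODE_NODATA))
    if (length(unknown)) {
      stop("unknown source class code(s): ",
           paste(sort(unknown), collapse = ", "))
    }
    resource <- catalog$resource_class[cls_idx]
  } else {
    cls_idx <- match(as.vector(base), class_map)
    unknown <- unique(as.vector(base)[is.na(cls_idx) & !is.na(as.vector(base))])
    if (length(unknown)) {
      stop("unknown source class code(s): ",
           paste(sort(unknown), collapse = ", "))
    }
    resource <- names(class_map)[cls_idx]
    resource[resource == "other"] <- NA_character_  # no foraging class
  }

  nr <- nrow(base); nc <- ncol(base)
  cx <- geom$origin[1] + (seq_len(nc) - 0.5) * geom$res_m / 1000
  cy <- geom$origin[2] + (seq_len(nr) - 0.5) * geom$res_m / 1000
  # cell-centre coordinate matrices, column-major like `base`
  xm <- rep(cx, each = nr)
  ym <- rep(cy, times = nc)

  # 2. flooded agriculture parcels
  if (!is.null(flooded_parcels) && length(flooded_parcels)) {
    is_ag <- !is.na(resource) & resource == "agriculture"
    for (p in flooded_parcels) {
      inside <- point_in_polygon(xm, ym, p$x, p$y)
      resource[is_ag & inside] <- "flooded agriculture"
    }
  }

  # 3. ownership per cell
  own <- resolve_ownership(ownership, nr, nc, xm, ym)

  # 4. cross, then feed-refuge buffer (ownership-preserving)
  if (!is.null(feed_sites) && nrow(feed_sites) > 0) {
    ext <- c(geom$origin[1], geom$origin[1] + nc * geom$res_m / 1000,
             geom$origin[2], geom$origin[2] + nr * geom$res_m / 1000)
    if (any(feed_sites$easting_km < ext[1] | feed_sites$easting_km > ext[2] |
            feed_sites$northing_km < ext[3] | feed_sites$northing_km > ext[4])) {
      stop("feed site outside the raster extent")
    }
    buf_km <- buffer_m / 1000
    near <- rep(FALSE, length(xm))
    for (i in seq_len(nrow(feed_sites))) {
      dx <- xm - feed_sites$easting_km[i]
      dy <- ym - feed_sites$northing_km[i]
      near <- near | (dx * dx + dy * dy <= buf_km^2)
    }
    # recode only where the catalog defines a feed-refuge variable for the
    # cell's ownership; NODATA ownership stays NODATA
    has_supp <- own %in%
      catalog$ownership[!is.na(catalog$resource_class) &
                          catalog$resource_class == "supplemental feeding refuge"]
    resource[near & has_supp] <- "supplemental feeding refuge"
  }

  codes <- crossing_code(catalog, resource, own)
  codes[is.na(own)] <- CODE_NODATA
  landscape_grid(matrix(codes, nr, nc), origin = geom$origin,
                 res_m = geom$res_m, catalog = catalog)
}

#' @keywords internal
resolve_ownership <- function(ownership, nr, nc, xm, ym) {
  if (is.matrix(ownership)) {
    stopifnot(nrow(ownership) == nr, ncol(ownership) == nc)
    own <- as.vector(ownership)
    own[own %in% c("", "NODATA")] <- NA_character_
    return(own)
  }
  # polygon list: paint in increasing priority so the highest wins last
  priority <- c("public", "private", "Michigan", "MICH-DNR", "Walpole", "CWS")
  own <- rep(NA_character_, nr * nc)
  owners <- vapply(ownership, function(p) p$owner, character(1))
  ord <- order(match(owners, priority, nomatch = 0L))
  for (p in ownership[ord]) {
    inside <- point_in_polygon(xm, ym, p$x, p$y)
    own[inside] <- p$owner
  }
  own
}

#' Even-odd ray-cast point-in-polygon test
#'
#' Planar even-odd rule on a single ring; points exactly on an edge may fall
#' on either side (raster cell centres are almost never on parcel edges).
#'
#' @param px,py Point coordinates.
#' @param vx,vy Polygon vertex coordinates (ring, closed or open).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py[crosses] - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Per-variable covariate areas within an axis-aligned square
#'
#' Sums the areas (ha) of raster cells whose centres fall inside the
#' half-open square `[x0, x0 + side) x [y0, y0 + side)`.  Membership by cell
#' centre makes adjacent squares partition the raster without double
#' counting.
#'
#' @param grid A `landscape_grid`.
#' @param center Square centre, `c(x, y)` in km.
#' @param side_km Square side length in km.
#' @return Named numeric vector of ha per catalog variable, with attributes
#'   `other_ha`, `nodata_ha`, and `disjoint` (TRUE with a warning when the
#'   square misses the raster entirely).
#' @export
covariate_areas <- function(grid, center, side_km) {
  stopifnot(side_km > 0, length(center) == 2)
  x0 <- center[1] - side_km / 2; x1 <- x0 + side_km
  y0 <- center[2] - side_km / 2; y1 <- y0 + side_km
  cx <- cell_centers_x(grid); cy <- cell_centers_y(grid)
  cols <- which(cx >= x0 & cx < x1)
  rows <- which(cy >= y0 & cy < y1)
  out <- stats::setNames(numeric(nrow(grid$catalog)), grid$catalog$abbrev)
  other <- 0; nodata <- 0
  if (length(cols) == 0 || length(rows) == 0) {
    warning("square is disjoint from the raster extent")
    attr(out, "other_ha") <- 0; attr(out, "nodata_ha") <- 0
    attr(out, "disjoint") <- TRUE
    return(out)
  }
  sub <- grid$codes[rows, cols, drop = FALSE]
  tab <- tabulate(factor(as.vector(sub),
                         levels = c(grid$catalog$code, CODE_OTHER, CODE_NODATA)),
                  nbins = nrow(grid$catalog) + 2L)
  a <- cell_area_ha(grid)
  out[] <- tab[seq_len(nrow(grid$catalog))] * a
  attr(out, "other_ha") <- tab[nrow(grid$catalog) + 1L] * a
  attr(out, "nodata_ha") <- tab[nrow(grid$catalog) + 2L] * a
  attr(out, "disjoint") <- FALSE
  out
}
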