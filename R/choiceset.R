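#' Square analysis (choice) grid
#'
#' The choice grid tiles the plane with square cells of a fixed spacing
#' (default 2.12 km, the cell edge derived from the mean local step length).
#' Cells are indexed by integer (row, col); a point maps to exactly one cell
#' via half-open intervals.
#'
#' @param origin Lower-left anchor `c(x, y)` in km.
#' @param spacing_km Cell edge length in km (default 2.12).
#' @return Object of class `choice_grid`.
#' @export
choice_grid <- function(origin = c(0, 0), spacing_km = 2.12) {
  stopifnot(spacing_km > 0, length(origin) == 2)
  structure(list(origin = as.numeric(origin), spacing_km = spacing_km),
            class = "choice_grid")
}

#' Map points to choice-grid cells, and cells to centres
#'
#' @param cgrid A `choice_grid`.
#' @param x,y Coordinates in km.
#' @return `cell_of()`: data frame of integer `row`, `col`.
#' @export
cell_of <- function(cgrid, x, y) {
  data.frame(row = as.integer(floor((y - cgrid$origin[2]) / cgrid$spacing_km)) + 1L,
             col = as.integer(floor((x - cgrid$origin[1]) / cgrid$spacing_km)) + 1L)
}

#' @rdname cell_of
#' @param row,col Integer cell indices.
#' @export
cell_center <- function(cgrid, row, col) {
  data.frame(x = cgrid$origin[1] + (col - 0.5) * cgrid$spacing_km,
             y = cgrid$origin[2] + (row - 0.5) * cgrid$spacing_km)
}

#' Data-driven availability radius
#'
#' The availability radius is an upper quantile (default the 97.5th
#' percentile) of local-scale step lengths, computed with the
#' linear-interpolation quantile definition.  The unrounded value is used
#' internally; a value rounded to 0.1 km is attached for reporting (the
#' study's radius printed as 9.6 km).
#'
#' @param local_steps Numeric vector of local-scale step lengths (km).
#' @param q Quantile level (default 0.975).
#' @return The unrounded radius (km) with attribute `reported`.
#' @export
availability_radius <- function(local_steps, q = 0.975) {
  if (length(local_steps) < 2) stop("need at least 2 local steps")
  r <- unname(stats::quantile(local_steps, probs = q, type = 7))
  attr(r, "reported") <- round(r, 1)
  r
}

#' Lattice offsets within an availability radius
#'
#' Integer cell offsets `(i, j)` of a square lattice with the given spacing
#' whose centres lie within Euclidean `radius` of a reference centre,
#' `(i^2 + j^2) * spacing^2 <= radius^2`.  `count_available_cells()` is the
#' number of such offsets — the maximum possible choice-set size on an
#' unbounded grid.
#'
#' @param spacing_km Cell spacing (km).
#' @param radius_km Availability radius (km); radius 0 gives only the
#'   reference cell.
#' @return `lattice_offsets()`: 2-column integer matrix (includes `(0,0)`);
#'   `count_available_cells()`: integer count.
#' @export
lattice_offsets <- function(spacing_km, radius_km) {
  stopifnot(spacing_km > 0, radius_km >= 0)
  m <- floor(radius_km / spacing_km)
  ij <- expand.grid(i = -m:m, j = -m:m)
  keep <- (ij$i^2 + ij$j^2) * spacing_km^2 <= radius_km^2
  as.matrix(ij[keep, , drop = FALSE])
}

#' @rdname lattice_offsets
#' @export
count_available_cells <- function(spacing_km, radius_km) {
  nrow(lattice_offsets(spacing_km, radius_km))
}

#' Resource units: per-cell covariate areas over the landscape
#'
#' Intersects the choice grid with the landscape raster and tallies, for
#' every grid cell touching the raster extent, the area (ha) of each catalog
#' variable among raster cells whose centres fall in that grid cell.  A unit
#' is `in_extent` when it contains at least one classified (non-NODATA)
#' raster cell centre.
#'
#' @param cgrid A `choice_grid`.
#' @param landscape A `landscape_grid`.
#' @return Data frame: `unit_id` ("row_col"), `row`, `col`, `center_x`,
#'   `center_y`, `in_extent`, then one ha column per catalog variable.
#' @export
resource_units <- function(cgrid, landscape) {
  cx <- cell_centers_x(landscape)
  cy <- cell_centers_y(landscape)
  nr <- length(cy); ncl <- length(cx)
  col_of <- floor((cx - cgrid$origin[1]) / cgrid$spacing_km) + 1L
  row_of <- floor((cy - cgrid$origin[2]) / cgrid$spacing_km) + 1L
  # unit index per raster cell (column-major over the code matrix)
  urow <- rep(row_of, times = ncl)
  ucol <- rep(col_of, each = nr)
  uid <- paste0(urow, "_", ucol)
  codes <- as.vector(landscape$codes)
  catalog <- landscape$catalog
  lev_units <- unique(uid)
  fu <- factor(uid, levels = lev_units)
  fc <- factor(codes, levels = c(catalog$code, CODE_OTHER, CODE_NODATA))
  tab <- unclass(table(fu, fc))  # plain matrix: units x codes
  a <- cell_area_ha(landscape)
  k <- nrow(catalog)
  cov <- as.matrix(tab[, seq_len(k), drop = FALSE]) * a
  colnames(cov) <- catalog$abbrev
  n_class <- rowSums(tab[, seq_len(k + 1L), drop = FALSE])  # non-NODATA cells
  rc <- do.call(rbind, strsplit(lev_units, "_"))
  out <- data.frame(unit_id = lev_units,
                    row = as.integer(rc[, 1]), col = as.integer(rc[, 2]),
                    stringsAsFactors = FALSE)
  ctr <- cell_center(cgrid, out$row, out$col)
  out$center_x <- ctr$x; out$center_y <- ctr$y
  out$in_extent <- as.vector(n_class) > 0
  cbind(out, as.data.frame(cov))
}

#' Build used/available choice sets
#'
#' For every retained (local-scale) fix: the used unit is the grid cell
#' containing the fix; the available alternatives are all in-extent cells
#' whose centre lies within `radius_km` of the used cell's centre (the used
#' unit always included).  Fixes whose used cell is out of extent are
#' dropped and counted.
#'
#' @param fixes Fix data frame with `retained`, `season`, `diel` columns.
#' @param cgrid A `choice_grid`.
#' @param units Resource-unit table from [resource_units()] (computed from
#'   `landscape` when omitted).
#' @param landscape Optional `landscape_grid` used to derive `units`.
#' @param radius_km Availability radius.
#' @return Long data frame of class `choice_sets`: `choice_set_id`,
#'   `animal_id`, `season`, `diel`, `unit_id`, `used` (0/1), plus one raw-ha
#'   column per variable.  Attribute `n_out_of_extent` counts dropped fixes.
#' @export
build_choice_sets <- function(fixes, cgrid, units = NULL, landscape = NULL,
                              radius_km) {
  stopifnot(radius_km > 0)
  if (is.null(units)) {
    if (is.null(landscape)) stop("supply either units or landscape")
    units <- resource_units(cgrid, landscape)
  }
  keep <- if ("retained" %in% names(fixes)) fixes$retained else rep(TRUE, nrow(fixes))
  f <- fixes[keep, , drop = FALSE]
  var_cols <- setdiff(names(units),
                      c("unit_id", "row", "col", "center_x", "center_y", "in_extent"))
  unit_key <- paste0(units$row, "_", units$col)
  idx <- stats::setNames(seq_len(nrow(units)), unit_key)
  off <- lattice_offsets(cgrid$spacing_km, radius_km)
  cc <- cell_of(cgrid, f$easting_km, f$northing_km)
  used_idx <- unname(idx[paste0(cc$row, "_", cc$col)])
  in_ext <- !is.na(used_idx) & units$in_extent[ifelse(is.na(used_idx), 1L, used_idx)]
  n_out <- sum(!in_ext)
  f <- f[in_ext, , drop = FALSE]
  cc <- cc[in_ext, , drop = FALSE]
  used_idx <- used_idx[in_ext]
  alt_list <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    alt <- idx[paste0(cc$row[i] + off[, "i"], "_", cc$col[i] + off[, "j"])]
    alt <- unname(alt[!is.na(alt)])
    alt_list[[i]] <- alt[units$in_extent[alt]]
  }
  n_alt <- lengths(alt_list)
  set_of_row <- rep(seq_along(alt_list), n_alt)
  alt_rows <- unlist(alt_list, use.names = FALSE)
  cs <- data.frame(
    choice_set_id = set_of_row,
    animal_id = f$animal_id[set_of_row],
    season = if ("season" %in% names(f))
      as.character(f$season)[set_of_row] else NA_character_,
    diel = if ("diel" %in% names(f))
      as.character(f$diel)[set_of_row] else NA_character_,
    unit_id = units$unit_id[alt_rows],
    used = as.integer(alt_rows == used_idx[set_of_row]),
    stringsAsFactors = FALSE)
  cs <- cbind(cs, units[alt_rows, var_cols, drop = FALSE])
  rownames(cs) <- NULL
  attr(cs, "n_out_of_extent") <- n_out
  attr(cs, "variables") <- var_cols
  class(cs) <- c("choice_sets", "data.frame")
  cs
}

#' Pairwise-correlation screening of covariates
#'
#' Removes covariates until all remaining pairwise Pearson correlations are
#' below the threshold in absolute value.  Constant (zero-variance) columns
#' are removed first.  From each offending pair (worst pair first) the
#' lower-priority variable is removed, so that variables of greater
#' biological interest survive.
#'
#' @param X Numeric matrix or data frame of design rows (one stratum).
#' @param threshold Absolute correlation at or above which a pair offends
#'   (default 0.8).
#' @param priority Character vector, highest priority first; defaults to
#'   [default_priority()].
#' @return List: `retained` (column names), `log` (data frame of removals
#'   with the triggering pair and r, or reason "zero variance").
#' @export
screen_correlation <- function(X, threshold = 0.8, priority = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 design rows")
  vars <- colnames(X)
  if (is.null(priority)) priority <- default_priority(vars)
  if (!all(vars %in% priority)) {
    stop("priority list must cover all variables")
  }
  rank_of <- function(v) match(v, priority)
  log <- data.frame(removed = character(0), kept = character(0),
                    r = numeric(0), reason = character(0))
  sds <- apply(X, 2, stats::sd)
  for (v in vars[sds == 0]) {
    log <- rbind(log, data.frame(removed = v, kept = NA, r = NA,
                                 reason = "zero variance"))
  }
  vars <- vars[sds > 0]
  repeat {
    if (length(vars) < 2) break
    r <- stats::cor(X[, vars, drop = FALSE])
    diag(r) <- 0
    if (max(abs(r)) < threshold) break
    worst <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
    a <- vars[worst[1]]; b <- vars[worst[2]]
    drop_v <- if (rank_of(a) > rank_of(b)) a else b
    keep_v <- setdiff(c(a, b), drop_v)
    log <- rbind(log, data.frame(removed = drop_v, kept = keep_v,
                                 r = r[worst[1], worst[2]],
                                 reason = "high correlation"))
    vars <- setdiff(vars, drop_v)
  }
  list(retained = vars, log = log)
}

#' Default removal-priority order for correlation screening
#'
#' Catalog variables in table order but with the marsh variables outranking
#' the water variables (so that, e.g., a federal marsh variable survives a
#' collinear federal water variable); unknown variables are appended last in
#' the order given.
#'
#' @param vars Variable names to order.
#' @return Character vector, highest priority first.
#' @export
default_priority <- function(vars) {
  base <- c("MICH-DNR",
            "PUB-MARSH", "PRI-MARSH", "WAL-MARSH", "CWS-MARSH",
            "PUB-WATER", "PRI-WATER", "WAL-WATER", "MICH-WATER", "CWS-WATER",
            "PRI-FLAG", "PRI-SUPP", "PRI-AGRI", "WAL-AGRI")
  c(intersect(base, vars), setdiff(vars, base))
}

#' Two-standard-deviation covariate standardization
#'
#' Transforms each column to `(x - mean) / (2 * SD)` (sample SD over the
#' stratum's design rows), putting continuous covariates on a scale
#' comparable to binary ones: a standardized column has mean 0 and SD 0.5.
#' Zero-variance columns are flagged and left out of `X_std`.
#'
#' @param X Numeric matrix or data frame of design rows.
#' @param params Optional list with `mean` and `sd` named vectors to reuse
#'   (e.g. from a simulation's ground truth); computed from `X` when NULL.
#' @return List: `X_std`, `params` (`mean`, `sd`), `excluded` (zero-SD
#'   variable names).
#' @export
standardize_2sd <- function(X, params = NULL) {
  X <- as.matrix(X)
  if (is.null(params)) {
    params <- list(mean = colMeans(X), sd = apply(X, 2, stats::sd))
  }
  excluded <- names(params$sd)[params$sd == 0]
  keep <- setdiff(colnames(X), excluded)
  Xs <- sweep(X[, keep, drop = FALSE], 2, params$mean[keep], "-")
  Xs <- sweep(Xs, 2, 2 * params$sd[keep], "/")
  list(X_std = Xs, params = params, excluded = excluded)
}

#' Invert a two-standard-deviation standardization
#'
#' @param X_std Standardized matrix.
#' @param params Parameter list from [standardize_2sd()].
#' @return Matrix on the original scale.
#' @export
unstandardize_2sd <- function(X_std, params) {
  keep <- colnames(X_std)
  X <- sweep(X_std, 2, 2 * params$sd[keep], "*")
  sweep(X, 2, params$mean[keep], "+")
}
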