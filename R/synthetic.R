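#' Configuration for the synthetic landscape and telemetry generator
#'
#' The generator emulates the study conditions: a multi-class raster at
#' 38.7 m resolution whose composition mirrors the published
#' resource-by-ownership area table (agriculture matrix, water-dominated
#' shoreline ownerships, rare federal marsh), supplemental feed sites inside
#' private land, 50-60 individuals carrying transmitters that take 6 or 8
#' fixes per day from late August to the end of January, and a step-length
#' mixture dominated by fine-scale movements with occasional long
#' relocations.  Choices of the next used grid cell are drawn from the
#' mixed conditional-logit model with known coefficients.
#'
#' @param seed Master seed.
#' @param n_animals Number of individuals (default 57, the analysed cohort).
#' @param fixes_per_day Candidate fix rates; each animal is assigned one
#'   (default 6 or 8, the two transmitter programmes).
#' @param start,end Date span of the fix schedule.
#' @param res_m Raster resolution in metres.
#' @param extent_km Side of the square landscape (km).
#' @param patch_cells Edge of the square patches (in raster cells) the class
#'   mosaic is built from.
#' @param composition Named target area shares per catalog variable plus
#'   `other` (defaults mirror the published area table; the feed-refuge
#'   variable is produced by the 400 m buffer, not sampled).
#' @param n_feed_sites Number of supplemental feed sites (private land).
#' @param spacing_km,radius_km Choice-grid spacing and availability radius.
#' @param p_fine,p_reloc Probabilities that a scheduled fix is a fine-scale
#'   or relocation-scale displacement instead of a modelled local choice
#'   (defaults match the observed step-scale mix: roughly 72% fine, 0.2%
#'   relocation).
#' @param fine_km,local_max_km Scale thresholds (km).
#' @param variables Covariate names (catalog abbreviations or `res_*` /
#'   `risk_*` aggregates) carrying the true selection coefficients.
#' @param mu_star,sigma_star True population means and SDs of the
#'   individual coefficients, on the 2-SD-standardized scale.
#' @param anchor Availability used when generating a local choice:
#'   `"previous"` (units within `radius_km` of the current cell — a movement
#'   process) or `"global"` (all in-extent units; distance-free, so any
#'   destination-anchored subset the analysis conditions on retains exact
#'   logit probabilities).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_animals = 57, fixes_per_day = c(6, 8),
                       start = "2015-08-30", end = "2016-01-31",
                       res_m = 38.7, extent_km = 30, patch_cells = 12,
                       composition = default_composition(),
                       n_feed_sites = 12, spacing_km = 2.12, radius_km = 9.6,
                       p_fine = 0.72, p_reloc = 0.002,
                       fine_km = 0.33, local_max_km = 25,
                       variables = c("res_water", "res_marsh"),
                       mu_star = c(1.0, -0.5), sigma_star = c(0.3, 0.3),
                       anchor = c("previous", "global")) {
  anchor <- match.arg(anchor)
  stopifnot(p_fine + p_reloc <= 1, all(sigma_star >= 0),
            length(mu_star) == length(variables),
            length(sigma_star) == length(mu_star),
            abs(sum(composition) - 1) < 1e-8)
  if (extent_km < 2 * radius_km && anchor == "previous") {
    stop("landscape extent must contain the availability radius (extent >= 2 * radius)")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Default landscape composition (area shares)
#'
#' Shares proportional to the published per-variable areas, scaled to leave
#' a 5% unclassified ("other") share; the supplemental feed refuge is
#' created by the buffer rule rather than sampled.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_composition <- function() {
  ha <- c("MICH-DNR" = 4548.95, "PUB-WATER" = 77796.36, "PRI-WATER" = 9904.84,
          "WAL-WATER" = 1325.88, "MICH-WATER" = 27759.99, "PUB-MARSH" = 201.55,
          "PRI-MARSH" = 2448.56, "WAL-MARSH" = 6307.78, "CWS-MARSH" = 308.40,
          "CWS-WATER" = 20.26, "PRI-FLAG" = 167.93, "PRI-AGRI" = 161110.09,
          "WAL-AGRI" = 3899.30)
  shares <- 0.95 * ha / sum(ha)
  c(shares, other = 0.05)
}

#' @keywords internal
largest_remainder <- function(shares, n) {
  # integer apportionment of n blocks to target shares; every positive
  # share gets at least one block
  raw <- shares * n
  base <- floor(raw)
  base[shares > 0 & base == 0] <- 1
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(base - raw, decreasing = TRUE)
    i <- 1L
    while (rem < 0 && i <= length(ord)) {
      if (base[ord[i]] > 1) { base[ord[i]] <- base[ord[i]] - 1; rem <- rem + 1 }
      i <- i + 1L
    }
  }
  as.integer(base)
}

#' Generate a synthetic classified landscape
#'
#' Builds a random patch mosaic: the extent is tiled with square patches of
#' `patch_cells` raster cells, each patch is assigned a catalog variable (or
#' "other") so that patch counts match the target composition exactly
#' (largest-remainder apportionment, random placement), and the implied
#' base-class / ownership / flooded-parcel / feed-site inputs are fed
#' through [reclassify()] so the emitted grid exercises the same path as
#' real inputs.  Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `landscape` (a `landscape_grid`), `catalog`, plus the
#'   generator's inputs (`base`, `ownership`, `feed_sites`,
#'   `flooded_parcels`) for reuse in tests.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  catalog <- default_catalog()
  nr <- nc <- as.integer(round(cfg$extent_km * 1000 / cfg$res_m))
  bs <- cfg$patch_cells
  nbr <- ceiling(nr / bs); nbc <- ceiling(nc / bs)
  nb <- nbr * nbc
  counts <- largest_remainder(cfg$composition, nb)
  labels <- sample(rep(names(cfg$composition), counts))
  block_lab <- matrix(labels, nbr, nbc)
  row_block <- ((seq_len(nr) - 1L) %/% bs) + 1L
  col_block <- ((seq_len(nc) - 1L) %/% bs) + 1L
  cell_lab <- block_lab[row_block, col_block, drop = FALSE]

  idx <- match(cell_lab, catalog$abbrev)
  res_cls <- catalog$resource_class[idx]
  own <- catalog$ownership[idx]
  own[cell_lab == "other"] <- "public"
  # flooded agriculture enters as agriculture plus parcel polygons
  base_name <- res_cls
  base_name[is.na(idx)] <- "other"                    # "other" blocks
  base_name[cell_lab == "MICH-DNR"] <- "other"        # ownership-only stratum
  base_name[!is.na(base_name) &
              base_name == "flooded agriculture"] <- "agriculture"
  class_map <- c(agriculture = 1L, water = 2L, marsh = 3L, other = 4L)
  base <- matrix(class_map[ifelse(is.na(base_name), "other", base_name)], nr, nc)

  res_km <- cfg$res_m / 1000
  flooded_parcels <- list()
  flag_blocks <- which(block_lab == "PRI-FLAG")
  for (b in flag_blocks) {
    br <- (b - 1L) %% nbr + 1L; bc <- (b - 1L) %/% nbr + 1L
    x0 <- (bc - 1L) * bs * res_km; y0 <- (br - 1L) * bs * res_km
    x1 <- min(bc * bs, nc) * res_km; y1 <- min(br * bs, nr) * res_km
    flooded_parcels[[length(flooded_parcels) + 1L]] <-
      list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }

  # feed sites on private land, away from the border
  priv <- which(matrix(own, nr, nc) == "private", arr.ind = TRUE)
  margin <- ceiling(0.4 / res_km)
  priv <- priv[priv[, 1] > margin & priv[, 1] < nr - margin &
                 priv[, 2] > margin & priv[, 2] < nc - margin, , drop = FALSE]
  pick <- priv[sample(nrow(priv), min(cfg$n_feed_sites, nrow(priv))), ,
               drop = FALSE]
  feed_sites <- data.frame(easting_km = (pick[, 2] - 0.5) * res_km,
                           northing_km = (pick[, 1] - 0.5) * res_km)

  template <- landscape_grid(matrix(CODE_OTHER, nr, nc), origin = c(0, 0),
                             res_m = cfg$res_m, catalog = catalog)
  landscape <- reclassify(base, ownership = matrix(own, nr, nc),
                          feed_sites = feed_sites,
                          flooded_parcels = flooded_parcels,
                          catalog = catalog, class_map = class_map,
                          grid_template = template)
  list(landscape = landscape, catalog = catalog, base = base,
       ownership = matrix(own, nr, nc), feed_sites = feed_sites,
       flooded_parcels = flooded_parcels)
}

#' @keywords internal
#' Build the per-unit model design (possibly aggregate variables) for the
#' simulator, on the raw hectare scale.
unit_design <- function(units, variables, catalog) {
  cols <- lapply(variables, function(v) {
    if (v %in% names(units)) return(units[[v]])
    if (startsWith(v, "res_")) {
      cl <- gsub("_", " ", sub("^res_", "", v))
      members <- catalog$abbrev[!is.na(catalog$resource_class) &
                                  catalog$resource_class == cl]
    } else if (startsWith(v, "risk_")) {
      members <- catalog$abbrev[catalog$risk_tier == sub("^risk_", "", v)]
    } else stop("unknown simulator variable: ", v)
    rowSums(units[, intersect(members, names(units)), drop = FALSE])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- variables
  X
}

#' Simulate GPS trajectories from the mixed-logit choice model
#'
#' Each animal receives coefficients `b_i ~ Normal(mu_star, sigma_star^2)`
#' on the 2-SD-standardized unit-covariate scale (standardization over all
#' in-extent units).  At every scheduled fix time the animal either makes a
#' fine-scale or relocation-scale displacement (with the configured
#' probabilities; these movements are noise to the selection model) or
#' draws its next used unit from the conditional-logit probabilities over
#' the available units, then lands uniformly inside the chosen cell.
#'
#' @param cfg A [sim_config()].
#' @param ls A landscape bundle from [generate_landscape()] (generated from
#'   `cfg` when omitted).
#' @return List of class `sim_result`: `fixes` (fix data frame), `truth`
#'   (`mu_star`, `sigma_star`, `beta` matrix, `std_params`, `chosen` record
#'   of modelled choices), `units`, `cgrid`.
#' @export
simulate_trajectories <- function(cfg, ls = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(ls)) ls <- generate_landscape(cfg)
  set.seed(cfg$seed + 1L)
  landscape <- ls$landscape
  catalog <- landscape$catalog
  cgrid <- choice_grid(origin = landscape$origin, spacing_km = cfg$spacing_km)
  units <- resource_units(cgrid, landscape)
  inx <- which(units$in_extent)
  Xraw <- unit_design(units, cfg$variables, catalog)
  std <- standardize_2sd(Xraw[inx, , drop = FALSE])
  if (length(std$excluded)) {
    stop("simulator variable has zero variance over units: ",
         paste(std$excluded, collapse = ", "))
  }
  Z <- matrix(0, nrow(units), ncol(Xraw))
  Z[inx, ] <- std$X_std
  K <- length(cfg$mu_star)
  I <- cfg$n_animals
  beta <- matrix(stats::rnorm(I * K, rep(cfg$mu_star, each = I),
                              rep(cfg$sigma_star, each = I)), I, K)

  off <- lattice_offsets(cfg$spacing_km, cfg$radius_km)
  key <- paste0(units$row, "_", units$col)
  idx <- stats::setNames(seq_len(nrow(units)), key)
  avail_of <- function(u) {
    if (cfg$anchor == "global") return(inx)
    a <- idx[paste0(units$row[u] + off[, "i"], "_", units$col[u] + off[, "j"])]
    a <- unname(a[!is.na(a)])
    a[units$in_extent[a]]
  }

  start_t <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  end_t <- as.POSIXct(paste(cfg$end, "23:59:59"), tz = "UTC")
  ext <- grid_extent(landscape)
  fixes_list <- vector("list", I)
  chosen_list <- vector("list", I)
  for (i in seq_len(I)) {
    fpd <- if (length(cfg$fixes_per_day) > 1)
      sample(cfg$fixes_per_day, 1) else cfg$fixes_per_day
    times <- seq(start_t + stats::runif(1, 0, 86400 / fpd), end_t,
                 by = 86400 / fpd)
    nt <- length(times)
    u <- sample(inx, 1)
    pos <- c(units$center_x[u], units$center_y[u]) +
      stats::runif(2, -0.5, 0.5) * cfg$spacing_km
    xs <- numeric(nt); ys <- numeric(nt)
    ch_t <- ch_u <- integer(0)
    xs[1] <- pos[1]; ys[1] <- pos[2]
    for (t in 2:nt) {
      move <- stats::runif(1)
      if (move < cfg$p_fine) {
        ang <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, 0.005, cfg$fine_km * 0.95)
        pos <- pos + r * c(cos(ang), sin(ang))
      } else if (move < cfg$p_fine + cfg$p_reloc) {
        ang <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, cfg$local_max_km * 1.02, cfg$local_max_km * 1.6)
        pos <- pos + r * c(cos(ang), sin(ang))
      } else {
        cur <- cell_of(cgrid, pos[1], pos[2])
        cu <- idx[paste0(cur$row, "_", cur$col)]
        avail <- if (!is.na(cu)) avail_of(unname(cu)) else integer(0)
        if (!length(avail)) avail <- inx  # off-layer: return to the study area
        w <- Z[avail, , drop = FALSE] %*% beta[i, ]
        p <- exp(w - max(w)); p <- p / sum(p)
        u <- avail[sample.int(length(avail), 1, prob = p)]
        pos <- c(units$center_x[u], units$center_y[u]) +
          stats::runif(2, -0.5, 0.5) * cfg$spacing_km
        ch_t <- c(ch_t, t); ch_u <- c(ch_u, u)
      }
      xs[t] <- pos[1]; ys[t] <- pos[2]
    }
    fixes_list[[i]] <- data.frame(
      animal_id = sprintf("A%03d", i), timestamp = times,
      easting_km = xs, northing_km = ys, stringsAsFactors = FALSE)
    chosen_list[[i]] <- if (length(ch_t)) data.frame(
      animal_id = sprintf("A%03d", i), fix_index = ch_t,
      unit_id = units$unit_id[ch_u], stringsAsFactors = FALSE) else NULL
  }
  fixes <- do.call(rbind, fixes_list)
  truth <- list(mu_star = stats::setNames(cfg$mu_star, cfg$variables),
                sigma_star = stats::setNames(cfg$sigma_star, cfg$variables),
                beta = beta, std_params = std$params,
                chosen = do.call(rbind, chosen_list))
  structure(list(fixes = fixes, truth = truth, units = units, cgrid = cgrid,
                 landscape = landscape),
            class = "sim_result")
}

#' Write simulator ground truth as JSON
#'
#' @param truth The `truth` element of a [simulate_trajectories()] result.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(mu_star = as.list(truth$mu_star),
         sigma_star = as.list(truth$sigma_star),
         std_mean = as.list(truth$std_params$mean),
         std_sd = as.list(truth$std_params$sd)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
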