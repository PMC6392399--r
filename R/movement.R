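#' Filter ledger: accounting for every removed fix
#'
#' The movement filter removes, in order: fine-scale steps, relocation-scale
#' steps (leaving local-scale movements), and destinations outside the
#' spatial layer.  The ledger records those counts and enforces the
#' conservation identities `local = total - fine - relocation` and
#' `final = local - out_of_extent`.
#'
#' @param total Total steps (fixes with a measured incoming movement).
#' @param fine,relocation,out_of_extent Removal counts.
#' @param censored_initial Fixes removed by the post-release censor.
#' @return An object of class `filter_ledger`.
#' @export
filter_ledger <- function(total, fine, relocation, out_of_extent = 0,
                          censored_initial = 0) {
  local <- total - fine - relocation
  final <- local - out_of_extent
  if (local < 0 || final < 0) stop("ledger counts are inconsistent")
  structure(
    list(total = total, censored_initial = censored_initial, fine = fine,
         relocation = relocation, local = local,
         out_of_extent = out_of_extent, final = final),
    class = "filter_ledger"
  )
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("<filter_ledger>\n")
  cat(sprintf("  censored (post-release): %d fixes\n", x$censored_initial))
  cat(sprintf("  steps total: %d\n", x$total))
  cat(sprintf("  - fine scale: %d\n  - relocation scale: %d\n", x$fine, x$relocation))
  cat(sprintf("  = local scale: %d\n", x$local))
  cat(sprintf("  - out of extent: %d\n  = final: %d\n", x$out_of_extent, x$final))
  invisible(x)
}

#' Censor the post-release recovery period
#'
#' Drops each animal's fixes taken within `days` (96 h by default) of its
#' first fix, the recovery window after capture and transmitter attachment.
#' Animals left with no fixes are removed entirely and counted.
#'
#' @param fixes Fix data frame (`animal_id`, `timestamp`, coordinates).
#' @param days Length of the censor window in days.
#' @return A list: `fixes` (retained), `n_censored` (fixes removed),
#'   `animals_dropped` (ids with no remaining fixes), `n_animals` left.
#' @export
censor_initial <- function(fixes, days = 4) {
  if (nrow(fixes) == 0) {
    return(list(fixes = fixes, n_censored = 0L,
                animals_dropped = character(0), n_animals = 0L))
  }
  fixes <- validate_fixes(fixes)
  first <- stats::ave(as.numeric(fixes$timestamp), fixes$animal_id, FUN = min)
  keep <- as.numeric(fixes$timestamp) >= first + days * 86400
  out <- fixes[keep, , drop = FALSE]
  dropped <- setdiff(unique(fixes$animal_id), unique(out$animal_id))
  list(fixes = out, n_censored = sum(!keep), animals_dropped = dropped,
       n_animals = length(unique(out$animal_id)))
}

#' Diel classification by legal shooting time
#'
#' A fix is diurnal when it falls between 30 minutes before sunrise and 30
#' minutes after sunset (the legal shooting window), nocturnal otherwise.
#'
#' @param fixes Fix data frame.
#' @param lat,lon Reference coordinates (decimal degrees) for solar times;
#'   defaults to the Lake St. Clair study region.
#' @param solar A provider `function(date, lat, lon)` returning a data frame
#'   with `sunrise`/`sunset` POSIXct columns; defaults to [solar_times()].
#' @param margin_min Shoulder width in minutes (default 30).
#' @return `fixes` with a `diel` factor column (`diurnal`/`nocturnal`).
#' @export
classify_diel <- function(fixes, lat = 42.47, lon = -82.66,
                          solar = solar_times, margin_min = 30) {
  if (nrow(fixes) == 0) {
    fixes$diel <- factor(character(0), levels = c("diurnal", "nocturnal"))
    return(fixes)
  }
  st <- solar(as.Date(fixes$timestamp, tz = "UTC"), lat, lon)
  diurnal <- fixes$timestamp >= st$sunrise - margin_min * 60 &
    fixes$timestamp <= st$sunset + margin_min * 60
  fixes$diel <- factor(ifelse(diurnal, "diurnal", "nocturnal"),
                       levels = c("diurnal", "nocturnal"))
  fixes
}

#' Default hunting-season calendar windows
#'
#' The four analysis seasons over the two monitoring years, anchored to the
#' 106-day southern-Ontario duck season: PRE (before opening), FIRST and
#' SECOND halves of the open season, and POST (after closing, to 31 Jan).
#' All windows are inclusive of both endpoint dates.
#'
#' @return Data frame with columns `season`, `start`, `end` (Date).
#' @export
default_season_windows <- function() {
  w <- rbind(
    c("PRE",    "2014-08-27", "2014-09-26"),
    c("PRE",    "2015-08-30", "2015-09-25"),
    c("FIRST",  "2014-09-27", "2014-11-18"),
    c("FIRST",  "2015-09-26", "2015-11-17"),
    c("SECOND", "2014-11-19", "2015-01-10"),
    c("SECOND", "2015-11-18", "2016-01-09"),
    c("POST",   "2015-01-11", "2015-01-31"),
    c("POST",   "2016-01-10", "2016-01-31")
  )
  data.frame(season = w[, 1], start = as.Date(w[, 2]), end = as.Date(w[, 3]),
             stringsAsFactors = FALSE)
}

#' Assign hunting-season labels to timestamps
#'
#' @param timestamps POSIXct (UTC) or Date vector.
#' @param windows Season windows as from [default_season_windows()].
#' @param tz Time zone whose calendar dates the windows refer to.
#' @return Factor with levels PRE, FIRST, SECOND, POST, out_of_window.
#' @export
assign_season <- function(timestamps, windows = default_season_windows(),
                          tz = "UTC") {
  d <- as.Date(timestamps, tz = tz)
  lab <- rep("out_of_window", length(d))
  for (i in seq_len(nrow(windows))) {
    hit <- !is.na(d) & d >= windows$start[i] & d <= windows$end[i]
    lab[hit] <- windows$season[i]
  }
  factor(lab, levels = c("PRE", "FIRST", "SECOND", "POST", "out_of_window"))
}

#' Step lengths and movement-scale classification
#'
#' Builds consecutive-fix steps per animal, classifies each step length as
#' fine (< `fine_km`), local (in `[fine_km, local_max_km]`) or relocation
#' (> `local_max_km`), and flags each fix as retained for the selection
#' analysis when its *incoming* step is local scale.  Boundary lengths equal
#' to a threshold are classed local (closed interval).
#'
#' @param fixes Fix data frame (time-sorted per animal).
#' @param fine_km Upper bound of fine-scale movements (default 0.33 km).
#' @param local_max_km Upper bound of local movements (default 25 km).
#' @return A list: `steps` (data frame `animal_id`, `from`, `to` row indices
#'   into `fixes`, `length_km`, `scale`), `fixes` with a logical `retained`
#'   column, and `ledger` (a [filter_ledger()] with `out_of_extent = 0`).
#' @export
steps_and_scales <- function(fixes, fine_km = 0.33, local_max_km = 25) {
  fixes <- validate_fixes(fixes)
  n <- nrow(fixes)
  if (n == 0) {
    return(list(steps = data.frame(), fixes = fixes,
                ledger = filter_ledger(0, 0, 0)))
  }
  same <- c(FALSE, fixes$animal_id[-1] == fixes$animal_id[-n])
  to <- which(same)
  from <- to - 1L
  len <- sqrt((fixes$easting_km[to] - fixes$easting_km[from])^2 +
                (fixes$northing_km[to] - fixes$northing_km[from])^2)
  scale <- ifelse(len < fine_km, "fine",
                  ifelse(len > local_max_km, "relocation", "local"))
  steps <- data.frame(animal_id = fixes$animal_id[to], from = from, to = to,
                      length_km = len,
                      scale = factor(scale,
                                     levels = c("fine", "local", "relocation")))
  fixes$retained <- FALSE
  fixes$retained[to[scale == "local"]] <- TRUE
  ledger <- filter_ledger(total = nrow(steps),
                          fine = sum(scale == "fine"),
                          relocation = sum(scale == "relocation"))
  list(steps = steps, fixes = fixes, ledger = ledger)
}

#' @keywords internal
#' Half-even rounding to 2 decimals with trailing zeros trimmed ("37.90" ->
#' "37.9"), the convention of the descriptive summary table.
fmt_trim <- function(x) {
  s <- sprintf("%.2f", round(x, 2))
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Descriptive statistics by season and diel period
#'
#' For each season-by-diel stratum: number of distinct animals (`IDs`),
#' total fixes (`N`), mean fixes per individual (`N/IDs`, reported half-even
#' rounded to two decimals with trailing zeros trimmed), the sample SD of
#' per-animal fix counts (0 when only one animal), and the min-max range.
#'
#' @param fixes Fix data frame with `season` and `diel` columns.
#' @param seasons Season levels to tabulate (default the four study seasons).
#' @return Data frame, one row per stratum.
#' @export
descriptive_table <- function(fixes,
                              seasons = c("PRE", "FIRST", "SECOND", "POST")) {
  out <- list()
  for (s in seasons) for (dl in c("diurnal", "nocturnal")) {
    sub <- fixes[fixes$season == s & fixes$diel == dl, , drop = FALSE]
    if (nrow(sub) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        season = s, diel = dl, IDs = 0L, N = 0L, mean_fixes = 0,
        mean_label = "0", sd_fixes = 0, range = "0-0")
      next
    }
    cnt <- table(sub$animal_id)
    cnt <- cnt[cnt > 0]
    m <- nrow(sub) / length(cnt)
    sdv <- if (length(cnt) > 1) stats::sd(as.numeric(cnt)) else 0
    out[[length(out) + 1L]] <- data.frame(
      season = s, diel = dl, IDs = length(cnt), N = nrow(sub),
      mean_fixes = m, mean_label = fmt_trim(m), sd_fixes = round(sdv, 2),
      range = paste0(min(cnt), "-", max(cnt)))
  }
  do.call(rbind, out)
}
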