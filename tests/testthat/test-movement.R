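test_that("the post-release censor removes the recovery window", {
  f <- walk_fixes(rep(0.1, 80), dt_hours = 3)  # 10 days of fixes
  out <- censor_initial(f, days = 4)
  expect_true(all(out$fixes$timestamp >= f$timestamp[1] + 4 * 86400))
  expect_equal(out$n_censored, sum(f$timestamp < f$timestamp[1] + 4 * 86400))
  expect_equal(nrow(out$fixes) + out$n_censored, nrow(f))
  # days = 0 is the identity
  out0 <- censor_initial(f, days = 0)
  expect_equal(nrow(out0$fixes), nrow(f))
  expect_equal(out0$n_censored, 0L)
})

test_that("animals whose transmitters fail inside the window are dropped", {
  long <- walk_fixes(rep(0.1, 60), id = "ok")
  short <- walk_fixes(rep(0.1, 5), id = "early")  # all fixes in 18 h
  out <- censor_initial(rbind(long, short), days = 4)
  expect_equal(out$animals_dropped, "early")
  expect_equal(out$n_animals, 1L)
})

test_that("a marked cohort of 59 with 2 early failures leaves 57 analysed", {
  cohort <- do.call(rbind, lapply(1:59, function(i) {
    n <- if (i <= 2) 10L else 80L  # 2 transmitters die within 4 days
    walk_fixes(rep(0.05, n), id = sprintf("D%02d", i), dt_hours = 3)
  }))
  out <- censor_initial(cohort, days = 4)
  expect_equal(length(out$animals_dropped), 2L)
  expect_equal(out$n_animals, 57L)
})

test_that("diel boundaries follow the 30-minute shooting-time shoulders", {
  mk <- function(min_offset, anchor_h) {
    data.frame(animal_id = "A1",
               timestamp = as.POSIXct("2015-10-10 00:00:00", tz = "UTC") +
                 anchor_h * 3600 + min_offset * 60,
               easting_km = 0, northing_km = 0)
  }
  lab <- function(f) as.character(classify_diel(f, solar = fixed_solar)$diel)
  expect_equal(lab(mk(-31, 6)), "nocturnal")  # 31 min before sunrise
  expect_equal(lab(mk(-29, 6)), "diurnal")    # 29 min before sunrise
  expect_equal(lab(mk(0, 12)), "diurnal")     # solar noon
  expect_equal(lab(mk(29, 18)), "diurnal")    # 29 min after sunset
  expect_equal(lab(mk(31, 18)), "nocturnal")
})

test_that("sunrise/sunset inversion agrees with elevation root-finding", {
  lat <- 42.3; lon <- -82.5
  dates <- seq(as.Date("2015-02-01"), as.Date("2016-01-20"), by = 21)
  st <- solar_times(dates, lat, lon)
  for (i in seq_along(dates)) {
    midnight <- as.POSIXct(paste(dates[i], "00:00:00"), tz = "UTC")
    f <- function(h) solar_elevation(midnight + h * 3600, lat, lon) + 0.833
    # sunrise root in the local-morning window, sunset in the evening
    rise <- stats::uniroot(f, c(6, 15))$root    # UTC hours (UTC-5 zone)
    set <- stats::uniroot(f, c(15, 27))$root
    expect_lt(abs(as.numeric(st$sunrise[i] - midnight, units = "hours") - rise),
              2 / 60)
    expect_lt(abs(as.numeric(st$sunset[i] - midnight, units = "hours") - set),
              2 / 60)
  }
  # day length ordering: summer solstice > equinox > winter solstice
  dl <- function(d) as.numeric(solar_times(d, lat, lon)$sunset -
                                 solar_times(d, lat, lon)$sunrise,
                               units = "hours")
  expect_gt(dl("2015-06-21"), dl("2015-09-22"))
  expect_gt(dl("2015-09-22"), dl("2015-12-21"))
  expect_error(solar_times("2015-12-21", lat = 80, lon = 0), "polar")
})

test_that("diel labels over a year match an independent rule evaluation", {
  set.seed(21)
  days <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = 5)
  f <- data.frame(
    animal_id = "A1",
    timestamp = as.POSIXct(paste(days, "00:00:00"), tz = "UTC") +
      sort(sample(0:86399, length(days))) %% 86400 +
      seq_along(days) * 0,  # keep strictly increasing via the date spacing
    easting_km = 0, northing_km = 0)
  f <- f[order(f$timestamp), ]
  got <- classify_diel(f, lat = 42.3, lon = -82.5)$diel
  st <- solar_times(as.Date(f$timestamp, tz = "UTC"), 42.3, -82.5)
  want <- ifelse(f$timestamp >= st$sunrise - 1800 &
                   f$timestamp <= st$sunset + 1800, "diurnal", "nocturnal")
  expect_equal(as.character(got), want)
})

test_that("season windows map dates from both study years", {
  s <- function(x) as.character(assign_season(as.POSIXct(x, tz = "UTC")))
  expect_equal(s("2015-10-01 12:00:00"), "FIRST")
  expect_equal(s("2016-01-15 12:00:00"), "POST")
  expect_equal(s("2015-02-15 12:00:00"), "out_of_window")
  expect_equal(s("2014-08-27 00:30:00"), "PRE")    # first day inclusive
  expect_equal(s("2016-01-31 23:00:00"), "POST")   # last day inclusive
  expect_equal(s("2014-11-18 12:00:00"), "FIRST")
  expect_equal(s("2014-11-19 12:00:00"), "SECOND")
})

test_that("step scales follow the thresholds with closed local bounds", {
  f <- walk_fixes(c(0.2, 9.6, 30, 0.33, 25, 2))
  out <- steps_and_scales(f)
  expect_equal(as.character(out$steps$scale),
               c("fine", "local", "relocation", "local", "local", "local"))
  expect_equal(out$steps$length_km, c(0.2, 9.6, 30, 0.33, 25, 2))
  # retention keyed to the incoming step
  expect_equal(which(out$fixes$retained), c(3, 5, 6, 7))
  expect_true(out$ledger$total == out$ledger$fine +
                out$ledger$relocation + out$ledger$local)
})

test_that("scale classification is invariant to rotation and translation", {
  set.seed(9)
  n <- 40
  f <- data.frame(animal_id = "A1",
                  timestamp = as.POSIXct("2015-10-01", tz = "UTC") +
                    (1:n) * 3600,
                  easting_km = cumsum(rnorm(n, 0, 3)),
                  northing_km = cumsum(rnorm(n, 0, 3)))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- as.matrix(f[, c("easting_km", "northing_km")]) %*% R
  g <- f; g$easting_km <- xy[, 1] + 100; g$northing_km <- xy[, 2] - 50
  expect_equal(as.character(steps_and_scales(g)$steps$scale),
               as.character(steps_and_scales(f)$steps$scale))
})

test_that("ledger conservation holds on simulated mixtures", {
  set.seed(4)
  for (rep in 1:5) {
    lengths <- sample(c(runif(30, 0, 0.32), runif(40, 0.34, 24), runif(5, 26, 40)))
    out <- steps_and_scales(walk_fixes(lengths))
    l <- out$ledger
    expect_equal(l$total, l$fine + l$relocation + l$local)
    expect_equal(l$local, sum(lengths >= 0.33 & lengths <= 25))
    expect_equal(l$final, l$local - l$out_of_extent)
  }
})

test_that("descriptive means reproduce the printed-table arithmetic", {
  # the published strata: mean = N / IDs at printed precision
  expect_equal(duckchoice:::fmt_trim(1724 / 57), "30.25")
  expect_equal(duckchoice:::fmt_trim(1895 / 50), "37.9")
  expect_equal(duckchoice:::fmt_trim(242 / 19), "12.74")
  # a single animal with k fixes: mean k, SD reported 0, degenerate range
  f <- data.frame(animal_id = "A1", season = "PRE", diel = "diurnal")
  f <- f[rep(1, 7), ]
  tb <- descriptive_table(f, seasons = "PRE")
  row <- tb[tb$diel == "diurnal", ]
  expect_equal(row$IDs, 1L)
  expect_equal(row$mean_label, "7")
  expect_equal(row$sd_fixes, 0)
  expect_equal(row$range, "7-7")
})

test_that("descriptive table aggregates strata correctly", {
  set.seed(14)
  f <- do.call(rbind, lapply(1:6, function(i) {
    k <- sample(3:12, 1)
    data.frame(animal_id = sprintf("A%d", i),
               season = "FIRST",
               diel = sample(c("diurnal", "nocturnal"), k, replace = TRUE))
  }))
  tb <- descriptive_table(f, seasons = "FIRST")
  for (dl in c("diurnal", "nocturnal")) {
    sub <- f[f$diel == dl, ]
    row <- tb[tb$diel == dl, ]
    expect_equal(row$N, nrow(sub))
    expect_equal(row$IDs, length(unique(sub$animal_id)))
    expect_equal(row$mean_fixes, nrow(sub) / length(unique(sub$animal_id)))
    expect_equal(row$sd_fixes,
                 round(sd(as.numeric(table(sub$animal_id))), 2))
  }
})
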