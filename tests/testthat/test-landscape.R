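test_that("default catalog satisfies its invariants", {
  cat <- default_catalog()
  expect_silent(validate_catalog(cat))
  expect_equal(nrow(cat), 14)
  expect_equal(anyDuplicated(cat$abbrev), 0)
  expect_equal(cat$risk_tier[cat$abbrev == "PUB-WATER"], "high")
  expect_equal(cat$risk_tier[cat$abbrev == "CWS-MARSH"], "none")
  expect_true(all(cat$risk_tier[cat$ownership %in%
                                  c("private", "Walpole", "MICH-DNR")] ==
                    "intermediate"))
  expect_equal(cat$risk_tier[cat$abbrev == "PRI-SUPP"], "intermediate")
})

test_that("crossing maps resource x ownership to catalog codes", {
  cat <- default_catalog()
  expect_equal(crossing_code(cat, "marsh", "CWS"),
               cat$code[cat$abbrev == "CWS-MARSH"])
  # ownership-only stratum swallows every resource class
  expect_equal(crossing_code(cat, c("marsh", "water", NA),
                             rep("MICH-DNR", 3)),
               rep(cat$code[cat$abbrev == "MICH-DNR"], 3))
  # unregistered crossing falls through to OTHER
  expect_equal(crossing_code(cat, "agriculture", "CWS"), 0L)
})

test_that("reclassify crosses classes with ownership and rejects bad codes", {
  tpl <- flat_landscape(n = 20)
  base <- matrix(3L, 20, 20)  # marsh
  own <- matrix("CWS", 20, 20)
  g <- reclassify(base, own, grid_template = tpl)
  cat <- g$catalog
  expect_true(all(g$codes == cat$code[cat$abbrev == "CWS-MARSH"]))

  bad <- base; bad[5, 5] <- 99L
  expect_error(reclassify(bad, own, grid_template = tpl), "99")
  expect_error(reclassify(matrix(integer(0), 0, 0), own, grid_template = tpl),
               "empty")
})

test_that("the feed buffer recodes by centre distance and keeps ownership", {
  tpl <- landscape_grid(matrix(0L, 41, 41), origin = c(0, 0), res_m = 100)
  base <- matrix(1L, 41, 41)                    # agriculture
  own <- matrix("private", 41, 41)
  # site 1 m east of the centre of cell (21, 21), so the centres of cells 4
  # and 5 columns east sit 399 m and 499 m away: just inside / outside
  sites <- data.frame(easting_km = 2.051, northing_km = 2.05)
  g <- reclassify(base, own, feed_sites = sites, grid_template = tpl)
  cat <- g$catalog
  supp <- cat$code[cat$abbrev == "PRI-SUPP"]
  agri <- cat$code[cat$abbrev == "PRI-AGRI"]
  expect_equal(g$codes[21, 25], supp)   # 399 m east
  expect_equal(g$codes[21, 26], agri)   # 499 m east
  # brute-force count of centres within 400 m
  cx <- (col(base) - 0.5) * 0.1; cy <- (row(base) - 0.5) * 0.1
  inside <- (cx - 2.051)^2 + (cy - 2.05)^2 <= 0.4^2
  expect_equal(sum(g$codes == supp), sum(inside))
})

test_that("feed buffer at 38.7 m resolution matches a brute-force scan", {
  tpl <- flat_landscape(n = 100)
  base <- matrix(2L, 100, 100)  # water
  own <- matrix("private", 100, 100)
  ctr <- 100 * 38.7 / 1000 / 2
  sites <- data.frame(easting_km = ctr, northing_km = ctr)
  g <- reclassify(base, own, feed_sites = sites, grid_template = tpl)
  supp <- g$catalog$code[g$catalog$abbrev == "PRI-SUPP"]
  cx <- (col(base) - 0.5) * 0.0387; cy <- (row(base) - 0.5) * 0.0387
  expect_equal(sum(g$codes == supp),
               sum((cx - ctr)^2 + (cy - ctr)^2 <= 0.4^2))
})

test_that("reclassify is idempotent and flooded parcels recode agriculture only", {
  tpl <- flat_landscape(n = 30)
  set.seed(7)
  base <- matrix(sample(1:4, 900, replace = TRUE), 30, 30)
  own <- matrix("private", 30, 30)
  parcel <- list(x = c(0.2, 0.6, 0.6, 0.2), y = c(0.2, 0.2, 0.6, 0.6))
  g1 <- reclassify(base, own, flooded_parcels = list(parcel),
                   grid_template = tpl)
  cat <- g1$catalog
  flag <- cat$code[cat$abbrev == "PRI-FLAG"]
  cx <- (col(base) - 0.5) * 0.0387; cy <- (row(base) - 0.5) * 0.0387
  in_parcel <- cx >= 0.2 & cx <= 0.6 & cy >= 0.2 & cy <= 0.6
  expect_equal(g1$codes == flag, base == 1L & in_parcel,
               ignore_attr = TRUE)
  # non-agriculture cells in the parcel untouched by the flooding rule
  expect_true(all(g1$codes[base == 2L] == cat$code[cat$abbrev == "PRI-WATER"]))
  # re-running the rules on the crossed grid with the same inputs is a no-op
  g2 <- reclassify(g1, own, flooded_parcels = list(parcel),
                   codes_are = "catalog")
  expect_equal(g2$codes, g1$codes)
})

test_that("covariate areas: arithmetic, NODATA, and brute-force agreement", {
  cat <- default_catalog()
  pri_water <- cat$code[cat$abbrev == "PRI-WATER"]
  g <- landscape_grid(matrix(pri_water, 10, 10), res_m = 38.7)
  # square covering exactly the 100 cells
  side <- 10 * 0.0387
  a <- covariate_areas(g, center = c(side / 2, side / 2), side_km = side)
  expect_equal(unname(a["PRI-WATER"]), 100 * 0.149769, tolerance = 1e-12)
  expect_equal(sum(a) - a[["PRI-WATER"]], 0)

  gn <- landscape_grid(matrix(-1L, 10, 10), res_m = 38.7)
  expect_warning(an <- covariate_areas(gn, center = c(-5, -5), side_km = 0.1),
                 "disjoint")
  expect_true(all(an == 0))
  a0 <- covariate_areas(gn, center = c(side / 2, side / 2), side_km = side)
  expect_true(all(a0 == 0))
  expect_equal(attr(a0, "nodata_ha"), 100 * 0.149769, tolerance = 1e-12)

  set.seed(11)
  codes <- matrix(sample(c(cat$code, 0L, -1L), 400, replace = TRUE), 20, 20)
  gr <- landscape_grid(codes, res_m = 38.7)
  ctr <- c(0.31, 0.42); side <- 0.25
  got <- covariate_areas(gr, center = ctr, side_km = side)
  cx <- (col(codes) - 0.5) * 0.0387; cy <- (row(codes) - 0.5) * 0.0387
  sel <- cx >= ctr[1] - side / 2 & cx < ctr[1] + side / 2 &
    cy >= ctr[2] - side / 2 & cy < ctr[2] + side / 2
  for (v in cat$abbrev) {
    expect_equal(unname(got[v]),
                 sum(sel & codes == cat$code[cat$abbrev == v]) * 0.149769,
                 tolerance = 1e-12)
  }
})

test_that("areas are conserved over any interior square", {
  set.seed(3)
  cat <- default_catalog()
  codes <- matrix(sample(c(cat$code, 0L, -1L), 2500, replace = TRUE), 50, 50)
  g <- landscape_grid(codes, res_m = 38.7)
  for (side in c(0.2, 0.5, 1.1)) {
    a <- covariate_areas(g, center = c(0.95, 0.95), side_km = side)
    total <- sum(a) + attr(a, "other_ha") + attr(a, "nodata_ha")
    # centre-in-square membership makes the covered count differ from the
    # geometric area by at most one cell rank per axis
    n_expect <- (side / 0.0387)^2
    expect_lt(abs(total / 0.149769 - n_expect), 2 * side / 0.0387 + 1)
  }
})

test_that("ASCII grid round-trips a landscape", {
  set.seed(5)
  cat <- default_catalog()
  codes <- matrix(sample(c(cat$code, 0L, -1L), 120, replace = TRUE), 10, 12)
  g <- landscape_grid(codes, origin = c(3.5, -2.25), res_m = 50)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(g, f)
  g2 <- read_ascii_grid(f)
  expect_equal(g2$codes, g$codes)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$res_m, 50)
})

test_that("ownership polygons rasterize with the fixed priority order", {
  tpl <- flat_landscape(n = 10, res_m = 100)
  base <- matrix(3L, 10, 10)
  big <- list(owner = "public", x = c(-1, 2, 2, -1), y = c(-1, -1, 2, 2))
  inner <- list(owner = "CWS", x = c(0.2, 0.6, 0.6, 0.2),
                y = c(0.2, 0.2, 0.6, 0.6))
  g <- reclassify(base, list(big, inner), grid_template = tpl)
  cat <- g$catalog
  expect_equal(g$codes[3, 3], cat$code[cat$abbrev == "CWS-MARSH"])
  expect_equal(g$codes[8, 8], cat$code[cat$abbrev == "PUB-MARSH"])
  # the same polygons in the opposite order give the same result
  g2 <- reclassify(base, list(inner, big), grid_template = tpl)
  expect_equal(g2$codes, g$codes)
})
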