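# Small in-code fixtures shared by the tests.

# A uniform single-code landscape.
flat_landscape <- function(code = 3L, n = 60, res_m = 38.7) {
  landscape_grid(matrix(code, n, n), origin = c(0, 0), res_m = res_m)
}

# Regularly scheduled fixes for one animal walking east with given step
# lengths (km); the first fix sits at the origin.
walk_fixes <- function(lengths, id = "A1", start = "2015-10-01 00:00:00",
                       dt_hours = 3) {
  n <- length(lengths) + 1
  data.frame(
    animal_id = id,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * dt_hours * 3600,
    easting_km = cumsum(c(0, lengths)),
    northing_km = 0,
    stringsAsFactors = FALSE
  )
}

# Fixed sunrise/sunset provider for boundary tests (06:00 / 18:00 UTC).
fixed_solar <- function(date, lat, lon) {
  midnight <- as.POSIXct(paste(format(as.Date(date)), "00:00:00"), tz = "UTC")
  data.frame(sunrise = midnight + 6 * 3600, sunset = midnight + 18 * 3600)
}

# Hand-built choice sets: `sizes[s]` alternatives per set, covariates drawn
# from a seeded normal, chooser assignment round-robin over `n_animals`.
toy_choice_sets <- function(sizes, K = 2, n_animals = 2, seed = 42,
                            beta = NULL) {
  set.seed(seed)
  rows <- sum(sizes)
  X <- matrix(rnorm(rows * K), rows, K,
              dimnames = list(NULL, paste0("v", seq_len(K))))
  set_id <- rep(seq_along(sizes), sizes)
  set_animal <- rep_len(seq_len(n_animals), length(sizes))
  used_row <- integer(length(sizes))
  first <- cumsum(c(1, sizes[-length(sizes)]))
  for (s in seq_along(sizes)) {
    rows_s <- first[s]:(first[s] + sizes[s] - 1)
    if (is.null(beta)) {
      used_row[s] <- rows_s[sample.int(length(rows_s), 1)]
    } else {
      u <- X[rows_s, , drop = FALSE] %*% beta[set_animal[s], ]
      p <- exp(u - max(u)); p <- p / sum(p)
      used_row[s] <- rows_s[sample.int(length(rows_s), 1, prob = p)]
    }
  }
  df <- data.frame(choice_set_id = set_id,
                   animal_id = paste0("A", set_animal[set_id]),
                   unit_id = as.character(seq_len(rows)),
                   used = as.integer(seq_len(rows) %in% used_row))
  cbind(df, as.data.frame(X))
}
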