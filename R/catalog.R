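#' Variable catalog for resource-by-ownership covariates
#'
#' The analysis describes every cell of the classified landscape by one of a
#' small set of resource-by-ownership variables: a foraging resource class
#' (agriculture, water, marsh, supplemental feeding refuge, flooded
#' agriculture) crossed with an ownership stratum (public, private, Walpole
#' Island, Canadian Wildlife Service, Michigan open water, or
#' Michigan-DNR-managed land).  Each ownership stratum carries a presumed
#' hunting-mortality risk tier: public access means high risk, the federal
#' (CWS) refuge none, and regulated ownerships (private, Walpole, MICH-DNR,
#' and the no-hunting supplemental feed buffer) an intermediate risk.
#'
#' `default_catalog()` returns the 14 standard variables plus reserved codes
#' for unclassified (`OTHER`) and missing (`NODATA`) cells.  A catalog is a
#' data frame with columns `code` (integer raster code), `abbrev`,
#' `resource_class`, `ownership` and `risk_tier`.  The MICH-DNR variable is
#' an ownership-only stratum: cells there are not broken out by resource
#' class.
#'
#' @return A data frame of class `variable_catalog`.
#' @export
default_catalog <- function() {
  cat <- data.frame(
    code = 1:14,
    abbrev = c(
      "MICH-DNR",
      "PUB-WATER", "PRI-WATER", "WAL-WATER", "MICH-WATER",
      "PUB-MARSH", "PRI-MARSH", "WAL-MARSH", "CWS-MARSH", "CWS-WATER",
      "PRI-FLAG", "PRI-SUPP", "PRI-AGRI", "WAL-AGRI"
    ),
    resource_class = c(
      NA,
      "water", "water", "water", "water",
      "marsh", "marsh", "marsh", "marsh", "water",
      "flooded agriculture", "supplemental feeding refuge",
      "agriculture", "agriculture"
    ),
    ownership = c(
      "MICH-DNR",
      "public", "private", "Walpole", "Michigan",
      "public", "private", "Walpole", "CWS", "CWS",
      "private", "private", "private", "Walpole"
    ),
    stringsAsFactors = FALSE
  )
  cat$risk_tier <- risk_tier_of(cat$ownership, cat$resource_class)
  structure(cat, class = c("variable_catalog", "data.frame"))
}

#' @keywords internal
risk_tier_of <- function(ownership, resource_class) {
  tier <- rep("intermediate", length(ownership))
  tier[ownership %in% c("public", "Michigan")] <- "high"
  tier[ownership == "CWS"] <- "none"
  # the feed-refuge buffer is no-hunting but sits inside hunted private land
  tier[!is.na(resource_class) &
         resource_class == "supplemental feeding refuge"] <- "intermediate"
  tier
}

# reserved raster codes
CODE_OTHER <- 0L
CODE_NODATA <- -1L

#' Validate a variable catalog
#'
#' Checks the invariants a catalog must satisfy: unique positive codes,
#' unique abbreviations, known resource classes, ownerships and risk tiers.
#'
#' @param catalog A catalog data frame as from [default_catalog()].
#' @return The catalog, invisibly; errors on violation.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  needed <- c("code", "abbrev", "resource_class", "ownership", "risk_tier")
  missing_cols <- setdiff(needed, names(catalog))
  if (length(missing_cols)) {
    stop("catalog lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(catalog$abbrev)) stop("catalog abbreviations must be unique")
  if (anyDuplicated(catalog$code)) stop("catalog codes must be unique")
  if (any(catalog$code <= 0)) stop("catalog codes must be positive integers")
  ok_class <- c("agriculture", "water", "marsh",
                "supplemental feeding refuge", "flooded agriculture")
  bad <- setdiff(stats::na.omit(catalog$resource_class), ok_class)
  if (length(bad)) stop("unknown resource class: ", paste(bad, collapse = ", "))
  ok_tier <- c("high", "intermediate", "none")
  if (!all(catalog$risk_tier %in% ok_tier)) stop("unknown risk tier")
  invisible(catalog)
}

#' Read or write a variable catalog as CSV
#'
#' @param path File path.
#' @return `read_catalog()` returns a validated catalog data frame.
#' @export
read_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  cat$resource_class[cat$resource_class == ""] <- NA_character_
  validate_catalog(cat)
  structure(cat, class = c("variable_catalog", "data.frame"))
}

#' @rdname read_catalog
#' @param catalog Catalog to write.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Look up the catalog code for a resource class / ownership crossing
#'
#' Crossings absent from the catalog map to the `OTHER` code, except that any
#' cell in MICH-DNR ownership maps to the ownership-only MICH-DNR variable.
#' The base resource class "other" always maps to `OTHER`.
#'
#' @param catalog A variable catalog.
#' @param resource_class,ownership Character vectors (recycled).
#' @return Integer vector of raster codes.
#' @export
crossing_code <- function(catalog, resource_class, ownership) {
  n <- max(length(resource_class), length(ownership))
  resource_class <- rep_len(resource_class, n)
  ownership <- rep_len(ownership, n)
  out <- rep(CODE_OTHER, n)
  is_dnr <- !is.na(ownership) & ownership == "MICH-DNR"
  if (any(is_dnr)) {
    dnr_code <- catalog$code[catalog$ownership == "MICH-DNR"][1L]
    out[is_dnr] <- if (is.na(dnr_code)) CODE_OTHER else dnr_code
  }
  key <- paste(resource_class, ownership, sep = "\r")
  cat_key <- paste(catalog$resource_class, catalog$ownership, sep = "\r")
  hit <- match(key, cat_key)
  use <- !is_dnr & !is.na(hit)
  out[use] <- catalog$code[hit[use]]
  out[is.na(ownership)] <- CODE_NODATA
  out
}
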