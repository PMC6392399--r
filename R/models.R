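#' Aggregate covariates for reduced candidate models
#'
#' The candidate model set contrasts hypotheses about what drives selection:
#' the "resource" model collapses the per-ownership variables into the five
#' foraging resource classes, the "risk" model collapses them into the
#' hunting-risk tiers implied by ownership, and the "full" model keeps every
#' resource-by-ownership variable.  This helper appends the aggregate
#' columns (summed hectares) to a choice-set table.  Variables without a
#' resource class (the ownership-only stratum) contribute to risk
#' aggregates only.
#'
#' @param cs A `choice_sets` data frame.
#' @param catalog Variable catalog matching the covariate columns.
#' @return `cs` with added columns `res_<class>` and `risk_<tier>`.
#' @export
aggregate_covariates <- function(cs, catalog = default_catalog()) {
  vars <- intersect(catalog$abbrev, names(cs))
  for (cl in unique(stats::na.omit(catalog$resource_class))) {
    members <- intersect(catalog$abbrev[!is.na(catalog$resource_class) &
                                          catalog$resource_class == cl], vars)
    nm <- paste0("res_", gsub(" ", "_", cl))
    cs[[nm]] <- if (length(members))
      rowSums(cs[, members, drop = FALSE]) else 0
  }
  for (tier in unique(catalog$risk_tier)) {
    members <- intersect(catalog$abbrev[catalog$risk_tier == tier], vars)
    nm <- paste0("risk_", tier)
    cs[[nm]] <- if (length(members))
      rowSums(cs[, members, drop = FALSE]) else 0
  }
  cs
}

#' Canonical candidate model variable sets
#'
#' Four registered candidates: `random` (no covariates), `resource` (the
#' five resource-class aggregates), `risk` (the risk-tier aggregates), and
#' `full` (all screened catalog variables).  Variable sets are intersected
#' with `retained` so that screening removals propagate to every candidate.
#'
#' @param catalog Variable catalog.
#' @param retained Variables surviving correlation screening (defaults to
#'   all catalog variables).
#' @return Named list of character vectors.
#' @export
candidate_models <- function(catalog = default_catalog(),
                             retained = catalog$abbrev) {
  classes <- unique(stats::na.omit(catalog$resource_class))
  tiers <- unique(catalog$risk_tier)
  list(
    random = character(0),
    resource = paste0("res_", gsub(" ", "_", classes)),
    risk = paste0("risk_", tiers),
    full = intersect(catalog$abbrev, retained)
  )
}
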