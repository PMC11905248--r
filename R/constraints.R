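# Institutional dose-volume constraint template and its evaluation. Each
# constraint is a volume-at-dose bound in % or cc; percent deviations are
# signed toward the violating direction so a single +/-3% trigger can be
# applied across mixed constraint types.

#' Construct a single dose-volume constraint
#'
#' @param structure structure name.
#' @param doseGy dose level of the V-metric (Gy).
#' @param bound bound value (in `unit`).
#' @param direction `"<="` or `">="`.
#' @param unit `"pct"` or `"cc"`.
#' @return a constraint (named list).
#' @export
constraint <- function(structure, doseGy, bound,
                       direction = c("<=", ">="), unit = c("pct", "cc")) {
  direction <- match.arg(direction)
  unit <- match.arg(unit)
  stopifnot(doseGy >= 0, bound >= 0)
  if (unit == "pct" && bound > 100)
    stop("a percent bound cannot exceed 100")
  list(structure = structure, metric = sprintf("V%gGy", doseGy),
       doseGy = doseGy, bound = bound, direction = direction, unit = unit)
}

#' The packaged institutional constraint template (prostate SBRT, 5 x 7.25 Gy)
#'
#' Volume-at-dose limits for PTV_eval coverage and the organs at risk:
#' rectum, bladder, urethra PRV, femoral heads, penile bulb. Femoral-head
#' limits apply per femur.
#'
#' @return list of constraints (see [constraint()]).
#' @export
defaultConstraintTemplate <- function() {
  list(
    constraint("PTV_eval", 36.25, 95, ">=", "pct"),
    constraint("PTV_eval", 34.40, 98, ">=", "pct"),
    constraint("PTV_eval", 33.70, 99, ">=", "pct"),
    constraint("PTV_eval", 38.78, 20, "<=", "cc"),
    constraint("PTV_eval", 43.50, 0.03, "<=", "cc"),
    constraint("rectum", 38.06, 0.03, "<=", "cc"),
    constraint("rectum", 34.40, 3.00, "<=", "cc"),
    constraint("rectum", 32.60, 10, "<=", "pct"),
    constraint("rectum", 29.00, 20, "<=", "pct"),
    constraint("rectum", 18.13, 50, "<=", "pct"),
    constraint("bladder", 38.06, 0.03, "<=", "cc"),
    constraint("bladder", 18.12, 10, "<=", "pct"),
    constraint("urethra_prv", 38.78, 0.03, "<=", "cc"),
    constraint("femur_r", 19.90, 10, "<=", "cc"),
    constraint("femur_l", 19.90, 10, "<=", "cc"),
    constraint("penile_bulb", 36.25, 0.03, "<=", "cc"),
    constraint("penile_bulb", 19.90, 3, "<=", "cc")
  )
}

#' Read a constraint template from YAML or JSON
#'
#' The file holds a list of records with fields `structure`, `doseGy`,
#' `bound`, `direction`, `unit`.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return list of constraints.
#' @export
readConstraintTemplate <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    constraint(r$structure, r$doseGy, r$bound, r$direction, r$unit))
}

#' Evaluate a constraint template against a dose distribution
#'
#' Achieved values are computed with the DVH engine; the percent deviation
#' is signed toward violation: positive deviations violate the bound,
#' negative ones have margin.
#'
#' @param dose an [ImageVolume-class] (e.g. planned or composite dose).
#' @param structures a [StructureSet-class] on the same grid.
#' @param template list of constraints, see [defaultConstraintTemplate()].
#' @param binGy DVH bin width.
#' @return a `data.frame` with one row per constraint: achieved value,
#'   bound, pass flag and signed percent deviation; constraints whose
#'   structure is missing are returned with `evaluated = FALSE`.
#' @export
evaluateTemplate <- function(dose, structures, template =
                               defaultConstraintTemplate(), binGy = 0.01) {
  curves <- list()
  rows <- lapply(template, function(cn) {
    row <- data.frame(structure = cn$structure, metric = cn$metric,
                      unit = cn$unit, direction = cn$direction,
                      bound = cn$bound, achieved = NA_real_,
                      deviationPct = NA_real_, pass = NA,
                      evaluated = FALSE, stringsAsFactors = FALSE)
    if (!cn$structure %in% structureNames(structures)) return(row)
    if (is.null(curves[[cn$structure]]))
      curves[[cn$structure]] <<- computeDVH(dose,
                                            getMask(structures, cn$structure),
                                            binGy = binGy,
                                            structure = cn$structure)
    achieved <- dvhMetric(curves[[cn$structure]], cn$metric, unit = cn$unit)
    dev <- if (cn$direction == "<=") {
      (achieved - cn$bound) / cn$bound * 100
    } else {
      (cn$bound - achieved) / cn$bound * 100
    }
    row$achieved <- achieved
    row$deviationPct <- dev
    row$pass <- dev <= 0
    row$evaluated <- TRUE
    row
  })
  do.call(rbind, rows)
}

#' Replanning trigger from a constraint report
#'
#' Flags adaptive replanning when any constraint deviates into violation by
#' strictly more than the tolerance (default 3%); a deviation of exactly
#' the tolerance does not trigger.
#'
#' @param report a constraint report from [evaluateTemplate()].
#' @param tolerancePct trigger tolerance in percent (default 3).
#' @return list(flag = logical, violating = data.frame of triggering rows).
#' @export
adaptationFlag <- function(report, tolerancePct = 3) {
  ev <- report[report$evaluated %in% TRUE, , drop = FALSE]
  hit <- ev$deviationPct > tolerancePct
  list(flag = any(hit), violating = ev[hit, , drop = FALSE])
}
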