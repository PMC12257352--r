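#' Parse a DVH metric string
#'
#' Understands the clinical metric grammar: `"D95%"` (minimum dose to the
#' hottest 95% of the volume), `"D0.03cc"` (minimum dose to the hottest
#' 0.03 cc) and `"V60Gy"` (volume receiving at least 60 Gy).
#'
#' @param text metric string.
#' @return List with `type` (`"D_pct"`, `"D_cc"`, `"V_Gy"`) and `param`.
#' @export
parse_metric <- function(text) {
  m <- regmatches(text, regexec("^\\s*([DV])\\s*([0-9.]+)\\s*(%|cc|Gy)\\s*$", text))[[1]]
  if (length(m) == 0) stop(sprintf("cannot parse DVH metric '%s'", text))
  kind <- m[2]; param <- as.numeric(m[3]); unit <- m[4]
  type <- if (kind == "D" && unit == "%") "D_pct"
          else if (kind == "D" && unit == "cc") "D_cc"
          else if (kind == "V" && unit == "Gy") "V_Gy"
          else stop(sprintf("unsupported metric '%s'", text))
  list(type = type, param = param, text = trimws(text))
}

#' Parse a clinical goal string
#'
#' Grammar as printed on clinical goal sheets:
#' `"<metric> < threshold[unit] (variation[unit])"`, e.g.
#' `"D0.03cc < 105% (109%)"`, `"V60Gy > 95% (93%)"`, `"V45Gy < 50cc"`.
#' Percent thresholds of `D` metrics are relative to the prescription dose;
#' percent thresholds of `V` metrics are fractions of the structure volume.
#' The parenthesized value is the allowed-variation (fallback) threshold.
#'
#' @param structure structure name the goal applies to.
#' @param text goal string.
#' @return An object of class `clinical_goal`.
#' @export
parse_goal <- function(structure, text) {
  pat <- paste0("^\\s*([DV]\\s*[0-9.]+\\s*(?:%|cc|Gy))\\s*([<>])\\s*([0-9.]+)\\s*",
                "(%|Gy|cc)\\s*(?:\\(\\s*([0-9.]+)\\s*(%|Gy|cc)?\\s*\\))?\\s*$")
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) == 0) stop(sprintf("cannot parse clinical goal '%s'", text))
  metric <- parse_metric(m[2])
  direction <- if (m[3] == "<") "less_than" else "greater_than"
  threshold <- as.numeric(m[4])
  unit <- m[5]
  variation <- if (nzchar(m[6])) as.numeric(m[6]) else NULL
  if (threshold <= 0) stop("goal thresholds must be > 0")
  report_unit <- if (metric$type %in% c("D_pct", "D_cc")) "Gy" else unit
  structure(list(structure = structure, metric = metric,
                 direction = direction, threshold = threshold,
                 threshold_unit = unit, variation = variation,
                 report_unit = report_unit, text = trimws(text)),
            class = "clinical_goal")
}

#' @export
print.clinical_goal <- function(x, ...) {
  cat(sprintf("<clinical_goal> %s: %s\n", x$structure, x$text))
  invisible(x)
}

# Dose at cumulative volume v_cc on the sorted dose-coverage curve:
# piecewise-linear through (0, d_max) and (i * voxel_cc, d_(i)) with doses
# sorted hot-to-cold, i.e. partial-voxel linear interpolation.
dose_at_volume <- function(doses_sorted, vv_cc, v_cc) {
  n <- length(doses_sorted)
  t <- v_cc / vv_cc
  if (t <= 1) return(doses_sorted[1])
  if (t >= n) return(doses_sorted[n])
  i0 <- floor(t)
  frac <- t - i0
  doses_sorted[i0] + frac * (doses_sorted[i0 + 1] - doses_sorted[i0])
}

#' Evaluate a DVH metric on a dose and structure mask
#'
#' `D` metrics use partial-voxel linear interpolation on the cumulative
#' sorted dose-volume curve (so sub-voxel volumes like 0.03 cc are
#' grid-independent) and are returned in Gy. `V` metrics count voxels with
#' dose at or above the level and are returned as percent of the structure
#' volume or absolute cc.
#'
#' @param dose `scalar_volume` (Gy).
#' @param mask binary array on the dose grid.
#' @param metric metric string or [parse_metric()] result.
#' @param report_unit for `V` metrics: `"%"` (default) or `"cc"`.
#' @return Numeric scalar in the report unit.
#' @export
eval_metric <- function(dose, mask, metric, report_unit = "%") {
  if (is.character(metric)) metric <- parse_metric(metric)
  mask <- as.array(mask) != 0
  if (!any(mask)) stop("structure mask is empty")
  vals <- dose$values[mask]
  vv <- voxel_volume_cc(dose$grid)
  total_cc <- length(vals) * vv
  switch(metric$type,
    D_pct = dose_at_volume(sort(vals, decreasing = TRUE), vv,
                           metric$param / 100 * total_cc),
    D_cc = {
      if (metric$param > total_cc)
        stop(sprintf("D%gcc requested but the structure holds only %.2f cc",
                     metric$param, total_cc))
      dose_at_volume(sort(vals, decreasing = TRUE), vv, metric$param)
    },
    V_Gy = {
      frac <- mean(vals >= metric$param)
      if (identical(report_unit, "cc")) frac * total_cc else 100 * frac
    })
}

#' Scale a single-fraction dose to the full course
#'
#' Voxel-wise multiplication by the number of fractions, so that one
#' fraction's accumulated dose can be judged against course-level clinical
#' goals (all goal evaluation happens at the prescribed fractionation).
#'
#' @param per_fraction_dose `scalar_volume` (Gy).
#' @param n_fractions integer >= 1.
#' @return A `scalar_volume` (Gy).
#' @export
scale_to_course <- function(per_fraction_dose, n_fractions) {
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  scalar_volume(per_fraction_dose$values * n_fractions,
                per_fraction_dose$grid, "Gy")
}

#' Evaluate one clinical goal
#'
#' Resolves relative-dose thresholds (% of prescription) against the
#' prescription context, evaluates the metric at full floating precision
#' and applies the goal's strict inequality (ties fail). When an
#' allowed-variation threshold is present, `within_variation` applies the
#' same strict comparison against it; a met goal is always within
#' variation.
#'
#' @param goal a `clinical_goal`.
#' @param dose course-scaled `scalar_volume` (Gy).
#' @param structures `structure_set` containing the goal's structure.
#' @param rx `prescription_context` (for relative thresholds).
#' @return List (`goal_result`) with `value` (report unit), `met`,
#'   `within_variation`.
#' @export
eval_goal <- function(goal, dose, structures, rx) {
  mask <- get_mask(structures, goal$structure)
  is_d <- goal$metric$type %in% c("D_pct", "D_cc")
  value <- eval_metric(dose, mask, goal$metric,
                       report_unit = if (is_d) "Gy" else goal$threshold_unit)
  resolve <- function(thr) {
    if (is_d && goal$threshold_unit == "%") thr / 100 * rx$total_dose_Gy else thr
  }
  cmp <- function(v, thr) if (goal$direction == "less_than") v < thr else v > thr
  met <- cmp(value, resolve(goal$threshold))
  within <- if (is.null(goal$variation)) met else met || cmp(value, resolve(goal$variation))
  structure(list(goal = goal, value = value, met = met, within_variation = within),
            class = "goal_result")
}

#' Evaluate a goal set on a dose
#'
#' @param goals list of `clinical_goal` objects.
#' @param dose course-scaled dose.
#' @param structures a `structure_set`.
#' @param rx a `prescription_context`.
#' @return A data.frame with one row per goal: structure, goal text, value,
#'   met, within_variation.
#' @export
eval_goal_set <- function(goals, dose, structures, rx) {
  rows <- lapply(goals, function(g) {
    r <- eval_goal(g, dose, structures, rx)
    data.frame(structure = g$structure, goal = g$text, unit = g$report_unit,
               value = r$value, met = r$met, within_variation = r$within_variation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

met_flags <- function(results) {
  # accepts a logical matrix (fractions x goals), a list of per-fraction
  # logical vectors, or a list of per-fraction lists of goal_result objects
  if (is.matrix(results)) return(results)
  rows <- lapply(results, function(fr) {
    if (is.logical(fr)) fr
    else vapply(fr, function(r) isTRUE(r$met), logical(1))
  })
  do.call(rbind, rows)
}

#' Goal-adherence discrepancy between system and true accumulated dose
#'
#' Counts, over matched fractions and goals, `a` = goals reported met by
#' the system-accumulated dose but not met on the true dose, and `b` = the
#' reverse, and reports the discrepancy percentage
#' `100 (a + b) / (goals x fractions)`, rounded to the nearest integer for
#' reporting. Pass/fail uses the primary goal threshold (not the allowed
#' variation) unless `use_variation` is set, in which case the
#' `within_variation` flags must be supplied as the inputs.
#'
#' @param results_sys,results_true matched per-fraction goal results:
#'   logical matrices (fractions x goals), lists of per-fraction logical
#'   vectors, or lists of per-fraction lists of [eval_goal()] results.
#' @param use_variation kept for explicitness; flags are taken as given.
#' @return An object of class `discrepancy_summary`: `a`, `b`, `n_goals`,
#'   `n_fractions`, `percentage` (integer-rounded) and `percentage_raw`.
#' @export
goal_discrepancy <- function(results_sys, results_true, use_variation = FALSE) {
  sys <- met_flags(results_sys)
  tru <- met_flags(results_true)
  if (!identical(dim(sys), dim(tru)))
    stop("system and true goal tables disagree in shape")
  a <- sum(sys & !tru)
  b <- sum(!sys & tru)
  G <- ncol(sys); F_ <- nrow(sys)
  raw <- 100 * (a + b) / (G * F_)
  structure(list(a = a, b = b, n_goals = G, n_fractions = F_,
                 percentage = as.integer(round(raw)), percentage_raw = raw),
            class = "discrepancy_summary")
}

#' @export
print.discrepancy_summary <- function(x, ...) {
  cat(sprintf(paste0("<discrepancy> %d goals x %d fractions: %d passed-in-system-",
                     "only, %d passed-in-truth-only -> %d%%\n"),
              x$n_goals, x$n_fractions, x$a, x$b, x$percentage))
  invisible(x)
}

#' Worst per-goal value across fractions
#'
#' For each goal, the value farthest in the failing direction across the
#' fractions: the maximum for `less_than` goals, the minimum for
#' `greater_than` goals (the bracketed worst-case convention of clinical
#' goal reports).
#'
#' @param per_fraction_values numeric matrix, goals x fractions.
#' @param directions character vector per goal, `"less_than"` or
#'   `"greater_than"`.
#' @return Numeric vector of per-goal worst values.
#' @export
worst_per_goal <- function(per_fraction_values, directions) {
  per_fraction_values <- as.matrix(per_fraction_values)
  if (nrow(per_fraction_values) != length(directions))
    stop("one direction per goal row is required")
  vapply(seq_len(nrow(per_fraction_values)), function(i) {
    v <- per_fraction_values[i, ]
    if (directions[i] == "less_than") max(v) else min(v)
  }, numeric(1))
}
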