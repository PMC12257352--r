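#' Scenario configuration
#'
#' Bundles everything one simulated treatment fraction needs: the phantom,
#' the authored deformation, the delivery technique, the registration under
#' test (or the perfect-registration oracle) and the gamma criteria.
#'
#' @param phantom a [phantom_config()].
#' @param deformations list of [deformation_spec()] (empty = no-change
#'   fraction).
#' @param technique `"imrt9"` or `"vmat"`.
#' @param registration a [registration_params()] or the string `"oracle"`.
#' @param gamma_criteria list of [gamma_config()] objects.
#' @param name scenario label used in reports.
#' @param seed integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(phantom = phantom_config(),
                            deformations = list(),
                            technique = c("imrt9", "vmat"),
                            registration = registration_params(),
                            gamma_criteria = standard_gamma_criteria(),
                            name = "scenario",
                            seed = 1L) {
  technique <- match.arg(technique)
  if (!(identical(registration, "oracle") || inherits(registration, "registration_params")))
    stop("registration must be registration_params() or \"oracle\"")
  structure(list(phantom = phantom, deformations = deformations,
                 technique = technique, registration = registration,
                 gamma_criteria = gamma_criteria, name = name,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Run one simulated fraction end to end
#'
#' Executes the full per-fraction validation chain: build the phantom,
#' author the true pull-back field, synthesize the deformed treatment image
#' and day-of-treatment structures, compute the scheduled-plan fraction
#' dose on the deformed anatomy, accumulate it back to the planning grid
#' through (i) the inverse of the true field and (ii) the registration
#' under test, then compare the two accumulated doses by gamma analysis,
#' goal adherence, displacement statistics and contour metrics.
#'
#' @param cfg a [scenario_config()].
#' @param phantom optional pre-built phantom (from [build_phantom()]) so a
#'   course can share one planning anatomy.
#' @param keep_volumes keep the dose volumes and fields in the result (the
#'   course runner needs them; set FALSE to save memory).
#' @return An object of class `scenario_result`.
#' @export
run_scenario <- function(cfg, phantom = NULL, keep_volumes = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(phantom)) phantom <- build_phantom(cfg$phantom)
  structs <- phantom$structures
  rx <- phantom$rx
  grid <- structs$grid

  u_true <- author_field(structs, cfg$deformations)
  ct_mod <- warp_image(phantom$ct, u_true, grid)
  structs_mod <- warp_structure_set(structs, u_true, grid)

  fx_dose <- synth_fraction_dose(structs_mod, rx, cfg$technique,
                                 seed = cfg$seed, plan_structures = structs)

  body <- structs$masks$body != 0
  phi_true <- invert_field(u_true, mask = body)
  d_true <- accumulate_dose_ddm(fx_dose, phi_true)

  phi_est <- if (identical(cfg$registration, "oracle"))
    register_with_oracle(u_true)
  else
    estimate_field(phantom$ct, ct_mod, cfg$registration)
  d_est <- accumulate_dose_ddm(fx_dose, resample_field(phi_est, grid))

  gamma_table <- multi_criteria_gamma(d_true, d_est, cfg$gamma_criteria)

  dvf_true_stats <- dvf_stats_per_structure(phi_true, structs)
  dvf_est_stats <- dvf_stats_per_structure(phi_est, structs)
  ferr <- dvf_error(resample_field(phi_est, grid), phi_true, body)
  mag_class <- classify_magnitude(phi_true, body)

  goals_true <- eval_goal_set(rx$goal_set, scale_to_course(d_true, rx$n_fractions),
                              structs, rx)
  goals_est <- eval_goal_set(rx$goal_set, scale_to_course(d_est, rx$n_fractions),
                             structs, rx)

  structs_back <- warp_structure_set(structs_mod, resample_field(phi_est, grid), grid)
  contours <- contour_metrics(structs, structs_back,
                              setdiff(names(structs$masks), "body"))

  out <- list(name = cfg$name, config = cfg,
              gamma = gamma_table,
              dvf_true = dvf_true_stats, dvf_est = dvf_est_stats,
              field_error = ferr, magnitude_class = mag_class,
              goals_true = goals_true, goals_est = goals_est,
              contours = contours,
              inversion_residual_mm = attr(phi_true, "residual_mm"))
  if (keep_volumes)
    out <- c(out, list(d_true = d_true, d_est = d_est, fraction_dose = fx_dose,
                       u_true = u_true, phi_true = phi_true, phi_est = phi_est,
                       ct_mod = ct_mod, phantom = phantom))
  class(out) <- "scenario_result"
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s' (%s deformation)\n", x$name, x$magnitude_class))
  g <- x$gamma
  for (i in seq_len(nrow(g)))
    cat(sprintf("  gamma %g%%/%g mm: %.1f%%\n", g$dose_criterion_pct[i],
                g$distance_criterion_mm[i], g$pass_rate_pct[i]))
  cat(sprintf("  field error vs truth: mean %.2f mm, max %.2f mm over body\n",
              x$field_error$mean_mm, x$field_error$max_mm))
  cat(sprintf("  goals met (true/system): %d/%d of %d\n",
              sum(x$goals_true$met), sum(x$goals_est$met), nrow(x$goals_true)))
  invisible(x)
}

#' Run a multi-fraction validation course
#'
#' Treats each anatomical scenario as one delivered fraction of a course
#' sharing a single planning phantom, runs every fraction with
#' [run_scenario()], then analyzes the summed accumulated doses: course
#' gamma, course goal adherence (summed dose rescaled to the prescribed
#' fractionation), the per-fraction goal-discrepancy summary and the
#' worst-per-goal bracket values.
#'
#' @param scenarios named list of deformation-spec lists, e.g. from
#'   [scenario_presets()].
#' @param phantom_cfg a [phantom_config()] shared by all fractions.
#' @param technique,registration,gamma_criteria,seed as in
#'   [scenario_config()].
#' @return An object of class `validation_report`.
#' @export
run_course <- function(scenarios,
                       phantom_cfg = phantom_config(),
                       technique = "imrt9",
                       registration = registration_params(),
                       gamma_criteria = standard_gamma_criteria(),
                       seed = 1L) {
  phantom <- build_phantom(phantom_cfg)
  rx <- phantom$rx
  F_ <- length(scenarios)
  results <- vector("list", F_)
  for (i in seq_len(F_)) {
    cfg <- scenario_config(phantom_cfg, scenarios[[i]], technique, registration,
                           gamma_criteria, name = names(scenarios)[i], seed = seed)
    results[[i]] <- run_scenario(cfg, phantom = phantom, keep_volumes = TRUE)
  }

  sum_true <- sum_doses(lapply(results, `[[`, "d_true"))
  sum_est <- sum_doses(lapply(results, `[[`, "d_est"))
  course_gamma <- multi_criteria_gamma(sum_true, sum_est, gamma_criteria)

  # the F scenario-fractions stand for the whole course: rescale their sum
  # to the prescribed fractionation before judging course-level goals
  scale <- rx$n_fractions / F_
  course_true <- scalar_volume(sum_true$values * scale, sum_true$grid, "Gy")
  course_est <- scalar_volume(sum_est$values * scale, sum_est$grid, "Gy")
  goals_course_true <- eval_goal_set(rx$goal_set, course_true, phantom$structures, rx)
  goals_course_est <- eval_goal_set(rx$goal_set, course_est, phantom$structures, rx)

  met_true <- do.call(rbind, lapply(results, function(r) r$goals_true$met))
  met_est <- do.call(rbind, lapply(results, function(r) r$goals_est$met))
  discrepancy <- goal_discrepancy(met_est, met_true)

  vals_true <- do.call(cbind, lapply(results, function(r) r$goals_true$value))
  vals_est <- do.call(cbind, lapply(results, function(r) r$goals_est$value))
  dirs <- vapply(rx$goal_set, `[[`, character(1), "direction")
  goals_course_true$worst_across_fractions <- worst_per_goal(vals_true, dirs)
  goals_course_est$worst_across_fractions <- worst_per_goal(vals_est, dirs)

  per_fraction_gamma <- do.call(rbind, lapply(seq_len(F_), function(i) {
    g <- results[[i]]$gamma
    cbind(data.frame(fraction = i, scenario = results[[i]]$name), g)
  }))
  dvf_table <- do.call(rbind, lapply(seq_len(F_), function(i) {
    r <- results[[i]]
    merge(cbind(data.frame(fraction = i, scenario = r$name,
                           magnitude_class = r$magnitude_class),
                stats::setNames(r$dvf_true[c("structure", "max_dvf_mm")],
                                c("structure", "true_max_mm"))),
          stats::setNames(r$dvf_est[c("structure", "max_dvf_mm")],
                          c("structure", "est_max_mm")),
          by = "structure", sort = TRUE)
  }))
  contour_table <- do.call(rbind, lapply(seq_len(F_), function(i) {
    cbind(data.frame(fraction = i, scenario = results[[i]]$name),
          results[[i]]$contours)
  }))

  structure(list(site = phantom_cfg$site,
                 fractions = results,
                 per_fraction_gamma = per_fraction_gamma,
                 course_gamma = course_gamma,
                 goals_course_true = goals_course_true,
                 goals_course_est = goals_course_est,
                 discrepancy = discrepancy,
                 dvf_table = dvf_table,
                 contour_table = contour_table,
                 rx = rx),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s course, %d fractions\n",
              x$site, length(x$fractions)))
  g <- x$course_gamma
  for (i in seq_len(nrow(g)))
    cat(sprintf("  summed-dose gamma %g%%/%g mm: %.1f%%\n", g$dose_criterion_pct[i],
                g$distance_criterion_mm[i], g$pass_rate_pct[i]))
  print(x$discrepancy)
  invisible(x)
}

#' Write a validation report to disk
#'
#' Emits deterministic CSV tables (per-fraction and summed-dose gamma,
#' per-structure displacement maxima, goal adherence with
#' worst-across-fractions brackets, discrepancy summary, contour metrics)
#' plus a JSON summary.
#'
#' @param report a `validation_report`.
#' @param outdir output directory (created if missing).
#' @return Character vector of written files, invisibly.
#' @export
emit_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create output directory '%s'", outdir))
  wr <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  files <- c(
    wr(report$per_fraction_gamma, "gamma_per_fraction.csv"),
    wr(report$course_gamma, "gamma_course.csv"),
    wr(report$dvf_table, "dvf_stats.csv"),
    wr(report$goals_course_true, "goals_course_true.csv"),
    wr(report$goals_course_est, "goals_course_system.csv"),
    wr(report$contour_table, "contour_metrics.csv"),
    wr(data.frame(a = report$discrepancy$a, b = report$discrepancy$b,
                  n_goals = report$discrepancy$n_goals,
                  n_fractions = report$discrepancy$n_fractions,
                  percentage = report$discrepancy$percentage),
       "discrepancy.csv"))
  summary_file <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(site = report$site,
         n_fractions = length(report$fractions),
         course_gamma = report$course_gamma,
         discrepancy_percentage = report$discrepancy$percentage,
         goals_met_true = sum(report$goals_course_true$met),
         goals_met_system = sum(report$goals_course_est$met),
         n_goals = nrow(report$goals_course_true)),
    summary_file, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(files, summary_file))
}

#' Read a course configuration from YAML
#'
#' Schema (all fields optional unless noted):
#' \preformatted{
#' site: prostate_like | cervix_like
#' grid: {size: [128, 128, 64], spacing: [2, 2, 2.5]}
#' ptv_margin_mm: 7
#' seed: 1
#' technique: imrt9 | vmat
#' registration: oracle            # or a mapping of registration_params()
#' scenarios: preset               # the shipped per-site course, or a list:
#' #  - name: bladder_med_expand
#' #    deformations:
#' #      - {organ: bladder, mode: expand, magnitude_mm: 7.5}
#' }
#'
#' @param path YAML file.
#' @return List of arguments for [run_course()].
#' @export
read_course_config <- function(path) {
  y <- yaml::read_yaml(path)
  site <- y$site %||% "prostate_like"
  grid <- y$grid %||% list()
  pc <- phantom_config(site,
                       size = unlist(grid$size %||% c(128L, 128L, 64L)),
                       spacing = unlist(grid$spacing %||% c(2, 2, 2.5)),
                       ptv_margin_mm = y$ptv_margin_mm %||% 7,
                       seed = y$seed %||% 1L)
  reg <- if (identical(y$registration, "oracle")) "oracle"
  else do.call(registration_params, y$registration %||% list())
  scen <- if (is.null(y$scenarios) || identical(y$scenarios, "preset"))
    scenario_presets(site)
  else {
    out <- lapply(y$scenarios, function(s)
      lapply(s$deformations %||% list(), function(d) do.call(deformation_spec, d)))
    names(out) <- vapply(y$scenarios, function(s) s$name, character(1))
    out
  }
  list(scenarios = scen, phantom_cfg = pc,
       technique = y$technique %||% "imrt9",
       registration = reg, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
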