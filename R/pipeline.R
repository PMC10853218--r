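# End-to-end design pipeline: synthetic patient -> calibrated trunk model ->
# over-corrected initial brace -> surrogate optimization of the patch
# offsets -> run report.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Build the brace evaluator for a patient
#'
#' Returns a closure `rho -> list(of, feasible, max_pressure, phi_ib,
#' phi_pg, metrics_ib, metrics_pg)` that rebuilds the brace from the offset
#' vector, runs the supine in-brace simulation, propagates the
#' compliance-combined plate stresses through two years of growth, and scores
#' the objective.  Used by [run_pipeline()] and directly in tests.
#'
#' @param model Calibrated `trunk_model`.
#' @param brace0 `brace_points` of the initial (trimmed) brace.
#' @param grid `patch_grid` over it.
#' @param oob `sim_result` of the standing configuration.
#' @param ctx `metrics_context` fixed on the presenting deformity.
#' @param metrics_ini Presenting `deformity_metrics`.
#' @param config `run_config`.
#' @return Evaluator closure.
#' @export
brace_evaluator <- function(model, brace0, grid, oob, ctx, metrics_ini,
                            config = default_config()) {
  smoother <- smoothing_operator(brace0, grid)
  weights <- objective_weights(
    w_ib = config$objective$w_ib, w_pg = config$objective$w_pg,
    w_c = config$objective$w_c, w_s = config$objective$w_s,
    w_t = config$objective$w_t,
    tk_normal = config$objective$tk_normal,
    ll_normal = config$objective$ll_normal,
    denom_floor_deg = config$objective$denom_floor_deg)
  gp <- growth_params(C = config$growth$C,
                      G_m_thoracic = config$growth$G_m_thoracic,
                      G_m_lumbar = config$growth$G_m_lumbar,
                      beta = config$growth$beta,
                      duration_years = config$growth$duration_years,
                      floor_zero = config$growth$floor_zero)

  function(rho) {
    displaced <- apply_offsets(brace0, grid, rho,
                               bound = config$brace$rho_bound_mm)
    shape <- finalize_brace(displaced, grid, smoother = smoother,
                            opening_deg = config$brace$opening_deg,
                            strap_tension_N = config$brace$strap_tension_N,
                            thickness_mm = config$brace$thickness_mm,
                            E_MPa = config$brace$E_MPa, nu = config$brace$nu)
    ib <- simulate_inbrace(model, shape,
                           increments = config$solver$increments_ib)
    m_ib <- measure_metrics(ib$anatomy, ctx)
    phi_ib <- deformity_term(m_ib, metrics_ini, weights)

    comb <- combine_stresses(oob$plate_stresses, ib$plate_stresses, gp$C)
    rates <- plate_growth_rates(comb, gp)
    pg <- simulate_growth(model, rates, gp)
    m_pg <- measure_metrics(pg$anatomy, ctx)
    phi_pg <- deformity_term(m_pg, metrics_ini, weights)

    pc <- check_pressure(ib$pressures_kpa,
                         config$objective$pressure_limit_kpa)
    sc <- objective(phi_ib, phi_pg, weights,
                    max_pressure_kpa = pc$max_pressure_kpa,
                    pressure_limit_kpa = config$objective$pressure_limit_kpa)
    list(of = sc$value, feasible = pc$feasible,
         max_pressure = pc$max_pressure_kpa,
         phi_ib = phi_ib, phi_pg = phi_pg,
         metrics_ib = m_ib, metrics_pg = m_pg, shape = shape)
  }
}

#' Run the complete automated brace design pipeline
#'
#' Generates (or accepts) the synthetic patient, calibrates the standing
#' model, derives the over-corrected initial brace, and optimizes the 36
#' patch offsets under the pressure constraint.  All randomness derives from
#' `config$seed`.
#'
#' @param config A `run_config` (see [default_config()], [read_config()]).
#' @param out_dir Optional directory; when given, writes `metrics.csv`,
#'   `history.csv`, `report.json`, the skin/brace STL files and the
#'   optimization plot there.
#' @param progress Print per-stage progress if `TRUE`.
#' @return A `run_report`: patient spec, presenting/in-brace/post-growth
#'   metric tables for the initial and optimized braces, optimization
#'   history, best offsets, and provenance (seed, config echo).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  pc <- config$patient

  spec <- stage("generate", {
    if (isTRUE(pc$sample_from_cohort)) {
      sample_patient_spec(seed = config$seed)
    } else {
      patient_spec(mt_cobb_deg = pc$mt_cobb_deg, tll_cobb_deg = pc$tll_cobb_deg,
                   mt_apex_level = pc$mt_apex_level,
                   tll_apex_level = pc$tll_apex_level,
                   tk_deg = pc$tk_deg, ll_deg = pc$ll_deg,
                   avr_mt_deg = pc$avr_mt_deg, avr_tll_deg = pc$avr_tll_deg,
                   trunk_height_mm = pc$trunk_height_mm,
                   trunk_mass_kg = pc$trunk_mass_kg,
                   flexibility_factor = pc$flexibility_factor,
                   seed = config$seed)
    }
  })
  anatomy <- stage("generate", generate_patient(spec, n_phi = pc$n_phi))
  say("patient generated (MT %.1f, TL/L %.1f deg)", spec$mt_cobb_deg,
      spec$tll_cobb_deg)

  model <- stage("calibrate", {
    m <- assemble_model(anatomy, params = do.call(model_params_default,
                                                  config$model))
    calibrate_standing(m, tol_rms_mm = config$solver$calibration_tol_mm)
  })
  say("standing calibration RMS %.2f mm", model$calibration_rms_mm)

  ctx <- baseline_context(anatomy)
  metrics_ini <- measure_metrics(anatomy, ctx)
  oob <- stage("simulate", simulate_oob(model))

  brace0 <- stage("initial_brace", {
    oc <- find_max_overcorrection(model,
                                  distortion_threshold = config$brace$distortion_threshold)
    say("over-correction W_max = %.1f", oc$W_max)
    trim_initial_brace(oc$deformed_skin, trim_profile_default(anatomy))
  })
  grid <- stage("initial_brace",
                build_patch_grid(brace0, config$brace$grid_nz,
                                 config$brace$grid_nphi))

  evaluator <- brace_evaluator(model, brace0, grid, oob, ctx, metrics_ini,
                               config)
  ocfg <- opt_config(dim = grid$nz * grid$nphi,
                     n_initial = config$optimizer$n_initial,
                     max_iter_phase1 = config$optimizer$max_iter_phase1,
                     max_iter_extended = config$optimizer$max_iter_extended,
                     conv_window = config$optimizer$conv_window,
                     conv_rel_improvement = config$optimizer$conv_rel_improvement,
                     bound = config$brace$rho_bound_mm,
                     n_candidates = config$optimizer$n_candidates,
                     seed = config$seed)
  opt <- stage("optimize", optimize_brace(evaluator, ocfg,
                                          progress = if (progress)
                                            function(i, b) if (i %% 25 == 0)
                                              say("iter %d best OF %.3f", i, b)))

  best_eval <- stage("report", evaluator(opt$best_feasible$x))
  init_eval <- stage("report", evaluator(rep(0, ocfg$dim)))

  metrics_tab <- rbind(
    data.frame(configuration = "initial", as.data.frame(unclass(metrics_ini))),
    data.frame(configuration = "inbrace_initial_brace",
               as.data.frame(unclass(init_eval$metrics_ib))),
    data.frame(configuration = "inbrace_optimal_brace",
               as.data.frame(unclass(best_eval$metrics_ib))),
    data.frame(configuration = "postgrowth_optimal_brace",
               as.data.frame(unclass(best_eval$metrics_pg))))

  report <- structure(list(
    spec = spec, metrics = metrics_tab, metrics_ini = metrics_ini,
    initial_of = init_eval$of, best_of = opt$best_feasible$of,
    best_rho = opt$best_feasible$x,
    best_max_pressure_kpa = best_eval$max_pressure,
    best_feasible = !opt$best_feasible$fallback,
    history = opt$history, iterations = opt$iterations,
    converged_at = opt$converged_at,
    correction = list(
      mt_inbrace_pct = 100 * (1 - abs(best_eval$metrics_ib$cobb_mt) /
                                abs(metrics_ini$cobb_mt)),
      tll_inbrace_pct = 100 * (1 - abs(best_eval$metrics_ib$cobb_tll) /
                                 abs(metrics_ini$cobb_tll))),
    seed = config$seed, config = config,
    best_shape = best_eval$shape, anatomy = anatomy
  ), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the artifacts of a run report
#'
#' @param report A `run_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    seed = report$seed,
    initial_of = report$initial_of, best_of = report$best_of,
    best_rho_mm = as.numeric(report$best_rho),
    best_max_pressure_kpa = report$best_max_pressure_kpa,
    best_feasible = report$best_feasible,
    correction = report$correction,
    iterations = report$iterations, converged_at = report$converged_at
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_stl(list(vertices = report$anatomy$skin$verts,
                 triangles = report$anatomy$skin$tris),
            file.path(out_dir, "skin.stl"))
  write_stl(brace_mesh(report$best_shape), file.path(out_dir, "brace.stl"))
  write_anatomy(report$anatomy, file.path(out_dir, "anatomy.tsv"))
  plot_history(report, file.path(out_dir, "history.png"))
  invisible(out_dir)
}

#' Plot the optimization history
#'
#' Objective score of every evaluation with the best-so-far line, mirroring
#' the usual surrogate-optimization progress chart.
#'
#' @param report A `run_report` (or anything with a `history` data frame).
#' @param path Output image path (`.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
plot_history <- function(report, path) {
  h <- report$history
  if (is.null(h) || !nrow(h)) stop("empty optimization history")
  if (grepl("\\.pdf$", path)) grDevices::pdf(path, width = 7, height = 5)
  else grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(h$evaluation, h$of, pch = 16, cex = 0.6,
                 col = ifelse(h$feasible, "steelblue", "firebrick"),
                 xlab = "evaluation", ylab = "objective score",
                 main = "Brace shape optimization")
  ok <- !is.na(h$best_so_far)
  graphics::lines(h$evaluation[ok], h$best_so_far[ok], lwd = 2, col = "black")
  graphics::legend("topright", c("feasible", "infeasible", "best so far"),
                   pch = c(16, 16, NA), lty = c(NA, NA, 1),
                   col = c("steelblue", "firebrick", "black"), bty = "n")
  invisible(path)
}
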