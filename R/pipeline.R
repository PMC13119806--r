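# Pipeline orchestration: simulate -> traits -> stats -> importance ->
# report, as reproducible seeded stages writing tidy CSV/JSON artifacts
# plus a manifest of input/output digests. One master seed; every stage
# derives named substreams, so re-running one stage never perturbs the
# others.

.PIPELINE_STAGES <- c("simulate", "traits", "stats", "importance", "report")

#' Load a pipeline configuration
#'
#' Either returns the built-in default configuration or reads a YAML file
#' with optional overrides: `seed`, `ntree`, `n_perm_importance`,
#' `n_perm_model`, `target_vars`, `alpha`, `response_traits`.
#'
#' @param path Optional YAML config path.
#' @return Named list of run settings including the `experiment_config`.
#' @export
load_pipeline_config <- function(path = NULL) {
  settings <- list(seed = 1L, ntree = 500L, n_perm_importance = 100L,
                   n_perm_model = 99L, target_vars = 14L, alpha = 0.05,
                   response_traits = c("Lstar", "astar", "bstar"),
                   schema = "leafdrought-run-1")
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), c(names(settings), "experiment"))
    if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
    settings[names(user)] <- user
  }
  settings$experiment <- default_experiment_config()
  settings
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order under one master
#' seed and writes every artifact plus a manifest (`manifest.json`)
#' recording the config hash, seed, per-file md5 digests and package
#' version. Re-running with the same config and seed reproduces
#' byte-identical artifacts.
#'
#' Stages: `simulate` (trait table + example raw measurement streams),
#' `traits` (estimator demonstrations on the raw streams: color
#' aggregation, Kmax, ge, PV parameters), `stats` (letter grids and the
#' correlation matrix), `importance` (backward selection + permutation
#' tests per color parameter), `report` (plain-text summary).
#'
#' @param outdir Output directory (created if needed).
#' @param config A [load_pipeline_config()] list or a YAML path.
#' @param stages Subset of stages to run.
#' @param seed Optional master-seed override.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(outdir, config = load_pipeline_config(),
                         stages = .PIPELINE_STAGES, seed = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message(sprintf(...))
  files <- character()
  seed0 <- config$seed

  path <- function(f) file.path(outdir, f)
  if ("simulate" %in% stages) {
    log("[simulate] seed %d", seed0)
    tab <- generate_trait_table(config$experiment, seed0)
    write_trait_table(tab, path("trait_table.csv"))
    cm <- config$experiment$cell_means
    cell <- function(tr, trt, pe) cm$mean[cm$trait == tr & cm$treatment == trt &
                                            cm$period == pe]
    rd <- generate_color_readings(
      c(cell("Lstar", "T3", "S3"), cell("astar", "T3", "S3"),
        cell("bstar", "T3", "S3")),
      seed = substream_seed(seed0, "color"))
    utils::write.csv(rd, path("raw_color_readings.csv"), row.names = FALSE)
    an <- generate_vessel_anatomy(seed = substream_seed(seed0, "vessels"))
    utils::write.csv(
      data.frame(vessel_area_um2 = an$vessel_areas, n_total = an$n_total,
                 leaf_area_m2 = an$leaf_area,
                 petiole_length_m = an$petiole_length,
                 water_temperature_c = an$water_temperature),
      path("raw_vessel_anatomy.csv"), row.names = FALSE)
    ml <- generate_mass_loss_series(ge_true = cell("ge", "CK", "S1"),
                                    seed = substream_seed(seed0, "drydown"))
    utils::write.csv(
      data.frame(time_s = ml$times, fresh_weight_g = ml$fresh_weights,
                 leaf_area_m2 = ml$leaf_area, delta_e = ml$delta_e,
                 saturated_weight_g = ml$saturated_weight,
                 dry_weight_g = ml$dry_weight),
      path("raw_mass_loss.csv"), row.names = FALSE)
    pvp <- pv_gen_params(psi_sat = cell("PsiSat", "CK", "S1"))
    pv <- generate_pv_curve(pvp, seed = substream_seed(seed0, "pv"))
    utils::write.csv(
      data.frame(balance_pressure_mpa = pv$balance_pressure,
                 fresh_weight_g = pv$fresh_weight,
                 saturated_weight_g = pv$saturated_weight,
                 dry_weight_g = pv$dry_weight),
      path("raw_pv_curve.csv"), row.names = FALSE)
    files <- c(files, "trait_table.csv", "raw_color_readings.csv",
               "raw_vessel_anatomy.csv", "raw_mass_loss.csv",
               "raw_pv_curve.csv")
  }

  if ("traits" %in% stages) {
    log("[traits] deriving estimator outputs from raw streams")
    rd <- utils::read.csv(path("raw_color_readings.csv"))
    col <- aggregate_color(rd)
    va <- utils::read.csv(path("raw_vessel_anatomy.csv"))
    an <- vessel_anatomy(va$vessel_area_um2, va$n_total[1L],
                         va$leaf_area_m2[1L], va$petiole_length_m[1L],
                         va$water_temperature_c[1L])
    ml <- utils::read.csv(path("raw_mass_loss.csv"))
    series <- mass_loss_series(ml$time_s, ml$fresh_weight_g,
                               ml$leaf_area_m2[1L], ml$delta_e[1L],
                               ml$saturated_weight_g[1L], ml$dry_weight_g[1L])
    pvd <- utils::read.csv(path("raw_pv_curve.csv"))
    pvfit <- fit_pv(pv_curve(pvd$balance_pressure_mpa, pvd$fresh_weight_g,
                             pvd$saturated_weight_g[1L], pvd$dry_weight_g[1L]))
    derived <- rbind(
      data.frame(trait = paste0("color_", col$channel), value = col$mean,
                 se = col$se),
      data.frame(trait = "Kmax", value = as.numeric(leaf_kmax(an)), se = NA),
      data.frame(trait = "ge", value = as.numeric(epidermal_conductance(series)),
                 se = NA),
      data.frame(trait = names(coef(pvfit)), value = unname(coef(pvfit)),
                 se = NA))
    utils::write.csv(derived, path("derived_traits.csv"), row.names = FALSE)
    files <- c(files, "derived_traits.csv")
  }

  if ("stats" %in% stages) {
    log("[stats] letter grids and correlations")
    tab <- read_trait_table(path("trait_table.csv"))
    grids <- lapply(unique(tab$trait), function(tr) {
      g <- letter_matrix(tab, tr, alpha = config$alpha)
      cbind(trait = tr, g)
    })
    utils::write.csv(do.call(rbind, grids), path("stats_letters.csv"),
                     row.names = FALSE)
    pm <- pearson_matrix(tab)
    rr <- as.data.frame(as.table(pm$r)); names(rr) <- c("trait1", "trait2", "r")
    rr$p <- as.vector(pm$p)
    utils::write.csv(rr, path("correlation.csv"), row.names = FALSE)
    files <- c(files, "stats_letters.csv", "correlation.csv")
  }

  if ("importance" %in% stages) {
    log("[importance] backward selection + permutation tests")
    tab <- read_trait_table(path("trait_table.csv"))
    out <- list()
    color_traits <- c("Lstar", "astar", "bstar")
    for (resp in config$response_traits) {
      fm <- feature_matrix(tab, resp,
                           setdiff(unique(tab$trait),
                                   union(color_traits, config$response_traits)))
      sel <- backward_select(fm$predictors, fm$response,
                             target_count = config$target_vars,
                             ntree = config$ntree,
                             seed = substream_seed(seed0, paste0("bs_", resp)))
      imp <- importance_significance(sel$predictors, fm$response,
                                     n_perm = config$n_perm_importance,
                                     ntree = config$ntree,
                                     seed = substream_seed(seed0,
                                                           paste0("imp_", resp)))
      mod <- model_significance(sel$predictors, fm$response,
                                n_perm = config$n_perm_model,
                                ntree = config$ntree,
                                seed = substream_seed(seed0,
                                                      paste0("mod_", resp)))
      out[[resp]] <- list(retained = sel$retained,
                          drop_order = sel$drop_order,
                          importance = imp$importance,
                          model_r2 = mod$r2, model_p = mod$p)
    }
    .write_json(out, path("importance.json"))
    imp_csv <- do.call(rbind, lapply(names(out), function(r)
      cbind(response = r, out[[r]]$importance)))
    utils::write.csv(imp_csv, path("importance.csv"), row.names = FALSE)
    files <- c(files, "importance.json", "importance.csv")
  }

  if ("report" %in% stages) {
    txt <- report_run(outdir)
    writeLines(txt, path("report.txt"))
    files <- c(files, "report.txt")
  }

  manifest <- list(
    schema = config$schema,
    package_version = as.character(utils::packageVersion("leafdrought")),
    seed = seed0,
    config_hash = object_md5(config[setdiff(names(config), "experiment")]),
    experiment_hash = object_md5(config$experiment),
    stages = stages,
    files = as.list(stats::setNames(
      vapply(files, function(f) unname(tools::md5sum(path(f))), ""), files)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  .write_json(manifest, path("manifest.json"))
  invisible(manifest)
}

#' Plain-text summary of a pipeline run
#'
#' Tables mirroring the published shapes: a letter-annotated trait grid,
#' hydraulic/pigment estimator outputs, the strongest correlations, and
#' the retained-predictor importance rankings with significance stars.
#' Missing stages are flagged, not fatal.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also used by the `report`
#'   stage to write `report.txt`).
#' @export
report_run <- function(run_dir) {
  out <- c("leafdrought pipeline report", strrep("=", 27), "")
  p <- function(f) file.path(run_dir, f)
  any_stage <- FALSE
  if (file.exists(p("trait_table.csv"))) {
    any_stage <- TRUE
    tab <- read_trait_table(p("trait_table.csv"))
    out <- c(out, sprintf("Simulated trait table: %d records, %d traits.",
                          nrow(tab), length(unique(tab$trait))), "")
  }
  if (file.exists(p("derived_traits.csv"))) {
    any_stage <- TRUE
    der <- utils::read.csv(p("derived_traits.csv"))
    out <- c(out, "Derived estimator outputs:",
             utils::capture.output(print(der, row.names = FALSE)), "")
  }
  if (file.exists(p("stats_letters.csv"))) {
    any_stage <- TRUE
    gl <- utils::read.csv(p("stats_letters.csv"))
    show <- gl[gl$trait %in% c("Mvt", "astar"), ]
    out <- c(out, "Letter grids (uppercase: periods within treatment;",
             "lowercase: treatments within period). Shown: Mvt, astar.",
             utils::capture.output(print(show, row.names = FALSE)), "")
  }
  if (file.exists(p("correlation.csv"))) {
    any_stage <- TRUE
    co <- utils::read.csv(p("correlation.csv"))
    co <- co[co$trait1 < co$trait2 & !is.na(co$r), ]
    co <- co[order(-abs(co$r)), ][1:10, ]
    out <- c(out, "Strongest trait correlations:",
             utils::capture.output(print(co, row.names = FALSE)), "")
  }
  if (file.exists(p("importance.json"))) {
    any_stage <- TRUE
    imp <- jsonlite::read_json(p("importance.json"), simplifyVector = TRUE)
    for (resp in names(imp)) {
      d <- imp[[resp]]$importance
      d <- d[order(-d$inc_mse), ]
      d$sig <- ifelse(d$p_value < 0.01, "**",
                      ifelse(d$p_value < 0.05, "*", ""))
      out <- c(out,
               sprintf("Importance for %s (%d retained predictors; R^2 = %.2f, model p = %.3g):",
                       resp, length(imp[[resp]]$retained),
                       imp[[resp]]$model_r2, imp[[resp]]$model_p),
               utils::capture.output(print(d, row.names = FALSE)), "")
    }
  } else if (any_stage) {
    out <- c(out, "[importance stage not run]", "")
  }
  if (!any_stage) out <- c(out, "No stages have been run in this directory.")
  out
}
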