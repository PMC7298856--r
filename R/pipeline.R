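#' Load and validate a run configuration
#'
#' Configurations are YAML key/value files; every numeric parameter is
#' range-checked and all violations are reported together. See the
#' bundled demo at
#' `system.file("extdata", "demo_config.yml", package = "vectorenm")`.
#'
#' @param path YAML config path, or a named list already in memory.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    d_km = 22, fraction = 0.5, B_km = 200, r_max = 0.80, min_size = 2,
    rms = c(0.5, 1, 2), class_subsets = list("lq"),
    E = 0.05, alpha = 0.05, n_boot = 10, cutoff_frac = 0.6,
    mop_reference_fraction = 0.1, mop_sample_cap = 5000,
    breakpoints = c(0, 1, 5, 10, 20, 50, 100),
    strong_only = TRUE, flag_cutoff = 10,
    proc_iterations = 500, proc_fraction = 0.5,
    bg_max = 10000, knots = 10, max_sets = NULL,
    n_occurrences = 400, seed = 1, synthetic = list())
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$d_km > 0, "d_km must be > 0")
  chk(cfg$fraction > 0 && cfg$fraction < 1, "fraction must be in (0, 1)")
  chk(cfg$B_km >= 0, "B_km must be >= 0")
  chk(cfg$r_max > 0 && cfg$r_max <= 1, "r_max must be in (0, 1]")
  chk(cfg$min_size >= 2, "min_size must be >= 2")
  chk(all(cfg$rms > 0), "rms must all be > 0")
  chk(cfg$E > 0 && cfg$E < 1, "E must be in (0, 1)")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$n_boot >= 1, "n_boot must be >= 1")
  chk(cfg$cutoff_frac > 0 && cfg$cutoff_frac <= 1,
      "cutoff_frac must be in (0, 1]")
  chk(cfg$mop_reference_fraction > 0 && cfg$mop_reference_fraction <= 1,
      "mop_reference_fraction must be in (0, 1]")
  chk(all(diff(cfg$breakpoints) > 0),
      "breakpoints must be strictly increasing")
  chk(cfg$n_occurrences >= 2, "n_occurrences must be >= 2")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg$class_subsets <- lapply(cfg$class_subsets, function(s)
    strsplit(s, "")[[1]])
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in dependency order: simulate environmental,
#' occurrence, cattle and region data; thin and split occurrences; build
#' the accessible area and crop the calibration stack; filter collinear
#' variables and enumerate candidate variable sets; calibrate and select
#' the best candidate; fit the final bootstrap-median model and project
#' it to present and all future scenarios; run MOP; binarize at the
#' E-percentile threshold; build per-scenario ensemble agreement and
#' change maps; and compute the exposure tables. All artifacts are
#' written under `out_dir` and summarized in a JSON run manifest with
#' per-stage timings and output checksums.
#'
#' @param config A [load_config()] result (or a path to one).
#' @param out_dir Output directory.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_all <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  manifest <- list(config = cfg[setdiff(names(cfg), "class_subsets")],
                   stages = list(), outputs = list(), warnings = list())
  t_stage <- function(nm, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      manifest$warnings[[length(manifest$warnings) + 1L]] <<-
        paste0(nm, ": ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[nm]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # -- simulate ------------------------------------------------------
  spec <- do.call(synthetic_spec,
                  c(cfg$synthetic, list(seed = derive_seed(seed, "simulate"))))
  sim <- t_stage("simulate", {
    baseline <- gen_env_stack(spec)
    truth <- truth_surface(baseline, spec)
    futures <- gen_future_stacks(baseline, spec)
    occ <- sample_occurrences(truth, cfg$n_occurrences,
                              seed = derive_seed(seed, "occurrences"))
    aux <- gen_cattle_and_regions(spec, baseline$mask)
    list(baseline = baseline, truth = truth, futures = futures,
         occ = occ, cattle = aux$cattle, regions = aux$regions)
  })

  # -- occurrence prep ----------------------------------------------
  prep <- t_stage("occurrence_prep", {
    thinned <- thin_occurrences(sim$occ, cfg$d_km,
                                seed = derive_seed(seed, "thin"))
    sp <- split_calibration(thinned, cfg$fraction,
                            seed = derive_seed(seed, "split"))
    area <- build_accessible_area(sp$calibration, sim$baseline$grid,
                                  cfg$B_km)
    list(thinned = thinned, cal = sp$calibration, eval = sp$evaluation,
         area = area)
  })
  write_occurrences(prep$cal, file.path(out_dir, "occ_calibration.csv"))
  write_occurrences(prep$eval, file.path(out_dir, "occ_evaluation.csv"))

  # -- environmental filtering --------------------------------------
  env <- t_stage("env_layers", {
    cal_stack <- crop_stack(sim$baseline, prep$area)
    retained <- pearson_filter(cal_stack, r_max = cfg$r_max)
    sets <- enumerate_variable_sets(retained, cfg$min_size)
    if (!is.null(cfg$max_sets) && length(sets) > cfg$max_sets)
      sets <- sets[order(-lengths(sets))][seq_len(cfg$max_sets)]
    list(cal_stack = subset_stack(cal_stack, retained),
         retained = retained, sets = sets)
  })
  writeLines(env$retained, file.path(out_dir, "retained_variables.txt"))

  # -- calibration and selection ------------------------------------
  cands <- t_stage("calibrate", calibrate_candidates(
    env$cal_stack, prep$cal, prep$eval, env$sets, cfg$class_subsets,
    cfg$rms, E = cfg$E, alpha = cfg$alpha,
    proc_iterations = cfg$proc_iterations,
    proc_fraction = cfg$proc_fraction, bg_max = cfg$bg_max,
    knots = cfg$knots, seed = derive_seed(seed, "calibrate")))
  utils::write.csv(as.data.frame(cands),
                   file.path(out_dir, "candidates.csv"), row.names = FALSE)
  report <- t_stage("select", select_best(cands, cfg$alpha, cfg$E))
  best_vars <- strsplit(report$best$variables, "+", fixed = TRUE)[[1]]
  best_classes <- strsplit(report$best$classes, "")[[1]]
  jsonlite::write_json(list(
    counts = as.list(report$counts), best = as.list(report$best),
    delta_aicc = report$delta_aicc, relaxed = report$relaxed),
    file.path(out_dir, "selection_report.json"),
    digits = NA, auto_unbox = TRUE)

  # -- final model and projections ----------------------------------
  targets <- c(list(present = subset_stack(sim$baseline, best_vars)),
               lapply(sim$futures, subset_stack, layers = best_vars))
  proj <- t_stage("project", bootstrap_median_model(
    env$cal_stack, prep$cal, best_vars, best_classes, report$best$rm,
    targets, n_boot = cfg$n_boot, seed = derive_seed(seed, "final"),
    bg_max = cfg$bg_max, knots = cfg$knots))
  write_ascii_grid(proj$projections$present$values, sim$baseline$grid,
                   file.path(out_dir, "suitability_present.asc"))

  # -- MOP -----------------------------------------------------------
  mop_out <- t_stage("mop", {
    future_keys <- names(sim$futures)
    probe <- subset_stack(sim$futures[[future_keys[1]]], best_vars)
    mop(subset_stack(env$cal_stack, best_vars), probe,
        reference_fraction = cfg$mop_reference_fraction,
        sample_cap = cfg$mop_sample_cap,
        seed = derive_seed(seed, "mop"))
  })
  write_ascii_grid(mop_out$similarity$values, sim$baseline$grid,
                   file.path(out_dir, "mop_similarity.asc"))

  # -- binarize / ensemble / change ---------------------------------
  ens <- t_stage("ensemble", {
    cal_suit <- prediction_at(proj$projections$present, prep$cal)
    present_bin <- binarize(proj$projections$present, cal_suit, cfg$E)
    idx <- attr(sim$futures, "index")
    change_maps <- list()
    for (r in spec$rcps) {
      keys <- idx$key[idx$rcp == r]   # both periods pooled per scenario
      bins <- lapply(keys, function(k)
        binarize_with(proj$projections[[k]], present_bin$threshold))
      agr <- agreement(bins, cfg$cutoff_frac)
      change_maps[[r]] <- classify_change(present_bin, agr)
      write_ascii_grid(ifelse(is.na(change_maps[[r]]$classes), NA,
                              change_maps[[r]]$classes),
                       sim$baseline$grid,
                       file.path(out_dir, paste0("change_", r, ".asc")))
    }
    list(present = present_bin, change_maps = change_maps)
  })

  # -- exposure ------------------------------------------------------
  expo <- t_stage("exposure", {
    cats <- categorize_cattle(sim$cattle, cfg$breakpoints)
    tab <- exposure_table(ens$present, ens$change_maps, cats,
                          sim$regions, strong_only = cfg$strong_only)
    flag_high(tab, cfg$flag_cutoff)
  })
  write_exposure_table(expo, file.path(out_dir, "exposure_table.csv"),
                       file.path(out_dir, "exposure_table.txt"))

  # -- manifest ------------------------------------------------------
  outputs <- list.files(out_dir, recursive = TRUE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(manifest$outputs) <- outputs
  manifest$selection <- list(best = report$best$id,
                             counts = as.list(report$counts),
                             delta_aicc = report$delta_aicc)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# binarize a prediction at a fixed, already-computed threshold (the
# present-day threshold is applied unchanged to all future projections)
binarize_with <- function(pred, threshold) {
  structure(list(binary = pred$values >= threshold, threshold = threshold,
                 grid = pred$grid), class = "binary_map")
}
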