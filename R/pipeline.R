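# End-to-end orchestration: one validated config, one master seed with
# stage-scoped derived seeds, structured artifacts and a reproducibility
# manifest.

pipeline_defaults <- function() {
  list(
    # synthetic cohort
    n_subjects = 20, n_global_electrodes = 40, n_modules = 6,
    electrodes_per_subject = c(15, 25), sampling_rate = 512,
    duration = 120, within_module_correlation = 0.8,
    between_module_correlation = 0.1, effect_strength = 0.5,
    connectivity_shift = 0.12, artifact_rate = 0.3, n_boundary = 0,
    # preprocessing
    kurtosis_max = 10, block_s = 60, target_hours = NULL,
    # brain model
    width_mm = 20,
    # parcellation
    gamma = NULL, gamma_min = 0.5, gamma_max = 2.1, gamma_steps = 17,
    allegiance_runs = 20, louvain_restarts = 10,
    # features
    feature_order = "z_then_average", window_s = 30,
    # classifier
    n_components = 4, l1_c = 1.0, classifier_perms = 0,
    # NEPs
    loading_min = 0.2, logodds_min = 0.15, n_neps = 2,
    dominance_margin = 0.05,
    # connectivity
    connectivity_perms = 1000, connectivity_alpha = 0.001,
    # global
    seed = 1L)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, type/range-checks every parameter, records whether each
#' value is a default or user-supplied, and rejects unknown keys with a
#' closest-match suggestion. All violations are reported together.
#'
#' @param config named list of overrides (possibly empty).
#' @return list of class `ndp_pipeline_config` with attribute
#'   `"provenance"`.
#' @export
validate_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errors <- character(0)
  for (k in unknown) {
    sug <- agrep(k, names(defaults), max.distance = 0.3, value = TRUE)
    errors <- c(errors, paste0("unknown key '", k, "'",
                               if (length(sug)) paste0(" (did you mean '",
                                                       sug[1], "'?")))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(cfg$n_subjects >= 4, "n_subjects must be >= 4")
  chk(cfg$sampling_rate >= 512, "sampling_rate must be >= 512")
  chk(cfg$within_module_correlation > cfg$between_module_correlation &&
        cfg$between_module_correlation >= 0,
      "require within_module_correlation > between_module_correlation >= 0")
  chk(cfg$width_mm > 0, "width_mm (RBF width) must be > 0")
  chk(cfg$kurtosis_max > 0, "kurtosis_max must be > 0")
  chk(is.null(cfg$gamma) || cfg$gamma > 0, "gamma must be > 0")
  chk(cfg$gamma_min > 0 && cfg$gamma_max > cfg$gamma_min,
      "require 0 < gamma_min < gamma_max")
  chk(cfg$gamma_steps >= 3, "gamma_steps must be >= 3")
  chk(cfg$n_components >= 1, "n_components must be >= 1")
  chk(cfg$l1_c > 0, "l1_c must be > 0")
  chk(cfg$loading_min >= 0 && cfg$logodds_min >= 0,
      "thresholds must be >= 0")
  chk(cfg$connectivity_alpha > 0 && cfg$connectivity_alpha < 1,
      "connectivity_alpha must be in (0,1)")
  chk(is.null(cfg$target_hours) || cfg$target_hours > 0,
      "target_hours must be NULL or > 0")
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  attr(cfg, "provenance") <- ifelse(names(cfg) %in% names(config),
                                    "user", "default")
  class(cfg) <- "ndp_pipeline_config"
  cfg
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the complete analysis chain
#'
#' simulate -> preprocess -> model -> parcellate -> features -> classify
#' -> neps -> connectivity, with stage-scoped seeds derived from the
#' master seed, artifacts written under `out_dir` and a manifest with
#' config snapshot, per-stage seeds and timings, and file digests.
#'
#' @param config list of overrides, see [validate_config()].
#' @param out_dir artifact directory (created).
#' @return list of class `ndp_run`: all stage results plus `manifest`.
#' @export
run_all <- function(config = list(), out_dir = tempfile("ndp_run_")) {
  cfg <- if (inherits(config, "ndp_pipeline_config")) config else
    validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- sapply(c("simulate", "preprocess", "model", "parcellate",
                    "features", "classify", "neps", "connectivity"),
                  function(s) derive_seed(cfg$seed, s))
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  cohort <- stage_wrap("simulate", {
    sc <- synthetic_config(
      n_subjects = cfg$n_subjects,
      n_global_electrodes = cfg$n_global_electrodes,
      n_modules = cfg$n_modules,
      electrodes_per_subject = cfg$electrodes_per_subject,
      sampling_rate = cfg$sampling_rate, duration = cfg$duration,
      within_module_correlation = cfg$within_module_correlation,
      between_module_correlation = cfg$between_module_correlation,
      effect_strength = cfg$effect_strength,
      connectivity_shift = cfg$connectivity_shift,
      artifact_rate = cfg$artifact_rate, n_boundary = cfg$n_boundary,
      rng_seed = seeds[["simulate"]])
    generate_cohort(sc)
  })
  timing["simulate"] <- tic() - t0; t0 <- tic()

  clean <- stage_wrap("preprocess", {
    out <- lapply(names(cohort$recordings), function(sid)
      preprocess_subject(cohort$recordings[[sid]], cohort$fs,
                         subject_id = sid,
                         start_time = cohort$start_time,
                         kurtosis_max = cfg$kurtosis_max,
                         block_s = cfg$block_s,
                         target_hours = cfg$target_hours,
                         seed = derive_seed(seeds[["preprocess"]], sid)))
    stats::setNames(out, names(cohort$recordings))
  })
  timing["preprocess"] <- tic() - t0; t0 <- tic()

  full_locations <- stage_wrap("model", {
    el <- cohort$electrodes
    fl <- el[!duplicated(el$global_id),
             c("global_id", "electrode_id", "x_mm", "y_mm", "z_mm",
               "region_label")]
    fl[order(fl$global_id), ]
  })
  model_res <- stage_wrap("model", {
    expanded <- lapply(names(clean), function(sid) {
      loc <- cohort$electrodes[cohort$electrodes$subject_id == sid, ]
      m <- subject_correlation_model(clean[[sid]]$data, loc)
      rbf_expand(m, full_locations, cfg$width_mm)
    })
    names(expanded) <- names(clean)
    list(expanded = expanded,
         population = aggregate_population_model(expanded))
  })
  timing["model"] <- tic() - t0; t0 <- tic()

  K <- model_correlation(model_res$population)
  parc <- stage_wrap("parcellate", {
    if (!is.null(cfg$gamma)) {
      louvain_partition(K, cfg$gamma, seed = seeds[["parcellate"]],
                        n_restarts = cfg$louvain_restarts)
    } else {
      grid <- seq(cfg$gamma_min, cfg$gamma_max, length.out = cfg$gamma_steps)
      sw <- gamma_sweep(K, grid, full_locations$region_label,
                        n_runs = cfg$allegiance_runs,
                        n_restarts = cfg$louvain_restarts,
                        seed = seeds[["parcellate"]])
      sw$selected$sweep <- sw$table
      sw$selected
    }
  })
  timing["parcellate"] <- tic() - t0; t0 <- tic()

  features <- stage_wrap("features", {
    rel <- lapply(names(clean), function(sid) {
      loc <- cohort$electrodes[cohort$electrodes$subject_id == sid, ]
      rec <- reconstruct_timeseries(model_res$population,
                                    clean[[sid]]$data, loc$global_id)
      pw <- morlet_band_power(rec$data, fs = 512, window_s = cfg$window_s)
      relative_power(pw)
    })
    names(rel) <- names(clean)
    build_feature_matrix(rel, parc$assignment, order = cfg$feature_order)
  })
  timing["features"] <- tic() - t0; t0 <- tic()

  core <- cohort$subjects$group %in% c("depressed", "control")
  labels <- factor(cohort$subjects$group[core],
                   levels = c("control", "depressed"))
  clf <- stage_wrap("classify", {
    res <- loocv_classify(features$x[core, , drop = FALSE], labels,
                          n_components = cfg$n_components,
                          l1_c = cfg$l1_c, seed = seeds[["classify"]])
    if (cfg$classifier_perms >= 100) {
      res$null <- permutation_null(features$x[core, , drop = FALSE],
                                   labels, cfg$n_components, cfg$l1_c,
                                   n_perm = cfg$classifier_perms,
                                   seed = seeds[["classify"]])
    }
    res
  })
  timing["classify"] <- tic() - t0; t0 <- tic()

  neps <- stage_wrap("neps", {
    lo <- feature_logodds(clf, features$x[core, , drop = FALSE],
                          loading_min = cfg$loading_min,
                          logodds_min = cfg$logodds_min)
    cl <- cluster_neps(lo, n_clusters = cfg$n_neps)
    sens <- nep_sensitivity(clf, features$x[core, , drop = FALSE],
                            cl$feature_nep, labels = labels,
                            dominance_margin = cfg$dominance_margin)
    list(logodds = lo, clusters = cl, sensitivity = sens)
  })
  timing["neps"] <- tic() - t0; t0 <- tic()

  connectivity <- stage_wrap("connectivity", {
    gm <- group_models(model_res$expanded[core], labels)
    permutation_significance(gm$depressed, gm$control, parc$assignment,
                             n_perm = cfg$connectivity_perms,
                             alpha = cfg$connectivity_alpha,
                             seed = seeds[["connectivity"]])
  })
  timing["connectivity"] <- tic() - t0

  # artifacts
  utils::write.csv(data.frame(features$x, check.names = FALSE),
                   file.path(out_dir, "features.csv"))
  utils::write.table(data.frame(electrode_id = full_locations$electrode_id,
                                module_id = parc$assignment),
                     file.path(out_dir, "parcellation.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(contrast_table(connectivity),
                   file.path(out_dir, "connectivity.csv"),
                   row.names = FALSE)
  utils::write.table(neps$sensitivity, file.path(out_dir, "neps.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(balanced_accuracy = clf$balanced_accuracy,
         probabilities = as.list(clf$probabilities)),
    file.path(out_dir, "classifier.json"), auto_unbox = TRUE, digits = NA)

  artifact_files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("neurodep")),
    config = unclass(cfg), seeds = as.list(seeds),
    timing_s = as.list(round(timing, 3)),
    digests = as.list(tools::md5sum(artifact_files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  structure(list(cohort = cohort, clean = clean, model = model_res,
                 parcellation = parc, features = features,
                 classifier = clf, neps = neps,
                 connectivity = connectivity, manifest = manifest,
                 out_dir = out_dir),
            class = "ndp_run")
}

#' Command-line entry point
#'
#' `neurodep simulate --out DIR --seed N [--subjects N] [--duration S]`
#' writes a synthetic cohort; `neurodep run --out DIR --seed N [...]`
#' runs the full pipeline. Invoked by the `inst/cli/neurodep.R` script.
#'
#' @param args character vector of CLI arguments.
#' @return exit status (invisibly).
#' @export
neurodep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: neurodep <simulate|run> --out DIR [--seed N] [--subjects N] [--duration S]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(out = NULL, seed = 1L, subjects = NULL, duration = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option --", key)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$out)) stop(usage)
  cfg <- list(seed = as.integer(opt$seed))
  if (!is.null(opt$subjects)) cfg$n_subjects <- as.integer(opt$subjects)
  if (!is.null(opt$duration)) cfg$duration <- as.numeric(opt$duration)
  if (cmd == "simulate") {
    full <- utils::modifyList(pipeline_defaults(), cfg)
    sc <- synthetic_config(n_subjects = full$n_subjects,
                           duration = full$duration,
                           rng_seed = derive_seed(full$seed, "simulate"))
    write_cohort(generate_cohort(sc), opt$out,
                 format = if (requireNamespace("rhdf5", quietly = TRUE))
                   "hdf5" else "text")
    message("cohort written to ", opt$out)
  } else if (cmd == "run") {
    run_all(cfg, out_dir = opt$out)
    message("pipeline artifacts written to ", opt$out)
  } else stop(usage)
  invisible(0L)
}
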