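#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline stages:
#' `simulation` ([sim_config()]), `binning` (bins per topology: 5 for LEN
#' and FC, 4 for SC and RSN, giving repeated-measures ANOVAs with
#' F(4, 156) and F(3, 117) degrees of freedom at 40 patients),
#' `mahalanobis`
#' ([mahal_config()]; the pipeline default uses 100 x 100 permutations,
#' `full = TRUE` in [run_pipeline()] restores 500 x 500), `ica`
#' ([ica_config()]) and `duration_boundaries`. A single top-level `seed`
#' feeds every stage's RNG stream.
#'
#' @param seed Integer master seed.
#' @return Nested configuration list of class `netprog_config`.
#' @export
netprog_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulation = unclass(sim_config(seed = seed)),
    binning = list(n_bins_len = 5, n_bins_fc = 5, n_bins_sc = 4),
    mahalanobis = list(k_subset = 7, n_edge_permutations = 100,
                       n_control_permutations = 100,
                       n_controls_drawn = 50, min_controls_complete = 45,
                       shrinkage = "ledoit-wolf", lambda = 0.2,
                       squared = TRUE),
    ica = list(n_runs = 40, merge_r_threshold = 0.8, pca_variance = 0.90,
               fc_threshold = 0.55, sc_threshold = 0.175,
               max_missing_fraction = 0.1),
    duration_boundaries = c(10, 30),
    anova_alpha_fc = 0.0125, anova_alpha_sc = 0.0167
  ), class = "netprog_config")
}

merge_config <- function(defaults, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(defaults))
      stop("unknown config key: ", paste0(path, key))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(override[[key]]))
        stop("config key ", paste0(path, key), " must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]],
                                      paste0(path, key, "."))
    } else {
      value <- override[[key]]
      if (is.list(value)) value <- unlist(value)
      defaults[[key]] <- value
    }
  }
  defaults
}

#' Load a pipeline configuration from JSON
#'
#' Reads a JSON file holding any subset of the keys of
#' [netprog_config()] and merges it over the defaults. Unknown keys are a
#' hard error naming the key.
#'
#' @param path JSON file path.
#' @param seed Master seed used for any key the file does not set.
#' @return A `netprog_config` list.
#' @export
load_config <- function(path, seed = 1) {
  override <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- netprog_config(seed = seed)
  cfg <- merge_config(cfg, override)
  class(cfg) <- "netprog_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate, normalize, topology models, hippocampal
#' Mahalanobis profiles with the gradient test battery (four topologies
#' for FC at threshold 0.0125; LEN/SC/FC for SC at 0.0167), duration
#' group analysis for the best model per modality, and the whole-brain
#' hybrid ICA with model correlations. All stage outputs, a run manifest
#' (resolved configuration, seeds, stage wall times, warnings) and a
#' plain-text report are written under `out_dir`. A rerun with the same
#' configuration is bitwise identical.
#'
#' @param config A `netprog_config` list (or path to a JSON config).
#' @param out_dir Output directory.
#' @param full Use the full 500 x 500 permutation counts instead of the
#'   configured desk-scale defaults.
#' @param write_cohort Also write the simulated cohort matrices (large).
#' @return The results list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config = netprog_config(), out_dir,
                         full = FALSE, write_cohort = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "netprog_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  timings <- list()
  note <- function(stage, t0)
    timings[[stage]] <<- round(as.numeric(Sys.time()) - t0, 3)
  withCallingHandlers({
    t0 <- as.numeric(Sys.time())
    simc <- do.call(sim_config, config$simulation)
    sim <- simulate_cohort(simc)
    coh <- normalize_cohort(sim$cohort)
    atlas <- coh$atlas
    note("simulate_normalize", t0)
    if (write_cohort) save_cohort(sim$cohort, file.path(out_dir, "cohort"))

    t0 <- as.numeric(Sys.time())
    topos <- list(LEN = build_topology(coh, "LEN"),
                  SC = build_topology(coh, "SC"),
                  FC = build_topology(coh, "FC"),
                  RSN = build_topology(coh, "RSN"))
    nb <- config$binning
    binnings <- list(
      LEN = hippocampal_binnings(topos$LEN, atlas, nb$n_bins_len),
      SC = hippocampal_binnings(topos$SC, atlas, nb$n_bins_sc),
      FC = hippocampal_binnings(topos$FC, atlas, nb$n_bins_fc),
      RSN = hippocampal_binnings(topos$RSN, atlas))
    note("topologies", t0)

    t0 <- as.numeric(Sys.time())
    mc <- config$mahalanobis
    if (full) {
      mc$n_edge_permutations <- 500
      mc$n_control_permutations <- 500
    }
    mcfg <- do.call(mahal_config, c(mc, list(seed = config$seed)))
    hip <- list()
    tests <- list()
    for (mod in c("FC", "SC")) {
      alpha <- if (mod == "FC") config$anova_alpha_fc else config$anova_alpha_sc
      topo_set <- if (mod == "FC") c("LEN", "SC", "FC", "RSN")
                  else c("LEN", "SC", "FC")
      for (kind in topo_set) {
        prof <- hippocampal_profiles(coh, binnings[[kind]], mod, mcfg)
        hip[[paste(mod, kind, sep = "_")]] <- prof
        for (sd_ in c("ipsi", "contra")) {
          Mm <- profiles_matrix(prof, sd_)
          key <- paste("M", mod, "T", kind, sd_, sep = "_")
          tests[[key]] <- tryCatch(gradient_test(Mm, alpha = alpha),
                                   error = function(e) e$message)
        }
      }
    }
    note("hippocampal", t0)

    t0 <- as.numeric(Sys.time())
    # duration-group analysis for the best (largest-F verdict-eligible)
    # ipsilateral model per modality
    dur_groups <- list()
    pats <- cohort_subjects(coh, "patient")
    for (mod in c("FC", "SC")) {
      keys <- grep(paste0("^M_", mod, "_.*_ipsi$"), names(tests), value = TRUE)
      fs <- vapply(keys, function(k)
        if (inherits(tests[[k]], "gradient_test")) tests[[k]]$F else NA_real_,
        0)
      if (all(is.na(fs))) next
      best <- keys[which.max(fs)]
      kind <- sub(paste0("^M_", mod, "_T_"), "", sub("_ipsi$", "", best))
      Mm <- profiles_matrix(hip[[paste(mod, kind, sep = "_")]], "ipsi")
      dur <- pats$duration[match(rownames(Mm), pats$subject_id)]
      dur_groups[[mod]] <- c(list(model = kind),
                             duration_group_analysis(Mm, dur,
                                                     config$duration_boundaries))
    }
    note("duration_groups", t0)

    t0 <- as.numeric(Sys.time())
    icfg <- do.call(ica_config, c(config$ica, list(seed = config$seed)))
    wb <- wholebrain_analysis(coh, topos, icfg)
    note("wholebrain_ica", t0)

    results <- list(tests = tests, duration_groups = dur_groups,
                    wholebrain = wb, binnings = binnings)
    write_pipeline_outputs(results, hip, config, timings, warnings_log,
                           out_dir)
    invisible(results)
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

gradient_test_json <- function(x) {
  if (!inherits(x, "gradient_test")) return(list(error = unclass(x)))
  list(F = x$F, df1 = x$df1, df2 = x$df2, p = x$p,
       bin_means = unname(x$bin_means),
       monotone_decrease = x$monotone_decrease, alpha = x$alpha,
       n_patients = x$n_patients, verdict = x$verdict)
}

write_pipeline_outputs <- function(results, hip, config, timings,
                                   warnings_log, out_dir) {
  for (key in names(hip))
    utils::write.csv(as.data.frame(hip[[key]]),
                     file.path(out_dir, paste0("profiles_", key, ".csv")),
                     row.names = FALSE)
  tests_json <- lapply(results$tests, gradient_test_json)
  dg <- lapply(results$duration_groups, function(d) {
    list(model = d$model,
         group_sizes = as.list(table(d$groups)),
         per_group = lapply(d$per_group, gradient_test_json),
         interaction = d$interaction)
  })
  wb <- results$wholebrain
  wb_json <- list(
    n_components = ncol(wb$result$components),
    frequency = wb$result$frequency,
    duration_rho = wb$result$duration_rho,
    duration_p = wb$result$duration_p,
    primary = wb$result$primary,
    model_correlations = wb$model_correlations)
  report <- list(tests = tests_json, duration_groups = dg,
                 wholebrain = wb_json)
  jsonlite::write_json(report, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("netprog")),
                   config = unclass(config), seed = config$seed,
                   stage_seconds = timings, warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report_txt <- c(
    "netprog pipeline report",
    "=======================",
    "",
    "Gradient tests (M by topology, ipsi/contra):",
    vapply(names(tests_json), function(k) {
      tj <- tests_json[[k]]
      if (!is.null(tj$error)) sprintf("  %-22s %s", k, tj$error)
      else sprintf("  %-22s F(%d,%d)=%.2f p=%.4g monotone=%s verdict=%s",
                   k, tj$df1, tj$df2, tj$F, tj$p,
                   tj$monotone_decrease, tj$verdict)
    }, ""),
    "",
    sprintf("Whole-brain ICA: %d merged components, primary = %s",
            wb_json$n_components,
            ifelse(is.na(wb_json$primary), "none", wb_json$primary)))
  writeLines(report_txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
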