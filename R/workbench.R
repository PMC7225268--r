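#' Run an end-to-end two-group recording study
#'
#' Simulates a longitudinal two-group study, derives per-channel unit
#' statistics either from ground truth (`pipeline = "ground_truth"`, the
#' default, suitable for full-size statistical studies) or by running the
#' full detection pipeline on synthesized voltage traces
#' (`pipeline = "full"`, heavier; intended for reduced designs), restricts
#' metrics to each animal's most-active channel window, and fits the
#' 5-metric x 3-time-range nested GLM suite.
#'
#' @param spec a [study_spec()].
#' @param windows consecutive-channel window length per group.
#' @param pipeline `"ground_truth"` or `"full"`.
#' @param duration session length (s) when `pipeline = "full"`.
#' @param out_dir optional directory; when given, writes `metrics.csv`,
#'   `glm_results.csv` and `report.json` (including removed-data
#'   bookkeeping and the spec echo needed to reproduce the run).
#' @param alpha significance level for the comparison suite.
#' @return A list: `study_table` (metrics per session), `results` (15 GLM
#'   rows), `report` (bookkeeping list).
#' @export
run_full_study <- function(spec, windows = c(rat = 10L, mouse = 8L),
                           pipeline = c("ground_truth", "full"),
                           duration = 6, out_dir = NULL, alpha = 0.05) {
  pipeline <- match.arg(pipeline)
  study <- simulate_study(spec, traces = pipeline == "full",
                          duration = duration)
  if (pipeline == "ground_truth") {
    chan <- study_channel_truth(study)
  } else {
    rows <- vector("list", nrow(study))
    for (i in seq_len(nrow(study))) {
      pr <- process_session(study$recording[[i]]$session)
      rows[[i]] <- bind_cols(
        study[i, c("group", "animal", "week", "session")], pr$channels)
    }
    chan <- list_rbind(rows)
  }
  tbl <- build_study_table(chan, windows = windows)
  res <- run_comparison_suite(tbl, alpha = alpha)
  n_sessions <- nrow(distinct(chan, .data$animal, .data$week, .data$session))
  report <- list(
    seed = spec$seed,
    n_animals = sum(spec$groups),
    n_sessions = n_sessions,
    frac_sessions_removed = 0,
    frac_channels_removed = mean(!(chan$working %in% TRUE)),
    n_significant = sum(res$significant, na.rm = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tbl, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res[, names(res) != "amp"],
                     file.path(out_dir, "glm_results.csv"), row.names = FALSE)
    spec_echo <- unclass(spec)
    spec_echo$groups <- as.list(spec_echo$groups)
    jsonlite::write_json(c(report, list(spec = spec_echo)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(study_table = tbl, results = res, report = report)
}

#' Run the rat-vs-mouse strain comparison
#'
#' Builds and solves both species' probe-in-cortex models, normalizes the
#' von Mises strain fields by their joint maximum, extracts the lateral
#' strain profiles at the brain top, probe mid-point and tip, and computes
#' the Pearson correlation between the two species' profile sets.
#'
#' @param configs list of two [fem_config()]s (default rat and mouse).
#' @param coarse_size,fine_size mesh sizes, um.
#' @param out_dir optional directory; when given, writes per-species VTK
#'   fields, `profiles.csv` and `summary.json`.
#' @return A list: `correlation`, `joint_max`, `profiles` (tidy tibble for
#'   both species), `runs` (the two [run_strain_model()] results, fields
#'   normalized), `mesh_stats`.
#' @export
run_strain_comparison <- function(configs = list(fem_config("rat"),
                                                 fem_config("mouse")),
                                  coarse_size = 500, fine_size = 85,
                                  out_dir = NULL) {
  stopifnot(length(configs) == 2)
  runs <- lapply(configs, run_strain_model, coarse_size = coarse_size,
                 fine_size = fine_size)
  nz <- normalize_fields_jointly(runs[[1]]$field, runs[[2]]$field)
  profs <- vector("list", 2)
  for (i in 1:2) {
    runs[[i]]$field <- nz$fields[[i]]
    profs[[i]] <- extract_profiles(nz$fields[[i]], runs[[i]]$mesh,
                                   runs[[i]]$model) |>
      mutate(species = configs[[i]]$species, .before = 1)
  }
  r <- correlate_profiles(profs[[1]][, c("location", "distance", "strain")],
                          profs[[2]][, c("location", "distance", "strain")])
  mesh_stats <- lapply(runs, function(x)
    list(species = x$model$species, n_nodes = nrow(x$mesh$nodes),
         n_elements = nrow(x$mesh$elems)))
  out <- list(correlation = r, joint_max = nz$joint_max,
              profiles = list_rbind(profs), runs = runs,
              mesh_stats = mesh_stats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in 1:2)
      write_vtk(runs[[i]]$mesh,
                list(von_mises = runs[[i]]$field$von_mises,
                     normalized = runs[[i]]$field$normalized),
                file.path(out_dir, paste0(configs[[i]]$species, ".vtk")))
    utils::write.csv(out$profiles, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(correlation = r, joint_max = nz$joint_max,
                              mesh = mesh_stats,
                              coarse_size = coarse_size,
                              fine_size = fine_size),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
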