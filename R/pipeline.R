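#' Pipeline configuration
#'
#' Collects every knob of the scan-analysis pipeline with its default.
#' Any subset can be overridden; `run_pipeline()` also accepts a YAML or
#' JSON file holding these keys.
#'
#' @param energies Energy table: a data frame or a CSV path with columns
#'   `mode,i,state,energy`.
#' @param unit Unit of the energy column (`"hartree"` or `"ev"`).
#' @param geometry,modes Optional paths to the equilibrium XYZ and the
#'   modes file; when given, PED categories and frequencies are included
#'   in the outputs.
#' @param ground,excited,second State labels for the ground state, the
#'   fitted excited state and the state checked for crossings against
#'   the excited state (`NULL` disables crossing detection).
#' @param gap_threshold Crossing gap threshold (eV).
#' @param excitation_offset `"auto"` or a fixed vertical excitation
#'   energy (eV).
#' @param k_sd,sd_convention Threshold multiplier and SD convention.
#' @param dominance PED dominance threshold (percent).
#' @param outdir Output directory for the report CSVs (`NULL` = no
#'   files, results returned only).
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic; the seed matters only for synthetic inputs).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(energies = NULL, unit = "ev",
                            geometry = NULL, modes = NULL,
                            ground = "S0", excited = "S1", second = "S2",
                            gap_threshold = 0.15,
                            excitation_offset = "auto",
                            k_sd = 1, sd_convention = "sample",
                            dominance = 60,
                            outdir = NULL, seed = NULL) {
  structure(list(
    energies = energies, unit = unit, geometry = geometry, modes = modes,
    ground = ground, excited = excited, second = second,
    gap_threshold = gap_threshold, excitation_offset = excitation_offset,
    k_sd = k_sd, sd_convention = sd_convention, dominance = dominance,
    outdir = outdir, seed = seed
  ), class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, cfg[intersect(names(cfg), known)])
}

#' Run the full scan-analysis pipeline
#'
#' Assembles scans from an energy table, detects and diabatizes
#' excited-state crossings, computes per-mode fit metrics, PED
#' categories (when geometry and modes are supplied), mean + k.SD
#' thresholds and the eight-case assignment, and (optionally) writes
#' `metrics.csv`, `ped.csv`, `cases.csv`, `crossings.csv` and a
#' `manifest.yaml` echoing the configuration.
#'
#' @param config A [pipeline_config()], a plain named list of its keys,
#'   or a path to a YAML/JSON config file.
#' @param ... Individual config keys overriding `config`.
#' @return Invisibly, a list with `scans` (diabatized), `crossings`,
#'   `metrics`, `thresholds`, `cases` and `ped` (NULL without
#'   geometry/modes inputs).
#' @examples
#' suite <- generate_benchmark_suite(20, seed = 42)
#' res <- run_pipeline(pipeline_config(energies = suite$energies))
#' table(res$cases$case)
#' @export
run_pipeline <- function(config = pipeline_config(), ...) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(as.list(config), list(...))
  cfg <- do.call(pipeline_config, config[intersect(names(config), names(formals(pipeline_config)))])
  if (is.null(cfg$energies)) stop("pipeline stage 'scan': no energy table configured", call. = FALSE)

  tab <- if (is.character(cfg$energies)) readr::read_csv(cfg$energies, show_col_types = FALSE)
         else cfg$energies
  scans <- assemble_scans(tab, unit = cfg$unit, ground = cfg$ground)

  crossings <- if (!is.null(cfg$second) && cfg$second %in% scans$state) {
    detect_crossings(scans, state_a = cfg$excited, state_b = cfg$second,
                     gap_threshold = cfg$gap_threshold)
  } else {
    detect_crossings(scans[0, ], state_a = cfg$excited, state_b = cfg$second %||% "S2")
  }
  scans <- diabatize(scans, crossings)
  crossings <- attr(scans, "diabatization")

  ms <- NULL
  if (!is.null(cfg$geometry) && !is.null(cfg$modes)) {
    geom <- load_geometry(cfg$geometry)
    ms <- load_modes(cfg$modes, geom)
  }
  metrics <- mode_metrics(scans, ground = cfg$ground, excited = cfg$excited,
                          excitation_offset = cfg$excitation_offset, mode_set = ms)
  thresholds <- compute_thresholds(metrics, k_sd = cfg$k_sd,
                                   sd_convention = cfg$sd_convention)
  cases <- assign_cases(metrics, thresholds)
  ped <- if (!is.null(ms)) ped_table(ms, dominance = cfg$dominance) else NULL
  if (!is.null(ped)) {
    cases <- dplyr::left_join(cases, ped[, c("mode", "category")], by = "mode")
  }

  if (!is.null(cfg$outdir)) {
    if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
    readr::write_csv(metrics, file.path(cfg$outdir, "metrics.csv"))
    readr::write_csv(cases, file.path(cfg$outdir, "cases.csv"))
    readr::write_csv(crossings, file.path(cfg$outdir, "crossings.csv"))
    if (!is.null(ped)) readr::write_csv(ped, file.path(cfg$outdir, "ped.csv"))
    manifest <- list(
      package = "modescan",
      version = as.character(utils::packageVersion("modescan")),
      seed = cfg$seed,
      config = lapply(as.list(cfg), function(x) if (is.data.frame(x)) "<in-memory table>" else x),
      thresholds = as.list(thresholds[1, 1:3]),
      diabatized_modes = crossings$mode[crossings$swapped],
      lambda_fallback_modes = metrics$mode[metrics$lambda_fallback]
    )
    yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  }
  invisible(list(scans = scans, crossings = crossings, metrics = metrics,
                 thresholds = thresholds, cases = cases, ped = ped))
}
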