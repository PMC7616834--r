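#' Run the full connectome + physiology analysis pipeline
#'
#' Chains the stages end to end: (optional) synthetic-data simulation or
#' loading of real input files, synapse counting, input fractions, cluster
#' budgets, sensory pathway scores with modality rollup, bilateral
#' symmetry report, geodesic synapse placement, and (optional) trace
#' physiology — writing every table plus a JSON run manifest whose file
#' digests are identical across reruns with the same config and seed.
#'
#' @param config Either a list, or a path to a YAML/JSON config file. Keys:
#'   `synthgen` (a list of [circuit_config] arguments, and optionally
#'   `trace` with [trace_config] arguments) to simulate inputs; or
#'   `inputs` with `skeleton_manifest`, `connectors`, `annotations` and
#'   optionally `trace_csv` naming real files. Optional `pathways` list
#'   (`max_layers`), `physiology` list (`threshold_k`, `min_interval`,
#'   `min_prominence`, `window`), `symmetry` list (`measure`).
#' @param out_dir Output directory.
#' @param seed Seed overriding `config$synthgen$seed`.
#' @param through Last stage to execute (`"simulate"`, `"counts"`,
#'   `"fractions"`, `"pathways"`, `"symmetry"`, `"placement"`,
#'   `"physiology"`, `"report"`); `"all"` is a synonym for `"report"`.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` as well.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, through = "all") {
  stage_order <- c(simulate = 0L, counts = 1L, fractions = 2L,
                   pathways = 3L, symmetry = 4L, placement = 5L,
                   physiology = 6L, report = 7L, all = 7L)
  if (!through %in% names(stage_order))
    abort_validation(paste0("unknown stage: ", through))
  lim <- stage_order[[through]]
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character(0)
  note <- function(w) warnings_seen <<- c(warnings_seen, conditionMessage(w))
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  stage <- "config"
  tryCatch(withCallingHandlers({
    stage <- "inputs"
    if (!is.null(config$synthgen)) {
      stage <- "simulate"
      args <- config$synthgen
      args$trace <- NULL
      if (!is.null(seed)) args$seed <- seed
      cfg <- do.call(circuit_config, args)
      gen <- generate_circuit(cfg)
      paths <- write_circuit(gen, file.path(out_dir, "inputs"))
      skeletons <- gen$skeletons
      connectors <- gen$connectors
      neurons <- gen$neurons
      input_files <- unlist(paths)
      trace_cfg_args <- config$synthgen$trace
      trace <- if (!is.null(trace_cfg_args)) {
        if (!is.null(seed)) trace_cfg_args$seed <- seed
        tgen <- generate_trace(do.call(trace_config, trace_cfg_args))
        p <- file.path(out_dir, "inputs", "trace.csv")
        write_trace(tgen, p)
        input_files <- c(input_files, p)
        tgen$trace
      }
    } else if (!is.null(config$inputs)) {
      inp <- config$inputs
      for (f in c(inp$skeleton_manifest, inp$connectors, inp$annotations,
                  inp$trace_csv))
        if (!file.exists(f))
          abort_validation(sprintf("stage inputs: missing file %s", f))
      skeletons <- read_skeleton_manifest(inp$skeleton_manifest)
      connectors <- read_connectors(inp$connectors)
      neurons <- read_neuron_annotations(inp$annotations)
      input_files <- c(inp$skeleton_manifest, inp$connectors,
                       inp$annotations)
      trace <- if (!is.null(inp$trace_csv)) {
        input_files <- c(input_files, inp$trace_csv)
        read_trace(inp$trace_csv)
      }
    } else {
      abort_validation("config needs either a 'synthgen' or an 'inputs' block")
    }

    rollup <- sym <- physiology_summary <- NULL

    if (lim >= 1L) {
    stage <- "counts"
    counts <- build_counts(connectors, neurons)
    emit(write_matrix_csv(counts, file.path(out_dir, "counts.csv")))
    cluster_pct <- aggregate_by_cluster(counts, neurons, percent_out = TRUE)
    emit(write_matrix_csv(cluster_pct,
                          file.path(out_dir, "cluster_output_percent.csv")))
    pz <- peripheral_zone_tally(connectors)
    emit({
      utils::write.csv(pz, file.path(out_dir, "peripheral_zones.csv"),
                       row.names = FALSE)
      file.path(out_dir, "peripheral_zones.csv")
    })
    }

    if (lim >= 2L) {
    stage <- "fractions"
    fractions <- suppressMessages(input_fractions(counts))
    emit(write_matrix_csv(fractions, file.path(out_dir, "fractions.csv")))
    }

    if (lim >= 3L) {
    stage <- "pathways"
    sensory <- neurons$neuron_id[neurons$cell_class == "sensory"]
    inter <- neurons$neuron_id[neurons$cell_class == "interneuron"]
    targets <- neurons$neuron_id[neurons$cell_class == "modulatory"]
    max_layers <- config$pathways$max_layers %||% 2L
    if (length(sensory) && length(targets)) {
      ds <- suppressMessages(direct_scores(fractions, sensory, targets))
      is_ <- suppressMessages(
        indirect_scores(fractions, sensory, inter, targets,
                        max_layers = max_layers))
      pt <- rbind(ds, is_)
      emit({
        utils::write.csv(pt, file.path(out_dir, "pathways.csv"),
                         row.names = FALSE)
        file.path(out_dir, "pathways.csv")
      })
      modality_map <- stats::setNames(neurons$modality, neurons$neuron_id)
      modality_map <- modality_map[!is.na(modality_map)]
      rollup <- suppressMessages(modality_rollup(ds, is_, modality_map))
      emit({
        utils::write.csv(rollup, file.path(out_dir, "modality_weights.csv"),
                         row.names = FALSE)
        file.path(out_dir, "modality_weights.csv")
      })
    }
    }

    if (lim >= 4L) {
    stage <- "symmetry"
    paired_clusters <- unique(
      neurons$cluster[neurons$hemisphere %in% c("L", "R")])
    budgets <- do.call(rbind, lapply(paired_clusters, function(clu) {
      do.call(rbind, lapply(c("in", "out"), function(dir) {
        b <- hemisphere_budgets(connectors, neurons, clu, dir)
        data.frame(cluster = clu, direction = dir, LL = b$LL, RR = b$RR,
                   LR = b$LR, RL = b$RL)
      }))
    }))
    sym <- suppressMessages(
      symmetry_report(budgets,
                      measure = config$symmetry$measure %||% "percent"))
    emit(write_symmetry_report(sym, file.path(out_dir, "symmetry.csv"),
                               file.path(out_dir, "symmetry.json")))
    emit(file.path(out_dir, "symmetry.json"))
    }

    if (lim >= 5L) {
    stage <- "placement"
    cluster_of <- stats::setNames(neurons$cluster, neurons$neuron_id)
    placements <- do.call(rbind, lapply(skeletons, function(s) {
      if (is.null(s$origin_node)) return(NULL)
      synapse_distances(s, connectors, partner_group = cluster_of)
    }))
    emit({
      utils::write.csv(placements, file.path(out_dir, "placement.csv"),
                       row.names = FALSE)
      file.path(out_dir, "placement.csv")
    })
    }

    if (lim >= 6L && !is.null(trace)) {
      stage <- "physiology"
      ph <- config$physiology %||% list()
      res <- analyze_trace(trace,
                           threshold_k = ph$threshold_k %||% 3,
                           min_interval = ph$min_interval %||% 1,
                           min_prominence = ph$min_prominence %||% 0.1,
                           window = ph$window %||% 2)
      physiology_summary <- list(
        n_triggers = length(res$roi1_events),
        n_waves = length(res$roi2_events),
        cycle_freq_trigger_per_min = res$cycle_freq_trigger_per_min,
        cycle_freq_wave_per_min = res$cycle_freq_wave_per_min,
        completion_rate_percent = res$completion_rate_percent,
        n_orphan_waves = length(res$pairing$orphan_roi2_events))
      jsonlite::write_json(physiology_summary,
                           file.path(out_dir, "physiology.json"),
                           auto_unbox = TRUE, digits = NA)
      emit(file.path(out_dir, "physiology.json"))
    }

    if (lim >= 7L) {
    stage <- "report"
    summary <- list(
      n_neurons = nrow(neurons),
      n_connectors = length(unique(connectors$connector_id)),
      n_synaptic_pairs = sum(!is.na(connectors$post_neuron)),
      n_peripheral_zones = sum(is.na(connectors$post_neuron)),
      modality_weights = rollup,
      symmetry = if (!is.null(sym)) sym$correlation,
      physiology = physiology_summary)
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    emit(file.path(out_dir, "report.json"))

    report_txt <- c(
      sprintf("neurons: %d", summary$n_neurons),
      sprintf("connectors: %d (synaptic pairs %d, peripheral zones %d)",
              summary$n_connectors, summary$n_synaptic_pairs,
              summary$n_peripheral_zones),
      if (!is.null(physiology_summary))
        sprintf("completion rate: %.1f%% (%d triggers)",
                physiology_summary$completion_rate_percent,
                physiology_summary$n_triggers))
    writeLines(report_txt, file.path(out_dir, "report.txt"))
    emit(file.path(out_dir, "report.txt"))
    }
  },
  warning = function(w) { note(w); invokeRestart("muffleWarning") },
  message = function(m) invokeRestart("muffleMessage")),
  vagusnet_error = function(e)
    abort(sprintf("stage %s: %s", stage, conditionMessage(e)), class(e)[1L]))

  manifest <- list(
    config_hash = digest_config(config),
    seed = seed %||% config$synthgen$seed %||% NA,
    inputs = as.list(stats::setNames(unname(tools::md5sum(input_files)),
                                     basename(input_files))),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    n_warnings = length(warnings_seen),
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_validation("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

digest_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
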