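#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis with the published
#' defaults: detection parameters, graph mode (`R > 0.3` fixed threshold or
#' shuffle-calibrated), shuffle counts and level, bias-control iterations,
#' FOV inclusion minimum (20 cells), cohort size and the base seed. Inputs
#' come either from the synthetic generator (`sim`) or from a directory
#' previously written by [run_pipeline()] (`input_dir`).
#'
#' @param sim A [sim_config()] template for simulated cohorts.
#' @param n_animals Number of animals to simulate (ignored with `input_dir`).
#' @param input_dir Optional directory of inputs from a previous run.
#' @param params [detection_params()].
#' @param graph_mode `"fixed"`, `"shuffle"` or `"shuffle-bonferroni"`.
#' @param r_threshold Fixed-mode threshold.
#' @param alpha,n_shuffles Shuffle-mode settings.
#' @param n_bias_iter Partner-bias-control iterations.
#' @param min_cells FOV inclusion minimum.
#' @param seed Base seed; every random stage derives its seed from it.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), n_animals = 12, input_dir = NULL,
                       params = detection_params(),
                       graph_mode = c("fixed", "shuffle",
                                      "shuffle-bonferroni"),
                       r_threshold = 0.3, alpha = 0.05, n_shuffles = 1000,
                       n_bias_iter = 10000, min_cells = 20, seed = 1L) {
  graph_mode <- match.arg(graph_mode)
  stopifnot(inherits(sim, "sim_config"), inherits(params, "detection_params"),
            n_animals >= 1L, min_cells >= 0L)
  structure(list(sim = sim, n_animals = as.integer(n_animals),
                 input_dir = input_dir, params = params,
                 graph_mode = graph_mode, r_threshold = r_threshold,
                 alpha = alpha, n_shuffles = n_shuffles,
                 n_bias_iter = n_bias_iter, min_cells = min_cells,
                 seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(log_path, stage, msg, seed = NA) {
  line <- sprintf("%s\t%s\tseed=%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), stage,
                  as.character(seed), msg)
  cat(line, "\n", file = log_path, sep = "", append = TRUE)
  invisible(line)
}

## analyze one animal's dataset; writes artifacts under dir, returns the
## per-FOV summary row(s) used by the cohort regression
analyze_animal <- function(dataset, config, dir, log_path, animal) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- names(dataset$traces)
  seed0 <- dataset$seed
  trains <- list()
  graphs <- list()
  metrics <- list()
  files <- character(0)

  for (s in seq_along(sessions)) {
    lab <- sessions[s]
    p_tr <- file.path(dir, sprintf("traces_%s.csv", lab))
    write_traces_csv(dataset$traces[[lab]], p_tr)
    p_tl <- file.path(dir, sprintf("timeline_%s.json", lab))
    write_timeline_json(dataset$timelines[[lab]], p_tl)
    files <- c(files, p_tr, paste0(p_tr, ".json"), p_tl)

    log_line(log_path, "detect", sprintf("%s session %s", animal, lab))
    tr <- detect_transients(dataset$traces[[lab]], config$params)
    tr$duration <- dataset$timelines[[lab]]$duration
    trains[[lab]] <- tr
    p_ev <- file.path(dir, sprintf("events_%s.tsv", lab))
    write_events_tsv(tr, p_ev)
    files <- c(files, p_ev)

    log_line(log_path, "graph", sprintf("%s session %s (%s)", animal, lab,
                                        config$graph_mode))
    g <- correlation_graph(tr, mode = config$graph_mode,
                           r_threshold = config$r_threshold,
                           min_cells = 0,
                           n_shuffles = config$n_shuffles,
                           alpha = config$alpha,
                           seed = derive_seed(seed0, 601L + s))
    graphs[[lab]] <- g
    metrics[[lab]] <- node_metrics(g, n_cells_fov = length(g$cell_ids))
    p_edge <- file.path(dir, sprintf("edges_%s.tsv", lab))
    write_edges_tsv(g, p_edge)
    p_met <- file.path(dir, sprintf("metrics_%s.tsv", lab))
    write_metrics_tsv(metrics[[lab]], lab, p_met)
    files <- c(files, p_edge, p_met)
  }

  ## shock-cell classification on the encoding session
  enc <- sessions[vapply(dataset$timelines,
                         function(t) !is.null(t$shock), logical(1L))][1L]
  labels <- NULL
  summary_rows <- NULL
  bias <- NULL
  if (!is.na(enc) && "A2" %in% sessions) {
    log_line(log_path, "classify", sprintf("%s shock cells (%s)", animal, enc))
    shock <- classify_shock_cells(trains[[enc]], dataset$timelines[[enc]],
                                  seed = derive_seed(seed0, 701L))
    part <- partition_partners(graphs[["A2"]], shock)
    labels <- merge(shock, part, by = "cell_id", sort = TRUE)
    p_lab <- file.path(dir, "labels.tsv")
    write_tsv(labels, p_lab)
    files <- c(files, p_lab)

    deltas <- session_deltas(metrics, labels = part, reference = enc)
    p_del <- file.path(dir, "deltas.tsv")
    write_tsv(deltas, p_del)
    files <- c(files, p_del)

    d_a2 <- deltas[deltas$session == "A2", ]
    if (any(d_a2$class == "A2_shock_partner")) {
      log_line(log_path, "bias_control", animal)
      bias <- partner_bias_control(d_a2, graphs[["A2"]],
                                   n_iter = config$n_bias_iter,
                                   seed = derive_seed(seed0, 801L))
      p_bias <- file.path(dir, "bias_control.tsv")
      write_tsv(bias, p_bias)
      files <- c(files, p_bias)
    }

    frz_change <-
      (percent_freezing(dataset$timelines[["A2"]]) -
         percent_freezing(dataset$timelines[[enc]],
                          window = c(0, dataset$timelines[[enc]]$shock[1L]))) / 100
    sm <- delta_summary(deltas)
    un <- sm[sm$class == "shock_and_partner" & sm$session == "A2", ]
    summary_rows <- data.frame(animal = animal, metric = un$metric,
                               mean_delta = un$mean_delta,
                               freezing_change = frz_change)
  }
  list(files = files, labels = labels, summary = summary_rows, bias = bias)
}

#' Run the full analysis pipeline
#'
#' One-command end-to-end run: simulate (or load) per-animal datasets,
#' detect transients, build per-session correlation graphs and node
#' metrics, classify shock cells, partition A2 shock-partners, compute
#' cross-session deltas and the partner-bias control, regress per-FOV mean
#' deltas on freezing change, and write every artifact plus a manifest
#' (file list with MD5 hashes, parameter echo, seeds) and a timestamped
#' log. FOVs below the inclusion minimum are skipped and the exclusion
#' recorded in the manifest.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(NULL, file = log_path)
  log_line(log_path, "start", "pipeline run", seed = config$seed)

  ## assemble datasets
  datasets <- list()
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      stop(sprintf("missing input: %s", config$input_dir), call. = FALSE)
    animal_dirs <- list.dirs(config$input_dir, recursive = FALSE)
    if (!length(animal_dirs)) stop("input_dir has no animal directories",
                                   call. = FALSE)
    for (ad in animal_dirs) {
      tls <- Sys.glob(file.path(ad, "timeline_*.json"))
      timelines <- lapply(tls, read_timeline_json)
      names(timelines) <- vapply(timelines, `[[`, character(1L), "label")
      traces <- lapply(names(timelines), function(lab)
        read_traces_csv(file.path(ad, sprintf("traces_%s.csv", lab))))
      names(traces) <- names(timelines)
      datasets[[basename(ad)]] <- structure(
        list(trains = NULL, traces = traces, timelines = timelines,
             centroids = NULL, config = config$sim, seed = config$seed),
        class = "ca_dataset")
    }
  } else {
    for (a in seq_len(config$n_animals)) {
      cfg <- config$sim
      cfg$seed <- derive_seed(config$seed, 900L + a)
      log_line(log_path, "simulate", sprintf("animal_%02d", a), seed = cfg$seed)
      datasets[[sprintf("animal_%02d", a)]] <- simulate_animal(cfg)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("caensemble")),
    seed = config$seed,
    parameters = list(
      detection = unclass(config$params), graph_mode = config$graph_mode,
      r_threshold = config$r_threshold, alpha = config$alpha,
      n_shuffles = config$n_shuffles, n_bias_iter = config$n_bias_iter,
      min_cells = config$min_cells, n_animals = length(datasets)),
    exclusions = list(), animals = character(0), files = list())

  all_files <- character(0)
  cohort <- NULL
  for (animal in names(datasets)) {
    ds <- datasets[[animal]]
    n_cells <- nrow(ds$traces[[1L]]$values)
    if (n_cells < config$min_cells) {
      msg <- sprintf("%s excluded: %d cells < FOV minimum %d", animal,
                     n_cells, config$min_cells)
      log_line(log_path, "exclude", msg)
      manifest$exclusions[[animal]] <-
        list(n_cells = n_cells, min_cells = config$min_cells)
      next
    }
    res <- tryCatch(
      analyze_animal(ds, config, file.path(out_dir, animal), log_path, animal),
      error = function(e) stop(sprintf("stage failure in %s: %s", animal,
                                       conditionMessage(e)), call. = FALSE))
    manifest$animals <- c(manifest$animals, animal)
    all_files <- c(all_files, res$files)
    if (!is.null(res$summary)) cohort <- rbind(cohort, res$summary)
  }

  ## cohort-level memory-strength regression (needs >= 3 FOVs)
  if (!is.null(cohort) && length(unique(cohort$animal)) >= 3L) {
    log_line(log_path, "regression",
             sprintf("%d FOVs", length(unique(cohort$animal))))
    p_coh <- file.path(out_dir, "cohort_deltas.tsv")
    write_tsv(cohort, p_coh)
    all_files <- c(all_files, p_coh)
    reg <- lapply(split(cohort, cohort$metric), function(d)
      regress_deltas_on_freezing(d, delta_col = "mean_delta"))
    p_reg <- file.path(out_dir, "regression.json")
    jsonlite::write_json(reg, p_reg, auto_unbox = TRUE, digits = NA)
    all_files <- c(all_files, p_reg)
  }

  manifest$files <- lapply(sort(all_files), function(f)
    list(path = sub(paste0("^", out_dir, "/?"), "", f),
         md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_path, "done", sprintf("%d files", length(all_files)))
  invisible(manifest)
}
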