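#' Analysis run configuration
#'
#' All tunable parameters of an analysis run, serializable to/from YAML so
#' every output bundle can embed the exact configuration that produced it.
#'
#' @param input Path to the tidy track CSV.
#' @param output_dir Directory for the report bundle.
#' @param dt Frame interval, minutes.
#' @param nk_threshold,ck_threshold Event thresholds, um (strict).
#' @param min_duration QC minimum track duration, minutes.
#' @param reference_vector SVZ-to-OB axis, length-2 numeric.
#' @param group Cohort label attached to every cell.
#' @param dataset_id Dataset identifier.
#' @param seed Seed for any stochastic statistics (Monte-Carlo Fisher).
#' @param nk_merge Merge consecutive supra-threshold steps into one NK.
#' @param ck_frame `"relative"` or `"absolute"` (see [detect_ck_events()]).
#' @param max_gap Gap-splitting threshold, minutes (default `dt`).
#' @return A `saltmig_config` list.
#' @export
run_config <- function(input, output_dir, dt = 3, nk_threshold = 6,
                       ck_threshold = 2, min_duration = 30,
                       reference_vector = c(1, 0), group = "unknown",
                       dataset_id = NA_character_, seed = 1,
                       nk_merge = TRUE, ck_frame = "relative",
                       max_gap = NULL) {
  cfg <- list(input = input, output_dir = output_dir, dt = dt,
              nk_threshold = nk_threshold, ck_threshold = ck_threshold,
              min_duration = min_duration,
              reference_vector = as.numeric(reference_vector),
              group = group, dataset_id = dataset_id, seed = seed,
              nk_merge = nk_merge, ck_frame = ck_frame,
              max_gap = max_gap %||% dt)
  class(cfg) <- "saltmig_config"
  cfg
}

#' Read/write a run configuration
#'
#' @param path YAML file path.
#' @param config A `saltmig_config`.
#' @return `read_config()` a `saltmig_config`; `write_config()` `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

hash_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes read, gap-splitting, nucleus/centrosome pairing, QC, per-cell
#' metrics, radar binning, and writes the report bundle: `metrics.csv`,
#' `nk_events.csv`, `ck_events.csv`, `radar.json`, `config.yaml` and
#' `log.txt` (stage-by-stage counts). Every output embeds the configuration
#' and the MD5 of the input, so each number is traceable to config + input.
#'
#' @param config A `saltmig_config` from [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list: `metrics` (QC-passing rows), `metrics_all`,
#'   `excluded`, `nk_events`, `ck_events`, `radar`, `log` (character),
#'   `config`, `input_md5`, `config_md5`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "saltmig_config"))
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    if (!quiet) inform(msg)
  }
  tracks <- read_tracks(config$input, dt = config$dt)
  n_tracks <- nrow(dplyr::distinct(tracks, .data$cell_id, .data$role))
  say("tracks read: ", n_tracks)
  tracks <- split_at_gaps(tracks, max_gap = config$max_gap, dt = config$dt)
  say("tracks after gap splitting: ",
      nrow(dplyr::distinct(tracks, .data$cell_id, .data$role)))
  cells <- pair_cells(tracks, group = config$group,
                      reference_vector = config$reference_vector,
                      dataset_id = config$dataset_id)
  say("cells paired: ", nrow(cells))
  qc <- qc_filter(cells, min_duration = config$min_duration,
                  nk_threshold = config$nk_threshold,
                  merge = config$nk_merge)
  n_short <- sum(qc$excluded$reason == "too_short")
  n_nonk <- sum(qc$excluded$reason == "no_nk")
  say("excluded too_short: ", n_short, "; excluded no_nk: ", n_nonk)
  if (nrow(qc$kept) == 0) {
    abort(paste0("no cells pass QC (", n_short, " too_short, ", n_nonk,
                 " no_nk)"))
  }
  metrics_all <- compute_cell_metrics(
    cells, nk_threshold = config$nk_threshold,
    ck_threshold = config$ck_threshold,
    min_duration = config$min_duration, merge = config$nk_merge,
    ck_frame = config$ck_frame)
  metrics <- dplyr::filter(metrics_all, .data$qc_pass)
  say("cells analyzed: ", nrow(metrics))
  events <- collect_events(qc$kept, nk_threshold = config$nk_threshold,
                           ck_threshold = config$ck_threshold,
                           merge = config$nk_merge,
                           ck_frame = config$ck_frame)
  radar <- radar_bin(metrics$angle_deg[!is.na(metrics$angle_deg)])
  input_md5 <- unname(tools::md5sum(config$input))
  config_md5 <- hash_config(config)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  readr::write_csv(metrics_all, out("metrics.csv"), progress = FALSE)
  readr::write_csv(events$nk_events, out("nk_events.csv"), progress = FALSE)
  readr::write_csv(events$ck_events, out("ck_events.csv"), progress = FALSE)
  jsonlite::write_json(
    list(radar = radar,
         provenance = list(input_md5 = input_md5, config_md5 = config_md5)),
    out("radar.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_config(config, out("config.yaml"))
  writeLines(c(log, paste0("input_md5: ", input_md5),
               paste0("config_md5: ", config_md5)), out("log.txt"))

  invisible(list(metrics = metrics, metrics_all = metrics_all,
                 excluded = qc$excluded, nk_events = events$nk_events,
                 ck_events = events$ck_events, radar = radar, log = log,
                 config = config, input_md5 = input_md5,
                 config_md5 = config_md5))
}

#' Compare cohort metric tables and write a stats bundle
#'
#' Statistical comparison of two or more per-cell metric tables on the
#' requested metrics: Mann-Whitney for two groups, Kruskal-Wallis plus
#' Dunn/Benjamini-Hochberg for more, with median/IQR summaries, serialized
#' to JSON.
#'
#' @param metrics_list Named list of metrics tibbles (names become group
#'   labels) or a single tibble with a `group` column.
#' @param metrics Character vector of metric columns to compare.
#' @param out Optional path of the JSON file to write.
#' @param seed Recorded seed for stochastic components.
#' @return Named list of `saltmig_comparison` objects, invisibly if `out`
#'   is given.
#' @export
compare_metrics <- function(metrics_list,
                            metrics = c("speed", "pausing_pct", "sinuosity",
                                        "nk_mean_distance", "nk_freq"),
                            out = NULL, seed = 1) {
  if (is.data.frame(metrics_list)) {
    combined <- metrics_list
  } else {
    combined <- purrr::imap(metrics_list,
                            ~ dplyr::mutate(.x, group = .y)) |>
      dplyr::bind_rows()
  }
  combined <- dplyr::filter(combined, .data$qc_pass)
  res <- purrr::map(setNames(metrics, metrics), function(m) {
    compare_cohorts(combined, !!rlang::sym(m))
  })
  if (!is.null(out)) {
    ser <- purrr::map(res, function(r) {
      list(test = r$test_name, statistic = r$statistic, df = r$df,
           p_value = r$p_value,
           posthoc = if (!is.null(r$posthoc)) r$posthoc,
           summaries = r$summaries, seed = seed)
    })
    jsonlite::write_json(ser, out, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, null = "null")
    return(invisible(res))
  }
  res
}
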