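#' Quality-control filter for tracked cells
#'
#' Cells tracked for less than `min_duration` minutes and cells that do not
#' perform any NK during the whole tracking are excluded from the migration
#' analysis.
#'
#' @param cells Nested cell tibble from [pair_cells()] or
#'   [simulate_cohort()].
#' @param min_duration Minimum nucleus track duration in minutes.
#' @param nk_threshold Strict NK displacement threshold in um.
#' @param merge Passed to [detect_nk_events()].
#' @return A list with elements `kept` (cell tibble) and `excluded` (tibble
#'   `cell_id`, `reason` with machine-readable reasons `too_short` /
#'   `no_nk`).
#' @export
qc_filter <- function(cells, min_duration = 30, nk_threshold = 6,
                      merge = TRUE) {
  status <- purrr::map_chr(cells$nucleus, function(nuc) {
    dur <- nuc$t_min[nrow(nuc)] - nuc$t_min[1]
    if (dur < min_duration) return("too_short")
    if (nrow(detect_nk_events(nuc, nk_threshold, merge = merge)) == 0) {
      return("no_nk")
    }
    "pass"
  })
  list(
    kept = cells[status == "pass", , drop = FALSE],
    excluded = tibble::tibble(cell_id = cells$cell_id[status != "pass"],
                              reason = status[status != "pass"])
  )
}

#' Compute per-cell migration metrics
#'
#' One row per cell summarising nuclear kinematics (speed, pausing,
#' sinuosity, migration angle, NK statistics) and, when a centrosome track
#' is present, centrosome dynamics (CK frequency, median CK speed, CK
#' efficiency). Rows carry a `qc_pass` flag plus reason instead of being
#' dropped, so exclusions stay auditable; filter on `qc_pass` before group
#' statistics.
#'
#' @param cells Nested cell tibble from [pair_cells()] or
#'   [simulate_cohort()].
#' @param nk_threshold,ck_threshold Event thresholds in um (strict).
#' @param min_duration QC minimum track duration, minutes.
#' @param merge Merge consecutive supra-threshold NK steps into one event.
#' @param ck_frame Passed to [detect_ck_events()].
#' @return Tibble with one row per cell: identification (`cell_id`, `group`,
#'   `dataset_id`), `duration_hr`, `speed` (um/hr), `pausing_pct`,
#'   `sinuosity`, `angle_deg`, `nk_count`, `nk_freq` (NK/hr),
#'   `nk_mean_distance` (um, mean per-event path distance), `ck_count`,
#'   `ck_freq` (CK/hr), `ck_speed_median` (um/hr), `ck_efficiency_pct`
#'   (`NA` when `ck_count` is 0 or no centrosome), `qc_pass`, `qc_reason`.
#' @export
compute_cell_metrics <- function(cells, nk_threshold = 6, ck_threshold = 2,
                                 min_duration = 30, merge = TRUE,
                                 ck_frame = "relative") {
  one <- function(i) {
    nuc <- cells$nucleus[[i]]
    cen <- cells$centrosome[[i]]
    rv <- c(cells$ref_x[i], cells$ref_y[i])
    dur_min <- nuc$t_min[nrow(nuc)] - nuc$t_min[1]
    dur_hr <- dur_min / 60
    nks <- detect_nk_events(nuc, nk_threshold, merge = merge)
    cks <- detect_ck_events(nuc, cen, ck_threshold, frame = ck_frame,
                            reference_vector = rv)
    cks <- classify_ck_efficiency(cks, nks,
                                  track_end_t = nuc$t_min[nrow(nuc)])
    has_cen <- !is.null(cen)
    net <- sqrt((nuc$x_um[nrow(nuc)] - nuc$x_um[1])^2 +
                (nuc$y_um[nrow(nuc)] - nuc$y_um[1])^2)
    qc_reason <- if (dur_min < min_duration) {
      "too_short"
    } else if (nrow(nks) == 0) "no_nk" else NA_character_
    tibble::tibble(
      cell_id = cells$cell_id[i],
      group = cells$group[i],
      dataset_id = cells$dataset_id[i],
      duration_hr = dur_hr,
      speed = migration_speed(nuc),
      pausing_pct = pausing_fraction(nuc, nk_threshold),
      sinuosity = if (net > 0) sinuosity(nuc) else NA_real_,
      angle_deg = if (net > 0) migration_angle(nuc, rv) else NA_real_,
      nk_count = nrow(nks),
      nk_freq = nrow(nks) / dur_hr,
      nk_mean_distance = if (nrow(nks) > 0) mean(nks$path_distance) else NA_real_,
      ck_count = if (has_cen) nrow(cks) else NA_integer_,
      ck_freq = if (has_cen) nrow(cks) / dur_hr else NA_real_,
      ck_speed_median = if (has_cen && nrow(cks) > 0) median(cks$ck_speed) else NA_real_,
      ck_efficiency_pct = if (has_cen && nrow(cks) > 0) {
        100 * mean(cks$efficient)
      } else NA_real_,
      qc_pass = is.na(qc_reason),
      qc_reason = qc_reason
    )
  }
  purrr::map(seq_len(nrow(cells)), one) |> dplyr::bind_rows()
}

#' Collect per-cell NK and CK event tables
#'
#' Runs event detection for every cell and returns tidy event tables, for
#' export alongside the per-cell metrics.
#'
#' @inheritParams compute_cell_metrics
#' @return List with tibbles `nk_events` and `ck_events`, each with a
#'   leading `cell_id` column.
#' @export
collect_events <- function(cells, nk_threshold = 6, ck_threshold = 2,
                           merge = TRUE, ck_frame = "relative") {
  nk <- purrr::map(seq_len(nrow(cells)), function(i) {
    ev <- detect_nk_events(cells$nucleus[[i]], nk_threshold, merge = merge)
    if (nrow(ev) > 0) dplyr::mutate(ev, cell_id = cells$cell_id[i], .before = 1)
  }) |> dplyr::bind_rows()
  ck <- purrr::map(seq_len(nrow(cells)), function(i) {
    nuc <- cells$nucleus[[i]]
    ev <- detect_ck_events(nuc, cells$centrosome[[i]], ck_threshold,
                           frame = ck_frame,
                           reference_vector = c(cells$ref_x[i], cells$ref_y[i]))
    ev <- classify_ck_efficiency(
      ev, detect_nk_events(nuc, nk_threshold, merge = merge),
      track_end_t = nuc$t_min[nrow(nuc)])
    if (nrow(ev) > 0) dplyr::mutate(ev, cell_id = cells$cell_id[i], .before = 1)
  }) |> dplyr::bind_rows()
  if (nrow(nk) == 0) {
    nk <- tibble::tibble(cell_id = character(), start_t = numeric(),
                         end_t = numeric(), n_steps = integer(),
                         path_distance = numeric(), net_distance = numeric())
  }
  if (nrow(ck) == 0) {
    ck <- tibble::tibble(cell_id = character(), onset_t = numeric(),
                         peak_t = numeric(), end_t = numeric(),
                         forward_amplitude = numeric(),
                         backward_amplitude = numeric(), ck_speed = numeric(),
                         efficient = logical())
  }
  list(nk_events = nk, ck_events = ck)
}
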