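#' Read a tidy track table
#'
#' Reads manually tracked positions (MTrackJ-style export converted to tidy
#' CSV) into a validated track table. One row is one tracked structure at one
#' frame; each (`cell_id`, `role`) pair forms a track.
#'
#' Coordinates are consumed in micrometres and time in minutes; tracking is
#' two-dimensional. If `t_min` is absent it is derived as `frame * dt`
#' (0-based frames); when both are present the explicit `t_min` wins and
#' `frame` is recomputed from it.
#'
#' @param path Path to a CSV file with header columns `cell_id`, `role`
#'   (`"nucleus"` or `"centrosome"`), `x_um`, `y_um`, and at least one of
#'   `frame` (0-based) and `t_min` (minutes).
#' @param dt Nominal frame interval in minutes (default 3, the usual
#'   time-lapse acquisition interval).
#' @param dialect Input dialect; only `"tidy_csv"` is supported.
#' @return A tibble with columns `cell_id`, `role`, `frame`, `t_min`,
#'   `x_um`, `y_um`, sorted by cell, role and time, with attribute
#'   `dt_nominal`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(cell_id = "c1", role = "nucleus", frame = 0:3,
#'                      t_min = c(0, 3, 6, 9), x_um = c(0, 1, 8, 8.5),
#'                      y_um = 0), f, row.names = FALSE)
#' read_tracks(f)
read_tracks <- function(path, dt = 3, dialect = "tidy_csv") {
  if (!identical(dialect, "tidy_csv")) {
    abort(paste0("unsupported dialect: ", dialect))
  }
  if (!file.exists(path)) {
    abort(paste0("track file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_tracks(raw, dt = dt, source = path)
}

#' Validate a raw track table
#'
#' Checks column presence, numeric coordinates, duplicate timepoints, and
#' that inter-point intervals are positive multiples of the nominal frame
#' interval. Called by [read_tracks()]; exported so in-memory tables (e.g.
#' simulator output re-imported from another tool) can be validated the same
#' way.
#'
#' @param tracks Data frame with the columns described in [read_tracks()].
#' @param dt Nominal frame interval (minutes).
#' @param source Label used in error messages.
#' @return Validated tibble (see [read_tracks()]).
#' @export
validate_tracks <- function(tracks, dt = 3, source = "tracks") {
  tracks <- tibble::as_tibble(tracks)
  needed <- c("cell_id", "role", "x_um", "y_um")
  missing_cols <- setdiff(needed, names(tracks))
  if (length(missing_cols) > 0) {
    abort(paste0(source, ": missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("frame", "t_min") %in% names(tracks))) {
    abort(paste0(source, ": missing required column(s): frame or t_min"))
  }

  num <- function(col) {
    if (!col %in% names(tracks)) return(NULL)
    v <- tracks[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad) > 0) {
      abort(paste0(source, ": non-numeric value in column '", col,
                   "' at data row(s) ", paste(head(bad, 5), collapse = ", "),
                   " (line ", bad[1] + 1L, " of file)"))
    }
    out
  }
  tracks$x_um <- num("x_um")
  tracks$y_um <- num("y_um")
  if ("frame" %in% names(tracks)) tracks$frame <- num("frame")
  if ("t_min" %in% names(tracks)) tracks$t_min <- num("t_min")

  if (!"t_min" %in% names(tracks) || all(is.na(tracks$t_min))) {
    tracks$t_min <- tracks$frame * dt
  } else if (anyNA(tracks$t_min)) {
    i <- is.na(tracks$t_min)
    tracks$t_min[i] <- tracks$frame[i] * dt
  }
  tracks$frame <- as.integer(round(tracks$t_min / dt))

  if (any(!is.finite(tracks$x_um)) || any(!is.finite(tracks$y_um))) {
    abort(paste0(source, ": non-finite coordinate(s)"))
  }
  if (any(!is.finite(tracks$t_min)) || any(tracks$t_min < 0)) {
    abort(paste0(source, ": t_min must be finite and >= 0"))
  }
  bad_role <- setdiff(unique(tracks$role), c("nucleus", "centrosome"))
  if (length(bad_role) > 0) {
    abort(paste0(source, ": unknown role(s): ", paste(bad_role, collapse = ", ")))
  }

  tracks <- dplyr::arrange(tracks, .data$cell_id, .data$role, .data$t_min)
  dup <- dplyr::summarise(
    dplyr::group_by(tracks, .data$cell_id, .data$role),
    dup = anyDuplicated(.data$t_min) > 0, .groups = "drop")
  if (any(dup$dup)) {
    offenders <- dup$cell_id[dup$dup]
    abort(paste0(source, ": duplicate timepoints within track(s): ",
                 paste(unique(offenders), collapse = ", ")))
  }
  chk <- dplyr::summarise(
    dplyr::group_by(tracks, .data$cell_id, .data$role),
    n = dplyr::n(),
    ok = dplyr::n() < 2 ||
      all(abs(diff(.data$t_min) / dt - round(diff(.data$t_min) / dt)) < 1e-6 / dt) &&
      all(diff(.data$t_min) > 0),
    .groups = "drop")
  if (any(chk$n < 2)) {
    abort(paste0(source, ": track(s) with fewer than 2 points: ",
                 paste(unique(chk$cell_id[chk$n < 2]), collapse = ", ")))
  }
  if (any(!chk$ok)) {
    abort(paste0(source, ": inter-point intervals must be positive multiples of dt=",
                 dt, " min (tracks: ",
                 paste(unique(chk$cell_id[!chk$ok]), collapse = ", "), ")"))
  }
  tracks <- dplyr::select(tracks, "cell_id", "role", "frame", "t_min",
                          "x_um", "y_um")
  attr(tracks, "dt_nominal") <- dt
  tracks
}

#' Write a track table
#'
#' Emits the same tidy CSV dialect consumed by [read_tracks()], so that a
#' read/write round trip is lossless for coordinates to at least six decimal
#' places.
#'
#' @param tracks Track tibble as returned by [read_tracks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks[, c("cell_id", "role", "frame", "t_min", "x_um", "y_um")],
                   path, progress = FALSE)
  invisible(path)
}

#' Split tracks at acquisition gaps
#'
#' Thresholded per-interval displacement tests (e.g. 6 um per 3 min) are
#' undefined over longer intervals, so tracks with missing frames are split
#' into maximal gap-free sub-tracks rather than interpolated. Sub-track ids
#' are suffixed deterministically (`id.1`, `id.2`, ...); gap-free tracks keep
#' their original id.
#'
#' @param tracks Track tibble (see [read_tracks()]).
#' @param max_gap Largest tolerated interval in minutes; defaults to the
#'   table's nominal frame interval.
#' @param dt Nominal frame interval, used when `tracks` lacks the
#'   `dt_nominal` attribute.
#' @return Track tibble whose (cell_id, role) tracks all have consecutive
#'   intervals `<= max_gap`. The union of output points equals the input
#'   points.
#' @export
split_at_gaps <- function(tracks, max_gap = NULL, dt = NULL) {
  dt <- dt %||% attr(tracks, "dt_nominal") %||% 3
  max_gap <- max_gap %||% dt
  if (max_gap < dt - 1e-9) abort("max_gap must be >= dt")
  split_one <- function(df) {
    gaps <- diff(df$t_min)
    seg <- cumsum(c(0, gaps > max_gap + 1e-9))
    if (max(seg) == 0) {
      df$segment <- 0L
      return(df)
    }
    df$segment <- seg
    df$cell_id <- paste0(df$cell_id, ".", seg + 1L)
    df
  }
  pieces <- split(tracks, interaction(tracks$cell_id, tracks$role, drop = TRUE))
  out <- purrr::map(pieces, split_one) |> dplyr::bind_rows()
  out$segment <- NULL
  out <- dplyr::arrange(out, .data$cell_id, .data$role, .data$t_min)
  attr(out, "dt_nominal") <- dt
  # drop singleton fragments: a 1-point sub-track carries no interval
  keep <- out |>
    dplyr::count(.data$cell_id, .data$role) |>
    dplyr::filter(.data$n >= 2)
  out <- dplyr::semi_join(out, keep, by = c("cell_id", "role"))
  attr(out, "dt_nominal") <- dt
  out
}

#' Pair nucleus and centrosome tracks into per-cell records
#'
#' Every nucleus track yields one cell record; a centrosome track with the
#' same `cell_id` is attached (CK analysis is later restricted to the
#' timepoint overlap). Centrosome-only cell ids are reported via a message
#' and dropped.
#'
#' @param tracks Track tibble (see [read_tracks()]).
#' @param group Experimental group label (e.g. `"control"`, `"fmr1_null"`,
#'   `"fmr1_null_mirMap1b"`).
#' @param reference_vector Length-2 numeric, the tissue axis pointing from
#'   the SVZ toward the olfactory bulb; normalised on construction.
#' @param dataset_id Animal/slice identifier attached to every cell.
#' @return Nested tibble with one row per cell: `cell_id`, `group`,
#'   `dataset_id`, `ref_x`, `ref_y`, list-columns `nucleus` and `centrosome`
#'   (each a tibble of `frame`, `t_min`, `x_um`, `y_um`; `centrosome` entries
#'   may be `NULL`), and `dt` (minutes).
#' @export
pair_cells <- function(tracks, group = "unknown", reference_vector = c(1, 0),
                       dataset_id = NA_character_) {
  dt <- attr(tracks, "dt_nominal") %||% 3
  rv <- as.numeric(reference_vector)
  if (length(rv) != 2 || !all(is.finite(rv)) || sqrt(sum(rv^2)) == 0) {
    abort("reference_vector must be a finite, non-zero 2D vector")
  }
  rv <- rv / sqrt(sum(rv^2))

  n_per <- dplyr::count(tracks, .data$cell_id, .data$role)
  if (any(n_per$n < 1)) abort("empty track")
  dup_nuc <- tracks |>
    dplyr::distinct(.data$cell_id, .data$role) |>
    dplyr::count(.data$cell_id, .data$role) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_nuc) > 0) {
    abort("multiple tracks with the same (cell_id, role)")
  }

  one <- function(df) dplyr::select(df, "frame", "t_min", "x_um", "y_um")
  nuc <- tracks |> dplyr::filter(.data$role == "nucleus")
  cen <- tracks |> dplyr::filter(.data$role == "centrosome")
  nuc_ids <- unique(nuc$cell_id)
  cen_ids <- unique(cen$cell_id)
  orphans <- setdiff(cen_ids, nuc_ids)
  if (length(orphans) > 0) {
    inform(paste0("dropping centrosome-only cell_id(s): ",
                  paste(orphans, collapse = ", ")))
  }
  nuc_l <- split(nuc, nuc$cell_id)
  cen_l <- split(cen, cen$cell_id)
  tibble::tibble(
    cell_id = nuc_ids,
    group = group,
    dataset_id = dataset_id,
    ref_x = rv[1],
    ref_y = rv[2],
    dt = dt,
    nucleus = purrr::map(nuc_ids, ~ one(nuc_l[[.x]])),
    centrosome = purrr::map(nuc_ids, ~ if (.x %in% names(cen_l)) one(cen_l[[.x]]) else NULL)
  )
}

#' Flatten per-cell records back to a tidy track table
#'
#' Inverse of [pair_cells()]: useful for writing simulated cohorts with
#' [write_tracks()].
#'
#' @param cells Nested cell tibble from [pair_cells()] or [simulate_cohort()].
#' @return Track tibble (see [read_tracks()]).
#' @export
cells_to_tracks <- function(cells, dt = NULL) {
  dt <- dt %||% (if (nrow(cells) > 0) cells$dt[1] else 3)
  rows <- purrr::map2(cells$cell_id, seq_len(nrow(cells)), function(id, i) {
    nuc <- dplyr::mutate(cells$nucleus[[i]], cell_id = id, role = "nucleus")
    cen <- cells$centrosome[[i]]
    if (!is.null(cen)) {
      cen <- dplyr::mutate(cen, cell_id = id, role = "centrosome")
      dplyr::bind_rows(nuc, cen)
    } else nuc
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("cell_id", "role", "frame", "t_min", "x_um", "y_um") |>
    dplyr::arrange(.data$cell_id, .data$role, .data$t_min)
  attr(out, "dt_nominal") <- dt
  out
}
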