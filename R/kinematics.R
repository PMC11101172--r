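#' Per-interval step displacements
#'
#' Euclidean displacement of a tracked structure between consecutive frames.
#' All event detection and speed/pausing computations are built on this
#' sequence; positions are used raw (no smoothing or interpolation).
#'
#' @param track Data frame with columns `t_min`, `x_um`, `y_um` (extra
#'   columns ignored), time-sorted, `>= 2` points.
#' @return Tibble with one row per consecutive point pair: `t_start`,
#'   `t_end` (minutes) and `displacement` (um).
#' @export
#' @examples
#' step_displacements(data.frame(t_min = c(0, 3), x_um = c(0, 3), y_um = c(0, 4)))
step_displacements <- function(track) {
  if (nrow(track) < 2) abort("track needs at least 2 points")
  n <- nrow(track)
  tibble::tibble(
    t_start = track$t_min[-n],
    t_end = track$t_min[-1],
    displacement = sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  )
}

#' Detect nucleokinesis (NK) events
#'
#' An NK step is an inter-frame nuclear displacement strictly greater than
#' `nk_threshold` (default 6 um at 3-min sampling). Consecutive
#' supra-threshold steps are merged into one event (`merge = TRUE`, the
#' default): the printed per-NK distances exceed the single-step threshold
#' enough that multi-frame translocations are treated as one jump. With
#' `merge = FALSE` every supra-threshold step is its own event (sensitivity
#' analysis).
#'
#' @param track Nucleus track (gap-free; see [split_at_gaps()]).
#' @param nk_threshold Strict displacement threshold in um.
#' @param merge Merge consecutive supra-threshold steps into one event.
#' @return Tibble of events ordered by `start_t`: `start_t`, `end_t`
#'   (minutes), `n_steps`, `path_distance` (sum of step displacements within
#'   the event, um) and `net_distance` (start-to-end Euclidean distance, um).
#' @export
detect_nk_events <- function(track, nk_threshold = 6, merge = TRUE) {
  if (!is.numeric(nk_threshold) || nk_threshold <= 0) {
    abort("nk_threshold must be > 0")
  }
  steps <- step_displacements(track)
  supra <- steps$displacement > nk_threshold
  empty <- tibble::tibble(start_t = numeric(), end_t = numeric(),
                          n_steps = integer(), path_distance = numeric(),
                          net_distance = numeric())
  if (!any(supra)) return(empty)
  if (merge) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    starts <- starts[keep]; ends <- ends[keep]
  } else {
    starts <- which(supra); ends <- starts
  }
  net <- function(i0, i1) {
    sqrt((track$x_um[i1 + 1] - track$x_um[i0])^2 +
         (track$y_um[i1 + 1] - track$y_um[i0])^2)
  }
  tibble::tibble(
    start_t = steps$t_start[starts],
    end_t = steps$t_end[ends],
    n_steps = as.integer(ends - starts + 1L),
    path_distance = purrr::map2_dbl(starts, ends,
                                    ~ sum(steps$displacement[.x:.y])),
    net_distance = purrr::map2_dbl(starts, ends, net)
  )
}

#' Migration speed
#'
#' Total path length travelled by the nucleus divided by total tracking
#' time, pauses included, in um/hr.
#'
#' @inheritParams step_displacements
#' @return Speed in um/hr.
#' @export
migration_speed <- function(track) {
  dur <- track$t_min[nrow(track)] - track$t_min[1]
  if (dur <= 0) abort("track duration must be > 0")
  sum(step_displacements(track)$displacement) / (dur / 60)
}

#' Pausing time
#'
#' Percentage of time slots in which the nucleus moves less than the NK
#' threshold. A step of exactly the threshold counts as a pause, because an
#' NK requires a displacement strictly greater than the threshold.
#'
#' @inheritParams detect_nk_events
#' @return Percentage in `[0, 100]`.
#' @export
pausing_fraction <- function(track, nk_threshold = 6) {
  steps <- step_displacements(track)
  100 * mean(steps$displacement <= nk_threshold)
}

#' Sinuosity index
#'
#' Ratio of the total distance covered to the Euclidean distance between the
#' start and end points; 1 is perfectly straight. Undefined (returned as
#' `NA` with a warning) when the net displacement is zero.
#'
#' @inheritParams step_displacements
#' @return Dimensionless index `>= 1`, or `NA`.
#' @export
sinuosity <- function(track) {
  n <- nrow(track)
  net <- sqrt((track$x_um[n] - track$x_um[1])^2 +
              (track$y_um[n] - track$y_um[1])^2)
  if (net == 0) {
    warn("net displacement is zero; sinuosity undefined")
    return(NA_real_)
  }
  sum(step_displacements(track)$displacement) / net
}

#' Migration angle
#'
#' Angle between the cell's net displacement vector (start to end) and the
#' reference SVZ-to-OB axis, measured counter-clockwise in standard x,y
#' coordinates and mapped to `[0, 360)` degrees; 0 means exactly toward the
#' olfactory bulb.
#'
#' @inheritParams step_displacements
#' @param reference_vector Length-2 numeric; normalised internally.
#' @return Angle in degrees in `[0, 360)`, or `NA` if the net displacement
#'   is zero.
#' @export
migration_angle <- function(track, reference_vector = c(1, 0)) {
  n <- nrow(track)
  dx <- track$x_um[n] - track$x_um[1]
  dy <- track$y_um[n] - track$y_um[1]
  if (dx == 0 && dy == 0) {
    warn("net displacement is zero; migration angle undefined")
    return(NA_real_)
  }
  rv <- as.numeric(reference_vector)
  ang <- (atan2(dy, dx) - atan2(rv[2], rv[1])) * 180 / pi
  ang <- ang %% 360
  if (ang >= 360) ang <- ang - 360  # guard fp edge
  ang
}

#' Bin migration angles into a four-dial radar
#'
#' Migration radars summarise per-cell migration angles into four 90-degree
#' dials centred on the forward (toward OB), left, backward and right
#' directions: forward `[315, 45)`, left `[45, 135)`, backward `[135, 225)`,
#' right `[225, 315)`. A boundary angle belongs to the dial it opens.
#'
#' @param angles Numeric vector of angles in degrees in `[0, 360)`; `NA`s
#'   are dropped.
#' @param n_dials Number of dials; only 4 is supported.
#' @return A tibble of class `saltmig_radar`: `dial`, `from_deg`, `to_deg`,
#'   `count`, `pct`. Counts sum to the number of non-missing angles and
#'   percentages to 100.
#' @export
radar_bin <- function(angles, n_dials = 4) {
  if (n_dials != 4) abort("only the four-dial radar is supported")
  angles <- angles[!is.na(angles)]
  if (any(angles < 0 | angles >= 360)) abort("angles must lie in [0, 360)")
  idx <- (floor((angles + 45) / 90) %% 4) + 1
  counts <- tabulate(idx, nbins = 4)
  out <- tibble::tibble(
    dial = c("forward", "left", "backward", "right"),
    from_deg = c(315, 45, 135, 225),
    to_deg = c(45, 135, 225, 315),
    count = as.integer(counts),
    pct = if (length(angles) > 0) 100 * counts / length(angles) else rep(NA_real_, 4)
  )
  class(out) <- c("saltmig_radar", class(out))
  out
}

#' Centrosome-nucleus separation series
#'
#' Euclidean distance between the centrosome and the nucleus at every
#' timepoint shared by the two tracks (the centrosome track may cover only a
#' subset of the nucleus timepoints; CK analysis is restricted to the
#' overlap).
#'
#' @param nucleus,centrosome Tracks with columns `t_min`, `x_um`, `y_um`.
#' @return Tibble `t_min`, `separation` (um), plus the centrosome
#'   coordinates `cx`, `cy` at the shared timepoints.
#' @export
centrosome_separation_series <- function(nucleus, centrosome) {
  j <- dplyr::inner_join(
    dplyr::select(nucleus, "t_min", nx = "x_um", ny = "y_um"),
    dplyr::select(centrosome, "t_min", cx = "x_um", cy = "y_um"),
    by = "t_min")
  tibble::tibble(
    t_min = j$t_min,
    separation = sqrt((j$cx - j$nx)^2 + (j$cy - j$ny)^2),
    cx = j$cx, cy = j$cy
  )
}

# Greedy left-to-right rise/fall scan of a scalar series.
# An event opens at a running-minimum baseline, is armed once some point has
# risen > thr above the minimum preceding it, peaks at the highest armed
# point, and closes at the first point that has fallen > thr below that
# peak. Returns integer indices (onset, peak, close) per event.
scan_rise_fall <- function(s, thr) {
  n <- length(s)
  events <- list()
  r <- 1L
  while (r <= n - 2L) {
    min_val <- s[r]
    armed_val <- -Inf
    armed_idx <- NA_integer_
    closed <- FALSE
    j <- r
    while (j < n) {
      j <- j + 1L
      if (s[j] - min_val > thr && s[j] > armed_val) {
        armed_val <- s[j]
        armed_idx <- j
      }
      if (!is.na(armed_idx) && armed_val - s[j] > thr) {
        seg <- s[r:armed_idx]
        onset <- r + which.min(seg) - 1L
        events[[length(events) + 1L]] <- c(onset = onset, peak = armed_idx,
                                           close = j)
        r <- j
        closed <- TRUE
        break
      }
      if (s[j] < min_val) min_val <- s[j]
    }
    if (!closed) break
  }
  if (length(events) == 0) {
    return(tibble::tibble(onset = integer(), peak = integer(), close = integer()))
  }
  tibble::as_tibble(do.call(rbind, events))
}

#' Detect centrokinesis (CK) events
#'
#' A CK is a forward movement of the centrosome greater than `ck_threshold`
#' (default 2 um) followed by a backward movement greater than
#' `ck_threshold`. Forward/backward are measured on the scalar
#' centrosome-nucleus separation (`frame = "relative"`, the default, so that
#' centrosome motion is not conflated with nucleokinesis); the alternative
#' `frame = "absolute"` measures the centrosome's displacement projected on
#' the reference axis, as a sensitivity analysis.
#'
#' The separation series is scanned greedily left to right: an event opens
#' at a local baseline (running minimum), peaks once the separation has
#' risen more than the threshold above that baseline, and closes at the
#' first timepoint more than the threshold below the running peak.
#'
#' @param nucleus,centrosome Tracks with columns `t_min`, `x_um`, `y_um`;
#'   `centrosome` may be `NULL`.
#' @param ck_threshold Rise/fall threshold in um (strict).
#' @param frame `"relative"` (separation to the nucleus) or `"absolute"`
#'   (projection of the centrosome position on `reference_vector`).
#' @param reference_vector Used only for `frame = "absolute"`.
#' @return Tibble of events: `onset_t`, `peak_t`, `end_t` (minutes),
#'   `forward_amplitude`, `backward_amplitude` (um), `ck_speed` (centrosome
#'   path length over `[onset_t, end_t]` divided by the event duration,
#'   um/hr). `NULL` centrosome or fewer than 3 shared timepoints gives a
#'   zero-row tibble (missing data, not an error).
#' @export
detect_ck_events <- function(nucleus, centrosome, ck_threshold = 2,
                             frame = c("relative", "absolute"),
                             reference_vector = c(1, 0)) {
  frame <- match.arg(frame)
  if (!is.numeric(ck_threshold) || ck_threshold <= 0) {
    abort("ck_threshold must be > 0")
  }
  empty <- tibble::tibble(onset_t = numeric(), peak_t = numeric(),
                          end_t = numeric(), forward_amplitude = numeric(),
                          backward_amplitude = numeric(), ck_speed = numeric())
  if (is.null(centrosome)) return(empty)
  ser <- centrosome_separation_series(nucleus, centrosome)
  if (nrow(ser) < 3) return(empty)
  s <- if (frame == "relative") {
    ser$separation
  } else {
    rv <- as.numeric(reference_vector)
    rv <- rv / sqrt(sum(rv^2))
    ser$cx * rv[1] + ser$cy * rv[2]
  }
  ev <- scan_rise_fall(s, ck_threshold)
  if (nrow(ev) == 0) return(empty)
  path_speed <- function(i0, i1) {
    dx <- diff(ser$cx[i0:i1]); dy <- diff(ser$cy[i0:i1])
    sum(sqrt(dx^2 + dy^2)) / ((ser$t_min[i1] - ser$t_min[i0]) / 60)
  }
  tibble::tibble(
    onset_t = ser$t_min[ev$onset],
    peak_t = ser$t_min[ev$peak],
    end_t = ser$t_min[ev$close],
    forward_amplitude = s[ev$peak] - s[ev$onset],
    backward_amplitude = s[ev$peak] - s[ev$close],
    ck_speed = purrr::map2_dbl(ev$onset, ev$close, path_speed)
  )
}

#' Classify CK efficiency
#'
#' An efficient CK is followed by a subsequent NK; an inefficient CK is not.
#' CK `k` is efficient if and only if some NK event starts in the window
#' `(peak_t(k), onset_t(k+1)]` (for the last CK the window extends to the
#' end of the track). Because consecutive windows are disjoint, each NK
#' validates at most one CK.
#'
#' @param cks CK event tibble from [detect_ck_events()].
#' @param nks NK event tibble from [detect_nk_events()].
#' @param track_end_t End time of the track in minutes (closes the last
#'   window); defaults to `Inf`.
#' @return `cks` with a logical `efficient` column.
#' @export
classify_ck_efficiency <- function(cks, nks, track_end_t = Inf) {
  if (nrow(cks) == 0) {
    cks$efficient <- logical(0)
    return(cks)
  }
  win_lo <- cks$peak_t
  win_hi <- c(cks$onset_t[-1], track_end_t)
  cks$efficient <- purrr::map2_lgl(win_lo, win_hi, function(lo, hi) {
    any(nks$start_t > lo & nks$start_t <= hi)
  })
  cks
}
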