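# Von Mises sampler, Best & Fisher (1979) wrapping rejection method.
# mu in radians; kappa >= 0. kappa ~ 0 falls back to uniform.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    return(((runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        u3 <- runif(1)
        out[i] <- mu + sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# Left-truncated lognormal via inverse-CDF (exact, no rejection loop).
rlnorm_trunc <- function(n, median, logsd, lower) {
  meanlog <- log(median)
  p_lo <- plnorm(lower, meanlog, logsd)
  qlnorm(runif(n, p_lo, 1), meanlog, logsd)
}

#' Simulation parameters for saltatory migration
#'
#' Generative parameters of the two-stroke saltatory cycle: the neuron
#' pauses, the centrosome advances into the leading process and retreats
#' (centrokinesis), and with some probability the nucleus then jumps forward
#' (nucleokinesis) before the cycle reinitiates.
#'
#' @param dt Frame interval, minutes.
#' @param duration Track duration, minutes (time-lapse sessions run 2-3 hr).
#' @param cycle_rate Expected NK events per hour.
#' @param p_efficient_ck Probability that a CK is followed by an NK.
#' @param extra_ck_rate Rate of additional inefficient CKs per hour.
#' @param nk_step_median Median NK path distance, um (must exceed the 6-um
#'   detection threshold).
#' @param nk_step_logsd Log-scale SD of the NK step distribution.
#' @param nk_min_step Detectability floor of the truncated lognormal step
#'   distribution, um.
#' @param nk_steps_max Frames an NK may span (1 or 2; large jumps are split
#'   over two frames).
#' @param ck_amplitude_median Median CK forward amplitude, um.
#' @param ck_amplitude_logsd Log-scale SD of the CK amplitude.
#' @param sep_baseline Resting centrosome-nucleus separation, um.
#' @param jitter_sd Per-frame isotropic positional noise of the nucleus, um;
#'   must keep P(single jitter step > 6 um) below 1e-4.
#' @param sep_noise_sd Per-frame noise on the separation, um.
#' @param heading_kappa Von Mises concentration of NK headings around the
#'   reference direction.
#' @return A `saltmig_params` list.
#' @export
sim_params <- function(dt = 3, duration = 150, cycle_rate = 2.5,
                       p_efficient_ck = 0.54, extra_ck_rate = 0,
                       nk_step_median = 11.5, nk_step_logsd = 0.25,
                       nk_min_step = 6.5, nk_steps_max = 2,
                       ck_amplitude_median = 4.5, ck_amplitude_logsd = 0.2,
                       sep_baseline = 1.5, jitter_sd = 0.9,
                       sep_noise_sd = 0.25, heading_kappa = 8) {
  p <- list(dt = dt, duration = duration, cycle_rate = cycle_rate,
            p_efficient_ck = p_efficient_ck, extra_ck_rate = extra_ck_rate,
            nk_step_median = nk_step_median, nk_step_logsd = nk_step_logsd,
            nk_min_step = nk_min_step, nk_steps_max = nk_steps_max,
            ck_amplitude_median = ck_amplitude_median,
            ck_amplitude_logsd = ck_amplitude_logsd,
            sep_baseline = sep_baseline, jitter_sd = jitter_sd,
            sep_noise_sd = sep_noise_sd, heading_kappa = heading_kappa)
  stopifnot(p$dt > 0, p$duration >= 2 * p$dt, p$cycle_rate >= 0,
            p$p_efficient_ck >= 0, p$p_efficient_ck <= 1,
            p$extra_ck_rate >= 0, p$nk_steps_max %in% c(1L, 2L))
  if (p$cycle_rate > 0 && p$nk_step_median <= 6) {
    abort("nk_step_median must exceed 6 um so NK events are detectable")
  }
  # P(jitter step > 6): step between two jittered frames is Rayleigh with
  # scale jitter_sd * sqrt(2)
  if (p$jitter_sd > 0 &&
      exp(-36 / (2 * (p$jitter_sd * sqrt(2))^2)) > 1e-4) {
    abort("jitter_sd too large: P(single jitter step > 6 um) exceeds 1e-4")
  }
  class(p) <- "saltmig_params"
  p
}

#' Genotype presets for the simulator
#'
#' Presets emulate the three experimental regimes. NK rate, NK step size and
#' CK efficiency are pinned to the reported per-genotype values (control
#' 2.5 NK/hr, 11.5 um, 54% efficient CK; Fmr1-null 1.2 NK/hr, 9.3 um, 33%);
#' directional persistence (von Mises kappa) is high in controls and low in
#' mutants. The MAP1B-knockdown rescue restores the control rates but keeps
#' the mutant's low directional persistence, since sinuosity/directionality
#' is the parameter that is not rescued.
#'
#' @param name One of `"control"`, `"fmr1_null"`, `"fmr1_null_mirMap1b"`.
#' @return A `saltmig_params` list (see [sim_params()]).
#' @export
preset <- function(name = c("control", "fmr1_null", "fmr1_null_mirMap1b")) {
  name <- match.arg(name)
  switch(name,
    control = sim_params(cycle_rate = 2.5, p_efficient_ck = 0.54,
                         nk_step_median = 11.5, ck_amplitude_median = 4.5,
                         jitter_sd = 0.9, heading_kappa = 8),
    fmr1_null = sim_params(cycle_rate = 1.2, p_efficient_ck = 0.33,
                           nk_step_median = 9.3, ck_amplitude_median = 3.0,
                           jitter_sd = 0.85, heading_kappa = 1.5),
    fmr1_null_mirMap1b = sim_params(cycle_rate = 2.5, p_efficient_ck = 0.54,
                                    nk_step_median = 11.5,
                                    ck_amplitude_median = 4.5,
                                    jitter_sd = 0.9, heading_kappa = 1.5)
  )
}

#' Simulate one saltatory cell
#'
#' Semi-Markov two-stroke cycle on an exact `dt` grid: geometric pause,
#' triangular centrosome excursion (rise one frame, fall one or two), then
#' with probability `p_efficient_ck` a nucleokinesis jump with lognormal
#' path distance along a von Mises heading, split over at most
#' `nk_steps_max` frames. Sub-threshold Gaussian jitter is added to every
#' nuclear position; the centrosome sits at the separation profile along the
#' current heading, with its own small noise. Fully reproducible from
#' `seed`.
#'
#' @param params `saltmig_params` from [sim_params()] or [preset()].
#' @param reference_vector SVZ-to-OB axis (normalised internally); the mean
#'   NK heading.
#' @param cell_id Identifier for the emitted tracks.
#' @param seed Optional integer seed (set by [simulate_cohort()] per cell).
#' @param group Group label stored on the cell record.
#' @return List with `cell` (one-row nested cell tibble, as from
#'   [pair_cells()]) and `truth` (list of tibbles `nk` and `ck` with the
#'   generated event log: times in minutes, distances/amplitudes in um, and
#'   the efficient flag for CKs).
#' @export
simulate_cell <- function(params, reference_vector = c(1, 0),
                          cell_id = "cell_1", seed = NULL,
                          group = "simulated") {
  stopifnot(inherits(params, "saltmig_params"))
  if (params$duration < 2 * params$dt) abort("duration must be >= 2*dt")
  if (!is.null(seed)) set.seed(seed)
  rv <- as.numeric(reference_vector)
  rv <- rv / sqrt(sum(rv^2))
  ref_angle <- atan2(rv[2], rv[1])
  dt <- params$dt
  n_steps <- floor(params$duration / dt)
  n_pts <- n_steps + 1L

  fph <- 60 / dt  # frames per hour
  attempt_rate <- if (params$p_efficient_ck > 0) {
    params$cycle_rate / params$p_efficient_ck + params$extra_ck_rate
  } else {
    params$extra_ck_rate
  }
  p_nk <- if (attempt_rate > 0) params$cycle_rate / attempt_rate else 0

  # mean cycle length (frames) targets the attempt rate; CK occupies
  # ~2.5 frames (rise 1, fall 1-2) and an NK ~1-1.3 frames
  pause_mean <- if (attempt_rate > 0) {
    max(0.2, fph / attempt_rate - 2.5 - p_nk * 1.2)
  } else {
    Inf
  }

  # per-frame nucleus displacement vectors and separation profile
  disp <- matrix(0, nrow = n_steps, ncol = 2)
  sep <- rep(params$sep_baseline, n_pts)
  heading <- rep(ref_angle, n_pts)  # direction the leading process points
  nk_log <- list()
  ck_log <- list()

  f <- 0L  # frames consumed (step index; step f covers t[f] -> t[f+1])
  while (is.finite(pause_mean)) {
    pause <- rgeom(1, 1 / (1 + pause_mean))
    f <- f + pause
    # CK: rise 1 frame, fall 1-2 frames
    fall <- sample(1:2, 1)
    if (f + 1L + fall > n_steps) break
    amp <- rlnorm_trunc(1, params$ck_amplitude_median,
                        params$ck_amplitude_logsd, 2.3)
    do_nk <- runif(1) < p_nk
    phi <- rvonmises(1, ref_angle, params$heading_kappa)
    onset_i <- f + 1L          # point index of baseline (1-based)
    peak_i <- onset_i + 1L
    end_i <- peak_i + fall
    sep[peak_i] <- params$sep_baseline + amp
    if (fall == 2L) {
      sep[peak_i + 1L] <- params$sep_baseline + amp / 2
    }
    sep[end_i] <- params$sep_baseline
    heading[onset_i:min(end_i + 2L, n_pts)] <- phi
    f <- f + 1L + fall  # frames consumed by the excursion
    if (do_nk) {
      d <- rlnorm_trunc(1, params$nk_step_median, params$nk_step_logsd,
                        params$nk_min_step)
      k <- if (params$nk_steps_max >= 2L && d > 2 * params$nk_min_step) 2L else 1L
      # NK starts the frame after the CK peak (during the fall), so its
      # start time lies strictly inside the efficiency window (peak, next onset]
      nk_start_step <- peak_i + 1L  # step s covers t[s] -> t[s+1]
      if (nk_start_step + k - 1L > n_steps) {
        # does not fit; discard the jump (CK stays, now inefficient)
        do_nk <- FALSE
      } else {
        u <- c(cos(phi), sin(phi))
        for (j in seq_len(k)) {
          disp[nk_start_step + j - 1L, ] <-
            disp[nk_start_step + j - 1L, ] + (d / k) * u
        }
        nk_log[[length(nk_log) + 1L]] <- tibble::tibble(
          start_t = (nk_start_step - 1L) * dt,
          end_t = (nk_start_step - 1L + k) * dt,
          n_steps = k, distance = d, heading = phi)
      }
    }
    ck_log[[length(ck_log) + 1L]] <- tibble::tibble(
      onset_t = (onset_i - 1L) * dt, peak_t = (peak_i - 1L) * dt,
      end_t = (end_i - 1L) * dt, amplitude = amp, efficient = do_nk)
  }

  # Emission: pause frames scatter around the anchor path with fresh
  # sub-threshold jitter; NK frames are applied exactly from the previously
  # emitted position, so a generated jump of d/k um is an inter-frame step of
  # exactly d/k um and ground truth is detectable by construction.
  base <- rbind(c(0, 0), apply(disp, 2, cumsum))
  jit <- matrix(rnorm(2 * n_pts, 0, params$jitter_sd), ncol = 2)
  is_jump <- rowSums(abs(disp)) > 0
  nuc_xy <- base + jit
  for (s in which(is_jump)) {
    nuc_xy[s + 1L, ] <- nuc_xy[s, ] + disp[s, ]
  }
  sep_obs <- sep + rnorm(n_pts, 0, params$sep_noise_sd)
  cen_xy <- nuc_xy + sep_obs * cbind(cos(heading), sin(heading))

  t_min <- (seq_len(n_pts) - 1) * dt
  nuc <- tibble::tibble(frame = seq_len(n_pts) - 1L, t_min = t_min,
                        x_um = nuc_xy[, 1], y_um = nuc_xy[, 2])
  cen <- tibble::tibble(frame = seq_len(n_pts) - 1L, t_min = t_min,
                        x_um = cen_xy[, 1], y_um = cen_xy[, 2])
  cell <- tibble::tibble(
    cell_id = cell_id, group = group, dataset_id = "sim",
    ref_x = rv[1], ref_y = rv[2], dt = dt,
    nucleus = list(nuc), centrosome = list(cen))
  nk_t <- dplyr::bind_rows(nk_log)
  ck_t <- dplyr::bind_rows(ck_log)
  if (nrow(nk_t) == 0) {
    nk_t <- tibble::tibble(start_t = numeric(), end_t = numeric(),
                           n_steps = integer(), distance = numeric(),
                           heading = numeric())
  }
  if (nrow(ck_t) == 0) {
    ck_t <- tibble::tibble(onset_t = numeric(), peak_t = numeric(),
                           end_t = numeric(), amplitude = numeric(),
                           efficient = logical())
  }
  list(cell = cell, truth = list(nk = nk_t, ck = ck_t))
}

#' Simulate a cohort of saltatory cells
#'
#' Independent cells generated via seed-derived substreams: one master seed
#' draws a per-cell seed for each cell, so cohorts are reproducible and
#' individual cells can be regenerated in isolation.
#'
#' @inheritParams simulate_cell
#' @param n_cells Number of cells.
#' @param seed Master seed (integer).
#' @return List with `cells` (nested cell tibble, one row per cell),
#'   `truth_nk` and `truth_ck` (event tibbles with a `cell_id` column).
#' @export
simulate_cohort <- function(params, n_cells = 100, seed = 1,
                            reference_vector = c(1, 0), group = "simulated") {
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)
  sims <- purrr::map(seq_len(n_cells), function(i) {
    simulate_cell(params, reference_vector,
                  cell_id = sprintf("%s_%04d", group, i),
                  seed = cell_seeds[i], group = group)
  })
  cells <- purrr::map(sims, "cell") |> dplyr::bind_rows()
  truth_nk <- purrr::imap(sims, function(s, i) {
    if (nrow(s$truth$nk) > 0) {
      dplyr::mutate(s$truth$nk, cell_id = cells$cell_id[i], .before = 1)
    }
  }) |> dplyr::bind_rows()
  truth_ck <- purrr::imap(sims, function(s, i) {
    if (nrow(s$truth$ck) > 0) {
      dplyr::mutate(s$truth$ck, cell_id = cells$cell_id[i], .before = 1)
    }
  }) |> dplyr::bind_rows()
  if (nrow(truth_nk) == 0) {
    truth_nk <- tibble::tibble(cell_id = character(), start_t = numeric(),
                               end_t = numeric(), n_steps = integer(),
                               distance = numeric(), heading = numeric())
  }
  if (nrow(truth_ck) == 0) {
    truth_ck <- tibble::tibble(cell_id = character(), onset_t = numeric(),
                               peak_t = numeric(), end_t = numeric(),
                               amplitude = numeric(), efficient = logical())
  }
  list(cells = cells, truth_nk = truth_nk, truth_ck = truth_ck)
}

#' Match detected NK events against simulator ground truth
#'
#' A true NK is recovered when a detected event overlaps its time window
#' `[start_t, end_t]`; a detected event matching no true event is spurious.
#'
#' @param detected NK events with a `cell_id` column (see
#'   [collect_events()]).
#' @param truth Ground-truth NK table from [simulate_cohort()].
#' @return One-row tibble: `n_true`, `n_detected`, `n_recovered`,
#'   `recovery_pct`, `spurious_pct`.
#' @export
match_nk_truth <- function(detected, truth) {
  overlap <- dplyr::inner_join(
    dplyr::select(truth, "cell_id", true_start = "start_t", true_end = "end_t"),
    dplyr::select(detected, "cell_id", det_start = "start_t", det_end = "end_t"),
    by = "cell_id", relationship = "many-to-many") |>
    dplyr::filter(.data$det_start <= .data$true_end,
                  .data$det_end >= .data$true_start)
  n_true <- nrow(truth)
  n_det <- nrow(detected)
  n_rec <- nrow(dplyr::distinct(overlap, .data$cell_id, .data$true_start))
  n_matched_det <- nrow(dplyr::distinct(overlap, .data$cell_id, .data$det_start))
  tibble::tibble(
    n_true = n_true, n_detected = n_det, n_recovered = n_rec,
    recovery_pct = if (n_true > 0) 100 * n_rec / n_true else NA_real_,
    spurious_pct = if (n_det > 0) 100 * (n_det - n_matched_det) / n_det else NA_real_
  )
}
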