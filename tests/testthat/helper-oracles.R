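# Brute-force reference implementations and track builders used across the
# suite. These stay deliberately naive (explicit loops, no shared code with
# the package internals) so they can serve as independent oracles.

# build a track tibble from per-step displacement vectors
track_from_steps <- function(dx, dy, dt = 3) {
  tibble::tibble(
    frame = seq_len(length(dx) + 1) - 1L,
    t_min = (seq_len(length(dx) + 1) - 1) * dt,
    x_um = cumsum(c(0, dx)),
    y_um = cumsum(c(0, dy))
  )
}

# straight-line track along +x with given per-step displacements
track_along_x <- function(steps, dt = 3) {
  track_from_steps(steps, rep(0, length(steps)), dt = dt)
}

# random track mixing sub- and supra-threshold steps
random_track <- function(n_steps, p_big = 0.25, dt = 3) {
  big <- runif(n_steps) < p_big
  mag <- ifelse(big, runif(n_steps, 6.01, 15), runif(n_steps, 0, 5.9))
  ang <- runif(n_steps, 0, 2 * pi)
  track_from_steps(mag * cos(ang), mag * sin(ang), dt = dt)
}

# ---- NK oracle: explicit scan over the boolean supra-threshold sequence ----
brute_nk <- function(track, thr = 6, merge = TRUE) {
  n <- nrow(track)
  disp <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    disp[i] <- sqrt((track$x_um[i + 1] - track$x_um[i])^2 +
                    (track$y_um[i + 1] - track$y_um[i])^2)
  }
  supra <- disp > thr
  events <- list()
  i <- 1
  while (i <= length(supra)) {
    if (supra[i]) {
      j <- i
      if (merge) while (j < length(supra) && supra[j + 1]) j <- j + 1
      events[[length(events) + 1]] <- list(
        start_t = track$t_min[i], end_t = track$t_min[j + 1],
        n_steps = j - i + 1L,
        path_distance = sum(disp[i:j]),
        net_distance = sqrt((track$x_um[j + 1] - track$x_um[i])^2 +
                            (track$y_um[j + 1] - track$y_um[i])^2))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(events) == 0) {
    return(tibble::tibble(start_t = numeric(), end_t = numeric(),
                          n_steps = integer(), path_distance = numeric(),
                          net_distance = numeric()))
  }
  dplyr::bind_rows(lapply(events, tibble::as_tibble))
}

# ---- CK oracle: exhaustive search over (onset, peak, close) triples -------
# Events are found greedily left to right. Within the open region, the close
# index is the first c for which some pair o < p < c satisfies a rise
# s[p]-s[o] > thr and a fall s[p]-s[c] > thr; the reported peak is the first
# index attaining the maximum over all rise-satisfying p before c, and the
# onset the first minimum of s up to that peak.
brute_ck_indices <- function(s, thr = 2) {
  n <- length(s)
  events <- list()
  r <- 1
  repeat {
    found <- NULL
    if (r <= n - 2) {
      for (c in (r + 2):n) {
        valid_p <- c()
        for (p in (r + 1):(c - 1)) {
          rise <- FALSE
          for (o in r:(p - 1)) {
            if (s[p] - s[o] > thr) { rise <- TRUE; break }
          }
          if (rise) valid_p <- c(valid_p, p)
        }
        ok <- FALSE
        for (p in valid_p) if (s[p] - s[c] > thr) { ok <- TRUE; break }
        if (ok) {
          peak <- valid_p[which.max(s[valid_p])]
          onset <- which.min(s[r:peak]) + r - 1
          found <- c(onset = onset, peak = peak, close = c)
          break
        }
      }
    }
    if (is.null(found)) break
    events[[length(events) + 1]] <- found
    r <- found[["close"]]
  }
  if (length(events) == 0) {
    return(tibble::tibble(onset = integer(), peak = integer(),
                          close = integer()))
  }
  tibble::as_tibble(do.call(rbind, events))
}

# ---- CK efficiency oracle: assign each NK to the unique window holding it --
brute_efficiency <- function(cks, nks, track_end_t = Inf) {
  eff <- rep(FALSE, nrow(cks))
  if (nrow(cks) == 0) return(eff)
  for (s in nks$start_t) {
    for (k in seq_len(nrow(cks))) {
      hi <- if (k < nrow(cks)) cks$onset_t[k + 1] else track_end_t
      if (s > cks$peak_t[k] && s <= hi) {
        eff[k] <- TRUE
        break
      }
    }
  }
  eff
}

# absolute angular deviation from the reference direction, in [0, 180]
angular_deviation <- function(angle_deg) pmin(angle_deg, 360 - angle_deg)
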