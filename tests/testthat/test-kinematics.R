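test_that("step displacements are per-pair Euclidean distances", {
  still <- track_from_steps(rep(0, 9), rep(0, 9))
  expect_equal(step_displacements(still)$displacement, rep(0, 9))

  tri <- tibble::tibble(t_min = c(0, 3), x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(step_displacements(tri)$displacement, 5)

  set.seed(5)
  tr <- random_track(25)
  got <- step_displacements(tr)
  manual <- sapply(seq_len(nrow(tr) - 1), function(i) {
    sqrt((tr$x_um[i + 1] - tr$x_um[i])^2 + (tr$y_um[i + 1] - tr$y_um[i])^2)
  })
  expect_equal(got$displacement, manual)
  expect_equal(got$t_start, tr$t_min[-nrow(tr)])
  expect_error(step_displacements(tr[1, ]), "2 points")
})

test_that("NK detection merges runs of strictly supra-threshold steps", {
  one <- track_along_x(c(1, 1, 8, 1, 1))
  ev <- detect_nk_events(one)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$path_distance, 8)
  expect_equal(ev$n_steps, 1L)
  expect_equal(ev$start_t, 6)
  expect_equal(ev$end_t, 9)

  run <- track_along_x(c(1, 7, 7, 1))
  ev2 <- detect_nk_events(run)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$path_distance, 14)
  expect_equal(ev2$n_steps, 2L)
  expect_equal(ev2$end_t - ev2$start_t, 2 * 3)

  # a step of exactly the threshold is not an NK (strictly "superior to")
  expect_equal(nrow(detect_nk_events(track_along_x(c(6, 6, 6)))), 0)
  expect_error(detect_nk_events(one, nk_threshold = 0), "nk_threshold")

  # merge off: one event per supra-threshold step
  ev3 <- detect_nk_events(run, merge = FALSE)
  expect_equal(nrow(ev3), 2)
  expect_equal(ev3$path_distance, c(7, 7))
})

test_that("NK events agree with the brute-force run scan on random tracks", {
  set.seed(101)
  for (rep in 1:200) {
    tr <- random_track(sample(2:30, 1))
    for (merge in c(TRUE, FALSE)) {
      got <- detect_nk_events(tr, merge = merge)
      ref <- brute_nk(tr, merge = merge)
      expect_equal(as.data.frame(got), as.data.frame(ref))
    }
  }
})

test_that("NK event union equals the set of supra-threshold steps", {
  set.seed(77)
  for (rep in 1:50) {
    tr <- random_track(sample(5:30, 1))
    steps <- step_displacements(tr)
    ev <- detect_nk_events(tr)
    in_event <- rep(FALSE, nrow(steps))
    for (k in seq_len(nrow(ev))) {
      in_event <- in_event |
        (steps$t_start >= ev$start_t[k] & steps$t_end <= ev$end_t[k])
    }
    expect_equal(in_event, steps$displacement > 6)
    if (nrow(ev) > 1) {
      expect_true(all(ev$start_t[-1] > ev$end_t[-nrow(ev)]))  # non-overlap
    }
    expect_true(all(ev$path_distance >= ev$net_distance))
    expect_true(all(ev$path_distance > ev$n_steps * 6))
  }
})

test_that("speed is total path over total time including pauses", {
  tr <- track_along_x(c(4, 6))  # 10 um over 6 min
  expect_equal(migration_speed(tr), 100)
  expect_equal(migration_speed(track_from_steps(rep(0, 5), rep(0, 5))), 0)
})

test_that("pausing time counts sub- and exactly-threshold slots", {
  expect_equal(pausing_fraction(track_from_steps(rep(0, 8), rep(0, 8))), 100)
  expect_equal(pausing_fraction(track_along_x(rep(8, 6))), 0)
  steps <- c(rep(2, 9), rep(7, 3))  # 3 of 12 above threshold
  expect_equal(pausing_fraction(track_along_x(steps)), 75)
  expect_equal(pausing_fraction(track_along_x(c(6, 6))), 100)  # boundary
})

test_that("sinuosity is path over net distance", {
  expect_equal(sinuosity(track_along_x(rep(2, 10))), 1)
  back <- track_from_steps(c(10, -5), c(0, 0))
  expect_equal(sinuosity(back), 3)
  loop <- track_from_steps(c(1, -1), c(0, 0))
  expect_warning(s <- sinuosity(loop), "undefined")
  expect_true(is.na(s))
  set.seed(3)
  tr <- random_track(15)
  net <- sqrt((tr$x_um[16] - tr$x_um[1])^2 + (tr$y_um[16] - tr$y_um[1])^2)
  expect_equal(sinuosity(tr), sum(step_displacements(tr)$displacement) / net)
})

test_that("migration angle is measured CCW from the reference axis", {
  fwd <- track_from_steps(c(5), c(0))
  expect_equal(migration_angle(fwd, c(1, 0)), 0)
  expect_equal(migration_angle(track_from_steps(-5, 0), c(1, 0)), 180)
  expect_equal(migration_angle(track_from_steps(0, 5), c(1, 0)), 90)
  expect_equal(migration_angle(track_from_steps(0, -5), c(1, 0)), 270)
  # non-axis reference
  expect_equal(migration_angle(track_from_steps(1, 1), c(0, 1)), 315)
  expect_warning(a <- migration_angle(track_from_steps(c(1, -1), c(0, 0))),
                 "undefined")
  expect_true(is.na(a))
})

test_that("radar dials are 90-degree sectors centred on 0/90/180/270", {
  r <- radar_bin(c(0, 90, 180, 270))
  expect_equal(r$count, rep(1L, 4))
  expect_equal(sum(r$pct), 100)

  r2 <- radar_bin(rep(10, 7))
  expect_equal(r2$count[r2$dial == "forward"], 7L)
  expect_equal(r2$pct[r2$dial == "forward"], 100)

  # boundary angles open the next dial
  r3 <- radar_bin(c(45, 135, 225, 315))
  expect_equal(r3$count, rep(1L, 4))
  expect_equal(r3$count[r3$dial == "left"], 1L)

  set.seed(21)
  ang <- runif(1000, 0, 360)
  r4 <- radar_bin(ang)
  ref <- c(
    forward = sum(ang >= 315 | ang < 45),
    left = sum(ang >= 45 & ang < 135),
    backward = sum(ang >= 135 & ang < 225),
    right = sum(ang >= 225 & ang < 315))
  expect_equal(setNames(r4$count, r4$dial), ref)
  expect_equal(sum(r4$count), 1000L)
  expect_equal(sum(r4$pct), 100, tolerance = 1e-10)
  expect_error(radar_bin(c(10, 400)), "0, 360")
})

test_that("separation series is the per-timepoint distance on the overlap", {
  nuc <- track_from_steps(rep(1, 9), rep(0, 9))
  cen0 <- nuc
  expect_equal(centrosome_separation_series(nuc, cen0)$separation, rep(0, 10))

  cen5 <- dplyr::mutate(nuc, y_um = y_um + 5)
  expect_equal(centrosome_separation_series(nuc, cen5)$separation, rep(5, 10))

  # centrosome covering a subset of timepoints restricts the series
  cen_sub <- cen5[3:7, ]
  ser <- centrosome_separation_series(nuc, cen_sub)
  expect_equal(ser$t_min, nuc$t_min[3:7])

  set.seed(9)
  cen_r <- dplyr::mutate(nuc, x_um = x_um + rnorm(10), y_um = y_um + rnorm(10))
  ser2 <- centrosome_separation_series(nuc, cen_r)
  manual <- sqrt((cen_r$x_um - nuc$x_um)^2 + (cen_r$y_um - nuc$y_um)^2)
  expect_equal(ser2$separation, manual)
})

test_that("metrics are scale-equivariant and rotation-invariant", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- random_track(20)
    rv <- c(1, 0)
    # doubling coordinates (and thresholds) doubles distances, keeps shape
    tr2 <- dplyr::mutate(tr, x_um = 2 * x_um, y_um = 2 * y_um)
    expect_equal(migration_speed(tr2), 2 * migration_speed(tr))
    expect_equal(sinuosity(tr2), sinuosity(tr))
    expect_equal(migration_angle(tr2, rv), migration_angle(tr, rv))
    expect_equal(pausing_fraction(tr2, 12), pausing_fraction(tr, 6))
    ev <- detect_nk_events(tr, 6); ev2 <- detect_nk_events(tr2, 12)
    expect_equal(ev2$path_distance, 2 * ev$path_distance)
    expect_equal(ev2$start_t, ev$start_t)

    # rotating coordinates and reference together changes nothing
    th <- runif(1, 0, 2 * pi)
    rot <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                               y = sin(th) * x + cos(th) * y)
    p <- rot(tr$x_um, tr$y_um)
    trR <- dplyr::mutate(tr, x_um = p$x, y_um = p$y)
    rvR <- unlist(rot(rv[1], rv[2]))
    expect_equal(migration_speed(trR), migration_speed(tr))
    expect_equal(sinuosity(trR), sinuosity(tr))
    expect_equal(pausing_fraction(trR), pausing_fraction(tr))
    expect_equal(migration_angle(trR, rvR), migration_angle(tr, rv))
    evR <- detect_nk_events(trR)
    expect_equal(evR$path_distance, ev$path_distance)
  }
})
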