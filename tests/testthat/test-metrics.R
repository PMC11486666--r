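test_that("centered differences are exact on linear motion", {
  tt <- make_track(0:2, cbind(0:2, 0, 0))  # 1 um per 0.5 min step
  cv <- centered_velocities(tt)
  expect_equal(cv$valid, c(FALSE, TRUE, FALSE))
  expect_equal(cv$ux_um_min[2], 2)
})

test_that("any gap invalidates neighbouring centered velocities", {
  tt <- make_track(c(0, 1, 3, 4), cbind(c(0, 1, 3, 4), 0, 0))
  cv <- centered_velocities(tt)
  expect_false(any(cv$valid))  # every interior slot misses a neighbour
})

test_that("centered velocities match a brute-force recomputation", {
  withr::with_seed(41, {
    for (i in 1:40) {
      tt <- random_gapped_track(50, drop = 0.25, id = "r")
      cv <- centered_velocities(tt)
      oracle <- brute_centered(tibble::as_tibble(tt), dt = 0.5)
      got <- cv[cv$valid, c("frame", "ux_um_min", "uy_um_min", "uz_um_min")]
      if (is.null(oracle)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$frame, oracle[, 1])
        expect_equal(as.matrix(got[, 2:4]), oracle[, 2:4, drop = FALSE],
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  })
})

test_that("frame speeds skip gap-spanning pairs", {
  tt <- make_step_track(rep(1, 4))         # 5 frames, all 2 um/min
  expect_equal(frame_speeds(tt)$speed_um_min, rep(2, 4))

  still <- make_track(0:4, matrix(1, 5, 3) * c(1, 1, 1))
  expect_true(all(frame_speeds(still)$speed_um_min == 0))

  gapped <- make_track(c(0, 1, 3, 4), cbind(c(0, 1, 3, 4), 0, 0))
  expect_equal(nrow(frame_speeds(gapped)), 4 - 2)  # observed slots - 2
})

test_that("mean track speed averages frame speeds", {
  expect_equal(mean_track_speed(make_ballistic(3, 10))$mean_speed_um_min, 3)
  tt <- make_step_track(c(0, 2))  # speeds 0 and 4 um/min
  expect_equal(mean_track_speed(tt)$mean_speed_um_min, 2)
  single <- make_track(0, cbind(0, 0, 0))
  res <- mean_track_speed(single)
  expect_true(is.na(res$mean_speed_um_min))
  expect_equal(res$n_speeds, 0L)
})

test_that("arrest coefficient counts strictly sub-threshold speeds", {
  tt <- make_step_track(c(0.5, 1.5, 0.5, 1.5))  # speeds 1,3,1,3
  expect_equal(arrest_coefficient(tt)$arrest_pct, 50)
  expect_equal(arrest_coefficient(make_track(0:3, matrix(0, 4, 3)))$arrest_pct, 100)
  exactly2 <- make_step_track(rep(1, 5))        # all speeds exactly 2
  expect_equal(arrest_coefficient(exactly2)$arrest_pct, 0)
})

test_that("arrest coefficient is invariant under rigid motion", {
  withr::with_seed(42, {
    tt <- random_gapped_track(40, drop = 0.1)
    base <- arrest_coefficient(tt)$arrest_pct
    theta <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
    pos <- as.matrix(tibble::as_tibble(tt)[, c("x_um", "y_um", "z_um")])
    moved <- make_track(tt$frame, pos %*% t(R) + 100, id = "rot")
    expect_equal(arrest_coefficient(moved)$arrest_pct, base)
  })
})

test_that("mean speed dominates net displacement over duration", {
  withr::with_seed(43, {
    for (i in 1:20) {
      tt <- random_gapped_track(30, drop = 0)
      m <- track_metrics(tt)
      expect_gte(m$mean_speed_um_min + 1e-9, m$net_disp_um / m$duration_min)
    }
  })
})

test_that("turning angles recover canonical geometries", {
  fwd <- make_ballistic(2, 5)
  expect_true(all(abs(turning_angles(fwd)$angle_deg) < 1e-8))

  rev <- make_track(0:2, cbind(c(0, 1, 0), 0, 0))
  expect_equal(turning_angles(rev)$angle_deg, 180)

  ra <- make_track(0:2, cbind(c(0, 1, 1), c(0, 0, 1), 0))
  expect_equal(turning_angles(ra)$angle_deg, 90)

  # sub-resolution steps carry no direction
  tiny <- make_track(0:2, cbind(c(0, 0.05, 1), 0, 0))
  expect_equal(nrow(turning_angles(tiny, min_step = 0.2)), 0L)
})

test_that("ballistic ensemble MSD equals (v tau)^2 at every lag", {
  tt <- make_ballistic(3, 21)  # 10 min at 0.5 min frames
  msd <- msd_ensemble(tt, max_lag = 10, require_continuous = 10)
  expect_equal(msd$msd_um2, (3 * msd$lag_min)^2)
  expect_equal(msd$msd_um2[msd$lag_min == 2], 36)
  expect_equal(msd$msd_um2[msd$lag_min == 0], 0)
})

test_that("stationary tracks have identically zero MSD", {
  still <- make_track(0:20, matrix(5, 21, 3))
  msd <- msd_ensemble(still, max_lag = 5, require_continuous = 5)
  expect_true(all(msd$msd_um2 == 0))
})

test_that("MSD honours the continuous-tracking requirement", {
  ok <- make_ballistic(2, 21, id = "ok")
  short <- make_ballistic(2, 9, id = "short")             # 4 min only
  gap <- make_track(c(0:5, 7:20), cbind(c(0:5, 7:20), 0, 0), id = "gap")
  tt <- as_track_tbl(dplyr::bind_rows(tibble::as_tibble(ok),
                                      tibble::as_tibble(short),
                                      tibble::as_tibble(gap)))
  msd <- msd_ensemble(tt, max_lag = 10, require_continuous = 10)
  expect_true(all(msd$n_tracks == 1))  # only the continuous 10-min track
  expect_error(msd_ensemble(tt, max_lag = 0.7), "multiple")
})
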