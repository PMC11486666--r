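test_that("parameter grids are uniform and reject degenerate requests", {
  g <- make_grid(c(-1, 1), c(0, 10), n_q = 5, n_a = 100)
  expect_equal(g$q, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(g$a[1], 0.1)
  expect_equal(diff(g$a), rep(0.1, 99))
  expect_error(make_grid(n_q = 1), "at least 2")
  expect_error(make_grid(q_bounds = c(-2, 1)), "within \\[-1, 1\\]")
  expect_error(make_grid(a_bounds = c(-1, 10)), ">= 0")
})

test_that("the one-step likelihood matches its closed form", {
  g <- make_grid(n_q = 21, n_a = 20)
  L <- step_likelihood(c(0, 0, 0), c(0, 0, 0), g)
  # zero velocities: L = (2 pi a^2)^(-3/2), independent of q
  j1 <- which.min(abs(g$a - 1))
  expect_equal(L[1, j1], (2 * pi)^(-3 / 2))
  expect_equal(L[1, j1], 0.0634936, tolerance = 1e-6)
  expect_true(all(apply(L, 2, function(col) diff(range(col)) == 0)))

  # noiseless AR step: maximum over q at the grid point nearest q0
  u_prev <- c(2, -1, 0.5)
  q0 <- 0.62
  L2 <- step_likelihood(u_prev, q0 * u_prev, g)
  for (j in c(1, 10, 20)) {
    expect_equal(which.max(L2[, j]), which.min(abs(g$q - q0)))
  }
  expect_error(step_likelihood(c(Inf, 0, 0), c(0, 0, 0), g), "finite")
})

test_that("the likelihood surface equals a dense brute-force evaluation", {
  g <- make_grid(n_q = 15, n_a = 12)
  withr::with_seed(51, {
    for (i in 1:5) {
      u_prev <- rnorm(3, 0, 3); u_curr <- rnorm(3, 0, 3)
      L <- step_likelihood(u_prev, u_curr, g)
      brute <- matrix(0, 15, 12)
      for (qi in 1:15) for (aj in 1:12) {
        a <- g$a[aj]
        brute[qi, aj] <- (2 * pi * a^2)^(-3 / 2) *
          exp(-sum((u_curr - g$q[qi] * u_prev)^2) / (2 * a^2))
      }
      expect_equal(L, brute, tolerance = 1e-14)
    }
  })
})

test_that("a single update equals brute-force product-and-normalize", {
  g <- make_grid()
  u <- rbind(c(1, 2, -1), c(0.5, 1.8, -0.4))
  vel <- tibble::tibble(track_id = "t", frame = 0:1, observed = TRUE,
                        valid = TRUE,
                        ux_um_min = u[, 1], uy_um_min = u[, 2],
                        uz_um_min = u[, 3])
  ps <- sequential_filter(vel, g, spread_kernel(0, 0), keep_posteriors = TRUE)
  expect_equal(ps$n_updates, 1L)
  oracle <- brute_posterior(u[1, ], u[2, ], g)
  expect_lt(max(abs(ps$posteriors[[1]] - oracle)), 1e-12)
  expect_equal(sum(ps$posteriors[[1]]), 1, tolerance = 1e-10)
})

test_that("width-0 kernel reduces to static-parameter Bayes", {
  g <- make_grid(n_q = 41, n_a = 30)
  withr::with_seed(52, {
    tr <- simulate_track(parameter_path(6, q = 0.5, a = 1.5))
    vel <- forward_velocities(tr)
    ps <- sequential_filter(vel, g, spread_kernel(0, 0), keep_posteriors = TRUE)
    # oracle: normalized product of all step likelihoods in log space
    u <- as.matrix(vel[vel$valid, c("ux_um_min", "uy_um_min", "uz_um_min")])
    logpost <- matrix(0, 41, 30)
    for (t in 2:nrow(u)) {
      logpost <- logpost + log(step_likelihood(u[t - 1, ], u[t, ], g))
    }
    oracle <- exp(logpost - max(logpost))
    oracle <- oracle / sum(oracle)
    expect_equal(ps$posteriors[[ps$n_updates]], oracle, tolerance = 1e-10)
  })
})

test_that("every stored posterior is a normalized distribution", {
  withr::with_seed(53, {
    tr <- simulate_track(parameter_path(30, q = 0.6, a = 2))
    ps <- sequential_filter(forward_velocities(tr), make_grid(),
                            spread_kernel(), keep_posteriors = TRUE)
    sums <- vapply(ps$posteriors, sum, numeric(1))
    expect_true(all(abs(sums - 1) <= 1e-10))
    expect_true(all(ps$q_hat >= -1 & ps$q_hat <= 1))
    expect_true(all(ps$a_hat > 0))
  })
})

test_that("fewer than two usable velocities yields an empty result", {
  short <- make_track(0:1, cbind(0:1, 0, 0))
  ps <- sequential_filter(centered_velocities(short))
  expect_equal(ps$n_updates, 0L)
  expect_length(ps$q_hat, 0L)
})

test_that("a gap never pairs velocities across it", {
  # frames 0..5 and 7..12: centered velocities valid at 1..4 and 8..11 only;
  # updates happen inside each segment, never bridging the gap
  tt <- make_track(c(0:5, 7:12), cbind(c(0:5, 7:12)^1.1, 1, 0))
  ps <- sequential_filter(centered_velocities(tt))
  expect_true(all(ps$steps %in% c(2:4, 9:11)))
})

test_that("posteriors before a gap match the gap-free prefix run alone", {
  withr::with_seed(54, {
    tr <- simulate_track(parameter_path(40, q = 0.6, a = 2))
    full <- tibble::as_tibble(tr)
    gapped <- as_track_tbl(full[-25, ],
                           acquisition = acquisition_spec())
    g <- make_grid(n_q = 51, n_a = 40)
    ps_gap <- sequential_filter(centered_velocities(gapped), g,
                                keep_posteriors = TRUE)
    prefix <- as_track_tbl(full[1:23, ], acquisition = acquisition_spec())
    ps_pre <- sequential_filter(centered_velocities(prefix), g,
                                keep_posteriors = TRUE)
    shared <- intersect(ps_pre$steps, ps_gap$steps)
    expect_gt(length(shared), 10)
    for (s in shared) {
      expect_equal(ps_gap$posteriors[[match(s, ps_gap$steps)]],
                   ps_pre$posteriors[[match(s, ps_pre$steps)]],
                   tolerance = 1e-12)
    }
  })
})

test_that("a straight near-deterministic track drives q to the top of the grid", {
  withr::with_seed(55, {
    tr <- simulate_track(parameter_path(40, q = 1, a = 0.1),
                         initial_speed_mode = "zero")
    ps <- sequential_filter(forward_velocities(tr), make_grid(),
                            keep_posteriors = TRUE)
    post20 <- ps$posteriors[[20]]
    mass_top <- sum(rowSums(post20)[make_grid()$q >= 0.9])
    expect_gte(mass_top, 0.5)
  })
})

test_that("the Brownian limit centres q_hat near zero", {
  withr::with_seed(56, {
    qbars <- vapply(1:12, function(i) {
      tr <- simulate_track(parameter_path(300, q = 0, a = 2))
      mean(sequential_filter(forward_velocities(tr))$q_hat)
    }, numeric(1))
    expect_lte(abs(mean(qbars)), 0.1)
  })
})

test_that("cell summaries enforce the 15-velocity / 240-s eligibility", {
  # exactly 14 valid velocities -> ineligible
  tr14 <- make_ballistic(3, 16)
  v14 <- centered_velocities(tr14)
  ps14 <- sequential_filter(v14)
  s14 <- summarize_cell(ps14, v14)
  expect_equal(s14$n_valid, 14L)
  expect_false(s14$eligible)

  # 230 s (7.7 frames -> use 8 frames = 3.5 min < 4 min) with enough grid:
  # a dense short track has < 240 s duration -> ineligible
  tr_short <- make_ballistic(3, 8)
  v_short <- centered_velocities(tr_short)
  s_short <- summarize_cell(sequential_filter(v_short), v_short)
  expect_false(s_short$eligible)

  tr_ok <- make_ballistic(3, 21)
  v_ok <- centered_velocities(tr_ok)
  s_ok <- summarize_cell(sequential_filter(v_ok), v_ok)
  expect_true(s_ok$eligible)
  expect_equal(s_ok$q_bar, mean(sequential_filter(v_ok)$q_hat))
})

test_that("infer_cells summarises a cohort and expands a cramped grid", {
  co <- simulate_cohort(simulation_config(n_cells = 6, seed = 57))
  fit <- infer_cells(co$tracks, method = "forward")
  expect_equal(nrow(fit$summary), 6L)
  expect_true(all(c("q_bar", "a_bar", "eligible", "population")
                  %in% names(fit$summary)))
  expect_equal(sort(unique(tidy(fit)$track_id)),
               sort(fit$summary$track_id[fit$summary$n_updates > 0]))

  fast <- simulate_cohort(simulation_config(
    population_spec("fast", 1, q = 0.5, a = 8, n_steps = 40),
    n_cells = 3, seed = 58))
  expect_warning(
    fit2 <- infer_cells(fast$tracks, grid = make_grid(a_bounds = c(0, 4)),
                        method = "forward"),
    "expanding")
  expect_gt(max(fit2$grid$a), 4)
})
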