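test_that("family phase embeds the Zahnreihe period", {
  cfg <- wave_config(n_positions = 8, z_true = 2, seed = 1, t = 0.37)
  expect_equal(family_phase(1, cfg), family_phase(3, cfg))
  cfg0 <- wave_config(n_positions = 8, z_true = 3, seed = 1, t = 0)
  expect_equal(family_phase(3, cfg0), 0)
  cfg4 <- wave_config(n_positions = 8, z_true = 4, seed = 1, t = 0.25)
  expect_equal(family_phase(1, cfg4), 0)
  expect_error(family_phase(9, cfg), "out of range")
})

test_that("phase bins map onto the co-occurring stage pairs", {
  w <- rep(0.2, 5)
  expect_equal(phase_to_stages(0, w)$stage, "F1")
  expect_equal(phase_to_stages(0.5, w)$stage, c("F3", "R1"))
  expect_equal(phase_to_stages(0.99, w)$stage, c("F4", "R3"))
  expect_equal(phase_to_stages(0.99, w)$kind, c("functional", "replacement"))
  expect_error(phase_to_stages(1, w), "\\[0, 1\\)")
  # skewed weights move the bin edges
  expect_equal(phase_to_stages(0.5, c(0.6, 0.1, 0.1, 0.1, 0.1))$stage, "F1")
})

test_that("the config validator names every offending field", {
  expect_error(wave_config(n_positions = 3, z_true = 2),
               "n_positions")
  expect_error(wave_config(n_positions = 8, z_true = 0.8),
               "z_true")
  expect_error(
    wave_config(n_positions = 8, z_true = 2, stage_weights = rep(0.25, 4),
                noise_p = 2),
    "stage_weights.*noise_p"
  )
})

test_that("simulation is deterministic and honours the quadrant invariants", {
  cfg <- wave_config(n_positions = 13, z_true = 2.5, noise_p = 0.2,
                     missing_p = 0.15, seed = 77)
  a <- simulate_quadrant(cfg)
  b <- simulate_quadrant(cfg)
  expect_identical(a, b)

  set.seed(12)
  for (k in 1:20) {
    cfg_k <- wave_config(
      n_positions = sample(4:16, 1),
      z_true = stats::runif(1, 1.2, 4),
      t = stats::runif(1),
      noise_p = stats::runif(1, 0, 0.3),
      missing_p = stats::runif(1, 0, 0.3),
      seed = sample.int(2^31 - 1, 1)
    )
    expect_silent(validate_dentition(simulate_quadrant(cfg_k)))
  }
})

test_that("integer Z-spacing makes scores periodic at zero noise", {
  for (z in c(2, 3)) {
    cfg <- wave_config(n_positions = 12, z_true = z, t = 0.61, seed = 5)
    pts <- plot_points(simulate_quadrant(cfg))
    by_pos <- lapply(split(pts$score, pts$position), sort)
    for (p in seq_len(12 - z)) {
      expect_identical(by_pos[[as.character(p)]], by_pos[[as.character(p + z)]])
    }
  }
})

test_that("alternation at Z = 2 splits scores by position parity", {
  cfg <- wave_config(n_positions = 6, z_true = 2, t = 0.3, seed = 9)
  pts <- plot_points(simulate_quadrant(cfg))
  odd <- unique(split(pts$score, pts$position %% 2)$`1`)
  even <- unique(split(pts$score, pts$position %% 2)$`0`)
  expect_true(length(intersect(odd, even)) == 0)
  # the analysis pipeline calls this quadrant alternating
  ms <- compute_z_spacing(segment_zahnreihen(pts))$mean_spacing
  expect_equal(classify_wave_direction(ms), "alternating")
})

test_that("recovery tables stay well-formed at the edges", {
  one <- run_recovery_experiment(c(2.0), reps = 1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$rmse, abs(one$bias))
  alt <- run_recovery_experiment(c(2.0), reps = 20, noise_p = 0, seed = 8)
  expect_equal(alt$bias, 0, tolerance = 1e-12)
  expect_equal(alt$n_undetermined, 0L)
  expect_error(run_recovery_experiment(c(2.0), reps = 0), "reps")
})

test_that("mean spacing recovers a fractional true Z on a 13-tooth row", {
  res <- run_recovery_experiment(c(2.5), n_positions = 13, reps = 40,
                                 noise_p = 0, seed = 21)
  expect_lte(abs(res$bias), 0.3)
})

test_that("direction calls recover the simulated wave direction", {
  set.seed(31)
  for (z in c(1.6, 2.0, 2.4)) {
    expected <- classify_wave_direction(z)
    seeds <- sample.int(2^31 - 1, 30)
    ts <- stats::runif(30)
    calls <- vapply(1:30, function(k) {
      q <- simulate_quadrant(wave_config(n_positions = 12, z_true = z,
                                         t = ts[k], seed = seeds[k]))
      ms <- compute_z_spacing(segment_zahnreihen(plot_points(q)))$mean_spacing
      classify_wave_direction(ms)
    }, character(1))
    expect_gte(mean(calls == expected), 0.9)
  }
})
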