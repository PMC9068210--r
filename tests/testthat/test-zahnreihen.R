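test_that("a single descending row forms one Zahnreihe", {
  pts <- tibble::tibble(position = 1:4, score = c(7L, 6L, 5L, 4L))
  seg <- segment_zahnreihen(pts)
  expect_equal(greedy_counts(seg)$runs, 1)
  expect_equal(greedy_counts(seg)$exceptions, 0)
})

test_that("pure alternation splits into two-point runs spaced exactly 2.0", {
  pts <- tibble::tibble(position = 1:6, score = rep(c(5L, 4L), 3))
  seg <- segment_zahnreihen(pts)
  expect_equal(greedy_counts(seg)$runs, 3)
  expect_true(all(table(seg$zahnreihe) == 2))
  zs <- compute_z_spacing(seg)
  expect_equal(zs$mean_spacing, 2.0)
  expect_equal(classify_wave_direction(zs$mean_spacing), "alternating")
  # any even length
  for (n in c(4, 10, 16)) {
    pts_n <- tibble::tibble(position = seq_len(n), score = rep(c(5L, 4L), n / 2))
    expect_equal(compute_z_spacing(segment_zahnreihen(pts_n))$mean_spacing, 2.0)
  }
})

test_that("segmentation validates its input", {
  expect_error(
    segment_zahnreihen(tibble::tibble(position = c(2L, 1L), score = c(5L, 4L))),
    "sorted by position"
  )
  expect_error(
    segment_zahnreihen(tibble::tibble(position = c(1L, 1L, 1L), score = c(7L, 4L, 1L))),
    "at most two plotted points"
  )
  empty <- segment_zahnreihen(tibble::tibble(position = integer(0), score = integer(0)))
  expect_equal(nrow(empty), 0)
  expect_true("zahnreihe" %in% names(empty))
})

test_that("every point lands in exactly one run or in the exceptions", {
  set.seed(7)
  for (k in 1:50) {
    pts <- random_points(sample(4:12, 1))
    if (nrow(pts) == 0) next
    seg <- segment_zahnreihen(pts)
    counts <- greedy_counts(seg)
    in_runs <- sum(!is.na(seg$zahnreihe))
    expect_equal(in_runs + counts$exceptions, nrow(pts))
    # strict caudal descent within every emitted run
    for (r in unique(stats::na.omit(seg$zahnreihe))) {
      run <- seg[!is.na(seg$zahnreihe) & seg$zahnreihe == r, ]
      expect_true(all(diff(run$position) > 0))
      expect_true(all(diff(run$score) < 0))
      expect_gte(nrow(run), 2)
    }
  }
})

test_that("Z-spacing measures score-matched positional offsets", {
  seg <- tibble::tibble(
    position = c(1L, 2L, 3L, 4L),
    score = c(5L, 4L, 5L, 4L),
    zahnreihe = c(1L, 1L, 2L, 2L)
  )
  zs <- compute_z_spacing(seg)
  expect_equal(zs$pair_spacings$spacing, 2.0)
  expect_equal(zs$mean_spacing, 2.0)

  # interpolation: offset measured at a level only one run holds exactly
  seg2 <- tibble::tibble(
    position = c(1L, 2L, 3L, 5L),
    score = c(7L, 4L, 6L, 5L),
    zahnreihe = c(1L, 1L, 2L, 2L)
  )
  zs2 <- compute_z_spacing(seg2)
  # run 1 interpolated at 6 -> 4/3, 5 -> 5/3; run 2 at 6 -> 3, 5 -> 5
  expect_equal(zs2$pair_spacings$spacing, mean(c(3 - 4 / 3, 5 - 5 / 3)))

  # single Zahnreihe: no adjacent pair, spacing undetermined
  one <- tibble::tibble(position = 1:2, score = c(5L, 4L), zahnreihe = c(1L, 1L))
  expect_true(is.na(compute_z_spacing(one)$mean_spacing))

  # non-overlapping score ranges: pair skipped and flagged
  apart <- tibble::tibble(
    position = c(1L, 2L, 3L, 4L),
    score = c(3L, 2L, 7L, 6L),
    zahnreihe = c(1L, 1L, 2L, 2L)
  )
  zsa <- compute_z_spacing(apart)
  expect_true(is.na(zsa$pair_spacings$spacing))
  expect_equal(zsa$pair_spacings$n_shared_levels, 0L)
  expect_true(is.na(zsa$mean_spacing))
})

test_that("wave direction is a two-threshold step function around 2.0", {
  expect_equal(
    classify_wave_direction(c(2.54, 2.0, 1.8, NA)),
    c("rostral_to_caudal", "alternating", "caudal_to_rostral", "undetermined")
  )
  eps <- 0.05
  grid <- c(1.5, 2 - eps - 1e-6, 2 - eps + 1e-6, 2, 2 + eps - 1e-6,
            2 + eps + 1e-6, 3.3)
  got <- classify_wave_direction(grid, eps = eps)
  expect_equal(got, c("caudal_to_rostral", "caudal_to_rostral", "alternating",
                      "alternating", "alternating", "rostral_to_caudal",
                      "rostral_to_caudal"))
  expect_error(classify_wave_direction(-1), "positive")
})

test_that("regional spacing splits pairs at the row midpoint", {
  pairs <- tibble::tibble(
    pair_index = 1:2, spacing = c(3.0, 1.5),
    midpoint_position = c(3.0, 10.0), n_shared_levels = c(2L, 2L)
  )
  reg <- regional_z_spacing(pairs, row_length = 13)
  expect_equal(reg$rostral_mean, 3.0)
  expect_equal(reg$caudal_mean, 1.5)

  rostral_only <- dplyr::filter(pairs, midpoint_position < 5)
  reg2 <- regional_z_spacing(rostral_only, row_length = 13)
  expect_true(is.na(reg2$caudal_mean))
  expect_error(regional_z_spacing(pairs, row_length = 8), "row_length")
})

test_that("report accessors expose the quadrant summary", {
  rep <- analyze_quadrant(load_fixture("v18638_right_maxilla_stages"))
  g <- glance(rep)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_zahnreihen, 4L)
  expect_equal(g$direction, "rostral_to_caudal")
  expect_equal(tidy(rep), rep$pair_spacings)
  expect_output(print(rep), "Zahnreihen: 4")
  # rostral spacing exceeds caudal spacing in this quadrant
  expect_gt(g$rostral_mean, g$caudal_mean)
})

test_that("half-up rounding resolves ties upward", {
  expect_equal(round_half_up(2.665, 2), 2.67)
  expect_equal(round_half_up(2.664, 2), 2.66)
  expect_equal(round_half_up(-2.665, 2), -2.67)
  expect_equal(round_half_up(0.5), 1)
})
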