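# Periodic replacement-wave simulator.
#
# Tooth families along the jaw cycle through eruption, wear and replacement;
# a replacement wave couples neighbouring families with a fixed positional
# offset (the true Z-spacing), so the family at position p and the family at
# p + Z are exactly in phase. Discretising each family's phase into the
# seven-step maturity ladder yields synthetic jaw quadrants with a known
# Z-spacing, used to validate the analysis pipeline by parameter recovery.

#' Configure the replacement-wave model
#'
#' @param n_positions Number of tooth positions in the quadrant (>= 4).
#' @param z_true True Z-spacing in tooth-position units (> 1).
#' @param cycle Duration of one full functional/replacement cycle, in
#'   arbitrary time units (default 1).
#' @param t Observation time, same units as `cycle` (default 0).
#' @param stage_weights Five positive phase-duration weights summing to 1
#'   for the phases F1, F2, F3 (with an R1 bud), F4 (with an R2 successor),
#'   and F4 (with an R3 successor). Default: equal fifths.
#' @param noise_p Probability that a point's maturity score is perturbed by
#'   one step up or down the 1..7 ladder (clipped at the ends).
#' @param missing_p Probability that a position is recorded as an empty
#'   alveolus instead of its teeth.
#' @param seed Integer seed making [simulate_quadrant()] deterministic.
#' @return A validated `wave_config` list.
#' @examples
#' wave_config(n_positions = 13, z_true = 2.5, seed = 1)
#' @export
wave_config <- function(n_positions, z_true, cycle = 1, t = 0,
                        stage_weights = rep(0.2, 5),
                        noise_p = 0, missing_p = 0, seed = 1L) {
  bad <- character(0)
  if (!is.numeric(n_positions) || length(n_positions) != 1 ||
      n_positions < 4 || n_positions != as.integer(n_positions)) {
    bad <- c(bad, "n_positions (integer >= 4)")
  }
  if (!is.numeric(z_true) || length(z_true) != 1 || z_true <= 1) {
    bad <- c(bad, "z_true (real > 1)")
  }
  if (!is.numeric(cycle) || length(cycle) != 1 || cycle <= 0) {
    bad <- c(bad, "cycle (real > 0)")
  }
  if (!is.numeric(t) || length(t) != 1 || is.na(t)) {
    bad <- c(bad, "t (real)")
  }
  if (!is.numeric(stage_weights) || length(stage_weights) != 5 ||
      any(stage_weights <= 0) || abs(sum(stage_weights) - 1) > 1e-9) {
    bad <- c(bad, "stage_weights (5 positive reals summing to 1)")
  }
  if (!is.numeric(noise_p) || noise_p < 0 || noise_p > 1) {
    bad <- c(bad, "noise_p (in [0, 1])")
  }
  if (!is.numeric(missing_p) || missing_p < 0 || missing_p > 1) {
    bad <- c(bad, "missing_p (in [0, 1])")
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != as.integer(seed)) {
    bad <- c(bad, "seed (integer)")
  }
  if (length(bad) > 0) {
    stop("invalid wave model configuration; offending field(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  structure(
    list(n_positions = as.integer(n_positions), z_true = z_true,
         cycle = cycle, t = t, stage_weights = stage_weights,
         noise_p = noise_p, missing_p = missing_p, seed = as.integer(seed)),
    class = "wave_config"
  )
}

#' Replacement-cycle phase of a tooth family
#'
#' The family at position p observed at time t sits at phase
#' `frac(t / cycle - p / z_true)` of its replacement cycle, so families at
#' positions p and p + Z are exactly in phase and the phase decreases
#' caudally (rostral teeth are more mature, as in a Zahnreihe).
#'
#' @param position Integer vector of tooth positions (1..`n_positions`).
#' @param config A [wave_config()].
#' @return Numeric vector of phases in `[0, 1)`.
#' @examples
#' cfg <- wave_config(n_positions = 6, z_true = 2, seed = 1)
#' family_phase(c(1, 3), cfg) # period 2: equal phases
#' @export
family_phase <- function(position, config) {
  if (any(position < 1 | position > config$n_positions)) {
    stop("position out of range 1..", config$n_positions, call. = FALSE)
  }
  x <- config$t / config$cycle - position / config$z_true
  phase <- x - floor(x)
  # round away last-bit noise so mathematically in-phase positions (p and
  # p + Z) land in the same stage bin, then re-wrap 1 back to 0
  phase <- round(phase, 9)
  ifelse(phase >= 1, phase - 1, phase)
}

#' Discretise a cycle phase into staged tooth records
#'
#' Cumulative-weight bins map the phase onto the observable state of the
#' tooth family: a young functional tooth alone (F1, then F2), then late
#' functional stages accompanied by their developing successor (F3 with an
#' R1 bud, F4 with an R2 crown, F4 with an R3 crown at the functional crown
#' base), mirroring how replacement buds co-occur with heavily worn teeth.
#'
#' @param phase Numeric scalar in `[0, 1)`.
#' @param weights Five phase-duration weights (see [wave_config()]).
#' @return A tibble with columns `kind` and `stage`: one row (functional
#'   tooth) in the early bins, two rows (functional + replacement) in the
#'   late bins.
#' @examples
#' phase_to_stages(0.5, rep(0.2, 5)) # F3 with an R1 bud
#' @export
phase_to_stages <- function(phase, weights = rep(0.2, 5)) {
  if (phase < 0 || phase >= 1) {
    stop("phase must lie in [0, 1)", call. = FALSE)
  }
  bin <- findInterval(phase, cumsum(weights)[-5]) + 1L
  states <- list(
    list(functional = "F1", replacement = NULL),
    list(functional = "F2", replacement = NULL),
    list(functional = "F3", replacement = "R1"),
    list(functional = "F4", replacement = "R2"),
    list(functional = "F4", replacement = "R3")
  )[[bin]]
  tibble::tibble(
    kind = c("functional", if (!is.null(states$replacement)) "replacement"),
    stage = c(states$functional, states$replacement)
  )
}

#' Simulate a jaw quadrant from the replacement-wave model
#'
#' Applies the phase model at every position, then observation noise (each
#' point's maturity score moves one step up or down the 1..7 ladder with
#' probability `noise_p`; a perturbation that would collide with the
#' position's other record is dropped so the quadrant stays valid) and
#' missingness (a position becomes a single empty-alveolus record with
#' probability `missing_p`). Deterministic given `config$seed`.
#'
#' @param config A [wave_config()].
#' @return A dentition tibble for one simulated left maxilla, passing
#'   [validate_dentition()].
#' @examples
#' simulate_quadrant(wave_config(n_positions = 6, z_true = 2, seed = 42))
#' @export
simulate_quadrant <- function(config) {
  if (!inherits(config, "wave_config")) {
    config <- do.call(wave_config, config)
  }
  withr::with_seed(config$seed, {
    rows <- purrr::map(seq_len(config$n_positions), function(p) {
      st <- phase_to_stages(family_phase(p, config), config$stage_weights)
      dplyr::mutate(st, position = p)
    }) |>
      dplyr::bind_rows()

    if (config$noise_p > 0) {
      score <- maturity_score(rows$stage)
      perturb <- stats::runif(nrow(rows)) < config$noise_p
      step <- sample(c(-1L, 1L), nrow(rows), replace = TRUE)
      new_score <- pmin(7L, pmax(1L, score + ifelse(perturb, step, 0L)))
      for (i in seq_len(nrow(rows))) {
        if (new_score[i] == score[i]) next
        new_kind <- if (new_score[i] >= 4L) "functional" else "replacement"
        collides <- any(rows$position == rows$position[i] &
                          seq_len(nrow(rows)) != i &
                          rows$kind == new_kind)
        if (!collides) {
          rows$stage[i] <- score_to_stage(new_score[i])
          rows$kind[i] <- new_kind
        }
      }
    }

    if (config$missing_p > 0) {
      gone <- unique(rows$position)[
        stats::runif(length(unique(rows$position))) < config$missing_p]
      if (length(gone) > 0) {
        rows <- dplyr::filter(rows, !.data$position %in% gone)
        rows <- dplyr::bind_rows(
          rows,
          tibble::tibble(kind = "empty_alveolus", stage = NA_character_,
                         position = gone)
        )
      }
    }

    rows |>
      dplyr::arrange(.data$position, .data$kind != "functional") |>
      dplyr::mutate(
        specimen_id = sprintf("SIM-%d", config$seed),
        taxon = "simulated",
        element = "maxilla",
        side = "left",
        label = dplyr::case_when(
          kind == "functional" ~ paste0("M", position),
          kind == "replacement" ~ paste0("rM", position),
          TRUE ~ paste0("A", position)
        )
      ) |>
      dplyr::select("specimen_id", "taxon", "element", "side", "position",
                    "kind", "stage", "label")
  })
}

#' Parameter-recovery experiment for the Z-spacing estimator
#'
#' For each true Z-spacing on the grid, simulates `reps` quadrants with
#' independent sub-seeds and observation times drawn uniformly over one
#' cycle, runs the full segmentation + Z-spacing pipeline on each, and
#' aggregates the bias and root-mean-square error of the recovered mean
#' spacing. Replicates whose spacing is undetermined (fewer than two
#' Zahnreihen) are counted and excluded from the error summaries.
#'
#' @param z_grid Numeric vector of true Z-spacings (> 1).
#' @param n_positions Positions per simulated quadrant (default 16).
#' @param reps Replicates per grid value (>= 1).
#' @param noise_p Score-perturbation probability passed to the simulator.
#' @param seed Master seed; sub-seeds and observation times derive from it.
#' @param allow_gap Gap tolerance passed to [segment_zahnreihen()].
#' @return A tibble with one row per grid value: `z_true`, `mean_estimate`,
#'   `bias`, `rmse`, `n_determined`, `n_undetermined`.
#' @examples
#' run_recovery_experiment(c(2.0), reps = 5, seed = 7)
#' @export
run_recovery_experiment <- function(z_grid, n_positions = 16, reps = 50,
                                    noise_p = 0, seed = 1L, allow_gap = 1) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  draws <- withr::with_seed(seed, {
    tibble::tibble(
      sub_seed = sample.int(.Machine$integer.max, length(z_grid) * reps),
      t = stats::runif(length(z_grid) * reps)
    )
  })
  grid <- tidyr::expand_grid(z_true = z_grid, rep = seq_len(reps))
  grid$sub_seed <- draws$sub_seed
  grid$t <- draws$t
  est <- purrr::pmap_dbl(grid, function(z_true, rep, sub_seed, t) {
    cfg <- wave_config(n_positions = n_positions, z_true = z_true, t = t,
                       noise_p = noise_p, seed = sub_seed)
    quad <- simulate_quadrant(cfg)
    segments <- segment_zahnreihen(plot_points(quad), allow_gap = allow_gap)
    compute_z_spacing(segments)$mean_spacing
  })
  grid$estimate <- est
  grid |>
    dplyr::group_by(.data$z_true) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate, na.rm = TRUE),
      bias = mean(.data$estimate - .data$z_true, na.rm = TRUE),
      rmse = sqrt(mean((.data$estimate - .data$z_true)^2, na.rm = TRUE)),
      n_determined = sum(!is.na(.data$estimate)),
      n_undetermined = sum(is.na(.data$estimate)),
      .groups = "drop"
    )
}
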