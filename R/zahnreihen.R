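# Zahnreihen reconstruction and Z-spacing estimation.
#
# A Zahnreihe is a maximal caudally-descending maturity run: a series of
# plotted tooth points in which each more rostral tooth is more mature than
# the next caudal one. The perpendicular distance between successive runs,
# in tooth-position units, is the Z-spacing; it encodes the direction of the
# replacement wave sweeping along the jaw.

#' Segment Zahnreihen from plotted tooth points
#'
#' Greedy rostral-to-caudal run construction. Starting from the rostral-most
#' unassigned point, the run is extended caudally to the nearest position
#' holding an unassigned point with a strictly lower maturity score; where a
#' position holds both a functional and a replacement point, the functional
#' point is consumed first. Positions carrying no plotted point at all (empty
#' alveoli, unrecorded positions) may be skipped, at most `allow_gap` of them
#' per step; a position that carries any plotted point is never skipped.
#' Runs of at least two points become Zahnreihen, indexed rostral-to-caudal
#' by first position (runs truncated at the rostral jaw margin can share a
#' first position; the lower-scoring one belongs to the younger, more
#' rostral wave and is indexed first). Leftover single points are exceptions.
#'
#' @param points A data frame of plotted points with columns `position` and
#'   `score`, sorted by position (as produced by [plot_points()]). At most
#'   two points (one functional, one replacement) per position.
#' @param allow_gap Number of point-free positions a run may skip in a
#'   single step (default 1).
#' @return The points tibble with a `zahnreihe` column: the run index for
#'   members of a Zahnreihe, `NA` for exception points.
#' @examples
#' pts <- tibble::tibble(position = 1:4, score = c(7, 6, 5, 4))
#' segment_zahnreihen(pts)
#' @export
segment_zahnreihen <- function(points, allow_gap = 1) {
  pts <- tibble::as_tibble(points)
  if (nrow(pts) == 0) {
    return(dplyr::mutate(pts, zahnreihe = integer(0)))
  }
  if (!all(c("position", "score") %in% names(pts))) {
    stop("points must have columns position and score", call. = FALSE)
  }
  if (is.unsorted(pts$position)) {
    stop("points must be sorted by position (rostral to caudal)", call. = FALSE)
  }
  if (any(table(pts$position) > 2)) {
    stop("at most two plotted points (one functional, one replacement) per position",
         call. = FALSE)
  }
  # canonical order: position ascending, score descending (functional first)
  ord <- order(pts$position, -pts$score)
  pos <- pts$position[ord]
  sco <- pts$score[ord]
  n <- length(pos)
  run_of <- rep(NA_integer_, n)

  next_member <- function(i) {
    # nearest caudal position with an eligible point, skipping at most
    # allow_gap point-free positions; never skipping an occupied position
    q <- pos[i] + 1L
    gaps <- 0L
    pmax <- max(pos)
    while (q <= pmax) {
      here <- which(pos == q)
      if (length(here) > 0) {
        elig <- here[is.na(run_of[here]) & sco[here] < sco[i]]
        if (length(elig) > 0) {
          return(elig[which.max(sco[elig])]) # functional before replacement
        }
        return(NA_integer_) # occupied but nothing to take: run ends
      }
      gaps <- gaps + 1L
      if (gaps > allow_gap) return(NA_integer_)
      q <- q + 1L
    }
    NA_integer_
  }

  run_id <- 0L
  repeat {
    start <- which(is.na(run_of))
    if (length(start) == 0) break
    i <- start[1]
    run_id <- run_id + 1L
    run_of[i] <- run_id
    repeat {
      j <- next_member(i)
      if (is.na(j)) break
      run_of[j] <- run_id
      i <- j
    }
  }

  # demote singleton runs to exceptions, then index runs rostral->caudal by
  # (first position, first score) -- ascending score breaks rostral-margin ties
  sizes <- table(run_of)
  keep <- as.integer(names(sizes)[sizes >= 2])
  run_of[!run_of %in% keep] <- NA_integer_
  if (length(keep) > 0) {
    first_pos <- vapply(keep, function(r) min(pos[which(run_of == r)]), numeric(1))
    first_sco <- vapply(keep, function(r) {
      m <- which(run_of == r)
      sco[m[which.min(pos[m])]]
    }, numeric(1))
    ranked <- keep[order(first_pos, first_sco)]
    run_of <- match(run_of, ranked)
  }
  out <- pts[ord, , drop = FALSE]
  out$zahnreihe <- run_of
  out
}

# piecewise-linear position of a run at integer maturity levels; a run has
# strictly decreasing scores caudally, so position is a function of score
run_position_at <- function(run, levels) {
  ord <- order(run$score)
  stats::approx(x = run$score[ord], y = run$position[ord], xout = levels,
                method = "linear", ties = "ordered")$y
}

#' Compute Z-spacing between successive Zahnreihen
#'
#' For each adjacent pair of runs, the spacing is the mean positional offset
#' measured at every integer maturity level shared by both runs' score
#' ranges; within a run, the position at a level is obtained by exact match
#' or linear interpolation along the run. Spacings are in tooth-position
#' units and may be fractional. A pair whose score ranges do not overlap is
#' skipped and flagged (`NA` spacing); the overall mean is taken over the
#' measured pairs and is `NA` when fewer than two Zahnreihen exist.
#'
#' @param segments Output of [segment_zahnreihen()].
#' @return A list with `pair_spacings`, a tibble of
#'   `pair_index`/`spacing`/`midpoint_position`/`n_shared_levels` (one row
#'   per adjacent run pair, `midpoint_position` the mean midpoint of the
#'   matched positions), and `mean_spacing`.
#' @examples
#' pts <- tibble::tibble(position = 1:4, score = c(5, 4, 5, 4))
#' compute_z_spacing(segment_zahnreihen(pts))
#' @export
compute_z_spacing <- function(segments) {
  runs <- segments |>
    dplyr::filter(!is.na(.data$zahnreihe)) |>
    dplyr::group_by(.data$zahnreihe) |>
    dplyr::group_split()
  empty <- tibble::tibble(pair_index = integer(0), spacing = numeric(0),
                          midpoint_position = numeric(0),
                          n_shared_levels = integer(0))
  if (length(runs) < 2) {
    return(list(pair_spacings = empty, mean_spacing = NA_real_))
  }
  pairs <- purrr::map(seq_len(length(runs) - 1), function(k) {
    a <- runs[[k]]
    b <- runs[[k + 1]]
    levels <- seq(max(min(a$score), min(b$score)),
                  min(max(a$score), max(b$score)))
    if (length(levels) == 0 || levels[1] > levels[length(levels)]) {
      return(tibble::tibble(pair_index = k, spacing = NA_real_,
                            midpoint_position = NA_real_, n_shared_levels = 0L))
    }
    pa <- run_position_at(a, levels)
    pb <- run_position_at(b, levels)
    tibble::tibble(pair_index = k,
                   spacing = mean(pb - pa),
                   midpoint_position = mean((pa + pb) / 2),
                   n_shared_levels = length(levels))
  })
  pair_spacings <- dplyr::bind_rows(pairs)
  measured <- pair_spacings$spacing[!is.na(pair_spacings$spacing)]
  list(pair_spacings = pair_spacings,
       mean_spacing = if (length(measured) > 0) mean(measured) else NA_real_)
}

#' Classify the replacement-wave direction from the mean Z-spacing
#'
#' Replacement waves sweep rostral-to-caudal when the Z-spacing exceeds 2.0
#' tooth positions, caudal-to-rostral (reversed) when below 2.0, and the
#' dentition replaces in simple alternation between odd- and even-numbered
#' positions when the spacing is exactly 2.0. `eps` gives the half-width of
#' the band treated as "exactly 2.0" (default 0.05 position units).
#'
#' @param mean_spacing Numeric vector of mean Z-spacings (`NA` allowed).
#' @param eps Numeric tolerance around 2.0 for the alternation call.
#' @return Character vector: `"rostral_to_caudal"`, `"alternating"`,
#'   `"caudal_to_rostral"`, or `"undetermined"` for missing spacings.
#' @examples
#' classify_wave_direction(c(2.54, 2.0, 1.8, NA))
#' @export
classify_wave_direction <- function(mean_spacing, eps = 0.05) {
  if (any(!is.na(mean_spacing) & mean_spacing <= 0)) {
    stop("Z-spacing must be positive", call. = FALSE)
  }
  dplyr::case_when(
    is.na(mean_spacing) ~ "undetermined",
    abs(mean_spacing - 2.0) <= eps ~ "alternating",
    mean_spacing > 2.0 + eps ~ "rostral_to_caudal",
    TRUE ~ "caudal_to_rostral"
  )
}

#' Regional Z-spacing means
#'
#' Splits the per-pair spacings into rostral and caudal halves of the tooth
#' row (a pair is rostral when its midpoint position lies at or before
#' `row_length / 2`) and averages each region.
#'
#' @param pair_spacings Pair table from [compute_z_spacing()].
#' @param row_length Total number of tooth positions in the row; must be at
#'   least the largest position among the measured pairs.
#' @return A tibble with columns `rostral_mean` and `caudal_mean` (`NA` when
#'   a region holds no measured pair).
#' @export
regional_z_spacing <- function(pair_spacings, row_length) {
  measured <- dplyr::filter(pair_spacings, !is.na(.data$spacing))
  if (nrow(measured) > 0 && row_length < max(measured$midpoint_position)) {
    stop("row_length is smaller than the largest pair midpoint position",
         call. = FALSE)
  }
  rostral <- measured$spacing[measured$midpoint_position <= row_length / 2]
  caudal <- measured$spacing[measured$midpoint_position > row_length / 2]
  tibble::tibble(
    rostral_mean = if (length(rostral) > 0) mean(rostral) else NA_real_,
    caudal_mean = if (length(caudal) > 0) mean(caudal) else NA_real_
  )
}

#' Pool Z-spacing measurements
#'
#' The Z-spacing of a taxon or jaw element is summarised by the arithmetic
#' mean of all its per-pair measurements, pooled across quadrants.
#'
#' @param spacings Numeric vector of Z-spacing measurements.
#' @return The pooled mean (`NA` if no measurements).
#' @examples
#' pool_z_spacing(c(2.0, 3.33))
#' @export
pool_z_spacing <- function(spacings) {
  s <- spacings[!is.na(spacings)]
  if (length(s) == 0) return(NA_real_)
  mean(s)
}

#' Round half away from zero
#'
#' Decimal rounding in which ties go up (0.005 -> 0.01), matching how
#' summary Z-spacings are conventionally reported, unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.665, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Analyse one jaw quadrant
#'
#' The full Zahnreihen pipeline for a single quadrant: plot the staged teeth
#' as (position, maturity score) points, segment them into Zahnreihen,
#' measure per-pair and mean Z-spacing, split spacings into rostral and
#' caudal regions, and classify the replacement-wave direction.
#'
#' @param quadrant A dentition table holding one staged quadrant.
#' @param eps Tolerance around a spacing of 2.0 for the alternation call.
#' @param allow_gap Gap tolerance for run construction
#'   (see [segment_zahnreihen()]).
#' @param row_length Number of positions in the tooth row; defaults to the
#'   largest recorded position (empty alveoli included).
#' @return An object of class `zspacing_report`: a list with `specimen_id`,
#'   `element`, `side`, `points` (the segmented point table), `pair_spacings`,
#'   `mean_spacing`, `rostral_mean`, `caudal_mean`, `direction`, `row_length`,
#'   `eps` and `allow_gap`. Use [generics::tidy()] for the pair table,
#'   [generics::glance()] for a one-row summary, and
#'   [ggplot2::autoplot()] for the Zahnreihen graph.
#' @examples
#' rep <- analyze_quadrant(load_fixture("v18638_right_maxilla_stages"))
#' glance(rep)
#' @export
analyze_quadrant <- function(quadrant, eps = 0.05, allow_gap = 1,
                             row_length = NULL) {
  x <- validate_dentition(quadrant)
  pts <- plot_points(x)
  if (is.null(row_length)) {
    row_length <- if (nrow(x) > 0) max(x$position) else 0L
  }
  segments <- segment_zahnreihen(pts, allow_gap = allow_gap)
  zs <- compute_z_spacing(segments)
  regional <- regional_z_spacing(zs$pair_spacings, row_length)
  structure(
    list(
      specimen_id = if (nrow(x) > 0) x$specimen_id[1] else NA_character_,
      element = if (nrow(x) > 0) x$element[1] else NA_character_,
      side = if (nrow(x) > 0) x$side[1] else NA_character_,
      points = segments,
      pair_spacings = zs$pair_spacings,
      mean_spacing = zs$mean_spacing,
      rostral_mean = regional$rostral_mean,
      caudal_mean = regional$caudal_mean,
      direction = classify_wave_direction(zs$mean_spacing, eps = eps),
      row_length = row_length,
      eps = eps,
      allow_gap = allow_gap
    ),
    class = "zspacing_report"
  )
}

#' @export
print.zspacing_report <- function(x, ...) {
  n_runs <- dplyr::n_distinct(x$points$zahnreihe, na.rm = TRUE)
  n_exc <- sum(is.na(x$points$zahnreihe))
  cat("Z-spacing report:", x$specimen_id, x$element, x$side, "\n")
  cat("  Zahnreihen:", n_runs, " exceptions:", n_exc, "\n")
  cat("  mean Z-spacing:",
      if (is.na(x$mean_spacing)) "undetermined" else round_half_up(x$mean_spacing, 2),
      " direction:", x$direction, "\n")
  if (!is.na(x$rostral_mean) || !is.na(x$caudal_mean)) {
    cat("  rostral mean:", round_half_up(x$rostral_mean, 2),
        " caudal mean:", round_half_up(x$caudal_mean, 2), "\n")
  }
  invisible(x)
}

#' Tidy a Z-spacing report
#'
#' @param x A `zspacing_report`.
#' @param ... Unused.
#' @return `tidy()` returns the per-pair spacing tibble; `glance()` returns a
#'   one-row summary (counts, mean and regional spacings, direction).
#' @method tidy zspacing_report
#' @export
tidy.zspacing_report <- function(x, ...) {
  x$pair_spacings
}

#' @rdname tidy.zspacing_report
#' @method glance zspacing_report
#' @export
glance.zspacing_report <- function(x, ...) {
  tibble::tibble(
    specimen_id = x$specimen_id,
    element = x$element,
    side = x$side,
    n_points = nrow(x$points),
    n_zahnreihen = dplyr::n_distinct(x$points$zahnreihe, na.rm = TRUE),
    n_exceptions = sum(is.na(x$points$zahnreihe)),
    n_pairs_measured = sum(!is.na(x$pair_spacings$spacing)),
    n_pairs_skipped = sum(is.na(x$pair_spacings$spacing)),
    mean_spacing = x$mean_spacing,
    rostral_mean = x$rostral_mean,
    caudal_mean = x$caudal_mean,
    direction = x$direction
  )
}
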