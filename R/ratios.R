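# Replacement-to-functional tooth ratios and their change through ontogeny.
# The ratio RT/FT indexes the standing crop of developing successor teeth;
# within a taxon, a falling ratio across a growth series suggests a slowing
# tooth replacement rate with age.

#' Replacement-to-functional tooth ratio per quadrant
#'
#' Counts functional and replacement records in each jaw quadrant of the
#' table and forms the ratio of replacement to functional teeth. Empty
#' alveoli and remnants are never counted as teeth.
#'
#' @param dentition A dentition table (one or many quadrants).
#' @return A tibble with one row per quadrant: `specimen_id`, `taxon`,
#'   `element`, `side`, `n_functional`, `n_replacement`, `ratio`.
#' @examples
#' replacement_ratio(load_fixture("v18638_right_maxilla_stages"))
#' @export
replacement_ratio <- function(dentition) {
  x <- validate_dentition(dentition)
  out <- x |>
    dplyr::group_by(.data$specimen_id, .data$taxon, .data$element, .data$side) |>
    dplyr::summarise(
      n_functional = sum(.data$kind == "functional"),
      n_replacement = sum(.data$kind == "replacement"),
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = .data$n_replacement / .data$n_functional)
  no_ft <- out$n_functional == 0
  if (any(no_ft)) {
    bad <- out[no_ft, ]
    stop("replacement ratio undefined: no functional teeth in quadrant(s) ",
         paste(paste(bad$specimen_id, bad$element, bad$side, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  out
}

#' Ontogenetic series of replacement ratios
#'
#' Orders specimens by skull length and tabulates functional and replacement
#' tooth counts and their ratio for one jaw element, to expose ontogenetic
#' trends in the replacement rate. Sides are pooled by default (counts
#' summed across left and right before forming the ratio); `per_side`
#' keeps each side as its own row for symmetry checks.
#'
#' @param dentition A dentition table covering two or more specimens; a
#'   `skull_length_cm` column supplies the size ordering (rows missing it
#'   are retained, sorted last, and excluded from the trend flag).
#' @param element Jaw element to tabulate (default `"maxilla"`).
#' @param side_policy `"pool_sides"` (default) or `"per_side"`.
#' @return A tibble sorted by ascending skull length with columns
#'   `specimen_id`, `skull_length_cm`, (`side` under `per_side`),
#'   `n_functional`, `n_replacement`, `ratio`, and an attribute
#'   `ratio_non_increasing`: `TRUE`/`FALSE` whether the ratio never rises
#'   with size (ties allowed), or `NA` when fewer than two sized specimens
#'   are available. Read it with [ratio_non_increasing()].
#' @examples
#' series <- ontogenetic_series(load_fixture("yinlong_ontogeny"))
#' ratio_non_increasing(series)
#' @export
ontogenetic_series <- function(dentition, element = "maxilla",
                               side_policy = c("pool_sides", "per_side")) {
  side_policy <- match.arg(side_policy)
  x <- validate_dentition(dentition)
  if (!"skull_length_cm" %in% names(x)) {
    x$skull_length_cm <- NA_real_
  }
  x <- dplyr::filter(x, .data$element == !!element)
  if (nrow(x) == 0) {
    stop("no records for element '", element, "'", call. = FALSE)
  }
  keys <- if (side_policy == "per_side") c("specimen_id", "side") else "specimen_id"
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      skull_length_cm = .data$skull_length_cm[1],
      n_functional = sum(.data$kind == "functional"),
      n_replacement = sum(.data$kind == "replacement"),
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = .data$n_replacement / .data$n_functional) |>
    dplyr::arrange(.data$skull_length_cm) # NA skull lengths sort last
  sized <- dplyr::filter(out, !is.na(.data$skull_length_cm))
  flag <- if (nrow(sized) < 2) {
    NA
  } else {
    all(diff(sized$ratio) <= 0)
  }
  attr(out, "ratio_non_increasing") <- flag
  out
}

#' @rdname ontogenetic_series
#' @param series A tibble returned by [ontogenetic_series()].
#' @export
ratio_non_increasing <- function(series) {
  attr(series, "ratio_non_increasing")
}
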