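# Ordinal staging schemes for functional and replacement teeth, and the
# unified maturity ladder used as the y-axis of Zahnreihen graphs.

#' Stage vocabularies
#'
#' Ordered level sets used throughout the package. Replacement stages R1-R3
#' describe unerupted successor teeth (R1 an incipient crown tip, R2 a fully
#' formed crown, R3 a crown reaching the base of the functional crown).
#' Functional stages F1-F4 describe erupted teeth of increasing wear and
#' pulp-cavity closure. The unified maturity ladder places replacement stages
#' below functional stages (a developing successor is always younger than any
#' erupted tooth), giving the seven-step ordinal scale R1 < R2 < R3 < F1 <
#' F2 < F3 < F4 scored 1..7.
#'
#' @format Character vectors of ordered stage labels.
#' @name stage_levels
NULL

#' @rdname stage_levels
#' @export
replacement_stages <- c("R1", "R2", "R3")

#' @rdname stage_levels
#' @export
functional_stages <- c("F1", "F2", "F3", "F4")

#' @rdname stage_levels
#' @export
maturity_ladder <- c(replacement_stages, functional_stages)

# ordered feature vocabularies (index = severity rank)
wear_levels <- c("none_or_slight", "worn", "extensive", "polished")
facet_levels <- c("flat", "slightly_concave", "concave", "highly_concave")
pulp_levels <- c("open_at_tip", "large", "reduced", "broken")
tooth_kinds <- c("functional", "replacement", "empty_alveolus", "remnant")

#' Map stage labels to maturity scores and back
#'
#' `maturity_score()` converts stage labels (`"R1"`..`"R3"`, `"F1"`..`"F4"`)
#' to the unified 1..7 maturity ladder; `score_to_stage()` inverts it. The
#' mapping is the strictly increasing bijection R1=1, R2=2, R3=3, F1=4,
#' F2=5, F3=6, F4=7.
#'
#' @param stage Character vector of stage labels.
#' @param score Integer vector of scores in 1..7.
#' @return An integer vector of scores, or a character vector of stages.
#' @examples
#' maturity_score(c("R1", "F1", "F4"))
#' score_to_stage(1:7)
#' @export
maturity_score <- function(stage) {
  idx <- match(stage, maturity_ladder)
  bad <- is.na(idx) & !is.na(stage)
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(stage[bad]), collapse = ", "),
         " (empty alveoli and remnants carry no stage and no maturity score)",
         call. = FALSE)
  }
  if (anyNA(stage)) {
    stop("missing stage: only staged functional/replacement teeth have a maturity score",
         call. = FALSE)
  }
  idx
}

#' @rdname maturity_score
#' @export
score_to_stage <- function(score) {
  if (any(is.na(score) | score < 1L | score > 7L | score != as.integer(score))) {
    stop("maturity scores must be integers in 1..7", call. = FALSE)
  }
  maturity_ladder[as.integer(score)]
}

#' Stage functional teeth from wear and pulp-cavity features
#'
#' Assigns each functional tooth the highest wear stage whose defining
#' criteria are met:
#'
#' * **F1** - no or slight wear on the marginal denticles, open pulp cavity.
#' * **F2** - worn marginal denticles and an at least slightly concave
#'   lingual wear facet.
#' * **F3** - extensive wear, a concave lingual facet, and either a
#'   resorption depression on the root or a replacement-tooth bud.
#' * **F4** - polished, greatly worn denticles, a highly concave facet, and
#'   either a broken pulp cavity or an emerged replacement tooth.
#'
#' The stage definitions are conjunctive descriptions, so staging proceeds by
#' testing each stage's criteria with ordinal thresholds (worsening a wear or
#' facet field can never lower the assigned stage) and keeping the highest
#' match. Contradictory combinations -- heavy wear (extensive or polished
#' denticles) on a tooth whose pulp cavity is still open at the tip, the
#' signature of a newly erupted crown -- raise a staging-conflict error that
#' names the clashing fields and rows.
#'
#' @param features A data frame with one row per functional tooth and columns
#'   `denticle_wear` (`"none_or_slight"`, `"worn"`, `"extensive"`,
#'   `"polished"`), `lingual_facet` (`"flat"`, `"slightly_concave"`,
#'   `"concave"`, `"highly_concave"`), `pulp_cavity` (`"open_at_tip"`,
#'   `"large"`, `"reduced"`, `"broken"`), and logicals
#'   `root_resorption_depression`, `replacement_bud_present`,
#'   `replacement_emerged`. All fields must be present and non-missing;
#'   unknown states must be handled upstream, never defaulted silently.
#' @return The input as a tibble with a `functional_stage` column added.
#' @examples
#' stage_functional_teeth(tibble::tibble(
#'   denticle_wear = c("none_or_slight", "worn"),
#'   lingual_facet = c("flat", "slightly_concave"),
#'   pulp_cavity = c("open_at_tip", "large"),
#'   root_resorption_depression = FALSE,
#'   replacement_bud_present = FALSE,
#'   replacement_emerged = FALSE
#' ))
#' @export
stage_functional_teeth <- function(features) {
  needed <- c("denticle_wear", "lingual_facet", "pulp_cavity",
              "root_resorption_depression", "replacement_bud_present",
              "replacement_emerged")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  features <- tibble::as_tibble(features)
  if (nrow(features) == 0) {
    return(dplyr::mutate(features, functional_stage = character(0)))
  }
  wear <- match(features$denticle_wear, wear_levels)
  facet <- match(features$lingual_facet, facet_levels)
  pulp <- match(features$pulp_cavity, pulp_levels)
  flags <- features[c("root_resorption_depression", "replacement_bud_present",
                      "replacement_emerged")]
  if (!all(purrr::map_lgl(flags, is.logical))) {
    stop("replacement/resorption flags must be logical (TRUE/FALSE)", call. = FALSE)
  }
  bad_level <- is.na(wear) | is.na(facet) | is.na(pulp)
  bad_flag <- purrr::reduce(purrr::map(flags, is.na), `|`)
  if (any(bad_level | bad_flag)) {
    stop("incomplete or unrecognised feature values in row(s): ",
         paste(which(bad_level | bad_flag), collapse = ", "),
         " (all six feature fields are required; mark unknowns explicitly upstream)",
         call. = FALSE)
  }

  # contradiction: an open pulp cavity marks a newly erupted crown and cannot
  # co-occur with extensive or polished wear
  conflict <- pulp == 1L & wear >= 3L
  if (any(conflict)) {
    stop("staging conflict in row(s) ", paste(which(conflict), collapse = ", "),
         ": denticle_wear = ",
         paste(unique(features$denticle_wear[conflict]), collapse = "/"),
         " clashes with pulp_cavity = open_at_tip",
         call. = FALSE)
  }

  meets_f2 <- wear >= 2L & facet >= 2L
  meets_f3 <- wear >= 3L & facet >= 3L &
    (features$root_resorption_depression | features$replacement_bud_present |
       features$replacement_emerged)
  meets_f4 <- wear >= 4L & facet >= 4L &
    (features$pulp_cavity == "broken" | features$replacement_emerged)
  stage <- dplyr::case_when(
    meets_f4 ~ "F4",
    meets_f3 ~ "F3",
    meets_f2 ~ "F2",
    TRUE ~ "F1"
  )
  dplyr::mutate(features, functional_stage = stage)
}

#' Stage replacement teeth from crown development
#'
#' Maps the developmental state of an unerupted successor tooth onto the
#' three-step replacement ladder: a small incipient tooth showing only the
#' tip of its crown is R1; a fully formed crown is R2; a crown reaching the
#' base of the functional crown is R3.
#'
#' @param descriptor Character vector with values `"tip_of_crown_only"`,
#'   `"crown_complete"`, or `"crown_at_functional_crown_base"`.
#' @return Character vector of replacement stages (`"R1"`, `"R2"`, `"R3"`).
#' @examples
#' stage_replacement(c("tip_of_crown_only", "crown_at_functional_crown_base"))
#' @export
stage_replacement <- function(descriptor) {
  map <- c(tip_of_crown_only = "R1",
           crown_complete = "R2",
           crown_at_functional_crown_base = "R3")
  out <- unname(map[descriptor])
  if (anyNA(out)) {
    bad <- unique(descriptor[is.na(out)])
    stop("unknown crown-development descriptor(s): ",
         paste(bad, collapse = ", "), "; expected one of ",
         paste(names(map), collapse = ", "), call. = FALSE)
  }
  out
}
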