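# The dentition table: one row per tooth record (functional tooth,
# replacement tooth, empty alveolus, or resorbed-tooth remnant) at a jaw
# position. A jaw quadrant (specimen x element x side) is the unit of
# Zahnreihen analysis.

dentition_required_cols <- c("specimen_id", "taxon", "element", "side",
                             "position", "kind", "stage", "label")
jaw_elements <- c("premaxilla", "maxilla", "dentary")
jaw_sides <- c("left", "right")

#' Validate a dentition table
#'
#' Checks the per-tooth observational table against the structural rules of
#' the data model and reports every violation with its row number:
#'
#' * required columns present (`specimen_id`, `taxon`, `element`, `side`,
#'   `position`, `kind`, `stage`, `label`);
#' * `element` in premaxilla/maxilla/dentary, `side` in left/right,
#'   `kind` in functional/replacement/empty_alveolus/remnant;
#' * `position` a positive integer;
#' * stage tokens consistent with kind: functional teeth carry F-stages (or
#'   `NA` in count-only tables), replacement teeth carry R-stages (or `NA`),
#'   empty alveoli and remnants carry no stage;
#' * within a quadrant, at most one functional and at most one replacement
#'   record per position (the taxa modelled here have at most one
#'   replacement tooth per alveolus; tables with second-generation
#'   replacement teeth may add a `generation` column, and the one-per-position
#'   rule is then applied within each generation).
#'
#' @param dentition A data frame of per-tooth records.
#' @return The validated table as a tibble (invisibly unchanged), or an error
#'   listing every offending row.
#' @export
validate_dentition <- function(dentition) {
  missing_cols <- setdiff(dentition_required_cols, names(dentition))
  if (length(missing_cols) > 0) {
    stop("dentition table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(dentition)
  problems <- character(0)
  row_problem <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems,
                     paste0("row(s) ", paste(rows, collapse = ", "), ": ", msg))
    }
  }

  row_problem(which(!x$element %in% jaw_elements),
              "element must be premaxilla, maxilla or dentary")
  row_problem(which(!x$side %in% jaw_sides), "side must be left or right")
  row_problem(which(!x$kind %in% tooth_kinds),
              "kind must be functional, replacement, empty_alveolus or remnant")
  pos_ok <- !is.na(x$position) & x$position >= 1 & x$position == as.integer(x$position)
  row_problem(which(!pos_ok), "position must be a positive integer")

  staged <- !is.na(x$stage)
  row_problem(which(staged & !x$stage %in% maturity_ladder),
              "stage must be one of F1-F4, R1-R3 or NA")
  row_problem(which(x$kind == "functional" & staged & !x$stage %in% functional_stages),
              "functional teeth cannot carry a replacement stage")
  row_problem(which(x$kind == "replacement" & staged & !x$stage %in% replacement_stages),
              "replacement teeth cannot carry a functional stage")
  row_problem(which(x$kind %in% c("empty_alveolus", "remnant") & staged),
              "empty alveoli and remnants carry no stage")

  # per-quadrant positional rules
  gen <- if ("generation" %in% names(x)) x$generation else rep(1L, nrow(x))
  key <- paste(x$specimen_id, x$element, x$side, x$position, x$kind, gen, sep = "\r")
  countable <- x$kind %in% c("functional", "replacement")
  dup <- countable & duplicated(key) | countable & duplicated(key, fromLast = TRUE)
  first_dup <- which(dup & duplicated(key))
  row_problem(first_dup,
              "at most one functional and one replacement record per position in a quadrant")

  if (length(problems) > 0) {
    stop("invalid dentition table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(x)
}

#' Extract the plotted points of a Zahnreihen graph
#'
#' Converts the staged records of one jaw quadrant into the (position,
#' maturity score) points of a Zahnreihen graph. Functional and replacement
#' teeth with a stage each contribute one point, so a position undergoing
#' replacement contributes two points (its worn functional tooth high on the
#' ladder and its developing successor low). Empty alveoli, remnants and
#' unstaged records contribute no point.
#'
#' @param quadrant A dentition table holding a single quadrant (one
#'   specimen/element/side combination).
#' @return A tibble with columns `position`, `score` (1..7), `stage`,
#'   `kind`, and `label`, sorted by position with the functional point first
#'   at shared positions.
#' @examples
#' q <- load_fixture("v18638_right_maxilla_stages")
#' plot_points(q)
#' @export
plot_points <- function(quadrant) {
  x <- validate_dentition(quadrant)
  quad_id <- unique(paste(x$specimen_id, x$element, x$side, sep = "/"))
  if (length(quad_id) > 1) {
    stop("plot_points() expects a single quadrant; got: ",
         paste(quad_id, collapse = "; "),
         ". Split the table by specimen_id/element/side first.", call. = FALSE)
  }
  x |>
    dplyr::filter(.data$kind %in% c("functional", "replacement"), !is.na(.data$stage)) |>
    dplyr::mutate(score = maturity_score(.data$stage)) |>
    dplyr::select("position", "score", "stage", "kind", "label") |>
    dplyr::arrange(.data$position, dplyr::desc(.data$score))
}

# split a multi-quadrant table into a named list of quadrant tibbles
split_quadrants <- function(dentition) {
  x <- validate_dentition(dentition)
  key <- paste(x$specimen_id, x$element, x$side, sep = "/")
  split(x, factor(key, levels = unique(key)))
}
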