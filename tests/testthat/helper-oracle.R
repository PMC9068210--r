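# Shared test helpers: an exhaustive minimum-chain-cover oracle for the
# greedy segmentation, a random plotted-point generator, and a feature-row
# constructor for the staging tests.

# Exhaustive minimum run cover: the smallest number of caudally-descending
# chains that covers every plotted point, where consecutive chain members
# may only skip point-free positions (at most allow_gap of them per step).
# Branch-and-bound over all assignments; independent of the greedy code.
min_chain_cover <- function(pos, sco, allow_gap = 1) {
  ord <- order(pos, -sco)
  pos <- pos[ord]
  sco <- sco[ord]
  n <- length(pos)
  if (n == 0) {
    return(0L)
  }
  can_follow <- function(i, j) {
    if (pos[j] <= pos[i] || sco[j] >= sco[i]) {
      return(FALSE)
    }
    if (pos[j] - pos[i] - 1L > allow_gap) {
      return(FALSE)
    }
    between <- seq(pos[i] + 1L, length.out = pos[j] - pos[i] - 1L)
    !any(between %in% pos)
  }
  best <- Inf
  rec <- function(k, tails) {
    if (length(tails) >= best) {
      return(invisible())
    }
    if (k > n) {
      best <<- length(tails)
      return(invisible())
    }
    for (ti in seq_along(tails)) {
      if (can_follow(tails[ti], k)) {
        old <- tails[ti]
        tails[ti] <- k
        rec(k + 1L, tails)
        tails[ti] <- old
      }
    }
    rec(k + 1L, c(tails, k))
  }
  rec(1L, integer(0))
  as.integer(best)
}

# Random quadrant-like plotted points: per position an optional functional
# point (score 4..7), an optional replacement point (score 1..3), or no
# point at all. Caller controls the RNG state.
random_points <- function(n_positions, p_empty = 0.2, p_replacement = 0.4) {
  rows <- list()
  for (p in seq_len(n_positions)) {
    if (stats::runif(1) < p_empty) next
    rows[[length(rows) + 1]] <- c(p, sample(4:7, 1))
    if (stats::runif(1) < p_replacement) {
      rows[[length(rows) + 1]] <- c(p, sample(1:3, 1))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(position = integer(0), score = integer(0)))
  }
  m <- do.call(rbind, rows)
  pts <- tibble::tibble(position = as.integer(m[, 1]), score = as.integer(m[, 2]))
  pts[order(pts$position, -pts$score), ]
}

greedy_counts <- function(segments) {
  list(
    runs = dplyr::n_distinct(segments$zahnreihe, na.rm = TRUE),
    exceptions = sum(is.na(segments$zahnreihe)),
    total = dplyr::n_distinct(segments$zahnreihe, na.rm = TRUE) +
      sum(is.na(segments$zahnreihe))
  )
}

feature_row <- function(wear, facet, pulp, depression = FALSE, bud = FALSE,
                        emerged = FALSE) {
  tibble::tibble(
    denticle_wear = wear,
    lingual_facet = facet,
    pulp_cavity = pulp,
    root_resorption_depression = depression,
    replacement_bud_present = bud,
    replacement_emerged = emerged
  )
}

# the stage-defining feature vectors of the four functional wear stages
stage_defining_features <- function() {
  dplyr::bind_rows(
    feature_row("none_or_slight", "flat", "open_at_tip"),
    feature_row("worn", "slightly_concave", "large"),
    feature_row("extensive", "concave", "reduced", depression = TRUE),
    feature_row("polished", "highly_concave", "broken", emerged = TRUE)
  )
}
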