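test_that("functional staging reproduces the defining criteria of each stage", {
  staged <- stage_functional_teeth(stage_defining_features())
  expect_equal(staged$functional_stage, c("F1", "F2", "F3", "F4"))

  # F4 via the broken-pulp route, without an emerged replacement tooth
  f4_pulp <- stage_functional_teeth(
    feature_row("polished", "highly_concave", "broken")
  )
  expect_equal(f4_pulp$functional_stage, "F4")

  # heavy wear without the F3/F4 co-criteria stays at F2
  f2_cap <- stage_functional_teeth(
    feature_row("extensive", "concave", "reduced")
  )
  expect_equal(f2_cap$functional_stage, "F2")
})

test_that("functional staging is monotone in wear and facet severity", {
  wear_levels <- c("none_or_slight", "worn", "extensive", "polished")
  facet_levels <- c("flat", "slightly_concave", "concave", "highly_concave")
  set.seed(421)
  for (k in 1:60) {
    base <- feature_row(
      wear = sample(wear_levels[1:3], 1),
      facet = sample(facet_levels[1:3], 1),
      pulp = sample(c("large", "reduced", "broken"), 1),
      depression = sample(c(TRUE, FALSE), 1),
      bud = sample(c(TRUE, FALSE), 1),
      emerged = sample(c(TRUE, FALSE), 1)
    )
    s0 <- match(stage_functional_teeth(base)$functional_stage, functional_stages)
    worse_wear <- dplyr::mutate(
      base, denticle_wear = wear_levels[match(denticle_wear, wear_levels) + 1]
    )
    worse_facet <- dplyr::mutate(
      base, lingual_facet = facet_levels[match(lingual_facet, facet_levels) + 1]
    )
    expect_gte(match(stage_functional_teeth(worse_wear)$functional_stage,
                     functional_stages), s0)
    expect_gte(match(stage_functional_teeth(worse_facet)$functional_stage,
                     functional_stages), s0)
  }
})

test_that("contradictory feature combinations raise a staging conflict", {
  expect_error(
    stage_functional_teeth(
      feature_row("polished", "highly_concave", "open_at_tip", emerged = TRUE)
    ),
    "staging conflict.*polished.*open_at_tip"
  )
  expect_error(
    stage_functional_teeth(dplyr::mutate(stage_defining_features(),
                                         pulp_cavity = NA_character_)),
    "incomplete or unrecognised"
  )
  expect_error(
    stage_functional_teeth(feature_row("worn", "flat", "large")["denticle_wear"]),
    "missing column"
  )
})

test_that("replacement staging maps crown development onto R1-R3", {
  expect_equal(
    stage_replacement(c("tip_of_crown_only", "crown_complete",
                        "crown_at_functional_crown_base")),
    c("R1", "R2", "R3")
  )
  expect_error(stage_replacement("half_grown"), "unknown crown-development")
})

test_that("the maturity ladder is a strictly increasing bijection on 1..7", {
  scores <- maturity_score(maturity_ladder)
  expect_equal(scores, 1:7)
  expect_equal(score_to_stage(scores), maturity_ladder)
  expect_equal(maturity_score(c("R1", "F1", "F4")), c(1L, 4L, 7L))
  # replacement stages always score below functional stages
  expect_true(max(maturity_score(replacement_stages)) <
                min(maturity_score(functional_stages)))
  expect_error(maturity_score("A3"), "unknown stage")
  expect_error(maturity_score(NA_character_), "missing stage")
})

test_that("staging a stage's defining feature vector returns that stage", {
  # functional ladder round trip
  expect_equal(stage_functional_teeth(stage_defining_features())$functional_stage,
               functional_stages)
  # replacement ladder round trip
  descriptors <- c("tip_of_crown_only", "crown_complete",
                   "crown_at_functional_crown_base")
  expect_equal(stage_replacement(descriptors), replacement_stages)
})
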