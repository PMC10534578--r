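test_that("instrument definition reproduces the printed scoring grid", {
  expect_length(instr$variables, 10)
  w <- vapply(instr$variables, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 10)
  expect_equal(unname(w[c("mental_status", "movement", "mood")]),
               c(1.6, 1.3, 1.4))
  # every ranking value is weight x level, to one decimal place
  for (v in instr$variables) {
    expect_equal(v$modalities$ranking_value,
                 round(v$weight * v$modalities$level, 1))
    expect_true(all(diff(v$modalities$ranking_value) > 0))
    # scale identity: ranking / weight recovers an integer level in 1..7
    lv <- v$modalities$ranking_value / v$weight
    expect_equal(lv, round(lv), tolerance = 1e-9)
    expect_true(all(round(lv) %in% 1:7))
  }
  # movement/ambulation ships exactly the 6 printed modalities
  expect_equal(instr$variables$movement$modalities$level, c(1:5, 7L))
  ms <- vapply(instr$variables, `[[`, logical(1), "multi_select")
  expect_setequal(names(ms)[ms],
                  c("circulation", "elimination", "feeding", "sensory"))
})

test_that("ASGO scoring matches the sum-of-ranking-values rule", {
  floor_res <- score_asgo(asgo_assessment(uniform_selections(1L)))
  expect_identical(floor_res$raw_score, 10)
  expect_identical(floor_res$fd_index, 1)
  # highest printed modality everywhere (single selections)
  top <- lapply(instr$variables, function(v) max(v$modalities$level))
  expect_equal(score_asgo(asgo_assessment(top))$raw_score, 70)
  # baseline with feeding raised to spoon-fed
  sel <- uniform_selections(); sel$feeding <- 7L
  expect_equal(score_asgo(asgo_assessment(sel))$raw_score, 13.6)
  # multi-select circulation {1, 7} contributes 0.4 + 2.8
  sel <- uniform_selections(); sel$circulation <- c(1L, 7L)
  res <- score_asgo(asgo_assessment(sel))
  expect_equal(unname(res$per_variable["circulation"]), 3.2)
  expect_equal(res$raw_score, 10 - 0.4 + 3.2)
  # max combination rule keeps only the largest selected value
  res_max <- score_asgo(asgo_assessment(sel), combine = "max")
  expect_equal(unname(res_max$per_variable["circulation"]), 2.8)
})

test_that("raising any single variable's level strictly increases the score", {
  base <- score_asgo(asgo_assessment(uniform_selections(1L)))$raw_score
  for (nm in names(instr$variables)) {
    levels <- instr$variables[[nm]]$modalities$level
    prev <- base
    for (lv in levels[-1]) {
      sel <- uniform_selections(1L); sel[[nm]] <- lv
      cur <- score_asgo(asgo_assessment(sel))$raw_score
      expect_gt(cur, prev)
      prev <- cur
    }
  }
})

test_that("assessment validation names the offending variable", {
  sel <- uniform_selections()
  expect_error(asgo_assessment(sel[-3]), "circulation")
  bad <- sel; bad$mood <- c(1L, 2L)
  expect_error(asgo_assessment(bad), "mood.*single-select")
  bad <- sel; bad$movement <- 6L  # level 6 is not a printed modality
  expect_error(asgo_assessment(bad), "movement.*unknown level")
})

test_that("care-profile bands are left-closed and exhaustive above 1", {
  expect_equal(profile_category(c(1.0, 2.0, 2.59)), rep("minimum", 3))
  expect_equal(profile_category(c(2.6, 3.0, 3.69)), rep("medium", 3))
  expect_equal(profile_category(c(3.7, 4.79)), rep("high", 2))
  expect_equal(profile_category(c(4.8, 7.0)), rep("maximum", 2))
  expect_error(profile_category(0.99), ">= 1")
})

test_that("Barthel scoring, permutation invariance and the 60 cut-off", {
  items <- barthel_items()
  expect_equal(score_barthel(barthel_assessment(vapply(items, max, 0))), 100L)
  expect_equal(score_barthel(barthel_assessment(vapply(items, min, 0))), 0L)
  one <- vapply(items, min, 0); one["bathing"] <- 5
  expect_equal(score_barthel(barthel_assessment(one)), 5L)
  # total invariant under item permutation of the input
  shuffled <- sample(one)
  expect_equal(score_barthel(barthel_assessment(shuffled)), 5L)
  expect_error(barthel_assessment(replace(one, "walking", 7)),
               "walking.*allowed set")
  # dichotomization: single jump at 60
  st <- dichotomize_barthel(c(0, 59, 60, 100))
  expect_equal(unclass(st)[1:4],
               c("dependence", "dependence", "independence", "independence"),
               ignore_attr = TRUE)
  expect_error(dichotomize_barthel(101), "0, 100")
})

test_that("ASGO dependence classification puts ties at the cut-off on the dependent side", {
  st <- classify_asgo(c(10, 22.4, 22.5, 30), cutoff = 22.5)
  expect_equal(unclass(st)[1:4],
               c("independence", "independence", "dependence", "dependence"),
               ignore_attr = TRUE)
  expect_equal(attr(st, "cutoff"), 22.5)
})
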