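test_that("candidate space excludes boundary, spontaneous, diffusion and orphan reactions", {
  tm <- generate_toy_model(toy_model_spec(1, c(2), 2, seed = 41))
  cand <- candidate_space(tm$model)
  rx <- tm$model$reactions
  expect_true(all(cand %in% rx$reaction_id[rx$reaction_class == "internal"]))
  expect_false(any(startsWith(cand, "EX_")))
  expect_false(any(startsWith(cand, "DM_")))
  expect_false("GLCt" %in% cand)      # spontaneous (s0001)
  expect_false("O2t" %in% cand)       # diffusion-flagged
  expect_false("BIOMASS_toy" %in% cand)  # no GPR
  expect_setequal(cand, c("ESS1", "GRP1_B1", "GRP1_B2", "DCY1", "DCY2"))
})

test_that("DFS enumeration equals the brute-force oracle on seeded fixtures", {
  media <- toy_media()
  for (spec in toy_specs_small()[1:5]) {
    tm <- generate_toy_model(spec)
    e <- enumerate_lethal_sets(tm$model, media[["R-H"]], max_order = 3)
    b <- brute_force_lethal_sets(tm$model, media[["R-H"]], max_order = 3)
    expect_identical(e$reactions, b$reactions,
                     label = sprintf("seed %d enumerator", spec$seed))
  }
})

test_that("enumeration recovers exactly the planted truth", {
  media <- toy_media()
  for (spec in toy_specs_small()[c(2, 4, 7)]) {
    tm <- generate_toy_model(spec)
    e <- enumerate_lethal_sets(tm$model, media[["R-H"]],
                               max_order = max(c(1, spec$sl_orders)))
    expect_identical(sort(e$reactions), truth_strings(tm$truth),
                     label = sprintf("seed %d", spec$seed))
  }
})

test_that("order cap, minimality and determinism hold", {
  media <- toy_media()
  tm <- generate_toy_model(toy_model_spec(1, c(2, 3), 2, seed = 43))
  # order cap: only the essential at max_order 1
  e1 <- enumerate_lethal_sets(tm$model, media[["R-H"]], max_order = 1)
  expect_equal(e1$reactions, "ESS1")
  # no returned set contains another ({ESS1, x} never reported)
  e <- enumerate_lethal_sets(tm$model, media[["R-H"]], max_order = 3)
  for (i in seq_len(nrow(e))) {
    for (j in seq_len(nrow(e))) {
      if (i != j) {
        expect_false(all(e$reaction_ids[[i]] %in% e$reaction_ids[[j]]))
      }
    }
  }
  # minimality via direct FBA: every proper subset grows
  conditioned <- apply_medium(tm$model, media[["R-H"]])
  wt <- optimize_growth(conditioned)$growth
  for (ids in e$reaction_ids) {
    if (length(ids) > 1) {
      for (k in seq_along(ids)) {
        expect_gte(knockout_growth(conditioned, ids[-k])$growth, 0.01 * wt)
      }
    }
  }
  # byte-identical reruns
  expect_identical(e, enumerate_lethal_sets(tm$model, media[["R-H"]],
                                            max_order = 3))
})

test_that("exhaustive (no-prune) mode agrees with the pruned search", {
  media <- toy_media()
  tm <- generate_toy_model(toy_model_spec(1, c(2, 2), 2, seed = 45))
  pruned <- enumerate_lethal_sets(tm$model, media[["R-H"]], max_order = 3)
  full <- enumerate_lethal_sets(tm$model, media[["R-H"]], max_order = 3,
                                prune = FALSE)
  expect_identical(pruned$reactions, full$reactions)
})

test_that("brute force guards its search-space size and handles edge cases", {
  media <- toy_media()
  tm <- generate_toy_model(toy_model_spec(2, c(2), 8, seed = 47))
  expect_error(
    brute_force_lethal_sets(tm$model, media[["R-H"]], max_order = 3,
                            max_tests = 10),
    "force = TRUE")
  expect_equal(nrow(brute_force_lethal_sets(tm$model, media[["R-H"]],
                                            max_order = 0)), 0)
  # no candidates at all
  empty <- generate_toy_model(toy_model_spec(0, integer(0), 0, seed = 48))
  expect_equal(nrow(brute_force_lethal_sets(empty$model, media[["R-H"]],
                                            max_order = 3)), 0)
})

test_that("enumeration refuses a non-growing wild type", {
  tm <- generate_toy_model(toy_model_spec(1, c(2), 1, seed = 49))
  dead <- medium_spec("R-H", character(0), uptake = 0, oxygen = 0)
  expect_error(enumerate_lethal_sets(tm$model, dead), "cannot grow")
})
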