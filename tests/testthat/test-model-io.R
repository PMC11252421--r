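test_that("the bundled six-reaction BiGG JSON fixture loads with its objective", {
  path <- system.file("extdata", "toy6.json", package = "selscreen")
  m <- read_metabolic_model(path)
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$reactions), 6)
  expect_equal(m$objective_reaction_id, "BIOMASS")
  expect_equal(m$model_id, "toy6")
  # classification: prefix rules + spontaneous token
  cls <- stats::setNames(m$reactions$reaction_class, m$reactions$reaction_id)
  expect_equal(unname(cls[c("EX_a_e", "DM_a_c", "At", "AB1")]),
               c("exchange", "demand", "spontaneous", "internal"))
})

test_that("BiGG JSON write/read round trip preserves the model", {
  tm <- generate_toy_model(toy_model_spec(1, c(2, 3), 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_bigg_json(tm$model, path)
  back <- read_metabolic_model(path, diffusion_ids = "O2t")
  expect_equal(back$reactions$reaction_id, tm$model$reactions$reaction_id)
  expect_equal(back$reactions$lower_bound, tm$model$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, tm$model$reactions$upper_bound)
  expect_equal(back$reactions$gpr, tm$model$reactions$gpr)
  expect_equal(back$reactions$subsystem, tm$model$reactions$subsystem)
  expect_equal(back$reactions$reaction_class, tm$model$reactions$reaction_class)
  expect_equal(back$objective_reaction_id, tm$model$objective_reaction_id)
  # and the stoichiometry supports the same optimum
  media <- toy_media()
  expect_equal(optimize_growth(apply_medium(back, media[["R-H"]]))$growth,
               optimize_growth(apply_medium(tm$model, media[["R-H"]]))$growth,
               tolerance = 1e-9)
})

test_that("malformed inputs fail loudly", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id": "x", "metabolites": [], "reactions": [
    {"id": "A", "metabolites": {}, "lower_bound": 0, "upper_bound": 1,
     "gene_reaction_rule": "", "objective_coefficient": 1},
    {"id": "A", "metabolites": {}, "lower_bound": 0, "upper_bound": 1,
     "gene_reaction_rule": "", "objective_coefficient": 0}]}', bad)
  expect_error(read_metabolic_model(bad), "duplicate reaction IDs")

  noobj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id": "x", "metabolites": [], "reactions": [
    {"id": "A", "metabolites": {}, "lower_bound": 0, "upper_bound": 1,
     "gene_reaction_rule": ""}]}', noobj)
  expect_error(read_metabolic_model(noobj), "objective")

  expect_error(read_metabolic_model(withr::local_tempfile()), "not found")
})

test_that("SBML L3 FBC models parse: bounds, GPRs, subsystems, objective", {
  path <- tiny_sbml(withr::local_tempfile(fileext = ".xml"))
  m <- read_metabolic_model(path, format = "sbml")
  expect_equal(sort(m$reactions$reaction_id),
               c("AB", "At", "BIOMASS", "EX_a_e"))
  rx <- m$reactions
  expect_equal(rx$lower_bound[rx$reaction_id == "EX_a_e"], -10)
  expect_equal(rx$gpr[rx$reaction_id == "AB"], "gA and gB")
  expect_equal(rx$subsystem[rx$reaction_id == "AB"],
               "Glycolysis/Gluconeogenesis")
  expect_equal(m$objective_reaction_id, "BIOMASS")
  # and it grows: uptake 10 through the chain
  sol <- optimize_growth(m)
  expect_equal(sol$growth, 10, tolerance = 1e-8)
})

test_that("common_reactions is exact ID intersection", {
  a <- generate_toy_model(toy_model_spec(1, c(2), 1, seed = 1))$model
  b <- a
  expect_setequal(common_reactions(list(a, b)), a$reactions$reaction_id)
  fam <- generate_family(toy_family_spec(3, seed = 31))
  shared <- common_reactions(unname(fam$models))
  # family cores share IDs; accessory IDs are member-private
  core_ids <- fam$models[[1]]$reactions$reaction_id
  core_ids <- core_ids[!grepl("^P\\d\\d_", core_ids)]
  expect_setequal(shared, core_ids)
  expect_error(common_reactions(list()), "at least one")
})

test_that("the synthetic generators are seed-deterministic", {
  spec <- toy_model_spec(1, c(2), 3, seed = 7)
  a <- generate_toy_model(spec)
  b <- generate_toy_model(spec)
  expect_identical(a$model$reactions, b$model$reactions)
  expect_identical(a$truth, b$truth)
  f1 <- generate_family(toy_family_spec(3, seed = 9))
  f2 <- generate_family(toy_family_spec(3, seed = 9))
  expect_identical(lapply(f1$models, `[[`, "reactions"),
                   lapply(f2$models, `[[`, "reactions"))
  expect_identical(f1$truths, f2$truths)
  # and the caller's RNG stream is left untouched
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(generate_toy_model(spec)); y <- runif(1)
  expect_identical(x, y)
})

test_that("model invariants are enforced at construction", {
  mets <- tibble::tibble(metabolite_id = "a_c", compartment = "c")
  rx <- tibble::tibble(
    reaction_id = "EX_bad", lower_bound = 0, upper_bound = 1, gpr = "",
    subsystem = NA_character_, reaction_class = "exchange",
    stoichiometry = list(c(a_c = -1, b_c = 1))
  )
  expect_error(metabolic_model("m", mets, rx, "EX_bad"), "unknown metabolites")
  rx$stoichiometry <- list(c(a_c = -1))
  expect_error(metabolic_model("m", mets, rx, "nope"), "objective")
  rx$lower_bound <- 2
  expect_error(metabolic_model("m", mets, rx, "EX_bad"), "lower_bound")
})
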