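chain_model <- function() {
  # A_ext -> A -> B -> biomass, uptake bound 10: optimum is 10 by hand
  mets <- tibble::tibble(metabolite_id = c("a_e", "a_c", "b_c"),
                         compartment = c("e", "c", "c"))
  rx <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "EX_a_e", lower_bound = -10,
                   upper_bound = 1000, gpr = "", subsystem = NA,
                   stoichiometry = list(c(a_e = -1))),
    tibble::tibble(reaction_id = "At", lower_bound = 0, upper_bound = 1000,
                   gpr = "gT", subsystem = NA,
                   stoichiometry = list(c(a_e = -1, a_c = 1))),
    tibble::tibble(reaction_id = "AB", lower_bound = 0, upper_bound = 1000,
                   gpr = "gAB", subsystem = NA,
                   stoichiometry = list(c(a_c = -1, b_c = 1))),
    tibble::tibble(reaction_id = "BIO", lower_bound = 0, upper_bound = 1000,
                   gpr = "", subsystem = NA,
                   stoichiometry = list(c(b_c = -1)))
  )
  metabolic_model("chain", mets, classify_reactions(rx), "BIO")
}

test_that("optimal growth matches the hand-solved chain LP", {
  m <- chain_model()
  sol <- optimize_growth(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$growth, 10, tolerance = 1e-9)
  # optimal fluxes satisfy mass balance and bounds
  expect_lt(max(abs(as.matrix(m$S) %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-9))
  expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-9))
})

test_that("degenerate models report zero growth", {
  m <- chain_model()
  m$reactions$upper_bound[m$reactions$reaction_id == "BIO"] <- 0
  expect_equal(optimize_growth(metabolic_model(
    "capped", m$metabolites, m$reactions, "BIO"))$growth, 0)

  # biomass consumes a metabolite nothing can make
  m2 <- chain_model()
  mets <- dplyr::bind_rows(m2$metabolites,
                           tibble::tibble(metabolite_id = "ghost_c",
                                          compartment = "c"))
  rx <- m2$reactions
  rx$stoichiometry[rx$reaction_id == "BIO"] <-
    list(c(b_c = -1, ghost_c = -1))
  expect_equal(optimize_growth(metabolic_model("ghost", mets, rx, "BIO"))$growth, 0)
})

test_that("knockouts zero the named reactions and nothing else", {
  m <- chain_model()
  expect_equal(knockout_growth(m, character(0))$growth,
               optimize_growth(m)$growth)
  expect_equal(knockout_growth(m, "BIO")$growth, 0)
  expect_equal(knockout_growth(m, "AB")$growth, 0)   # chain is essential
  expect_error(knockout_growth(m, c("AB", "nope")), "nope")
  # input untouched
  knockout_growth(m, "AB")
  expect_equal(m$reactions$upper_bound[m$reactions$reaction_id == "AB"], 1000)
})

test_that("parallel branches: single knockout harmless, joint knockout fatal", {
  tm <- generate_toy_model(toy_model_spec(0, c(2), 0, seed = 21))
  media <- toy_media()
  m <- apply_medium(tm$model, media[["R-H"]])
  pair <- tm$truth[[1]]
  g0 <- optimize_growth(m)$growth
  expect_equal(knockout_growth(m, pair[1])$growth, g0, tolerance = 1e-8)
  expect_equal(knockout_growth(m, pair[2])$growth, g0, tolerance = 1e-8)
  expect_equal(knockout_growth(m, pair)$growth, 0)
})

test_that("superset knockouts can only lower growth", {
  tm <- generate_toy_model(toy_model_spec(1, c(2, 3), 3, seed = 23))
  m <- apply_medium(tm$model, toy_media()[["R-H"]])
  cand <- candidate_space(tm$model)
  set.seed(42)
  for (rep in 1:10) {
    s <- sample(cand, sample(1:3, 1))
    sub <- sample(s, sample(seq_along(s), 1))
    g_small <- knockout_growth(m, sub)$growth
    g_big <- knockout_growth(m, s)$growth
    expect_lte(g_big, g_small + 1e-6)
  }
})

test_that("lethality threshold: at-threshold growth is non-lethal", {
  # two branches of capacity 5: knocking one leaves exactly half the
  # wild-type growth, which equals the threshold at frac = 0.5
  mets <- tibble::tibble(metabolite_id = c("a_e", "a_c", "b_c"),
                         compartment = c("e", "c", "c"))
  rx <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "EX_a_e", lower_bound = -10,
                   upper_bound = 1000, gpr = "", subsystem = NA,
                   stoichiometry = list(c(a_e = -1))),
    tibble::tibble(reaction_id = "At", lower_bound = 0, upper_bound = 1000,
                   gpr = "s0001", subsystem = NA,
                   stoichiometry = list(c(a_e = -1, a_c = 1))),
    tibble::tibble(reaction_id = "B1", lower_bound = 0, upper_bound = 5,
                   gpr = "g1", subsystem = NA,
                   stoichiometry = list(c(a_c = -1, b_c = 1))),
    tibble::tibble(reaction_id = "B2", lower_bound = 0, upper_bound = 5,
                   gpr = "g2", subsystem = NA,
                   stoichiometry = list(c(a_c = -1, b_c = 1))),
    tibble::tibble(reaction_id = "BIO", lower_bound = 0, upper_bound = 1000,
                   gpr = "", subsystem = NA,
                   stoichiometry = list(c(b_c = -1)))
  )
  m <- metabolic_model("halved", mets, classify_reactions(rx), "BIO")
  med <- medium_spec("R-H", "EX_a_e", uptake = 10, oxygen = 20,
                     oxygen_exchange = "EX_a_e")
  v <- is_lethal(m, "B1", med, threshold_frac = 0.5)
  expect_equal(v$wild_type_growth, 10, tolerance = 1e-9)
  expect_equal(v$knockout_growth, 5, tolerance = 1e-9)
  expect_false(v$lethal)                       # exactly at threshold
  expect_true(is_lethal(m, "B1", med, threshold_frac = 0.6)$lethal)
  expect_true(is_lethal(m, c("B1", "B2"), med)$lethal)
})

test_that("is_lethal refuses a medium the wild type cannot grow in", {
  tm <- generate_toy_model(toy_model_spec(1, c(2), 1, seed = 25))
  dead <- medium_spec("M-L", character(0), uptake = 0, oxygen = 0)
  expect_error(is_lethal(tm$model, "ESS1", dead), "cannot grow")
})
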