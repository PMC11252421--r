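test_that("case generation matches the 3^n - 2^n accounting", {
  for (n in 2:4) {
    ids <- sprintf("org%02d", seq_len(n))
    cases <- generate_cases(ids)
    expect_equal(nrow(cases), 3^n - 2^n)
    expect_equal(sum(cases$n_conserved == 0), 2^n - 1)
    expect_true(all(cases$n_targeted >= 1))
    expect_false(anyDuplicated(cases$case_id) > 0)
  }
  expect_equal(nrow(generate_cases(c("a", "b"))), 5)
  expect_error(generate_cases(c("a", "a")), "duplicate")
})

test_that("case IDs are a base-3 encoding over sorted organisms", {
  cases <- generate_cases(c("b_org", "a_org"))   # sorted: a_org, b_org
  row <- cases[cases$case_id == "12", ]
  expect_equal(row$targeted[[1]], "a_org")
  expect_equal(row$conserved[[1]], "b_org")
  # permuting input labels leaves the case set unchanged
  expect_identical(cases, generate_cases(c("a_org", "b_org")))
})

test_that("common targeted solutions are the exact set-of-sets intersection", {
  ls <- dplyr::bind_rows(
    selscreen:::lethal_set_tibble("m1", "R-H",
                                  list("A", c("B", "C"), c("D", "E"))),
    selscreen:::lethal_set_tibble("m2", "R-H", list(c("B", "C"), "F"))
  )
  case12 <- generate_cases(c("m1", "m2"))
  both <- case12[case12$case_id == "11", ]
  got <- common_targeted_solutions(both, ls)
  expect_equal(got$reactions, "B+C")
  # single targeted organism: full collection unchanged
  single <- case12[case12$case_id == "10", ]   # m1 targeted, m2 excluded
  expect_equal(common_targeted_solutions(single, ls)$reactions,
               c("A", "B+C", "D+E"))
  # disjoint collections
  ls2 <- dplyr::bind_rows(
    selscreen:::lethal_set_tibble("m1", "R-H", list("A")),
    selscreen:::lethal_set_tibble("m2", "R-H", list("F"))
  )
  expect_equal(nrow(common_targeted_solutions(both, ls2)), 0)
  expect_error(common_targeted_solutions(both, ls2[1, ]), "m2")
})

test_that("conserved-neutrality screening accepts and rejects per construction", {
  fam <- generate_family(toy_family_spec(3, seed = 61))
  media <- toy_media()
  ls <- dplyr::bind_rows(lapply(names(fam$models), function(org) {
    enumerate_lethal_sets(fam$models[[org]], media[["R-H"]], max_order = 4)
  }))
  cases <- generate_cases(names(fam$models))

  # target org01, conserve org02 (rescued): the shared core group passes,
  # the core essential chain is rejected, and org01's private accessory
  # set survives step 3 as a knockout no-op on org02
  case <- cases[cases$case_id == "120", ]
  cand <- common_targeted_solutions(case, ls)
  sols <- filter_conserved_neutral(cand, case, fam$models, media)
  expect_true("GRP1_B1+GRP1_B2" %in% sols$reactions)
  expect_false("ESS1" %in% sols$reactions)
  expect_true("P01_GRP1_B1+P01_GRP1_B2" %in% sols$reactions)
  acc_row <- sols[sols$reactions == "P01_GRP1_B1+P01_GRP1_B2", ]
  expect_false(acc_row$step4_pass)
  core_row <- sols[sols$reactions == "GRP1_B1+GRP1_B2", ]
  expect_true(core_row$step4_pass)

  # no conserved organisms: everything is kept
  wo <- cases[cases$case_id == "100", ]
  kept <- filter_conserved_neutral(common_targeted_solutions(wo, ls), wo,
                                   fam$models, media)
  expect_equal(nrow(kept), nrow(common_targeted_solutions(wo, ls)))
  expect_true(all(kept$step4_pass))   # vacuously

  # step 4 removes exactly the absent-reaction solutions
  step4 <- strict_presence_filter(sols)
  expect_setequal(step4$reactions, c("GRP1_B1+GRP1_B2"))
  expect_true(all(step4$reactions %in% sols$reactions))

  # recomputing presence from the models agrees with the stored flag
  expect_identical(strict_presence_filter(sols, fam$models)$reactions,
                   step4$reactions)
})

test_that("emitted solutions are re-verifiable by direct FBA", {
  fam <- generate_family(toy_family_spec(3, seed = 63))
  media <- toy_media()
  scr <- run_pipeline(fam$models, media, max_order = 3)
  sols <- scr$solutions_step3
  idx <- head(seq_len(nrow(sols)), 12)
  for (i in idx) {
    out <- sols$outcomes[[i]]
    for (j in seq_len(nrow(out))) {
      org <- out$organism_id[j]
      ids <- intersect(sols$reaction_ids[[i]],
                       fam$models[[org]]$reactions$reaction_id)
      med <- media[[out$medium[j]]]
      if (length(ids)) {
        v <- is_lethal(fam$models[[org]], ids, med)
        expect_equal(v$lethal, out$lethal[j])
        expect_equal(v$knockout_growth, out$growth[j], tolerance = 1e-8)
      } else {
        expect_false(out$lethal[j])
      }
    }
  }
})

test_that("solution tables round-trip through TSV", {
  fam <- generate_family(toy_family_spec(3, seed = 65))
  media <- toy_media()
  scr <- run_pipeline(fam$models, media, max_order = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_solution_table(scr$solutions_step3, path)
  back <- read_solution_table(path)
  expect_equal(back, scr$solutions_step3[names(back)])

  # empty store writes a header-only file that reads back empty
  write_solution_table(scr$solutions_step3[0, ], path)
  expect_equal(nrow(read_solution_table(path)), 0)

  # malformed order field is reported with its line number
  lines <- readr::read_lines(path)
  writeLines(c(lines[1], "00\t00\tnot_an_int\tA\tm:targeted:R-H:1:TRUE:1\tTRUE"),
             path)
  expect_error(read_solution_table(path), "line 2")
})
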