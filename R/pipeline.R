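#' Run the selective-targeting screen end to end
#'
#' The four stages: (1) condition each model on the four media and check
#' it grows in the rich/high-oxygen (`R-H`) and minimal/low-oxygen
#' (`M-L`) states; (2) enumerate each model's minimal lethal reaction sets
#' up to `max_order` under `R-H`; (3) for every targeted/conserved case,
#' keep the sets common to all targeted organisms and neutral for every
#' conserved organism under `M-L`; (4) apply the strict presence filter.
#' Pathway participation and greedy key-reaction collections are computed
#' from the step-4 solutions; the step-3 table is kept alongside.
#'
#' @param models Named list of [metabolic_model()]s, or a named character
#'   vector of file paths readable by [read_metabolic_model()].
#' @param media Named list of [medium_spec()]s (needs `"R-H"` and
#'   `"M-L"`), or the path of a medium configuration file for
#'   [read_medium_config()].
#' @param max_order Maximum lethal-set order, 1 to 4 (default 4).
#' @param threshold_frac,threshold_abs Lethality threshold, see
#'   [is_lethal()].
#' @param prune Use flux-support pruning in the enumerator (default).
#' @param organisms Optional subset of model names to screen.
#' @param cover_budget_single,cover_budget_sl Budgets for the two greedy
#'   key-reaction collections (single essentials only, and pure synthetic
#'   lethal certificates).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV plus a JSON run manifest.
#' @param seed Optional integer recorded in the manifest (the screen
#'   itself is deterministic).
#' @return A `selectivity_screen` object: list with `models` (names),
#'   `lethal_sets`, `cases`, `solutions_step3`, `solutions_step4`,
#'   `no_solution_cases`, `pathways`, `sl_only`, `cover_single`,
#'   `cover_sl`, `params`.
#' @export
run_pipeline <- function(models, media, max_order = 4,
                         threshold_frac = 0.01, threshold_abs = 1e-6,
                         prune = TRUE, organisms = NULL,
                         cover_budget_single = 4, cover_budget_sl = 7,
                         out_dir = NULL, seed = NULL) {
  if (is.character(models)) {
    if (is.null(names(models))) names(models) <- basename(models)
    models <- lapply(models, read_metabolic_model)
    names(models) <- vapply(models, function(m) m$model_id, character(1))
  }
  stopifnot(is.list(models), !is.null(names(models)))
  if (is.character(media)) media <- read_medium_config(media)
  if (!all(c("R-H", "M-L") %in% names(media))) {
    stop("media must include 'R-H' and 'M-L'", call. = FALSE)
  }
  if (!is.null(organisms)) models <- models[organisms]

  for (org in names(models)) {
    for (mn in c("R-H", "M-L")) {
      g <- optimize_growth(apply_medium(models[[org]], media[[mn]]))
      if (g$status != "optimal" || g$growth <= 0) {
        stop("stage 1 (model prep): model '", org, "' does not grow under '",
             mn, "'", call. = FALSE)
      }
    }
  }

  lethal_sets <- dplyr::bind_rows(lapply(names(models), function(org) {
    tryCatch(
      enumerate_lethal_sets(models[[org]], media[["R-H"]],
                            max_order = max_order,
                            threshold_frac = threshold_frac,
                            threshold_abs = threshold_abs, prune = prune),
      error = function(e) stop("stage 2 (enumeration) failed for model '",
                               org, "': ", conditionMessage(e), call. = FALSE)
    )
  }))

  cases <- generate_cases(names(models))
  step3 <- screen_cases(models, lethal_sets, media, cases = cases,
                        threshold_frac = threshold_frac,
                        threshold_abs = threshold_abs)
  step4 <- strict_presence_filter(step3)
  no_solution <- dplyr::mutate(
    dplyr::filter(cases, !.data$case_id %in% step4$case_id),
    had_step3_solution = .data$case_id %in% step3$case_id
  )

  pathways <- participation_table(step4, models)
  sl_only <- sl_only_pathways(step4, models)
  cover_single <- greedy_cover(step4, cover_budget_single, "single")
  cover_sl <- greedy_cover(step4, cover_budget_sl, "sl")

  params <- list(max_order = max_order, threshold_frac = threshold_frac,
                 threshold_abs = threshold_abs, prune = prune,
                 cover_budget_single = cover_budget_single,
                 cover_budget_sl = cover_budget_sl, seed = seed)
  res <- structure(
    list(models = names(models), media = names(media),
         lethal_sets = lethal_sets, cases = cases,
         solutions_step3 = step3, solutions_step4 = step4,
         no_solution_cases = no_solution,
         pathways = pathways, sl_only = sl_only,
         cover_single = cover_single, cover_sl = cover_sl,
         params = params),
    class = "selectivity_screen"
  )
  if (!is.null(out_dir)) write_screen_reports(res, out_dir)
  res
}

#' @export
print.selectivity_screen <- function(x, ...) {
  cat("<selectivity_screen> ", length(x$models), " organisms, ",
      nrow(x$cases), " cases\n",
      "  lethal sets enumerated: ", nrow(x$lethal_sets), "\n",
      "  step-3 solutions: ", nrow(x$solutions_step3),
      " (", dplyr::n_distinct(x$solutions_step3$case_id), " cases)\n",
      "  step-4 solutions: ", nrow(x$solutions_step4),
      " (", dplyr::n_distinct(x$solutions_step4$case_id), " cases)\n",
      "  cases without step-4 solutions: ", nrow(x$no_solution_cases), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a selectivity screen (its step-4 solution table)
#'
#' @param x A `selectivity_screen`.
#' @param step Which solution table, `4` (default, strict) or `3`.
#' @param ... Unused.
#' @return The solutions tibble.
#' @method tidy selectivity_screen
#' @export
tidy.selectivity_screen <- function(x, step = 4, ...) {
  if (step == 4) x$solutions_step4 else x$solutions_step3
}

#' One-row summary of a selectivity screen
#'
#' @param x A `selectivity_screen`.
#' @param ... Unused.
#' @return Tibble with organism, case and solution counts.
#' @method glance selectivity_screen
#' @export
glance.selectivity_screen <- function(x, ...) {
  tibble::tibble(
    n_organisms = length(x$models),
    n_cases = nrow(x$cases),
    n_lethal_sets = nrow(x$lethal_sets),
    n_solutions_step3 = nrow(x$solutions_step3),
    n_solutions_step4 = nrow(x$solutions_step4),
    n_cases_solved_step3 = dplyr::n_distinct(x$solutions_step3$case_id),
    n_cases_solved_step4 = dplyr::n_distinct(x$solutions_step4$case_id),
    n_cases_unsolved = nrow(x$no_solution_cases),
    cover_single_cases = x$cover_single$coverage_count,
    cover_sl_cases = x$cover_sl$coverage_count
  )
}

write_screen_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(
    dplyr::select(res$lethal_sets, -"reaction_ids"), p("lethal_sets.tsv"))
  write_solution_table(res$solutions_step3, p("solutions_step3.tsv"))
  write_solution_table(res$solutions_step4, p("solutions_step4.tsv"))
  readr::write_tsv(
    dplyr::select(res$no_solution_cases, "case_id", "assignment",
                  "n_targeted", "n_conserved", "had_step3_solution"),
    p("no_solution_cases.tsv"))
  readr::write_tsv(tibble::as_tibble(res$pathways),
                   p("pathway_participation.tsv"))
  readr::write_tsv(res$sl_only, p("sl_only_pathways.tsv"))
  readr::write_tsv(glance(res$cover_single), p("cover_single_summary.tsv"))
  readr::write_tsv(
    dplyr::select(tidy(res$cover_single), -"certificate_ids"),
    p("cover_single.tsv"))
  readr::write_tsv(
    dplyr::select(tidy(res$cover_sl), -"certificate_ids"),
    p("cover_sl.tsv"))
  manifest <- list(
    package = "selscreen",
    package_version = as.character(utils::packageVersion("selscreen")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    organisms = res$models,
    params = res$params,
    config_hash = rlang::hash(list(res$models, res$params))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Write a solution table as TSV
#'
#' Columns: `case_id`, `assignment`, `order`, `reactions` (sorted IDs
#' joined by `"+"`), `outcomes` (per-organism records
#' `organism:role:medium:growth:lethal` joined by `";"`, growth at full
#' precision) and `step4_pass`. The round trip through
#' [read_solution_table()] is lossless.
#'
#' @param solutions A solutions tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_solution_table <- function(solutions, path) {
  pack <- vapply(seq_len(nrow(solutions)), function(i) {
    out <- solutions$outcomes[[i]]
    paste(sprintf("%s:%s:%s:%.17g:%s:%d", out$organism_id, out$role,
                  out$medium, out$growth, out$lethal, out$n_present),
          collapse = ";")
  }, character(1))
  tb <- tibble::tibble(
    case_id = solutions$case_id,
    assignment = solutions$assignment,
    order = solutions$order,
    reactions = solutions$reactions,
    outcomes = pack,
    step4_pass = solutions$step4_pass
  )
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Read a solution table written by [write_solution_table()]
#'
#' @param path TSV path.
#' @return A solutions tibble with `reaction_ids` and `outcomes`
#'   reconstructed.
#' @export
read_solution_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- readr::read_tsv(path, col_types = readr::cols(
    case_id = readr::col_character(),
    assignment = readr::col_character(),
    order = readr::col_character(),   # validated below for line numbers
    reactions = readr::col_character(),
    outcomes = readr::col_character(),
    step4_pass = readr::col_logical()
  ))
  if (!setequal(names(tb), c("case_id", "assignment", "order", "reactions",
                             "outcomes", "step4_pass"))) {
    stop("schema mismatch in '", path, "': expected columns case_id, ",
         "assignment, order, reactions, outcomes, step4_pass", call. = FALSE)
  }
  ord <- suppressWarnings(as.integer(tb$order))
  bad <- which(is.na(ord) & !is.na(tb$order))
  if (length(bad)) {
    stop("malformed order field in '", path, "' at line ", bad[1] + 1L,
         call. = FALSE)
  }
  tb$order <- ord
  tb$reaction_ids <- strsplit(tb$reactions, "+", fixed = TRUE)
  tb$outcomes <- lapply(tb$outcomes, function(s) {
    if (is.na(s) || s == "") {
      return(tibble::tibble(organism_id = character(), role = character(),
                            medium = character(), growth = numeric(),
                            lethal = logical(), n_present = integer()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(
      organism_id = vapply(parts, `[`, character(1), 1),
      role = vapply(parts, `[`, character(1), 2),
      medium = vapply(parts, `[`, character(1), 3),
      growth = as.numeric(vapply(parts, `[`, character(1), 4)),
      lethal = as.logical(vapply(parts, `[`, character(1), 5)),
      n_present = as.integer(vapply(parts, `[`, character(1), 6))
    )
  })
  dplyr::select(tb, "case_id", "assignment", "order", "reactions",
                "reaction_ids", "outcomes", "step4_pass")
}
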