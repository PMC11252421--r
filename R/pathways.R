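#' Map solution reactions to subsystem labels
#'
#' Labels come from the lexicographically first targeted model (of the
#' solution's own case) that carries the reaction; disagreements between
#' models are resolved that way deterministically. Reactions without a
#' subsystem anywhere are reported as `"(unannotated)"` with a warning.
#'
#' @noRd
subsystem_lookup <- function(models) {
  lapply(models, function(m) {
    stats::setNames(m$reactions$subsystem, m$reactions$reaction_id)
  })
}

solution_pathways <- function(solutions, models) {
  lut <- subsystem_lookup(models)
  n_unannotated <- 0L
  res <- lapply(seq_len(nrow(solutions)), function(i) {
    out <- solutions$outcomes[[i]]
    targeted <- sort(out$organism_id[out$role == "targeted"])
    ids <- solutions$reaction_ids[[i]]
    paths <- vapply(ids, function(r) {
      for (org in targeted) {
        s <- lut[[org]][r]
        if (!is.na(s)) return(unname(s))
      }
      NA_character_
    }, character(1))
    if (anyNA(paths)) {
      n_unannotated <<- n_unannotated + sum(is.na(paths))
      paths[is.na(paths)] <- "(unannotated)"
    }
    unique(paths)
  })
  if (n_unannotated > 0L) {
    warning(n_unannotated, " solution reaction(s) had no subsystem label in ",
            "any targeted model; counted under \"(unannotated)\"",
            call. = FALSE)
  }
  res
}

#' Pathway participation table
#'
#' For each pathway (subsystem label) and case group — *without-conservation*
#' (no conserved organism) vs *with-conservation* — counts the cases
#' fulfillable via the pathway at each solution order: a case counts at
#' order *k* when at least one accepted order-*k* solution for it contains
#' a reaction of the pathway. Counts aggregate cases, not solutions.
#'
#' @param solutions Accepted solutions tibble ([screen_cases()] output,
#'   optionally after [strict_presence_filter()]).
#' @param models Named list of [metabolic_model()]s (for subsystem labels).
#' @return A `pathway_participation` tibble: one row per pathway and case
#'   group, columns `n_order1`..`n_order4`, plus per-pathway flags
#'   `participates_in_all_without_conservation` (the pathway appears in
#'   every without-conservation case that has any accepted solution) and
#'   `sl_only` (never hit at order 1 in either group).
#' @export
participation_table <- function(solutions, models) {
  empty <- tibble::tibble(
    pathway = character(), case_group = character(),
    n_order1 = integer(), n_order2 = integer(), n_order3 = integer(),
    n_order4 = integer(),
    participates_in_all_without_conservation = logical(),
    sl_only = logical()
  )
  if (!nrow(solutions)) return(structure(empty, class = c("pathway_participation", class(empty))))

  paths <- solution_pathways(solutions, models)
  long <- tidyr::unnest(
    dplyr::mutate(
      dplyr::select(solutions, "case_id", "assignment", "order"),
      pathway = paths,
      case_group = ifelse(stringr::str_count(.data$assignment, "2") == 0,
                          "without-conservation", "with-conservation")
    ),
    "pathway"
  )
  counts <- dplyr::summarise(
    dplyr::group_by(long, .data$pathway, .data$case_group, .data$order),
    n_cases = dplyr::n_distinct(.data$case_id), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    counts, names_from = "order", values_from = "n_cases",
    names_prefix = "n_order", values_fill = 0L
  )
  for (k in paste0("n_order", 1:4)) {
    if (!k %in% names(wide)) wide[[k]] <- 0L
  }
  wide <- dplyr::select(wide, "pathway", "case_group",
                        "n_order1", "n_order2", "n_order3", "n_order4")

  wo_cases <- unique(long$case_id[long$case_group == "without-conservation"])
  in_all_wo <- vapply(unique(wide$pathway), function(p) {
    covered <- unique(long$case_id[long$pathway == p &
                                     long$case_group == "without-conservation"])
    length(wo_cases) > 0 && setequal(covered, wo_cases)
  }, logical(1))
  hit_order1 <- unique(long$pathway[long$order == 1])
  wide$participates_in_all_without_conservation <-
    unname(in_all_wo[wide$pathway])
  wide$sl_only <- !(wide$pathway %in% hit_order1)
  out <- dplyr::arrange(wide, .data$pathway, .data$case_group)
  structure(out, class = c("pathway_participation", class(out)))
}

#' Pathways attacked only by synthetic lethal sets
#'
#' Lists the pathways never hit by an accepted single essential (order-1
#' solution). For each, `spans_multiple_pathways` records whether every
#' accepted synthetic lethal set touching the pathway also touches at
#' least one other pathway (i.e. no SL set maps to that pathway alone).
#'
#' @inheritParams participation_table
#' @return Tibble with columns `pathway`, `spans_multiple_pathways`.
#' @export
sl_only_pathways <- function(solutions, models) {
  if (!nrow(solutions)) {
    return(tibble::tibble(pathway = character(),
                          spans_multiple_pathways = logical()))
  }
  paths <- solution_pathways(solutions, models)
  order1 <- unique(unlist(paths[solutions$order == 1]))
  sl_idx <- which(solutions$order >= 2)
  sl_paths <- paths[sl_idx]
  touched <- sort(setdiff(unique(unlist(sl_paths)), order1))
  spans <- vapply(touched, function(p) {
    touching <- sl_paths[vapply(sl_paths, function(x) p %in% x, logical(1))]
    all(vapply(touching, function(x) length(x) >= 2, logical(1)))
  }, logical(1))
  tibble::tibble(pathway = touched, spans_multiple_pathways = unname(spans))
}

#' @method autoplot pathway_participation
#' @export
autoplot.pathway_participation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::starts_with("n_order"),
    names_to = "order", names_prefix = "n_order", values_to = "n_cases"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$n_cases,
                               y = stats::reorder(.data$pathway, .data$n_cases,
                                                  sum),
                               fill = .data$order)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~case_group, scales = "free_x") +
    ggplot2::labs(x = "cases fulfillable via pathway", y = NULL,
                  fill = "solution\norder") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
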