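#' Generate every targeted/conserved/excluded case
#'
#' A case assigns each organism one of three roles: *targeted* (the
#' candidate set must kill it), *conserved* (the set must spare it) or
#' *excluded* (not considered). Every assignment with at least one
#' targeted organism is a case, so `n` organisms give `3^n - 2^n` cases.
#' Organisms are sorted lexicographically and the assignment is encoded as
#' a base-3 case ID (one digit per organism: 0 excluded, 1 targeted,
#' 2 conserved), which makes case identity stable across runs.
#'
#' @param organism_ids Character vector of unique organism/model IDs.
#' @return A tibble with columns `case_id`, `assignment` (the digit
#'   string), list-columns `targeted`, `conserved`, `excluded`, and counts
#'   `n_targeted`, `n_conserved`; ordered by base-3 value.
#' @export
generate_cases <- function(organism_ids) {
  organism_ids <- as.character(organism_ids)
  if (!length(organism_ids)) stop("need at least one organism", call. = FALSE)
  if (anyDuplicated(organism_ids)) {
    stop("duplicate organism IDs: ",
         paste(unique(organism_ids[duplicated(organism_ids)]), collapse = ", "),
         call. = FALSE)
  }
  orgs <- sort(organism_ids)
  n <- length(orgs)
  vals <- 0:(3^n - 1)
  digits <- matrix(0L, length(vals), n)
  v <- vals
  for (j in n:1) {           # last organism = least significant digit
    digits[, j] <- v %% 3L
    v <- v %/% 3L
  }
  keep <- rowSums(digits == 1L) >= 1L
  digits <- digits[keep, , drop = FALSE]
  assignment <- apply(digits, 1, paste, collapse = "")
  tibble::tibble(
    case_id = assignment,
    assignment = assignment,
    targeted = apply(digits, 1, function(d) orgs[d == 1L], simplify = FALSE),
    conserved = apply(digits, 1, function(d) orgs[d == 2L], simplify = FALSE),
    excluded = apply(digits, 1, function(d) orgs[d == 0L], simplify = FALSE),
    n_targeted = rowSums(digits == 1L),
    n_conserved = rowSums(digits == 2L)
  )
}

#' Lethal sets common to the targeted organisms of a case
#'
#' Intersects the targeted organisms' minimal-lethal-set collections as
#' sets of sorted reaction-ID tuples: a set qualifies only if it is a
#' minimal lethal set of *every* targeted organism (a set minimal in one
#' model but non-minimal in another is not common).
#'
#' @param case A single row of [generate_cases()] output (or any list with
#'   a `targeted` character vector).
#' @param lethal_sets A tibble of enumerated lethal sets covering all
#'   targeted organisms (as returned by [enumerate_lethal_sets()], rows
#'   from several models bound together).
#' @return Tibble with columns `order`, `reactions`, `reaction_ids` —
#'   the common candidate sets, sorted.
#' @export
common_targeted_solutions <- function(case, lethal_sets) {
  targeted <- case_targeted(case)
  have <- unique(lethal_sets$model_id)
  missing <- setdiff(targeted, have)
  if (length(missing)) {
    stop("no enumerated lethal sets for targeted organism(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per_org <- lapply(targeted, function(org) {
    unique(lethal_sets$reactions[lethal_sets$model_id == org])
  })
  common <- Reduce(intersect, per_org)
  out <- dplyr::filter(lethal_sets, .data$model_id == targeted[[1]],
                       .data$reactions %in% common)
  dplyr::arrange(
    dplyr::select(out, "order", "reactions", "reaction_ids"),
    .data$order, .data$reactions
  )
}

case_targeted <- function(case) {
  t <- if (is.data.frame(case)) case$targeted[[1]] else case$targeted
  as.character(t)
}
case_conserved <- function(case) {
  c <- if (is.data.frame(case)) case$conserved[[1]] else case$conserved
  as.character(c)
}
case_id_of <- function(case) {
  if (is.data.frame(case)) case$case_id[[1]] else case$case_id
}

#' Keep candidate sets that spare every conserved organism
#'
#' A candidate survives when, for every conserved organism, knocking out
#' the member reactions *present in that organism's model* leaves it
#' viable under the minimal-medium / low-oxygen (`M-L`) state — its most
#' vulnerable condition. Reactions absent from a conserved model are a
#' no-op on it (the candidate is kept here but flagged, and the strict
#' presence filter handles the epistemic risk downstream). Per-organism
#' knockout growth is recorded for both targeted (`R-H`) and conserved
#' (`M-L`) organisms, so every emitted solution can be re-verified by
#' direct FBA.
#'
#' @param candidates Tibble from [common_targeted_solutions()].
#' @param case A single case row.
#' @param models Named list of [metabolic_model()]s covering all targeted
#'   and conserved organisms.
#' @param media Named list of [medium_spec()]s including `"R-H"` and
#'   `"M-L"`.
#' @param threshold_frac,threshold_abs Lethality threshold, see
#'   [is_lethal()].
#' @param cache Optional environment memoizing knockout growth across
#'   calls (keyed by organism, medium and reaction set).
#' @return A solutions tibble: `case_id`, `assignment`, `order`,
#'   `reactions`, `reaction_ids`, `outcomes` (list-column of per-organism
#'   tibbles), `step4_pass`.
#' @export
filter_conserved_neutral <- function(candidates, case, models, media,
                                     threshold_frac = 0.01,
                                     threshold_abs = 1e-6,
                                     cache = NULL) {
  targeted <- case_targeted(case)
  conserved <- case_conserved(case)
  need <- c(targeted, conserved)
  if (!all(need %in% names(models))) {
    stop("models missing for: ",
         paste(setdiff(need, names(models)), collapse = ", "), call. = FALSE)
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  conditioned <- function(org, medium_name) {
    key <- paste0(".cond|", org, "|", medium_name)
    got <- cache[[key]]
    if (is.null(got)) {
      got <- apply_medium(models[[org]], media[[medium_name]])
      wt <- optimize_growth(got)
      if (wt$status != "optimal" || wt$growth <= 0) {
        stop("model '", org, "' cannot grow in medium '", medium_name, "'",
             call. = FALSE)
      }
      got <- list(model = got, wt = wt$growth)
      cache[[key]] <- got
    }
    got
  }
  ko_growth_of <- function(org, medium_name, ids) {
    present <- intersect(ids, models[[org]]$reactions$reaction_id)
    key <- paste0(org, "|", medium_name, "|", set_key(present))
    got <- cache[[key]]
    if (is.null(got)) {
      cm <- conditioned(org, medium_name)
      g <- if (length(present)) {
        s <- knockout_growth(cm$model, present)
        if (s$status == "optimal") s$growth else 0
      } else cm$wt
      got <- c(growth = g, wt = cm$wt)
      cache[[key]] <- got
    }
    got
  }

  empty <- tibble::tibble(
    case_id = character(), assignment = character(), order = integer(),
    reactions = character(), reaction_ids = list(), outcomes = list(),
    step4_pass = logical()
  )
  if (!nrow(candidates)) return(empty)

  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    ids <- candidates$reaction_ids[[i]]
    outcome <- dplyr::bind_rows(lapply(c(targeted, conserved), function(org) {
      role <- if (org %in% targeted) "targeted" else "conserved"
      med <- if (role == "targeted") "R-H" else "M-L"
      g <- ko_growth_of(org, med, ids)
      thr <- max(threshold_frac * g[["wt"]], threshold_abs)
      tibble::tibble(
        organism_id = org, role = role, medium = med,
        growth = g[["growth"]],
        lethal = g[["growth"]] < thr,
        n_present = length(intersect(ids, models[[org]]$reactions$reaction_id))
      )
    }))
    keep <- all(outcome$lethal[outcome$role == "targeted"]) &&
      !any(outcome$lethal[outcome$role == "conserved"])
    if (!keep) return(NULL)
    all_present <- all(vapply(conserved, function(org) {
      all(ids %in% models[[org]]$reactions$reaction_id)
    }, logical(1)))
    tibble::tibble(
      case_id = case_id_of(case),
      assignment = case_id_of(case),
      order = length(ids),
      reactions = candidates$reactions[[i]],
      reaction_ids = list(ids),
      outcomes = list(outcome),
      step4_pass = all_present
    )
  })
  rows <- purrr::compact(rows)
  if (!length(rows)) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$order, .data$reactions)
}

#' Strict presence filter (step 4)
#'
#' Retains only solutions whose member reactions are present in every
#' conserved model of their case. A reaction absent from a conserved model
#' is a knockout no-op there, but the genome may well encode it outside
#' the model's scope, so such solutions are cautiously set aside. Keep
#' both the pre- and post-filter tables: both are results.
#'
#' @param solutions A solutions tibble from [filter_conserved_neutral()]
#'   (or several bound together).
#' @param models Optional named list of models; when supplied,
#'   `step4_pass` is recomputed from the models instead of trusting the
#'   stored flag (the `conserved` organisms are read from each row's
#'   `outcomes`).
#' @return The filtered solutions tibble.
#' @export
strict_presence_filter <- function(solutions, models = NULL) {
  if (!nrow(solutions)) return(solutions)
  if (!is.null(models)) {
    pass <- vapply(seq_len(nrow(solutions)), function(i) {
      out <- solutions$outcomes[[i]]
      cons <- out$organism_id[out$role == "conserved"]
      ids <- solutions$reaction_ids[[i]]
      all(vapply(cons, function(org) {
        all(ids %in% models[[org]]$reactions$reaction_id)
      }, logical(1)))
    }, logical(1))
    solutions$step4_pass <- pass
  }
  dplyr::filter(solutions, .data$step4_pass)
}

#' Screen all cases of a model collection
#'
#' Runs the case engine end to end: for every case, intersect the
#' targeted organisms' lethal-set collections, drop candidates lethal to
#' any conserved organism in its most vulnerable state, and flag strict
#' presence. Knockout growth values are memoized across cases.
#'
#' @param models Named list of [metabolic_model()]s.
#' @param lethal_sets Tibble of enumerated minimal lethal sets for all
#'   models (bound rows of [enumerate_lethal_sets()] output).
#' @param media Named list of [medium_spec()]s with `"R-H"` and `"M-L"`.
#' @param cases Optional subset of [generate_cases()] output; defaults to
#'   all cases over `names(models)`.
#' @inheritParams filter_conserved_neutral
#' @return Solutions tibble covering all cases (step-3 output; apply
#'   [strict_presence_filter()] for step 4).
#' @export
screen_cases <- function(models, lethal_sets, media, cases = NULL,
                         threshold_frac = 0.01, threshold_abs = 1e-6) {
  stopifnot(is.list(models), !is.null(names(models)))
  if (is.null(cases)) cases <- generate_cases(names(models))
  cache <- new.env(parent = emptyenv())
  out <- lapply(seq_len(nrow(cases)), function(i) {
    case <- cases[i, ]
    cand <- common_targeted_solutions(case, lethal_sets)
    filter_conserved_neutral(cand, case, models, media,
                             threshold_frac, threshold_abs, cache = cache)
  })
  dplyr::bind_rows(out)
}
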