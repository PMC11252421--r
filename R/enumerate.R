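#' Candidate reaction space for lethality enumeration
#'
#' Drug-targetable candidates are the gene-associated internal reactions:
#' exchange, demand and sink pseudo-reactions, spontaneous (enzyme-free)
#' reactions, passive diffusion reactions and reactions without a GPR are
#' excluded, which also removes trivial and non-actionable knockouts from
#' the search space.
#'
#' @param model A [metabolic_model()].
#' @return Lexicographically sorted character vector of reaction IDs.
#' @export
candidate_space <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  keep <- rx$reaction_class == "internal" &
    !is.na(rx$gpr) & trimws(rx$gpr) != ""
  sort(rx$reaction_id[keep])
}

set_key <- function(ids) paste(sort(ids), collapse = "+")

lethal_set_tibble <- function(model_id, medium_name, sets) {
  if (!length(sets)) {
    return(tibble::tibble(model_id = character(), medium = character(),
                          order = integer(), reactions = character(),
                          reaction_ids = list()))
  }
  sets <- lapply(sets, sort)
  tb <- tibble::tibble(
    model_id = model_id,
    medium = medium_name,
    order = vapply(sets, length, integer(1)),
    reactions = vapply(sets, paste, character(1), collapse = "+"),
    reaction_ids = sets
  )
  dplyr::arrange(dplyr::distinct(tb, .data$reactions, .keep_all = TRUE),
                 .data$order, .data$reactions)
}

# Drop recorded sets that strictly contain another recorded set, then
# verify minimality of the survivors directly: every proper subset must be
# viable. `grow_fun(ids)` returns knockout growth on the conditioned model.
minimalize_sets <- function(sets, grow_fun, thr) {
  if (!length(sets)) return(sets)
  keys <- vapply(sets, set_key, character(1))
  sets <- sets[!duplicated(keys)]
  ord <- order(vapply(sets, length, integer(1)))
  sets <- sets[ord]
  kept <- list()
  for (s in sets) {
    if (any(vapply(kept, function(k) all(k %in% s), logical(1)))) next
    kept[[length(kept) + 1L]] <- s
  }
  ok <- vapply(kept, function(s) {
    if (length(s) == 1L) return(TRUE)
    subsets <- lapply(seq_along(s), function(i) s[-i])
    all(vapply(subsets, function(ss) grow_fun(ss) >= thr, logical(1)))
  }, logical(1))
  kept[ok]
}

#' Enumerate minimal lethal reaction sets by depth-first search
#'
#' Finds every minimal set of up to `max_order` candidate reactions whose
#' joint knockout abolishes growth under `medium`. The search descends
#' from the empty set; at each viable node it computes a
#' 1-norm-minimizing optimal flux distribution of the reduced model and
#' branches only on candidate reactions carrying flux there — a further
#' knockout can only abolish growth if it cuts every optimal flux pattern,
#' so any lethal extension must intersect that support. Supersets of
#' already-recorded lethal sets are pruned, and minimality of every
#' recorded set is verified post hoc by testing all proper subsets.
#'
#' Enumeration is conventionally run only under the rich/high-oxygen
#' medium: when the four media nest, any set lethal there is lethal in the
#' other three.
#'
#' @param model A [metabolic_model()] (medium bounds not yet applied).
#' @param medium A [medium_spec()]; the wild type must grow in it.
#' @param max_order Maximum set size, 1 to 4.
#' @param threshold_frac,threshold_abs Lethality threshold, see
#'   [is_lethal()].
#' @param prune Use flux-support pruning (default). `FALSE` branches on
#'   every remaining candidate in lexicographic order — exhaustive, slow,
#'   and useful only to cross-check the pruning.
#' @param candidates Optional subset of the candidate space to search.
#' @return A tibble with columns `model_id`, `medium`, `order`,
#'   `reactions` (sorted IDs joined by `"+"`), and list-column
#'   `reaction_ids`, sorted by order then reactions.
#' @export
enumerate_lethal_sets <- function(model, medium, max_order = 4,
                                  threshold_frac = 0.01,
                                  threshold_abs = 1e-6,
                                  prune = TRUE, candidates = NULL) {
  stopifnot(inherits(model, "metabolic_model"), max_order >= 1, max_order <= 4)
  conditioned <- apply_medium(model, medium)
  wt <- optimize_growth(conditioned)
  if (wt$status != "optimal" || wt$growth <= 0) {
    stop("model '", model$model_id, "' cannot grow in medium '", medium$name,
         "'; enumeration requires a growing wild type", call. = FALSE)
  }
  thr <- max(threshold_frac * wt$growth, threshold_abs)
  cand <- candidates %||% candidate_space(model)
  cand <- sort(intersect(cand, candidate_space(model)))

  grow <- function(ids) {
    g <- knockout_growth(conditioned, ids)
    if (g$status == "optimal") g$growth else 0
  }
  support <- function(ids, growth) {
    red <- conditioned
    hit <- red$reactions$reaction_id %in% ids
    red$reactions$lower_bound[hit] <- 0
    red$reactions$upper_bound[hit] <- 0
    v <- minimal_norm_flux(red, growth)
    if (is.null(v)) v <- knockout_growth(conditioned, ids)$fluxes
    names(v)[abs(v) > 1e-6]
  }

  found <- list()
  visited <- new.env(parent = emptyenv())
  superset_of_found <- function(ids) {
    any(vapply(found, function(f) all(f %in% ids), logical(1)))
  }

  dfs <- function(partial, growth) {
    pool <- if (prune) {
      sort(setdiff(intersect(cand, support(partial, growth)), partial))
    } else {
      if (length(partial)) cand[cand > max(partial)] else cand
    }
    for (r in pool) {
      nxt <- c(partial, r)
      key <- set_key(nxt)
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      if (superset_of_found(nxt)) next
      g <- grow(nxt)
      if (g < thr) {
        found[[length(found) + 1L]] <<- sort(nxt)
      } else if (length(nxt) < max_order) {
        dfs(nxt, g)
      }
    }
  }
  dfs(character(0), wt$growth)

  found <- minimalize_sets(found, grow, thr)
  lethal_set_tibble(model$model_id, medium$name, found)
}

#' Enumerate minimal lethal sets by exhaustive subset testing
#'
#' The independent oracle for [enumerate_lethal_sets()]: tests every
#' candidate subset of size 1 to `max_order` in increasing order, skipping
#' supersets of sets already found, and verifies minimality explicitly.
#' Refuses candidate spaces requiring more than `max_tests` subset
#' evaluations unless `force = TRUE`.
#'
#' @inheritParams enumerate_lethal_sets
#' @param max_tests Guard on the number of subsets examined
#'   (default 20000, roughly 40 candidates at order 3 or 15 at order 4).
#' @param force Override the guard.
#' @return Same shape as [enumerate_lethal_sets()].
#' @export
brute_force_lethal_sets <- function(model, medium, max_order = 4,
                                    threshold_frac = 0.01,
                                    threshold_abs = 1e-6,
                                    candidates = NULL,
                                    max_tests = 20000, force = FALSE) {
  stopifnot(inherits(model, "metabolic_model"), max_order >= 0, max_order <= 4)
  conditioned <- apply_medium(model, medium)
  wt <- optimize_growth(conditioned)
  if (wt$status != "optimal" || wt$growth <= 0) {
    stop("model '", model$model_id, "' cannot grow in medium '", medium$name,
         "'", call. = FALSE)
  }
  thr <- max(threshold_frac * wt$growth, threshold_abs)
  cand <- candidates %||% candidate_space(model)
  cand <- sort(intersect(cand, candidate_space(model)))
  if (max_order == 0 || !length(cand)) {
    return(lethal_set_tibble(model$model_id, medium$name, list()))
  }
  n_tests <- sum(vapply(seq_len(min(max_order, length(cand))),
                        function(k) choose(length(cand), k), numeric(1)))
  if (n_tests > max_tests && !force) {
    stop("brute force would test ", format(n_tests, big.mark = ","),
         " subsets (> ", max_tests, "); pass force = TRUE to override",
         call. = FALSE)
  }
  grow <- function(ids) {
    g <- knockout_growth(conditioned, ids)
    if (g$status == "optimal") g$growth else 0
  }
  found <- list()
  for (k in seq_len(min(max_order, length(cand)))) {
    combos <- utils::combn(cand, k, simplify = FALSE)
    for (s in combos) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1)))) next
      if (grow(s) < thr) found[[length(found) + 1L]] <- s
    }
  }
  found <- minimalize_sets(found, grow, thr)
  lethal_set_tibble(model$model_id, medium$name, found)
}
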