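#' Flux balance analysis: optimal growth
#'
#' Solves the FBA linear program
#' \deqn{\max_v\ c^\top v \quad \text{s.t.}\quad S v = 0,\ lb \le v \le ub,}
#' where the objective picks out the biomass reaction. The package carries
#' its own two-phase simplex; non-finite bounds are clamped to
#' `bound_cap` before solving.
#'
#' @param model A [metabolic_model()], usually after [apply_medium()].
#' @param tol Growth values below `tol` are reported as 0.
#' @param bound_cap Magnitude replacing infinite bounds.
#' @return A `flux_solution`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `growth` (objective value, 1/h; `NA` when
#'   infeasible) and `fluxes` (named numeric vector, mmol/gDW/h).
#' @export
optimize_growth <- function(model, tol = 1e-9, bound_cap = 1e6) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  lb <- pmax(rx$lower_bound, -bound_cap)
  ub <- pmin(rx$upper_bound, bound_cap)
  obj <- as.numeric(rx$reaction_id == model$objective_reaction_id)
  res <- lp_solve(obj, as.matrix(model$S), lb = lb, ub = ub, maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(list(status = "infeasible", growth = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, nrow(rx)),
                                                   rx$reaction_id)),
                     class = "flux_solution"))
  }
  growth <- res$objective
  if (abs(growth) < tol) growth <- 0
  structure(
    list(status = "optimal", growth = growth,
         fluxes = stats::setNames(res$solution, rx$reaction_id)),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      if (x$status == "optimal") sprintf(", growth: %.6g 1/h", x$growth),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble with columns `reaction_id`, `flux`.
#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble::tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes))
}

#' Growth after knocking out a reaction set
#'
#' Sets both bounds of every named reaction to zero and re-optimizes. The
#' input model is unchanged.
#'
#' @param model A [metabolic_model()].
#' @param reaction_set Character vector of reaction IDs (possibly empty).
#' @param ... Passed to [optimize_growth()].
#' @return A `flux_solution`.
#' @export
knockout_growth <- function(model, reaction_set, ...) {
  stopifnot(inherits(model, "metabolic_model"))
  reaction_set <- unique(as.character(reaction_set))
  unknown <- setdiff(reaction_set, model$reactions$reaction_id)
  if (length(unknown)) {
    stop("unknown reaction ID(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hit <- model$reactions$reaction_id %in% reaction_set
  model$reactions$lower_bound[hit] <- 0
  model$reactions$upper_bound[hit] <- 0
  optimize_growth(model, ...)
}

#' Lethality of a knockout under a medium
#'
#' A knockout is lethal when its growth falls below
#' `max(threshold_frac * wild-type growth, threshold_abs)`; growth exactly
#' at the threshold is non-lethal. The 1%-of-wild-type rule is the
#' prevailing convention in essentiality screens; the absolute floor
#' guards against vanishing wild-type growth.
#'
#' @param model A [metabolic_model()] (without medium bounds applied).
#' @param reaction_set Reaction IDs to knock out jointly.
#' @param medium A [medium_spec()].
#' @param threshold_frac Fraction of wild-type growth, default 0.01.
#' @param threshold_abs Absolute growth floor, 1/h, default 1e-6.
#' @return A `lethality_verdict`: list with `reaction_set`, `medium`,
#'   `wild_type_growth`, `knockout_growth`, `lethal`.
#' @export
is_lethal <- function(model, reaction_set, medium,
                      threshold_frac = 0.01, threshold_abs = 1e-6) {
  conditioned <- apply_medium(model, medium)
  wt <- optimize_growth(conditioned)
  if (wt$status != "optimal" || wt$growth <= 0) {
    stop("model '", model$model_id, "' cannot grow in medium '",
         medium$name, "'", call. = FALSE)
  }
  ko <- knockout_growth(conditioned, reaction_set)
  g <- if (ko$status == "optimal") ko$growth else 0
  thr <- max(threshold_frac * wt$growth, threshold_abs)
  structure(
    list(reaction_set = sort(unique(as.character(reaction_set))),
         medium = medium$name,
         wild_type_growth = wt$growth,
         knockout_growth = g,
         lethal = g < thr),
    class = "lethality_verdict"
  )
}

#' @export
print.lethality_verdict <- function(x, ...) {
  cat("<lethality_verdict> {", paste(x$reaction_set, collapse = ", "),
      "} under ", x$medium, ": ",
      if (x$lethal) "LETHAL" else "viable",
      sprintf(" (KO %.4g vs WT %.4g)", x$knockout_growth,
              x$wild_type_growth), "\n", sep = "")
  invisible(x)
}

# Optimal flux distribution with minimal total flux (1-norm) at a fixed
# growth level: fix the biomass flux at `growth`, split v = p - q with
# p, q >= 0 and minimize sum(p + q). Used by the lethal-set DFS to shrink
# the branching support; any optimal distribution would be sound, the
# 1-norm-minimal one is just small.
minimal_norm_flux <- function(model, growth, bound_cap = 1e6) {
  rx <- model$reactions
  n <- nrow(rx)
  lb <- pmax(rx$lower_bound, -bound_cap)
  ub <- pmin(rx$upper_bound, bound_cap)
  i_obj <- match(model$objective_reaction_id, rx$reaction_id)
  lb[i_obj] <- growth - max(1e-9, 1e-9 * abs(growth))
  S <- as.matrix(model$S)
  S2 <- cbind(S, -S)
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  obj2 <- rep(-1, 2 * n)   # maximize -(sum p + sum q)
  res <- lp_solve(obj2, S2, lb = lb2, ub = ub2, maximize = TRUE)
  if (res$status != "optimal") return(NULL)
  v <- res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
  stats::setNames(v, rx$reaction_id)
}
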