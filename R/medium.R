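#' Medium specification
#'
#' A medium is a named nutrient/oxygen bound profile. The screen uses four:
#' rich or minimal nutrients crossed with high or low oxygen uptake
#' (`R-H`, `R-L`, `M-H`, `M-L`). `R-H` is the most resilient state of a
#' cell and `M-L` its most vulnerable; because the minimal nutrient set is
#' a subset of the rich one and low oxygen uptake is below high, the
#' feasible flux region under `M-L` is contained in that under `R-H`, so
#' any knockout lethal under `R-H` is lethal under the other three media.
#'
#' @param name Medium name, conventionally one of `"R-H"`, `"R-L"`,
#'   `"M-H"`, `"M-L"`.
#' @param nutrients Character vector of exchange reaction IDs opened for
#'   uptake (oxygen excluded; it has its own bound).
#' @param uptake Maximum uptake rate applied to every nutrient exchange,
#'   mmol/gDW/h (non-negative; imposed as a negative lower bound).
#' @param oxygen Maximum oxygen uptake rate, mmol/gDW/h.
#' @param oxygen_exchange Exchange reaction ID for oxygen.
#'
#' @return A `medium_spec` object.
#' @export
medium_spec <- function(name, nutrients, uptake = 10, oxygen = 20,
                        oxygen_exchange = "EX_o2_e") {
  stopifnot(is.character(name), length(name) == 1,
            is.character(nutrients),
            uptake >= 0, oxygen >= 0)
  structure(
    list(name = name, nutrients = unique(nutrients), uptake = uptake,
         oxygen = oxygen, oxygen_exchange = oxygen_exchange),
    class = "medium_spec"
  )
}

#' @export
print.medium_spec <- function(x, ...) {
  cat("<medium_spec> ", x$name, ": ", length(x$nutrients),
      " nutrient exchanges @ ", x$uptake, ", oxygen ", x$oxygen,
      " (", x$oxygen_exchange, ")\n", sep = "")
  invisible(x)
}

#' Read a medium configuration file
#'
#' The file (JSON or YAML) maps medium names to
#' `{nutrients: [exchange IDs], uptake: number, oxygen: number}` with an
#' optional per-medium or top-level `oxygen_exchange` key. Nothing about a
#' medium is hard-coded in the package; the rich/minimal compositions and
#' the high/low oxygen rates all live in this file.
#'
#' @param path Path to the JSON or YAML configuration.
#' @return Named list of [medium_spec()] objects.
#' @export
read_medium_config <- function(path) {
  if (!file.exists(path)) stop("medium config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  top_oxex <- cfg$oxygen_exchange %||% "EX_o2_e"
  cfg$oxygen_exchange <- NULL
  media <- purrr::imap(cfg, function(m, nm) {
    medium_spec(
      name = nm,
      nutrients = as.character(unlist(m$nutrients)),
      uptake = as.numeric(m$uptake %||% 10),
      oxygen = as.numeric(m$oxygen %||% 20),
      oxygen_exchange = m$oxygen_exchange %||% top_oxex
    )
  })
  check_medium_nesting(media)
  media
}

# Warn (not error) when the conventional four media do not nest: the
# R-H-only enumeration shortcut is only valid under nesting.
check_medium_nesting <- function(media) {
  if (all(c("R-H", "M-L") %in% names(media))) {
    rh <- media[["R-H"]]; ml <- media[["M-L"]]
    if (!all(ml$nutrients %in% rh$nutrients) || ml$oxygen > rh$oxygen ||
        ml$uptake > rh$uptake) {
      warning("media do not nest: M-L is not contained in R-H; ",
              "R-H-only lethality enumeration is not sound for this config",
              call. = FALSE)
    }
  }
  invisible(media)
}

#' The four standard media for a model
#'
#' Convenience constructor for the rich/minimal x high/low-oxygen media
#' used throughout the screen. The rich medium opens every nutrient in
#' `rich_nutrients`, the minimal medium only `minimal_nutrients` (which
#' must be a subset).
#'
#' @param rich_nutrients,minimal_nutrients Exchange reaction IDs.
#' @param uptake Nutrient uptake rate, mmol/gDW/h (default 10).
#' @param oxygen_high,oxygen_low High/low oxygen uptake rates,
#'   mmol/gDW/h (defaults 20 and 0.1).
#' @param oxygen_exchange Oxygen exchange reaction ID.
#' @return Named list of four [medium_spec()] objects
#'   (`R-H`, `R-L`, `M-H`, `M-L`).
#' @export
standard_media <- function(rich_nutrients, minimal_nutrients, uptake = 10,
                           oxygen_high = 20, oxygen_low = 0.1,
                           oxygen_exchange = "EX_o2_e") {
  if (!all(minimal_nutrients %in% rich_nutrients)) {
    stop("minimal nutrient set must be a subset of the rich set",
         call. = FALSE)
  }
  if (oxygen_low > oxygen_high) {
    stop("low oxygen uptake must not exceed high oxygen uptake", call. = FALSE)
  }
  list(
    "R-H" = medium_spec("R-H", rich_nutrients, uptake, oxygen_high, oxygen_exchange),
    "R-L" = medium_spec("R-L", rich_nutrients, uptake, oxygen_low, oxygen_exchange),
    "M-H" = medium_spec("M-H", minimal_nutrients, uptake, oxygen_high, oxygen_exchange),
    "M-L" = medium_spec("M-L", minimal_nutrients, uptake, oxygen_low, oxygen_exchange)
  )
}

#' Impose a medium on a model
#'
#' Sets the lower bound of every exchange reaction: `-uptake` for
#' nutrients named by the medium, `-oxygen` for the oxygen exchange, and 0
#' for every other exchange (no uptake). Secretion (upper bounds) and all
#' internal reaction bounds are untouched. The input model is not mutated.
#'
#' @param model A [metabolic_model()].
#' @param medium A [medium_spec()].
#' @return A new `metabolic_model` with the medium's bounds applied and a
#'   `medium` attribute recording the medium name.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metabolic_model"), inherits(medium, "medium_spec"))
  rx <- model$reactions
  is_ex <- rx$reaction_class == "exchange"
  if (!medium$oxygen_exchange %in% rx$reaction_id[is_ex]) {
    stop("oxygen exchange '", medium$oxygen_exchange,
         "' absent from model '", model$model_id, "'", call. = FALSE)
  }
  missing <- setdiff(medium$nutrients, rx$reaction_id[is_ex])
  if (length(missing)) {
    warning("medium '", medium$name, "': ", length(missing),
            " exchange ID(s) absent from model '", model$model_id,
            "' were skipped: ", paste(utils::head(missing, 5), collapse = ", "),
            call. = FALSE)
  }
  lb <- rx$lower_bound
  lb[is_ex] <- 0
  lb[is_ex & rx$reaction_id %in% medium$nutrients] <- -medium$uptake
  lb[rx$reaction_id == medium$oxygen_exchange] <- -medium$oxygen
  model$reactions$lower_bound <- lb
  attr(model, "medium") <- medium$name
  model
}
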