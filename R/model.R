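#' Constraint-based metabolic model
#'
#' A `metabolic_model` bundles the stoichiometry, flux bounds,
#' gene-protein-reaction (GPR) rules, subsystem labels and reaction-class
#' flags of a genome-scale (or toy) metabolic network, together with the
#' biomass objective used by flux balance analysis. The stoichiometric
#' matrix is assembled once at construction as a sparse
#' [Matrix::sparseMatrix()] (metabolites x reactions) and reused by every
#' growth computation; bound edits such as [apply_medium()] and reaction
#' knockouts never touch it.
#'
#' @param model_id Character scalar naming the model (e.g. `"iML1515"`).
#' @param metabolites Tibble with columns `metabolite_id`, `compartment`.
#' @param reactions Tibble with columns `reaction_id`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem`, `reaction_class`, and a list-column
#'   `stoichiometry` of named numeric vectors (metabolite -> coefficient).
#' @param objective_reaction_id Reaction carrying the biomass objective.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, metabolites, reactions,
                            objective_reaction_id) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stopifnot(is.character(model_id), length(model_id) == 1)
  if (anyDuplicated(reactions$reaction_id)) {
    dup <- unique(reactions$reaction_id[duplicated(reactions$reaction_id)])
    stop("duplicate reaction IDs in model '", model_id, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!objective_reaction_id %in% reactions$reaction_id) {
    stop("objective reaction '", objective_reaction_id,
         "' not found in model '", model_id, "'", call. = FALSE)
  }
  if (any(reactions$lower_bound > reactions$upper_bound)) {
    bad <- reactions$reaction_id[reactions$lower_bound > reactions$upper_bound]
    stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  refd <- unique(unlist(lapply(reactions$stoichiometry, names)))
  missing_met <- setdiff(refd, metabolites$metabolite_id)
  if (length(missing_met)) {
    stop("reactions reference unknown metabolites: ",
         paste(utils::head(missing_met, 5), collapse = ", "), call. = FALSE)
  }
  classes <- c("internal", "exchange", "demand", "sink", "spontaneous",
               "diffusion")
  if (!all(reactions$reaction_class %in% classes)) {
    stop("invalid reaction_class values", call. = FALSE)
  }
  boundary <- reactions$reaction_class %in% c("exchange", "demand", "sink")
  n_met <- vapply(reactions$stoichiometry, length, integer(1))
  if (any(boundary & n_met != 1L)) {
    bad <- reactions$reaction_id[boundary & n_met != 1L]
    stop("boundary reactions must touch exactly one metabolite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  S <- build_stoich_matrix(metabolites$metabolite_id, reactions)
  structure(
    list(model_id = model_id,
         metabolites = metabolites,
         reactions = reactions,
         objective_reaction_id = objective_reaction_id,
         S = S),
    class = "metabolic_model"
  )
}

build_stoich_matrix <- function(met_ids, reactions) {
  i <- unlist(lapply(reactions$stoichiometry, function(s) match(names(s), met_ids)))
  j <- rep(seq_len(nrow(reactions)),
           vapply(reactions$stoichiometry, length, integer(1)))
  x <- unlist(reactions$stoichiometry, use.names = FALSE)
  Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(met_ids), nrow(reactions)),
    dimnames = list(met_ids, reactions$reaction_id)
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cls <- table(x$reactions$reaction_class)
  cat("<metabolic_model> ", x$model_id, "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", nrow(x$reactions), " (",
      paste(sprintf("%s %d", names(cls), as.integer(cls)), collapse = ", "),
      ")\n",
      "  objective:   ", x$objective_reaction_id, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metabolic model into its reaction table
#'
#' @param x A `metabolic_model`.
#' @param ... Unused.
#' @return A tibble, one row per reaction, with an extra `equation` column
#'   giving a human-readable stoichiometric equation.
#' @method tidy metabolic_model
#' @export
tidy.metabolic_model <- function(x, ...) {
  eq <- vapply(x$reactions$stoichiometry, format_equation, character(1))
  dplyr::mutate(
    dplyr::select(x$reactions, -"stoichiometry"),
    equation = eq, .after = "reaction_id"
  )
}

format_equation <- function(s) {
  lhs <- s[s < 0]
  rhs <- s[s > 0]
  term <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v), paste0(abs(v), " ", names(v))),
          collapse = " + ")
  }
  paste(term(lhs), "-->", term(rhs))
}

# --- reaction classification ------------------------------------------------

#' Classify reactions by BiGG-style conventions
#'
#' Boundary pseudo-reactions are recognised by ID prefix (`EX_` exchange,
#' `DM_` demand, `SK_` sink); reactions whose GPR consists solely of the
#' spontaneous-gene token (BiGG `s0001`) are flagged spontaneous; reactions
#' named in `diffusion_ids` are flagged diffusion. Everything else is
#' internal.
#'
#' @param reactions Tibble with at least `reaction_id` and `gpr` columns.
#' @param spontaneous_gene Token marking enzyme-free reactions.
#' @param diffusion_ids Character vector of reaction IDs to flag as passive
#'   diffusion (no operational definition exists in BiGG; supply your own
#'   list).
#' @return The tibble with a `reaction_class` column added or replaced.
#' @export
classify_reactions <- function(reactions, spontaneous_gene = "s0001",
                               diffusion_ids = character()) {
  id <- reactions$reaction_id
  gpr <- gsub("[()\\s]", "", reactions$gpr %||% "", perl = TRUE)
  cls <- dplyr::case_when(
    startsWith(id, "EX_") ~ "exchange",
    startsWith(id, "DM_") ~ "demand",
    startsWith(id, "SK_") ~ "sink",
    id %in% diffusion_ids ~ "diffusion",
    gpr == spontaneous_gene ~ "spontaneous",
    .default = "internal"
  )
  dplyr::mutate(reactions, reaction_class = cls)
}

# --- BiGG JSON --------------------------------------------------------------

#' Read a constraint-based model
#'
#' Reads BiGG-style JSON (the native format of the BiGG model repository)
#' or SBML Level 3 with the FBC package. Reaction classes are inferred with
#' [classify_reactions()].
#'
#' @param path Path to the model file.
#' @param format `"bigg-json"` or `"sbml"`; `"auto"` guesses from the file
#'   extension.
#' @param model_id Optional override for the model's ID.
#' @param diffusion_ids Reaction IDs to flag as diffusion, passed through to
#'   [classify_reactions()].
#' @param spontaneous_gene Spontaneous-gene token, default BiGG's `"s0001"`.
#' @param default_bound Magnitude used to replace non-finite bounds.
#' @return A [metabolic_model()].
#' @export
read_metabolic_model <- function(path, format = c("auto", "bigg-json", "sbml"),
                                 model_id = NULL,
                                 diffusion_ids = character(),
                                 spontaneous_gene = "s0001",
                                 default_bound = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "bigg-json"
              else "sbml"
  }
  switch(format,
    "bigg-json" = read_bigg_json(path, model_id, diffusion_ids,
                                 spontaneous_gene, default_bound),
    "sbml" = read_sbml_fbc(path, model_id, diffusion_ids,
                           spontaneous_gene, default_bound)
  )
}

read_bigg_json <- function(path, model_id, diffusion_ids, spontaneous_gene,
                           default_bound) {
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) stop("cannot parse BiGG JSON '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$reactions)) {
    stop("BiGG JSON '", path, "' has no 'reactions' element", call. = FALSE)
  }
  mets <- tibble::tibble(
    metabolite_id = vapply(doc$metabolites, function(m) m$id, character(1)),
    compartment = vapply(doc$metabolites,
                         function(m) m$compartment %||% NA_character_,
                         character(1))
  )
  rxns <- tibble::tibble(
    reaction_id = vapply(doc$reactions, function(r) r$id, character(1)),
    lower_bound = vapply(doc$reactions,
                         function(r) as.numeric(r$lower_bound %||% -default_bound),
                         numeric(1)),
    upper_bound = vapply(doc$reactions,
                         function(r) as.numeric(r$upper_bound %||% default_bound),
                         numeric(1)),
    gpr = vapply(doc$reactions,
                 function(r) r$gene_reaction_rule %||% "", character(1)),
    subsystem = vapply(doc$reactions,
                       function(r) r$subsystem %||% NA_character_, character(1)),
    stoichiometry = lapply(doc$reactions, function(r) {
      s <- unlist(r$metabolites)
      if (is.null(s)) stats::setNames(numeric(0), character(0)) else s
    })
  )
  rxns$lower_bound[!is.finite(rxns$lower_bound)] <- -default_bound
  rxns$upper_bound[!is.finite(rxns$upper_bound)] <- default_bound
  rxns <- classify_reactions(rxns, spontaneous_gene, diffusion_ids)

  obj <- NULL
  coef <- vapply(doc$reactions,
                 function(r) as.numeric(r$objective_coefficient %||% 0),
                 numeric(1))
  if (any(coef != 0)) obj <- rxns$reaction_id[which(coef != 0)[1]]
  if (is.null(obj)) {
    hit <- grep("biomass", rxns$reaction_id, ignore.case = TRUE, value = TRUE)
    if (length(hit)) obj <- hit[1]
  }
  if (is.null(obj)) {
    stop("no objective (biomass) reaction declared in '", path, "'",
         call. = FALSE)
  }
  metabolic_model(model_id %||% doc$id %||% tools::file_path_sans_ext(basename(path)),
                  mets, rxns, obj)
}

#' Write a model as BiGG-style JSON
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bigg_json <- function(model, path) {
  rx <- model$reactions
  doc <- list(
    id = model$model_id,
    metabolites = purrr::pmap(model$metabolites, function(metabolite_id, compartment) {
      list(id = metabolite_id, compartment = compartment)
    }),
    reactions = lapply(seq_len(nrow(rx)), function(i) {
      list(
        id = rx$reaction_id[i],
        metabolites = as.list(rx$stoichiometry[[i]]),
        lower_bound = rx$lower_bound[i],
        upper_bound = rx$upper_bound[i],
        gene_reaction_rule = rx$gpr[i],
        subsystem = rx$subsystem[i],
        objective_coefficient =
          as.numeric(rx$reaction_id[i] == model$objective_reaction_id)
      )
    }),
    genes = list()
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

# --- SBML L3 FBC ------------------------------------------------------------

read_sbml_fbc <- function(path, model_id, diffusion_ids, spontaneous_gene,
                          default_bound) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(mod)) stop("no <model> element in '", path, "'", call. = FALSE)

  params <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(mod, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gps, "label"),
                            xml2::xml_attr(gps, "id"))

  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  sp_boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- tibble::tibble(
    metabolite_id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment")
  )[!sp_boundary, ]
  boundary_species <- xml2::xml_attr(sp, "id")[sp_boundary]

  rnodes <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  parse_side <- function(rn, xp, sign) {
    refs <- xml2::xml_find_all(rn, xp, ns)
    if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                    xml2::xml_attr(refs, "species"))
  }
  gpr_of <- function(rn) {
    assoc <- xml2::xml_find_first(rn, ".//fbc:geneProductAssociation", ns)
    if (is.na(assoc)) return("")
    render <- function(node) {
      nm <- xml2::xml_name(node)
      if (nm == "geneProductRef") {
        id <- xml2::xml_attr(node, "geneProduct")
        lbl <- glabel[[id]]
        if (is.null(lbl) || is.na(lbl)) id else lbl
      } else if (nm %in% c("and", "or")) {
        kids <- vapply(xml2::xml_children(node), render, character(1))
        paste0("(", paste(kids, collapse = paste0(" ", nm, " ")), ")")
      } else {
        ""
      }
    }
    out <- render(xml2::xml_child(assoc))
    gsub("^\\((.*)\\)$", "\\1", out)
  }
  bound_of <- function(rn, attr, fallback) {
    ref <- xml2::xml_attr(rn, attr)
    if (is.na(ref)) return(fallback)
    v <- pval[[ref]]
    if (is.null(v) || !is.finite(v)) fallback else v
  }
  rxns <- tibble::tibble(
    reaction_id = xml2::xml_attr(rnodes, "id"),
    lower_bound = vapply(rnodes, bound_of, numeric(1),
                         attr = "lowerFluxBound", fallback = -default_bound),
    upper_bound = vapply(rnodes, bound_of, numeric(1),
                         attr = "upperFluxBound", fallback = default_bound),
    gpr = vapply(rnodes, gpr_of, character(1)),
    subsystem = NA_character_,
    stoichiometry = lapply(rnodes, function(rn) {
      s <- c(parse_side(rn, ".//s:listOfReactants/s:speciesReference", -1),
             parse_side(rn, ".//s:listOfProducts/s:speciesReference", 1))
      s[!(names(s) %in% boundary_species)]
    })
  )
  # irreversible default when no fbc bound and reversible="false"
  rev_attr <- xml2::xml_attr(rnodes, "reversible")
  no_lb <- is.na(xml2::xml_attr(rnodes, "lowerFluxBound"))
  rxns$lower_bound[no_lb & rev_attr %in% c("false", "0")] <- 0

  # subsystems from the groups package, when present
  groups <- xml2::xml_find_all(mod, ".//g:listOfGroups/g:group", ns)
  for (grp in groups) {
    label <- xml2::xml_attr(grp, "name")
    members <- xml2::xml_attr(
      xml2::xml_find_all(grp, ".//g:listOfMembers/g:member", ns), "idRef")
    rxns$subsystem[rxns$reaction_id %in% members] <- label
  }

  # strip SBML "R_"/"M_" prefixes so IDs line up with BiGG identifiers
  strip <- function(x, p) ifelse(startsWith(x, p), substring(x, nchar(p) + 1), x)
  rxns$reaction_id <- strip(rxns$reaction_id, "R_")
  mets$metabolite_id <- strip(mets$metabolite_id, "M_")
  rxns$stoichiometry <- lapply(rxns$stoichiometry, function(s) {
    stats::setNames(as.numeric(s), strip(names(s), "M_"))
  })

  rxns <- classify_reactions(rxns, spontaneous_gene, diffusion_ids)

  obj_ref <- xml2::xml_attr(
    xml2::xml_find_first(mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns),
    "reaction")
  if (is.na(obj_ref)) {
    stop("no FBC objective declared in '", path, "'", call. = FALSE)
  }
  obj <- strip(obj_ref, "R_")
  metabolic_model(model_id %||% xml2::xml_attr(mod, "id") %||%
                    tools::file_path_sans_ext(basename(path)),
                  mets, rxns, obj)
}

# --- cross-model overlap ----------------------------------------------------

#' Reactions shared by every model of a collection
#'
#' Cross-model identity is exact reaction-ID string equality (BiGG IDs are
#' shared across reconstructions by construction); no fuzzy matching is
#' attempted.
#'
#' @param models A list of [metabolic_model()] objects.
#' @return Sorted character vector of reaction IDs present in every model.
#' @export
common_reactions <- function(models) {
  if (!length(models)) stop("need at least one model", call. = FALSE)
  ids <- lapply(models, function(m) m$reactions$reaction_id)
  sort(Reduce(intersect, ids))
}
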