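#' Specification of a synthetic toy metabolic model
#'
#' Describes a small network whose complete inventory of minimal lethal
#' reaction sets is known by construction, so every stage of the screen can
#' be tested against ground truth. The network is a linear
#' glucose-assimilation chain feeding a hub metabolite; each planted
#' synthetic lethal set of order *k* is realized as *k* parallel,
#' identical-capacity branches that are the only producers of one biomass
#' precursor (no single branch is rate-limiting, so exactly the full branch
#' group is a minimal lethal set); each chain reaction is a planted single
#' essential. Decoy side-reactions drain the hub into secreted waste and
#' can never become limiting. Glucose transport is spontaneous, oxygen
#' transport is passive diffusion, and a demand reaction is included, so
#' the candidate-space exclusion rules are all exercised.
#'
#' @param n_linear_essentials Number of planted single essential reactions
#'   (the chain length).
#' @param sl_orders Integer vector with values in 2..4; one planted minimal
#'   synthetic lethal set per entry, of that order.
#' @param n_decoys Number of non-essential decoy reactions.
#' @param subsystem_labels Pathway labels sampled onto gene-associated
#'   reactions.
#' @param seed Integer seed controlling subsystem assignment.
#' @param model_id Model name.
#' @param id_prefix Prefix prepended to all chain/branch/decoy reaction and
#'   metabolite IDs (used to keep accessory IDs private within families).
#' @return A `toy_model_spec` object.
#' @export
toy_model_spec <- function(n_linear_essentials = 1, sl_orders = 2,
                           n_decoys = 2,
                           subsystem_labels = c("Cell Envelope Biosynthesis",
                                                "Glycolysis/Gluconeogenesis",
                                                "Nucleotide Salvage Pathway",
                                                "Membrane Lipid Metabolism"),
                           seed = 1L, model_id = "toy", id_prefix = "") {
  sl_orders <- as.integer(sl_orders)
  if (length(sl_orders) && (any(sl_orders < 2) || any(sl_orders > 4))) {
    stop("sl_orders must lie in 2..4", call. = FALSE)
  }
  stopifnot(n_linear_essentials >= 0, n_decoys >= 0,
            length(subsystem_labels) >= 1)
  structure(
    list(n_linear_essentials = as.integer(n_linear_essentials),
         sl_orders = sl_orders, n_decoys = as.integer(n_decoys),
         subsystem_labels = subsystem_labels, seed = as.integer(seed),
         model_id = model_id, id_prefix = id_prefix),
    class = "toy_model_spec"
  )
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Internal: reaction-row helper.
toy_rxn <- function(id, stoich, gpr = "", subsystem = NA_character_,
                    lb = 0, ub = 1000) {
  tibble::tibble(reaction_id = id, lower_bound = lb, upper_bound = ub,
                 gpr = gpr, subsystem = subsystem,
                 stoichiometry = list(stoich))
}

# Internal: chain + branch-group + decoy block with IDs under `prefix`,
# rooted at metabolite `root`. Returns reactions, metabolites, the list of
# produced biomass precursors, and the planted truth contributed.
toy_block <- function(spec, prefix, root, gene_offset = 0L) {
  rxns <- list(); mets <- character(); truth <- list()
  labels <- spec$subsystem_labels
  gi <- gene_offset
  gene <- function() { gi <<- gi + 1L; sprintf("g%03d", gi) }
  lab <- function() sample(labels, 1)

  hub <- root
  if (spec$n_linear_essentials > 0) {
    for (j in seq_len(spec$n_linear_essentials)) {
      nxt <- sprintf("%schain%d_c", prefix, j)
      id <- sprintf("%sESS%d", prefix, j)
      rxns[[length(rxns) + 1L]] <- toy_rxn(
        id, stats::setNames(c(-1, 1), c(hub, nxt)), gpr = gene(),
        subsystem = lab())
      mets <- c(mets, nxt)
      truth[[length(truth) + 1L]] <- id
      hub <- nxt
    }
  }
  precursors <- character()
  for (g in seq_along(spec$sl_orders)) {
    o <- spec$sl_orders[g]
    prec <- sprintf("%sprec%d_c", prefix, g)
    mets <- c(mets, prec)
    precursors <- c(precursors, prec)
    grp_lab <- lab()
    ids <- sprintf("%sGRP%d_B%d", prefix, g, seq_len(o))
    for (id in ids) {
      rxns[[length(rxns) + 1L]] <- toy_rxn(
        id, stats::setNames(c(-1, 1), c(hub, prec)), gpr = gene(),
        subsystem = grp_lab)
    }
    truth[[length(truth) + 1L]] <- ids
  }
  if (spec$n_decoys > 0) {
    for (j in seq_len(spec$n_decoys)) {
      rxns[[length(rxns) + 1L]] <- toy_rxn(
        sprintf("%sDCY%d", prefix, j),
        stats::setNames(c(-1, 1), c(hub, "waste_c")),
        gpr = if (j %% 2L == 0L) paste(gene(), "or", gene()) else gene(),
        subsystem = lab())
    }
  }
  list(reactions = dplyr::bind_rows(rxns), metabolites = mets,
       precursors = precursors, hub = hub, truth = truth, gene_max = gi)
}

#' Generate a toy model with planted lethality structure
#'
#' @param spec A [toy_model_spec()].
#' @return A list with elements `model` (a [metabolic_model()]) and
#'   `truth` (list of character vectors: the complete inventory of minimal
#'   lethal reaction sets over the candidate space, up to the max planted
#'   order).
#' @seealso [toy_media()] for the matching four media.
#' @export
generate_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  with_local_seed(spec$seed, {
    block <- toy_block(spec, spec$id_prefix, root = "glc__D_c")
    assemble_toy_model(list(block), spec$model_id)
  })
}

# Internal: wire pre-built chain/branch blocks into a growing model with
# the shared scaffold (exchanges, transports, respiration, demand, biomass).
assemble_toy_model <- function(blocks, model_id) {
  scaffold_mets <- tibble::tibble(
    metabolite_id = c("glc__D_e", "glc__D_c", "o2_e", "o2_c", "aux_e",
                      "nrg_c", "waste_c", "waste_e", "dm_c"),
    compartment = c("e", "c", "e", "c", "e", "c", "c", "e", "c")
  )

  precursors <- unlist(lapply(blocks, `[[`, "precursors"))
  biomass_stoich <- stats::setNames(
    c(rep(-1, length(precursors)), -1),
    c(precursors, "nrg_c")
  )
  scaffold_rxns <- dplyr::bind_rows(
    toy_rxn("EX_glc__D_e", c(glc__D_e = -1), lb = 0),
    toy_rxn("EX_o2_e", c(o2_e = -1), lb = 0),
    toy_rxn("EX_aux_e", c(aux_e = -1), lb = 0),
    toy_rxn("EX_waste_e", c(waste_e = -1), lb = 0),
    toy_rxn("GLCt", c(glc__D_e = -1, glc__D_c = 1), gpr = "s0001"),
    toy_rxn("O2t", c(o2_e = -1, o2_c = 1)),
    toy_rxn("RESP", c(glc__D_c = -1, o2_c = -1, nrg_c = 1), gpr = "s0001"),
    toy_rxn("WASTEt", c(waste_c = -1, waste_e = 1), gpr = "s0001"),
    toy_rxn("DM_dm_c", c(dm_c = -1)),
    toy_rxn("FEED_dm", c(glc__D_c = -1, dm_c = 1), gpr = "s0001"),
    toy_rxn("BIOMASS_toy", biomass_stoich)
  )
  rxns <- dplyr::bind_rows(scaffold_rxns,
                           dplyr::bind_rows(lapply(blocks, `[[`, "reactions")))
  rxns <- classify_reactions(rxns, spontaneous_gene = "s0001",
                             diffusion_ids = "O2t")
  mets <- dplyr::bind_rows(
    scaffold_mets,
    tibble::tibble(
      metabolite_id = unlist(lapply(blocks, `[[`, "metabolites")),
      compartment = "c"
    )
  )
  model <- metabolic_model(model_id, mets, rxns, "BIOMASS_toy")
  truth <- unlist(lapply(blocks, `[[`, "truth"), recursive = FALSE)
  truth <- lapply(truth, sort)
  list(model = model, truth = truth)
}

#' The four standard media matching the toy generator
#'
#' Rich medium: glucose plus an auxiliary nutrient; minimal: glucose only;
#' oxygen uptake 20 (high) / 0.1 (low) mmol/gDW/h, nutrient uptake 10.
#'
#' @inheritParams standard_media
#' @return Named list of four [medium_spec()] objects.
#' @export
toy_media <- function(uptake = 10, oxygen_high = 20, oxygen_low = 0.1) {
  standard_media(
    rich_nutrients = c("EX_glc__D_e", "EX_aux_e"),
    minimal_nutrients = "EX_glc__D_e",
    uptake = uptake, oxygen_high = oxygen_high, oxygen_low = oxygen_low,
    oxygen_exchange = "EX_o2_e"
  )
}

#' Specification of a family of related toy models
#'
#' Emulates a set of phylogenetically related organisms: every member
#' shares the core network (identical reaction IDs), and each member adds
#' private accessory structure (its own chain essentials and planted
#' synthetic lethal branch groups feeding member-private biomass
#' precursors). A member may also carry a private *rescue* bypass of a
#' core branch group: the core group is then no longer lethal in that
#' member (its minimal set grows by the bypass reaction), which creates
#' selective targets composed purely of core reactions — targets that pass
#' the strict presence filter.
#'
#' @param n_models Number of family members (>= 2).
#' @param core A [toy_model_spec()] for the shared core.
#' @param accessory A list of `n_models` [toy_model_spec()]s (or a single
#'   spec recycled) describing each member's private structure.
#' @param rescue_groups A list of `n_models` integer vectors: indices of
#'   core branch groups bypassed in each member (the bypassed group's
#'   order must be at most 3 so the rescued minimal set stays within
#'   order 4). Defaults to member *i* rescuing core group
#'   `((i - 1) %% n_groups) + 1` for members beyond the first, when a core
#'   group of order <= 3 exists.
#' @param seed Integer seed.
#' @return A `toy_family_spec` object.
#' @export
toy_family_spec <- function(n_models = 3, core = toy_model_spec(),
                            accessory = toy_model_spec(
                              n_linear_essentials = 0, sl_orders = 2,
                              n_decoys = 1),
                            rescue_groups = NULL, seed = 1L) {
  stopifnot(n_models >= 2, inherits(core, "toy_model_spec"))
  if (inherits(accessory, "toy_model_spec")) {
    accessory <- rep(list(accessory), n_models)
  }
  stopifnot(length(accessory) == n_models)
  n_groups <- length(core$sl_orders)
  rescuable <- which(core$sl_orders <= 3)
  if (is.null(rescue_groups)) {
    rescue_groups <- lapply(seq_len(n_models), function(i) {
      if (i == 1L || !length(rescuable)) integer() else
        rescuable[((i - 2L) %% length(rescuable)) + 1L]
    })
  }
  stopifnot(length(rescue_groups) == n_models)
  for (rg in rescue_groups) {
    if (length(rg) && (any(rg < 1) || any(rg > n_groups))) {
      stop("rescue_groups indices out of range", call. = FALSE)
    }
    if (length(rg) && any(core$sl_orders[rg] > 3)) {
      stop("cannot rescue a core group of order 4 (rescued set would ",
           "exceed order 4)", call. = FALSE)
    }
  }
  structure(
    list(n_models = as.integer(n_models), core = core,
         accessory = accessory, rescue_groups = rescue_groups,
         seed = as.integer(seed)),
    class = "toy_family_spec"
  )
}

#' Generate a family of related toy models
#'
#' @param spec A [toy_family_spec()].
#' @return A list with elements `models` (named list of
#'   [metabolic_model()]s) and `truths` (named list; per model, the list of
#'   minimal lethal reaction-ID sets over its candidate space).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "toy_family_spec"))
  with_local_seed(spec$seed, {
    models <- list(); truths <- list()
    for (i in seq_len(spec$n_models)) {
      mid <- sprintf("org%02d", i)
      core <- spec$core
      core$id_prefix <- ""
      acc <- spec$accessory[[i]]
      acc$id_prefix <- sprintf("P%02d_", i)

      core_block <- toy_block(core, core$id_prefix, root = "glc__D_c")
      acc_block <- toy_block(acc, acc$id_prefix, root = core_block$hub,
                             gene_offset = 500L + i * 40L)

      # private rescue bypasses of core branch groups
      rg <- spec$rescue_groups[[i]]
      rescue_ids <- character(0)
      if (length(rg)) {
        rescue_ids <- sprintf("%sRSC%d", acc$id_prefix, rg)
        for (k in seq_along(rg)) {
          prec <- sprintf("prec%d_c", rg[k])
          acc_block$reactions <- dplyr::bind_rows(
            acc_block$reactions,
            toy_rxn(rescue_ids[k],
                    stats::setNames(c(-1, 1), c(core_block$hub, prec)),
                    gpr = sprintf("g%03d", 900L + i * 10L + k),
                    subsystem = sample(acc$subsystem_labels, 1))
          )
        }
        # rescued core groups: minimal set = branches + bypass
        for (k in seq_along(rg)) {
          g <- rg[k]
          hit <- which(vapply(core_block$truth, function(s)
            setequal(s, sprintf("GRP%d_B%d", g, seq_len(core$sl_orders[g]))),
            logical(1)))
          core_block$truth[[hit]] <- sort(c(core_block$truth[[hit]],
                                            rescue_ids[k]))
        }
      }

      built <- assemble_toy_model(list(core_block, acc_block), mid)
      models[[mid]] <- built$model
      truths[[mid]] <- built$truth
    }
    list(models = models, truths = truths)
  })
}
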