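# Data model and JSON I/O for strain-level metabolic reconstructions.
#
# A reconstruction is a plain list with class "reconstruction":
#   strain_id           character(1)
#   biomass_reaction_id character(1)
#   metabolites         data.frame(id, compartment, name, is_sulfur)
#   reactions           named list; each element has id, stoichiometry
#                       (named numeric, keys "id[compartment]"), lb, ub,
#                       ec (character vector), subsystem (character(1) or NA)
#
# Metabolite row keys are "id[compartment]" (e.g. "met_L[c]"); stoichiometry
# keys must resolve to declared metabolites. Exchange reactions have exactly
# one metabolite with coefficient -1 ("met ->"): negative flux is uptake,
# positive flux is secretion.

COMPARTMENTS <- c("c", "lu", "d", "fe")

met_key <- function(id, compartment) paste0(id, "[", compartment, "]")

#' Create a metabolite record
#'
#' @param id metabolite identifier (standard short ids, e.g. "met_L").
#' @param compartment one of `"c"` (cytosol), `"lu"` (lumen), `"d"` (diet),
#'   `"fe"` (feces).
#' @param name human-readable name.
#' @param is_sulfur does the compound contain a sulfur atom?
#' @return one-row data.frame.
#' @export
metabolite <- function(id, compartment = "c", name = id, is_sulfur = FALSE) {
  if (!compartment %in% COMPARTMENTS)
    stopf("unknown compartment '%s' for metabolite '%s'", compartment, id)
  if (!is_flag(is_sulfur)) stopf("is_sulfur must be TRUE or FALSE for '%s'", id)
  data.frame(id = id, compartment = compartment, name = name,
             is_sulfur = is_sulfur, stringsAsFactors = FALSE)
}

#' Create a reaction record
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector; keys are `"id[compartment]"`,
#'   negative coefficients are consumed, positive produced.
#' @param lb,ub flux bounds (mmol per person per day; day^-1 for biomass).
#' @param ec optional character vector of EC numbers.
#' @param subsystem optional subsystem label.
#' @return a list describing the reaction.
#' @export
reaction <- function(id, stoichiometry, lb = -1000, ub = 1000,
                     ec = character(0), subsystem = NA_character_) {
  if (length(stoichiometry) == 0L)
    stopf("reaction '%s' has empty stoichiometry", id)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stopf("reaction '%s': stoichiometry must be a named vector", id)
  if (!is.finite(lb) || !is.finite(ub)) stopf("reaction '%s': bounds must be finite", id)
  if (lb > ub) stopf("reaction '%s': lower bound exceeds upper bound", id)
  list(id = id, stoichiometry = stoichiometry, lb = as.numeric(lb),
       ub = as.numeric(ub), ec = as.character(ec), subsystem = subsystem)
}

is_exchange <- function(rxn) length(rxn$stoichiometry) == 1L

#' Assemble and validate a strain-level reconstruction
#'
#' @param strain_id strain identifier.
#' @param metabolites data.frame as produced by row-binding [metabolite()].
#' @param reactions list of [reaction()] records.
#' @param biomass_reaction_id id of the biomass reaction.
#' @return object of class `"reconstruction"`.
#' @export
reconstruction <- function(strain_id, metabolites, reactions, biomass_reaction_id) {
  if (length(reactions) == 0L) stopf("reconstruction '%s' has no reactions", strain_id)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  obj <- structure(list(strain_id = strain_id,
                        biomass_reaction_id = biomass_reaction_id,
                        metabolites = metabolites,
                        reactions = reactions),
                   class = "reconstruction")
  validate_reconstruction(obj)
  obj
}

#' Validate a reconstruction's invariants
#'
#' Checks uniqueness of metabolite keys, resolvability of every stoichiometry
#' key, bound sanity, and presence of the biomass reaction.
#'
#' @param recon a `"reconstruction"`.
#' @return the object, invisibly.
#' @export
validate_reconstruction <- function(recon) {
  mets <- recon$metabolites
  keys <- met_key(mets$id, mets$compartment)
  if (anyDuplicated(keys))
    stopf("duplicate metabolite ids within a compartment: %s",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  if (any(!mets$compartment %in% COMPARTMENTS))
    stopf("unknown compartment codes: %s",
          paste(setdiff(mets$compartment, COMPARTMENTS), collapse = ", "))
  rids <- vapply(recon$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stopf("duplicate reaction ids: %s", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  dangling <- character(0)
  for (rxn in recon$reactions) {
    if (any(!is.finite(rxn$lb)) || any(!is.finite(rxn$ub)) || rxn$lb > rxn$ub)
      stopf("reaction '%s': invalid bounds", rxn$id)
    if (length(rxn$stoichiometry) == 0L)
      stopf("reaction '%s': empty stoichiometry", rxn$id)
    dangling <- c(dangling, setdiff(names(rxn$stoichiometry), keys))
  }
  if (length(dangling))
    stopf("stoichiometry references undeclared metabolites: %s",
          paste(unique(dangling), collapse = ", "))
  if (!recon$biomass_reaction_id %in% rids)
    stopf("biomass reaction '%s' not found among reactions", recon$biomass_reaction_id)
  invisible(recon)
}

#' Read a reconstruction from its JSON dialect
#'
#' The dialect is
#' `{"strain_id", "biomass_reaction_id", "metabolites": [{"id", "compartment",
#' "name", "is_sulfur"}], "reactions": [{"id", "stoichiometry": {...}, "lb",
#' "ub", "ec": [...]}]}`.
#'
#' @param path path to a JSON file.
#' @return a validated `"reconstruction"`.
#' @export
load_reconstruction <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopf("malformed JSON in '%s': %s", path, conditionMessage(e)))
  for (k in c("strain_id", "biomass_reaction_id", "metabolites", "reactions"))
    if (is.null(raw[[k]])) stopf("reconstruction file '%s' is missing key '%s'", path, k)
  mets <- do.call(rbind, lapply(raw$metabolites, function(m) {
    for (k in c("id", "compartment")) if (is.null(m[[k]]))
      stopf("metabolite entry missing key '%s' in '%s'", k, path)
    metabolite(m$id, m$compartment, m$name %||% m$id, isTRUE(m$is_sulfur))
  }))
  rxns <- lapply(raw$reactions, function(r) {
    for (k in c("id", "stoichiometry", "lb", "ub")) if (is.null(r[[k]]))
      stopf("reaction entry missing key '%s' in '%s'", k, path)
    reaction(r$id, unlist(r$stoichiometry), r$lb, r$ub,
             ec = as.character(unlist(r$ec)),
             subsystem = r$subsystem %||% NA_character_)
  })
  reconstruction(raw$strain_id, mets, rxns, raw$biomass_reaction_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reconstruction to its JSON dialect
#'
#' Metabolites, reactions and stoichiometry keys are written in sorted order so
#' that files are diffable and write-then-load is the identity.
#'
#' @param recon a valid `"reconstruction"`.
#' @param path output path.
#' @export
write_reconstruction <- function(recon, path) {
  validate_reconstruction(recon)
  for (rxn in recon$reactions)
    if (any(!is.finite(c(rxn$lb, rxn$ub, rxn$stoichiometry))))
      stopf("reaction '%s' has non-finite entries; refusing to write", rxn$id)
  mets <- recon$metabolites[order(met_key(recon$metabolites$id, recon$metabolites$compartment)), ]
  met_list <- lapply(seq_len(nrow(mets)), function(i)
    list(id = mets$id[i], compartment = mets$compartment[i],
         name = mets$name[i], is_sulfur = mets$is_sulfur[i]))
  rxns <- recon$reactions[order(names(recon$reactions))]
  rxn_list <- lapply(rxns, function(r) {
    s <- r$stoichiometry[order(names(r$stoichiometry))]
    list(id = r$id, stoichiometry = as.list(s), lb = r$lb, ub = r$ub,
         ec = r$ec, subsystem = r$subsystem)
  })
  out <- list(strain_id = recon$strain_id,
              biomass_reaction_id = recon$biomass_reaction_id,
              metabolites = met_list, reactions = unname(rxn_list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Sparse stoichiometric matrix of a model
#'
#' @param model a `"reconstruction"` or `"community_model"`.
#' @return list with `S` (dgCMatrix, rows = metabolite keys, cols = reaction
#'   ids), `lb`, `ub` (named numeric), `mets`, `rxns` (index maps).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- met_key(model$metabolites$id, model$metabolites$compartment)
  rxns <- names(model$reactions)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(model$reactions)) {
    s <- model$reactions[[k]]$stoichiometry
    i <- c(i, match(names(s), mets))
    j <- c(j, rep(k, length(s)))
    x <- c(x, unname(s))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  list(S = S,
       lb = stats::setNames(vapply(model$reactions, `[[`, 0, "lb"), rxns),
       ub = stats::setNames(vapply(model$reactions, `[[`, 0, "ub"), rxns),
       mets = mets, rxns = rxns)
}
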