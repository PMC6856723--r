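# Flux balance analysis and net maximal secretion potentials.

#' Flux balance analysis
#'
#' Optimises the flux through one reaction subject to steady-state mass balance
#' (`S v = 0`) and the model's flux bounds.
#'
#' @param model a `"reconstruction"` or `"community_model"`.
#' @param objective_reaction reaction id to optimise.
#' @param sense `"max"` or `"min"`.
#' @return list with `objective_value`, `fluxes` (named numeric) and `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`). Infeasibility is reported
#'   in `status`, not raised.
#' @export
fba <- function(model, objective_reaction, sense = c("max", "min")) {
  sense <- match.arg(sense)
  sm <- stoichiometric_matrix(model)
  if (!objective_reaction %in% sm$rxns)
    stopf("objective reaction '%s' not in model", objective_reaction)
  obj <- as.numeric(sm$rxns == objective_reaction)
  sol <- solve_lp(sm$S, rep(0, length(sm$mets)), sm$lb, sm$ub, obj,
                  maximize = sense == "max")
  if (sol$status != "optimal")
    return(list(objective_value = NA_real_, fluxes = NULL, status = sol$status))
  list(objective_value = sol$objective,
       fluxes = stats::setNames(sol$x, sm$rxns),
       status = "optimal")
}

# Lexicographic second stage: with the fecal exchange pinned at its optimum,
# minimise total absolute flux so that degenerate diet fluxes are resolved
# deterministically. Variables are split v = p - m, p, m >= 0.
min_total_flux <- function(sm, fixed_id, fixed_value) {
  n <- length(sm$rxns)
  lb <- sm$lb; ub <- sm$ub
  k <- match(fixed_id, sm$rxns)
  lb[k] <- fixed_value; ub[k] <- fixed_value
  S2 <- cbind(as.matrix(sm$S), -as.matrix(sm$S))
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  sol <- solve_lp(S2, rep(0, length(sm$mets)), lb2, ub2, rep(1, 2 * n),
                  maximize = FALSE)
  if (sol$status != "optimal") return(NULL)
  stats::setNames(sol$x[seq_len(n)] - sol$x[n + seq_len(n)], sm$rxns)
}

#' Net maximal secretion potential of one metabolite
#'
#' Maximises the fecal exchange of the metabolite by FBA and returns the
#' absolute difference between secretion and diet uptake at that optimum: the
#' community's net capability to produce the compound, over and above what it
#' merely passes through from the diet. Because the diet flux at the optimum
#' can be non-unique, a second linear program minimises total absolute flux
#' with the fecal exchange pinned, which makes the value deterministic.
#'
#' @param model a `"community_model"`.
#' @param metabolite_id lumen metabolite id (without compartment suffix).
#' @return non-negative scalar (mmol per person per day).
#' @export
secretion_potential <- function(model, metabolite_id) {
  fe <- paste0("EX_", metabolite_id, "[fe]")
  di <- paste0("Diet_EX_", metabolite_id, "[d]")
  rxns <- names(model$reactions)
  if (!fe %in% rxns || !di %in% rxns)
    stopf("metabolite '%s' lacks diet and fecal exchange reactions", metabolite_id)
  sol <- fba(model, fe, "max")
  if (sol$status != "optimal")
    stopf("FBA %s while maximising '%s'", sol$status, fe)
  v <- min_total_flux(stoichiometric_matrix(model), fe, sol$objective_value)
  if (is.null(v)) v <- sol$fluxes
  pot <- abs(v[[fe]] + v[[di]])   # diet flux <= 0 encodes uptake
  if (pot < 1e-6) pot <- 0
  pot
}

#' Secretion-potential screen over a metabolite set
#'
#' Applies [secretion_potential()] per metabolite; any infeasibility is
#' recorded as `NA` with a log entry rather than raised.
#'
#' @param model a `"community_model"`.
#' @param metabolite_ids character vector of lumen metabolite ids.
#' @param absent_as_zero a metabolite no present strain can transport has no
#'   exchanges in the model; the community cannot secrete it, so its
#'   potential is recorded as 0 (logged). Set `FALSE` to record `NA` instead.
#' @return data.frame with `subject_id`, `metabolite`, `potential`; per-
#'   metabolite LP status in attribute `"log"`.
#' @export
secretion_screen <- function(model, metabolite_ids, absent_as_zero = TRUE) {
  if (length(metabolite_ids) == 0L)
    return(data.frame(subject_id = character(0), metabolite = character(0),
                      potential = numeric(0), stringsAsFactors = FALSE))
  log <- character(0)
  rxns <- names(model$reactions)
  pots <- vapply(metabolite_ids, function(m) {
    if (!paste0("EX_", m, "[fe]") %in% rxns) {
      log[[m]] <<- "no exchanges in model (metabolite not transportable here)"
      return(if (absent_as_zero) 0 else NA_real_)
    }
    tryCatch(secretion_potential(model, m),
             error = function(e) {
               log[[m]] <<- conditionMessage(e)
               NA_real_
             })
  }, 0)
  out <- data.frame(subject_id = model$subject_id %||% NA_character_,
                    metabolite = metabolite_ids,
                    potential = unname(pots),
                    stringsAsFactors = FALSE)
  attr(out, "log") <- log
  out
}
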