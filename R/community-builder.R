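# Personalised community model assembly: strain reconstructions + relative
# abundances + diet -> one diet-constrained community model with a shared
# lumen compartment.

#' Diet constraints
#'
#' @param name diet label.
#' @param uptake_bounds named non-negative numeric: maximal uptake flux per
#'   diet metabolite (mmol per person per day), names are bare metabolite ids.
#' @return object of class `"diet"`.
#' @export
diet <- function(name, uptake_bounds) {
  if (any(uptake_bounds < 0)) stopf("diet uptake bounds must be non-negative")
  structure(list(name = name, uptake_bounds = uptake_bounds), class = "diet")
}

#' Read a diet from CSV
#'
#' Expects columns `reaction_id` (`Diet_EX_<met>[d]` naming) and `max_uptake`.
#'
#' @param path CSV path.
#' @param name diet label (defaults to the file name).
#' @return a `"diet"`.
#' @export
read_diet <- function(path, name = basename(path)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "max_uptake") %in% names(d)))
    stopf("diet file must have columns reaction_id, max_uptake")
  mets <- sub("^Diet_EX_", "", sub("\\[d\\]$", "", d$reaction_id))
  diet(name, stats::setNames(d$max_uptake, mets))
}

#' Built-in toy European diet
#'
#' A small glucose-rich diet with the amino-acid, sulfite and conjugated
#' bile-acid inputs the toy strain panel can use. Shipped as
#' `inst/extdata/diet_toy_european.csv`.
#'
#' @return a `"diet"`.
#' @export
toy_european_diet <- function() {
  read_diet(system.file("extdata", "diet_toy_european.csv",
                        package = "sulfurflux", mustWork = TRUE),
            name = "toy_european")
}

#' Coverage to relative abundance
#'
#' Strains with genome coverage below `threshold` are treated as absent
#' (false-positive control); survivors are renormalised to sum to one.
#'
#' @param coverage_row named non-negative numeric, one subject's coverage per
#'   strain.
#' @param threshold detection threshold on coverage (default 0.1).
#' @param subject_id optional subject label.
#' @return an abundance profile: list with `subject_id` and `abundances`
#'   (named numeric summing to 1).
#' @export
coverage_to_abundance <- function(coverage_row, threshold = 0.1,
                                  subject_id = NA_character_) {
  if (any(coverage_row < 0)) stopf("coverages must be non-negative")
  keep <- coverage_row >= threshold
  if (!any(keep)) stopf("empty community: all strains below coverage threshold")
  ab <- coverage_row[keep] / sum(coverage_row[keep])
  list(subject_id = subject_id, abundances = ab)
}

biomass_metabolite <- function(recon) {
  s <- recon$reactions[[recon$biomass_reaction_id]]$stoichiometry
  prod <- names(s)[s > 0]
  if (length(prod) != 1L)
    stopf("strain '%s': biomass reaction must produce exactly one metabolite",
          recon$strain_id)
  prod
}

#' Build a personalised community model
#'
#' Copies each detected strain's reactions with strain-prefixed identifiers
#' into a strain-private compartment, converts the strain exchanges into
#' reversible lumen transporters, creates one diet exchange
#' (`Diet_EX_<met>[d]`, uptake only, bounded by the diet) and one fecal
#' exchange (`EX_<met>[fe]`, secretion only) per lumen metabolite, and adds a
#' community biomass reaction consuming each strain's biomass metabolite with
#' a stoichiometric coefficient equal to its relative abundance.
#'
#' @param panel list of `"reconstruction"` objects.
#' @param profile abundance profile (see [coverage_to_abundance()]).
#' @param diet a `"diet"`.
#' @param biomass_bounds community biomass flux bounds in day^-1; the default
#'   `c(0.4, 1)` corresponds to fecal excretion between every 3 days and daily.
#' @return object of class `"community_model"`.
#' @export
build_community <- function(panel, profile, diet = toy_european_diet(),
                            biomass_bounds = c(0.4, 1)) {
  names(panel) <- vapply(panel, `[[`, "", "strain_id")
  ab <- profile$abundances[profile$abundances > 0]
  missing_strains <- setdiff(names(ab), names(panel))
  if (length(missing_strains))
    stopf("profile references unknown strains: %s", paste(missing_strains, collapse = ", "))
  if (abs(sum(profile$abundances) - 1) > 1e-9)
    stopf("abundances must sum to 1")

  mets <- list(); rxns <- list()
  lumen <- data.frame(id = character(0), name = character(0),
                      is_sulfur = logical(0), stringsAsFactors = FALSE)
  biomass_terms <- numeric(0)

  for (sid in names(ab)) {
    recon <- panel[[sid]]
    bm_key <- biomass_metabolite(recon)
    pref_key <- function(keys) paste0(sid, "_", keys)
    sm <- recon$metabolites
    mets[[sid]] <- data.frame(id = paste0(sid, "_", sm$id),
                              compartment = sm$compartment,
                              name = sm$name, is_sulfur = sm$is_sulfur,
                              stringsAsFactors = FALSE)
    for (rxn in recon$reactions) {
      if (is_exchange(rxn)) {
        key <- names(rxn$stoichiometry)
        if (key == bm_key) next                      # biomass sink -> community biomass
        base <- sub("\\[[a-z]+\\]$", "", key)
        row <- sm[met_key(sm$id, sm$compartment) == key, ]
        if (!base %in% lumen$id)
          lumen <- rbind(lumen, data.frame(id = base, name = row$name,
                                           is_sulfur = row$is_sulfur,
                                           stringsAsFactors = FALSE))
        # transporter: positive flux secretes from the strain into the lumen
        st <- stats::setNames(c(-1, 1), c(pref_key(key), met_key(base, "lu")))
        rxns[[paste0(sid, "_IEX_", base)]] <-
          reaction(paste0(sid, "_IEX_", base), st, rxn$lb, rxn$ub)
      } else {
        st <- stats::setNames(unname(rxn$stoichiometry), pref_key(names(rxn$stoichiometry)))
        rid <- paste0(sid, "_", rxn$id)
        rxns[[rid]] <- reaction(rid, st, rxn$lb, rxn$ub, rxn$ec, rxn$subsystem)
      }
    }
    biomass_terms[pref_key(bm_key)] <- ab[[sid]]
  }

  unmatched <- setdiff(names(diet$uptake_bounds), lumen$id)
  if (length(unmatched))
    warnf("diet metabolites without a lumen counterpart (ignored): %s",
          paste(unmatched, collapse = ", "))

  met_df <- do.call(rbind, c(mets, list(
    data.frame(id = lumen$id, compartment = "lu", name = lumen$name,
               is_sulfur = lumen$is_sulfur, stringsAsFactors = FALSE))))

  for (i in seq_len(nrow(lumen))) {
    bid <- lumen$id[i]
    key <- met_key(bid, "lu")
    dmax <- if (bid %in% names(diet$uptake_bounds)) diet$uptake_bounds[[bid]] else 0
    did <- paste0("Diet_EX_", bid, "[d]")
    fid <- paste0("EX_", bid, "[fe]")
    rxns[[did]] <- reaction(did, stats::setNames(-1, key), -dmax, 0)
    rxns[[fid]] <- reaction(fid, stats::setNames(-1, key), 0, 1000)
  }

  cb <- "communityBiomass"
  rxns[[cb]] <- reaction(cb, -biomass_terms, biomass_bounds[1], biomass_bounds[2])

  structure(list(subject_id = profile$subject_id,
                 strains = data.frame(strain_id = names(ab),
                                      relative_abundance = unname(ab),
                                      stringsAsFactors = FALSE),
                 metabolites = met_df,
                 reactions = rxns,
                 community_biomass_id = cb,
                 biomass_reaction_id = cb,   # so shared validators/S work
                 diet = diet$name,
                 lumen_metabolites = lumen),
            class = c("community_model"))
}
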