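# Seeded generators for toy strain panels, coverage tables and abundance
# profiles. The two keystone archetypes emulate a mucin-degrading
# methionine/H2S producer (A. muciniphila-like) and a taurine-respiring
# sulfite producer (B. wadsworthia-like); background strains are generic
# glucose fermenters without sulfur chemistry.

#' Strain panel specification
#'
#' @param n_background_strains number of generic fermenters (>= 0).
#' @param include_mucin_degrader,include_taurine_respirer include the keystone
#'   archetypes?
#' @param seed integer seed.
#' @return list of class `"panel_spec"`.
#' @export
panel_spec <- function(n_background_strains = 3,
                       include_mucin_degrader = TRUE,
                       include_taurine_respirer = TRUE,
                       seed = 1L) {
  if (!is_count(n_background_strains)) stopf("n_background_strains must be a count")
  total <- n_background_strains + include_mucin_degrader + include_taurine_respirer
  if (total < 1) stopf("panel must contain at least one strain")
  structure(list(n_background_strains = as.integer(n_background_strains),
                 include_mucin_degrader = isTRUE(include_mucin_degrader),
                 include_taurine_respirer = isTRUE(include_taurine_respirer),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

sulfur_mets <- c("cys_L", "cyst_L", "hcys_L", "met_L", "h2s", "so3", "taur", "tchola")

toy_met <- function(id, name = id) metabolite(id, "c", name, id %in% sulfur_mets)

mucin_degrader_recon <- function() {
  mets <- do.call(rbind, lapply(
    c("glc_D", "ac", "asp_L", "aspsa", "hom_L", "suchms", "cys_L", "cyst_L",
      "hcys_L", "met_L", "h2s", "so3", "asn_L", "biomass"), toy_met))
  r <- list(
    reaction("EX_glc_D", c("glc_D[c]" = -1), -1000, 1000),
    reaction("FERM",     c("glc_D[c]" = -1, "ac[c]" = 2), 0, 1000),
    reaction("EX_ac",    c("ac[c]" = -1), -1000, 1000),
    reaction("EX_asp_L", c("asp_L[c]" = -1), -1000, 1000),
    # aspartate -> methionine chain (lumped kinase/semialdehyde step first)
    reaction("ASPK",  c("asp_L[c]" = -1, "aspsa[c]" = 1), 0, 1000, ec = "2.7.2.4"),
    reaction("HSDH",  c("aspsa[c]" = -1, "hom_L[c]" = 1), 0, 1000, ec = "1.1.1.3"),
    reaction("HSST",  c("hom_L[c]" = -1, "suchms[c]" = 1), 0, 1000, ec = "2.3.1.46"),
    reaction("SHSL",  c("suchms[c]" = -1, "cys_L[c]" = -1, "cyst_L[c]" = 1), 0, 1000, ec = "2.5.1.48"),
    reaction("CYSTL", c("cyst_L[c]" = -1, "hcys_L[c]" = 1), 0, 1000, ec = "4.4.1.8"),
    reaction("METS",  c("hcys_L[c]" = -1, "met_L[c]" = 1), 0, 1000, ec = "2.1.1.14"),
    reaction("EX_met_L", c("met_L[c]" = -1), -1000, 1000),
    # cysteine desulfhydration and assimilatory sulfite reduction
    reaction("EX_cys_L", c("cys_L[c]" = -1), -1000, 1000),
    reaction("CYSDS", c("cys_L[c]" = -1, "h2s[c]" = 1), 0, 1000, ec = "4.4.1.28"),
    reaction("SO3R",  c("so3[c]" = -1, "h2s[c]" = 1), 0, 1000, ec = "1.8.2.2"),
    reaction("EX_so3", c("so3[c]" = -1), -1000, 1000),
    reaction("EX_h2s", c("h2s[c]" = -1), -1000, 1000),
    # asparagine synthesis and secretion
    reaction("ASNS", c("asp_L[c]" = -1, "asn_L[c]" = 1), 0, 1000, ec = "6.3.5.4"),
    reaction("EX_asn_L", c("asn_L[c]" = -1), -1000, 1000),
    reaction("BIOMASS_mucin", c("glc_D[c]" = -0.5, "asp_L[c]" = -0.02, "biomass[c]" = 1), 0, 1000),
    reaction("SK_biomass", c("biomass[c]" = -1), 0, 1000))
  reconstruction("mucin_degrader", mets, r, "BIOMASS_mucin")
}

taurine_respirer_recon <- function() {
  mets <- do.call(rbind, lapply(
    c("glc_D", "ac", "tchola", "cholate", "taur", "so3", "h2s", "biomass"), toy_met))
  mets$is_sulfur[mets$id == "cholate"] <- FALSE
  r <- list(
    reaction("EX_glc_D", c("glc_D[c]" = -1), -1000, 1000),
    reaction("FERM",     c("glc_D[c]" = -1, "ac[c]" = 2), 0, 1000),
    reaction("EX_ac",    c("ac[c]" = -1), -1000, 1000),
    # bile-salt hydrolase releases taurine from taurocholate
    reaction("EX_tchola", c("tchola[c]" = -1), -1000, 0),
    reaction("BSH", c("tchola[c]" = -1, "cholate[c]" = 1, "taur[c]" = 1), 0, 1000, ec = "3.5.1.24"),
    reaction("EX_cholate", c("cholate[c]" = -1), 0, 1000),
    reaction("EX_taur", c("taur[c]" = -1), -1000, 1000),
    # taurine dissimilation to sulfite, then sulfite respiration to H2S
    reaction("TAURDS", c("taur[c]" = -1, "so3[c]" = 1, "ac[c]" = 1), 0, 1000, ec = "2.6.1.77"),
    reaction("SO3RD",  c("so3[c]" = -1, "h2s[c]" = 1), 0, 1000, ec = "1.8.99.5"),
    reaction("EX_so3", c("so3[c]" = -1), -1000, 1000),
    reaction("EX_h2s", c("h2s[c]" = -1), -1000, 1000),
    reaction("BIOMASS_taur", c("glc_D[c]" = -0.5, "biomass[c]" = 1), 0, 1000),
    reaction("SK_biomass", c("biomass[c]" = -1), 0, 1000))
  reconstruction("taurine_respirer", mets, r, "BIOMASS_taur")
}

background_recon <- function(k, yield) {
  sid <- sprintf("bg%02d", k)
  mets <- do.call(rbind, lapply(c("glc_D", "ac", "biomass"), toy_met))
  r <- list(
    reaction("EX_glc_D", c("glc_D[c]" = -1), -1000, 1000),
    reaction("FERM",     c("glc_D[c]" = -1, "ac[c]" = 2), 0, 1000),
    reaction("EX_ac",    c("ac[c]" = -1), -1000, 1000),
    reaction("BIOMASS_bg", c("glc_D[c]" = -yield, "biomass[c]" = 1), 0, 1000),
    reaction("SK_biomass", c("biomass[c]" = -1), 0, 1000))
  reconstruction(sid, mets, r, "BIOMASS_bg")
}

#' Standalone growth of one strain on a diet
#'
#' Restricts the strain's exchange uptake bounds to the diet (zero uptake for
#' metabolites absent from the diet) and maximises the biomass reaction.
#'
#' @param recon a `"reconstruction"`.
#' @param diet a `"diet"`.
#' @return maximal biomass flux (day^-1); `NA` if infeasible.
#' @export
standalone_growth <- function(recon, diet = toy_european_diet()) {
  rxns <- lapply(recon$reactions, function(rxn) {
    if (is_exchange(rxn) && rxn$lb < 0) {
      base <- sub("\\[[a-z]+\\]$", "", names(rxn$stoichiometry))
      dmax <- if (base %in% names(diet$uptake_bounds)) diet$uptake_bounds[[base]] else 0
      rxn$lb <- -dmax
      if (rxn$ub < rxn$lb) rxn$ub <- rxn$lb
    }
    rxn
  })
  constrained <- recon
  constrained$reactions <- rxns
  sol <- fba(constrained, recon$biomass_reaction_id, "max")
  if (sol$status != "optimal") return(NA_real_)
  sol$objective_value
}

#' Generate a toy strain panel
#'
#' Every generated strain is self-checked to grow (biomass flux > 0) on the
#' default diet as a standalone FBA problem; a panel that fails this check is
#' a generation error.
#'
#' @param spec a [panel_spec()].
#' @param diet diet used for the growth self-check.
#' @return named list of `"reconstruction"` objects.
#' @export
generate_strain_panel <- function(spec, diet = toy_european_diet()) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  panel <- list()
  if (spec$include_mucin_degrader) panel <- c(panel, list(mucin_degrader_recon()))
  if (spec$include_taurine_respirer) panel <- c(panel, list(taurine_respirer_recon()))
  if (spec$n_background_strains > 0) {
    yields <- stats::runif(spec$n_background_strains, 0.3, 0.8)
    panel <- c(panel, lapply(seq_len(spec$n_background_strains),
                             function(k) background_recon(k, yields[k])))
  }
  names(panel) <- vapply(panel, `[[`, "", "strain_id")
  growth <- vapply(panel, standalone_growth, 0, diet = diet)
  if (any(is.na(growth) | growth <= 1e-9))
    stopf("generated strain(s) cannot grow on the default diet: %s",
          paste(names(panel)[is.na(growth) | growth <= 1e-9], collapse = ", "))
  panel
}

#' Group-shifted Dirichlet abundance profiles
#'
#' Keystone strains (the two archetypes) have base relative abundance 0.3%
#' each; background strains share the remainder uniformly. In cases, the
#' expected keystone abundance is multiplied by `1 + keystone_shift` before
#' renormalisation. Abundances are Dirichlet draws around those expectations.
#'
#' @param panel strain panel (list of reconstructions).
#' @param n_cases,n_controls subjects per group.
#' @param keystone_shift relative increase of expected keystone abundance in
#'   cases (>= 0).
#' @param seed integer seed.
#' @param concentration Dirichlet concentration multiplier (default 50).
#' @param keystone_base base keystone proportion (default 0.003).
#' @return list with `profiles` (list of abundance profiles) and `groups`
#'   (data.frame subject_id, group).
#' @export
generate_abundance_profiles <- function(panel, n_cases, n_controls,
                                        keystone_shift = 0, seed = 1L,
                                        concentration = 50,
                                        keystone_base = 0.003) {
  if (length(panel) == 0L) stopf("empty strain panel")
  if (keystone_shift < 0) stopf("keystone_shift must be >= 0")
  set.seed(seed)
  sids <- vapply(panel, `[[`, "", "strain_id")
  keystone <- sids %in% c("mucin_degrader", "taurine_respirer")
  base <- numeric(length(sids))
  base[keystone] <- keystone_base
  nb <- sum(!keystone)
  if (nb > 0) base[!keystone] <- (1 - sum(base)) / nb
  base <- base / sum(base)

  draw <- function(subject_id, shifted) {
    p <- base
    if (shifted && any(keystone)) p[keystone] <- p[keystone] * (1 + keystone_shift)
    p <- p / sum(p)
    g <- stats::rgamma(length(p), shape = concentration * p, rate = 1)
    if (sum(g) == 0) g[] <- p
    list(subject_id = subject_id, abundances = stats::setNames(g / sum(g), sids))
  }
  ids <- c(sprintf("PD%03d", seq_len(n_cases)), sprintf("C%03d", seq_len(n_controls)))
  grp <- rep(c("PD", "control"), c(n_cases, n_controls))
  profiles <- lapply(seq_along(ids), function(i) draw(ids[i], grp[i] == "PD"))
  names(profiles) <- ids
  list(profiles = profiles,
       groups = data.frame(subject_id = ids, group = grp, stringsAsFactors = FALSE))
}

#' Synthetic strain coverage table
#'
#' Emulates genome-coverage input: a fraction `dropout_rate` of entries fall
#' below the 0.1 detection threshold (drawn on \[0, 0.1)), the rest on
#' \[0.1, 2\].
#'
#' @param panel strain panel.
#' @param n_subjects number of subjects.
#' @param dropout_rate fraction of sub-threshold entries, in \[0, 1).
#' @param seed integer seed.
#' @return numeric matrix (subjects x strains).
#' @export
generate_coverage_table <- function(panel, n_subjects, dropout_rate = 0.2, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  set.seed(seed)
  sids <- vapply(panel, `[[`, "", "strain_id")
  n <- n_subjects * length(sids)
  drop <- stats::runif(n) < dropout_rate
  vals <- ifelse(drop, stats::runif(n, 0, 0.0999), stats::runif(n, 0.1, 2))
  matrix(vals, nrow = n_subjects, ncol = length(sids),
         dimnames = list(sprintf("S%03d", seq_len(n_subjects)), sids))
}
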