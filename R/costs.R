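# Energy and carbon accounting over flux components.
#
# Every component is mass-balanced, so the ATP it produces net of its own
# consumption is exactly its flux through the maintenance hydrolysis
# reaction, and the sum over components equals J_ATPM. Costs are expressed
# per molecule of product (dividing by the demand flux) or per gDW
# (multiplying by J_gamma / mu).

#' Net ATP balance per functional component
#'
#' Returns, per function, the component's flux through the ATP maintenance
#' reaction with the production-positive sign convention: a positive value
#' is ATP delivered to the maintenance pool by that function's pathway, a
#' negative value is net consumption covered by the other components. The
#' balances sum to J_ATPM exactly.
#'
#' @param decomp a `flux_decomposition` (typically after coupling).
#' @param atpm_reaction id of the maintenance reaction.
#' @return data.frame with `function_id`, `atp_flux` (mmol/gDW/h),
#'   `category` (respiration, fermentation, biosynthesis or mixed).
#' @export
component_atp_balance <- function(decomp, atpm_reaction = "ATPM") {
  if (!atpm_reaction %in% colnames(decomp$components)) {
    stop("maintenance reaction not in decomposition: ", atpm_reaction)
  }
  atp <- decomp$components[, atpm_reaction]
  cat_map <- function(x) {
    if (x %in% c("respiration", "fermentation")) return(x)
    if (x %in% c("building_block")) return("biosynthesis")
    if (x %in% c("maintenance")) return("respiration")
    "mixed"
  }
  data.frame(function_id = rownames(decomp$components),
             atp_flux = unname(atp),
             category = vapply(decomp$categories[rownames(decomp$components)],
                               cat_map, ""),
             stringsAsFactors = FALSE)
}

#' Carbon and ATP costs of biosynthetic functions
#'
#' The carbon cost of a building block is the substrate carbon consumed by
#' its flux component per molecule produced; the ATP cost is the negative of
#' the component's maintenance flux per molecule (so net ATP-producing
#' pathways have negative cost). With `mu` supplied, demand-weighted
#' variants per gDW (cost * J_gamma / mu) are added.
#'
#' @param decomp a `flux_decomposition`.
#' @param substrate_id substrate exchange reaction id.
#' @param carbon_atoms_per_substrate carbon atoms per substrate molecule.
#' @param atpm_reaction maintenance reaction id.
#' @param functions function ids to cost (default: all with category
#'   `building_block`).
#' @param mu growth rate (1/h), for the per-gDW weighting.
#' @return data.frame of cost records.
#' @export
biosynthesis_costs <- function(decomp, substrate_id, carbon_atoms_per_substrate,
                               atpm_reaction = "ATPM", functions = NULL,
                               mu = NULL) {
  comp <- decomp$components
  if (is.null(functions)) {
    functions <- rownames(comp)[decomp$categories[rownames(comp)] == "building_block"]
  }
  J <- decomp$demands$J[match(functions, decomp$demands$function_id)]
  keep <- J > 0
  if (any(!keep)) {
    warning("skipping zero-demand functions: ",
            paste(functions[!keep], collapse = ", "))
  }
  functions <- functions[keep]; J <- J[keep]
  uptake <- -comp[functions, substrate_id]          # uptake is negative flux
  atp <- comp[functions, atpm_reaction]
  out <- data.frame(function_id = functions,
                    carbon_cost = unname(uptake * carbon_atoms_per_substrate / J),
                    atp_cost = unname(-atp / J),
                    stringsAsFactors = FALSE)
  if (!is.null(mu)) {
    out$carbon_cost_per_gDW <- out$carbon_cost * J / mu
    out$atp_cost_per_gDW <- out$atp_cost * J / mu
  }
  out
}

#' Pathway-only ATP costs (central carbon pathways removed)
#'
#' Recomputes each function's ATP cost from its component restricted to the
#' non-central reactions, crediting only the ATP made or spent inside the
#' biosynthetic pathway proper. The net ATP of the restricted sub-component
#' is evaluated from the stoichiometry of the energy currency, excluding the
#' maintenance reaction itself. With an empty central set this reduces
#' exactly to the full-network ATP cost.
#'
#' @param decomp a `flux_decomposition`.
#' @param model the [metabolic_model()] the decomposition was computed on.
#' @param central_reactions character vector of reaction ids (or a character
#'   vector of subsystem names via `central_subsystems`).
#' @param atp_metabolite id of the energy-currency metabolite.
#' @param atpm_reaction maintenance reaction id.
#' @param central_subsystems subsystem names whose reactions are treated as
#'   central (used when `central_reactions` is NULL); defaults to the usual
#'   central carbon pathway tags.
#' @param functions functions to cost (default: building blocks).
#' @return data.frame with `function_id`, `atp_cost_pathway_only`,
#'   `atp_cost_full`, `central_credit`.
#' @export
pathway_only_costs <- function(decomp, model, central_reactions = NULL,
                               atp_metabolite = "atp", atpm_reaction = "ATPM",
                               central_subsystems = c("glycolysis", "TCA",
                                 "pentose phosphate", "oxidative phosphorylation",
                                 "anaplerotic"),
                               functions = NULL) {
  comp <- decomp$components
  if (is.null(functions)) {
    functions <- rownames(comp)[decomp$categories[rownames(comp)] == "building_block"]
  }
  if (is.null(central_reactions)) {
    central_reactions <- model$reactions$id[
      tolower(model$reactions$subsystem) %in% tolower(central_subsystems)]
  }
  S <- stoich_matrix(model)
  if (!atp_metabolite %in% rownames(S)) {
    stop("energy-currency metabolite not in model: ", atp_metabolite)
  }
  srow <- S[atp_metabolite, , drop = TRUE]
  J <- decomp$demands$J[match(functions, decomp$demands$function_id)]
  noncentral <- setdiff(colnames(comp), c(central_reactions, atpm_reaction))
  full <- -comp[functions, atpm_reaction, drop = TRUE] / J
  restricted <- vapply(functions, function(f) {
    -sum(srow[noncentral] * comp[f, noncentral])
  }, 0) / J
  data.frame(function_id = functions,
             atp_cost_pathway_only = unname(restricted),
             atp_cost_full = unname(full),
             central_credit = unname(restricted - full),
             stringsAsFactors = FALSE)
}

#' ATP yield per substrate carbon atom of the energy modes
#'
#' For each coupled energy mode (respiration, fermentation), divides the ATP
#' it delivers to the maintenance pool by the substrate carbon it takes up.
#' A mode with zero substrate uptake is reported as absent; when no
#' byproduct is excreted (fermentation mode missing) no fermentation record
#' is returned.
#'
#' @param decomp a coupled `flux_decomposition`.
#' @param substrate_id substrate exchange reaction id.
#' @param carbon_atoms carbon atoms per substrate molecule.
#' @param atpm_reaction maintenance reaction id.
#' @return data.frame with `pathway`, `atp_yield_per_carbon`,
#'   `substrate_uptake`, `atp_flux`.
#' @export
energy_yield_per_carbon <- function(decomp, substrate_id, carbon_atoms,
                                    atpm_reaction = "ATPM") {
  comp <- decomp$components
  modes <- rownames(comp)[decomp$categories[rownames(comp)] %in%
                          c("respiration", "fermentation")]
  out <- list()
  for (m in modes) {
    uptake <- -comp[m, substrate_id]
    atp <- comp[m, atpm_reaction]
    if (uptake <= 1e-12) next
    out[[m]] <- data.frame(
      pathway = unname(decomp$categories[[m]]), mode_id = m,
      atp_yield_per_carbon = atp / (uptake * carbon_atoms),
      substrate_uptake = uptake, atp_flux = atp, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(pathway = character(), mode_id = character(),
                      atp_yield_per_carbon = numeric(),
                      substrate_uptake = numeric(), atp_flux = numeric()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-component carbon balance over the model boundary
#'
#' Each component is mass-balanced, so the carbon it imports through
#' exchange reactions must leave through excretions and sinks. Returns the
#' net boundary carbon flux per function (should be ~0).
#'
#' @param decomp a `flux_decomposition`.
#' @param model the underlying [metabolic_model()].
#' @return Named numeric vector (mmol C/gDW/h) per function.
#' @export
component_carbon_balance <- function(decomp, model) {
  boundary <- model$reactions$id[vapply(model$stoichiometry, length, 1L) == 1L]
  carbon <- vapply(boundary, function(rid) {
    mid <- names(model$stoichiometry[[rid]])
    carbon_count(model, mid)
  }, 0)
  # boundary reactions consume their single metabolite (coefficient -1):
  # positive flux exports carbon, negative flux (uptake) imports it
  drop(decomp$components[, boundary, drop = FALSE] %*% carbon)
}
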