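#' Construct a demand set
#'
#' A demand set collects the fixed right-hand-side fluxes that parameterize
#' an optimal flux state: one entry per biological function (a biomass
#' building block, the maintenance ATP hydrolysis, or a constrained byproduct
#' excretion), each tied to the reaction that carries it.
#'
#' @param function_id character vector of unique function labels.
#' @param J non-negative demand fluxes (mmol/gDW/h).
#' @param reaction_id target reaction ids carrying each demand.
#' @param category one of `"building_block"`, `"maintenance"`, `"excretion"`
#'   per entry.
#' @return A data.frame of class `demand_set`.
#' @export
demand_set <- function(function_id, J, reaction_id, category) {
  if (anyDuplicated(function_id)) stop("function ids must be unique")
  if (any(J < 0)) stop("demand fluxes must be non-negative")
  category <- match.arg(category, c("building_block", "maintenance", "excretion"),
                        several.ok = TRUE)
  if (length(category) == 1) category <- rep(category, length(function_id))
  out <- data.frame(function_id = function_id, J = J,
                    reaction_id = reaction_id, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("demand_set", "data.frame")
  out
}

#' Read a biomass composition table
#'
#' @param path TSV with columns `metabolite_id`, `mu`, `coefficient_mmol_per_gDW`,
#'   `condition`.
#' @return data.frame of class `biomass_composition`.
#' @export
read_biomass_composition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "mu", "coefficient_mmol_per_gDW", "condition")
  if (!all(need %in% names(tab))) {
    stop("biomass composition table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$coefficient_mmol_per_gDW < 0)) stop("negative biomass coefficients")
  class(tab) <- c("biomass_composition", "data.frame")
  tab
}

#' Interpolate biomass coefficients at a growth rate
#'
#' Coefficients tabulated against growth rate are interpolated piecewise
#' linearly within the tabulated range; extrapolation beyond the range is an
#' error unless `extrapolate = TRUE` (which clamps to the range ends).
#'
#' @param composition a `biomass_composition` (or data.frame with the same
#'   columns).
#' @param mu growth rate (1/h).
#' @param condition condition label to select; `NULL` uses all rows.
#' @param extrapolate allow growth rates outside the tabulated range.
#' @return Named numeric vector of coefficients c_gamma (mmol/gDW) per
#'   metabolite.
#' @export
biomass_coefficients <- function(composition, mu, condition = NULL,
                                 extrapolate = FALSE) {
  tab <- composition
  if (!is.null(condition)) tab <- tab[tab$condition == condition, , drop = FALSE]
  if (nrow(tab) == 0) stop("no composition rows for condition ", condition)
  out <- numeric(0)
  for (mid in unique(tab$metabolite_id)) {
    sub <- tab[tab$metabolite_id == mid, , drop = FALSE]
    sub <- sub[order(sub$mu), , drop = FALSE]
    if (nrow(sub) == 1) {
      out[mid] <- sub$coefficient_mmol_per_gDW[1]
    } else {
      rng <- range(sub$mu)
      if ((mu < rng[1] || mu > rng[2]) && !extrapolate) {
        stop("growth rate ", mu, " outside tabulated range [", rng[1], ", ",
             rng[2], "] for ", mid, " (set extrapolate = TRUE to clamp)")
      }
      out[mid] <- stats::approx(sub$mu, sub$coefficient_mmol_per_gDW,
                                xout = min(max(mu, rng[1]), rng[2]),
                                rule = 2)$y
    }
  }
  out
}

#' Split a lumped biomass reaction into per-building-block demands
#'
#' Replaces the model's lumped biomass reaction with one irreversible sink
#' reaction per building block and returns the matching demand set with
#' J_gamma = c_gamma(mu) * mu. The growth-associated ATP hydrolysis
#' stoichiometry of the original biomass reaction (ATP + H2O -> ADP + Pi + H)
#' is preserved as a maintenance demand entry targeted at the ATPM reaction.
#'
#' @param model a [metabolic_model()] containing a lumped biomass reaction.
#' @param composition a `biomass_composition` table (see
#'   [read_biomass_composition()]), or a named numeric vector of coefficients
#'   (mmol/gDW).
#' @param mu growth rate (1/h).
#' @param biomass_id id of the lumped biomass reaction; by default the first
#'   reaction whose id contains "biomass" (case-insensitive).
#' @param condition condition label passed to [biomass_coefficients()].
#' @param atpm_id id of the maintenance reaction receiving the
#'   growth-associated ATP demand; required only if the biomass reaction
#'   consumes the metabolite in `gam_metabolite`.
#' @param gam_metabolite id of the energy currency whose biomass-reaction
#'   consumption is growth-associated maintenance (default `"atp_c"`, with
#'   `"atp"` and `"e"` also recognized).
#' @param extrapolate passed to [biomass_coefficients()].
#' @return list with elements `model` (biomass reaction replaced by sinks)
#'   and `demands` (a [demand_set()]).
#' @export
split_biomass <- function(model, composition, mu, biomass_id = NULL,
                          condition = NULL, atpm_id = NULL,
                          gam_metabolite = c("atp_c", "atp", "e"),
                          extrapolate = FALSE) {
  if (mu < 0) stop("growth rate must be non-negative")
  if (is.null(biomass_id)) {
    hit <- grep("biomass", model$reactions$id, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) stop("no biomass reaction found; supply biomass_id")
    biomass_id <- hit[1]
  }
  k <- match(biomass_id, model$reactions$id)
  if (is.na(k)) stop("unknown biomass reaction: ", biomass_id)
  coefs <- if (is.numeric(composition)) composition else {
    biomass_coefficients(composition, mu, condition = condition,
                         extrapolate = extrapolate)
  }
  missing <- setdiff(names(coefs), model$metabolites$id)
  if (length(missing) > 0) {
    stop("composition metabolites absent from model: ",
         paste(missing, collapse = ", "))
  }
  J <- coefs * mu
  if (any(J < 0)) stop("negative demand flux computed")

  # growth-associated maintenance from the lumped reaction's ATP stoichiometry
  bio_stoich <- model$stoichiometry[[k]]
  gam_met <- intersect(gam_metabolite, names(bio_stoich))
  gam <- if (length(gam_met) > 0 && bio_stoich[[gam_met[1]]] < 0) {
    -bio_stoich[[gam_met[1]]]
  } else 0

  # drop the lumped reaction
  model$stoichiometry[[k]] <- NULL
  model$reactions <- model$reactions[-k, , drop = FALSE]

  # add one sink per building block
  for (mid in names(coefs)) {
    sid <- paste0("DM_", mid)
    model$reactions <- rbind(model$reactions, data.frame(
      id = sid, name = paste("demand", mid), lower_bound = 0,
      upper_bound = Inf, gene_rule = "", subsystem = "demand",
      stringsAsFactors = FALSE))
    model$stoichiometry[[sid]] <- stats::setNames(-1, mid)
  }
  dem <- demand_set(function_id = names(coefs), J = unname(J),
                    reaction_id = paste0("DM_", names(coefs)),
                    category = rep("building_block", length(coefs)))
  if (gam > 0) {
    if (is.null(atpm_id)) stop("biomass reaction carries growth-associated ATP; ",
                               "supply atpm_id to receive it")
    if (!atpm_id %in% model$reactions$id) stop("unknown ATPM reaction: ", atpm_id)
    gam_dem <- demand_set("growth_ATP", gam * mu, atpm_id, "maintenance")
    dem <- rbind(dem, gam_dem)
    class(dem) <- c("demand_set", "data.frame")
  }
  list(model = model, demands = dem)
}

#' Assemble the full demand set for a growth condition
#'
#' Combines the building-block demands J_gamma = c_gamma(mu) * mu, the
#' maintenance demand J_ATPM = sigma0 + sigma * mu, and the condition's
#' constrained byproduct excretions evaluated from linear laws in mu
#' (clipped at zero). In aerobic conditions the acetate law applies; in
#' anaerobic conditions the succinate law replaces it.
#'
#' @param composition `biomass_composition` table or named coefficient vector
#'   (mmol/gDW).
#' @param condition a one-row data.frame (or list) with at least `mu` and
#'   `aerobic`; see [read_conditions()].
#' @param maintenance a [maintenance_fit()] or list with `sigma0`, `sigma`.
#' @param excretion_laws named list (by exchange reaction id) of lists with
#'   `intercept`, `slope` (flux vs mu) and `aerobic` (logical: does this law
#'   apply to aerobic conditions?).
#' @param atpm_id id of the maintenance reaction (default `"ATPM"`).
#' @param extrapolate passed to [biomass_coefficients()].
#' @return A [demand_set()].
#' @export
build_demand_set <- function(composition, condition, maintenance,
                             excretion_laws = list(), atpm_id = "ATPM",
                             extrapolate = FALSE) {
  mu <- condition$mu
  if (is.null(mu) || mu <= 0) stop("condition must carry a positive growth rate")
  coefs <- if (is.numeric(composition)) composition else {
    biomass_coefficients(composition, mu,
                         condition = condition$label %||% NULL,
                         extrapolate = extrapolate)
  }
  atpm <- maintenance$sigma0 + maintenance$sigma * mu
  if (atpm < 0) stop("unphysical maintenance: sigma0 + sigma*mu = ", atpm, " < 0")
  dem <- demand_set(
    function_id = c(names(coefs), "ATPM"),
    J = c(unname(coefs * mu), atpm),
    reaction_id = c(paste0("DM_", names(coefs)), atpm_id),
    category = c(rep("building_block", length(coefs)), "maintenance"))
  aerobic <- isTRUE(condition$aerobic)
  for (rid in names(excretion_laws)) {
    law <- excretion_laws[[rid]]
    if (isTRUE(law$aerobic) != aerobic) next
    Jx <- max(0, law$intercept + law$slope * mu)
    ex <- demand_set(rid, Jx, rid, "excretion")
    dem <- rbind(dem, ex)
  }
  class(dem) <- c("demand_set", "data.frame")
  dem
}

#' Read a growth-conditions table
#'
#' @param path TSV with columns `label`, `mu`, `substrate_exchange_id`,
#'   `uptake_mmol_gDW_h`, `acetate_mmol_gDW_h`, `limitation`, `aerobic`.
#' @return data.frame with one row per condition.
#' @export
read_conditions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "mu", "substrate_exchange_id", "limitation", "aerobic")
  if (!all(need %in% names(tab))) {
    stop("conditions table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$mu <= 0)) stop("growth rates must be positive")
  tab$aerobic <- as.logical(tab$aerobic)
  tab
}

#' Apply a growth condition and demand set to a model
#'
#' Fixes each demand reaction's bounds to its demand flux, closes the oxygen
#' exchange under anaerobic conditions, and leaves the substrate exchange
#' free in the uptake direction for subsequent minimization.
#'
#' @param model a [metabolic_model()].
#' @param condition list/row with `aerobic` (logical) and optionally
#'   `substrate_exchange_id`.
#' @param demands a [demand_set()].
#' @param o2_exchange_id id of the oxygen exchange, if the model has one.
#' @return The constrained model.
#' @export
apply_condition <- function(model, condition, demands,
                            o2_exchange_id = "EX_o2_e") {
  for (k in seq_len(nrow(demands))) {
    rid <- demands$reaction_id[k]
    j <- match(rid, model$reactions$id)
    if (is.na(j)) stop("demand target reaction not in model: ", rid)
    Jk <- demands$J[k]
    # exchanges carry excretion as positive flux; sinks likewise consume at +J
    lb0 <- model$reactions$lower_bound[j]; ub0 <- model$reactions$upper_bound[j]
    if (Jk < lb0 - 1e-12 || Jk > ub0 + 1e-12) {
      stop("demand ", demands$function_id[k], " = ", Jk,
           " conflicts with bounds [", lb0, ", ", ub0, "] of ", rid)
    }
    model$reactions$lower_bound[j] <- Jk
    model$reactions$upper_bound[j] <- Jk
  }
  if (!isTRUE(condition$aerobic) && o2_exchange_id %in% model$reactions$id) {
    model <- set_bounds(model, o2_exchange_id, lower = 0, upper = 0)
  }
  model
}
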