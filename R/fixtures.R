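# Deterministic toy networks with closed-form decompositions.
#
# Each fixture is small enough that its optimal flux state is determined by
# the mass-balance equalities alone (or by an unambiguous stage-1/stage-2
# optimum), so the response matrix xi can be written down analytically and
# used as an independent oracle for the finite-difference machinery.

new_fixture_model <- function(mets, rxns, stoich, genes = character(), id) {
  metabolites <- data.frame(
    id = names(mets),
    name = names(mets),
    compartment = ifelse(grepl("_e$", names(mets)), "e", "c"),
    formula = unname(vapply(mets, function(m) m$formula %||% NA_character_, "")),
    charge = 0L, stringsAsFactors = FALSE)
  reactions <- do.call(rbind, lapply(rxns, function(r) data.frame(
    id = r$id, name = r$name %||% r$id,
    lower_bound = r$lb, upper_bound = r$ub,
    gene_rule = r$gene %||% "", subsystem = r$sub %||% "",
    stringsAsFactors = FALSE)))
  metabolic_model(metabolites, reactions, stoich, genes = genes, id = id)
}

#' Generate a toy metabolic network with a known decomposition
#'
#' Six motif kinds are available, mirroring the structures that make flux
#' decompositions interesting: a linear pathway, two redundant parallel
#' routes (resolved by the L2 stage), a carbon-efficient/wasteful branch
#' (resolved by the uptake-minimizing stage), aerobic overflow metabolism
#' with a constrained acetate-analog excretion (whose raw component carries
#' negative respiratory entries), a two-cofactor network in which energy and
#' biosynthesis components mismatch irremovably on the balancing pathways,
#' and an anaerobic network with a constrained succinate-analog excretion
#' producing two fermentation modes.
#'
#' The returned list carries the constrained model, its demand set, the
#' substrate exchange id, and the analytic response matrix `xi_analytic` and
#' flux vector `v_analytic` for the packaged demand values.
#'
#' @param kind one of `"linear_chain"`, `"parallel_paths"`, `"branch"`,
#'   `"overflow"`, `"cofactor_mix"`, `"anaerobic_mix"`.
#' @param n chain length (linear_chain only).
#' @param J demand flux for the single-demand kinds.
#' @param J_atpm,J_ac,J_bm,J_sc,J1,J2 demand fluxes for the multi-demand
#'   kinds (defaults give strictly positive fluxes everywhere).
#' @param variant for `"overflow"`: `"atp_consuming_biosynthesis"` (default)
#'   or `"atp_producing_biosynthesis"` (biosynthesis co-produces ATP, so its
#'   component carries negative respiratory entries and couples to the
#'   maintenance component with a positive ATP yield).
#' @return list with `model`, `demands`, `substrate_id`, `xi_analytic`,
#'   `v_analytic`, and for the byproduct kinds `energy_id`/`byproduct_id`.
#' @export
make_toy_network <- function(kind = c("linear_chain", "parallel_paths", "branch",
                                      "overflow", "cofactor_mix", "anaerobic_mix"),
                             n = 3, J = 1,
                             J_atpm = NULL, J_ac = 2, J_bm = 1, J_sc = 1,
                             J1 = 2, J2 = 2,
                             variant = c("atp_consuming_biosynthesis",
                                         "atp_producing_biosynthesis")) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  switch(kind,
    linear_chain = fixture_linear_chain(n, J),
    parallel_paths = fixture_parallel_paths(J),
    branch = fixture_branch(J),
    overflow = fixture_overflow(J_atpm %||% 10, J_ac, J_bm, variant),
    cofactor_mix = fixture_cofactor_mix(J1, J2, J_atpm %||% 5),
    anaerobic_mix = fixture_anaerobic_mix(J_atpm %||% 6, J_sc, J_bm))
}

fixture_linear_chain <- function(n, J) {
  stopifnot(n >= 2)
  mids <- c("s_e", paste0("m", seq_len(n)))
  mets <- stats::setNames(lapply(mids, function(x) list(formula = "C3")), mids)
  rxns <- c(
    list(list(id = "EX_s_e", lb = -1000, ub = 1000)),
    list(list(id = "UPT", lb = 0, ub = 1000)),
    lapply(seq_len(n - 1), function(i) list(id = paste0("C", i), lb = 0, ub = 1000)),
    list(list(id = "DM_prod", lb = J, ub = J)))
  stoich <- c(
    list(EX_s_e = c(s_e = -1), UPT = c(s_e = -1, m1 = 1)),
    stats::setNames(lapply(seq_len(n - 1), function(i) {
      stats::setNames(c(-1, 1), c(paste0("m", i), paste0("m", i + 1)))
    }), paste0("C", seq_len(n - 1))),
    stats::setNames(list(stats::setNames(-1, paste0("m", n))), "DM_prod"))
  model <- new_fixture_model(mets, rxns, stoich, id = "fx_linear_chain")
  rids <- model$reactions$id
  xi <- matrix(1, 1, length(rids), dimnames = list("chain_product", rids))
  xi[1, "EX_s_e"] <- -1
  list(model = model,
       demands = demand_set("chain_product", J, "DM_prod", "building_block"),
       substrate_id = "EX_s_e",
       xi_analytic = xi, v_analytic = stats::setNames(drop(xi) * J, rids))
}

fixture_parallel_paths <- function(J) {
  mets <- list(s_e = list(formula = "C3"), a = list(formula = "C3"),
               b = list(formula = "C3"))
  rxns <- list(
    list(id = "EX_s_e", lb = -1000, ub = 1000),
    list(id = "UPT", lb = 0, ub = 1000),
    list(id = "P1", lb = 0, ub = 1000, gene = "g_p1"),
    list(id = "P2", lb = 0, ub = 1000, gene = "g_p2"),
    list(id = "DM_b", lb = J, ub = J))
  stoich <- list(EX_s_e = c(s_e = -1), UPT = c(s_e = -1, a = 1),
                 P1 = c(a = -1, b = 1), P2 = c(a = -1, b = 1),
                 DM_b = c(b = -1))
  model <- new_fixture_model(mets, rxns, stoich, genes = c("g_p1", "g_p2"),
                             id = "fx_parallel_paths")
  rids <- model$reactions$id
  xi <- matrix(c(-1, 1, 0.5, 0.5, 1), 1, dimnames = list("product", rids))
  list(model = model, demands = demand_set("product", J, "DM_b", "building_block"),
       substrate_id = "EX_s_e",
       xi_analytic = xi, v_analytic = stats::setNames(drop(xi) * J, rids))
}

fixture_branch <- function(J) {
  mets <- list(g_e = list(formula = "C6"), g = list(formula = "C6"),
               p = list(formula = "C3"), co2 = list(formula = "C1"))
  rxns <- list(
    list(id = "EX_g_e", lb = -1000, ub = 1000),
    list(id = "UPT", lb = 0, ub = 1000),
    list(id = "EFF", lb = 0, ub = 1000),
    list(id = "WASTE", lb = 0, ub = 1000),
    list(id = "EX_co2", lb = 0, ub = 1000),
    list(id = "DM_p", lb = J, ub = J))
  stoich <- list(EX_g_e = c(g_e = -1), UPT = c(g_e = -1, g = 1),
                 EFF = c(g = -1, p = 2), WASTE = c(g = -1, p = 1, co2 = 3),
                 EX_co2 = c(co2 = -1), DM_p = c(p = -1))
  model <- new_fixture_model(mets, rxns, stoich, id = "fx_branch")
  rids <- model$reactions$id
  xi <- matrix(c(-0.5, 0.5, 0.5, 0, 0, 1), 1, dimnames = list("precursor", rids))
  list(model = model, demands = demand_set("precursor", J, "DM_p", "building_block"),
       substrate_id = "EX_g_e",
       xi_analytic = xi, v_analytic = stats::setNames(drop(xi) * J, rids))
}

fixture_overflow <- function(J_atpm, J_ac, J_bm, variant) {
  atp_sign <- if (variant == "atp_producing_biosynthesis") 1 else -1
  mets <- list(glc_e = list(formula = "C6"), glc = list(formula = "C6"),
               pyr = list(formula = "C3"), atp = list(formula = NULL),
               ac = list(formula = "C2"), co2 = list(formula = "C1"),
               bm = list(formula = "C3"))
  rxns <- list(
    list(id = "EX_glc_e", lb = -1000, ub = 1000, sub = "exchange"),
    list(id = "PTS", lb = 0, ub = 1000, gene = "g_pts", sub = "transport"),
    list(id = "GLY", lb = 0, ub = 1000, gene = "g_gly1 and g_gly2", sub = "glycolysis"),
    list(id = "RESP", lb = 0, ub = 1000, gene = "g_nuo", sub = "oxidative phosphorylation"),
    # the low-yield dehydrogenase is open but unused at the optimum
    list(id = "RESP2", lb = 0, ub = 1000, gene = "g_ndh", sub = "oxidative phosphorylation"),
    list(id = "ACK", lb = 0, ub = 1000, gene = "g_pta or g_ack", sub = "fermentation"),
    list(id = "BIO", lb = 0, ub = 1000, gene = "g_bio", sub = "biosynthesis"),
    list(id = "EX_ac", lb = J_ac, ub = J_ac, sub = "exchange"),
    list(id = "EX_co2", lb = 0, ub = 1000, sub = "exchange"),
    list(id = "DM_bm", lb = J_bm, ub = J_bm, sub = "demand"),
    list(id = "ATPM", lb = J_atpm, ub = J_atpm, sub = "maintenance"))
  stoich <- list(
    EX_glc_e = c(glc_e = -1), PTS = c(glc_e = -1, glc = 1),
    GLY = c(glc = -1, pyr = 2, atp = 2),
    RESP = c(pyr = -1, co2 = 3, atp = 10),
    RESP2 = c(pyr = -1, co2 = 3, atp = 6),
    ACK = c(pyr = -1, ac = 1, co2 = 1, atp = 1),
    BIO = c(pyr = -1, bm = 1, atp = atp_sign),
    EX_ac = c(ac = -1), EX_co2 = c(co2 = -1), DM_bm = c(bm = -1),
    ATPM = c(atp = -1))
  genes <- c("g_pts", "g_gly1", "g_gly2", "g_nuo", "g_ndh", "g_pta", "g_ack", "g_bio")
  model <- new_fixture_model(mets, rxns, stoich, genes = genes, id = "fx_overflow")
  rids <- model$reactions$id
  # uptake u = (J_atpm + 9 J_ac + w J_bm)/22 with w = 11 (ATP-consuming
  # biosynthesis) or 9 (ATP-producing); RESP = 2u - J_ac - J_bm.
  w <- if (atp_sign < 0) 11 else 9
  u <- (J_atpm + 9 * J_ac + w * J_bm) / 22
  resp <- 2 * u - J_ac - J_bm
  stopifnot(resp > 0)
  v <- stats::setNames(numeric(length(rids)), rids)
  v[c("EX_glc_e", "PTS", "GLY", "RESP", "RESP2", "ACK", "BIO")] <-
    c(-u, u, u, resp, 0, J_ac, J_bm)
  v[c("EX_ac", "EX_co2", "DM_bm", "ATPM")] <-
    c(J_ac, 3 * resp + J_ac, J_bm, J_atpm)
  xi <- matrix(0, 3, length(rids),
               dimnames = list(c("ATPM", "acetate", "biomass_bm"), rids))
  xi["ATPM", ] <- stats::setNames(
    c(EX_glc_e = -1/22, PTS = 1/22, GLY = 1/22, RESP = 1/11, RESP2 = 0, ACK = 0,
      BIO = 0, EX_ac = 0, EX_co2 = 3/11, DM_bm = 0, ATPM = 1)[rids], rids)
  xi["acetate", ] <- stats::setNames(
    c(EX_glc_e = -9/22, PTS = 9/22, GLY = 9/22, RESP = -2/11, RESP2 = 0, ACK = 1,
      BIO = 0, EX_ac = 1, EX_co2 = 5/11, DM_bm = 0, ATPM = 0)[rids], rids)
  xi["biomass_bm", ] <- if (atp_sign < 0) {
    stats::setNames(
      c(EX_glc_e = -1/2, PTS = 1/2, GLY = 1/2, RESP = 0, RESP2 = 0, ACK = 0,
        BIO = 1, EX_ac = 0, EX_co2 = 0, DM_bm = 1, ATPM = 0)[rids], rids)
  } else {
    stats::setNames(
      c(EX_glc_e = -9/22, PTS = 9/22, GLY = 9/22, RESP = -2/11, RESP2 = 0, ACK = 0,
        BIO = 1, EX_ac = 0, EX_co2 = -6/11, DM_bm = 1, ATPM = 0)[rids], rids)
  }
  demands <- demand_set(c("ATPM", "acetate", "biomass_bm"),
                        c(J_atpm, J_ac, J_bm),
                        c("ATPM", "EX_ac", "DM_bm"),
                        c("maintenance", "excretion", "building_block"))
  list(model = model, demands = demands, substrate_id = "EX_glc_e",
       xi_analytic = xi, v_analytic = v,
       energy_id = "ATPM", byproduct_id = "acetate",
       atpm_id = "ATPM", variant = variant)
}

fixture_cofactor_mix <- function(J1, J2, J_atpm) {
  stopifnot(J_atpm / 5 < min(J1, J2))
  mets <- list(s_e = list(formula = "C3"), g = list(formula = "C3"),
               p = list(formula = "C3"), e = list(formula = NULL),
               n1 = list(formula = NULL), n2 = list(formula = NULL),
               co2 = list(formula = "C1"),
               bm1 = list(formula = "C3"), bm2 = list(formula = "C3"))
  rxns <- list(
    list(id = "EX_s_e", lb = -1000, ub = 1000, sub = "exchange"),
    list(id = "UPT", lb = 0, ub = 1000, sub = "transport"),
    list(id = "PPP1", lb = 0, ub = 1000, gene = "g_ppp1", sub = "pentose phosphate"),
    list(id = "PPP2", lb = 0, ub = 1000, gene = "g_ppp2", sub = "pentose phosphate"),
    list(id = "GLY", lb = 0, ub = 1000, gene = "g_gly", sub = "glycolysis"),
    list(id = "RESP", lb = 0, ub = 1000, gene = "g_resp", sub = "TCA"),
    list(id = "B1", lb = 0, ub = 1000, gene = "g_b1", sub = "biosynthesis"),
    list(id = "B2", lb = 0, ub = 1000, gene = "g_b2", sub = "biosynthesis"),
    list(id = "EX_co2", lb = 0, ub = 1000, sub = "exchange"),
    list(id = "DM_bm1", lb = J1, ub = J1, sub = "demand"),
    list(id = "DM_bm2", lb = J2, ub = J2, sub = "demand"),
    list(id = "ATPM", lb = J_atpm, ub = J_atpm, sub = "maintenance"))
  stoich <- list(
    EX_s_e = c(s_e = -1), UPT = c(s_e = -1, g = 1),
    PPP1 = c(g = -1, p = 1, n1 = 1), PPP2 = c(g = -1, p = 1, n2 = 1),
    GLY = c(g = -1, p = 1, e = 1),
    RESP = c(p = -1, e = 2, n1 = 1, n2 = 1, co2 = 3),
    B1 = c(p = -1, n1 = -1, bm1 = 1), B2 = c(p = -1, n2 = -1, bm2 = 1),
    EX_co2 = c(co2 = -1), DM_bm1 = c(bm1 = -1), DM_bm2 = c(bm2 = -1),
    ATPM = c(e = -1))
  genes <- c("g_ppp1", "g_ppp2", "g_gly", "g_resp", "g_b1", "g_b2")
  model <- new_fixture_model(mets, rxns, stoich, genes = genes, id = "fx_cofactor_mix")
  rids <- model$reactions$id
  R <- J_atpm / 5
  v <- stats::setNames(numeric(length(rids)), rids)
  v[rids] <- c(-(J1 + J2 + R), J1 + J2 + R, J1 - R, J2 - R, 3 * R, R,
               J1, J2, 3 * R, J1, J2, J_atpm)
  xi <- matrix(0, 3, length(rids),
               dimnames = list(c("ATPM", "biomass_bm1", "biomass_bm2"), rids))
  xi["ATPM", ] <- c(-1/5, 1/5, -1/5, -1/5, 3/5, 1/5, 0, 0, 3/5, 0, 0, 1)
  xi["biomass_bm1", ] <- c(-1, 1, 1, 0, 0, 0, 1, 0, 0, 1, 0, 0)
  xi["biomass_bm2", ] <- c(-1, 1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 0)
  demands <- demand_set(c("ATPM", "biomass_bm1", "biomass_bm2"),
                        c(J_atpm, J1, J2),
                        c("ATPM", "DM_bm1", "DM_bm2"),
                        c("maintenance", "building_block", "building_block"))
  list(model = model, demands = demands, substrate_id = "EX_s_e",
       xi_analytic = xi, v_analytic = v, atpm_id = "ATPM")
}

fixture_anaerobic_mix <- function(J_atpm, J_sc, J_bm) {
  mets <- list(glc_e = list(formula = "C6"), glc = list(formula = "C6"),
               pyr = list(formula = "C3"), atp = list(formula = NULL),
               ac = list(formula = "C2"), sc = list(formula = "C3"),
               co2 = list(formula = "C1"), bm = list(formula = "C3"))
  rxns <- list(
    list(id = "EX_glc_e", lb = -1000, ub = 1000, sub = "exchange"),
    list(id = "PTS", lb = 0, ub = 1000, gene = "g_pts", sub = "transport"),
    list(id = "GLY", lb = 0, ub = 1000, gene = "g_gly1 and g_gly2", sub = "glycolysis"),
    list(id = "FA", lb = 0, ub = 1000, gene = "g_pta or g_ack", sub = "fermentation"),
    list(id = "FS", lb = 0, ub = 1000, gene = "g_frd", sub = "fermentation"),
    list(id = "BIO", lb = 0, ub = 1000, gene = "g_bio", sub = "biosynthesis"),
    list(id = "EX_ac", lb = 0, ub = 1000, sub = "exchange"),
    list(id = "EX_sc", lb = J_sc, ub = J_sc, sub = "exchange"),
    list(id = "EX_co2", lb = 0, ub = 1000, sub = "exchange"),
    list(id = "DM_bm", lb = J_bm, ub = J_bm, sub = "demand"),
    list(id = "ATPM", lb = J_atpm, ub = J_atpm, sub = "maintenance"))
  stoich <- list(
    EX_glc_e = c(glc_e = -1), PTS = c(glc_e = -1, glc = 1),
    GLY = c(glc = -1, pyr = 2, atp = 2),
    FA = c(pyr = -1, ac = 1, co2 = 1, atp = 1),
    FS = c(pyr = -1, sc = 1),
    BIO = c(pyr = -1, atp = -2, bm = 1),
    EX_ac = c(ac = -1), EX_sc = c(sc = -1), EX_co2 = c(co2 = -1),
    DM_bm = c(bm = -1), ATPM = c(atp = -1))
  genes <- c("g_pts", "g_gly1", "g_gly2", "g_pta", "g_ack", "g_frd", "g_bio")
  model <- new_fixture_model(mets, rxns, stoich, genes = genes, id = "fx_anaerobic_mix")
  rids <- model$reactions$id
  u <- (3 * J_bm + J_atpm + J_sc) / 4
  fa <- 2 * J_bm + J_atpm - 2 * u
  stopifnot(fa > 0)
  v <- stats::setNames(
    c(-u, u, u, fa, J_sc, J_bm, fa, J_sc, fa, J_bm, J_atpm), rids)
  xi <- matrix(0, 3, length(rids),
               dimnames = list(c("ATPM", "succinate", "biomass_bm"), rids))
  xi["ATPM", ] <- c(-1/4, 1/4, 1/4, 1/2, 0, 0, 1/2, 0, 1/2, 0, 1)
  xi["succinate", ] <- c(-1/4, 1/4, 1/4, -1/2, 1, 0, -1/2, 1, -1/2, 0, 0)
  xi["biomass_bm", ] <- c(-3/4, 3/4, 3/4, 1/2, 0, 1, 1/2, 0, 1/2, 1, 0)
  demands <- demand_set(c("ATPM", "succinate", "biomass_bm"),
                        c(J_atpm, J_sc, J_bm),
                        c("ATPM", "EX_sc", "DM_bm"),
                        c("maintenance", "excretion", "building_block"))
  list(model = model, demands = demands, substrate_id = "EX_glc_e",
       xi_analytic = xi, v_analytic = v,
       energy_id = "ATPM", byproduct_id = "succinate", atpm_id = "ATPM")
}

#' Toy model with a lumped biomass reaction
#'
#' The overflow fixture's network, but with the fixed demand reactions
#' replaced by a single lumped biomass reaction consuming `c_bm` mmol of
#' precursor and `gam` mmol of ATP per gDW of biomass, for exercising
#' [split_biomass()].
#'
#' @param c_bm precursor coefficient (mmol/gDW).
#' @param gam growth-associated ATP (mmol/gDW).
#' @return A [metabolic_model()].
#' @export
toy_biomass_model <- function(c_bm = 0.6, gam = 2) {
  fx <- fixture_overflow(10, 2, 1, "atp_consuming_biosynthesis")
  model <- fx$model
  # unfix demands, drop the bm sink, add the lumped reaction
  model <- set_bounds(model, "ATPM", lower = 0, upper = 1000)
  model <- set_bounds(model, "EX_ac", lower = 0, upper = 1000)
  k <- match("DM_bm", model$reactions$id)
  model$stoichiometry[[k]] <- NULL
  model$reactions <- model$reactions[-k, , drop = FALSE]
  model$reactions <- rbind(model$reactions, data.frame(
    id = "BIOMASS_toy", name = "lumped biomass", lower_bound = 0,
    upper_bound = 1000, gene_rule = "", subsystem = "biomass",
    stringsAsFactors = FALSE))
  model$stoichiometry$BIOMASS_toy <- c(bm = -c_bm, atp = -gam)
  model
}
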