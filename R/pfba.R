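#' Two-stage parsimonious FBA
#'
#' Stage 1 minimizes the substrate uptake magnitude (the negative of the
#' substrate exchange flux under the BiGG sign convention). Stage 2 fixes the
#' uptake to the stage-1 optimum (relaxed by a relative tolerance) and
#' minimizes the squared L2 norm of all fluxes, which makes the returned
#' flux vector unique.
#'
#' @param model a constrained [metabolic_model()] (demand bounds already
#'   applied, e.g. by [apply_condition()]).
#' @param demands optional [demand_set()]; if supplied, its entries are
#'   verified to be fixed in the model, and infeasibility errors name them.
#' @param substrate_id id of the substrate exchange reaction.
#' @param settings solver settings, see `solver_defaults`.
#' @return An object of class `flux_state`: list with `fluxes` (named
#'   vector), `stage1_objective` (uptake magnitude, mmol/gDW/h),
#'   `stage2_objective` (sum of squared fluxes), `solver_status`.
#' @export
solve_pfba <- function(model, demands = NULL, substrate_id,
                       settings = solver_defaults()) {
  rids <- model$reactions$id
  j <- match(substrate_id, rids)
  if (is.na(j)) stop("unknown substrate exchange: ", substrate_id)
  if (!is.null(demands)) {
    miss <- setdiff(demands$reaction_id, rids)
    if (length(miss) > 0) stop("demand reactions missing from model: ",
                               paste(miss, collapse = ", "))
  }
  S <- as.matrix(stoich_matrix(model))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  inf <- settings$inf_bound
  lb <- pmax(lb, -inf); ub <- pmin(ub, inf)
  cvec <- numeric(length(rids)); cvec[j] <- -1   # uptake negative => -v_j = magnitude
  st1 <- tryCatch(
    lp_via_regularization(S, rep(0, nrow(S)), lb, ub, cvec, settings),
    error = function(e) {
      extra <- if (!is.null(demands)) {
        paste0("; binding demands: ",
               paste(sprintf("%s=%g", demands$function_id, demands$J), collapse = ", "))
      } else ""
      stop("stage-1 infeasible or failed: ", conditionMessage(e), extra,
           call. = FALSE)
    })
  uptake <- st1$objective
  # stage 2: min ||v||^2 with uptake fixed to its optimum (relaxed)
  relax <- settings$stage1_fix_tol * max(1, abs(uptake))
  v <- qp_core(S, rep(0, nrow(S)), lb, ub, quad_diag = 2, lin = numeric(length(rids)),
               ineq_A = matrix(-cvec, 1), ineq_b = -(uptake + relax),
               inf_bound = inf)
  names(v) <- rids
  res <- max(abs(S %*% v))
  if (res > settings$feasibility_tol * max(1, max(abs(v))) * 10) {
    stop("mass-balance residual ", format(res), " exceeds tolerance")
  }
  structure(list(fluxes = v, stage1_objective = uptake,
                 stage2_objective = sum(v^2), solver_status = "optimal"),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> ", length(x$fluxes), " reactions; uptake = ",
      format(x$stage1_objective), "; ||v||^2 = ",
      format(x$stage2_objective), "; status = ", x$solver_status, "\n", sep = "")
  invisible(x)
}

#' Minimal substrate uptake (stage 1 only)
#'
#' @inheritParams solve_pfba
#' @return Uptake magnitude (mmol/gDW/h).
#' @export
minimal_uptake <- function(model, substrate_id, settings = solver_defaults()) {
  rids <- model$reactions$id
  j <- match(substrate_id, rids)
  if (is.na(j)) stop("unknown substrate exchange: ", substrate_id)
  S <- as.matrix(stoich_matrix(model))
  lb <- pmax(model$reactions$lower_bound, -settings$inf_bound)
  ub <- pmin(model$reactions$upper_bound, settings$inf_bound)
  cvec <- numeric(length(rids)); cvec[j] <- -1
  lp_via_regularization(S, rep(0, nrow(S)), lb, ub, cvec, settings)$objective
}

#' Maintenance-fit result
#'
#' @param sigma0 growth-independent maintenance ATP flux (mmol/gDW/h).
#' @param sigma growth-associated maintenance (mmol ATP/gDW per unit growth
#'   rate).
#' @param se standard errors (length 2).
#' @param residuals per-condition uptake misfits.
#' @return list of class `maintenance_fit`.
#' @export
maintenance_fit <- function(sigma0, sigma, se = c(NA, NA), residuals = numeric()) {
  structure(list(sigma0 = sigma0, sigma = sigma, se = se, residuals = residuals),
            class = "maintenance_fit")
}

#' Fit the growth-rate-dependent ATP maintenance flux
#'
#' Finds (sigma0, sigma) of J_ATPM = sigma0 + sigma * mu minimizing the sum
#' of squared residuals between measured substrate uptakes and the minimal
#' uptake computed by stage-1 pFBA with the candidate maintenance flux. The
#' search is a deterministic coarse grid followed by Gauss-Newton refinement
#' (the modeled uptake is piecewise linear in the maintenance flux, so the
#' refinement converges to the exact optimum within one linearity region).
#'
#' @param model_factory function(condition, atpm_flux) returning a
#'   constrained [metabolic_model()] for that condition with the maintenance
#'   reaction fixed at `atpm_flux`.
#' @param conditions data.frame with columns `mu`, `uptake_mmol_gDW_h` and
#'   `substrate_exchange_id` (see [read_conditions()]).
#' @param bounds list with `sigma0 = c(lo, hi)`, `sigma = c(lo, hi)` search
#'   box (defaults c(0, 50) and c(0, 100)).
#' @param grid_n coarse grid points per axis.
#' @param settings solver settings.
#' @return A [maintenance_fit()].
#' @export
fit_maintenance <- function(model_factory, conditions,
                            bounds = list(sigma0 = c(0, 50), sigma = c(0, 100)),
                            grid_n = 9, settings = solver_defaults()) {
  if (nrow(conditions) < 2) stop("need at least 2 conditions to fit 2 parameters")
  if (is.null(conditions$uptake_mmol_gDW_h) ||
      any(!is.finite(conditions$uptake_mmol_gDW_h))) {
    stop("conditions must carry finite measured uptakes")
  }
  modeled <- function(s0, s1) {
    vapply(seq_len(nrow(conditions)), function(i) {
      cond <- conditions[i, ]
      atpm <- s0 + s1 * cond$mu
      if (atpm < 0) return(NA_real_)
      tryCatch({
        m <- model_factory(cond, atpm)
        minimal_uptake(m, cond$substrate_exchange_id, settings)
      }, error = function(e) NA_real_)
    }, 0)
  }
  rss <- function(p) {
    u <- modeled(p[1], p[2])
    if (any(is.na(u))) return(Inf)
    sum((u - conditions$uptake_mmol_gDW_h)^2)
  }
  g0 <- seq(bounds$sigma0[1], bounds$sigma0[2], length.out = grid_n)
  g1 <- seq(bounds$sigma[1], bounds$sigma[2], length.out = grid_n)
  grid <- expand.grid(s0 = g0, s1 = g1)
  vals <- apply(grid, 1, rss)
  if (all(!is.finite(vals))) stop("model infeasible at all candidate parameters")
  best <- as.numeric(grid[which.min(vals), ])
  # Gauss-Newton: uptake is (piecewise) linear in (sigma0, sigma)
  p <- best
  h <- c(max(1e-4, diff(bounds$sigma0) * 1e-6),
         max(1e-4, diff(bounds$sigma) * 1e-6))
  for (iter in 1:30) {
    u0 <- modeled(p[1], p[2])
    if (any(is.na(u0))) break
    Jmat <- cbind((modeled(p[1] + h[1], p[2]) - u0) / h[1],
                  (modeled(p[1], p[2] + h[2]) - u0) / h[2])
    r <- conditions$uptake_mmol_gDW_h - u0
    step <- tryCatch(qr.solve(Jmat, r), error = function(e) NULL)
    if (is.null(step)) break
    pn <- pmin(pmax(p + step, c(bounds$sigma0[1], bounds$sigma[1])),
               c(bounds$sigma0[2], bounds$sigma[2]))
    if (rss(pn) <= rss(p) + 1e-15) {
      moved <- max(abs(pn - p))
      p <- pn
      if (moved < 1e-10) break
    } else break
  }
  u0 <- modeled(p[1], p[2])
  r <- conditions$uptake_mmol_gDW_h - u0
  Jmat <- cbind((modeled(p[1] + h[1], p[2]) - u0) / h[1],
                (modeled(p[1], p[2] + h[2]) - u0) / h[2])
  dof <- max(1, nrow(conditions) - 2)
  s2 <- sum(r^2) / dof
  cov <- tryCatch(s2 * solve(crossprod(Jmat)), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  maintenance_fit(sigma0 = p[1], sigma = p[2],
                  se = sqrt(pmax(diag(cov), 0)), residuals = r)
}

#' Select the NADH dehydrogenase of the electron transport chain
#'
#' Models the choice between the proton-pumping NDH-I complex (nuo genes,
#' high ATP yield) and the non-pumping NDH-II enzyme (ndh gene, low yield)
#' by closing the reactions of the unused dehydrogenase. Modes are exclusive
#' and reversible: switching restores the stored original bounds of the
#' other set.
#'
#' @param model a [metabolic_model()].
#' @param mode `"NDH_I"` or `"NDH_II"`.
#' @param ndh1_ids,ndh2_ids reaction ids of the NDH-I and NDH-II reactions;
#'   defaults find ids containing "NADH16"/"nuo" and "NADH5"/"ndh".
#' @return The modified model.
#' @export
set_etc_mode <- function(model, mode = c("NDH_I", "NDH_II"),
                         ndh1_ids = NULL, ndh2_ids = NULL) {
  mode <- match.arg(mode)
  rids <- model$reactions$id
  if (is.null(ndh1_ids)) {
    ndh1_ids <- rids[grepl("NADH16|nuo", rids, ignore.case = TRUE) |
                     grepl("nuo", model$reactions$gene_rule, ignore.case = TRUE)]
  }
  if (is.null(ndh2_ids)) {
    ndh2_ids <- rids[grepl("NADH5$|NDH2", rids, ignore.case = TRUE) |
                     grepl("\\bndh\\b", model$reactions$gene_rule, ignore.case = TRUE)]
  }
  ndh2_ids <- setdiff(ndh2_ids, ndh1_ids)
  if (length(ndh1_ids) == 0 && length(ndh2_ids) == 0) {
    stop("no electron-transport dehydrogenase reactions found in model")
  }
  if (length(ndh1_ids) == 0 || length(ndh2_ids) == 0) {
    stop("model carries only one dehydrogenase set; cannot switch modes")
  }
  orig <- attr(model, "etc_original_bounds")
  both <- c(ndh1_ids, ndh2_ids)
  if (is.null(orig)) {
    k <- match(both, rids)
    orig <- data.frame(id = both, lower = model$reactions$lower_bound[k],
                       upper = model$reactions$upper_bound[k],
                       stringsAsFactors = FALSE)
  }
  open_ids <- if (mode == "NDH_I") ndh1_ids else ndh2_ids
  close_ids <- if (mode == "NDH_I") ndh2_ids else ndh1_ids
  for (rid in open_ids) {
    o <- orig[orig$id == rid, ]
    model <- set_bounds(model, rid, lower = o$lower, upper = o$upper)
  }
  for (rid in close_ids) model <- set_bounds(model, rid, lower = 0, upper = 0)
  attr(model, "etc_original_bounds") <- orig
  attr(model, "etc_mode") <- mode
  model
}

#' ATP demand of protein synthesis
#'
#' tRNA charging plus peptide-bond formation cost 4 ATP equivalents per
#' amino-acid residue polymerized, so a cell with protein mass fraction p
#' (g protein per gDW) growing at rate mu synthesizes p*mu/m_aa residues
#' per gDW per hour (m_aa = mean residue mass) and spends four times that
#' in ATP.
#'
#' @param protein_mass_fraction_of_dw protein g per gDW (dimensionless).
#' @param mu growth rate (1/h).
#' @param mean_aa_mass mean amino-acid residue mass (g/mmol), default 0.109.
#' @return ATP demand flux (mmol ATP/gDW/h).
#' @export
protein_synthesis_atp_demand <- function(protein_mass_fraction_of_dw, mu,
                                         mean_aa_mass = 0.109) {
  if (protein_mass_fraction_of_dw <= 0 || mean_aa_mass <= 0 || mu < 0) {
    stop("inputs must be positive (mu may be zero)")
  }
  4 * protein_mass_fraction_of_dw * mu / mean_aa_mass
}
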