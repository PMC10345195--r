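# Synthetic condition, flux and proteome series with known ground truth.
#
# The generators emulate the study design the package is built for:
# exponential growth across a ladder of carbon-limited (C-limited) and
# translation-inhibited (R-limited) conditions, with measured substrate
# uptake and byproduct excretion fluxes, proteome sector fractions, and
# per-function protein allocations. Defaults are chosen once to be
# physiologically plausible for a fast-growing bacterium: maintenance law
# J_ATPM = 20 + 50*mu mmol/gDW/h (about 70 at the reference growth rate of
# 1/h), acetate onset around mu = 0.4/h, biomass-sector allocation of
# roughly 25-30% and an energy sector of 7-12%, and pathway efficiencies
# eps_res = 5.33, eps_fer = 9.62 mmol ATP/gDW/h per percent proteome.

#' Default generating parameters for the synthetic series
#'
#' @return Named list: maintenance law (`sigma0`, `sigma`), biomass
#'   coefficient (`c_bm`, mmol/gDW), acetate excretion law (`ac_intercept`,
#'   `ac_slope`), sector parameters (a [sector_params()]), pathway
#'   efficiencies and noise standard deviations.
#' @export
synthetic_defaults <- function() {
  list(sigma0 = 20, sigma = 50,
       c_bm = 8, ac_intercept = -4, ac_slope = 10,
       sector = sector_params(phi_E0 = 0.05, kappa_C = 0.3, kappa_R = 0.1,
                              phi_B0 = 0.05, b = 0.2, phi_H0 = 0.25,
                              Psi = 0.905, eps_res = 5.33, eps_fer = 9.62),
       nu_R_ref = 4, nu_C_ref = 10,
       noise_uptake_rel = 0.02, noise_phi = 0.005, noise_mu = 0.02)
}

#' Synthetic growth conditions on the overflow toy network
#'
#' Builds a mu ladder of conditions on the overflow fixture, with demand
#' fluxes J_bm = c_bm * mu, J_ac from the clipped linear acetate law, and
#' J_ATPM = sigma0 + sigma * mu; the "measured" glucose uptake is the
#' closed-form minimal uptake of the fixture, (J_ATPM + 9 J_ac + 11 J_bm)/22,
#' optionally with multiplicative Gaussian noise.
#'
#' @param mu_grid growth rates (1/h).
#' @param params generating parameters, see [synthetic_defaults()].
#' @param noise_rel relative s.d. of the uptake noise (0 = noiseless).
#' @param seed RNG seed (integer).
#' @return data.frame with one row per condition (columns `label`, `mu`,
#'   `substrate_exchange_id`, `uptake_mmol_gDW_h`, `uptake_true`,
#'   `acetate_mmol_gDW_h`, `J_bm`, `J_atpm_true`, `limitation`, `aerobic`).
#' @export
synthetic_conditions <- function(mu_grid = seq(0.3, 1.0, length.out = 8),
                                 params = synthetic_defaults(),
                                 noise_rel = params$noise_uptake_rel,
                                 seed = 1L) {
  stopifnot(all(mu_grid > 0))
  set.seed(seed)
  J_ac <- pmax(0, params$ac_intercept + params$ac_slope * mu_grid)
  J_bm <- params$c_bm * mu_grid
  J_atpm <- params$sigma0 + params$sigma * mu_grid
  u_true <- (J_atpm + 9 * J_ac + 11 * J_bm) / 22
  u_obs <- u_true * (1 + stats::rnorm(length(mu_grid), sd = noise_rel))
  data.frame(label = sprintf("C%02d", seq_along(mu_grid)),
             mu = mu_grid, substrate_exchange_id = "EX_glc_e",
             uptake_mmol_gDW_h = u_obs, uptake_true = u_true,
             acetate_mmol_gDW_h = J_ac, J_bm = J_bm, J_atpm_true = J_atpm,
             limitation = "C", aerobic = TRUE, stringsAsFactors = FALSE)
}

#' Constrained overflow model for a synthetic condition
#'
#' Factory suitable for [fit_maintenance()]: returns the overflow fixture
#' model with the biomass and acetate demands of the condition applied and
#' the maintenance reaction fixed at the candidate flux.
#'
#' @param condition one row of [synthetic_conditions()].
#' @param atpm_flux candidate maintenance flux (mmol/gDW/h).
#' @return A constrained [metabolic_model()].
#' @export
synthetic_condition_model <- function(condition, atpm_flux) {
  fx <- make_toy_network("overflow", J_atpm = max(atpm_flux, 1e-9),
                         J_ac = condition$acetate_mmol_gDW_h,
                         J_bm = condition$J_bm)
  fx$model
}

#' Synthetic proteome sector series
#'
#' Generates C-limitation (varying nu_C at fixed nu_R) and R-limitation
#' (varying nu_R at fixed nu_C) condition series from a [sector_params()],
#' with optional Gaussian noise on sector fractions and growth rates.
#'
#' @param params generating parameters, see [synthetic_defaults()].
#' @param n_C,n_R conditions per limitation series.
#' @param noise_phi,noise_mu noise s.d. on fractions and growth rates.
#' @param seed RNG seed.
#' @return data.frame with `limitation`, `nu_C`, `nu_R`, `mu`, the five
#'   sector fractions, and the noiseless truth in `*_true` columns.
#' @export
synthetic_sector_series <- function(params = synthetic_defaults(),
                                    n_C = 6, n_R = 6,
                                    noise_phi = params$noise_phi,
                                    noise_mu = params$noise_mu,
                                    seed = 1L) {
  set.seed(seed + 1L)
  sp <- params$sector
  nu_C <- c(seq(2, params$nu_C_ref, length.out = n_C),
            rep(params$nu_C_ref, n_R))
  nu_R <- c(rep(params$nu_R_ref, n_C),
            seq(1.5, params$nu_R_ref, length.out = n_R))
  truth <- predict_sectors(sp, nu_C, nu_R)
  out <- truth
  sectors <- c("foraging", "translation", "energy", "biomass", "housekeeping")
  for (s in sectors) {
    out[[paste0(s, "_true")]] <- truth[[s]]
    out[[s]] <- truth[[s]] + stats::rnorm(nrow(truth), sd = noise_phi)
  }
  out$mu_true <- truth$mu
  out$mu <- truth$mu + stats::rnorm(nrow(truth), sd = noise_mu)
  out$limitation <- rep(c("C", "R"), c(n_C, n_R))
  out$nu_C <- nu_C; out$nu_R <- nu_R
  out
}

#' Synthetic pathway-efficiency observations
#'
#' ATP fluxes proportional to allocated proteome percent, with Gaussian
#' noise, for recovering eps_res / eps_fer by origin-constrained fits.
#'
#' @param eps true efficiency (ATP flux per percent proteome).
#' @param phi_grid proteome percents.
#' @param noise_rel relative noise s.d. on the ATP fluxes.
#' @param seed RNG seed.
#' @return data.frame with `phi_percent`, `atp_flux`, `atp_true`.
#' @export
synthetic_efficiency_series <- function(eps, phi_grid = seq(0.5, 4, by = 0.5),
                                        noise_rel = 0.05, seed = 1L) {
  set.seed(seed + 2L)
  atp_true <- eps * phi_grid
  data.frame(phi_percent = phi_grid,
             atp_flux = atp_true * (1 + stats::rnorm(length(phi_grid), sd = noise_rel)),
             atp_true = atp_true)
}

#' Synthetic protein-allocation series
#'
#' Per-condition proteome fractions linear in the demand flux,
#' fraction = offset + slope * J, with Gaussian noise.
#'
#' @param offset,slope generating parameters.
#' @param J_grid demand fluxes (mmol/gDW/h).
#' @param noise_rel relative noise s.d. on the fractions.
#' @param seed RNG seed.
#' @return data.frame with `J`, `fraction`, `fraction_true`.
#' @export
synthetic_allocation_series <- function(offset = 0.002, slope = 0.01,
                                        J_grid = seq(0.2, 2, length.out = 8),
                                        noise_rel = 0.05, seed = 1L) {
  set.seed(seed + 3L)
  f_true <- offset + slope * J_grid
  data.frame(J = J_grid,
             fraction = f_true * (1 + stats::rnorm(length(J_grid), sd = noise_rel)),
             fraction_true = f_true)
}

#' Generate the full synthetic data bundle
#'
#' Emits the condition table, sector series, efficiency series and
#' allocation series with one seed, optionally writing them as TSV files.
#' Regeneration with the same seed is bit-identical.
#'
#' @param seed RNG seed.
#' @param params generating parameters, see [synthetic_defaults()].
#' @param dir output directory for TSV files (`NULL` = in-memory only).
#' @param noiseless set all noise levels to zero.
#' @return list with `conditions`, `sectors`, `efficiency_res`,
#'   `efficiency_fer`, `allocation`, `params`.
#' @export
make_synthetic_series <- function(seed = 1L, params = synthetic_defaults(),
                                  dir = NULL, noiseless = FALSE) {
  if (noiseless) {
    params$noise_uptake_rel <- 0; params$noise_phi <- 0; params$noise_mu <- 0
  }
  out <- list(
    conditions = synthetic_conditions(params = params, seed = seed),
    sectors = synthetic_sector_series(params = params, seed = seed),
    efficiency_res = synthetic_efficiency_series(
      params$sector$eps_res, noise_rel = if (noiseless) 0 else 0.05, seed = seed),
    efficiency_fer = synthetic_efficiency_series(
      params$sector$eps_fer, noise_rel = if (noiseless) 0 else 0.05, seed = seed + 10L),
    allocation = synthetic_allocation_series(
      noise_rel = if (noiseless) 0 else 0.05, seed = seed),
    params = params)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("conditions", "sectors", "efficiency_res",
                 "efficiency_fer", "allocation")) {
      utils::write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
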