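# Five-sector coarse-grained model of proteome allocation.
#
# Two condition parameters set the phenotype: the carbon quality nu_C and
# the translational capacity nu_R. Writing x = mu/nu_C and y = mu/nu_R,
# the default growth closure is
#
#   foraging      phi_F = x
#   translation   phi_R = y
#   energy        phi_E = phi_E0 + kappa_C * x + kappa_R * y
#   housekeeping  phi_H = phi_H0
#   biomass       phi_B = phi_B0 + b * mu
#   budget        b * mu = Psi - phi_F - phi_R - phi_E - phi_H
#
# The unit response coefficients of foraging and translation define the
# scales of nu_C and nu_R, which removes the gauge freedom between sector
# offsets and the per-condition latent parameters and makes the fit
# identifiable. The closure is pluggable; all packaged defaults use this
# one.

#' Coarse-grained sector model parameters
#'
#' @param phi_E0 energy-sector offset (proteome fraction).
#' @param kappa_C,kappa_R energy-sector responses to carbon starvation and
#'   translational limitation (dimensionless multipliers of mu/nu).
#' @param phi_B0 biomass-sector offset; `b` its slope versus growth rate
#'   (h).
#' @param phi_H0 housekeeping fraction (constant).
#' @param Psi proteome budget available to the five modeled sectors plus
#'   growth-proportional biomass allocation.
#' @param eps_res,eps_fer pathway protein efficiencies (ATP flux mmol/gDW/h
#'   per percent proteome), e.g. from [fit_pathway_efficiency()].
#' @param c chi-square scale factor weighting growth-rate residuals (h^2),
#'   default 0.1.
#' @return list of class `sector_params`.
#' @export
sector_params <- function(phi_E0, kappa_C, kappa_R, phi_B0, b, phi_H0, Psi,
                          eps_res = NA_real_, eps_fer = NA_real_, c = 0.1) {
  if (phi_E0 < 0) stop("phi_E0 must be non-negative")
  structure(list(phi_E0 = phi_E0, kappa_C = kappa_C, kappa_R = kappa_R,
                 phi_B0 = phi_B0, b = b, phi_H0 = phi_H0, Psi = Psi,
                 eps_res = eps_res, eps_fer = eps_fer, c = c),
            class = "sector_params")
}

#' Predict growth rate and sector fractions from condition parameters
#'
#' Solves the closure for mu given (nu_C, nu_R) and returns the five sector
#' fractions. Vectorized over conditions.
#'
#' @param params a [sector_params()].
#' @param nu_C,nu_R positive condition parameters (1/h-compatible).
#' @return data.frame with `mu` and columns `foraging`, `translation`,
#'   `energy`, `biomass`, `housekeeping`.
#' @export
predict_sectors <- function(params, nu_C, nu_R) {
  if (any(nu_C <= 0) || any(nu_R <= 0)) stop("nu parameters must be positive")
  denom <- params$b + (1 + params$kappa_C) / nu_C + (1 + params$kappa_R) / nu_R
  mu <- (params$Psi - params$phi_E0 - params$phi_H0) / denom
  if (any(mu <= 0)) stop("parameter combination gives non-positive growth rate")
  x <- mu / nu_C; y <- mu / nu_R
  data.frame(mu = mu, foraging = x, translation = y,
             energy = params$phi_E0 + params$kappa_C * x + params$kappa_R * y,
             biomass = params$phi_B0 + params$b * mu,
             housekeeping = rep(params$phi_H0, length(mu)))
}

# predictions for given latent coordinates x = mu/nu_C, y = mu/nu_R
sector_predict_xy <- function(theta, x, y) {
  phi_E <- theta["phi_E0"] + theta["kappa_C"] * x + theta["kappa_R"] * y
  mu <- (theta["Psi"] - x - y - phi_E - theta["phi_H0"]) / theta["b"]
  cbind(mu = mu, foraging = x, translation = y, energy = phi_E,
        biomass = theta["phi_B0"] + theta["b"] * mu,
        housekeeping = rep(theta["phi_H0"], length(x)))
}

sector_chi2 <- function(theta, xy, obs, c_scale) {
  pred <- sector_predict_xy(theta, xy[, 1], xy[, 2])
  sum((pred[, colnames(obs$phi)] - obs$phi)^2) +
    c_scale * sum((pred[, "mu"] - obs$mu)^2)
}

#' Fit the coarse-grained sector model
#'
#' Minimizes chi^2 = sum (delta phi)^2 + c * sum (delta mu)^2 over the
#' global parameters and the per-condition latent coordinates
#' (x, y) = (mu/nu_C, mu/nu_R). Initialization is closed-form (ordinary
#' least squares on the observed sectors, exact for noiseless data),
#' followed by deterministic alternating refinement from a fixed lattice of
#' multi-starts.
#'
#' @param sector_data data.frame with columns `foraging`, `translation`,
#'   `energy`, `biomass`, `housekeeping` (proteome fractions), one row per
#'   condition.
#' @param growth_rates observed growth rates (1/h).
#' @param c chi-square scale factor (h^2), default 0.1.
#' @param n_starts number of deterministic multi-starts.
#' @return list of class `sector_fit`: `params` (a [sector_params()]),
#'   `nu_C`, `nu_R` (per condition), `chi2`, `chi2_phi`, `chi2_mu`,
#'   `predicted` (data.frame).
#' @export
fit_sector_model <- function(sector_data, growth_rates, c = 0.1, n_starts = 16) {
  need <- c("foraging", "translation", "energy", "biomass", "housekeeping")
  if (!all(need %in% names(sector_data))) {
    stop("sector data must have columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(sector_data)
  if (n < 2) stop("need at least 2 conditions")
  if (stats::sd(growth_rates) == 0) stop("degenerate data: all growth rates equal")
  obs <- list(phi = as.matrix(sector_data[, need]), mu = growth_rates)

  # closed-form initialization (exact when the data are noiseless)
  x0 <- sector_data$foraging
  y0 <- sector_data$translation
  fe <- stats::lm(sector_data$energy ~ x0 + y0)
  fb <- stats::lm(sector_data$biomass ~ growth_rates)
  theta0 <- c(phi_E0 = max(0, unname(stats::coef(fe)[1])),
              kappa_C = unname(stats::coef(fe)[2]),
              kappa_R = unname(stats::coef(fe)[3]),
              phi_B0 = unname(stats::coef(fb)[1]),
              b = unname(stats::coef(fb)[2]),
              phi_H0 = mean(sector_data$housekeeping),
              Psi = mean(unname(stats::coef(fb)[2]) * growth_rates +
                         x0 + y0 + sector_data$energy +
                         mean(sector_data$housekeeping)))
  if (anyNA(theta0)) stop("degenerate sector data (collinear observations)")

  refine <- function(theta, xy) {
    for (sweep in 1:12) {
      chi_before <- sector_chi2(theta, xy, obs, c)
      for (i in seq_len(n)) {   # per-condition latent update
        fi <- function(p) {
          xy2 <- xy; xy2[i, ] <- p
          sector_chi2(theta, xy2, obs, c)
        }
        o <- stats::optim(xy[i, ], fi, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 400))
        xy[i, ] <- o$par
      }
      o <- stats::optim(theta, sector_chi2, xy = xy, obs = obs, c_scale = c,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
      theta <- o$par
      if (chi_before - o$value < 1e-14) break
    }
    list(theta = theta, xy = xy, chi2 = sector_chi2(theta, xy, obs, c))
  }

  xy0 <- cbind(x0, y0)
  best <- refine(theta0, xy0)
  # deterministic multi-start lattice around the data-driven start
  scales <- expand.grid(a = c(0.8, 1, 1.25, 1.6), b = c(0.8, 1, 1.25, 1.6))
  for (s in seq_len(min(n_starts, nrow(scales)))) {
    if (best$chi2 < 1e-14) break   # data-driven start already at the optimum
    if (scales$a[s] == 1 && scales$b[s] == 1) next
    th <- theta0
    th["kappa_C"] <- th["kappa_C"] * scales$a[s]
    th["kappa_R"] <- th["kappa_R"] * scales$b[s]
    cand <- refine(th, xy0)
    if (cand$chi2 < best$chi2 - 1e-15) best <- cand
  }
  theta <- best$theta; xy <- best$xy
  pred <- sector_predict_xy(theta, xy[, 1], xy[, 2])
  chi2_phi <- sum((pred[, need] - obs$phi)^2)
  chi2_mu <- sum((pred[, "mu"] - obs$mu)^2)

  # standard errors from the observed information of the full parameter
  # vector (globals + per-condition latents): cov = 2 s^2 H^{-1}, with the
  # residual scale s^2 = chi2 / (N - P)
  p_full <- c(theta, as.vector(xy))
  chi2_full <- function(p) {
    th <- p[seq_along(theta)]; names(th) <- names(theta)
    sector_chi2(th, matrix(p[-seq_along(theta)], ncol = 2), obs, c)
  }
  P <- length(p_full); N <- 6 * n
  H <- matrix(NA_real_, P, P)
  h <- pmax(abs(p_full), 1) * 1e-5
  f0 <- chi2_full(p_full)
  for (a in seq_len(P)) {
    for (bidx in a:P) {
      pa <- p_full; pa[a] <- pa[a] + h[a]; pa[bidx] <- pa[bidx] + h[bidx]
      pb <- p_full; pb[a] <- pb[a] + h[a]; pb[bidx] <- pb[bidx] - h[bidx]
      pc <- p_full; pc[a] <- pc[a] - h[a]; pc[bidx] <- pc[bidx] + h[bidx]
      pd <- p_full; pd[a] <- pd[a] - h[a]; pd[bidx] <- pd[bidx] - h[bidx]
      H[a, bidx] <- H[bidx, a] <-
        (chi2_full(pa) - chi2_full(pb) - chi2_full(pc) + chi2_full(pd)) /
        (4 * h[a] * h[bidx])
    }
  }
  s2 <- max(f0, 0) / max(1, N - P)
  se <- tryCatch({
    cov <- 2 * s2 * solve(H)
    sqrt(pmax(diag(cov)[seq_along(theta)], 0))
  }, error = function(e) rep(NA_real_, length(theta)))
  names(se) <- names(theta)
  params <- sector_params(phi_E0 = unname(theta["phi_E0"]),
                          kappa_C = unname(theta["kappa_C"]),
                          kappa_R = unname(theta["kappa_R"]),
                          phi_B0 = unname(theta["phi_B0"]),
                          b = unname(theta["b"]),
                          phi_H0 = unname(theta["phi_H0"]),
                          Psi = unname(theta["Psi"]), c = c)
  structure(list(params = params, se = se,
                 nu_C = unname(pred[, "mu"] / xy[, 1]),
                 nu_R = unname(pred[, "mu"] / xy[, 2]),
                 chi2 = chi2_phi + c * chi2_mu,
                 chi2_phi = chi2_phi, chi2_mu = chi2_mu,
                 predicted = as.data.frame(pred)),
            class = "sector_fit")
}

#' Predict the respiration/fermentation split and byproduct overflow
#'
#' Given the energy-sector fraction phi_E from the allocation model and a
#' condition's ATP demand, splits phi_E into respiration- and
#' fermentation-associated protein so that their efficiency-weighted ATP
#' supply meets the demand: fermentation protein appears only when the
#' demand exceeds what respiration alone can deliver within phi_E
#' (phi_f = (J_E - eps_res * phi_E) / (eps_fer - eps_res), clipped to
#' [0, phi_E]). The byproduct excretion flux follows from the fermentation
#' ATP flux via the fermentation mode's ATP-per-byproduct stoichiometry.
#'
#' @param params a [sector_params()] with `eps_res`, `eps_fer` set.
#' @param conditions data.frame with columns `nu_C`, `nu_R` (or a
#'   precomputed `mu` and `phi_E`).
#' @param energy_demand function(mu) returning the ATP demand flux
#'   (mmol/gDW/h), e.g. from a fitted maintenance law.
#' @param atp_per_byproduct ATP delivered per byproduct molecule excreted by
#'   the fermentation mode (from the coupled decomposition, not a
#'   hard-coded constant).
#' @return data.frame with `mu`, `phi_E`, `phi_E_res`, `phi_E_fer`
#'   (fractions), `atp_demand`, `byproduct_flux`, `feasible`.
#' @export
predict_overflow <- function(params, conditions, energy_demand,
                             atp_per_byproduct) {
  if (is.na(params$eps_res) || is.na(params$eps_fer)) {
    stop("eps_res and eps_fer must be set in the sector parameters")
  }
  if (params$eps_fer <= params$eps_res) {
    stop("expected eps_fer > eps_res (fermentation is the protein-cheaper ",
         "ATP source per unit mass)")
  }
  if (!is.null(conditions$mu) && !is.null(conditions$phi_E)) {
    mu <- conditions$mu; phi_E <- conditions$phi_E
  } else {
    pred <- predict_sectors(params, conditions$nu_C, conditions$nu_R)
    mu <- pred$mu; phi_E <- pred$energy
  }
  JE <- energy_demand(mu)
  phiE_pct <- 100 * phi_E
  phif_pct <- (JE - params$eps_res * phiE_pct) /
    (params$eps_fer - params$eps_res)
  phif_pct <- pmin(pmax(phif_pct, 0), phiE_pct)
  feasible <- params$eps_fer * phiE_pct >= JE - 1e-9
  byp <- params$eps_fer * phif_pct / atp_per_byproduct
  data.frame(mu = mu, phi_E = phi_E,
             phi_E_res = (phiE_pct - phif_pct) / 100,
             phi_E_fer = phif_pct / 100,
             atp_demand = JE, byproduct_flux = byp, feasible = feasible)
}
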