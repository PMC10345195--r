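# Functional decomposition of optimal flux states.
#
# Around a unique two-stage pFBA optimum the flux vector is a linear
# function of the demand fluxes, v = sum_gamma xi^(gamma) J_gamma, where the
# response vectors xi^(gamma) are the derivatives of the optimal fluxes with
# respect to each demand. Each component v^(gamma) = xi^(gamma) J_gamma is
# itself mass-balanced and describes the complete pathway serving one
# biological function (a building block, maintenance ATP, or a constrained
# excretion).

#' Compute the demand-flux response matrix
#'
#' Estimates xi^(gamma) by finite differences: each demand flux is perturbed
#' by delta_gamma = delta * max(J_gamma, J_floor), the two-stage pFBA is
#' re-solved (with the substrate minimum re-optimized, since uptake is a
#' dependent variable), and a central difference is formed. If one side is
#' infeasible the one-sided difference is used.
#'
#' @param model a constrained [metabolic_model()] with demand bounds applied.
#' @param demands a [demand_set()].
#' @param substrate_id substrate exchange id.
#' @param delta relative perturbation size (default 1e-6).
#' @param J_floor absolute demand floor for zero demands (mmol/gDW/h).
#' @param settings solver settings.
#' @return Object of class `response_matrix`: list with `xi` (matrix,
#'   functions x reactions), `demand_ids`, `reaction_ids`, `delta`, `base`
#'   (the base `flux_state`).
#' @export
compute_response_matrix <- function(model, demands, substrate_id,
                                    delta = 1e-6, J_floor = 1e-6,
                                    settings = solver_defaults()) {
  if (delta <= 0) stop("delta must be positive")
  base <- solve_pfba(model, demands, substrate_id, settings)
  rids <- model$reactions$id
  solve_at <- function(k, J) {
    m <- model
    j <- match(demands$reaction_id[k], rids)
    m$reactions$lower_bound[j] <- J
    m$reactions$upper_bound[j] <- J
    solve_pfba(m, demands, substrate_id, settings)$fluxes
  }
  xi <- matrix(0, nrow(demands), length(rids),
               dimnames = list(demands$function_id, rids))
  for (k in seq_len(nrow(demands))) {
    Jk <- demands$J[k]
    dk <- delta * max(Jk, J_floor)
    vp <- tryCatch(solve_at(k, Jk + dk), error = function(e) NULL)
    vm <- if (Jk - dk >= 0) tryCatch(solve_at(k, Jk - dk), error = function(e) NULL)
          else NULL
    if (!is.null(vp) && !is.null(vm)) {
      xi[k, ] <- (vp - vm) / (2 * dk)
    } else if (!is.null(vp)) {
      xi[k, ] <- (vp - base$fluxes) / dk
    } else if (!is.null(vm)) {
      xi[k, ] <- (base$fluxes - vm) / dk
    } else {
      stop("perturbation infeasible in both directions for demand ",
           demands$function_id[k])
    }
  }
  structure(list(xi = xi, demand_ids = demands$function_id,
                 reaction_ids = rids, delta = delta, base = base),
            class = "response_matrix")
}

#' Decompose a flux state into functional components
#'
#' Forms the components v^(gamma) = xi^(gamma) * J_gamma and verifies the
#' reconstruction identity sum_gamma v^(gamma) = v. A residual above
#' tolerance signals an active-set change or a non-unique optimum and is an
#' error (try a smaller `delta` in [compute_response_matrix()]).
#'
#' @param xi a `response_matrix`.
#' @param demands the [demand_set()] used to compute `xi`.
#' @param v a `flux_state` (defaults to the base state stored in `xi`).
#' @param tol relative reconstruction tolerance.
#' @return Object of class `flux_decomposition`: list with `components`
#'   (matrix, functions x reactions, mmol/gDW/h), `fluxes`, `demands`,
#'   `categories` (named by function id), `reconstruction_residual`.
#' @export
decompose_fluxes <- function(xi, demands, v = NULL, tol = 1e-6) {
  if (!identical(rownames(xi$xi), demands$function_id)) {
    stop("response matrix and demand set are not aligned")
  }
  if (is.null(v)) v <- xi$base
  comp <- xi$xi * demands$J
  vvec <- v$fluxes[xi$reaction_ids]
  residual <- max(abs(colSums(comp) - vvec))
  scale <- max(1, max(abs(vvec)))
  if (residual > tol * scale) {
    stop("decomposition invalid: reconstruction residual ", format(residual),
         " exceeds ", format(tol * scale),
         " (active-set change or non-unique optimum; try a smaller delta)")
  }
  categories <- stats::setNames(as.character(demands$category), demands$function_id)
  structure(list(components = comp, fluxes = vvec, demands = demands,
                 categories = categories, reconstruction_residual = residual),
            class = "flux_decomposition")
}

#' @export
print.flux_decomposition <- function(x, ...) {
  cat("<flux_decomposition> ", nrow(x$components), " functions x ",
      ncol(x$components), " reactions; reconstruction residual ",
      format(x$reconstruction_residual), "\n", sep = "")
  invisible(x)
}

#' Mixed (cancellation) fraction per reaction
#'
#' F_mix = (sum_gamma |v_i^(gamma)| - |v_i|) / sum_gamma |v_i^(gamma)|.
#' Zero in the absence of opposite-signed components; approaches one for
#' large cancelling components. Reactions whose components are all zero get
#' F_mix = 0.
#'
#' @param decomp a `flux_decomposition` (or a plain components matrix with
#'   `v` supplied).
#' @param v total flux vector; taken from `decomp` if absent.
#' @return Named numeric vector in \[0, 1\].
#' @export
mixed_fractions <- function(decomp, v = NULL) {
  comp <- if (inherits(decomp, "flux_decomposition")) decomp$components else decomp
  if (is.null(v)) v <- decomp$fluxes
  tot <- colSums(abs(comp))
  # reactions whose components are numerically zero (finite-difference
  # noise only) carry no cancellation
  fmix <- ifelse(tot > 1e-9, (tot - abs(v)) / tot, 0)
  pmin(pmax(fmix, 0), 1)
}

#' Per-reaction functional shares
#'
#' Computes F_mix per reaction and distributes the remaining fraction
#' 1 - F_mix across the functions whose component sign matches the sign of
#' the total flux, proportionally to the component magnitudes.
#' Opposite-signed components contribute only to the mixed fraction. When no
#' components cancel this reduces exactly to F^(gamma) = v^(gamma) / v.
#'
#' @param decomp a `flux_decomposition`.
#' @param activity_threshold reactions with |v| below this flux
#'   (mmol/gDW/h) are flagged inactive and excluded from reports (default
#'   1e-4, the clustering flux filter).
#' @return Object of class `functional_shares`: list with `shares` (matrix,
#'   reactions x functions), `F_mix`, `flux`, `active`.
#' @export
functional_shares <- function(decomp, activity_threshold = 1e-4) {
  comp <- decomp$components
  v <- decomp$fluxes
  fmix <- mixed_fractions(decomp)
  n_r <- ncol(comp)
  shares <- matrix(0, n_r, nrow(comp),
                   dimnames = list(colnames(comp), rownames(comp)))
  for (i in seq_len(n_r)) {
    if (v[i] == 0) next
    ci <- comp[, i]
    match_sign <- sign(ci) == sign(v[i])
    wsum <- sum(abs(ci[match_sign]))
    if (wsum > 0) shares[i, match_sign] <- (1 - fmix[i]) * abs(ci[match_sign]) / wsum
  }
  active <- abs(v) >= activity_threshold
  # below the activity threshold the components are dominated by
  # finite-difference noise; such reactions are excluded from reports and
  # their shares zeroed
  shares[!active, ] <- 0
  fmix[!active] <- 0
  structure(list(shares = shares, F_mix = fmix, flux = v,
                 active = active, categories = decomp$categories),
            class = "functional_shares")
}

#' Define a coupling specification
#'
#' A coupling linearly recombines flux components into new ones. Each group
#' names a new function and lists member functions with non-negative weights;
#' weights over all groups must sum to one for every original function, so
#' the summed components are conserved exactly.
#'
#' @param groups list of lists with elements `id` (new function id),
#'   `members` (character), `weights` (numeric, same length), and optionally
#'   `category`.
#' @param provenance `"user"` or `"auto"`.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(groups, provenance = c("user", "auto")) {
  provenance <- match.arg(provenance)
  for (g in groups) {
    if (length(g$members) != length(g$weights)) {
      stop("group ", g$id, ": members and weights differ in length")
    }
    if (any(g$weights < 0)) stop("group ", g$id, ": negative weights")
  }
  structure(list(groups = groups, provenance = provenance),
            class = "coupling_spec")
}

#' Apply a coupling specification to a decomposition
#'
#' Functions not mentioned in any group pass through unchanged. The total
#' component sum is conserved exactly (this is checked): each original
#' function's weights across groups must add to one.
#'
#' @param decomp a `flux_decomposition`.
#' @param spec a [coupling_spec()].
#' @return A new `flux_decomposition` whose demand table aggregates member
#'   demands per group.
#' @export
couple_components <- function(decomp, spec) {
  comp <- decomp$components
  fids <- rownames(comp)
  used <- unlist(lapply(spec$groups, `[[`, "members"))
  unknown <- setdiff(used, fids)
  if (length(unknown) > 0) stop("coupling references unknown functions: ",
                                paste(unknown, collapse = ", "))
  wtot <- stats::setNames(rep(0, length(fids)), fids)
  for (g in spec$groups) wtot[g$members] <- wtot[g$members] + g$weights
  untouched <- fids[wtot == 0]
  if (any(wtot > 0 & abs(wtot - 1) > 1e-12)) {
    stop("coupling weights do not sum to one for: ",
         paste(fids[wtot > 0 & abs(wtot - 1) > 1e-12], collapse = ", "),
         " (would break component conservation)")
  }
  rows <- list(); cats <- character(0); Js <- numeric(0); targets <- character(0)
  for (g in spec$groups) {
    rows[[g$id]] <- colSums(comp[g$members, , drop = FALSE] * g$weights)
    cats[g$id] <- g$category %||% paste(
      unique(decomp$categories[g$members]), collapse = "+")
    Js[g$id] <- sum(decomp$demands$J[match(g$members, fids)] * g$weights)
    targets[g$id] <- decomp$demands$reaction_id[match(g$members[1], fids)]
  }
  for (f in untouched) {
    rows[[f]] <- comp[f, ]
    cats[f] <- decomp$categories[[f]]
    Js[f] <- decomp$demands$J[match(f, fids)]
    targets[f] <- decomp$demands$reaction_id[match(f, fids)]
  }
  newcomp <- do.call(rbind, rows)
  colnames(newcomp) <- colnames(comp)
  if (max(abs(colSums(newcomp) - colSums(comp))) > 1e-9 * max(1, max(abs(comp)))) {
    stop("coupling produced a non-conservative component set")
  }
  dem <- data.frame(function_id = names(rows), J = unname(Js[names(rows)]),
                    reaction_id = unname(targets[names(rows)]),
                    category = NA_character_, stringsAsFactors = FALSE)
  dem$category <- ifelse(cats[dem$function_id] %in%
                           c("building_block", "maintenance", "excretion"),
                         cats[dem$function_id], "coupled")
  structure(list(components = newcomp, fluxes = decomp$fluxes, demands = dem,
                 categories = cats[names(rows)],
                 reconstruction_residual = decomp$reconstruction_residual),
            class = "flux_decomposition")
}

#' Couple an energy component with a constrained byproduct component
#'
#' Re-expresses the pair as a fermentation mode (the byproduct component plus
#' a fraction beta of the energy component) and a respiration mode (the
#' remaining 1 - beta of the energy component). The respiration mode carries
#' no byproduct excretion; the fermentation mode carries all of it. beta is
#' derived, not fitted: candidate values are the sign-change breakpoints of
#' the fermentation-mode entries, and the smallest beta minimizing the
#' flux-weighted total mismatch is taken. At that beta the fermentation
#' mode's flux through the maintenance reaction equals the stoichiometric
#' ATP yield of the excretion route times the excretion flux.
#'
#' @param decomp a `flux_decomposition`.
#' @param energy_id function id of the energy (maintenance) component.
#' @param byproduct_id function id of the constrained excretion component.
#' @param mode_ids ids for the two new modes (fermentation, respiration).
#' @return A coupled `flux_decomposition` with attribute `"beta"`.
#' @export
couple_energy_byproduct <- function(decomp, energy_id, byproduct_id,
                                    mode_ids = c("fermentation", "respiration")) {
  comp <- decomp$components
  if (!all(c(energy_id, byproduct_id) %in% rownames(comp))) {
    stop("energy or byproduct function not present in decomposition")
  }
  e <- comp[energy_id, ]; b <- comp[byproduct_id, ]
  breaks <- -b[abs(e) > 1e-12] / e[abs(e) > 1e-12]
  cand <- sort(unique(c(0, 1, breaks[breaks > 0 & breaks < 1])))
  score <- function(beta) {
    spec <- coupling_spec(list(
      list(id = mode_ids[1], members = c(byproduct_id, energy_id),
           weights = c(1, beta), category = "fermentation"),
      list(id = mode_ids[2], members = c(energy_id), weights = 1 - beta,
           category = "respiration")))
    d2 <- couple_components(decomp, spec)
    sum(abs(d2$fluxes) * mixed_fractions(d2))
  }
  vals <- vapply(cand, score, 0)
  beta <- cand[which(vals <= min(vals) + 1e-12)[1]]
  spec <- coupling_spec(list(
    list(id = mode_ids[1], members = c(byproduct_id, energy_id),
         weights = c(1, beta), category = "fermentation"),
    list(id = mode_ids[2], members = c(energy_id), weights = 1 - beta,
         category = "respiration")))
  out <- couple_components(decomp, spec)
  attr(out, "beta") <- beta
  out
}

#' Greedy search for mismatch-reducing couplings
#'
#' Greedily merges pairs of candidate functions (by summing their
#' components), at each step performing the merge that maximally reduces the
#' flux-weighted total mixed fraction sum_i |v_i| F_i^mix, until no merge
#' improves it by more than `tol`. Ties break lexicographically by function
#' id. Returns the coupling specification (empty when nothing helps).
#'
#' @param decomp a `flux_decomposition`.
#' @param candidate_functions functions eligible for merging (default: all).
#' @param flux_weighting weight the mismatch by |v_i| (default TRUE).
#' @param tol minimal absolute improvement (flux-weighted mismatch,
#'   mmol/gDW/h) to accept a merge; the default sits above the
#'   finite-difference noise floor of the response matrix.
#' @return A [coupling_spec()] with provenance `"auto"`.
#' @export
auto_coupling_search <- function(decomp, candidate_functions = NULL,
                                 flux_weighting = TRUE, tol = 1e-6) {
  if (is.null(candidate_functions)) candidate_functions <- rownames(decomp$components)
  if (length(candidate_functions) < 2) stop("need at least 2 candidate functions")
  total_mismatch <- function(d) {
    w <- if (flux_weighting) abs(d$fluxes) else 1
    sum(w * mixed_fractions(d))
  }
  # track which original functions each working component aggregates
  membership <- stats::setNames(as.list(candidate_functions), candidate_functions)
  cur <- decomp
  repeat {
    ids <- sort(names(membership))
    if (length(ids) < 2) break
    best <- NULL; best_gain <- tol; base_score <- total_mismatch(cur)
    for (a_i in seq_len(length(ids) - 1)) {
      for (b_i in (a_i + 1):length(ids)) {
        a <- ids[a_i]; b <- ids[b_i]
        spec <- coupling_spec(list(list(
          id = paste(sort(c(a, b)), collapse = "+"),
          members = c(a, b), weights = c(1, 1))), provenance = "auto")
        trial <- couple_components(cur, spec)
        gain <- base_score - total_mismatch(trial)
        if (gain > best_gain) { best <- c(a, b); best_gain <- gain }
      }
    }
    if (is.null(best)) break
    new_id <- paste(sort(best), collapse = "+")
    spec <- coupling_spec(list(list(id = new_id, members = best,
                                    weights = c(1, 1))), provenance = "auto")
    cur <- couple_components(cur, spec)
    membership[[new_id]] <- unlist(membership[best])
    membership[best] <- NULL
  }
  merged <- membership[vapply(membership, length, 1L) > 1]
  coupling_spec(lapply(names(merged), function(id) {
    list(id = id, members = merged[[id]], weights = rep(1, length(merged[[id]])))
  }), provenance = "auto")
}

#' Cluster reactions into functional modules
#'
#' Agglomerative hierarchical clustering (average linkage) on the cityblock
#' (Manhattan) distance between reaction share profiles, restricted to a
#' subset of functions plus the mixed fraction. Only reactions whose flux
#' magnitude passes the activity filter enter the clustering.
#'
#' @param shares a `functional_shares` object.
#' @param function_subset functions to include (default: all).
#' @param distance_threshold height at which the dendrogram is cut into flat
#'   modules.
#' @param include_mixed include F_mix as an extra profile coordinate.
#' @return list with `tree` (hclust), `phylo` (ape phylogeny of the
#'   dendrogram, for Newick export), `modules` (named integer vector),
#'   `profiles` (the clustered matrix).
#' @export
cluster_functional_modules <- function(shares, function_subset = NULL,
                                       distance_threshold = 0.5,
                                       include_mixed = TRUE) {
  if (is.null(function_subset)) function_subset <- colnames(shares$shares)
  if (length(function_subset) == 0) stop("empty function subset")
  keep <- shares$active
  M <- shares$shares[keep, function_subset, drop = FALSE]
  if (include_mixed) M <- cbind(M, mixed = shares$F_mix[keep])
  if (nrow(M) < 2) stop("fewer than 2 reactions pass the flux filter")
  d <- stats::dist(M, method = "manhattan")
  tree <- stats::hclust(d, method = "average")
  modules <- stats::cutree(tree, h = distance_threshold)
  phylo <- ape::as.phylo(tree)
  list(tree = tree, phylo = phylo, modules = modules, profiles = M)
}

#' Write a module dendrogram in Newick format
#'
#' @param clustering result of [cluster_functional_modules()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_module_tree <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}
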