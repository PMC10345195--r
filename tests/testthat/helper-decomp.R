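# Shared helpers for the test suite.

fixture_kinds <- c("linear_chain", "parallel_paths", "branch",
                   "overflow", "cofactor_mix", "anaerobic_mix")

# full numeric chain: pFBA -> response matrix -> decomposition
decompose_fixture <- function(fx, delta = 1e-6) {
  xi <- compute_response_matrix(fx$model, fx$demands, fx$substrate_id,
                                delta = delta)
  decompose_fluxes(xi, fx$demands)
}

# build a flux_decomposition directly from a components matrix (for unit
# tests of the share/mixing arithmetic that need full control of the inputs)
fake_decomposition <- function(components, categories = NULL) {
  v <- colSums(components)
  demands <- demand_set(rownames(components),
                        J = rep(1, nrow(components)),
                        reaction_id = colnames(components)[seq_len(nrow(components))],
                        category = categories %||%
                          rep("building_block", nrow(components)))
  structure(list(components = components, fluxes = v, demands = demands,
                 categories = stats::setNames(as.character(demands$category),
                                              demands$function_id),
                 reconstruction_residual = 0),
            class = "flux_decomposition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
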