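# End-to-end orchestration: load -> constrain -> pFBA -> decompose ->
# couple -> shares -> costs, with a reproducible run manifest.

#' Validate a pipeline configuration
#'
#' @param config list; recognized fields: `fixture` (toy-network kind) or
#'   `model` (path) + `demands` (path to a TSV with columns `function_id`,
#'   `J`, `reaction_id`, `category`), `substrate_id`, `delta`,
#'   `activity_threshold`, `coupling` (`"auto"`, `"canonical"`, `"none"`),
#'   `cluster_threshold`, `atpm_id`, `out`.
#' @return The config with defaults filled in.
#' @export
validate_config <- function(config) {
  defaults <- list(delta = 1e-6, activity_threshold = 1e-4,
                   coupling = "auto", cluster_threshold = 0.5,
                   atpm_id = "ATPM")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$fixture) && is.null(config$model)) {
    stop("config needs either 'fixture' (toy kind) or 'model' (file path)")
  }
  if (!config$coupling %in% c("auto", "canonical", "none")) {
    stop("coupling must be auto, canonical or none")
  }
  if (is.null(config$out)) stop("config needs an output directory 'out'")
  config
}

#' Run the decomposition pipeline
#'
#' Executes the full chain on a fixture or a model file and writes all
#' stage outputs (fluxes, components, shares, modules, energy balance) plus
#' a manifest recording the configuration hash, package version and
#' tolerances. Rerunning with the same configuration reproduces the numeric
#' outputs.
#'
#' @param config see [validate_config()].
#' @return The output directory, invisibly; stage results are also returned
#'   in the attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("fluxdecomp")),
                   stages = character(0))
  tsv <- function(x, name) {
    utils::write.table(x, file.path(config$out, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  finish <- function(ok, error = NULL) {
    manifest$status <- if (ok) "complete" else "failed"
    manifest$error <- error
    cfg_file <- file.path(config$out, "config.json")
    jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    manifest$config_hash <- unname(tools::md5sum(cfg_file))
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res <- list()
  step <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      finish(FALSE, paste0(name, ": ", conditionMessage(e)))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    out
  }

  inputs <- step("load", {
    if (!is.null(config$fixture)) {
      fx <- make_toy_network(config$fixture)
      list(model = fx$model, demands = fx$demands,
           substrate_id = config$substrate_id %||% fx$substrate_id,
           energy_id = fx$energy_id, byproduct_id = fx$byproduct_id)
    } else {
      model <- load_model(config$model)
      if (!file.exists(config$demands)) {
        stop("demand table not found: ", config$demands)
      }
      dm <- utils::read.delim(config$demands, stringsAsFactors = FALSE)
      list(model = model,
           demands = demand_set(dm$function_id, dm$J, dm$reaction_id,
                                dm$category),
           substrate_id = config$substrate_id)
    }
  })
  res$flux <- step("pfba",
    solve_pfba(inputs$model, inputs$demands, inputs$substrate_id))
  tsv(data.frame(reaction_id = names(res$flux$fluxes),
                 flux_mmol_gDW_h = unname(res$flux$fluxes)), "fluxes")
  res$xi <- step("response_matrix",
    compute_response_matrix(inputs$model, inputs$demands, inputs$substrate_id,
                            delta = config$delta))
  res$decomp <- step("decompose", decompose_fluxes(res$xi, inputs$demands))
  res$coupled <- step("couple", switch(config$coupling,
    none = res$decomp,
    auto = {
      spec <- auto_coupling_search(res$decomp)
      if (length(spec$groups) > 0) couple_components(res$decomp, spec) else res$decomp
    },
    canonical = {
      if (is.null(inputs$energy_id) || is.null(inputs$byproduct_id)) {
        stop("canonical coupling needs energy and byproduct function ids")
      }
      couple_energy_byproduct(res$decomp, inputs$energy_id, inputs$byproduct_id)
    }))
  tsv(data.frame(reaction_id = colnames(res$coupled$components),
                 t(res$coupled$components)), "components")
  res$shares <- step("shares",
    functional_shares(res$coupled, config$activity_threshold))
  tsv(data.frame(reaction_id = rownames(res$shares$shares),
                 res$shares$shares, F_mix = res$shares$F_mix,
                 flux = res$shares$flux, active = res$shares$active), "shares")
  if (sum(res$shares$active) >= 2) {
    res$modules <- step("modules",
      cluster_functional_modules(res$shares,
                                 distance_threshold = config$cluster_threshold))
    tsv(data.frame(reaction_id = names(res$modules$modules),
                   module = unname(res$modules$modules)), "modules")
    write_module_tree(res$modules, file.path(config$out, "modules.nwk"))
  }
  if (config$atpm_id %in% colnames(res$coupled$components)) {
    res$energy <- step("energy_balance",
      component_atp_balance(res$coupled, config$atpm_id))
    tsv(res$energy, "energy_balance")
  }
  finish(TRUE)
  out <- config$out
  attr(out, "results") <- res
  invisible(out)
}
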