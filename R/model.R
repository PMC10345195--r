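#' Construct a genome-scale metabolic model
#'
#' A `metabolic_model` holds the stoichiometry, flux bounds and
#' gene-protein-reaction (GPR) rules of a constraint-based metabolic network.
#' Exchange fluxes follow the BiGG sign convention: a negative exchange flux
#' is uptake, a positive one excretion.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (chemical formula string, may be `NA` for pseudo-metabolites
#'   such as energy or redox tokens) and `charge` (integer, may be `NA`).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` (mmol/gDW/h), `gene_rule` (boolean expression over gene ids
#'   with `and`/`or`, `""` if spontaneous) and `subsystem`.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param genes character vector of gene ids.
#' @param id model identifier.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = character(), id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  n_m <- nrow(metabolites); n_r <- nrow(reactions)
  for (col in c("name", "compartment")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- metabolites$id
  }
  if (is.null(metabolites$formula)) metabolites$formula <- rep(NA_character_, n_m)
  if (is.null(metabolites$charge)) metabolites$charge <- rep(NA_integer_, n_m)
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- rep("", n_r)
  if (is.null(reactions$subsystem)) reactions$subsystem <- rep("", n_r)
  if (anyDuplicated(metabolites$id)) {
    stop("duplicated metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicated reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  }
  if (nrow(reactions) > 0 && !setequal(names(stoichiometry), reactions$id)) {
    stop("stoichiometry entries must match reaction ids one-to-one")
  }
  stoichiometry <- stoichiometry[reactions$id]
  # canonical order so that write/read round-trips compare field-by-field
  stoichiometry <- lapply(stoichiometry, function(s) s[order(names(s))])
  bad <- unlist(lapply(stoichiometry, function(s) setdiff(names(s), metabolites$id)))
  if (length(bad) > 0) {
    stop("stoichiometry references unknown metabolites: ",
         paste(unique(bad), collapse = ", "))
  }
  if (nrow(reactions) > 0 &&
      (any(!is.finite(reactions$lower_bound) & !is.infinite(reactions$lower_bound)) ||
       any(is.na(reactions$lower_bound)) || any(is.na(reactions$upper_bound)))) {
    stop("missing flux bounds (no silent defaults); offending reactions: ",
         paste(reactions$id[is.na(reactions$lower_bound) | is.na(reactions$upper_bound)],
               collapse = ", "))
  }
  if (any(reactions$lower_bound > reactions$upper_bound)) {
    stop("lower_bound > upper_bound for: ",
         paste(reactions$id[reactions$lower_bound > reactions$upper_bound],
               collapse = ", "))
  }
  structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = genes,
         annotations = list(id = id)),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$annotations$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   genes: ", length(x$genes), "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return Sparse `dgCMatrix`, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rids)) {
    s <- model$stoichiometry[[k]]
    if (length(s) == 0) next
    i <- c(i, match(names(s), mids))
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Identify exchange reactions
#'
#' Exchange (boundary) reactions are recognized by a single-metabolite
#' stoichiometry.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[vapply(model$stoichiometry, length, 1L) == 1L]
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  k <- match(reaction_id, model$reactions$id)
  if (is.na(k)) stop("unknown reaction: ", reaction_id)
  if (!is.null(lower)) model$reactions$lower_bound[k] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[k] <- upper
  if (model$reactions$lower_bound[k] > model$reactions$upper_bound[k]) {
    stop("conflicting bounds for ", reaction_id)
  }
  model
}

#' Parse a chemical formula into element counts
#'
#' @param formula formula string such as `"C6H12O6"`; `NA` or `""` gives an
#'   empty count vector.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  tapply(n, el, sum)[unique(el)]
}

#' Carbon atom count of a metabolite
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id metabolite id.
#' @return Number of carbon atoms (0 if the formula is absent).
#' @export
carbon_count <- function(model, metabolite_id) {
  k <- match(metabolite_id, model$metabolites$id)
  if (is.na(k)) stop("unknown metabolite: ", metabolite_id)
  cnt <- parse_formula(model$metabolites$formula[k])
  if ("C" %in% names(cnt)) unname(cnt[["C"]]) else 0
}

#' Check elemental balance of internal reactions
#'
#' Every non-exchange, non-sink reaction is checked for element conservation
#' using the metabolite formulas. Metabolites without a formula (e.g. energy
#' or redox tokens in toy networks) cause the check to be skipped for the
#' reactions involving them, with a warning listing those reactions.
#'
#' @param model a `metabolic_model`.
#' @return data.frame with columns `reaction_id`, `balanced`, `checked`;
#'   imbalances additionally raise a warning.
#' @export
check_element_balance <- function(model) {
  ex <- exchange_reactions(model)
  counts <- lapply(model$metabolites$formula, parse_formula)
  names(counts) <- model$metabolites$id
  has_formula <- vapply(counts, length, 1L) > 0
  res <- data.frame(reaction_id = model$reactions$id,
                    balanced = NA, checked = FALSE)
  for (k in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[k]
    if (rid %in% ex) next
    s <- model$stoichiometry[[k]]
    if (length(s) <= 1) next   # sink/demand
    if (!all(has_formula[names(s)])) next
    tot <- numeric(0)
    for (mid in names(s)) {
      cc <- counts[[mid]]
      for (el in names(cc)) {
        tot[el] <- (if (el %in% names(tot)) tot[el] else 0) + s[[mid]] * cc[[el]]
      }
    }
    res$checked[k] <- TRUE
    res$balanced[k] <- all(abs(tot) < 1e-9)
  }
  skipped <- res$reaction_id[!res$checked & !(res$reaction_id %in% ex) &
                             vapply(model$stoichiometry, length, 1L) > 1]
  if (length(skipped) > 0) {
    warning("element balance skipped (missing formulas): ",
            paste(skipped, collapse = ", "))
  }
  bad <- res$reaction_id[res$checked & !res$balanced]
  if (length(bad) > 0) {
    warning("elementally imbalanced reactions: ", paste(bad, collapse = ", "))
  }
  res
}

#' Genes referenced by a reaction's GPR rule
#'
#' @param rule gene rule string (`and`/`or` boolean expression).
#' @return Character vector of gene ids (empty for spontaneous reactions).
#' @export
genes_in_rule <- function(rule) {
  if (is.na(rule) || !nzchar(rule)) return(character(0))
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  unique(toks[!(tolower(toks) %in% c("and", "or"))])
}
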