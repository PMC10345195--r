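# Projection of reaction-level functional shares onto the proteome.

#' Read a protein-abundance table
#'
#' @param path TSV with columns `gene_id`, `condition`, `mass_fraction`
#'   (fraction of total protein mass).
#' @return data.frame.
#' @export
read_protein_abundances <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "mass_fraction")
  if (!all(need %in% names(tab))) {
    stop("abundance table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$mass_fraction < 0 | tab$mass_fraction > 1)) {
    stop("mass fractions must lie in [0, 1]")
  }
  tot <- tapply(tab$mass_fraction, tab$condition, sum)
  if (any(tot > 1 + 1e-6)) {
    stop("per-condition mass fractions sum above 1: ",
         paste(names(tot)[tot > 1 + 1e-6], collapse = ", "))
  }
  tab
}

#' Map reaction functional shares onto proteins
#'
#' Each gene inherits the functional shares of the reactions whose GPR rule
#' mentions it, averaged with weights equal to the reaction flux magnitudes
#' (so promiscuous enzymes are apportioned by how much each of their
#' reactions is used). Genes whose reactions all carry flux below the
#' activity threshold are flagged `zero-flux-metabolic`; genes outside the
#' model are `unassigned`.
#'
#' @param shares a `functional_shares` object.
#' @param fluxes a `flux_state` (or named flux vector).
#' @param model the [metabolic_model()].
#' @param genes genes to map (default: the model's genes).
#' @param activity_threshold flux magnitude below which a reaction does not
#'   contribute (mmol/gDW/h).
#' @return Object of class `protein_shares`: list with `shares` (genes x
#'   functions), `F_mix`, `sector` (per gene), `status`.
#' @export
map_protein_shares <- function(shares, fluxes, model, genes = NULL,
                               activity_threshold = 1e-4) {
  v <- if (inherits(fluxes, "flux_state")) fluxes$fluxes else fluxes
  if (is.null(genes)) genes <- model$genes
  rule_genes <- lapply(model$reactions$gene_rule, function(r) {
    tryCatch(genes_in_rule(r),
             error = function(e) stop("malformed gene rule: ", r, call. = FALSE))
  })
  names(rule_genes) <- model$reactions$id
  fids <- colnames(shares$shares)
  M <- matrix(0, length(genes), length(fids), dimnames = list(genes, fids))
  fmix <- stats::setNames(numeric(length(genes)), genes)
  status <- stats::setNames(rep("assigned", length(genes)), genes)
  energy_funcs <- fids[shares$categories[fids] %in%
                       c("maintenance", "excretion", "respiration", "fermentation")]
  sector <- stats::setNames(rep("zero-flux-metabolic", length(genes)), genes)
  for (g in genes) {
    rids <- model$reactions$id[vapply(rule_genes, function(x) g %in% x, TRUE)]
    if (length(rids) == 0) { status[g] <- "unassigned"; sector[g] <- "unassigned"; next }
    rids <- rids[rids %in% rownames(shares$shares)]
    wts <- abs(v[rids])
    act <- wts >= activity_threshold
    if (!any(act)) { status[g] <- "zero-flux"; next }
    rids <- rids[act]; wts <- wts[act]
    M[g, ] <- colSums(shares$shares[rids, , drop = FALSE] * wts) / sum(wts)
    fmix[g] <- sum(shares$F_mix[rids] * wts) / sum(wts)
    e_share <- sum(M[g, energy_funcs])
    b_share <- sum(M[g, setdiff(fids, energy_funcs)])
    sector[g] <- if (e_share >= b_share) "energy" else "biomass"
  }
  structure(list(shares = M, F_mix = fmix, sector = sector, status = status,
                 energy_functions = energy_funcs,
                 categories = shares$categories[fids]),
            class = "protein_shares")
}

#' Aggregate protein shares into proteome sectors
#'
#' Multiplies each gene's functional shares by its measured mass fraction
#' and sums per sector. The energy sector is split into respiration and
#' fermentation sub-fractions using the coupled function labels when
#' present.
#'
#' @param pshares a `protein_shares` object.
#' @param abundances named numeric vector of mass fractions per gene (one
#'   condition), or a data.frame as from [read_protein_abundances()] plus
#'   `condition`.
#' @param condition condition label (when `abundances` is a data.frame).
#' @param categories optional named category vector for the share columns
#'   (defaults to those stored during mapping).
#' @return list with `sectors` (named fractions: energy, biomass,
#'   zero_flux_metabolic, unassigned), `energy_split` (respiration /
#'   fermentation fractions), `by_function` (mass per function).
#' @export
aggregate_sectors <- function(pshares, abundances, condition = NULL,
                              categories = NULL) {
  if (is.data.frame(abundances)) {
    if (is.null(condition)) stop("supply a condition label")
    sub <- abundances[abundances$condition == condition, ]
    abundances <- stats::setNames(sub$mass_fraction, sub$gene_id)
  }
  genes <- rownames(pshares$shares)
  ab <- stats::setNames(rep(0, length(genes)), genes)
  common <- intersect(genes, names(abundances))
  ab[common] <- abundances[common]
  assigned <- pshares$status == "assigned"
  by_function <- colSums(pshares$shares[assigned, , drop = FALSE] * ab[assigned])
  fmix_mass <- sum(pshares$F_mix[assigned] * ab[assigned])
  e_funcs <- pshares$energy_functions
  sectors <- c(
    energy = sum(by_function[e_funcs]),
    biomass = sum(by_function[setdiff(names(by_function), e_funcs)]),
    mixed = fmix_mass,
    zero_flux_metabolic = sum(ab[pshares$status == "zero-flux"]),
    unassigned = sum(abundances[setdiff(names(abundances), genes)]) +
      sum(ab[pshares$status == "unassigned"]))
  cats <- categories %||% pshares$categories
  resp <- names(by_function)[cats[names(by_function)] == "respiration"]
  ferm <- names(by_function)[cats[names(by_function)] == "fermentation"]
  energy_split <- c(respiration = sum(by_function[resp]),
                    fermentation = sum(by_function[ferm]))
  list(sectors = sectors, energy_split = energy_split,
       by_function = by_function)
}

#' Greedy GO-term categorization of the proteome
#'
#' Iteratively selects the GO term whose yet-unassigned genes carry the
#' largest summed protein mass, assigns those genes exclusively to it, and
#' stops when the best remaining term falls below `stop_threshold` of the
#' proteome mass. Ties break lexicographically by GO id; unannotated
#' residual genes are labeled `"unclassified"`.
#'
#' @param abundances named numeric vector of protein mass fractions
#'   (typically averaged over the reference and extreme-limitation
#'   conditions).
#' @param annotations data.frame with columns `gene_id`, `go_id`.
#' @param stop_threshold minimal summed mass fraction for a term to be
#'   selected (default 0.001, i.e. 0.1%).
#' @return list with `category` (named character per gene) and `terms`
#'   (data.frame of selected terms in order, with captured mass).
#' @export
greedy_go_categorize <- function(abundances, annotations, stop_threshold = 0.001) {
  genes <- names(abundances)
  category <- stats::setNames(rep("unclassified", length(genes)), genes)
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  unassigned <- genes
  picked <- list()
  repeat {
    sub <- ann[ann$gene_id %in% unassigned, , drop = FALSE]
    if (nrow(sub) == 0) break
    mass <- tapply(abundances[sub$gene_id], sub$go_id, sum)
    mass <- sort(mass, decreasing = TRUE)
    best_mass <- mass[1]
    if (best_mass < stop_threshold) break
    best_terms <- names(mass)[mass >= best_mass - 1e-15]
    term <- sort(best_terms)[1]
    hit <- unique(sub$gene_id[sub$go_id == term])
    category[hit] <- term
    picked[[term]] <- sum(abundances[hit])
    unassigned <- setdiff(unassigned, hit)
  }
  terms <- data.frame(go_id = names(picked),
                      mass_fraction = unname(unlist(picked)),
                      stringsAsFactors = FALSE)
  list(category = category, terms = terms)
}

#' Fit a linear protein-allocation law
#'
#' Ordinary least squares of the proteome fraction allocated to a function
#' against its demand flux across conditions: fraction = offset + slope * J.
#'
#' @param protein_fractions per-condition proteome fractions.
#' @param demand_fluxes per-condition demand fluxes J_gamma (mmol/gDW/h).
#' @return list of class `linear_fit`: `slope`, `offset`, `slope_se`,
#'   `offset_se`, `r2`.
#' @export
fit_linear_allocation <- function(protein_fractions, demand_fluxes) {
  if (length(protein_fractions) != length(demand_fluxes)) {
    stop("fractions and fluxes differ in length")
  }
  if (length(protein_fractions) < 3) stop("need at least 3 conditions")
  fit <- stats::lm(protein_fractions ~ demand_fluxes)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(slope = unname(co["demand_fluxes", "Estimate"]),
                 offset = unname(co["(Intercept)", "Estimate"]),
                 slope_se = unname(co["demand_fluxes", "Std. Error"]),
                 offset_se = unname(co["(Intercept)", "Std. Error"]),
                 r2 = sm$r.squared),
            class = "linear_fit")
}

#' Fit a pathway protein efficiency (origin-constrained)
#'
#' Least-squares slope through the origin of ATP flux against allocated
#' proteome: epsilon = sum(phi * J_atp) / sum(phi^2), in ATP flux
#' (mmol/gDW/h) per percent of proteome when `protein_fractions` is given
#' in percent.
#'
#' @param atp_fluxes per-condition ATP fluxes of the pathway (mmol/gDW/h).
#' @param protein_fractions per-condition proteome allocated to the pathway
#'   (percent of total proteome).
#' @return list of class `efficiency_fit`: `epsilon`, `se`, `n`.
#' @export
fit_pathway_efficiency <- function(atp_fluxes, protein_fractions) {
  if (length(atp_fluxes) != length(protein_fractions)) {
    stop("inputs differ in length")
  }
  if (all(protein_fractions == 0)) stop("all protein fractions are zero")
  eps <- sum(protein_fractions * atp_fluxes) / sum(protein_fractions^2)
  n <- length(atp_fluxes)
  se <- if (n > 1) {
    s2 <- sum((atp_fluxes - eps * protein_fractions)^2) / (n - 1)
    sqrt(s2 / sum(protein_fractions^2))
  } else NA_real_
  structure(list(epsilon = eps, se = se, n = n), class = "efficiency_fit")
}
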