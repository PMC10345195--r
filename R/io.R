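#' Load a genome-scale model from file
#'
#' Reads either the BiGG JSON dialect or SBML Level 3 with the FBC v2
#' extension. Bounds, stoichiometry and gene rules are preserved exactly;
#' a model written by [write_model()] reads back field-by-field identical.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; `"auto"` guesses from the extension.
#' @return A [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a model to file
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @param format `"json"` or `"sbml"`; `"auto"` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e)))
  mets <- doc$metabolites
  if (is.null(mets)) stop("format error: no 'metabolites' array in ", path)
  metabolites <- data.frame(
    id = vapply(mets, function(m) m$id %||% stop("format error: metabolite without id"), ""),
    name = vapply(mets, function(m) m$name %||% m$id, ""),
    compartment = vapply(mets, function(m) m$compartment %||% "", ""),
    formula = vapply(mets, function(m) m$formula %||% NA_character_, ""),
    charge = vapply(mets, function(m) as.integer(m$charge %||% NA_integer_), 1L),
    stringsAsFactors = FALSE)
  rxns <- doc$reactions
  if (is.null(rxns)) stop("format error: no 'reactions' array in ", path)
  get_bound <- function(r, which) {
    b <- r[[which]]
    if (is.null(b)) stop("format error: reaction '", r$id %||% "?",
                         "' is missing ", which)
    as.numeric(b)
  }
  reactions <- data.frame(
    id = vapply(rxns, function(r) r$id %||% stop("format error: reaction without id"), ""),
    name = vapply(rxns, function(r) r$name %||% r$id, ""),
    lower_bound = vapply(rxns, get_bound, 0, which = "lower_bound"),
    upper_bound = vapply(rxns, get_bound, 0, which = "upper_bound"),
    gene_rule = vapply(rxns, function(r) r$gene_reaction_rule %||% "", ""),
    subsystem = vapply(rxns, function(r) r$subsystem %||% "", ""),
    stringsAsFactors = FALSE)
  stoich <- lapply(rxns, function(r) {
    s <- unlist(r$metabolites %||% list())
    if (is.null(s)) s <- stats::setNames(numeric(0), character(0))
    s
  })
  names(stoich) <- reactions$id
  genes <- vapply(doc$genes %||% list(), function(g) g$id %||% "", "")
  metabolic_model(metabolites, reactions, stoich, genes = genes,
                  id = doc$id %||% "model")
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$annotations$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(k) {
      m <- model$metabolites[k, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(k) {
      r <- model$reactions[k, ]
      list(id = r$id, name = r$name,
           metabolites = as.list(model$stoichiometry[[k]]),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = r$gene_rule, subsystem = r$subsystem)
    }),
    genes = lapply(model$genes, function(g) list(id = g, name = g)),
    version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sbml_ns <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e)))
  mdl <- xml2::xml_find_first(doc, "./s:model", sbml_ns)
  if (inherits(mdl, "xml_missing")) stop("format error: no <model> element in ", path)
  att <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }
  # flux-bound parameters
  pars <- xml2::xml_find_all(mdl, "./s:listOfParameters/s:parameter", sbml_ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  sp <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", sbml_ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "charge"))),
    stringsAsFactors = FALSE)
  gp <- xml2::xml_find_all(
    mdl, "./fbc:listOfGeneProducts/fbc:geneProduct", sbml_ns)
  genes <- xml2::xml_attr(gp, "id")
  rx <- xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", sbml_ns)
  n <- length(rx)
  ids <- character(n); lbs <- numeric(n); ubs <- numeric(n)
  nms <- character(n); rules <- character(n); subs <- character(n)
  stoich <- vector("list", n)
  for (k in seq_len(n)) {
    r <- rx[[k]]
    ids[k] <- xml2::xml_attr(r, "id")
    nms[k] <- att(r, "name") %||% ids[k]
    lbid <- xml2::xml_attr(r, "lowerFluxBound")
    ubid <- xml2::xml_attr(r, "upperFluxBound")
    if (is.na(lbid) || is.na(ubid) || !(lbid %in% names(parval)) ||
        !(ubid %in% names(parval))) {
      stop("format error: reaction '", ids[k], "' has missing flux bounds")
    }
    lbs[k] <- parval[[lbid]]; ubs[k] <- parval[[ubid]]
    subs[k] <- att(r, "subsystem") %||% ""
    reac <- xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", sbml_ns)
    prod <- xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", sbml_ns)
    s <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species")))
    stoich[[k]] <- s[!is.na(names(s))]
    ga <- xml2::xml_find_first(r, "./fbc:geneProductAssociation", sbml_ns)
    rules[k] <- if (inherits(ga, "xml_missing")) "" else {
      rule <- sbml_gpa_to_rule(xml2::xml_child(ga))
      # strip redundant outer parentheses for a canonical top-level form
      if (grepl("^\\(", rule) && grepl("\\)$", rule)) {
        inner <- substr(rule, 2, nchar(rule) - 1)
        depth <- cumsum((strsplit(inner, "")[[1]] == "(") -
                        (strsplit(inner, "")[[1]] == ")"))
        if (all(depth >= 0)) rule <- inner
      }
      rule
    }
  }
  reactions <- data.frame(id = ids, name = nms, lower_bound = lbs,
                          upper_bound = ubs, gene_rule = rules,
                          subsystem = subs, stringsAsFactors = FALSE)
  names(stoich) <- ids
  metabolic_model(metabolites, reactions, stoich, genes = genes,
                  id = att(mdl, "id") %||% "model")
}

sbml_gpa_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
  kids <- vapply(xml2::xml_children(node), sbml_gpa_to_rule, "")
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(kids, collapse = op), ")")
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- textConnection("sbml_out", "w", local = TRUE)
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', sbml_ns[["s"]], '" xmlns:fbc="', sbml_ns[["fbc"]],
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$annotations$id), '" fbc:strict="true">')
  comps <- unique(model$metabolites$compartment)
  comps <- comps[nzchar(comps)]
  if (length(comps) == 0) comps <- "c"
  w('    <listOfCompartments>')
  for (cp in comps) w('      <compartment id="', esc(cp), '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (k in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[k, ]
    cp <- if (nzchar(m$compartment)) m$compartment else "c"
    extra <- ""
    if (!is.na(m$formula)) extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
    if (!is.na(m$charge)) extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
    w('      <species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(cp),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
      extra, '/>')
  }
  w('    </listOfSpecies>')
  # one shared parameter per distinct bound value
  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)),
                         vapply(bounds, function(b) format(b, digits = 17), ""))
  w('    <listOfParameters>')
  for (b in bounds) {
    w('      <parameter id="', pid[[format(b, digits = 17)]], '" value="',
      format(b, digits = 17), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  if (length(model$genes) > 0) {
    w('    <fbc:listOfGeneProducts>')
    for (g in model$genes) {
      w('      <fbc:geneProduct fbc:id="', esc(g), '" fbc:label="', esc(g), '"/>')
    }
    w('    </fbc:listOfGeneProducts>')
  }
  w('    <listOfReactions>')
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    s <- model$stoichiometry[[k]]
    w('      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(r$lower_bound < 0),
      '" fast="false" subsystem="', esc(r$subsystem),
      '" fbc:lowerFluxBound="', pid[[format(r$lower_bound, digits = 17)]],
      '" fbc:upperFluxBound="', pid[[format(r$upper_bound, digits = 17)]], '">')
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac) > 0) {
      w('        <listOfReactants>')
      for (mid in names(reac)) {
        w('          <speciesReference species="', esc(mid), '" stoichiometry="',
          format(-reac[[mid]], digits = 17), '" constant="true"/>')
      }
      w('        </listOfReactants>')
    }
    if (length(prod) > 0) {
      w('        <listOfProducts>')
      for (mid in names(prod)) {
        w('          <speciesReference species="', esc(mid), '" stoichiometry="',
          format(prod[[mid]], digits = 17), '" constant="true"/>')
      }
      w('        </listOfProducts>')
    }
    if (nzchar(r$gene_rule)) {
      w('        <fbc:geneProductAssociation>')
      w(rule_to_sbml_gpa(r$gene_rule, indent = "          "))
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  close(con)
  writeLines(sbml_out, path)
}

# Convert a gene rule ("a and (b or c)") to nested fbc:and/fbc:or XML.
rule_to_sbml_gpa <- function(rule, indent = "") {
  node <- parse_gene_rule(rule)
  render <- function(nd, ind) {
    if (is.character(nd)) {
      return(paste0(ind, '<fbc:geneProductRef fbc:geneProduct="', nd, '"/>'))
    }
    tag <- paste0("fbc:", nd$op)
    inner <- vapply(nd$args, render, "", ind = paste0(ind, "  "))
    paste0(ind, "<", tag, ">\n", paste(inner, collapse = "\n"),
           "\n", ind, "</", tag, ">")
  }
  render(node, indent)
}

# Minimal recursive-descent parser for and/or gene rules with parentheses.
parse_gene_rule <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()\\s]+", rule, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed gene rule: ", rule)
    if (t == "(") {
      take(); e <- parse_or()
      if (is.na(peek()) || take() != ")") stop("malformed gene rule: ", rule)
      return(e)
    }
    take()
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("malformed gene rule: ", rule)
  out
}
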