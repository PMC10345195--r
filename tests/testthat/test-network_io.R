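# Model container, file formats, biomass splitting and condition assembly.

test_that("model constructor validates structure and bounds", {
  mets <- data.frame(id = c("a", "b"), formula = c("C1", "C1"))
  rxns <- data.frame(id = c("R1", "R2"), lower_bound = c(0, 0),
                     upper_bound = c(10, 10))
  st <- list(R1 = c(a = -1, b = 1), R2 = c(b = -1))
  m <- metabolic_model(mets, rxns, st)
  expect_s3_class(m, "metabolic_model")
  expect_equal(exchange_reactions(m), "R2")
  expect_error(metabolic_model(mets, rxns, list(R1 = c(zz = -1), R2 = c(b = -1))),
               "unknown metabolites")
  rxns_bad <- rxns; rxns_bad$lower_bound[1] <- 20
  expect_error(metabolic_model(mets, rxns_bad, st), "lower_bound > upper_bound")
  rxns_na <- rxns; rxns_na$upper_bound[2] <- NA
  expect_error(metabolic_model(mets, rxns_na, st), "missing flux bounds")
})

test_that("an empty model is valid and loadable", {
  m <- metabolic_model(data.frame(id = character()),
                       data.frame(id = character(), lower_bound = numeric(),
                                  upper_bound = numeric()),
                       stats::setNames(list(), character()))
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- load_model(path)
  expect_equal(nrow(m2$reactions), 0)
})

test_that("JSON and SBML round-trips preserve all model fields", {
  for (kind in fixture_kinds) {
    fx <- make_toy_network(kind)
    for (ext in c(".json", ".xml")) {
      path <- tempfile(fileext = ext)
      write_model(fx$model, path)
      m2 <- load_model(path)
      expect_equal(m2$reactions, fx$model$reactions, info = paste(kind, ext))
      expect_equal(m2$stoichiometry, fx$model$stoichiometry,
                   info = paste(kind, ext))
      expect_equal(m2$metabolites$id, fx$model$metabolites$id)
      expect_setequal(m2$genes, fx$model$genes)
    }
  }
})

test_that("parse failures and missing bounds are explicit errors", {
  bad <- tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', bad)
  expect_error(load_model(bad), "no 'reactions'")
  nob <- tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id":"a"}],
    "reactions": [{"id":"R1","metabolites":{"a":-1}}]}', nob)
  expect_error(load_model(nob), "missing lower_bound")
})

test_that("gene rules survive nesting and report their genes", {
  expect_setequal(genes_in_rule("g1 and (g2 or g3) and g4"),
                  c("g1", "g2", "g3", "g4"))
  expect_length(genes_in_rule(""), 0)
  m <- make_toy_network("overflow")$model
  m$reactions$gene_rule[3] <- "gA and (gB or (gC and gD))"
  path <- tempfile(fileext = ".xml")
  write_model(m, path)
  m2 <- load_model(path)
  expect_setequal(genes_in_rule(m2$reactions$gene_rule[3]),
                  c("gA", "gB", "gC", "gD"))
})

test_that("element balance checks internal reactions and skips tokens", {
  fx <- make_toy_network("branch")
  res <- expect_silent(check_element_balance(fx$model))
  expect_true(all(res$balanced[res$checked]))
  # overflow has an energy token without formula: affected reactions skipped
  fx2 <- make_toy_network("overflow")
  expect_warning(res2 <- check_element_balance(fx2$model), "missing formulas")
  expect_true(all(res2$balanced[res2$checked]))
  # introduce an imbalance
  m <- fx$model
  m$stoichiometry$EFF <- c(g = -1, p = 1)   # C6 -> C3 loses carbon
  expect_warning(check_element_balance(m), "imbalanced")
})

test_that("split_biomass produces per-building-block demands J = c * mu", {
  model <- toy_biomass_model(c_bm = 0.6, gam = 2)
  out <- split_biomass(model, c(bm = 0.6), mu = 1, biomass_id = "BIOMASS_toy",
                       atpm_id = "ATPM", gam_metabolite = "atp")
  expect_false("BIOMASS_toy" %in% out$model$reactions$id)
  expect_true("DM_bm" %in% out$model$reactions$id)
  expect_equal(out$demands$J[out$demands$function_id == "bm"], 0.6)
  # growth-associated ATP preserved as maintenance demand: gam * mu
  expect_equal(out$demands$J[out$demands$function_id == "growth_ATP"], 2)
  expect_equal(out$demands$category[out$demands$function_id == "growth_ATP"],
               "maintenance")
  # mu = 0: all demands zero
  out0 <- split_biomass(model, c(bm = 0.6), mu = 0, biomass_id = "BIOMASS_toy",
                        atpm_id = "ATPM", gam_metabolite = "atp")
  expect_equal(sum(out0$demands$J), 0)
  expect_error(split_biomass(model, c(nope = 1), mu = 1,
                             biomass_id = "BIOMASS_toy"),
               "absent from model")
})

test_that("solving a split model consumes building blocks at c * mu", {
  model <- toy_biomass_model(c_bm = 0.6, gam = 2)
  mu <- 0.8
  out <- split_biomass(model, c(bm = 0.6), mu = mu, biomass_id = "BIOMASS_toy",
                       atpm_id = "ATPM", gam_metabolite = "atp")
  dem <- rbind(out$demands,
               demand_set("base_ATPM", 10, "ATPM", "maintenance"),
               demand_set("acetate", 1, "EX_ac", "excretion"))
  # merge the two maintenance entries onto the single ATPM reaction
  atpm_total <- sum(dem$J[dem$reaction_id == "ATPM"])
  dem <- dem[!duplicated(dem$reaction_id), ]
  dem$J[dem$reaction_id == "ATPM"] <- atpm_total
  class(dem) <- c("demand_set", "data.frame")
  m <- apply_condition(out$model, list(aerobic = TRUE), dem)
  st <- solve_pfba(m, dem, "EX_glc_e")
  expect_equal(unname(st$fluxes[["DM_bm"]]), 0.6 * mu, tolerance = 1e-9)
})

test_that("build_demand_set combines blocks, maintenance and excretions", {
  comp <- c(gly = 0.6)
  cond <- list(label = "ref", mu = 1, aerobic = TRUE)
  maint <- maintenance_fit(sigma0 = 3, sigma = 5)
  laws <- list(EX_ac = list(intercept = -4, slope = 10, aerobic = TRUE),
               EX_sc = list(intercept = 0.5, slope = 0.5, aerobic = FALSE))
  dem <- build_demand_set(comp, cond, maint, laws)
  expect_equal(dem$J[dem$function_id == "ATPM"], 8)   # 3 + 5 * 1
  expect_equal(dem$J[dem$function_id == "EX_ac"], 6)
  expect_false("EX_sc" %in% dem$function_id)
  # acetate law negative at low mu: clipped at zero
  dem_lo <- build_demand_set(comp, list(mu = 0.2, aerobic = TRUE), maint, laws)
  expect_equal(dem_lo$J[dem_lo$function_id == "EX_ac"], 0)
  # anaerobic: succinate law replaces the acetate law
  dem_an <- build_demand_set(comp, list(mu = 1, aerobic = FALSE), maint, laws)
  expect_false("EX_ac" %in% dem_an$function_id)
  expect_equal(dem_an$J[dem_an$function_id == "EX_sc"], 1)
  # unphysical maintenance
  expect_error(build_demand_set(comp, list(mu = 1, aerobic = TRUE),
                                maintenance_fit(-10, 2), laws),
               "unphysical")
})

test_that("apply_condition fixes demands and closes oxygen when anaerobic", {
  mets <- data.frame(id = c("o2_e", "x"), formula = c("O2", "C1"))
  rxns <- data.frame(id = c("EX_o2_e", "SRC", "DM_x"),
                     lower_bound = c(-10, 0, 0), upper_bound = c(10, 10, 10))
  st <- list(EX_o2_e = c(o2_e = -1), SRC = c(x = 1), DM_x = c(x = -1))
  m <- metabolic_model(mets, rxns, st)
  dem <- demand_set("x", 2, "DM_x", "building_block")
  m_a <- apply_condition(m, list(aerobic = TRUE), dem)
  expect_equal(m_a$reactions$lower_bound[m_a$reactions$id == "DM_x"], 2)
  expect_equal(m_a$reactions$upper_bound[m_a$reactions$id == "DM_x"], 2)
  expect_equal(m_a$reactions$lower_bound[m_a$reactions$id == "EX_o2_e"], -10)
  m_an <- apply_condition(m, list(aerobic = FALSE), dem)
  expect_equal(m_an$reactions$lower_bound[m_an$reactions$id == "EX_o2_e"], 0)
  expect_equal(m_an$reactions$upper_bound[m_an$reactions$id == "EX_o2_e"], 0)
  # conflicting demand
  dem_bad <- demand_set("x", 99, "DM_x", "building_block")
  expect_error(apply_condition(m, list(aerobic = TRUE), dem_bad), "conflicts")
})

test_that("biomass coefficients interpolate over growth rate safely", {
  tab <- data.frame(metabolite_id = "gly", mu = c(0.5, 1.0),
                    coefficient_mmol_per_gDW = c(0.4, 0.8), condition = "C")
  expect_equal(unname(biomass_coefficients(tab, 0.75)["gly"]), 0.6)
  expect_error(biomass_coefficients(tab, 1.5), "outside tabulated range")
  expect_equal(unname(biomass_coefficients(tab, 1.5, extrapolate = TRUE)["gly"]),
               0.8)
})
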