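test_that("community assembly wires the shared pool and validates bounds", {
  fx <- f1()
  comm <- fx$community
  expect_setequal(comm$shared_ids, c("Sx", "Hx", "Bx"))
  expect_equal(comm$medium[["Sx"]], 10)
  expect_equal(comm$accumulation[["Hx"]], 0)
  expect_equal(comm$accumulation[["Bx"]], Inf)

  expect_error(build_community(list(comm$species$A), medium = c(Sx = -1)),
               class = "comfba_config_error")
  expect_error(build_community(list(comm$species$A), medium = c(Zz = 1)),
               class = "comfba_config_error")

  # accumulation defaults: 0 for consumed intermediates, Inf for terminal
  # by-products
  c0 <- build_community(list(comm$species$A, comm$species$B),
                        medium = c(Sx = 10))
  expect_equal(c0$accumulation[["Hx"]], 0)
  expect_equal(c0$accumulation[["Bx"]], Inf)

  # single species, nothing to eat
  solo <- build_community(list(comm$species$A))
  expect_equal(solve_predictive(solo)$outer_objective_value, 0)
})

test_that("interaction typing restricts flows as specified and is idempotent", {
  fx <- f1()
  spec <- interaction_spec("mutualism", rules = list(
    Hx = list(producers = "A", consumers = "B", must_consume_all = TRUE),
    Sx = list(producers = character(0), consumers = "A")))
  cm <- apply_interaction(fx$community, spec)
  sm <- solve_predictive(cm)
  expect_equal(sm$outer_objective_value, 20)
  expect_equal(sm$e["A", "Hx"], sm$u["B", "Hx"])

  cm2 <- apply_interaction(cm, spec)
  expect_equal(comfba:::interaction_effects(cm2),
               comfba:::interaction_effects(cm))
  expect_equal(solve_predictive(cm2)$outer_objective_value, 20)

  # neutral is the identity
  cn <- apply_interaction(fx$community, interaction_spec("neutral"))
  expect_equal(solve_predictive(cn)$outer_objective_value,
               solve_predictive(fx$community)$outer_objective_value)

  expect_error(apply_interaction(fx$community,
    interaction_spec("custom", rules = list(Zz = list(producers = "A")))),
    class = "comfba_config_error")
})

test_that("competitors draw on one medium bound with no cross-production", {
  fx <- f2()
  sol <- solve_predictive(fx$community)
  expect_equal(sol$outer_objective_value, 10)
  expect_lte(sum(sol$u[, "Sx"]), 10 + 1e-9)
  expect_equal(unname(sol$e[, "Sx"]), c(0, 0))
  # all substrate goes to the efficient member
  expect_equal(biomass_of(sol, "sp1"), 10)
  expect_equal(biomass_of(sol, "sp2"), 0)
})

test_that("amensalism couples a mandatory drain to the producer's export", {
  fx <- f1()
  am <- apply_interaction(fx$community, interaction_spec("amensalism",
    rules = list(Bx = list(producers = "A", consumers = "B", coupling = 0.5))))
  expect_true("drain_Bx" %in% names(am$species$B$reactions))
  sol <- solve_predictive(am)
  expect_equal(sol$u["B", "Bx"], 0.5 * sol$e["A", "Bx"], tolerance = 1e-9)
})

test_that("constraints commute and attach at the declared level", {
  fx <- f1()
  c1 <- add_constraint(add_constraint(fx$community,
                                      fixed_flux("A", "tS", 5)),
                       biomass_ratio("A", "B", 1))
  c2 <- add_constraint(add_constraint(fx$community,
                                      biomass_ratio("A", "B", 1)),
                       fixed_flux("A", "tS", 5))
  s1 <- solve_predictive(c1)
  s2 <- solve_predictive(c2)
  expect_equal(s1$outer_objective_value, s2$outer_objective_value)
  expect_equal(s1$species$A$values, s2$species$A$values)

  expect_error(add_constraint(fx$community, fixed_flux("A", "nope", 1)),
               class = "comfba_config_error")
  expect_error(add_constraint(fx$community, biomass_ratio("A", "Z", 1)),
               class = "comfba_config_error")

  # no carbon, no growth
  s0 <- solve_predictive(add_constraint(fx$community, fixed_flux("A", "tS", 0)))
  expect_equal(s0$outer_objective_value, 0)

  # an intra-species flux ratio binds that species' inner problem
  cr <- add_constraint(fx$community, flux_ratio("A", "tB", "tS", 0.5))
  sr <- solve_predictive(cr)
  expect_equal(sr$species$A$values[["tB"]],
               0.5 * sr$species$A$values[["tS"]], tolerance = 1e-9)
})

test_that("a unit biomass-ratio constraint recovers the symmetric optimum", {
  fx <- f1()
  cb <- add_constraint(fx$community, biomass_ratio("A", "B", 1))
  d <- solve_descriptive(cb, experimental = list())
  expect_equal(biomass_of(d, "A"), biomass_of(d, "B"), tolerance = 1e-9)
  expect_equal(d$c, c(A = 1, B = 1), tolerance = 1e-6)
})

test_that("community YAML configuration round-trips through the reader", {
  fx <- chain()
  dir <- tempfile(); dir.create(dir)
  for (sp in names(fx$community$species))
    write_species_model(fx$community$species[[sp]],
                        file.path(dir, paste0(sp, ".json")))
  yaml::write_yaml(list(
    models = as.list(paste0(names(fx$community$species), ".json")),
    medium = list(Sx = 10),
    accumulation = list(Px = "inf", Qx = "inf"),
    interaction = list(kind = "commensalism", rules = list(
      Px = list(producers = "A", consumers = "B"),
      Qx = list(producers = "B", consumers = "C"))),
    constraints = list(list(type = "fixed_flux", species = "A",
                            reaction = "tS", value = 4))),
    file.path(dir, "community.yaml"))
  comm <- read_community_config(file.path(dir, "community.yaml"))
  expect_s3_class(comm, "community_model")
  expect_equal(comm$interaction$kind, "commensalism")
  sol <- solve_predictive(comm)
  expect_equal(sol$species$A$values[["tS"]], 4, tolerance = 1e-9)

  yaml::write_yaml(list(models = list("ghost.json")),
                   file.path(dir, "broken.yaml"))
  expect_error(read_community_config(file.path(dir, "broken.yaml")),
               class = "comfba_config_error")
})
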