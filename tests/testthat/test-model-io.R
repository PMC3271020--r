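test_that("syntrophy fixture species parse, round-trip and count correctly", {
  comm <- f1()$community
  A <- comm$species$A
  expect_s3_class(A, "species_model")
  expect_length(A$reactions, 5)
  expect_equal(A$biomass_id, "bioA")

  path <- tempfile(fileext = ".json")
  write_species_model(A, path)
  A2 <- read_species_model(path)
  expect_equal(A2$species_id, A$species_id)
  expect_equal(stoich_matrix(A2), stoich_matrix(A))
  expect_equal(reaction_bounds(A2), reaction_bounds(A))
  expect_equal(comfba:::shared_ids(A2), comfba:::shared_ids(A))
  expect_equal(A2$biomass_id, A$biomass_id)
})

test_that("model construction enforces hard invariants", {
  expect_error(species_model("x", list(metabolite("m")), list()),
               class = "comfba_model_error")
  expect_error(reaction("r", numeric(0)), class = "comfba_model_error")
  expect_error(
    species_model("x", list(metabolite("m")),
                  list(reaction("r", c(m = -1)))),  # no biomass
    class = "comfba_model_error")
  expect_error(
    species_model("x", list(metabolite("m")),
                  list(reaction("r", c(m = -1), biomass = TRUE),
                       reaction("r2", c(m = 1), biomass = TRUE))),
    class = "comfba_model_error")
  expect_error(
    species_model("x", list(metabolite("m")),
                  list(reaction("r", c(ghost = -1), biomass = TRUE))),
    class = "comfba_model_error")
  expect_error(read_species_model(tempfile()), class = "comfba_format_error")
})

test_that("validation reports bound violations, dangling metabolites and blocked biomass", {
  ok <- validate_species_model(f1()$community$species$A)
  expect_equal(nrow(ok), 0)

  m <- species_model("bad",
    list(metabolite("a"), metabolite("lonely")),
    list(reaction("r", c(a = 1), lb = 2, ub = 1),
         reaction("bio", c(a = -1), biomass = TRUE)))
  rep <- validate_species_model(m)
  expect_setequal(rep$check, c("bound_violation", "dangling_metabolite"))
  expect_equal(rep$element[rep$check == "bound_violation"], "r")

  # biomass precursor unproducible: single LP shows zero growth
  blocked <- species_model("blk",
    list(metabolite("a"), metabolite("b")),
    list(reaction("r", c(a = -1, b = 1)),
         reaction("bio", c(b = -1), biomass = TRUE)))
  rep <- validate_species_model(blocked)
  expect_true("blocked_biomass" %in% rep$check)
})

test_that("SBML-FBC and JSON encodings yield identical stoichiometric matrices", {
  B <- f1()$community$species$B
  path <- sbml_scavenger(tempfile(fileext = ".xml"))
  Bs <- read_species_model(path)
  expect_equal(Bs$biomass_id, "bioB")
  Sj <- stoich_matrix(B)
  Ss <- stoich_matrix(Bs)[rownames(Sj), colnames(Sj)]
  expect_equal(Ss, Sj)
  expect_equal(comfba:::shared_ids(Bs), "Hx")
  # and it supports the same growth
  expect_equal(inner_optimum(Bs, list(Hx = c(uptake = 10, export = 0)))$z, 10)
})

test_that("an SBML file with two flux objectives is rejected as ambiguous biomass", {
  path <- sbml_scavenger(tempfile(fileext = ".xml"),
                         objectives = c("bioB", "rB"))
  expect_error(read_species_model(path), class = "comfba_model_error")
})

test_that("solutions round-trip through TSV and JSON to full precision", {
  fx <- f1()
  sol <- solve_predictive(fx$community)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_solution(sol, tsv)
  write_solution(sol, js)

  expect_true(any(grepl("^A\tbioA\t10$", readLines(tsv))))

  for (r in list(read_solution(tsv), read_solution(js))) {
    expect_equal(r$outer_objective_value, sol$outer_objective_value,
                 tolerance = 1e-12)
    for (sp in names(sol$species))
      expect_equal(r$species[[sp]]$values, sol$species[[sp]]$values,
                   tolerance = 1e-12)
    expect_equal(r$u, sol$u, tolerance = 1e-12)
    expect_equal(r$e, sol$e, tolerance = 1e-12)
    expect_equal(r$uc, sol$uc, tolerance = 1e-12)
    expect_equal(r$ec, sol$ec, tolerance = 1e-12)
    expect_equal(r$c, sol$c, tolerance = 1e-12)
    expect_equal(r$v_max, sol$v_max, tolerance = 1e-12)
    expect_equal(r$inner_gaps, sol$inner_gaps, tolerance = 1e-12)
  }
})

test_that("a failed scenario serializes as its status with no flux rows", {
  fx <- f1()
  res <- run_scenarios(fx$community, list(
    list(name = "bad", constraints = list(fixed_flux("A", "tS", 5),
                                          fixed_flux("A", "tH", 7)))))
  expect_s3_class(res$bad, "community_failure")
  path <- tempfile(fileext = ".tsv")
  write_solution(res$bad, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# status\tinfeasible$", lines)))
  expect_false(any(grepl("^A\t", lines)))
  back <- read_solution(path)
  expect_equal(back$status, "infeasible")
})
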