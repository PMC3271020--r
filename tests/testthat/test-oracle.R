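test_that("the grid oracle recovers the known optima of the deterministic fixtures", {
  o1 <- grid_oracle(f1()$community, resolution = 1)
  expect_equal(o1$best_objective, 20, tolerance = 1e-9)
  expect_equal(o1$evaluations, 1331)  # 11^3: substrate uptake, carrier export/uptake

  o2 <- grid_oracle(f2()$community, resolution = 1)
  expect_equal(o2$best_objective, 10, tolerance = 1e-9)

  # allocation table satisfies the enumerated balances
  alloc <- tidy(o1)
  expect_true(all(c("species", "metabolite", "uptake", "export") %in%
                    names(alloc)))
})

test_that("the oracle lower-bounds the exact solver and improves under refinement", {
  for (fx in list(f1(), f2(), chain())) {
    sol <- solve_predictive(fx$community)
    coarse <- grid_oracle(fx$community, resolution = 3)
    fine <- grid_oracle(fx$community, resolution = 1.5)
    expect_lte(coarse$best_objective, sol$outer_objective_value + 1e-6)
    expect_lte(fine$best_objective, sol$outer_objective_value + 1e-6)
    expect_gte(fine$best_objective, coarse$best_objective - 1e-9)
  }
})

test_that("a resolution beyond all bounds evaluates only the zero allocation", {
  o <- grid_oracle(f1()$community, resolution = 100)
  expect_equal(o$evaluations, 1)
  expect_equal(o$best_objective, 0)
})

test_that("certification re-solves inner problems at the reported allocation", {
  fx <- f1()
  sol <- solve_predictive(fx$community)
  expect_equal(unname(certify(sol, fx$community)), c(0, 0), tolerance = 1e-6)

  d <- solve_descriptive(fx$community,
                         experimental = list(fixed_flux("A", "bioA", 5)))
  # under a transfer of 5 the allocation-conditional optimum is 5 for both
  expect_equal(unname(certify(d, fx$community)), c(0, 0), tolerance = 1e-6)

  # a hand-tampered solution shows its gap
  bad <- sol
  bad$species$A$values[["bioA"]] <- 4
  gaps <- certify(bad, fx$community)
  expect_equal(gaps[["A"]], 6, tolerance = 1e-6)
})

test_that("unbounded shared flows are rejected before gridding", {
  B <- f1()$community$species$B
  cB <- build_community(list(B), medium = c(Hx = Inf),
                        accumulation = c(Hx = Inf))
  expect_error(grid_oracle(cB, resolution = 1),
               class = "comfba_config_error")
})
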