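test_that("both solution methods find the global syntrophic optimum with certificates", {
  fx <- f1()
  for (method in c("dual_milp", "bilinear")) {
    sol <- solve_predictive(fx$community, method = method)
    expect_equal(sol$outer_objective_value, 20, tolerance = 1e-6)
    expect_equal(biomass_of(sol, "A"), 10, tolerance = 1e-6)
    expect_equal(biomass_of(sol, "B"), 10, tolerance = 1e-6)
    expect_equal(sol$e["A", "Hx"], 10, tolerance = 1e-6)
    expect_true(all(sol$inner_gaps <= 1e-6))
    expect_equal(unname(sol$c), c(1, 1))
    expect_lt(sol$pool_residual, 1e-9)
  }
})

test_that("the outer objective can favour one member while others stay inner-optimal", {
  fx <- f1()
  sol <- solve_predictive(fx$community,
                          community_objective("single_species", species = "B"))
  expect_equal(biomass_of(sol, "B"), 10, tolerance = 1e-6)
  # the fermenter still sits at its allocation-conditional optimum
  expect_lte(max(certify(sol, fx$community)), 1e-6)

  solw <- solve_predictive(fx$community,
                           community_objective("weighted_biomass",
                                               weights = c(A = 2, B = 1)))
  expect_equal(solw$outer_objective_value, 30, tolerance = 1e-6)
})

test_that("a single-species community collapses to plain FBA", {
  for (fx in list(f1(), f2(), chain())) {
    for (sp in names(fx$community$species)) {
      m <- fx$community$species[[sp]]
      ref <- tryCatch(solve_fba(m), comfba_unbounded_error = function(e) e)
      got <- tryCatch(solve_predictive(solo_community(m)),
                      comfba_unbounded_error = function(e) e)
      if (inherits(ref, "comfba_unbounded_error")) {
        expect_s3_class(got, "comfba_unbounded_error")
      } else {
        expect_equal(got$outer_objective_value, ref$objective,
                     tolerance = 1e-9, info = sp)
      }
    }
  }
})

test_that("community-specific maxima report each member's best reachable growth", {
  expect_equal(compute_species_maxima(f1()$community), c(A = 10, B = 10),
               tolerance = 1e-6)
  expect_equal(compute_species_maxima(f2()$community), c(sp1 = 10, sp2 = 0),
               tolerance = 1e-6)
  empty <- build_community(list(f1()$community$species$A,
                                f1()$community$species$B))
  empty$medium[] <- 0
  expect_equal(unname(compute_species_maxima(empty)), c(0, 0), tolerance = 1e-9)

  mx <- compute_species_maxima(f1()$community, ranges = TRUE)
  rng <- attr(mx, "ranges")
  expect_equal(rng$min, c(10, 10), tolerance = 1e-6)
  expect_equal(rng$max, c(10, 10), tolerance = 1e-6)
})

test_that("descriptive mode quantifies sub- and super-optimal growth", {
  fx <- f1()
  d <- solve_descriptive(fx$community,
                         experimental = list(fixed_flux("A", "bioA", 5)))
  expect_equal(d$c, c(A = 0.5, B = 0.5), tolerance = 1e-6)
  expect_equal(d$v_max, c(A = 10, B = 10), tolerance = 1e-6)
  expect_equal(d$mode, "descriptive")

  # the losing competitor constrained to equal growth is super-optimal
  # relative to its zero community-specific maximum
  d2 <- solve_descriptive(f2()$community,
                          experimental = list(biomass_ratio("sp2", "sp1", 1)))
  expect_lt(d2$c[["sp1"]], 1)
  expect_true(is.nan(d2$c[["sp2"]]))
  expect_true(d2$super_optimal[["sp2"]])
  expect_false(d2$super_optimal[["sp1"]])

  # contradictory observations are reported with the violated subset
  err <- tryCatch(
    solve_descriptive(fx$community,
                      experimental = list(fixed_flux("A", "tS", 5),
                                          fixed_flux("A", "tH", 7))),
    comfba_infeasible_error = function(e) e)
  expect_s3_class(err, "comfba_infeasible_error")
  expect_match(conditionMessage(err), "fixed_flux")
})

test_that("community FVA respects inner optimality certificates", {
  fx <- f1()
  expect_equal(unname(community_fva(fx$community,
                                    target = flow_target("Hx", "export", species = "A"),
                                    fraction = 1)),
               c(10, 10), tolerance = 1e-6)
  expect_equal(unname(community_fva(fx$community,
                                    target = flux_target("B", "bioB"),
                                    fraction = 0)),
               c(0, 10), tolerance = 1e-6)
  # the growth-coupled by-product flow is pinned at the optimum
  expect_equal(unname(community_fva(fx$community,
                                    target = flow_target("Bx", "export", species = "A"),
                                    fraction = 1)),
               c(20, 20), tolerance = 1e-6)
  # ratio of the two biomasses is pinned at one
  rr <- community_fva(fx$community,
                      target = ratio_target(flux_target("A", "bioA"),
                                            flux_target("B", "bioB")),
                      fraction = 1)
  expect_equal(unname(rr), c(1, 1), tolerance = 1e-5)
})

test_that("scenario batches solve independently and record failures in place", {
  fx <- f1()
  res <- run_scenarios(fx$community, list(
    list(name = "s2", medium = c(Sx = 2)),
    list(name = "s5", medium = c(Sx = 5)),
    list(name = "s10", medium = c(Sx = 10))))
  expect_equal(vapply(res, function(s) s$outer_objective_value, numeric(1)),
               c(s2 = 4, s5 = 10, s10 = 20), tolerance = 1e-6)

  expect_length(run_scenarios(fx$community, list()), 0)

  res <- run_scenarios(fx$community, list(
    list(name = "a"),
    list(name = "b", constraints = list(fixed_flux("A", "tS", 5),
                                        fixed_flux("A", "tH", 7))),
    list(name = "c")))
  expect_equal(unname(vapply(res, function(s) s$status, character(1))),
               c("optimal", "infeasible", "optimal"))
})

test_that("big-M certificates are validated, auto-doubled, and failure is classed", {
  fx <- f1()
  # an M below the flux scale forces the doubling path but still certifies
  sol <- solve_predictive(fx$community, M = 6)
  expect_equal(sol$outer_objective_value, 20, tolerance = 1e-6)
  expect_true(all(sol$inner_gaps <= 1e-6))
  # an M that cannot recover within three doublings fails as a classed error
  expect_error(solve_predictive(fx$community, M = 1e-4),
               class = "comfba_bigM_error")
})

test_that("an unbounded outer objective is reported with a ray member", {
  B <- f1()$community$species$B
  cB <- build_community(list(B), medium = c(Hx = Inf),
                        accumulation = c(Hx = Inf))
  for (method in c("dual_milp", "bilinear"))
    expect_error(solve_predictive(cB, method = method),
                 class = "comfba_unbounded_error")
})
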