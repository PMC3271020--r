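test_that("single-species FBA matches hand-derived optima on the syntrophic fermenter", {
  A <- f1()$community$species$A
  fv <- solve_fba(A)
  expect_equal(fv$status, "optimal")
  expect_equal(fv$objective, 10)
  # steady state and bounds hold on the returned vector
  S <- stoich_matrix(A, "internal")
  expect_lt(max(abs(S %*% fv$values)), 1e-9)
  bb <- reaction_bounds(A)
  expect_true(all(fv$values >= bb$lb - 1e-9 & fv$values <= bb$ub + 1e-9))

  # venting the reduced carrier is obligatory: blocking it kills growth
  expect_equal(solve_fba(A, overrides = list(tH = c(0, 0)))$objective, 0)
  # closing every exchange reaction kills growth
  expect_equal(solve_fba(A, overrides = list(tS = c(0, 0), tH = c(0, 0),
                                             tB = c(0, 0)))$objective, 0)
})

test_that("allocation-conditional optima follow the scavenger's transfer supply", {
  B <- f1()$community$species$B
  expect_equal(inner_optimum(B, list(Hx = c(uptake = 10, export = 0)))$z, 10)
  expect_equal(inner_optimum(B, list(Hx = c(uptake = 0, export = 0)))$z, 0)
  expect_error(inner_optimum(B, list(Hx = c(uptake = -1, export = 0))),
               class = "comfba_config_error")
  # an allocation the stoichiometry cannot realize is infeasible, not zero
  io <- inner_optimum(B, list(Hx = c(uptake = 0, export = 5)))
  expect_equal(io$status, "infeasible")
  expect_true(is.na(io$z))
})

test_that("the inner value function matches its closed form and is concave", {
  tr <- two_route_species()
  us <- seq(0, 10, by = 0.5)
  zs <- vapply(us, function(u)
    inner_optimum(tr, list(Xx = c(uptake = u, export = 0)))$z, numeric(1))
  expect_equal(zs, two_route_z(us), tolerance = 1e-9)
  # concavity along random chords (fixed seed)
  set.seed(7)
  for (k in 1:25) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10); lam <- runif(1)
    zab <- inner_optimum(tr, list(Xx = c(uptake = lam * a + (1 - lam) * b,
                                         export = 0)))$z
    expect_gte(zab, lam * two_route_z(a) + (1 - lam) * two_route_z(b) - 1e-9)
  }
})

test_that("species-level FVA brackets the optimum and honours the objective fraction", {
  A <- f1()$community$species$A
  fva1 <- solve_fva(A, "tH", objective_fraction = 1)
  expect_equal(c(fva1$min, fva1$max), c(10, 10))
  fva0 <- solve_fva(A, "tH", objective_fraction = 0)
  expect_equal(c(fva0$min, fva0$max), c(0, 10))
  expect_equal(nrow(solve_fva(A, character(0))), 0)

  # FVA envelope contains the optimal solution's flux, for every reaction
  fv <- solve_fba(A)
  fva <- solve_fva(A, names(fv$values), objective_fraction = 1)
  for (i in seq_len(nrow(fva))) {
    expect_lte(fva$min[i], fv$values[[fva$reaction[i]]] + 1e-9)
    expect_gte(fva$max[i], fv$values[[fva$reaction[i]]] - 1e-9)
  }
  expect_error(solve_fva(A, "nope"), class = "comfba_config_error")
})

test_that("unbounded growth is reported with a ray member, not returned", {
  B <- f1()$community$species$B
  err <- tryCatch(solve_fba(B), comfba_unbounded_error = function(e) e)
  expect_s3_class(err, "comfba_unbounded_error")
  expect_match(conditionMessage(err), "unbounded")
})
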