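test_that("deterministic fixtures carry their known optima", {
  fx1 <- f1()
  expect_equal(fx1$known_optimum, 20)
  expect_equal(solve_predictive(fx1$community)$outer_objective_value,
               fx1$known_optimum, tolerance = 1e-6)

  fx2 <- f2()
  expect_equal(fx2$known_optimum, 10)
  expect_equal(solve_predictive(fx2$community)$outer_objective_value,
               fx2$known_optimum, tolerance = 1e-6)

  # scaling the substrate scales the syntrophic optimum
  half <- make_fixture("obligate_syntrophy", params = list(s_bound = 5))
  expect_equal(solve_predictive(half$community)$outer_objective_value, 10,
               tolerance = 1e-6)

  ch <- chain()
  expect_null(ch$known_optimum)
  sol <- solve_predictive(ch$community)
  orc <- grid_oracle(ch$community, resolution = 1)
  expect_equal(sol$outer_objective_value, orc$best_objective, tolerance = 1e-6)

  expect_error(make_fixture("nonsense"), class = "comfba_config_error")
})

test_that("every fixture species validates cleanly and admits zero flux", {
  for (fx in list(f1(), f2(), chain(), make_fixture("random", seed = 3))) {
    comm <- fx$community
    for (sp in names(comm$species)) {
      m <- comm$species[[sp]]
      expect_equal(nrow(validate_species_model(m)), 0, info = sp)
      bb <- reaction_bounds(m)
      expect_true(all(bb$lb <= 0 & 0 <= bb$ub), info = sp)
    }
  }
})

test_that("random communities are deterministic in the seed and cross-fed", {
  a <- make_fixture("random", seed = 7)
  b <- make_fixture("random", seed = 7)
  ser <- function(fx) {
    paths <- vapply(names(fx$community$species), function(sp) {
      f <- tempfile(fileext = ".json")
      write_species_model(fx$community$species[[sp]], f)
      f
    }, character(1))
    unlist(lapply(paths, readLines))
  }
  expect_identical(ser(a), ser(b))
  expect_false(identical(ser(a), ser(make_fixture("random", seed = 8))))

  # at least one metabolite is produced by one member and consumed by another
  comm <- a$community
  crossfed <- vapply(comm$shared_ids, function(i) {
    prod <- vapply(comm$species, comfba:::species_touches, logical(1),
                   met = i, side = "produce")
    cons <- vapply(comm$species, comfba:::species_touches, logical(1),
                   met = i, side = "consume")
    any(prod) && any(cons) && !identical(which(prod), which(cons))
  }, logical(1))
  expect_true(any(crossfed))

  # fixture generation does not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_fixture("random", seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("emitted fixtures round-trip through the YAML/JSON readers", {
  dir <- tempfile()
  emit_fixture("obligate_syntrophy", dir)
  expect_setequal(list.files(dir),
                  c("A.json", "B.json", "community.yaml", "run.yaml"))
  comm <- read_community_config(file.path(dir, "community.yaml"))
  expect_equal(solve_predictive(comm)$outer_objective_value, 20,
               tolerance = 1e-6)
})
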