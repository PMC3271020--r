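test_that("solutions tidy into flux tables and one-row summaries", {
  fx <- f1()
  sol <- solve_predictive(fx$community)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("species", "reaction", "flux", "is_biomass"))
  expect_equal(nrow(td), 8)  # 5 fermenter + 3 scavenger reactions
  expect_equal(td$flux[td$reaction == "bioA"], 10)
  expect_equal(sum(td$is_biomass), 2)

  g <- glance(sol)
  expect_equal(nrow(g), 1)
  expect_equal(g$outer_objective, 20)
  expect_lte(g$max_gap, 1e-6)
  expect_lte(g$pool_residual, 1e-9)

  fl <- exchange_flows(sol)
  expect_equal(fl$net[fl$species == "A" & fl$metabolite == "Hx"], 10)
  expect_equal(fl$net[fl$species == "B" & fl$metabolite == "Hx"], -10)

  ol <- optimality_levels(sol)
  expect_equal(ol$c, c(1, 1))

  orc <- grid_oracle(fx$community, resolution = 2)
  expect_s3_class(tidy(orc), "tbl_df")
  expect_equal(glance(orc)$best_objective, 20)
})

test_that("plot methods return ggplot objects", {
  sol <- solve_predictive(f1()$community)
  expect_s3_class(ggplot2::autoplot(sol), "ggplot")
  expect_s3_class(plot_exchange(sol), "ggplot")
})

test_that("scenario batches summarize into a tibble", {
  res <- run_scenarios(f1()$community, list(
    list(name = "ok", medium = c(Sx = 5)),
    list(name = "bad", constraints = list(fixed_flux("A", "tS", 5),
                                          fixed_flux("A", "tH", 7)))))
  sm <- scenario_summary(res)
  expect_equal(sm$status, c("optimal", "infeasible"))
  expect_equal(sm$outer_objective[1], 10)
  expect_true(is.na(sm$outer_objective[2]))
})
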