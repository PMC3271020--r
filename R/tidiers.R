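#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a community solution into a flux table
#'
#' @param x a `community_solution`.
#' @param ... unused.
#' @return tibble with one row per (species, reaction): columns `species`,
#'   `reaction`, `flux`, `is_biomass`.
#' @export
tidy.community_solution <- function(x, ...) {
  out <- lapply(names(x$species), function(sp) {
    fv <- x$species[[sp]]
    tibble::tibble(species = sp, reaction = names(fv$values),
                   flux = unname(fv$values),
                   is_biomass = names(fv$values) ==
                     (x$biomass_ids[sp] %||% NA_character_))
  })
  do.call(rbind, out)
}

#' One-row summary of a community solution
#'
#' @param x a `community_solution`.
#' @param ... unused.
#' @return tibble with `mode`, `method`, `status`, `outer_objective`,
#'   `n_species`, `max_gap`, `pool_residual`, `total_flow`.
#' @export
glance.community_solution <- function(x, ...) {
  tibble::tibble(mode = x$mode, method = x$method, status = x$status,
                 outer_objective = x$outer_objective_value,
                 n_species = length(x$species),
                 max_gap = max(x$inner_gaps),
                 pool_residual = x$pool_residual,
                 total_flow = sum(x$u) + sum(x$e))
}

#' Tidy the exchange flows of a community solution
#'
#' @param sol a `community_solution`.
#' @return tibble with one row per (species, shared metabolite): `uptake`,
#'   `export`, `net` (export minus uptake).
#' @export
exchange_flows <- function(sol) {
  out <- lapply(rownames(sol$u), function(sp)
    tibble::tibble(species = sp, metabolite = colnames(sol$u),
                   uptake = unname(sol$u[sp, ]), export = unname(sol$e[sp, ]),
                   net = unname(sol$e[sp, ] - sol$u[sp, ])))
  do.call(rbind, out)
}

#' Per-species summary of a community solution
#'
#' @param sol a `community_solution`.
#' @return tibble with `species`, `biomass`, `c` (optimality level),
#'   `super_optimal`, `v_max`, `gap`.
#' @export
optimality_levels <- function(sol) {
  tibble::tibble(species = names(sol$species),
                 biomass = vapply(sol$species, function(fv) fv$objective,
                                  numeric(1)),
                 c = unname(sol$c),
                 super_optimal = unname(sol$super_optimal),
                 v_max = unname(sol$v_max),
                 gap = unname(sol$inner_gaps))
}

#' @export
tidy.oracle_result <- function(x, ...) {
  x$best_allocation %||%
    tibble::tibble(species = character(), metabolite = character(),
                   uptake = numeric(), export = numeric())
}

#' @export
glance.oracle_result <- function(x, ...) {
  tibble::tibble(best_objective = x$best_objective,
                 evaluations = x$evaluations,
                 grid_resolution = x$grid_resolution)
}

#' @export
tidy.flux_vector <- function(x, ...) {
  tibble::tibble(reaction = names(x$values), flux = unname(x$values))
}

#' Summarize a scenario batch
#'
#' @param results list returned by [run_scenarios()].
#' @return tibble with `scenario`, `status`, `outer_objective`.
#' @export
scenario_summary <- function(results) {
  tibble::tibble(
    scenario = names(results),
    status = unname(vapply(results, function(s) s$status, character(1))),
    outer_objective = unname(vapply(results, function(s)
      if (inherits(s, "community_solution")) s$outer_objective_value
      else NA_real_, numeric(1))))
}

#' Plot per-species biomass and optimality levels
#'
#' Bar chart of biomass fluxes, filled by the optimality level `c` (grey for
#' species whose community-specific maximum is zero).
#'
#' @param object a `community_solution`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.community_solution <- function(object, ...) {
  df <- optimality_levels(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$biomass,
                                   fill = .data$c)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 1,
                                  na.value = "grey70",
                                  name = "optimality\nlevel c") +
    ggplot2::labs(x = NULL, y = "biomass flux (mmol/gDW/h)",
                  title = sprintf("%s community solution (outer objective %.3g)",
                                  object$mode, object$outer_objective_value)) +
    ggplot2::theme_minimal()
}

#' Plot inter-organism exchange flows
#'
#' Net flow of every shared metabolite per species: positive bars are exports
#' into the pool, negative bars uptakes from it.
#'
#' @param sol a `community_solution`.
#' @return a ggplot object.
#' @export
plot_exchange <- function(sol) {
  df <- exchange_flows(sol)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$net,
                                   fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "shared metabolite",
                  y = "net flow into pool (mmol/gDW/h)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
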