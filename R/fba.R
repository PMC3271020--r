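#' Flux balance analysis of a single species
#'
#' Maximizes the biomass flux subject to steady-state mass balance on all
#' internal metabolites and the reaction bounds. Shared-pool metabolites are
#' treated as boundary species (no mass-balance row): in isolation a species
#' may exchange them freely within its reaction bounds.
#'
#' @param m a [species_model()].
#' @param overrides named list, reaction id -> `c(lb, ub)` bound overrides.
#' @return a `flux_vector`: list with `species_id`, `values` (named fluxes,
#'   mmol/gDW/h), `objective` (biomass flux), `status` (`"optimal"` or
#'   `"infeasible"`), and `duals` (internal metabolite shadow prices).
#'   Unbounded biomass raises a `comfba_unbounded_error` naming a reaction on
#'   the unbounded ray.
#' @export
solve_fba <- function(m, overrides = list()) {
  lp <- species_lp(m, overrides = overrides)
  res <- lp_solve(lp$obj, lp$A, lp$rhs, lp$dir, lp$lb, lp$ub,
                  maximize = TRUE, var_names = lp$var_names)
  if (res$status == "unbounded")
    abort_unbounded(sprintf("species '%s': biomass unbounded along '%s'",
                            m$species_id, res$unbounded_var))
  if (res$status == "infeasible")
    return(new_flux_vector(m$species_id, NULL, NA_real_, "infeasible"))
  new_flux_vector(m$species_id, res$x, res$objective, "optimal", duals = res$duals)
}

new_flux_vector <- function(species_id, values, objective, status, duals = NULL) {
  structure(list(species_id = species_id, values = values,
                 objective = objective, status = status, duals = duals),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat(sprintf("<flux_vector> %s: status %s, biomass %s\n", x$species_id,
              x$status, format(x$objective)))
  invisible(x)
}

#' Build the LP of one species (internal)
#'
#' Rows: internal mass balances; optionally, for every shared metabolite in
#' `allocation`, the net-exchange fixing `sum_j coef(j,i) v_j = export - uptake`.
#' Inner-level constraint rows (fixed fluxes, flux ratios) are appended when a
#' community context supplies them.
#'
#' @keywords internal
species_lp <- function(m, overrides = list(), allocation = NULL,
                       inner_constraints = list(), objective = NULL) {
  rids <- reaction_ids(m)
  n <- length(rids)
  bb <- reaction_bounds(m)
  lb <- bb$lb; ub <- bb$ub
  for (rid in names(overrides)) {
    j <- match(rid, rids)
    if (is.na(j))
      abort_config(sprintf("override references unknown reaction '%s'", rid))
    lb[j] <- overrides[[rid]][1]
    ub[j] <- overrides[[rid]][2]
  }
  S_int <- stoich_matrix(m, "internal")
  A <- S_int
  rhs <- rep(0, nrow(S_int))
  dir <- rep("==", nrow(S_int))
  row_kind <- rep("balance", nrow(S_int))

  if (!is.null(allocation)) {
    S_sh <- stoich_matrix(m, "shared")
    for (mid in names(allocation)) {
      a <- allocation[[mid]]
      if (any(a < 0)) abort_config(
        sprintf("allocation for '%s' has negative flow", mid))
      net <- a[["export"]] - a[["uptake"]]
      coefs <- if (mid %in% rownames(S_sh)) S_sh[mid, ] else rep(0, n)
      A <- rbind(A, coefs)
      rhs <- c(rhs, net)
      dir <- c(dir, "==")
      row_kind <- c(row_kind, "allocation")
    }
  }
  for (cs in inner_constraints) {
    row <- rep(0, n)
    if (cs$form == "fixed_flux") {
      row[match(cs$reaction, rids)] <- 1
      rhs <- c(rhs, cs$value)
    } else if (cs$form == "flux_ratio") {
      row[match(cs$reaction_num, rids)] <- 1
      row[match(cs$reaction_den, rids)] <- row[match(cs$reaction_den, rids)] - cs$ratio
      rhs <- c(rhs, 0)
    } else next
    A <- rbind(A, row)
    dir <- c(dir, "==")
    row_kind <- c(row_kind, "inner_constraint")
  }
  obj <- if (is.null(objective)) {
    o <- rep(0, n); o[match(m$biomass_id, rids)] <- 1; o
  } else objective
  list(obj = obj, A = A, rhs = rhs, dir = dir, lb = lb, ub = ub,
       var_names = rids, row_kind = row_kind)
}

#' Community-conditional optimum of one species
#'
#' Maximal biomass of species `m` when its flows of the listed shared
#' metabolites are fixed to the given allocation; metabolites absent from the
#' allocation remain free boundary species. This is the value function of the
#' species' inner problem, a concave piecewise-linear function of the
#' allocation.
#'
#' @param m a [species_model()].
#' @param allocation named list, shared metabolite id -> `c(uptake =, export =)`
#'   (both >= 0, mmol/gDW/h).
#' @param overrides bound overrides as in [solve_fba()].
#' @param inner_constraints inner-level constraint list (internal use).
#' @return list with `status` (`"optimal"` or `"infeasible"` — an infeasible
#'   allocation is distinct from zero growth), `z` (the optimum, `NA` if
#'   infeasible) and `flux` (an optimal flux vector).
#' @export
inner_optimum <- function(m, allocation, overrides = list(),
                          inner_constraints = list()) {
  allocation <- lapply(allocation, function(a) {
    a <- unlist(a)
    if (is.null(names(a)) || !all(c("uptake", "export") %in% names(a))) {
      if (length(a) != 2L) abort_config("allocation entries need uptake and export")
      names(a) <- c("uptake", "export")
    }
    a
  })
  for (a in allocation) if (any(a < 0))
    abort_config("allocation flows must be >= 0")
  lp <- species_lp(m, overrides = overrides, allocation = allocation,
                   inner_constraints = inner_constraints)
  res <- lp_solve(lp$obj, lp$A, lp$rhs, lp$dir, lp$lb, lp$ub,
                  maximize = TRUE, var_names = lp$var_names)
  if (res$status == "unbounded")
    abort_unbounded(sprintf("species '%s': biomass unbounded along '%s'",
                            m$species_id, res$unbounded_var))
  if (res$status == "infeasible")
    return(list(status = "infeasible", z = NA_real_, flux = NULL))
  list(status = "optimal", z = res$objective, flux = res$x)
}

#' Flux variability analysis of a single species
#'
#' For each target reaction, the minimum and maximum flux subject to the
#' biomass flux staying at or above `objective_fraction` times its optimum.
#'
#' @param m a [species_model()].
#' @param targets character vector of reaction ids.
#' @param objective_fraction fraction of the biomass optimum to retain, in
#'   `[0, 1]`.
#' @param overrides bound overrides as in [solve_fba()].
#' @return tibble with columns `reaction`, `min`, `max`.
#' @export
solve_fva <- function(m, targets, objective_fraction = 1, overrides = list()) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  if (!length(targets))
    return(tibble::tibble(reaction = character(), min = numeric(), max = numeric()))
  rids <- reaction_ids(m)
  unknown <- setdiff(targets, rids)
  if (length(unknown))
    abort_config(sprintf("FVA target '%s' is not a reaction of '%s'",
                         unknown[1], m$species_id))
  fv <- solve_fba(m, overrides = overrides)
  if (fv$status != "optimal")
    abort_infeasible(sprintf("species '%s': model infeasible, no FVA possible",
                             m$species_id))
  lp <- species_lp(m, overrides = overrides)
  A <- rbind(lp$A, lp$obj)
  rhs <- c(lp$rhs, objective_fraction * fv$objective)
  dir <- c(lp$dir, ">=")
  out <- lapply(targets, function(t) {
    o <- rep(0, length(rids)); o[match(t, rids)] <- 1
    lo <- lp_solve(o, A, rhs, dir, lp$lb, lp$ub, maximize = FALSE,
                   var_names = rids)
    hi <- lp_solve(o, A, rhs, dir, lp$lb, lp$ub, maximize = TRUE,
                   var_names = rids)
    vmin <- if (lo$status == "optimal") lo$objective else
      if (lo$status == "unbounded") -Inf else NA_real_
    vmax <- if (hi$status == "optimal") hi$objective else
      if (hi$status == "unbounded") Inf else NA_real_
    tibble::tibble(reaction = t, min = vmin, max = vmax)
  })
  do.call(rbind, out)
}
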