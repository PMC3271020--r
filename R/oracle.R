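# Brute-force verification instruments: exhaustive grid search over
# inter-organism flow allocations with per-allocation inner LP solves, and
# independent optimality certification of returned solutions. These are test
# instruments for desk-scale communities, not production solvers.

#' Independently certify a community solution
#'
#' Re-solves every species' inner biomass-maximization LP at the solution's
#' reported allocation of pool flows and returns the per-species duality gap
#' `z_k - v_bio^k` (allocation-conditional optimum minus realized biomass).
#' Predictive solutions must certify with all gaps <= 1e-6; descriptive
#' solutions may certify with positive gaps where a species grows
#' sub-optimally below its allocation-conditional optimum.
#'
#' @param sol a `community_solution`.
#' @param comm the `community_model` it was solved on.
#' @return named numeric vector, species id -> gap.
#' @export
certify <- function(sol, comm) {
  out <- stats::setNames(rep(NA_real_, length(comm$species)),
                         names(comm$species))
  for (sp in names(comm$species)) {
    m <- comm$species[[sp]]
    alloc <- lapply(comm$shared_ids, function(i)
      c(uptake = sol$u[sp, i], export = sol$e[sp, i]))
    names(alloc) <- comm$shared_ids
    ov <- apply_bound_overrides(reaction_bounds(m)$lb, reaction_bounds(m)$ub,
                                comm$constraints, sp, reaction_ids(m))
    overrides <- stats::setNames(
      lapply(seq_along(ov$lb), function(j) c(ov$lb[j], ov$ub[j])),
      reaction_ids(m))
    io <- inner_optimum(m, alloc, overrides = overrides,
                        inner_constraints = inner_constraints_of(comm$constraints, sp))
    bio <- sol$species[[sp]]$values[[m$biomass_id]]
    out[sp] <- if (io$status == "optimal") io$z - bio else NA_real_
  }
  out
}

#' Exhaustive grid search over inter-organism flow allocations
#'
#' Enumerates allocations of the pool flows on a regular grid; for each
#' allocation, fixes every species' shared-metabolite flows, solves each
#' inner biomass LP to optimality (with optimistic secondary re-optimization
#' towards the outer objective at the fixed inner optimum), discards
#' allocations violating pool balances or attached flow/outer constraints
#' beyond the grid resolution, and returns the best outer objective found.
#' The community uptake and accumulation slacks are not gridded: the pool
#' balance fixes them given the species flows, so their feasibility is an
#' interval check against the medium and accumulation bounds.
#'
#' Grid bounds are derived by LP presolves (per-species maximal
#' production/consumption of each shared metabolite under the medium, with
#' cross-feeding availability propagated over a few rounds); a shared flow
#' that remains unbounded raises a configuration error, since a finite grid
#' requires finite bounds. Terminal by-products (consumed by nobody, with
#' unbounded accumulation and no constraint referencing their flows) are
#' excluded from the grid and left free in the inner LPs.
#'
#' @param comm a `community_model`.
#' @param objective a [community_objective()].
#' @param resolution grid spacing (mmol/gDW/h); the pool-balance tolerance
#'   during enumeration equals the resolution.
#' @return an `oracle_result`: list with `best_allocation` (tibble),
#'   `best_objective` (`-Inf` if no feasible grid point), `best_biomass`,
#'   `grid_resolution`, `evaluations` (product of grid sizes).
#' @export
grid_oracle <- function(comm, objective = community_objective("total_biomass"),
                        resolution = 1) {
  stopifnot(inherits(comm, "community_model"), resolution > 0)
  shared <- comm$shared_ids
  spn <- names(comm$species)
  caps <- oracle_flow_caps(comm)
  eff <- interaction_effects(comm)

  has_flow_constraint <- function(i) {
    any(vapply(eff$rows, function(fr) i %in% fr$terms$metabolite, logical(1))) ||
      any(vapply(comm$constraints, function(cs)
        cs$form == "fixed_flow" && cs$metabolite == i, logical(1)))
  }
  # decide which (species, metabolite, side) dimensions to grid
  dims <- list()
  free_export <- stats::setNames(vector("list", length(spn)), spn)
  for (i in shared) {
    any_uptake <- any(caps$u[, i] > 1e-12)
    byproduct <- !any_uptake && !is.finite(comm$accumulation[[i]]) &&
      !has_flow_constraint(i)
    for (sp in spn) {
      if (caps$u[sp, i] > 1e-12) {
        if (!is.finite(caps$u[sp, i]))
          abort_config(sprintf("unbounded shared flow u[%s,%s]; finite grid impossible", sp, i))
        dims[[length(dims) + 1L]] <- list(sp = sp, met = i, side = "u",
                                          vals = grid_vals(caps$u[sp, i], resolution))
      }
      can_export <- caps$e[sp, i] > 1e-12
      if (can_export && byproduct) {
        free_export[[sp]] <- c(free_export[[sp]], i)
      } else if (can_export) {
        if (!is.finite(caps$e[sp, i]))
          abort_config(sprintf("unbounded shared flow e[%s,%s]; finite grid impossible", sp, i))
        dims[[length(dims) + 1L]] <- list(sp = sp, met = i, side = "e",
                                          vals = grid_vals(caps$e[sp, i], resolution))
      }
    }
  }
  sizes <- if (length(dims)) vapply(dims, function(d) length(d$vals), integer(1))
           else integer(0)
  evaluations <- prod(sizes)
  if (evaluations > 2e5)
    abort_config(sprintf("oracle grid too large (%g points); coarsen the resolution",
                         evaluations))

  # per-species solver setup
  sp_setup <- lapply(spn, function(sp) {
    m <- comm$species[[sp]]
    ov <- apply_bound_overrides(reaction_bounds(m)$lb, reaction_bounds(m)$ub,
                                comm$constraints, sp, reaction_ids(m))
    list(m = m,
         overrides = stats::setNames(
           lapply(seq_along(ov$lb), function(j) c(ov$lb[j], ov$ub[j])),
           reaction_ids(m)),
         inner = inner_constraints_of(comm$constraints, sp))
  })
  names(sp_setup) <- spn

  obj_weights <- outer_objective_weights(comm, objective)

  best_obj <- -Inf
  best_alloc <- NULL
  best_bio <- NULL
  counter <- rep(1L, length(dims))
  n_pts <- max(1, evaluations)
  for (pt in seq_len(n_pts)) {
    u <- matrix(0, length(spn), length(shared), dimnames = list(spn, shared))
    e <- u
    if (length(dims)) {
      for (d in seq_along(dims)) {
        dd <- dims[[d]]
        val <- dd$vals[counter[d]]
        if (dd$side == "u") u[dd$sp, dd$met] <- val else e[dd$sp, dd$met] <- val
      }
      # advance mixed-radix counter
      for (d in seq_along(dims)) {
        counter[d] <- counter[d] + 1L
        if (counter[d] <= sizes[d]) break
        counter[d] <- 1L
      }
    }
    res <- oracle_evaluate(comm, sp_setup, u, e, free_export, obj_weights,
                           objective, resolution, eff)
    if (!is.null(res) && res$obj > best_obj + 1e-12) {
      best_obj <- res$obj
      best_alloc <- res$alloc
      best_bio <- res$bio
    }
  }
  structure(list(best_allocation = best_alloc, best_objective = best_obj,
                 best_biomass = best_bio,
                 grid_resolution = resolution, evaluations = evaluations),
            class = "oracle_result")
}

grid_vals <- function(cap, resolution) {
  # strictly the regular grid from zero: refining the resolution then always
  # keeps the coarser grid's points, so the best objective never decreases
  seq(0, cap, by = resolution)
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("<oracle_result> best objective %.6g over %g evaluations (resolution %g)\n",
              x$best_objective, x$evaluations, x$grid_resolution))
  invisible(x)
}

# linear weight of each species' biomass in the outer objective (NULL entry
# means the objective involves non-biomass reactions and needs a secondary LP)
outer_objective_weights <- function(comm, objective) {
  spn <- names(comm$species)
  w <- stats::setNames(rep(0, length(spn)), spn)
  extra <- NULL
  switch(objective$kind,
    total_biomass = w[] <- 1,
    weighted_biomass = {
      ww <- objective$weights %||% stats::setNames(rep(1, length(spn)), spn)
      for (sp in names(ww)) w[sp] <- ww[[sp]]
    },
    single_species = w[objective$species] <- 1,
    target_flux = {
      tg <- objective$target
      if (tg$kind == "flux") extra <- tg else if (tg$kind == "flow") extra <- tg
      else abort_config("ratio targets cannot be an oracle objective")
    })
  list(w = w, extra = extra)
}

oracle_evaluate <- function(comm, sp_setup, u, e, free_export, obj_weights,
                            objective, resolution, eff) {
  shared <- comm$shared_ids
  spn <- names(comm$species)
  # pool balance check on the gridded flows. The balance itself is checked
  # strictly (the grid is a common lattice, so balanced points are always
  # representable and the oracle stays a true lower bound of the exact
  # solver); only coupling constraints with off-lattice coefficients get the
  # resolution tolerance below.
  d <- colSums(u) - colSums(e)
  for (i in shared) {
    if (d[i] > comm$medium[[i]] + 1e-9) return(NULL)
    if (-d[i] > comm$accumulation[[i]] + 1e-9) return(NULL)
  }
  bio <- stats::setNames(rep(0, length(spn)), spn)
  flux <- list()
  for (sp in spn) {
    su <- sp_setup[[sp]]
    alloc_ids <- setdiff(shared, free_export[[sp]])
    alloc <- lapply(alloc_ids, function(i) c(uptake = u[sp, i], export = e[sp, i]))
    names(alloc) <- alloc_ids
    lp <- species_lp(su$m, overrides = su$overrides, allocation = alloc,
                     inner_constraints = su$inner)
    # metabolites left out of the allocation: export allowed, uptake forbidden
    S_sh <- stoich_matrix(su$m, "shared")
    for (i in free_export[[sp]]) {
      coefs <- if (i %in% rownames(S_sh)) S_sh[i, ] else rep(0, length(lp$obj))
      lp$A <- rbind(lp$A, coefs)
      lp$rhs <- c(lp$rhs, 0)
      lp$dir <- c(lp$dir, ">=")
    }
    res <- lp_solve(lp$obj, lp$A, lp$rhs, lp$dir, lp$lb, lp$ub,
                    maximize = TRUE, var_names = lp$var_names)
    if (res$status != "optimal") return(NULL)
    z <- res$objective
    vx <- res$x
    # optimistic secondary towards the outer objective at fixed inner optimum
    extra <- obj_weights$extra
    if (!is.null(extra) && extra$kind == "flux" && extra$species == sp) {
      o2 <- rep(0, length(lp$obj))
      o2[match(extra$reaction, reaction_ids(su$m))] <- 1
      res2 <- lp_solve(o2, rbind(lp$A, lp$obj), c(lp$rhs, z),
                       c(lp$dir, "=="), lp$lb, lp$ub, maximize = TRUE,
                       var_names = lp$var_names)
      if (res2$status == "optimal") vx <- res2$x
    }
    bio[sp] <- z
    flux[[sp]] <- vx
  }
  # realized exports of free by-products
  for (sp in spn) {
    if (!length(free_export[[sp]])) next
    S_sh <- stoich_matrix(comm$species[[sp]], "shared")
    for (i in free_export[[sp]]) {
      net <- if (i %in% rownames(S_sh)) sum(S_sh[i, ] * flux[[sp]]) else 0
      e[sp, i] <- max(0, net)
    }
  }
  # interaction flow rows (now with realized values)
  for (fr in eff$rows) {
    lhs <- sum(mapply(function(sp, mid, side, coef)
      coef * (if (side == "u") u[sp, mid] else e[sp, mid]),
      fr$terms$species, fr$terms$metabolite, fr$terms$side, fr$terms$coef))
    ok <- switch(fr$dir,
                 "==" = abs(lhs - fr$rhs) <= resolution + 1e-9,
                 "<=" = lhs <= fr$rhs + resolution + 1e-9,
                 ">=" = lhs >= fr$rhs - resolution - 1e-9)
    if (!ok) return(NULL)
  }
  # outer constraints on realized quantities
  d <- colSums(u) - colSums(e)
  uc <- pmax(d, 0); ec <- pmax(-d, 0)
  for (cs in comm$constraints) {
    if (cs$level != "outer") next
    if (cs$form == "biomass_ratio") {
      if (abs(bio[[cs$species_num]] - cs$ratio * bio[[cs$species_den]]) >
          resolution + 1e-9) return(NULL)
    } else if (cs$form == "fixed_flow") {
      val <- switch(cs$flow,
                    uptake = u[cs$species, cs$metabolite],
                    export = e[cs$species, cs$metabolite],
                    community_uptake = uc[[cs$metabolite]],
                    accumulation = ec[[cs$metabolite]])
      if (abs(val - cs$value) > resolution + 1e-9) return(NULL)
    }
  }
  # outer objective
  obj <- sum(obj_weights$w * bio)
  extra <- obj_weights$extra
  if (!is.null(extra)) {
    obj <- obj + if (extra$kind == "flux") {
      sum(flux[[extra$species]][extra$reaction])
    } else {
      switch(extra$flow,
             uptake = u[extra$species, extra$metabolite] -
               e[extra$species, extra$metabolite],
             export = e[extra$species, extra$metabolite] -
               u[extra$species, extra$metabolite],
             community_uptake = uc[[extra$metabolite]],
             accumulation = ec[[extra$metabolite]])
    }
  }
  alloc <- do.call(rbind, lapply(spn, function(sp)
    tibble::tibble(species = sp, metabolite = shared,
                   uptake = u[sp, ], export = e[sp, ])))
  list(obj = obj, alloc = alloc, bio = bio)
}

# per-species production/consumption caps of each shared metabolite,
# propagating cross-feeding availability over a few rounds
oracle_flow_caps <- function(comm, rounds = 4L) {
  shared <- comm$shared_ids
  spn <- names(comm$species)
  eff <- interaction_effects(comm)
  zero_has <- function(tab, sp, mid) any(tab$species == sp & tab$metabolite == mid)
  cap_lp <- function(sp, i, side, avail) {
    m <- comm$species[[sp]]
    ov <- apply_bound_overrides(reaction_bounds(m)$lb, reaction_bounds(m)$ub,
                                comm$constraints, sp, reaction_ids(m))
    S_int <- stoich_matrix(m, "internal")
    S_sh <- stoich_matrix(m, "shared")
    net_row <- function(j) if (j %in% rownames(S_sh)) S_sh[j, ] else
      rep(0, length(ov$lb))
    A <- S_int; rhs <- rep(0, nrow(S_int)); dir <- rep("==", nrow(S_int))
    for (j in shared) {
      if (is.finite(avail[[j]])) {
        A <- rbind(A, net_row(j)); rhs <- c(rhs, -avail[[j]]); dir <- c(dir, ">=")
      }
    }
    o <- net_row(i) * (if (side == "e") 1 else -1)
    res <- lp_solve(o, A, rhs, dir, ov$lb, ov$ub, maximize = TRUE,
                    var_names = reaction_ids(m))
    if (res$status == "unbounded") return(Inf)
    if (res$status != "optimal") return(0)
    max(0, res$objective)
  }
  avail <- comm$medium
  ecap <- ucap <- matrix(0, length(spn), length(shared),
                         dimnames = list(spn, shared))
  for (r in seq_len(rounds)) {
    for (sp in spn) for (i in shared) {
      ecap[sp, i] <- if (zero_has(eff$e_zero, sp, i)) 0 else cap_lp(sp, i, "e", avail)
    }
    avail_new <- comm$medium + colSums(ecap)
    if (all(avail_new == avail | (!is.finite(avail_new) & !is.finite(avail)))) break
    avail <- avail_new
  }
  for (sp in spn) for (i in shared) {
    ucap[sp, i] <- if (zero_has(eff$u_zero, sp, i)) 0 else {
      cl <- cap_lp(sp, i, "u", avail)
      min(cl, avail[[i]])
    }
  }
  list(u = ucap, e = ecap, avail = avail)
}
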