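# Single-level reformulation of the multilevel community problem and the
# branch-and-bound engines that solve it to global optimality.
#
# Predictive mode is an optimistic bilevel program: choose the inter-organism
# flow configuration maximizing the outer objective subject to every species'
# flux vector being optimal for its own biomass-maximization LP given its
# assigned pool flows. Inner optimality is encoded through the inner LPs'
# KKT conditions (stationarity + complementary slackness); two equivalent
# solution paths are provided:
#   method = "dual_milp": complementarity via big-M indicator binaries,
#     solved by branch-and-bound on the binaries (MILP);
#   method = "bilinear": the strong-duality form, whose bilinear products
#     (inner bound dual x primal slack) are driven to zero by branch-and-bound
#     directly on the complementarity disjunctions (no big-M).

# ---------------------------------------------------------------------------
# joint system builder

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$names <- character(0)
  env$lb <- numeric(0)
  env$ub <- numeric(0)
  env$rows <- list()
  env
}

add_var <- function(b, name, lb, ub) {
  b$names <- c(b$names, name)
  b$lb <- c(b$lb, lb)
  b$ub <- c(b$ub, ub)
  length(b$names)
}

add_row <- function(b, idx, coef, dir, rhs, label, primal = TRUE) {
  keep <- coef != 0
  b$rows[[length(b$rows) + 1L]] <- list(idx = idx[keep], coef = coef[keep],
                                        dir = dir, rhs = rhs, label = label,
                                        primal = primal)
}

#' Build the single-level reformulation of a community problem (internal)
#'
#' @param comm community model.
#' @param experimental extra constraints (descriptive mode).
#' @param enforce_inner add KKT certificates of per-species inner optimality.
#' @param method `"dual_milp"` (big-M binaries) or `"bilinear"`
#'   (complementarity disjunctions, no binaries).
#' @param M big-M constant for `dual_milp`.
#' @keywords internal
build_joint_system <- function(comm, experimental = list(),
                               enforce_inner = TRUE,
                               method = c("dual_milp", "bilinear"),
                               M = 1000) {
  method <- match.arg(method)
  b <- new_builder()
  species <- comm$species
  shared <- comm$shared_ids
  cons <- c(comm$constraints, experimental)
  eff <- interaction_effects(comm)

  vix <- list(v = list(), u = list(), e = list(), uc = integer(0), ec = integer(0),
              lam = list(), nu = list(), xi = list(), mul = list(), muu = list(),
              z = list(), w = list())

  # primal variables -------------------------------------------------------
  sp_bounds <- list()
  for (sp in names(species)) {
    m <- species[[sp]]
    rids <- reaction_ids(m)
    bb <- reaction_bounds(m)
    ov <- apply_bound_overrides(bb$lb, bb$ub, cons, sp, rids)
    sp_bounds[[sp]] <- ov
    vix$v[[sp]] <- stats::setNames(
      vapply(seq_along(rids), function(j)
        add_var(b, paste0("v.", sp, ".", rids[j]), ov$lb[j], ov$ub[j]),
        integer(1)), rids)
  }
  zero_flow <- function(tab, sp, mid)
    any(tab$species == sp & tab$metabolite == mid)
  for (sp in names(species)) {
    vix$u[[sp]] <- stats::setNames(vapply(shared, function(i)
      add_var(b, paste0("u.", sp, ".", i), 0,
              if (zero_flow(eff$u_zero, sp, i)) 0 else Inf), integer(1)), shared)
    vix$e[[sp]] <- stats::setNames(vapply(shared, function(i)
      add_var(b, paste0("e.", sp, ".", i), 0,
              if (zero_flow(eff$e_zero, sp, i)) 0 else Inf), integer(1)), shared)
  }
  vix$uc <- stats::setNames(vapply(shared, function(i)
    add_var(b, paste0("uc.", i), 0, comm$medium[[i]]), integer(1)), shared)
  vix$ec <- stats::setNames(vapply(shared, function(i)
    add_var(b, paste0("ec.", i), 0, comm$accumulation[[i]]), integer(1)), shared)

  # primal rows -------------------------------------------------------------
  inner_rows <- list()  # per species: list of list(idx, coef, rhs) inside inner LP
  for (sp in names(species)) {
    m <- species[[sp]]
    S_int <- stoich_matrix(m, "internal")
    for (mid in rownames(S_int))
      add_row(b, vix$v[[sp]], S_int[mid, ], "==", 0, paste0("bal.", sp, ".", mid))
    S_sh <- stoich_matrix(m, "shared")
    for (i in shared) {
      coefs <- if (i %in% rownames(S_sh)) S_sh[i, ] else rep(0, length(vix$v[[sp]]))
      add_row(b, c(vix$v[[sp]], vix$e[[sp]][i], vix$u[[sp]][i]),
              c(coefs, -1, 1), "==", 0, paste0("link.", sp, ".", i))
    }
    ics <- inner_constraints_of(cons, sp)
    inner_rows[[sp]] <- list()
    for (cs in ics) {
      rids <- reaction_ids(m)
      if (cs$form == "fixed_flux") {
        idx <- vix$v[[sp]][cs$reaction]; coef <- 1; rhs <- cs$value
      } else {
        idx <- vix$v[[sp]][c(cs$reaction_num, cs$reaction_den)]
        coef <- c(1, -cs$ratio); rhs <- 0
        if (cs$reaction_num == cs$reaction_den) { idx <- idx[1]; coef <- 1 - cs$ratio }
      }
      add_row(b, idx, coef, "==", rhs, paste0("innercon.", sp))
      inner_rows[[sp]][[length(inner_rows[[sp]]) + 1L]] <-
        list(idx = idx, coef = coef, rhs = rhs)
    }
  }
  for (i in shared) {
    idx <- c(vapply(names(species), function(sp) vix$e[[sp]][[i]], integer(1)),
             vapply(names(species), function(sp) vix$u[[sp]][[i]], integer(1)),
             vix$uc[[i]], vix$ec[[i]])
    coef <- c(rep(1, length(species)), rep(-1, length(species)), 1, -1)
    add_row(b, idx, coef, "==", 0, paste0("pool.", i))
  }
  # interaction flow rows
  for (fr in eff$rows) {
    idx <- mapply(function(sp, mid, side)
      if (side == "u") vix$u[[sp]][[mid]] else vix$e[[sp]][[mid]],
      fr$terms$species, fr$terms$metabolite, fr$terms$side)
    add_row(b, as.integer(idx), fr$terms$coef, fr$dir, fr$rhs, fr$label)
  }
  # outer constraint rows
  for (cs in cons) {
    if (cs$level != "outer") next
    if (cs$form == "biomass_ratio") {
      bi <- vix$v[[cs$species_num]][species[[cs$species_num]]$biomass_id]
      bj <- vix$v[[cs$species_den]][species[[cs$species_den]]$biomass_id]
      if (bi == bj) next
      add_row(b, c(bi, bj), c(1, -cs$ratio), "==", 0, "outer.biomass_ratio")
    } else if (cs$form == "fixed_flow") {
      idx <- switch(cs$flow,
                    uptake = vix$u[[cs$species]][[cs$metabolite]],
                    export = vix$e[[cs$species]][[cs$metabolite]],
                    community_uptake = vix$uc[[cs$metabolite]],
                    accumulation = vix$ec[[cs$metabolite]])
      add_row(b, idx, 1, "==", cs$value, "outer.fixed_flow")
    }
  }

  comp_pairs <- list()
  binaries <- integer(0)
  if (enforce_inner) {
    for (sp in names(species)) {
      m <- species[[sp]]
      rids <- reaction_ids(m)
      nv <- length(rids)
      ov <- sp_bounds[[sp]]
      S_int <- stoich_matrix(m, "internal")
      S_sh_full <- stoich_matrix(m, "shared")
      vix$lam[[sp]] <- stats::setNames(vapply(rownames(S_int), function(mid)
        add_var(b, paste0("lam.", sp, ".", mid), -Inf, Inf), integer(1)),
        rownames(S_int))
      vix$nu[[sp]] <- stats::setNames(vapply(shared, function(i)
        add_var(b, paste0("nu.", sp, ".", i), -Inf, Inf), integer(1)), shared)
      vix$xi[[sp]] <- vapply(seq_along(inner_rows[[sp]]), function(q)
        add_var(b, paste0("xi.", sp, ".", q), -Inf, Inf), integer(1))
      vix$mul[[sp]] <- stats::setNames(rep(NA_integer_, nv), rids)
      vix$muu[[sp]] <- stats::setNames(rep(NA_integer_, nv), rids)
      for (j in seq_len(nv)) {
        if (is.finite(ov$lb[j]))
          vix$mul[[sp]][j] <- add_var(b, paste0("mul.", sp, ".", rids[j]), 0, Inf)
        if (is.finite(ov$ub[j]))
          vix$muu[[sp]][j] <- add_var(b, paste0("muu.", sp, ".", rids[j]), 0, Inf)
      }
      # stationarity: c_j - S'lam - C'nu - A'xi + mul - muu = 0
      for (j in seq_len(nv)) {
        cj <- as.numeric(rids[j] == m$biomass_id)
        idx <- integer(0); coef <- numeric(0)
        if (nrow(S_int)) {
          idx <- c(idx, vix$lam[[sp]])
          coef <- c(coef, -S_int[, j])
        }
        idx <- c(idx, vix$nu[[sp]])
        coef <- c(coef, -vapply(shared, function(i)
          if (i %in% rownames(S_sh_full)) S_sh_full[i, j] else 0, numeric(1)))
        for (q in seq_along(inner_rows[[sp]])) {
          ir <- inner_rows[[sp]][[q]]
          pos <- match(vix$v[[sp]][j], ir$idx)
          if (!is.na(pos)) {
            idx <- c(idx, vix$xi[[sp]][q])
            coef <- c(coef, -ir$coef[pos])
          }
        }
        if (!is.na(vix$mul[[sp]][j])) { idx <- c(idx, vix$mul[[sp]][j]); coef <- c(coef, 1) }
        if (!is.na(vix$muu[[sp]][j])) { idx <- c(idx, vix$muu[[sp]][j]); coef <- c(coef, -1) }
        add_row(b, idx, coef, "==", -cj, paste0("stat.", sp, ".", rids[j]),
                primal = FALSE)
      }
      # complementarity bookkeeping / big-M rows
      for (j in seq_len(nv)) {
        vj <- vix$v[[sp]][j]
        if (!is.na(vix$mul[[sp]][j])) {
          # the slack cap is the natural bound range when finite; M only
          # stands in for a genuinely unbounded slack
          natural <- is.finite(ov$ub[j] - ov$lb[j])
          cap <- if (natural) ov$ub[j] - ov$lb[j] else M
          pair <- list(mu = vix$mul[[sp]][j], v = vj, bound = ov$lb[j],
                       type = "lb", cap = cap, natural = natural)
          comp_pairs[[length(comp_pairs) + 1L]] <- pair
          if (method == "dual_milp") {
            zi <- add_var(b, paste0("z.", sp, ".", rids[j]), 0, 1)
            binaries <- c(binaries, zi)
            comp_pairs[[length(comp_pairs)]]$bin <- zi
            add_row(b, c(pair$mu, zi), c(1, -M), "<=", 0,
                    paste0("bigM.mu.", sp, ".", rids[j]), primal = FALSE)
            add_row(b, c(vj, zi), c(1, cap), "<=", ov$lb[j] + cap,
                    paste0("bigM.slack.", sp, ".", rids[j]), primal = FALSE)
          }
        }
        if (!is.na(vix$muu[[sp]][j])) {
          natural <- is.finite(ov$ub[j] - ov$lb[j])
          cap <- if (natural) ov$ub[j] - ov$lb[j] else M
          pair <- list(mu = vix$muu[[sp]][j], v = vj, bound = ov$ub[j],
                       type = "ub", cap = cap, natural = natural)
          comp_pairs[[length(comp_pairs) + 1L]] <- pair
          if (method == "dual_milp") {
            wi <- add_var(b, paste0("w.", sp, ".", rids[j]), 0, 1)
            binaries <- c(binaries, wi)
            comp_pairs[[length(comp_pairs)]]$bin <- wi
            add_row(b, c(pair$mu, wi), c(1, -M), "<=", 0,
                    paste0("bigM.mu2.", sp, ".", rids[j]), primal = FALSE)
            add_row(b, c(vj, wi), c(-1, cap), "<=", cap - ov$ub[j],
                    paste0("bigM.slack2.", sp, ".", rids[j]), primal = FALSE)
          }
        }
      }
    }
  }

  n <- length(b$names)
  A <- matrix(0, length(b$rows), n)
  rhs <- numeric(length(b$rows))
  dir <- character(length(b$rows))
  labels <- character(length(b$rows))
  primal_row <- logical(length(b$rows))
  for (r in seq_along(b$rows)) {
    rr <- b$rows[[r]]
    A[r, rr$idx] <- A[r, rr$idx] + rr$coef
    rhs[r] <- rr$rhs; dir[r] <- rr$dir; labels[r] <- rr$label
    primal_row[r] <- rr$primal
  }
  primal_vars <- grep("^(v|u|e|uc|ec)\\.", b$names)
  list(A = A, rhs = rhs, dir = dir, lb = b$lb, ub = b$ub,
       var_names = b$names, labels = labels, primal_row = primal_row,
       primal_vars = primal_vars, vix = vix, comp_pairs = comp_pairs,
       binaries = binaries, M = M, comm = comm, cons = cons,
       enforce_inner = enforce_inner, method = method)
}

#' Linear objective vector over the joint variables (internal)
#' @keywords internal
objective_vector <- function(sys, obj) {
  n <- length(sys$var_names)
  out <- numeric(n)
  species <- sys$comm$species
  if (inherits(obj, "comfba_target")) {
    tg <- obj
    if (tg$kind == "flux") {
      if (!tg$species %in% names(species))
        abort_config(sprintf("target references unknown species '%s'", tg$species))
      vi <- sys$vix$v[[tg$species]][tg$reaction]
      if (is.na(vi))
        abort_config(sprintf("target references unknown reaction '%s'", tg$reaction))
      out[vi] <- 1
    } else if (tg$kind == "flow") {
      if (!tg$metabolite %in% sys$comm$shared_ids)
        abort_config(sprintf("target references unknown shared metabolite '%s'",
                             tg$metabolite))
      # per-species flows are measured net of pass-through (simultaneous
      # uptake and export of the same metabolite), which pool balances
      # otherwise permit in unbounded amounts
      switch(tg$flow,
        uptake = {
          out[sys$vix$u[[tg$species]][[tg$metabolite]]] <- 1
          out[sys$vix$e[[tg$species]][[tg$metabolite]]] <- -1
        },
        export = {
          out[sys$vix$e[[tg$species]][[tg$metabolite]]] <- 1
          out[sys$vix$u[[tg$species]][[tg$metabolite]]] <- -1
        },
        community_uptake = out[sys$vix$uc[[tg$metabolite]]] <- 1,
        accumulation = out[sys$vix$ec[[tg$metabolite]]] <- 1)
    } else abort_config("ratio targets cannot be used as a linear objective")
    return(out)
  }
  stopifnot(inherits(obj, "community_objective"))
  switch(obj$kind,
    total_biomass = {
      for (sp in names(species))
        out[sys$vix$v[[sp]][species[[sp]]$biomass_id]] <- 1
    },
    weighted_biomass = {
      w <- obj$weights %||% stats::setNames(rep(1, length(species)), names(species))
      for (sp in names(species))
        out[sys$vix$v[[sp]][species[[sp]]$biomass_id]] <- w[[sp]] %||% 1
    },
    single_species = {
      if (!obj$species %in% names(species))
        abort_config(sprintf("objective references unknown species '%s'", obj$species))
      out[sys$vix$v[[obj$species]][species[[obj$species]]$biomass_id]] <- 1
    },
    target_flux = return(objective_vector(sys, obj$target)))
  out
}

# ---------------------------------------------------------------------------
# branch-and-bound engine

# detect(x) -> NULL when x is certificate-feasible, else a list of two
# alternative bound fixes, each list(idx =, lb =, ub =) vectors
bb_solve <- function(sys, obj_vec, maximize = TRUE, detect,
                     heuristic = NULL, init = NULL,
                     gap_tol = 1e-9, node_limit = 200000L) {
  better <- function(a, b) if (maximize) a > b else a < b
  best_obj <- if (maximize) -Inf else Inf
  best_x <- NULL
  if (!is.null(init)) { best_obj <- init$obj; best_x <- init$x }
  stack <- list(list(lb = sys$lb, ub = sys$ub, depth = 0L))
  nodes <- 0L
  root_bound <- NA_real_
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) stop("branch-and-bound node limit exceeded")
    res <- lp_solve(obj_vec, sys$A, sys$rhs, sys$dir, node$lb, node$ub,
                    maximize = maximize, var_names = sys$var_names)
    if (res$status == "infeasible") next
    if (res$status == "unbounded") {
      if (node$depth == 0L)
        return(list(status = "unbounded", unbounded_var = res$unbounded_var,
                    nodes = nodes))
      stop("internal: non-root relaxation unbounded")
    }
    if (nodes == 1L) root_bound <- res$objective
    bound <- res$objective
    if (!is.null(best_x) && !better(bound - (if (maximize) gap_tol else -gap_tol),
                                    best_obj)) next
    viol <- detect(res$x)
    if (is.null(viol)) {
      if (is.null(best_x) || better(bound, best_obj)) {
        best_obj <- bound
        best_x <- res$x
      }
      next
    }
    if (!is.null(heuristic) && (node$depth %% 8L == 0L)) {
      h <- heuristic(res$x)
      if (!is.null(h) && (is.null(best_x) || better(h$obj, best_obj))) {
        best_obj <- h$obj
        best_x <- h$x
      }
    }
    for (alt in rev(viol)) {
      child <- node
      child$depth <- node$depth + 1L
      if (!is.null(alt$lb)) child$lb[alt$idx] <- pmax(child$lb[alt$idx], alt$lb)
      if (!is.null(alt$ub)) child$ub[alt$idx] <- pmin(child$ub[alt$idx], alt$ub)
      if (all(child$lb <= child$ub + 1e-12))
        stack[[length(stack) + 1L]] <- child
    }
  }
  if (is.null(best_x))
    return(list(status = "infeasible", nodes = nodes))
  list(status = "optimal", objective = best_obj, x = best_x,
       nodes = nodes, root_bound = root_bound)
}

detect_binary <- function(sys, tol = 1e-6) {
  bins <- sys$binaries
  force(bins)
  function(x) {
    if (!length(bins)) return(NULL)
    frac <- abs(x[bins] - round(x[bins]))
    j <- which.max(frac)
    if (frac[j] <= tol) return(NULL)
    bi <- bins[j]
    up_first <- round(x[bi]) == 1
    alts <- list(list(idx = bi, lb = 1, ub = NULL),
                 list(idx = bi, lb = NULL, ub = 0))
    if (!up_first) alts <- rev(alts)
    alts
  }
}

detect_complementarity <- function(sys, tol = 1e-7) {
  pairs <- sys$comp_pairs
  force(pairs)
  function(x) {
    if (!length(pairs)) return(NULL)
    viol <- vapply(pairs, function(p) {
      slack <- if (p$type == "lb") x[p$v] - p$bound else p$bound - x[p$v]
      max(0, x[p$mu]) * max(0, slack)
    }, numeric(1))
    j <- which.max(viol)
    if (viol[j] <= tol) return(NULL)
    p <- pairs[[j]]
    list(list(idx = p$mu, lb = NULL, ub = 0),                 # dual = 0
         list(idx = p$v, lb = p$bound, ub = p$bound))         # slack = 0
  }
}

# allocation-repair heuristic: take the relaxation's pool-flow configuration,
# solve every inner LP at that allocation, keep the point if it satisfies all
# primal rows (optimistic inner response w.r.t. the outer objective)
make_heuristic <- function(sys, obj_vec) {
  comm <- sys$comm
  function(x) {
    xc <- x
    ok <- TRUE
    for (sp in names(comm$species)) {
      m <- comm$species[[sp]]
      alloc <- lapply(comm$shared_ids, function(i)
        c(uptake = max(0, x[sys$vix$u[[sp]][[i]]]),
          export = max(0, x[sys$vix$e[[sp]][[i]]])))
      names(alloc) <- comm$shared_ids
      ov <- apply_bound_overrides(reaction_bounds(m)$lb, reaction_bounds(m)$ub,
                                  sys$cons, sp, reaction_ids(m))
      overrides <- stats::setNames(
        lapply(seq_along(ov$lb), function(j) c(ov$lb[j], ov$ub[j])),
        reaction_ids(m))
      io <- tryCatch(
        inner_optimum(m, alloc, overrides = overrides,
                      inner_constraints = inner_constraints_of(sys$cons, sp)),
        comfba_error = function(e) list(status = "infeasible"))
      if (io$status != "optimal") { ok <- FALSE; break }
      # optimistic secondary: reoptimize this species' contribution to the
      # outer objective at its fixed inner optimum
      co <- obj_vec[sys$vix$v[[sp]]]
      if (any(co != 0 & reaction_ids(m) != m$biomass_id)) {
        lp <- species_lp(m, overrides = overrides, allocation = alloc,
                         inner_constraints = inner_constraints_of(sys$cons, sp),
                         objective = co)
        bio_row <- rep(0, length(co)); bio_row[match(m$biomass_id, reaction_ids(m))] <- 1
        sec <- lp_solve(lp$obj, rbind(lp$A, bio_row), c(lp$rhs, io$z),
                        c(lp$dir, "=="), lp$lb, lp$ub, maximize = TRUE,
                        var_names = reaction_ids(m))
        if (sec$status == "optimal") io$flux <- sec$x
      }
      xc[sys$vix$v[[sp]]] <- io$flux[reaction_ids(m)]
    }
    if (!ok) return(NULL)
    # verify all primal rows (outer constraints included)
    pr <- which(sys$primal_row)
    lhs <- as.vector(sys$A[pr, , drop = FALSE][, sys$primal_vars, drop = FALSE] %*%
                       xc[sys$primal_vars])
    rhs <- sys$rhs[pr]; dir <- sys$dir[pr]
    bad <- (dir == "==" & abs(lhs - rhs) > 1e-7) |
      (dir == "<=" & lhs > rhs + 1e-7) | (dir == ">=" & lhs < rhs - 1e-7)
    if (any(bad)) return(NULL)
    xc[-c(sys$primal_vars)] <- NA_real_
    list(obj = sum(obj_vec * ifelse(is.na(xc), 0, xc)), x = xc)
  }
}

solve_joint <- function(sys, obj_vec, maximize = TRUE, init = NULL,
                        use_heuristic = TRUE) {
  detect <- if (!sys$enforce_inner) function(x) NULL
            else if (sys$method == "dual_milp") detect_binary(sys)
            else detect_complementarity(sys)
  heur <- if (sys$enforce_inner && use_heuristic) make_heuristic(sys, obj_vec)
          else NULL
  bb_solve(sys, obj_vec, maximize = maximize, detect = detect,
           heuristic = heur, init = init)
}

# big-M certificate check: no bound dual at its M cap and no primal slack
# truncated by an artificial (non-natural) cap
check_bigM <- function(sys, x, tol = 1e-6) {
  if (sys$method != "dual_milp" || !sys$enforce_inner) return(TRUE)
  for (p in sys$comp_pairs) {
    mu <- x[p$mu]
    if (!is.na(mu) && mu >= sys$M - tol) return(FALSE)
    if (!p$natural) {
      slack <- if (p$type == "lb") x[p$v] - p$bound else p$bound - x[p$v]
      if (!is.na(slack) && slack >= p$cap - tol) return(FALSE)
    }
  }
  TRUE
}

# ---------------------------------------------------------------------------
# public solvers

#' Predictive community solve
#'
#' Maximizes the outer community objective over all inter-organism flow
#' configurations in which every species is at the optimum of its own
#' biomass-maximization LP given its assigned pool flows (optimistic bilevel
#' semantics: among alternate inner optima the outer-favourable one is
#' chosen). The returned solution is certified: each species' inner problem
#' is independently re-solved at the reported allocation and the duality gap
#' must not exceed `1e-6`.
#'
#' Reported solutions are made deterministic by a lexicographic tie-break: at
#' the optimal outer objective, total inter-organism flow `sum(u + e)` is
#' minimized, which also suppresses simultaneous uptake and export of the
#' same metabolite.
#'
#' @param comm a `community_model`.
#' @param objective a [community_objective()].
#' @param method `"dual_milp"` (default; KKT with big-M indicator binaries)
#'   or `"bilinear"` (strong-duality path, branch-and-bound on the
#'   complementarity products).
#' @param M big-M constant (`dual_milp`); validated post-solve and doubled
#'   (up to 3 times) if any certificate touches it.
#' @param tie_break apply the deterministic secondary minimization.
#' @return a `community_solution`.
#' @export
solve_predictive <- function(comm, objective = community_objective("total_biomass"),
                             method = c("dual_milp", "bilinear"),
                             M = 1000, tie_break = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(comm, "community_model"))
  res <- NULL
  sys <- NULL
  for (attempt in 0:3) {
    sys <- build_joint_system(comm, enforce_inner = TRUE, method = method,
                              M = M * 2^attempt)
    obj_vec <- objective_vector(sys, objective)
    res <- solve_joint(sys, obj_vec, maximize = TRUE)
    if (res$status != "optimal") break
    if (check_bigM(sys, res$x)) break
    if (attempt == 3) {
      # distinguish a genuinely unbounded outer objective (which the big-M
      # caps mask by truncating the primal space) from a true certificate gap
      s0 <- build_joint_system(comm, enforce_inner = FALSE)
      r0 <- lp_solve(objective_vector(s0, objective), s0$A, s0$rhs, s0$dir,
                     s0$lb, s0$ub, maximize = TRUE, var_names = s0$var_names)
      if (r0$status == "unbounded")
        abort_unbounded(sprintf("outer objective unbounded along '%s'",
                                r0$unbounded_var %||% "?"))
      abort_comfba("comfba_bigM_error",
                   "big-M certificate failure persisted after 3 doublings (status gap_limit)")
    }
  }
  if (res$status == "infeasible")
    abort_infeasible(infeasibility_message(comm, sys))
  if (res$status == "unbounded")
    abort_unbounded(sprintf("outer objective unbounded along '%s'",
                            res$unbounded_var %||% "?"))
  obj_vec <- objective_vector(sys, objective)
  x <- res$x
  zstar <- res$objective
  if (tie_break) {
    # pin the outer objective to its certified optimum (exactly attainable:
    # zstar is the value of an LP vertex of this same system; if numerical
    # noise ever makes the face empty the un-tie-broken solution is kept)
    tie_vec <- flow_sum_vector(sys)
    sys2 <- sys
    sys2$A <- rbind(sys$A, obj_vec)
    sys2$rhs <- c(sys$rhs, zstar)
    sys2$dir <- c(sys$dir, "==")
    sys2$primal_row <- c(sys$primal_row, TRUE)
    init <- list(obj = sum(tie_vec * ifelse(is.na(x), 0, x)), x = x)
    res2 <- solve_joint(sys2, tie_vec, maximize = FALSE, init = init,
                        use_heuristic = FALSE)
    if (res2$status == "optimal") x <- res2$x
  }
  build_solution(sys, x, objective, mode = "predictive", method = method,
                 outer_value = sum(obj_vec * ifelse(is.na(x), 0, x)))
}

flow_sum_vector <- function(sys) {
  out <- numeric(length(sys$var_names))
  for (sp in names(sys$comm$species)) {
    out[sys$vix$u[[sp]]] <- 1
    out[sys$vix$e[[sp]]] <- 1
  }
  out
}

infeasibility_message <- function(comm, sys) {
  # deletion filter over user-attached constraints for a minimal culprit set
  culprits <- character(0)
  cons <- sys$cons
  if (length(cons)) {
    for (k in seq_along(cons)) {
      reduced <- comm
      reduced$constraints <- cons[-k]
      s2 <- build_joint_system(reduced, enforce_inner = FALSE)
      r2 <- lp_solve(numeric(length(s2$var_names)), s2$A, s2$rhs, s2$dir,
                     s2$lb, s2$ub)
      if (r2$status == "optimal")
        culprits <- c(culprits, constraint_label(cons[[k]]))
    }
  }
  if (length(culprits))
    sprintf("community infeasible; relaxing any of {%s} restores feasibility",
            paste(unique(culprits), collapse = ", "))
  else
    "community infeasible (pool balances and bounds admit no inner-optimal configuration)"
}

constraint_label <- function(cs) {
  switch(cs$form,
    fixed_flux = sprintf("fixed_flux(%s:%s=%g)", cs$species, cs$reaction, cs$value),
    flux_ratio = sprintf("flux_ratio(%s:%s/%s=%g)", cs$species, cs$reaction_num,
                         cs$reaction_den, cs$ratio),
    biomass_ratio = sprintf("biomass_ratio(%s/%s=%g)", cs$species_num,
                            cs$species_den, cs$ratio),
    bound_override = sprintf("bound_override(%s:%s)", cs$species, cs$reaction),
    fixed_flow = sprintf("fixed_flow(%s,%s=%g)", cs$metabolite,
                         cs$flow, cs$value),
    cs$form)
}

#' Community-specific growth maxima
#'
#' Solves the predictive problem under environmental constraints only and
#' returns every species' biomass flux: the community-specific maximum each
#' member can reach while all others also strive to grow maximally. These are
#' the reference values against which descriptive optimality levels are
#' measured.
#'
#' @inheritParams solve_predictive
#' @param ranges also report each biomass flux's alternate-optimum range at
#'   the fixed outer optimum (via [community_fva()]), attached as attribute
#'   `"ranges"`.
#' @return named numeric vector of biomass fluxes (mmol/gDW/h).
#' @export
compute_species_maxima <- function(comm, objective = community_objective("total_biomass"),
                                   method = c("dual_milp", "bilinear"),
                                   ranges = FALSE, M = 1000) {
  method <- match.arg(method)
  sol <- solve_predictive(comm, objective, method = method, M = M)
  vmax <- vapply(names(comm$species), function(sp)
    sol$species[[sp]]$values[[comm$species[[sp]]$biomass_id]], numeric(1))
  if (ranges) {
    rng <- lapply(names(comm$species), function(sp)
      community_fva(comm, objective,
                    flux_target(sp, comm$species[[sp]]$biomass_id),
                    fraction = 1, method = method, predictive = sol))
    attr(vmax, "ranges") <- tibble::tibble(
      species = names(comm$species),
      min = vapply(rng, `[[`, numeric(1), 1L),
      max = vapply(rng, `[[`, numeric(1), 2L))
  }
  vmax
}

#' Descriptive community solve: per-species optimality levels
#'
#' Quantifies how far each member's growth deviates from its
#' community-specific maximum under observed (experimental) constraints.
#' Three stages: (1) the community-specific maxima `v_max` are computed by a
#' predictive solve without the experimental constraints; (2) a single-level
#' problem — steady state, bounds, pool balances, all experimental
#' constraints, inner optimality *not* enforced — maximizes the outer
#' objective; (3) the optimality level of species `k` is
#' `c^k = v_bio^k / v_max^k`. `c^k < 1` marks sub-optimal growth (the member
#' grows at `100 c^k` % of its maximum), `c^k = 1` optimal growth, and
#' `c^k > 1` super-optimal growth — a higher biomass flux than the
#' community-specific maximum, achievable only by depleting resources from
#' other members. When `v_max^k = 0` the level is reported as `NaN` and the
#' species is flagged super-optimal if it grows at all.
#'
#' @inheritParams solve_predictive
#' @param experimental list of constraints encoding the observations
#'   (community composition, measured fluxes).
#' @return a `community_solution` with fields `c` (optimality levels) and
#'   `v_max`.
#' @export
solve_descriptive <- function(comm, objective = community_objective("total_biomass"),
                              experimental = list(),
                              method = c("dual_milp", "bilinear"), M = 1000) {
  method <- match.arg(method)
  stopifnot(inherits(comm, "community_model"))
  if (inherits(experimental, "comfba_constraint")) experimental <- list(experimental)
  for (cs in experimental) add_constraint(comm, cs)  # id validation only
  vmax <- compute_species_maxima(comm, objective, method = method, M = M)

  sys <- build_joint_system(comm, experimental = experimental,
                            enforce_inner = FALSE)
  obj_vec <- objective_vector(sys, objective)
  res <- lp_solve(obj_vec, sys$A, sys$rhs, sys$dir, sys$lb, sys$ub,
                  maximize = TRUE, var_names = sys$var_names)
  if (res$status == "infeasible")
    abort_infeasible(descriptive_infeasibility(comm, experimental))
  if (res$status == "unbounded")
    abort_unbounded(sprintf("outer objective unbounded along '%s'", res$unbounded_var))
  zstar <- res$objective
  tie_vec <- flow_sum_vector(sys)
  res2 <- lp_solve(tie_vec, rbind(sys$A, obj_vec), c(sys$rhs, zstar),
                   c(sys$dir, "=="), sys$lb, sys$ub, maximize = FALSE,
                   var_names = sys$var_names)
  x <- if (res2$status == "optimal") res2$x else res$x
  build_solution(sys, x, objective, mode = "descriptive", method = method,
                 outer_value = sum(obj_vec * x), v_max = vmax)
}

descriptive_infeasibility <- function(comm, experimental) {
  culprits <- character(0)
  for (k in seq_along(experimental)) {
    s2 <- build_joint_system(comm, experimental = experimental[-k],
                             enforce_inner = FALSE)
    r2 <- lp_solve(numeric(length(s2$var_names)), s2$A, s2$rhs, s2$dir,
                   s2$lb, s2$ub)
    if (r2$status == "optimal")
      culprits <- c(culprits, constraint_label(experimental[[k]]))
  }
  if (length(culprits))
    sprintf("experimental constraints infeasible; relaxing any of {%s} restores feasibility",
            paste(unique(culprits), collapse = ", "))
  else "experimental constraints infeasible"
}

#' Community-level flux variability analysis
#'
#' Minimum and maximum of a target quantity subject to the outer objective
#' staying at or above `fraction` times its predictive optimum while every
#' species' inner-optimality certificate is retained. Ratio targets
#' ([ratio_target()]) are handled by bisection on the feasibility of
#' `num - r * den = 0`.
#'
#' @inheritParams solve_predictive
#' @param target a [flux_target()], [flow_target()] or [ratio_target()].
#' @param fraction fraction of the outer optimum to retain, in `[0, 1]`.
#' @param predictive optionally, a precomputed predictive solution to reuse.
#' @return numeric `c(min, max)`.
#' @export
community_fva <- function(comm, objective = community_objective("total_biomass"),
                          target, fraction = 1,
                          method = c("dual_milp", "bilinear"),
                          predictive = NULL, M = 1000) {
  method <- match.arg(method)
  stopifnot(fraction >= 0, fraction <= 1)
  sol <- predictive %||% solve_predictive(comm, objective, method = method,
                                          M = M, tie_break = FALSE)
  zstar <- sol$outer_objective_value
  sys <- build_joint_system(comm, enforce_inner = TRUE, method = method, M = M)
  obj_vec <- objective_vector(sys, objective)
  sys$A <- rbind(sys$A, obj_vec)
  sys$rhs <- c(sys$rhs, fraction * zstar - 1e-9)
  sys$dir <- c(sys$dir, ">=")
  sys$primal_row <- c(sys$primal_row, TRUE)
  x0 <- solution_vector(sys, sol)

  if (inherits(target, "comfba_target") && target$kind == "ratio")
    return(ratio_fva(sys, comm, objective, target, fraction, method, sol, M))

  tvec <- objective_vector(sys, target)
  t0 <- sum(tvec * ifelse(is.na(x0), 0, x0))
  lo <- solve_joint(sys, tvec, maximize = FALSE,
                    init = if (!is.null(x0)) list(obj = t0, x = x0))
  hi <- solve_joint(sys, tvec, maximize = TRUE,
                    init = if (!is.null(x0)) list(obj = t0, x = x0))
  for (r in list(lo, hi)) {
    if (r$status == "infeasible")
      abort_infeasible("FVA system infeasible (fraction constraint too tight)")
  }
  vmin <- if (lo$status == "optimal") lo$objective else -Inf
  vmax <- if (hi$status == "optimal") hi$objective else Inf
  c(min = vmin, max = vmax)
}

ratio_fva <- function(sys, comm, objective, target, fraction, method, sol, M) {
  nvec <- objective_vector(sys, target$num)
  dvec <- objective_vector(sys, target$den)
  den_rng <- community_fva(comm, objective, target$den, fraction,
                           method = method, predictive = sol, M = M)
  if (den_rng[1] <= 1e-9)
    abort_config("ratio target denominator can vanish; ratio range undefined")
  num_rng <- community_fva(comm, objective, target$num, fraction,
                           method = method, predictive = sol, M = M)
  rlo_bound <- num_rng[1] / den_rng[2]
  rhi_bound <- num_rng[2] / den_rng[1]
  feasible_at <- function(r) {
    s2 <- sys
    s2$A <- rbind(sys$A, nvec - r * dvec)
    s2$rhs <- c(sys$rhs, 0)
    s2$dir <- c(sys$dir, "==")
    s2$primal_row <- c(sys$primal_row, TRUE)
    res <- solve_joint(s2, numeric(length(sys$var_names)), maximize = TRUE,
                       use_heuristic = FALSE)
    res$status == "optimal"
  }
  bisect <- function(lo, hi, want_low) {
    # invariant: feasible somewhere in [lo, hi]; shrink towards the
    # requested end of the feasible r interval
    for (it in 1:40) {
      if (hi - lo < 1e-7) break
      mid <- (lo + hi) / 2
      if (feasible_at(mid)) {
        if (want_low) hi <- mid else lo <- mid
      } else {
        if (want_low) lo <- mid else hi <- mid
      }
    }
    if (want_low) hi else lo
  }
  x0 <- solution_vector(sys, sol)
  r0 <- sum(nvec * ifelse(is.na(x0), 0, x0)) / sum(dvec * ifelse(is.na(x0), 0, x0))
  c(min = bisect(rlo_bound, r0, TRUE), max = bisect(r0, rhi_bound, FALSE))
}

#' Run a batch of community scenarios
#'
#' Independent solves over a list of scenario descriptions, one solution per
#' scenario in input order; a failing scenario (infeasible, unbounded, or
#' erroring) is recorded in place without aborting the batch.
#'
#' Each scenario is a list with optional fields `name`, `mode`
#' (`"predictive"`, default, or `"descriptive"`), `objective`, `constraints`
#' (added to the community), `experimental` (descriptive mode),
#' `medium`, `accumulation` (named bound overrides).
#'
#' @inheritParams solve_predictive
#' @param scenarios list of scenario descriptions.
#' @return named list of `community_solution` objects; failed scenarios are
#'   `community_failure` records with a `status` and `message`.
#' @export
run_scenarios <- function(comm, scenarios, method = c("dual_milp", "bilinear"),
                          M = 1000) {
  method <- match.arg(method)
  out <- lapply(seq_along(scenarios), function(k) {
    sc <- scenarios[[k]]
    tryCatch({
      c2 <- comm
      if (!is.null(sc$medium)) {
        med <- as_flow_bounds(sc$medium, "medium")
        c2$medium[names(med)] <- med
      }
      if (!is.null(sc$accumulation)) {
        acc <- as_flow_bounds(sc$accumulation, "accumulation")
        c2$accumulation[names(acc)] <- acc
      }
      for (cs in sc$constraints %||% list()) c2 <- add_constraint(c2, cs)
      obj <- sc$objective %||% community_objective("total_biomass")
      if (identical(sc$mode %||% "predictive", "descriptive"))
        solve_descriptive(c2, obj, experimental = sc$experimental %||% list(),
                          method = method, M = M)
      else
        solve_predictive(c2, obj, method = method, M = M)
    },
    comfba_infeasible_error = function(e)
      structure(list(status = "infeasible", message = conditionMessage(e)),
                class = "community_failure"),
    comfba_unbounded_error = function(e)
      structure(list(status = "unbounded", message = conditionMessage(e)),
                class = "community_failure"),
    comfba_error = function(e)
      structure(list(status = "error", message = conditionMessage(e)),
                class = "community_failure"))
  })
  names(out) <- vapply(seq_along(scenarios), function(k)
    scenarios[[k]]$name %||% paste0("scenario_", k), character(1))
  out
}

#' @export
print.community_failure <- function(x, ...) {
  cat(sprintf("<community_failure> %s: %s\n", x$status, x$message))
  invisible(x)
}
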