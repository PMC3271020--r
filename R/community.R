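#' Assemble species models into a community
#'
#' Couples per-species metabolic models through a shared metabolite pool.
#' Every shared metabolite `i` gets, for each species `k`, a nonnegative
#' uptake flow `u[k,i]` and export flow `e[k,i]` (mmol/gDW/h) linked to the
#' species' own exchange reactions, plus a community uptake `uc[i]` bounded
#' by the medium and an accumulation slack `ec[i]`. Solutions downstream
#' always satisfy the pool mass balance
#' `sum_k e[k,i] + uc[i] = sum_k u[k,i] + ec[i]`.
#'
#' Uptake and export are kept as separate nonnegative variables (not one
#' signed exchange flux) so that interaction typing and pool balances can
#' restrict flow directions independently; simultaneous nonzero uptake and
#' export of the same metabolite by one species is suppressed by the
#' reported-solution tie-break (secondary minimization of total
#' inter-organism flow), not by integer variables.
#'
#' @param models list of [species_model()] objects.
#' @param medium named numeric vector: shared metabolite id -> maximum
#'   community uptake from the environment (`uc` bound, >= 0). Unlisted
#'   shared metabolites get 0.
#' @param accumulation named numeric vector: shared metabolite id -> allowed
#'   accumulation (`ec` bound, >= 0; 0 forbids accumulation, `Inf` allows
#'   free accumulation). Default: 0 for shared intermediates (metabolites
#'   consumed by at least one member) and `Inf` for terminal by-products
#'   consumed by nobody.
#' @return a `community_model` object.
#' @export
build_community <- function(models, medium = numeric(), accumulation = NULL) {
  if (!length(models)) abort_config("community needs at least one species model")
  if (!all(vapply(models, inherits, logical(1), "species_model")))
    abort_config("all models must be species_model objects")
  ids <- vapply(models, function(m) m$species_id, character(1))
  if (anyDuplicated(ids))
    abort_config(sprintf("duplicated species id '%s'", ids[duplicated(ids)][1]))
  names(models) <- ids

  shared <- sort(unique(unlist(lapply(models, shared_ids))))
  medium <- as_flow_bounds(medium, "medium")
  if (length(setdiff(names(medium), shared)))
    abort_config(sprintf("medium bound for '%s' matches no shared metabolite of any species",
                         setdiff(names(medium), shared)[1]))
  med <- stats::setNames(rep(0, length(shared)), shared)
  med[names(medium)] <- medium

  consumed <- vapply(shared, function(i)
    any(vapply(models, species_touches, logical(1), met = i, side = "consume")),
    logical(1))
  acc_default <- ifelse(consumed, 0, Inf)
  acc <- stats::setNames(acc_default, shared)
  if (!is.null(accumulation)) {
    accumulation <- as_flow_bounds(accumulation, "accumulation")
    if (length(setdiff(names(accumulation), shared)))
      abort_config(sprintf("accumulation bound for '%s' matches no shared metabolite",
                           setdiff(names(accumulation), shared)[1]))
    acc[names(accumulation)] <- accumulation
  }

  comm <- structure(list(species = models,
                         shared_ids = shared,
                         medium = med,
                         accumulation = acc,
                         interaction = interaction_spec("neutral"),
                         constraints = list()),
                    class = "community_model")
  comm
}

as_flow_bounds <- function(x, what) {
  x <- unlist(x)
  if (!length(x)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    abort_config(sprintf("%s bounds must be named by shared metabolite id", what))
  x <- stats::setNames(as.numeric(x), names(x))
  if (any(is.na(x) | x < 0))
    abort_config(sprintf("%s bounds must be >= 0", what))
  x
}

#' @keywords internal
species_touches <- function(m, met, side = c("any", "consume", "produce")) {
  side <- match.arg(side)
  any(vapply(m$reactions, function(r) {
    co <- r$stoich[met]
    if (is.na(co)) return(FALSE)
    switch(side, any = co != 0, consume = co < 0, produce = co > 0)
  }, logical(1)))
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d species (%s); %d shared metabolites: %s\n",
              length(x$species), paste(names(x$species), collapse = ", "),
              length(x$shared_ids), paste(x$shared_ids, collapse = ", ")))
  cat(sprintf("  interaction: %s; %d attached constraints\n",
              x$interaction$kind, length(x$constraints)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Interactions

#' Specify an ecological interaction type
#'
#' Interaction types are encoded by restricting the directionality and
#' coupling of inter-organism flows of the involved shared metabolites:
#' \describe{
#'   \item{neutral}{no restriction.}
#'   \item{commensalism}{the donor's export of the metabolite is free, each
#'     recipient's uptake is capped by the total donor export, and recipient
#'     export of the same metabolite is fixed to zero.}
#'   \item{competition}{no member may produce the contested metabolite into
#'     the pool (exports fixed 0), so all uptakes draw on the single medium
#'     bound.}
#'   \item{mutualism}{two or more metabolites with opposite producer/consumer
#'     roles; per metabolite, non-producers cannot export and non-consumers
#'     cannot take up; `must_consume_all = TRUE` forces total export to equal
#'     total uptake.}
#'   \item{parasitism}{directional flow towards the parasite with back-flow
#'     fixed to zero (producer cannot take the metabolite back up, consumer
#'     cannot export it).}
#'   \item{amensalism}{the affected species is forced to absorb an
#'     inhibitory-cost flux: its uptake of the metabolite is coupled linearly
#'     (coefficient `coupling`) to the producer's export, and a drain
#'     reaction is auto-created in the victim if it cannot consume the
#'     metabolite. The linear coupling is this package's encoding of the
#'     inhibitory effect; no kinetic form is implied.}
#'   \item{custom}{the per-metabolite rules are applied literally.}
#' }
#'
#' @param kind interaction type.
#' @param rules named list (by shared metabolite id), each entry a list with
#'   optional fields `producers`, `consumers` (character vectors of species
#'   ids), `must_consume_all` (logical) and `coupling` (numeric, amensalism
#'   only).
#' @return an `interaction_spec` object.
#' @export
interaction_spec <- function(kind = c("neutral", "mutualism", "commensalism",
                                      "amensalism", "competition", "parasitism",
                                      "custom"),
                             rules = list()) {
  kind <- match.arg(kind)
  if (kind == "mutualism" && length(rules) && length(rules) < 2L)
    abort_config("mutualism needs rules for at least two metabolites")
  structure(list(kind = kind, rules = rules), class = "interaction_spec")
}

#' Apply an interaction specification to a community
#'
#' Re-derives all interaction-induced flow bounds, flow constraints and
#' auto-created drain reactions from scratch, so the operation is idempotent:
#' applying the same spec twice leaves the community unchanged.
#'
#' @param comm a `community_model`.
#' @param spec an [interaction_spec()].
#' @return the updated `community_model`.
#' @export
apply_interaction <- function(comm, spec) {
  stopifnot(inherits(comm, "community_model"), inherits(spec, "interaction_spec"))
  for (mid in names(spec$rules)) {
    if (!mid %in% comm$shared_ids)
      abort_config(sprintf("interaction rule references unknown shared metabolite '%s'", mid))
    rule <- spec$rules[[mid]]
    for (sp in c(rule$producers, rule$consumers))
      if (!sp %in% names(comm$species))
        abort_config(sprintf("interaction rule references unknown species '%s'", sp))
  }
  # drop previously auto-created drains, then re-derive
  comm$species <- lapply(comm$species, function(m) {
    keep <- !grepl("^drain_", reaction_ids(m))
    if (all(keep)) return(m)
    species_model(m$species_id, m$metabolites, m$reactions[keep])
  })
  comm$interaction <- spec
  if (spec$kind == "amensalism") {
    for (mid in names(spec$rules)) {
      rule <- spec$rules[[mid]]
      for (v in rule$consumers) {
        mv <- comm$species[[v]]
        if (!species_touches(mv, mid, "consume")) {
          drain <- reaction(paste0("drain_", mid),
                            stats::setNames(-1, mid), lb = 0, ub = Inf)
          if (!mid %in% vapply(mv$metabolites, function(x) x$id, character(1)))
            mv$metabolites <- c(mv$metabolites, list(metabolite(mid, shared = TRUE)))
          comm$species[[v]] <- species_model(mv$species_id, mv$metabolites,
                                             c(mv$reactions, list(drain)))
        }
      }
    }
  }
  comm
}

#' Interaction-induced flow bounds and constraints (derived, internal)
#'
#' @return list with `u_zero`, `e_zero` (data frames species/metabolite of
#'   flows fixed to zero) and `rows` (linear constraints on flows, each a
#'   list with `terms` = data.frame(species, metabolite, side, coef), `dir`,
#'   `rhs`, `label`).
#' @keywords internal
interaction_effects <- function(comm) {
  spec <- comm$interaction
  u_zero <- e_zero <- data.frame(species = character(), metabolite = character())
  rows <- list()
  zap_u <- function(sp, mid) u_zero <<- rbind(u_zero, data.frame(species = sp, metabolite = mid))
  zap_e <- function(sp, mid) e_zero <<- rbind(e_zero, data.frame(species = sp, metabolite = mid))
  all_sp <- names(comm$species)
  for (mid in names(spec$rules)) {
    rule <- spec$rules[[mid]]
    producers <- rule$producers %||% character(0)
    consumers <- rule$consumers %||% character(0)
    switch(spec$kind,
      neutral = NULL,
      competition = for (sp in all_sp) zap_e(sp, mid),
      commensalism = {
        for (sp in consumers) zap_e(sp, mid)
        for (sp in consumers) {
          terms <- rbind(
            data.frame(species = sp, metabolite = mid, side = "u", coef = 1),
            data.frame(species = producers, metabolite = mid, side = "e", coef = -1))
          rows[[length(rows) + 1L]] <- list(terms = terms, dir = "<=", rhs = 0,
                                            label = sprintf("commensal_%s_%s", mid, sp))
        }
      },
      mutualism = ,
      parasitism = {
        if (length(producers)) for (sp in setdiff(all_sp, producers)) zap_e(sp, mid)
        for (sp in producers) zap_u(sp, mid)
        if (length(consumers)) for (sp in setdiff(all_sp, consumers)) zap_u(sp, mid)
        for (sp in setdiff(all_sp, producers)) if (sp %in% consumers) zap_e(sp, mid)
        if (isTRUE(rule$must_consume_all)) {
          terms <- rbind(
            data.frame(species = producers, metabolite = mid, side = "e", coef = 1),
            data.frame(species = consumers, metabolite = mid, side = "u", coef = -1))
          rows[[length(rows) + 1L]] <- list(terms = terms, dir = "==", rhs = 0,
                                            label = sprintf("consume_all_%s", mid))
        }
      },
      amensalism = {
        alpha <- rule$coupling %||% 1
        for (sp in consumers) zap_e(sp, mid)
        terms <- rbind(
          data.frame(species = consumers, metabolite = mid, side = "u", coef = 1),
          data.frame(species = producers, metabolite = mid, side = "e", coef = -alpha))
        rows[[length(rows) + 1L]] <- list(terms = terms, dir = "==", rhs = 0,
                                          label = sprintf("amensal_%s", mid))
      },
      custom = {
        if (!is.null(rule$producers))
          for (sp in setdiff(all_sp, producers)) zap_e(sp, mid)
        if (!is.null(rule$consumers))
          for (sp in setdiff(all_sp, consumers)) zap_u(sp, mid)
        if (isTRUE(rule$must_consume_all)) {
          terms <- rbind(
            data.frame(species = producers, metabolite = mid, side = "e", coef = 1),
            data.frame(species = consumers, metabolite = mid, side = "u", coef = -1))
          rows[[length(rows) + 1L]] <- list(terms = terms, dir = "==", rhs = 0,
                                            label = sprintf("consume_all_%s", mid))
        }
      })
  }
  list(u_zero = unique(u_zero), e_zero = unique(e_zero), rows = rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Constraints

new_constraint <- function(form, level, fields) {
  structure(c(list(form = form, level = level), fields),
            class = "comfba_constraint")
}

#' Constraint constructors
#'
#' Experimental and structural constraints attach to either the inner problem
#' of one species (fixed fluxes, intra-species flux ratios, bound overrides)
#' or to the outer community problem (biomass ratios, pool-flow fixes).
#'
#' @param species,reaction,value,ratio,lb,ub,metabolite,flow see details.
#' @return a `comfba_constraint` object for [add_constraint()].
#' @name constraints
NULL

#' @rdname constraints
#' @export
fixed_flux <- function(species, reaction, value)
  new_constraint("fixed_flux", "inner",
                 list(species = species, reaction = reaction, value = as.numeric(value)))

#' @rdname constraints
#' @param reaction_num,reaction_den numerator/denominator reaction ids for a
#'   within-species flux ratio `v_num - ratio * v_den = 0`.
#' @export
flux_ratio <- function(species, reaction_num, reaction_den, ratio)
  new_constraint("flux_ratio", "inner",
                 list(species = species, reaction_num = reaction_num,
                      reaction_den = reaction_den, ratio = as.numeric(ratio)))

#' @rdname constraints
#' @param species_num,species_den species whose biomass fluxes form the outer
#'   ratio `bio_num - ratio * bio_den = 0`.
#' @export
biomass_ratio <- function(species_num, species_den, ratio)
  new_constraint("biomass_ratio", "outer",
                 list(species_num = species_num, species_den = species_den,
                      ratio = as.numeric(ratio)))

#' @rdname constraints
#' @export
bound_override <- function(species, reaction, lb = NULL, ub = NULL)
  new_constraint("bound_override", "inner",
                 list(species = species, reaction = reaction,
                      lb = if (is.null(lb)) NULL else as.numeric(lb),
                      ub = if (is.null(ub)) NULL else as.numeric(ub)))

#' @rdname constraints
#' @export
fixed_flow <- function(metabolite, species = NULL,
                       flow = c("uptake", "export", "community_uptake", "accumulation"),
                       value) {
  flow <- match.arg(flow)
  if (flow %in% c("uptake", "export") && is.null(species))
    abort_config("per-species flows need a species id")
  new_constraint("fixed_flow", "outer",
                 list(metabolite = metabolite, species = species, flow = flow,
                      value = as.numeric(value)))
}

#' Attach a constraint to a community
#'
#' Constraints commute: any order of `add_constraint()` calls yields the same
#' feasible set. A ratio that renders the model infeasible is accepted here;
#' infeasibility surfaces at solve time.
#'
#' @param comm a `community_model`.
#' @param spec a constraint from [fixed_flux()], [flux_ratio()],
#'   [biomass_ratio()], [bound_override()] or [fixed_flow()].
#' @return the updated `community_model`.
#' @export
add_constraint <- function(comm, spec) {
  stopifnot(inherits(comm, "community_model"))
  if (!inherits(spec, "comfba_constraint"))
    abort_config("spec must be a comfba_constraint")
  check_rxn <- function(sp, rid) {
    if (!sp %in% names(comm$species))
      abort_config(sprintf("constraint references unknown species '%s'", sp))
    if (!rid %in% reaction_ids(comm$species[[sp]]))
      abort_config(sprintf("constraint references unknown reaction '%s' of species '%s'",
                           rid, sp))
  }
  switch(spec$form,
    fixed_flux = check_rxn(spec$species, spec$reaction),
    flux_ratio = {
      check_rxn(spec$species, spec$reaction_num)
      check_rxn(spec$species, spec$reaction_den)
    },
    biomass_ratio = {
      for (sp in c(spec$species_num, spec$species_den))
        if (!sp %in% names(comm$species))
          abort_config(sprintf("constraint references unknown species '%s'", sp))
    },
    bound_override = check_rxn(spec$species, spec$reaction),
    fixed_flow = {
      if (!spec$metabolite %in% comm$shared_ids)
        abort_config(sprintf("constraint references unknown shared metabolite '%s'",
                             spec$metabolite))
      if (!is.null(spec$species) && !spec$species %in% names(comm$species))
        abort_config(sprintf("constraint references unknown species '%s'", spec$species))
    })
  comm$constraints <- c(comm$constraints, list(spec))
  comm
}

#' @keywords internal
inner_constraints_of <- function(constraints, sp) {
  Filter(function(cs) cs$level == "inner" &&
           cs$form %in% c("fixed_flux", "flux_ratio") && cs$species == sp,
         constraints)
}

#' @keywords internal
apply_bound_overrides <- function(lb, ub, constraints, sp, rids) {
  for (cs in constraints) {
    if (cs$form == "bound_override" && cs$species == sp) {
      j <- match(cs$reaction, rids)
      if (!is.null(cs$lb)) lb[j] <- cs$lb
      if (!is.null(cs$ub)) ub[j] <- cs$ub
    }
  }
  list(lb = lb, ub = ub)
}

# ---------------------------------------------------------------------------
# YAML community configuration

#' Read a community configuration from YAML
#'
#' Schema: `models` (list of model file paths, relative to the config file),
#' optional `medium` and `accumulation` maps (shared metabolite id -> bound;
#' the strings `inf`/`.inf` mean unbounded), optional `interaction` block
#' (`kind` plus `rules`), optional `constraints` list (each entry a map with
#' `type` = one of `fixed_flux`, `flux_ratio`, `biomass_ratio`,
#' `bound_override`, `fixed_flow` plus that constructor's fields).
#'
#' @param path YAML file path.
#' @return a `community_model`.
#' @export
read_community_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config '%s' does not exist", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_format(
                    sprintf("cannot parse '%s' as YAML: %s", path, conditionMessage(e))))
  if (is.null(cfg$models)) abort_config(sprintf("config '%s': no models listed", path))
  base <- dirname(normalizePath(path))
  paths <- vapply(cfg$models, identity, character(1))
  paths <- ifelse(grepl("^/", paths), paths, file.path(base, paths))
  for (p in paths) if (!file.exists(p))
    abort_config(sprintf("model file '%s' does not exist", p))
  models <- lapply(paths, read_species_model)
  to_num <- function(x) {
    if (is.null(x)) return(numeric(0))
    vapply(x, function(v) {
      if (is.character(v) && v %in% c("inf", ".inf", "Inf")) Inf else as.numeric(v)
    }, numeric(1))
  }
  comm <- build_community(models, medium = to_num(cfg$medium),
                          accumulation = if (is.null(cfg$accumulation)) NULL
                                         else to_num(cfg$accumulation))
  if (!is.null(cfg$interaction)) {
    spec <- interaction_spec(cfg$interaction$kind %||% "neutral",
                             rules = cfg$interaction$rules %||% list())
    comm <- apply_interaction(comm, spec)
  }
  for (cs in cfg$constraints %||% list()) {
    type <- cs$type
    if (is.null(type)) abort_config("constraint entry without 'type'")
    spec <- switch(type,
      fixed_flux = fixed_flux(cs$species, cs$reaction, cs$value),
      flux_ratio = flux_ratio(cs$species, cs$reaction_num, cs$reaction_den, cs$ratio),
      biomass_ratio = biomass_ratio(cs$species_num, cs$species_den, cs$ratio),
      bound_override = bound_override(cs$species, cs$reaction, cs$lb, cs$ub),
      fixed_flow = fixed_flow(cs$metabolite, cs$species,
                              cs$flow %||% "uptake", cs$value),
      abort_config(sprintf("unknown constraint type '%s'", type)))
    comm <- add_constraint(comm, spec)
  }
  comm
}
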