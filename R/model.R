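#' Construct a metabolite descriptor
#'
#' @param id unique metabolite identifier (case-sensitive; shared metabolites
#'   carry the same id across the species they connect).
#' @param name free-text name.
#' @param shared logical; `TRUE` marks membership in the community pool,
#'   `FALSE` an internal (cytosolic) metabolite.
#' @return a `comfba_metabolite` list.
#' @export
metabolite <- function(id, name = id, shared = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.logical(shared), length(shared) == 1L)
  structure(list(id = id, name = name, shared = shared),
            class = "comfba_metabolite")
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative for substrates, positive
#' for products. Flux bounds are in mmol/gDW/h; reversible reactions carry a
#' negative lower bound (irreversible splitting, where needed, happens inside
#' the solvers, never in the stored model).
#'
#' @param id unique reaction identifier.
#' @param stoich named numeric vector, metabolite id -> signed coefficient.
#' @param lb,ub flux bounds (mmol/gDW/h).
#' @param biomass logical; `TRUE` for the biomass reaction.
#' @return a `comfba_reaction` list.
#' @export
reaction <- function(id, stoich, lb = 0, ub = Inf, biomass = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    abort_model(sprintf("reaction '%s': stoichiometry must be a non-empty named vector", id))
  if (any(!is.finite(stoich)))
    abort_model(sprintf("reaction '%s': non-finite stoichiometric coefficient", id))
  structure(list(id = id, stoich = stoich, lb = as.numeric(lb),
                 ub = as.numeric(ub), biomass = isTRUE(biomass)),
            class = "comfba_reaction")
}

#' Construct a single-species metabolic model
#'
#' Hard structural invariants are enforced here (unique ids, resolvable
#' stoichiometry keys, exactly one biomass reaction); softer quality issues
#' (dangling metabolites, blocked biomass, bound violations) are reported by
#' [validate_species_model()] instead of erroring.
#'
#' @param species_id species identifier.
#' @param metabolites list of [metabolite()] entries.
#' @param reactions list of [reaction()] entries; exactly one must have
#'   `biomass = TRUE`.
#' @return a `species_model` object.
#' @export
species_model <- function(species_id, metabolites, reactions) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (length(reactions) == 0L)
    abort_model(sprintf("species '%s': empty reaction list", species_id))
  met_ids <- vapply(metabolites, function(m) m$id, character(1))
  if (anyDuplicated(met_ids))
    abort_model(sprintf("species '%s': duplicated metabolite id '%s'",
                        species_id, met_ids[duplicated(met_ids)][1]))
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids))
    abort_model(sprintf("species '%s': duplicated reaction id '%s'",
                        species_id, rxn_ids[duplicated(rxn_ids)][1]))
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), met_ids)
    if (length(unknown))
      abort_model(sprintf("species '%s': reaction '%s' references undeclared metabolite '%s'",
                          species_id, r$id, unknown[1]))
  }
  n_bio <- sum(vapply(reactions, function(r) r$biomass, logical(1)))
  if (n_bio == 0L)
    abort_model(sprintf("species '%s': no biomass reaction declared", species_id))
  if (n_bio > 1L)
    abort_model(sprintf("species '%s': ambiguous biomass (%d reactions flagged)",
                        species_id, n_bio))
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  structure(list(species_id = species_id,
                 metabolites = metabolites,
                 reactions = reactions,
                 biomass_id = rxn_ids[vapply(reactions, function(r) r$biomass, logical(1))]),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf("<species_model> %s: %d metabolites (%d shared), %d reactions, biomass '%s'\n",
              x$species_id, length(x$metabolites), length(shared_ids(x)),
              length(x$reactions), x$biomass_id))
  invisible(x)
}

#' @keywords internal
shared_ids <- function(m) {
  ids <- vapply(m$metabolites, function(x) x$id, character(1))
  unname(ids[vapply(m$metabolites, function(x) isTRUE(x$shared), logical(1))])
}

#' @keywords internal
internal_ids <- function(m) {
  ids <- vapply(m$metabolites, function(x) x$id, character(1))
  unname(ids[!vapply(m$metabolites, function(x) isTRUE(x$shared), logical(1))])
}

#' @keywords internal
reaction_ids <- function(m) unname(vapply(m$reactions, function(r) r$id, character(1)))

#' @keywords internal
reaction_bounds <- function(m) {
  list(lb = unname(vapply(m$reactions, function(r) r$lb, numeric(1))),
       ub = unname(vapply(m$reactions, function(r) r$ub, numeric(1))))
}

#' Stoichiometric matrix of a species model
#'
#' @param m a `species_model`.
#' @param rows which metabolites to include: all, internal only, or shared only.
#' @return dense numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(m, rows = c("all", "internal", "shared")) {
  rows <- match.arg(rows)
  met_ids <- switch(rows,
                    all = unname(vapply(m$metabolites, function(x) x$id,
                                        character(1))),
                    internal = internal_ids(m),
                    shared = shared_ids(m))
  S <- matrix(0, length(met_ids), length(m$reactions),
              dimnames = list(met_ids, reaction_ids(m)))
  for (r in m$reactions) {
    keep <- intersect(names(r$stoich), met_ids)
    if (length(keep)) S[keep, r$id] <- r$stoich[keep]
  }
  S
}

#' Is a reaction an exchange reaction?
#'
#' Exchange reactions are those touching at least one shared-pool metabolite;
#' they carry the species' uptake/export traffic with the community pool.
#' @keywords internal
is_exchange_reaction <- function(m, rid) {
  any(names(m$reactions[[rid]]$stoich) %in% shared_ids(m))
}

#' Validate a species model
#'
#' Report-only quality control: lists dangling metabolites (appearing in no
#' reaction), bound violations (`lb > ub`), and blocked biomass (the biomass
#' reaction cannot carry flux even with all exchange opened to its bounds,
#' established by a single LP solve).
#'
#' @param m a `species_model`.
#' @return a tibble of class `comfba_validation` with columns `check`,
#'   `element`, `message`; zero rows means no issues.
#' @export
validate_species_model <- function(m) {
  issues <- list()
  push <- function(check, element, message)
    issues[[length(issues) + 1L]] <<- tibble::tibble(check = check,
                                                     element = element,
                                                     message = message)
  used <- unique(unlist(lapply(m$reactions, function(r) names(r$stoich))))
  for (mid in setdiff(vapply(m$metabolites, function(x) x$id, character(1)), used))
    push("dangling_metabolite", mid, "metabolite appears in no reaction")
  bb <- reaction_bounds(m)
  for (i in which(bb$lb > bb$ub))
    push("bound_violation", reaction_ids(m)[i],
         sprintf("lb (%g) > ub (%g)", bb$lb[i], bb$ub[i]))
  if (!any(bb$lb > bb$ub)) {
    # unbounded growth counts as not blocked here; it is a bounds problem,
    # not a connectivity problem
    fv <- tryCatch(solve_fba(m), comfba_unbounded_error = function(e) NULL)
    if (!is.null(fv) && (fv$status != "optimal" || fv$objective <= 1e-9))
      push("blocked_biomass", m$biomass_id,
           "biomass cannot carry flux with exchange open to bounds")
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    tibble::tibble(check = character(), element = character(), message = character())
  class(out) <- c("comfba_validation", class(out))
  out
}

# ---------------------------------------------------------------------------
# JSON dialect

#' Read a species model
#'
#' Reads a single-species metabolic model from the package's JSON dialect or
#' from an SBML Level 3 file with the `fbc` extension (read-only; bounds via
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters, biomass via the
#' active `fbc:objective`). In the JSON dialect community-pool membership is
#' the explicit `"shared"` flag; in SBML it is inferred from a designated
#' boundary compartment.
#'
#' @param path file path.
#' @param dialect `"json"` or `"sbml"`; defaults from the file extension.
#' @param shared_compartment SBML compartment id whose species form the
#'   shared pool.
#' @return a validated [species_model()].
#' @export
read_species_model <- function(path, dialect = c("auto", "json", "sbml"),
                               shared_compartment = "shared") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format(sprintf("model file '%s' does not exist", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (dialect == "json") read_model_json(path) else
    read_model_sbml(path, shared_compartment)
}

read_model_json <- function(path) {
  dat <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_format(
                    sprintf("cannot parse '%s' as JSON: %s", path, conditionMessage(e))))
  for (field in c("species_id", "metabolites", "reactions"))
    if (is.null(dat[[field]]))
      abort_format(sprintf("model '%s': missing field '%s'", path, field))
  mets <- lapply(dat$metabolites, function(m) {
    if (is.null(m$id)) abort_format(sprintf("model '%s': metabolite without id", path))
    metabolite(m$id, if (is.null(m$name)) m$id else m$name, isTRUE(m$shared))
  })
  rxns <- lapply(dat$reactions, function(r) {
    if (is.null(r$id)) abort_format(sprintf("model '%s': reaction without id", path))
    st <- unlist(r$stoich)
    if (is.null(st)) abort_format(sprintf("model '%s': reaction '%s' without stoich",
                                          path, r$id))
    reaction(r$id, st,
             lb = parse_bound(r$lb, 0), ub = parse_bound(r$ub, Inf),
             biomass = isTRUE(r$biomass))
  })
  species_model(dat$species_id, mets, rxns)
}

parse_bound <- function(x, default) {
  if (is.null(x)) return(default)
  if (is.character(x)) {
    if (x %in% c("inf", "Inf", "+inf")) return(Inf)
    if (x %in% c("-inf", "-Inf")) return(-Inf)
    return(as.numeric(x))
  }
  as.numeric(x)
}

#' Write a species model in the JSON dialect
#'
#' The JSON dialect is the canonical on-disk format; `read_species_model()`
#' round-trips it field-by-field.
#'
#' @param m a `species_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_model <- function(m, path) {
  dat <- list(
    species_id = m$species_id,
    metabolites = lapply(unname(m$metabolites), function(x)
      list(id = x$id, name = x$name, shared = x$shared)),
    reactions = lapply(unname(m$reactions), function(r)
      list(id = r$id, stoich = as.list(r$stoich),
           lb = unbox_bound(r$lb), ub = unbox_bound(r$ub), biomass = r$biomass)))
  jsonlite::write_json(dat, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

unbox_bound <- function(x) {
  if (is.infinite(x)) (if (x > 0) "inf" else "-inf") else x
}

# ---------------------------------------------------------------------------
# SBML (read-only)

read_model_sbml <- function(path, shared_compartment = "shared") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort_format(
                    sprintf("cannot parse '%s' as XML: %s", path, conditionMessage(e))))
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing"))
    abort_format(sprintf("'%s': no <model> element", path))
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  sp_nodes <- xml2::xml_find_all(model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp_nodes)) abort_format(sprintf("'%s': no species declared", path))
  mets <- lapply(sp_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    comp <- xml2::xml_attr(nd, "compartment")
    bc <- identical(xml2::xml_attr(nd, "boundaryCondition"), "true")
    if (is.na(id)) abort_format(sprintf("'%s': species without id", path))
    nm <- xml2::xml_attr(nd, "name")
    metabolite(id, if (is.na(nm)) id else nm,
               shared = identical(comp, shared_compartment) || bc)
  })

  params <- xml2::xml_find_all(model, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  obj_refs <- xml2::xml_find_all(model, ".//*[local-name()='fluxObjective']")
  obj_rxns <- unique(xml2::xml_attr(obj_refs, "reaction"))
  if (length(obj_rxns) == 0L)
    abort_model(sprintf("'%s': no fbc objective (biomass) declared", path))
  if (length(obj_rxns) > 1L)
    abort_model(sprintf("'%s': ambiguous biomass, %d reactions flagged as fbc objective",
                        path, length(obj_rxns)))

  rx_nodes <- xml2::xml_find_all(model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx_nodes)) abort_model(sprintf("'%s': empty reaction list", path))
  rxns <- lapply(rx_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    if (is.na(id)) abort_format(sprintf("'%s': reaction without id", path))
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(
        nd, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (!length(refs)) return(numeric(0))
      st <- xml2::xml_attr(refs, "stoichiometry")
      st[is.na(st)] <- "1"
      stats::setNames(sign * as.numeric(st), xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", 1))
    # merge duplicated species across sides
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    lb_ref <- xml2::xml_attr(nd, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(nd, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else Inf
    rev <- identical(xml2::xml_attr(nd, "reversible"), "true")
    if (is.na(lb_ref) && rev) lb <- -Inf
    reaction(id, st, lb = lb, ub = ub, biomass = id %in% obj_rxns)
  })
  species_model(model_id, mets, rxns)
}
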