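#' Community-level (outer) objective
#'
#' The outer problem optimizes a community-level criterion over the
#' inter-organism flow configuration:
#' \describe{
#'   \item{total_biomass}{sum of all species' biomass fluxes.}
#'   \item{weighted_biomass}{weighted sum; unspecified weights default to 1.}
#'   \item{single_species}{one member's biomass flux.}
#'   \item{target_flux}{an arbitrary flux or pool-flow target from
#'     [flux_target()] or [flow_target()].}
#' }
#'
#' @param kind objective kind.
#' @param weights named numeric (species id -> weight >= 0, at least one
#'   positive) for `weighted_biomass`.
#' @param species species id for `single_species`.
#' @param target a target object for `target_flux`.
#' @return a `community_objective` object.
#' @export
community_objective <- function(kind = c("total_biomass", "weighted_biomass",
                                         "single_species", "target_flux"),
                                weights = NULL, species = NULL, target = NULL) {
  kind <- match.arg(kind)
  if (kind == "weighted_biomass") {
    if (!is.null(weights)) {
      if (any(weights < 0) || !any(weights > 0))
        abort_config("weights must be >= 0 with at least one positive")
    }
  }
  if (kind == "single_species" && is.null(species))
    abort_config("single_species objective needs a species id")
  if (kind == "target_flux" && is.null(target))
    abort_config("target_flux objective needs a target")
  structure(list(kind = kind, weights = weights, species = species,
                 target = target),
            class = "community_objective")
}

#' Flux and flow targets
#'
#' Targets name a quantity of a community solution: a reaction flux of one
#' species, a pool flow (per-species uptake/export, community uptake from the
#' medium, or accumulation), or a ratio of two such quantities (supported in
#' [community_fva()] via bisection).
#'
#' @param species,reaction,metabolite,flow,num,den see details.
#' @name targets
NULL

#' @rdname targets
#' @export
flux_target <- function(species, reaction)
  structure(list(kind = "flux", species = species, reaction = reaction),
            class = "comfba_target")

#' @rdname targets
#' @export
flow_target <- function(metabolite,
                        flow = c("uptake", "export", "community_uptake", "accumulation"),
                        species = NULL) {
  flow <- match.arg(flow)
  if (flow %in% c("uptake", "export") && is.null(species))
    abort_config("per-species flow targets need a species id")
  structure(list(kind = "flow", metabolite = metabolite, flow = flow,
                 species = species),
            class = "comfba_target")
}

#' @rdname targets
#' @export
ratio_target <- function(num, den) {
  stopifnot(inherits(num, "comfba_target"), inherits(den, "comfba_target"))
  structure(list(kind = "ratio", num = num, den = den), class = "comfba_target")
}
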