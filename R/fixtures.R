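#' Deterministic toy communities with known or oracle-computable optima
#'
#' Desk-scale stand-ins for published genome-scale case studies, built from
#' small-integer stoichiometries so every optimum can be verified by hand or
#' by exhaustive enumeration:
#' \describe{
#'   \item{obligate_syntrophy}{(F1) a fermenter A degrades substrate `Sx`
#'     (`tS: Sx -> Sa`, ub `s_bound`; `rA: Sa -> 2 Ba + Ha`), must vent the
#'     reduced carrier `Ha` to the pool (`tH: Ha -> Hx`), can dump precursor
#'     as by-product (`tB: Ba -> Bx`) and grows by `bioA: 2 Ba ->`. A
#'     scavenger B lives on the carrier (`tHup: Hx -> Hb`; `rB: Hb -> Mb`;
#'     `bioB: Mb ->`). Medium supplies `Sx` at `s_bound`; carrier
#'     accumulation is forbidden, by-product accumulation free. The coupling
#'     mirrors interspecies hydrogen transfer: neither member grows without
#'     the other taking/making the carrier. Known predictive total-biomass
#'     optimum: `2 * s_bound`.}
#'   \item{competition}{(F2) two members compete for `Sx` (medium
#'     `s_bound`); species 1 yields 1 biomass per substrate, species 2 only
#'     0.5. Known optimum `s_bound`, allocated entirely to the efficient
#'     competitor.}
#'   \item{commensal_chain}{A's by-product feeds B, B's feeds C; by-products
#'     may accumulate, so upstream members are unaffected by downstream
#'     consumption. Optimum left to the oracle.}
#'   \item{random}{seeded 2-3 member cross-feeding chains with integer
#'     stoichiometric coefficients, always containing at least one cross-fed
#'     metabolite; guaranteed feasible at zero flux, biomass path guaranteed
#'     producible.}
#' }
#'
#' @param topology fixture name.
#' @param params list; `s_bound` (substrate medium bound and transporter ub,
#'   default 10) for the deterministic fixtures.
#' @param seed integer seed (`random` topology only).
#' @return list with `community` (a `community_model`) and `known_optimum`
#'   (numeric or `NULL` when only the oracle knows).
#' @export
make_fixture <- function(topology = c("obligate_syntrophy", "competition",
                                      "commensal_chain", "random"),
                         params = list(), seed = NULL) {
  if (is.character(topology) &&
      !topology[1] %in% c("obligate_syntrophy", "competition",
                          "commensal_chain", "random"))
    abort_config(sprintf("unknown fixture topology '%s'", topology[1]))
  topology <- match.arg(topology)
  s <- params$s_bound %||% 10
  switch(topology,
    obligate_syntrophy = fixture_syntrophy(s),
    competition = fixture_competition(s),
    commensal_chain = fixture_chain(s),
    random = fixture_random(seed %||% 1L, params))
}

fixture_syntrophy <- function(s = 10) {
  A <- species_model("A",
    list(metabolite("Sx", shared = TRUE), metabolite("Sa"), metabolite("Ba"),
         metabolite("Ha"), metabolite("Hx", shared = TRUE),
         metabolite("Bq"), metabolite("Bx", shared = TRUE)),
    list(reaction("tS", c(Sx = -1, Sa = 1), ub = s),
         reaction("rA", c(Sa = -1, Ba = 2, Ha = 1)),
         reaction("tH", c(Ha = -1, Hx = 1)),
         reaction("tB", c(Bq = -1, Bx = 1)),
         reaction("bioA", c(Ba = -2, Bq = 2), biomass = TRUE)))
  B <- species_model("B",
    list(metabolite("Hx", shared = TRUE), metabolite("Hb"), metabolite("Mb")),
    list(reaction("tHup", c(Hx = -1, Hb = 1)),
         reaction("rB", c(Hb = -1, Mb = 1)),
         reaction("bioB", c(Mb = -1), biomass = TRUE)))
  comm <- build_community(list(A, B), medium = c(Sx = s),
                          accumulation = c(Hx = 0, Bx = Inf))
  list(community = comm, known_optimum = 2 * s)
}

fixture_competition <- function(s = 10) {
  sp1 <- species_model("sp1",
    list(metabolite("Sx", shared = TRUE), metabolite("C1")),
    list(reaction("t1", c(Sx = -1, C1 = 1), ub = s),
         reaction("bio1", c(C1 = -1), biomass = TRUE)))
  sp2 <- species_model("sp2",
    list(metabolite("Sx", shared = TRUE), metabolite("C2")),
    list(reaction("t2", c(Sx = -1, C2 = 1), ub = s),
         reaction("bio2", c(C2 = -2), biomass = TRUE)))
  comm <- build_community(list(sp1, sp2), medium = c(Sx = s))
  comm <- apply_interaction(comm, interaction_spec("competition",
    rules = list(Sx = list(consumers = c("sp1", "sp2")))))
  list(community = comm, known_optimum = s)
}

fixture_chain <- function(s = 10) {
  A <- species_model("A",
    list(metabolite("Sx", shared = TRUE), metabolite("Sa"), metabolite("Ba"),
         metabolite("Pa"), metabolite("Px", shared = TRUE)),
    list(reaction("tS", c(Sx = -1, Sa = 1), ub = s),
         reaction("rA", c(Sa = -1, Ba = 2, Pa = 1)),
         reaction("tP", c(Pa = -1, Px = 1)),
         reaction("bioA", c(Ba = -2), biomass = TRUE)))
  B <- species_model("B",
    list(metabolite("Px", shared = TRUE), metabolite("Pb"), metabolite("Mb"),
         metabolite("Qb"), metabolite("Qx", shared = TRUE)),
    list(reaction("tPup", c(Px = -1, Pb = 1)),
         reaction("rB", c(Pb = -1, Mb = 1, Qb = 1)),
         reaction("tQ", c(Qb = -1, Qx = 1)),
         reaction("bioB", c(Mb = -1), biomass = TRUE)))
  C <- species_model("C",
    list(metabolite("Qx", shared = TRUE), metabolite("Qc"), metabolite("Mc")),
    list(reaction("tQup", c(Qx = -1, Qc = 1)),
         reaction("rC", c(Qc = -1, Mc = 1)),
         reaction("bioC", c(Mc = -1), biomass = TRUE)))
  comm <- build_community(list(A, B, C), medium = c(Sx = s),
                          accumulation = c(Px = Inf, Qx = Inf))
  comm <- apply_interaction(comm, interaction_spec("commensalism",
    rules = list(Px = list(producers = "A", consumers = "B"),
                 Qx = list(producers = "B", consumers = "C"))))
  list(community = comm, known_optimum = NULL)
}

fixture_random <- function(seed, params = list()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  n_sp <- params$n_species %||% sample(2:3, 1)
  # three-member chains get smaller media and unit by-product yields to keep
  # the verification grid of the enumeration oracle desk-sized
  m0 <- params$medium %||% if (n_sp == 3L) sample(2:3, 1) else sample(2:5, 1)
  # species 1: substrate -> a biomass-precursor units + b cross-fed units
  a1 <- sample(1:2, 1)
  b1 <- if (n_sp == 3L) 1L else sample(1:2, 1)
  c1 <- sample(1:2, 1)
  sp1 <- species_model("sp1",
    list(metabolite("Sx", shared = TRUE), metabolite("I1"), metabolite("P1"),
         metabolite("W1"), metabolite("Wx", shared = TRUE)),
    list(reaction("t1", c(Sx = -1, I1 = 1), ub = m0),
         reaction("r1", c(I1 = -1, P1 = a1, W1 = b1)),
         reaction("x1", c(W1 = -1, Wx = 1)),
         reaction("bio1", stats::setNames(-c1, "P1"), biomass = TRUE)))
  a2 <- sample(1:2, 1); c2 <- sample(1:2, 1)
  mets2 <- list(metabolite("Wx", shared = TRUE), metabolite("I2"),
                metabolite("P2"))
  rxns2 <- list(reaction("t2", c(Wx = -1, I2 = 1)),
                reaction("r2", c(I2 = -1, P2 = a2)),
                reaction("bio2", stats::setNames(-c2, "P2"), biomass = TRUE))
  third <- n_sp == 3L
  if (third) {
    b2 <- 1L
    mets2 <- c(mets2, list(metabolite("V2"), metabolite("Vx", shared = TRUE)))
    rxns2[[2]] <- reaction("r2", c(I2 = -1, P2 = a2, V2 = b2))
    rxns2 <- c(rxns2, list(reaction("x2", c(V2 = -1, Vx = 1))))
  }
  sp2 <- species_model("sp2", mets2, rxns2)
  models <- list(sp1, sp2)
  acc <- c(Wx = sample(c(0, Inf), 1))
  if (third) {
    a3 <- sample(1:2, 1)
    sp3 <- species_model("sp3",
      list(metabolite("Vx", shared = TRUE), metabolite("I3"), metabolite("P3")),
      list(reaction("t3", c(Vx = -1, I3 = 1)),
           reaction("r3", c(I3 = -1, P3 = 1)),
           reaction("bio3", stats::setNames(-a3, "P3"), biomass = TRUE)))
    models <- c(models, list(sp3))
    acc <- c(acc, Vx = sample(c(0, Inf), 1))
  }
  comm <- build_community(models, medium = c(Sx = m0), accumulation = acc)
  list(community = comm, known_optimum = NULL)
}

#' Emit a fixture as files usable by the command-line front end
#'
#' Writes the species models (JSON dialect), a community YAML and a ready
#' `run.yaml` into a directory.
#'
#' @param topology fixture name, as in [make_fixture()].
#' @param dir output directory (created if missing).
#' @param seed seed for the `random` topology.
#' @param params fixture parameters.
#' @return path of the run config, invisibly.
#' @export
emit_fixture <- function(topology, dir, seed = NULL, params = list()) {
  fx <- make_fixture(topology, params = params, seed = seed)
  comm <- fx$community
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model_files <- character(0)
  for (sp in names(comm$species)) {
    f <- file.path(dir, paste0(sp, ".json"))
    write_species_model(comm$species[[sp]], f)
    model_files <- c(model_files, basename(f))
  }
  bound_chr <- function(x) ifelse(is.finite(x), x, "inf")
  cfg <- list(models = as.list(model_files),
              medium = as.list(bound_chr(comm$medium)),
              accumulation = as.list(bound_chr(comm$accumulation)))
  if (comm$interaction$kind != "neutral")
    cfg$interaction <- list(kind = comm$interaction$kind,
                            rules = comm$interaction$rules)
  yaml::write_yaml(cfg, file.path(dir, "community.yaml"))
  run <- list(community = "community.yaml",
              mode = "predictive",
              objective = list(kind = "total_biomass"),
              method = "dual_milp",
              output = ".")
  yaml::write_yaml(run, file.path(dir, "run.yaml"))
  invisible(file.path(dir, "run.yaml"))
}
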