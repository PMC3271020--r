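# community_solution: the result container shared by predictive and
# descriptive solves, with round-trippable TSV/JSON serialization.

build_solution <- function(sys, x, objective, mode, method, outer_value,
                           v_max = NULL) {
  comm <- sys$comm
  shared <- comm$shared_ids
  spn <- names(comm$species)
  species <- lapply(spn, function(sp) {
    m <- comm$species[[sp]]
    vals <- x[sys$vix$v[[sp]]]
    names(vals) <- reaction_ids(m)
    new_flux_vector(sp, vals, vals[[m$biomass_id]], "optimal")
  })
  names(species) <- spn
  u <- matrix(0, length(spn), length(shared), dimnames = list(spn, shared))
  e <- u
  for (sp in spn) {
    u[sp, ] <- pmax(0, x[sys$vix$u[[sp]]])
    e[sp, ] <- pmax(0, x[sys$vix$e[[sp]]])
  }
  uc <- stats::setNames(pmax(0, x[sys$vix$uc]), shared)
  ec <- stats::setNames(pmax(0, x[sys$vix$ec]), shared)
  bio <- vapply(spn, function(sp) species[[sp]]$objective, numeric(1))
  if (is.null(v_max)) v_max <- bio
  cvec <- ifelse(abs(v_max) > 1e-12, bio / v_max, NaN)
  if (mode == "predictive") cvec <- stats::setNames(rep(1, length(spn)), spn)
  super <- (is.finite(cvec) & cvec > 1 + 1e-9) |
    (!is.finite(cvec) & abs(v_max) <= 1e-12 & bio > 1e-9)
  biomass_ids <- vapply(spn, function(sp) comm$species[[sp]]$biomass_id,
                        character(1))
  sol <- structure(list(species = species, u = u, e = e, uc = uc, ec = ec,
                        biomass_ids = biomass_ids,
                        outer_objective_value = outer_value,
                        c = stats::setNames(as.numeric(cvec), spn),
                        super_optimal = stats::setNames(super, spn),
                        v_max = stats::setNames(as.numeric(v_max), spn),
                        inner_gaps = NULL,
                        status = "optimal", mode = mode, method = method,
                        objective = objective),
                   class = "community_solution")
  sol$pool_residual <- max(abs(pool_residuals(sol)))
  sol$inner_gaps <- certify(sol, comm)
  sol
}

#' Pool mass-balance residuals of a solution
#'
#' `sum_k e[k,i] + uc[i] - sum_k u[k,i] - ec[i]` per shared metabolite;
#' conservation requires every entry to vanish (|residual| <= 1e-9 in all
#' returned solutions).
#'
#' @param sol a `community_solution`.
#' @return named numeric vector by shared metabolite.
#' @export
pool_residuals <- function(sol) {
  colSums(sol$e) + sol$uc - colSums(sol$u) - sol$ec
}

# map a community_solution back onto a joint-system variable vector
# (primal entries only; dual entries NA)
solution_vector <- function(sys, sol) {
  x <- rep(NA_real_, length(sys$var_names))
  for (sp in names(sys$comm$species)) {
    x[sys$vix$v[[sp]]] <- sol$species[[sp]]$values
    x[sys$vix$u[[sp]]] <- sol$u[sp, ]
    x[sys$vix$e[[sp]]] <- sol$e[sp, ]
  }
  x[sys$vix$uc] <- sol$uc
  x[sys$vix$ec] <- sol$ec
  x
}

#' @export
print.community_solution <- function(x, ...) {
  cat(sprintf("<community_solution> %s/%s: status %s, outer objective %.6g\n",
              x$mode, x$method, x$status, x$outer_objective_value))
  for (sp in names(x$species)) {
    cat(sprintf("  %s: biomass %.6g, c = %.4g%s, gap %.2e\n", sp,
                x$species[[sp]]$objective,
                if (isTRUE(x$super_optimal[[sp]])) " (super-optimal)" else "",
                x$inner_gaps[[sp]]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# serialization

fmt_num <- function(x) {
  ifelse(is.finite(x), sprintf("%.17g", x), as.character(x))
}

#' Write a community solution
#'
#' TSV: preamble lines starting `#` carry status, mode, outer objective and
#' the per-species optimality levels `c`, community-specific maxima and
#' certification gaps; then one row per (species, reaction) with the flux,
#' plus rows for the pool flows (`u[...]`, `e[...]` per species and
#' `uc[...]`, `ec[...]` under the pseudo-species `community`). JSON: the full
#' nested structure. Both round-trip through [read_solution()] with all
#' numerics preserved to 1e-12.
#'
#' @param sol a `community_solution` (or a failure record from
#'   [run_scenarios()], which serializes as its status with no flux rows).
#' @param path output file.
#' @param fmt `"tsv"` or `"json"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, path, fmt = c("auto", "tsv", "json")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort_comfba("comfba_io_error",
                    sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  if (fmt == "json") {
    jsonlite::write_json(solution_to_list(sol), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "string")
    return(invisible(path))
  }
  wl <- function(...) writeLines(paste(..., sep = "\t"), con)
  if (!inherits(sol, "community_solution")) {
    wl("# status", sol$status)
    wl("# message", sol$message %||% "")
    return(invisible(path))
  }
  wl("# status", sol$status)
  wl("# mode", sol$mode)
  wl("# method", sol$method)
  wl("# outer_objective", fmt_num(sol$outer_objective_value))
  for (sp in names(sol$species)) {
    wl("# c", sp, fmt_num(sol$c[[sp]]))
    wl("# v_max", sp, fmt_num(sol$v_max[[sp]]))
    wl("# gap", sp, fmt_num(sol$inner_gaps[[sp]]))
  }
  wl("species", "reaction", "flux")
  for (sp in names(sol$species)) {
    fv <- sol$species[[sp]]
    for (rid in names(fv$values)) wl(sp, rid, fmt_num(fv$values[[rid]]))
    for (mid in colnames(sol$u)) {
      wl(sp, paste0("u[", mid, "]"), fmt_num(sol$u[sp, mid]))
      wl(sp, paste0("e[", mid, "]"), fmt_num(sol$e[sp, mid]))
    }
  }
  for (mid in names(sol$uc)) {
    wl("community", paste0("uc[", mid, "]"), fmt_num(sol$uc[[mid]]))
    wl("community", paste0("ec[", mid, "]"), fmt_num(sol$ec[[mid]]))
  }
  invisible(path)
}

solution_to_list <- function(sol) {
  if (!inherits(sol, "community_solution"))
    return(list(status = sol$status, message = sol$message %||% ""))
  list(status = sol$status, mode = sol$mode, method = sol$method,
       outer_objective = sol$outer_objective_value,
       species = lapply(sol$species, function(fv)
         list(species_id = fv$species_id, objective = fv$objective,
              fluxes = as.list(fv$values))),
       c = as.list(sol$c),
       super_optimal = as.list(sol$super_optimal),
       v_max = as.list(sol$v_max),
       gaps = as.list(sol$inner_gaps),
       u = mat_to_list(sol$u), e = mat_to_list(sol$e),
       uc = as.list(sol$uc), ec = as.list(sol$ec))
}

mat_to_list <- function(m) {
  out <- lapply(rownames(m), function(r) as.list(m[r, , drop = TRUE]))
  names(out) <- rownames(m)
  lapply(out, function(row) stats::setNames(as.list(unlist(row)), colnames(m)))
}

#' Read a community solution written by [write_solution()]
#'
#' @param path solution file.
#' @param fmt `"tsv"` or `"json"` (default from extension).
#' @return a `community_solution` (or a minimal status record for files
#'   written from a failed scenario).
#' @export
read_solution <- function(path, fmt = c("auto", "tsv", "json")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort_format(sprintf("'%s' does not exist", path))
  if (fmt == "auto")
    fmt <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (fmt == "json") return(solution_from_list(jsonlite::fromJSON(
    path, simplifyVector = FALSE)))
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("# ", key, "\t"))]
    lapply(strsplit(hit, "\t", fixed = TRUE), function(p) p[-1])
  }
  status <- get_meta("status")[[1]][1]
  if (status != "optimal")
    return(structure(list(status = status,
                          message = (get_meta("message")[[1]] %||% "")[1]),
                     class = "community_failure"))
  num <- function(s) as.numeric(s)
  per_sp <- function(key) {
    ps <- get_meta(key)
    stats::setNames(vapply(ps, function(p) num(p[2]), numeric(1)),
                    vapply(ps, function(p) p[1], character(1)))
  }
  cvec <- per_sp("c"); vmax <- per_sp("v_max"); gaps <- per_sp("gap")
  body <- body[nzchar(body)]
  stopifnot(identical(body[1], "species\treaction\tflux"))
  recs <- do.call(rbind, strsplit(body[-1], "\t", fixed = TRUE))
  df <- data.frame(species = recs[, 1], reaction = recs[, 2],
                   flux = as.numeric(recs[, 3]), stringsAsFactors = FALSE)
  spn <- setdiff(unique(df$species), "community")
  is_flow <- grepl("^(u|e|uc|ec)\\[.*\\]$", df$reaction)
  shared <- unique(sub("^.*\\[(.*)\\]$", "\\1", df$reaction[is_flow]))
  u <- matrix(0, length(spn), length(shared), dimnames = list(spn, shared))
  e <- u
  uc <- ec <- stats::setNames(rep(0, length(shared)), shared)
  species <- list()
  for (sp in spn) {
    sub <- df[df$species == sp, ]
    fl <- sub[!grepl("\\[", sub$reaction), ]
    vals <- stats::setNames(fl$flux, fl$reaction)
    species[[sp]] <- new_flux_vector(sp, vals, NA_real_, "optimal")
    for (mid in shared) {
      u[sp, mid] <- sub$flux[sub$reaction == paste0("u[", mid, "]")]
      e[sp, mid] <- sub$flux[sub$reaction == paste0("e[", mid, "]")]
    }
  }
  cm <- df[df$species == "community", ]
  for (mid in shared) {
    uc[mid] <- cm$flux[cm$reaction == paste0("uc[", mid, "]")]
    ec[mid] <- cm$flux[cm$reaction == paste0("ec[", mid, "]")]
  }
  structure(list(species = species, u = u, e = e, uc = uc, ec = ec,
                 outer_objective_value = num(get_meta("outer_objective")[[1]][1]),
                 c = cvec, super_optimal = stats::setNames(
                   is.finite(cvec) & cvec > 1 + 1e-9, names(cvec)),
                 v_max = vmax, inner_gaps = gaps, status = status,
                 mode = get_meta("mode")[[1]][1],
                 method = get_meta("method")[[1]][1], objective = NULL),
            class = "community_solution")
}

solution_from_list <- function(dat) {
  if (!identical(dat$status, "optimal"))
    return(structure(list(status = dat$status, message = dat$message %||% ""),
                     class = "community_failure"))
  spn <- names(dat$species)
  shared <- names(dat$uc)
  num1 <- function(x) vapply(x, function(v)
    if (is.character(v)) as.numeric(v) else as.numeric(v %||% NA), numeric(1))
  species <- lapply(spn, function(sp) {
    s <- dat$species[[sp]]
    new_flux_vector(s$species_id, num1(s$fluxes), as.numeric(s$objective), "optimal")
  })
  names(species) <- spn
  u <- do.call(rbind, lapply(spn, function(sp) num1(dat$u[[sp]])))
  e <- do.call(rbind, lapply(spn, function(sp) num1(dat$e[[sp]])))
  dimnames(u) <- dimnames(e) <- list(spn, shared)
  structure(list(species = species, u = u, e = e,
                 uc = num1(dat$uc), ec = num1(dat$ec),
                 outer_objective_value = as.numeric(dat$outer_objective),
                 c = num1(dat$c),
                 super_optimal = stats::setNames(
                   vapply(dat$super_optimal, isTRUE, logical(1)), spn),
                 v_max = num1(dat$v_max), inner_gaps = num1(dat$gaps),
                 status = dat$status, mode = dat$mode, method = dat$method,
                 objective = NULL),
            class = "community_solution")
}
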