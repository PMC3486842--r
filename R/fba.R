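# Minimal flux-balance-analysis engine: stoichiometric models, media,
# biomass maximization, growth labeling and yield measurement.

#' Construct a metabolic model
#'
#' @param reactions list of reactions; each a list with `id`, `stoich`
#'   (named numeric vector, metabolite -> signed coefficient; negative
#'   consumes, positive produces), `lb`, `ub`.  Reversible reactions are
#'   encoded by a negative lower bound, never by splitting.
#' @param biomass_reaction_id id of the biomass (objective) reaction.
#' @param exchange_reactions named character vector mapping nutrient id ->
#'   reaction id of its uptake exchange.  Each exchange reaction must touch
#'   exactly one metabolite (the imported species).
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, biomass_reaction_id,
                            exchange_reactions = character(0)) {
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_catapot("duplicate reaction ids")
  if (!biomass_reaction_id %in% ids) {
    stop_catapot("biomass reaction ", biomass_reaction_id, " not in model")
  }
  if (length(exchange_reactions)) {
    bad <- setdiff(exchange_reactions, ids)
    if (length(bad)) stop_catapot("exchange reaction(s) not in model: ",
                                  paste(bad, collapse = ", "))
    for (rid in exchange_reactions) {
      st <- reactions[[match(rid, ids)]]$stoich
      if (length(st) != 1L) {
        stop_catapot("exchange reaction ", rid,
                     " must involve exactly one metabolite")
      }
    }
  }
  structure(list(reactions = reactions,
                 biomass_reaction_id = biomass_reaction_id,
                 exchange_reactions = exchange_reactions),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$reactions), " reactions, ",
      length(model_metabolites(x)), " metabolites, ",
      length(x$exchange_reactions), " exchanges; biomass = ",
      x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

model_metabolites <- function(model) {
  sort(unique(unlist(lapply(model$reactions, function(r) names(r$stoich)))))
}

#' Stoichiometric matrix of a model
#'
#' One row per reaction, one column per metabolite; entry = signed
#' stoichiometric coefficient of the metabolite in the reaction.
#'
#' @param model a [metabolic_model()].
#' @return numeric matrix with reaction ids as row names.
#' @export
stoich_matrix <- function(model) {
  mets <- model_metabolites(model)
  rids <- reaction_ids(model)
  S <- matrix(0, length(rids), length(mets), dimnames = list(rids, mets))
  for (i in seq_along(model$reactions)) {
    st <- model$reactions[[i]]$stoich
    S[i, names(st)] <- st
  }
  S
}

#' Define a growth medium as non-negative uptake bounds
#'
#' @param uptake_bounds named numeric vector, nutrient id -> maximal uptake
#'   flux (mmol/gDW/h by convention).  Nutrients absent from the map have
#'   bound 0.
#' @return An object of class `fba_medium`.
#' @export
medium <- function(uptake_bounds = numeric(0)) {
  if (length(uptake_bounds)) {
    stopifnot(!is.null(names(uptake_bounds)), all(uptake_bounds >= 0))
  }
  structure(as.list(uptake_bounds), class = "fba_medium")
}

#' Merge media, adding one nutrient or combining bound maps
#' @param base an [medium()].
#' @param extra named numeric vector of additional bounds (overriding).
#' @return the combined `fba_medium`.
#' @export
medium_with <- function(base, extra) {
  out <- modifyList(unclass(base), as.list(extra))
  structure(out, class = "fba_medium")
}

# Effective reaction bounds once a medium is imposed: exchange reactions are
# uptake-only with upper bound from the medium (0 when absent).
effective_bounds <- function(model, medium) {
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  names(lb) <- names(ub) <- reaction_ids(model)
  for (nut in names(model$exchange_reactions)) {
    rid <- model$exchange_reactions[[nut]]
    b <- medium[[nut]] %||% 0
    lb[rid] <- 0
    ub[rid] <- b
  }
  list(lb = lb, ub = ub)
}

#' Maximize biomass production at steady state
#'
#' Solves the linear program: maximize the biomass flux subject to the
#' steady-state mass balance (for every metabolite, production equals
#' consumption) and reaction bounds, with exchange bounds taken from the
#' medium.  Blocked reactions (both bounds zero) are pruned before the
#' solve and reported with zero flux.
#'
#' @param model a [metabolic_model()].
#' @param medium an [medium()].
#' @param tol steady-state feasibility tolerance.
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `biomass_flux`, and the named flux
#'   vector `fluxes`.  The objective value is deterministic; the flux
#'   vector may be any optimal vertex.
#' @export
maximize_biomass <- function(model, medium = catapot::medium(), tol = 1e-9) {
  bounds <- effective_bounds(model, medium)
  rids <- reaction_ids(model)
  keep <- !(bounds$lb == 0 & bounds$ub == 0)
  fluxes <- setNames(rep(0, length(rids)), rids)
  if (!keep[match(model$biomass_reaction_id, rids)]) {
    return(structure(list(status = "optimal", biomass_flux = 0, fluxes = fluxes),
                     class = "flux_solution"))
  }
  S <- stoich_matrix(model)[keep, , drop = FALSE]
  live <- colSums(S != 0) > 0
  A <- t(S[, live, drop = FALSE])
  obj <- as.numeric(rids[keep] == model$biomass_reaction_id)
  sol <- lp_solve(obj, A, rep(0, nrow(A)), bounds$lb[keep], bounds$ub[keep],
                  maximize = TRUE, tol = tol)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, biomass_flux = NA_real_,
                          fluxes = fluxes), class = "flux_solution"))
  }
  fluxes[rids[keep]] <- sol$x
  structure(list(status = "optimal", biomass_flux = sol$objective,
                 fluxes = fluxes), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status=", x$status, ", biomass_flux=",
      format(x$biomass_flux), "\n", sep = "")
  invisible(x)
}

#' Label a nutrient as growth-supporting (G) or not (NG)
#'
#' A nutrient is `G` if adding it to the minimal medium raises the optimal
#' biomass flux above `epsilon`; the minimal medium on its own must not
#' (that is the definition of a minimal medium, and a violation is an
#' error, not a label).  Nutrients without an exchange reaction cannot be
#' taken up and are `NG` outright.  ATP maintenance should already have
#' been stripped (see [remove_atp_maintenance()]).
#'
#' @param model a [metabolic_model()].
#' @param minimal_medium an [medium()] that alone supports no growth.
#' @param nutrient nutrient id to test.
#' @param uptake_bound uptake flux granted to the tested nutrient.
#' @param epsilon growth-significance threshold on the biomass flux; values
#'   at or below it do not count as growth.
#' @return `"G"` or `"NG"`.
#' @export
label_growth <- function(model, minimal_medium, nutrient,
                         uptake_bound = 10, epsilon = 1e-6) {
  base <- maximize_biomass(model, minimal_medium)
  if (base$status == "optimal" && base$biomass_flux > epsilon) {
    stop_catapot("minimal medium alone yields biomass ", format(base$biomass_flux),
                 " > epsilon; it is not a minimal medium")
  }
  if (!nutrient %in% names(model$exchange_reactions)) return("NG")
  sol <- maximize_biomass(model, medium_with(minimal_medium, setNames(uptake_bound, nutrient)))
  if (sol$status == "optimal" && sol$biomass_flux > epsilon) "G" else "NG"
}

#' Measure the biomass yield of a growth-supporting nutrient
#'
#' Optimal biomass flux divided by the uptake flux actually used at the
#' optimum, i.e. biomass per mole of nutrient.  In a linear (no shared
#' bottleneck) model this is invariant to the uptake bound.
#'
#' @inheritParams label_growth
#' @return biomass per mole of nutrient (a positive number).
#' @export
measure_yield <- function(model, minimal_medium, nutrient, uptake_bound = 10) {
  if (!nutrient %in% names(model$exchange_reactions)) {
    stop_catapot("nutrient ", nutrient, " has no exchange reaction")
  }
  sol <- maximize_biomass(model, medium_with(minimal_medium, setNames(uptake_bound, nutrient)))
  if (sol$status != "optimal") stop_catapot("FBA not optimal: ", sol$status)
  uptake <- sol$fluxes[[model$exchange_reactions[[nutrient]]]]
  if (uptake <= 1e-9) stop_catapot("zero uptake of ", nutrient, " at the optimum")
  sol$biomass_flux / uptake
}

#' Strip the ATP-maintenance flux from a model
#'
#' Non-growth ATP maintenance is a fitted drain that distorts maximal
#' biomass conversion; for yield analysis its reaction is clamped to zero
#' flux (bounds `[0, 0]`).  The biomass stoichiometry is untouched.
#'
#' @param model a [metabolic_model()].
#' @param pattern regular expression identifying the maintenance reaction
#'   id.  Zero matches leaves the model unchanged with a warning; more than
#'   one match is an error listing them.
#' @return the modified model.
#' @export
remove_atp_maintenance <- function(model, pattern = "^ATPM") {
  rids <- reaction_ids(model)
  hits <- grep(pattern, rids)
  if (length(hits) > 1L) {
    stop_catapot("maintenance pattern matches several reactions: ",
                 paste(rids[hits], collapse = ", "))
  }
  if (!length(hits)) {
    warning("no ATP-maintenance reaction matched '", pattern, "'; model unchanged",
            call. = FALSE)
    return(model)
  }
  model$reactions[[hits]]$lb <- 0
  model$reactions[[hits]]$ub <- 0
  model
}

# ---- TSV reaction dialect --------------------------------------------------

# Accumulate `val` onto element `name` of a named numeric vector that may
# not yet contain it (indexing a missing name yields NA, not NULL).
acc_named <- function(vec, name, val) {
  vec[name] <- (if (name %in% names(vec)) vec[[name]] else 0) + val
  vec
}

parse_side <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(numeric(0))
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9.eE+-]+[ ]+)?([^ ]+)$", tm))[[1]]
    if (length(m) != 3L || !nzchar(m[3])) stop_catapot("cannot parse term '", tm, "'")
    coefs <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    out <- acc_named(out, m[3], coefs)
  }
  out
}

parse_equation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  lhs <- parse_side(sides[1])
  rhs <- parse_side(sides[2])
  st <- numeric(0)
  for (m in names(lhs)) st <- acc_named(st, m, -lhs[[m]])
  for (m in names(rhs)) st <- acc_named(st, m, rhs[[m]])
  st[st != 0]
}

format_equation <- function(stoich, reversible = FALSE) {
  fmt1 <- function(v) {
    paste(vapply(names(v), function(m) {
      if (v[m] == 1) m else paste(fmt_num(v[m]), m)
    }, ""), collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt1(lhs), if (reversible) "<->" else "->", fmt1(rhs))
}

#' Read a metabolic model from the TSV reaction dialect
#'
#' One reaction per line, tab-separated columns `id`, `equation`, `lb`,
#' `ub`, `role`.  Equations look like `A + 2 B -> C`; either side may be
#' empty (`-> A` imports, `B ->` drains); `<->` marks reversibility
#' (informational only - direction is governed by the bounds).  `role` is
#' empty, `biomass`, or `exchange=<nutrient id>`.  `inf`/`-inf` are valid
#' bounds.  [write_reaction_tsv()] round-trips exactly.
#'
#' @param path TSV file.
#' @return A [metabolic_model()].
#' @export
read_reaction_tsv <- function(path) {
  if (!file.exists(path)) stop_catapot("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  need <- c("id", "equation", "lb", "ub")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_catapot("reaction TSV lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(tab$role)) tab$role <- ""
  biomass <- NULL
  exch <- character(0)
  reactions <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    st <- parse_equation(tab$equation[i])
    reactions[[i]] <- list(id = tab$id[i], stoich = st,
                           lb = as.numeric(sub("^-inf$", "-Inf", tab$lb[i], ignore.case = TRUE)),
                           ub = as.numeric(sub("^inf$", "Inf", tab$ub[i], ignore.case = TRUE)))
    role <- trimws(tab$role[i])
    if (role == "biomass") biomass <- tab$id[i]
    else if (startsWith(role, "exchange=")) exch[sub("^exchange=", "", role)] <- tab$id[i]
  }
  if (is.null(biomass)) stop_catapot("no reaction with role 'biomass'")
  metabolic_model(reactions, biomass, exch)
}

#' Write a metabolic model in the TSV reaction dialect
#' @param model a [metabolic_model()].
#' @param path output TSV file.
#' @return `model`, invisibly.
#' @export
write_reaction_tsv <- function(model, path) {
  rids <- reaction_ids(model)
  role <- setNames(rep("", length(rids)), rids)
  role[model$biomass_reaction_id] <- "biomass"
  for (nut in names(model$exchange_reactions)) {
    role[model$exchange_reactions[[nut]]] <- paste0("exchange=", nut)
  }
  rows <- lapply(model$reactions, function(r) {
    data.frame(id = r$id,
               equation = format_equation(r$stoich, reversible = r$lb < 0),
               lb = fmt_num(r$lb), ub = fmt_num(r$ub),
               role = role[[r$id]], stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(model)
}

#' Read a medium from JSON (`{"nutrient": bound, ...}`)
#' @param path JSON file.
#' @return an [medium()].
#' @export
read_medium_json <- function(path) {
  medium(unlist(jsonlite::fromJSON(path)))
}
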