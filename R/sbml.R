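# Read-only SBML Level 3 (+fbc) import.  The canonical interchange format
# of this package is the TSV reaction dialect; SBML support exists so that
# published reconstructions can be loaded without conversion scripts.

#' Read a metabolic model from an SBML Level 3 file
#'
#' Supports the core `listOfSpecies`/`listOfReactions` structure with
#' `fbc:` flux bounds (bound parameters referenced via
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`) and an `fbc:listOfObjectives`
#' biomass objective.  Reactions with `reversible="true"` and no explicit
#' bounds default to `[-1000, 1000]`, otherwise `[0, 1000]`.  Exchange
#' reactions are recognized as single-metabolite reactions whose id starts
#' with `EX_` (or `R_EX_`); the nutrient id is the remainder of the
#' reaction id.
#'
#' @param path SBML file.
#' @param biomass_reaction_id optional explicit biomass reaction id,
#'   overriding (or replacing a missing) fbc objective.
#' @return a [metabolic_model()].
#' @export
read_sbml_model <- function(path, biomass_reaction_id = NULL) {
  if (!file.exists(path)) stop_catapot("file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop_catapot("no reactions in SBML file")
  get_side <- function(node, tag, sgn) {
    refs <- xml2::xml_find_all(node, paste0("./", tag, "/speciesReference"))
    if (!length(refs)) return(numeric(0))
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    setNames(sgn * st, xml2::xml_attr(refs, "species"))
  }
  reactions <- lapply(rx_nodes, function(node) {
    attrs <- xml2::xml_attrs(node)
    # fbc attributes may or may not carry their namespace prefix here.
    attr_of <- function(nm) {
      hit <- grep(paste0("(^|:)", nm, "$"), names(attrs))
      if (length(hit)) attrs[[hit[1]]] else NA_character_
    }
    st <- numeric(0)
    lhs <- get_side(node, "listOfReactants", -1)
    rhs <- get_side(node, "listOfProducts", 1)
    for (m in names(lhs)) st <- acc_named(st, m, lhs[[m]])
    for (m in names(rhs)) st <- acc_named(st, m, rhs[[m]])
    rev <- identical(attr_of("reversible"), "true")
    lb_ref <- attr_of("lowerFluxBound")
    ub_ref <- attr_of("upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    list(id = attrs[["id"]], stoich = st[st != 0], lb = lb, ub = ub)
  })
  rids <- vapply(reactions, `[[`, "", "id")
  if (is.null(biomass_reaction_id)) {
    # fbc-prefixed elements keep their prefix even after namespace stripping
    obj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(obj, "xml_missing")) {
      oat <- xml2::xml_attrs(obj)
      hit <- grep("(^|:)reaction$", names(oat))
      if (length(hit)) biomass_reaction_id <- oat[[hit[1]]]
    }
  }
  if (is.null(biomass_reaction_id) || is.na(biomass_reaction_id)) {
    stop_catapot("no biomass objective found; pass biomass_reaction_id")
  }
  exch <- character(0)
  for (r in reactions) {
    if (length(r$stoich) == 1L && grepl("^(R_)?EX_", r$id)) {
      exch[sub("^(R_)?EX_", "", r$id)] <- r$id
    }
  }
  metabolic_model(reactions, biomass_reaction_id, exch)
}
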