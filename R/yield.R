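# Single-nutrient biomass yield: the sugar-reference yield y_s, effective
# carbon counts, and the prediction B_i = y_s * C_eff.

#' Effective number of catabolizable carbons of a nutrient
#'
#' The carbons a species can actually turn into biomass:
#'
#' * simple, non-purine nutrients contribute all `C_i` carbons;
#' * purines leak three carbons as carbon dioxide and urea on the way to
#'   glyoxylate, so they contribute `C_i - 3` (floored at zero);
#' * complex nutrients are decomposed and contribute the carbons of their
#'   catabolizable (`G`) simple components only, with purine components
#'   again leaking three carbons each.
#'
#' Components are classified without the uptake gate: a decomposition
#' product is available intracellularly regardless of transporters.
#'
#' @param nutrient nutrient id.
#' @param organism an [organism_profile()].
#' @param catalog a [nutrient_catalog()].
#' @param model fitted [logistic_pathway_model()] (needed if any component
#'   routes to the logistic rule).
#' @param threshold logistic decision threshold.
#' @return effective carbon count (non-negative number).
#' @export
effective_carbons <- function(nutrient, organism, catalog, model = NULL,
                              threshold = 0.5) {
  row <- catalog_row(catalog, nutrient)
  purine_c <- function(ci) max(ci - 3, 0)
  if (!row$is_complex) {
    return(if (row$class == "Purines") purine_c(row$n_carbons) else row$n_carbons)
  }
  parts <- decompose(nutrient, catalog)
  total <- 0
  for (k in seq_len(nrow(parts))) {
    pid <- parts$id[k]
    prow <- catalog_row(catalog, pid)
    lab <- classify_impl(pid, organism, catalog, model, threshold,
                         gate_uptake = FALSE)$label
    if (lab != "G") next
    ci <- if (prow$class == "Purines") purine_c(prow$n_carbons) else prow$n_carbons
    total <- total + parts$mult[k] * ci
  }
  total
}

#' Sugar-reference biomass yield of a species
#'
#' The per-carbon yield `y_s` is the mean over the organism's uptaken,
#' growth-supporting sugars of (measured biomass per mole) / (carbon
#' count).  Sugars sit at the efficiency envelope, so `y_s` anchors the
#' yield predictions of all other nutrients.
#'
#' @param measurements data frame with columns `nutrient` and `biomass`
#'   (measured biomass per mole, e.g. from [measure_yield()]).
#' @param organism an [organism_profile()].
#' @param catalog a [nutrient_catalog()].
#' @param labels classification data frame for this organism (columns
#'   `nutrient`, `label`), e.g. from [classify_all()].
#' @return `y_s`, biomass per carbon.
#' @export
sugar_reference_yield <- function(measurements, organism, catalog, labels) {
  nut <- catalog$nutrients
  sugars <- nut$id[nut$class == "Sugars"]
  ok <- sugars[sugars %in% organism$uptaken &
                 sugars %in% labels$nutrient[labels$label == "G"] &
                 sugars %in% measurements$nutrient]
  if (!length(ok)) {
    stop_catapot("species ", organism$id, " has no measured growth-supporting ",
                 "sugar; fall back to the training-set class yield table ",
                 "(see class_yield_table)")
  }
  b <- measurements$biomass[match(ok, measurements$nutrient)]
  ci <- nut$n_carbons[match(ok, nut$id)]
  mean(b / ci)
}

#' Predict the biomass produced by a single nutrient
#'
#' `B_i = y_s * C_eff(i)` for growth-supporting nutrients; `NG` nutrients
#' predict zero biomass.
#'
#' @inheritParams effective_carbons
#' @param y_s sugar-reference yield of the species (see
#'   [sugar_reference_yield()]).
#' @return predicted biomass per mole of nutrient.
#' @export
predict_single_nutrient <- function(nutrient, y_s, organism, catalog,
                                    model = NULL, threshold = 0.5) {
  lab <- classify(nutrient, organism, catalog, model, threshold)$label
  if (lab != "G") return(0)
  y_s * effective_carbons(nutrient, organism, catalog, model, threshold)
}

#' Per-species yield table of growth-supporting nutrients
#'
#' One row per measured `G` nutrient with its carbon counts, effective
#' carbons, and yield normalized by the sugar envelope:
#' `normalized_yield = B / (y_s * C_i)`.  The model deliberately refuses
#' obligate anaerobes: anaerobic energetics change the cost of polymerizing
#' biomass and break the aerobic yield envelope the model is built on.
#'
#' @inheritParams sugar_reference_yield
#' @param model fitted [logistic_pathway_model()] used for component
#'   classification inside [effective_carbons()].
#' @param y_s optional precomputed sugar-reference yield; computed from the
#'   measurements when omitted.
#' @return An object of class `yield_table`: data frame with columns
#'   `nutrient`, `class`, `biomass`, `n_carbons`, `c_eff`,
#'   `normalized_yield`, plus attributes `y_s` and `organism`.
#' @export
yield_table <- function(measurements, organism, catalog, labels,
                        model = NULL, y_s = NULL) {
  if (organism$anaerobe) {
    stop_catapot("species ", organism$id, " is flagged anaerobic; the aerobic ",
                 "yield model does not apply")
  }
  if (is.null(y_s)) y_s <- sugar_reference_yield(measurements, organism, catalog, labels)
  g_ids <- intersect(measurements$nutrient, labels$nutrient[labels$label == "G"])
  nut <- catalog$nutrients
  rows <- data.frame(
    nutrient = g_ids,
    class = nut$class[match(g_ids, nut$id)],
    biomass = measurements$biomass[match(g_ids, measurements$nutrient)],
    n_carbons = nut$n_carbons[match(g_ids, nut$id)],
    c_eff = vapply(g_ids, effective_carbons, 0, organism = organism,
                   catalog = catalog, model = model),
    stringsAsFactors = FALSE
  )
  rows$normalized_yield <- rows$biomass / (y_s * rows$n_carbons)
  structure(rows, y_s = y_s, organism = organism$id,
            class = c("yield_table", "data.frame"))
}
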