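# Decision cascade for catabolic potential: uptake gate, class rules,
# enzyme gates, complex-nutrient decomposition, logistic fallback.

CLASS_NG <- c("Cell boundary", "Cofactors", "Inorganic compounds", "Pyrimidines")
CLASS_G <- c("Sugars", "Sugar derivatives")

#' Classify a nutrient as a carbon source (G) or not (NG) for an organism
#'
#' The cascade applies, in fixed order:
#'
#' 1. *Uptake gate* - a nutrient the organism does not transport is `NG`;
#'    fatty acids bypass the gate because they diffuse through the
#'    membrane.
#' 2. *Class rules* - Cell boundary, Cofactors, Inorganic compounds and
#'    Pyrimidines are `NG`; Sugars and Sugar derivatives are `G`.
#' 3. *Purines* are `G` iff the organism has 5-hydroxyisourate hydrolase
#'    (EC 3.5.2.17), the gatekeeper of urate degradation to glyoxylate.
#' 4. *Fatty acids* are `G` iff the organism has both terminal
#'    beta-oxidation enzymes (EC 1.1.1.35 and EC 2.3.1.16).
#' 5. *Complex nutrients* of the remaining classes are decomposed into
#'    simple nutrients and labeled `G` iff at least one component
#'    classifies `G`.  Components are evaluated without the uptake gate:
#'    once the parent is inside the cell its fragments are available
#'    regardless of transporters.
#' 6. Everything else (amino acids, the derivative classes, organic
#'    compounds) falls to the *logistic pathway model*: `G` iff the
#'    predicted probability exceeds `threshold`.  A probability exactly at
#'    the threshold is `NG` (the conservative call, since false positives
#'    dominate the cascade's error modes).
#'
#' @param nutrient nutrient id.
#' @param organism an [organism_profile()].
#' @param catalog a [nutrient_catalog()].
#' @param model a fitted [logistic_pathway_model()]; may be `NULL` if no
#'   nutrient reaches step 6 (reaching it without a model is an error).
#' @param threshold logistic decision threshold.
#' @return list with `label` (`"G"`/`"NG"`), `rule` (one of `not-uptaken`,
#'   `class-rule`, `purine-enzyme`, `fatty-acid-enzyme`,
#'   `complex-decomposition`, `logistic`), and `probability` (`NA` unless
#'   the logistic rule fired).
#' @export
classify <- function(nutrient, organism, catalog, model = NULL, threshold = 0.5) {
  classify_impl(nutrient, organism, catalog, model, threshold,
                gate_uptake = TRUE, partial = FALSE)
}

classify_impl <- function(nutrient, organism, catalog, model, threshold,
                          gate_uptake, partial = FALSE) {
  row <- catalog_row(catalog, nutrient)
  cls <- row$class
  res <- function(label, rule, probability = NA_real_) {
    list(nutrient = nutrient, label = label, rule = rule, probability = probability)
  }
  if (gate_uptake && cls != "Fatty acids" && !nutrient %in% organism$uptaken) {
    return(res("NG", "not-uptaken"))
  }
  if (cls %in% CLASS_NG) return(res("NG", "class-rule"))
  if (cls %in% CLASS_G) return(res("G", "class-rule"))
  if (cls == "Purines") {
    return(res(if (organism$has_ec_3_5_2_17) "G" else "NG", "purine-enzyme"))
  }
  if (cls == "Fatty acids") {
    ok <- organism$has_ec_1_1_1_35 && organism$has_ec_2_3_1_16
    return(res(if (ok) "G" else "NG", "fatty-acid-enzyme"))
  }
  if (row$is_complex) {
    parts <- decompose(nutrient, catalog)
    part_labels <- vapply(parts$id, function(pid) {
      classify_impl(pid, organism, catalog, model, threshold,
                    gate_uptake = FALSE, partial = partial)$label
    }, "")
    label <- if (any(part_labels == "G", na.rm = TRUE)) "G"
             else if (anyNA(part_labels)) NA_character_
             else "NG"
    return(res(label, "complex-decomposition"))
  }
  if (is.null(model)) {
    if (partial) return(res(NA_character_, "logistic"))
    stop_catapot("nutrient ", nutrient,
                 " requires the logistic rule but no fitted model was supplied")
  }
  p <- predict_logistic(model, membership_matrix(catalog, nutrient))[[1]]
  res(if (p > threshold) "G" else "NG", "logistic", p)
}

#' Classify every nutrient in a catalog for one organism
#'
#' @inheritParams classify
#' @return data frame with columns `nutrient`, `organism`, `label`, `rule`,
#'   `probability`, one row per catalog nutrient, in catalog order.  The
#'   result is deterministic and invariant to catalog row permutations
#'   (row order follows the input; labels do not depend on it).
#' @export
classify_all <- function(organism, catalog, model = NULL, threshold = 0.5) {
  ids <- catalog$nutrients$id
  rows <- lapply(ids, classify, organism = organism, catalog = catalog,
                 model = model, threshold = threshold)
  data.frame(nutrient = ids,
             organism = organism$id,
             label = vapply(rows, `[[`, "", "label"),
             rule = vapply(rows, `[[`, "", "rule"),
             probability = vapply(rows, `[[`, 0, "probability"),
             stringsAsFactors = FALSE)
}

#' Which cascade rule would fire, without requiring a fitted model
#'
#' Routing variant of [classify()] used to assemble the logistic training
#' set: nutrients that fall through to step 6 get `rule = "logistic"` and
#' an `NA` label instead of an error.
#'
#' @inheritParams classify_all
#' @return data frame as in [classify_all()], with `NA` labels for
#'   logistic-routed nutrients.
#' @export
route_nutrients <- function(organism, catalog, threshold = 0.5) {
  ids <- catalog$nutrients$id
  rows <- lapply(ids, function(id) {
    classify_impl(id, organism, catalog, model = NULL, threshold = threshold,
                  gate_uptake = TRUE, partial = TRUE)
  })
  data.frame(nutrient = ids, organism = organism$id,
             label = vapply(rows, `[[`, "", "label"),
             rule = vapply(rows, `[[`, "", "rule"),
             probability = vapply(rows, `[[`, 0, "probability"),
             stringsAsFactors = FALSE)
}
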