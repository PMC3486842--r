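# Additive model for biomass production on complex media, random media
# ensembles, and the slope/rank-correlation validation statistics.

MEDIA_CLASSES <- c("Sugars", "Fatty acids", "Amino acids", "Purines", "Pyrimidines")

#' Training-set average yield per carbon for the media nutrient classes
#'
#' For each of the five media classes (sugars, fatty acids, amino acids,
#' purines, pyrimidines) the per-carbon yield `y_c` is a two-level
#' average: within each training species, the mean over its `G` nutrients
#' of that class of biomass per *effective* carbon; then the mean across
#' species.  Classes with no `G` observation in any species get no entry,
#' and downstream predictions needing them raise errors.
#'
#' @param yield_tables named list of [yield_table()] objects, one per
#'   training species.
#' @param catalog a [nutrient_catalog()].
#' @return An object of class `class_yield_table`: data frame with columns
#'   `class`, `y_c`, `n_species`, `n_obs`.
#' @export
class_yield_table <- function(yield_tables, catalog) {
  per_class <- lapply(MEDIA_CLASSES, function(cl) {
    means <- c(); nobs <- 0L
    for (yt in yield_tables) {
      sub <- yt[yt$class == cl & yt$c_eff > 0, , drop = FALSE]
      if (!nrow(sub)) next
      means <- c(means, mean(sub$biomass / sub$c_eff))
      nobs <- nobs + nrow(sub)
    }
    if (!length(means)) return(NULL)
    data.frame(class = cl, y_c = mean(means), n_species = length(means),
               n_obs = nobs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_class)
  structure(out, class = c("class_yield_table", "data.frame"))
}

#' Generate an ensemble of random complex media
#'
#' Media draw from five nutrient classes (sugars, fatty acids, amino
#' acids, purines, pyrimidines), using nucleobases only - complex purines
#' and pyrimidines are already mixtures of a sugar and a base.  Each
#' eligible non-sugar nutrient enters a medium independently with
#' probability `p`.  Because regulation enforces one sugar at a time
#' (diauxie), the single sugar slot is glucose-only, also filled with
#' probability `p`.
#'
#' @param catalog a [nutrient_catalog()].
#' @param p inclusion probability, `0 < p < 1`.
#' @param n_media number of media to draw.
#' @param seed RNG seed (mandatory; ensembles must be reproducible).
#' @param glucose_id catalog id of glucose.
#' @return An object of class `media_ensemble`: list of media, each a list
#'   with `id` and `nutrients` (character vector); attributes `p`, `seed`,
#'   `eligible`.
#' @export
generate_media_ensemble <- function(catalog, p, n_media, seed,
                                    glucose_id = "glucose") {
  stopifnot(p > 0, p < 1, n_media >= 1)
  nut <- catalog$nutrients
  nonsugar <- nut$id[nut$class %in% setdiff(MEDIA_CLASSES, "Sugars") & !nut$is_complex]
  if (!glucose_id %in% nut$id) stop_catapot("glucose id ", glucose_id, " not in catalog")
  eligible <- c(glucose_id, sort(nonsugar))
  if (length(eligible) <= 1L) stop_catapot("catalog has no eligible media nutrients")
  media <- with_seed(seed, {
    lapply(seq_len(n_media), function(i) {
      keep <- runif(length(eligible)) < p
      list(id = sprintf("m%04d", i), nutrients = eligible[keep])
    })
  })
  structure(media, p = p, seed = seed, eligible = eligible,
            glucose_id = glucose_id, class = "media_ensemble")
}

#' @export
print.media_ensemble <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "nutrients"))
  cat("<media_ensemble> ", length(x), " media, p=", attr(x, "p"),
      ", mean size ", round(mean(sizes), 2), "\n", sep = "")
  invisible(x)
}

#' Predict biomass production on a complex medium
#'
#' The additive model: every growth-supporting nutrient in the medium
#' contributes independently, `B_m = sum y_c(i) * C_eff(i)` over present
#' nutrients labeled `G`; `NG` nutrients contribute nothing.  A `G`
#' nutrient whose class is missing from the class-yield table is an error
#' naming the nutrient.
#'
#' @param medium_nutrients character vector of nutrient ids (or one medium
#'   from [generate_media_ensemble()]).
#' @param class_yields a [class_yield_table()].
#' @param organism an [organism_profile()].
#' @param catalog a [nutrient_catalog()].
#' @param model fitted [logistic_pathway_model()] for logistic-routed
#'   nutrients.
#' @param threshold logistic decision threshold.
#' @return predicted biomass (per unit of molar uptake flux).
#' @export
predict_medium <- function(medium_nutrients, class_yields, organism, catalog,
                           model = NULL, threshold = 0.5) {
  if (is.list(medium_nutrients)) medium_nutrients <- medium_nutrients$nutrients
  total <- 0
  for (nid in medium_nutrients) {
    lab <- classify(nid, organism, catalog, model, threshold)$label
    if (lab != "G") next
    cl <- catalog_row(catalog, nid)$class
    yc <- class_yields$y_c[class_yields$class == cl]
    if (!length(yc)) {
      stop_catapot("nutrient ", nid, " is G but class '", cl,
                   "' is absent from the class yield table")
    }
    total <- total + yc * effective_carbons(nid, organism, catalog, model, threshold)
  }
  total
}

#' In silico biomass production on a complex medium via FBA
#'
#' Grants every medium nutrient the same molar uptake bound on top of the
#' minimal medium and maximizes biomass.  The default bound of 1 puts the
#' result on the same per-mole scale as [predict_medium()].
#'
#' @param model_fba a [metabolic_model()].
#' @param minimal_medium an [medium()].
#' @param medium_nutrients character vector of nutrient ids (or one medium
#'   from [generate_media_ensemble()]).
#' @param uptake_bound molar uptake flux granted to each present nutrient.
#' @return biomass flux (a number).
#' @export
measure_medium_biomass <- function(model_fba, minimal_medium, medium_nutrients,
                                   uptake_bound = 1) {
  if (is.list(medium_nutrients)) medium_nutrients <- medium_nutrients$nutrients
  present <- intersect(medium_nutrients, names(model_fba$exchange_reactions))
  med <- medium_with(minimal_medium, setNames(rep(uptake_bound, length(present)), present))
  sol <- maximize_biomass(model_fba, med)
  if (sol$status != "optimal") stop_catapot("FBA on medium not optimal: ", sol$status)
  sol$biomass_flux
}

#' Validate ensemble predictions against in silico measurements
#'
#' `K` is the through-origin least-squares slope of predicted on measured
#' biomass, `K = sum(pred * meas) / sum(meas^2)` (so `K < 1` means the
#' additive model under-predicts, the signature of synergistic pathway
#' use), and `spearman_rho` the rank correlation with average-rank ties.
#'
#' @param predictions numeric vector of additive-model predictions.
#' @param measurements numeric vector of in silico (FBA) biomass values,
#'   same length.
#' @param rank_tol relative tolerance for tie detection when ranking:
#'   values closer than `rank_tol * max(|series|)` are treated as tied.
#'   Media ensembles contain many exactly-tied biomass values that the LP
#'   solver reproduces only to round-off; without a tolerance such ties
#'   would be ranked on floating-point noise.
#' @return list with `K`, `spearman_rho` (`NA` with a warning when a
#'   series is constant), and `n`.
#' @export
validate_ensemble <- function(predictions, measurements, rank_tol = 1e-9) {
  stopifnot(length(predictions) == length(measurements))
  n <- length(predictions)
  if (n < 3L) stop_catapot("need at least 3 paired media")
  denom <- sum(measurements^2)
  K <- if (denom > 0) sum(predictions * measurements) / denom else NA_real_
  quantize <- function(x) {
    s <- rank_tol * max(abs(x), 1e-300)
    round(x / s) * s
  }
  qp <- quantize(predictions); qm <- quantize(measurements)
  rho <- if (stats::sd(qp) == 0 || stats::sd(qm) == 0) {
    warning("constant series; Spearman rho undefined", call. = FALSE)
    NA_real_
  } else {
    cor(qp, qm, method = "spearman")
  }
  list(K = K, spearman_rho = rho, n = n)
}
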