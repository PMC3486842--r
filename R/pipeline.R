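# End-to-end pipeline: fixture simulation -> FBA labeling -> model
# selection -> classification -> yields -> complex-media validation, with
# every stage's inputs and outputs on disk as CSV/JSON.

#' Default pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed global seed; every stochastic stage derives from it.
#' @param y0 per-carbon yield of the simulated networks.
#' @param synergy plant the media synergy reaction.
#' @param epsilon growth-significance threshold for FBA labeling.
#' @param uptake_bound uptake flux per tested carbon source.
#' @param threshold logistic decision threshold.
#' @param p_values inclusion probabilities of the media ensembles.
#' @param n_media media per ensemble.
#' @param media_uptake_bound molar uptake bound used when measuring media
#'   biomass (per-mole scale).
#' @param max_terms cap on selected logistic terms.
#' @return named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("catapot_run_"),
                       seed = 1L,
                       y0 = 0.1,
                       synergy = FALSE,
                       epsilon = 1e-6,
                       uptake_bound = 10,
                       threshold = 0.5,
                       p_values = c(0.1, 0.5, 0.9),
                       n_media = 1000L,
                       media_uptake_bound = 1,
                       max_terms = 10L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), y0 = y0,
                 synergy = isTRUE(synergy), epsilon = epsilon,
                 uptake_bound = uptake_bound, threshold = threshold,
                 p_values = p_values, n_media = as.integer(n_media),
                 media_uptake_bound = media_uptake_bound,
                 max_terms = as.integer(max_terms)),
            class = "run_config")
}

#' Run the full modeling pipeline on synthetic fixtures
#'
#' Executes, in order: fixture simulation, FBA growth labeling, logistic
#' model selection, cascade classification, yield measurement, and
#' complex-media prediction with validation statistics.  Every stage
#' writes its outputs into `config$out_dir` (catalog and pathway TSVs,
#' profile JSON, `labels.csv`, `model.json`, `trajectory.csv`,
#' `yields.csv`, `class_yields.csv`, `media.csv`, `predictions.csv`,
#' `validation.json`), along with the echoed configuration
#' (`run_config.json`) and a stage log (`log.txt`).  A failing stage
#' aborts with the stage named; partial outputs are retained.  Reruns with
#' the same configuration produce identical outputs.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "log.txt")
  cat("", file = logfile)
  logmsg <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
        file = logfile, append = TRUE)
  }
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- function(name, expr) {
    logmsg("stage", name, "start")
    out <- tryCatch(expr, error = function(e) {
      logmsg("stage", name, "FAILED:", conditionMessage(e))
      stop_catapot("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    logmsg("stage", name, "done")
    out
  }

  fix <- stage("simulate", {
    f <- make_catalog(fixture_spec(seed = config$seed, y0 = config$y0,
                                   synergy = config$synergy))
    write_nutrient_catalog(f$catalog,
                           file.path(config$out_dir, "catalog.tsv"),
                           file.path(config$out_dir, "pathways.tsv"))
    write_organism_profiles(f$organisms, file.path(config$out_dir, "profiles.json"))
    f
  })

  models <- stage("fba-label", {
    ms <- lapply(fix$organisms, function(org) {
      m <- make_linear_fba_model(fix, org, y0 = config$y0, synergy = config$synergy)
      write_reaction_tsv(m, file.path(config$out_dir, paste0("model_", org$id, ".tsv")))
      m
    })
    labels <- do.call(rbind, lapply(fix$organisms, function(org) {
      mm <- minimal_medium_of(org)
      data.frame(nutrient = fix$catalog$nutrients$id, organism = org$id,
                 label = vapply(fix$catalog$nutrients$id, label_growth, "",
                                model = ms[[org$id]], minimal_medium = mm,
                                uptake_bound = config$uptake_bound,
                                epsilon = config$epsilon),
                 stringsAsFactors = FALSE)
    }))
    write.csv(labels, file.path(config$out_dir, "labels.csv"), row.names = FALSE)
    attr(ms, "labels") <- labels
    ms
  })
  labels <- attr(models, "labels")

  fitted <- stage("select-model", {
    ds <- logistic_training_data(fix$organisms, fix$catalog, labels)
    traj <- greedy_select(ds, max_terms = config$max_terms,
                          threshold = config$threshold)
    mdl <- selected_model(traj)
    write_logistic_model(mdl, file.path(config$out_dir, "model.json"),
                         score = traj[[length(traj)]]$score)
    tr <- do.call(rbind, lapply(traj, function(st) {
      data.frame(action = st$action, term = st$term, aic = st$score$aic,
                 bic = st$score$bic, tp_rate = st$score$tp_rate,
                 tn_rate = st$score$tn_rate,
                 auc = st$score$auc, stringsAsFactors = FALSE)
    }))
    write.csv(tr, file.path(config$out_dir, "trajectory.csv"), row.names = FALSE)
    mdl
  })

  predicted <- stage("classify", {
    preds <- do.call(rbind, lapply(fix$organisms, classify_all,
                                   catalog = fix$catalog, model = fitted,
                                   threshold = config$threshold))
    write.csv(preds, file.path(config$out_dir, "labels_predicted.csv"),
              row.names = FALSE)
    preds
  })

  yields <- stage("yield", {
    out <- list()
    for (org in fix$organisms) {
      if (org$anaerobe) next
      orglab <- labels[labels$organism == org$id, ]
      g_ids <- orglab$nutrient[orglab$label == "G"]
      if (!length(g_ids)) next
      meas <- data.frame(nutrient = g_ids,
                         biomass = vapply(g_ids, measure_yield, 0,
                                          model = models[[org$id]],
                                          minimal_medium = minimal_medium_of(org),
                                          uptake_bound = config$uptake_bound))
      out[[org$id]] <- yield_table(meas, org, fix$catalog, orglab, model = fitted)
    }
    all <- do.call(rbind, lapply(names(out), function(oid) {
      cbind(organism = oid, as.data.frame(out[[oid]]),
            y_s = attr(out[[oid]], "y_s"))
    }))
    write.csv(all, file.path(config$out_dir, "yields.csv"), row.names = FALSE)
    out
  })

  stage("media-predict", {
    training <- names(Filter(function(o) o$training_member && !o$anaerobe,
                             fix$organisms))
    cyt <- class_yield_table(yields[intersect(names(yields), training)], fix$catalog)
    write.csv(as.data.frame(cyt), file.path(config$out_dir, "class_yields.csv"),
              row.names = FALSE)
    media_rows <- list(); pred_rows <- list(); val <- list()
    for (p in config$p_values) {
      ens <- generate_media_ensemble(fix$catalog, p, config$n_media,
                                     seed = config$seed + round(1000 * p))
      for (org in fix$organisms) {
        if (org$anaerobe || !org$id %in% names(yields)) next
        orglab <- labels[labels$organism == org$id, ]
        pred <- vapply(ens, predict_medium, 0, class_yields = cyt,
                       organism = org, catalog = fix$catalog, model = fitted,
                       threshold = config$threshold)
        meas <- vapply(ens, measure_medium_biomass, 0,
                       model_fba = models[[org$id]],
                       minimal_medium = minimal_medium_of(org),
                       uptake_bound = config$media_uptake_bound)
        v <- validate_ensemble(pred, meas)
        val[[sprintf("%s_p%s", org$id, p)]] <- v
        pred_rows[[length(pred_rows) + 1L]] <-
          data.frame(organism = org$id, p = p,
                     medium = vapply(ens, `[[`, "", "id"),
                     predicted = pred, measured = meas)
      }
      media_rows[[length(media_rows) + 1L]] <-
        data.frame(p = p, medium = vapply(ens, `[[`, "", "id"),
                   nutrients = vapply(ens, function(m) paste(m$nutrients, collapse = ";"), ""))
    }
    write.csv(do.call(rbind, media_rows), file.path(config$out_dir, "media.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, pred_rows), file.path(config$out_dir, "predictions.csv"),
              row.names = FALSE)
    jsonlite::write_json(val, file.path(config$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })
  logmsg("pipeline complete")
  invisible(config$out_dir)
}
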