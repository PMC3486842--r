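# Greedy forward selection of the logistic pathway model, in three phases
# mirroring how the model is grown: (1) pathways rich in G nutrients,
# (2) pathways rich in NG nutrients, (3) pairwise interaction terms that
# mop up false positives inside the selected G pathways.

balanced_accuracy <- function(prob, label, threshold = 0.5) {
  pred_g <- prob > threshold
  tp <- sum(pred_g & label == "G"); fn <- sum(!pred_g & label == "G")
  tn <- sum(!pred_g & label == "NG"); fp <- sum(pred_g & label == "NG")
  rates <- c(if (tp + fn) tp / (tp + fn), if (tn + fp) tn / (tn + fp))
  if (!length(rates)) return(NA_real_)
  mean(rates)
}

raw_accuracy <- function(prob, label, threshold = 0.5) {
  mean((prob > threshold) == (label == "G"))
}

#' Greedy forward selection of pathways and pathway pairs
#'
#' Starting from the null model (intercept only), terms are added one at a
#' time in three phases:
#'
#' 1. *G pathways*: candidate pathways whose not-yet-covered members are
#'    majority `G` (both many and mostly growth-supporting nutrients);
#' 2. *NG pathways*: candidates whose uncovered members are majority `NG`;
#' 3. *pairs*: interactions between a selected G pathway and any other
#'    pathway, which pick out false positives inside the G pathways.
#'
#' At every step the candidate giving the greatest increase in accuracy is
#' taken; for pathway candidates accuracy is evaluated only on the
#' nutrients *not already accounted for* by previously selected G pathways
#' (pathway overlap makes this exclusion essential), while pair candidates
#' act entirely inside covered pathways and are therefore scored on all
#' rows.  Ties break lexicographically on the term name.  An accepted term
#' must improve both AIC and BIC of the full-data fit; a phase ends when
#' the best candidate fails to.  Candidate pathways left with no uncovered
#' members are dropped from consideration.  The final fit always uses all
#' rows.
#'
#' @param dataset a [labeled_dataset()].
#' @param max_terms hard cap on the number of selected terms.
#' @param criterion accuracy flavour used to rank candidates on uncovered
#'   rows: `"balanced"` (mean of TP and TN rates; default) or `"raw"`.
#' @param cap coefficient cap passed to [fit_logistic()].
#' @param threshold decision threshold.
#' @return An object of class `selection_trajectory`: a list of steps, each
#'   with `action` (`"null"`, `"add-pathway"`, `"add-ng-pathway"`,
#'   `"add-pair"`), `term`, the fitted `model`, and its full-data `score`;
#'   the last step holds the selected model.
#' @export
greedy_select <- function(dataset, max_terms = 10L,
                          criterion = c("balanced", "raw"),
                          cap = 20, threshold = 0.5) {
  criterion <- match.arg(criterion)
  accfun <- if (criterion == "balanced") balanced_accuracy else raw_accuracy
  if (!nrow(dataset$table)) stop_catapot("empty dataset")
  memb <- dataset$membership
  lab <- dataset$table$label
  all_pw <- sort(colnames(memb))

  sel_pw <- character(0)     # all selected linear terms
  sel_g <- character(0)      # the subset selected in the G phase
  sel_pairs <- list()

  cur_model <- fit_logistic(dataset, cap = cap)
  cur_score <- score_model(cur_model, dataset, threshold)
  steps <- list(list(action = "null", term = NA_character_,
                     model = cur_model, score = cur_score))

  covered <- function() {
    if (!length(sel_g)) rep(FALSE, nrow(memb))
    else rowSums(memb[, sel_g, drop = FALSE]) > 0
  }
  n_terms <- function() length(sel_pw) + length(sel_pairs)

  try_candidates <- function(cands, build, action, scope_uncovered = TRUE) {
    # Evaluate candidate terms (on uncovered rows for pathway candidates;
    # pair terms act inside already-covered G pathways, so they are scored
    # on all rows); accept the best if it improves both AIC and BIC.
    # Returns TRUE if a term was accepted.
    uncov <- if (scope_uncovered) !covered() else rep(TRUE, nrow(memb))
    if (!any(uncov) || !length(cands)) return(FALSE)
    base_acc <- accfun(predict_logistic(cur_model, memb)[uncov], lab[uncov], threshold)
    best <- NULL
    for (cand in cands) {  # cands pre-sorted -> lexicographic tie-break
      spec <- build(cand)
      fit <- tryCatch(fit_logistic(dataset, spec$pathways, spec$pairs, cap = cap),
                      error = function(e) NULL)
      if (is.null(fit)) next
      acc <- accfun(predict_logistic(fit, memb)[uncov], lab[uncov], threshold)
      if (is.null(best) || acc > best$acc + 1e-12) {
        best <- list(cand = cand, fit = fit, acc = acc, spec = spec)
      }
    }
    if (is.null(best) || best$acc <= base_acc + 1e-12) return(FALSE)
    sc <- score_model(best$fit, dataset, threshold)
    if (sc$aic >= cur_score$aic - 1e-9 || sc$bic >= cur_score$bic - 1e-9) return(FALSE)
    cur_model <<- best$fit
    cur_score <<- sc
    sel_pw <<- best$spec$pathways
    sel_pairs <<- best$spec$pairs
    steps[[length(steps) + 1L]] <<- list(action = action,
                                         term = paste(best$cand, collapse = "&"),
                                         model = best$fit, score = sc)
    TRUE
  }

  # Phase 1: pathways whose uncovered members are majority G.
  repeat {
    if (n_terms() >= max_terms) break
    uncov <- !covered()
    gfrac <- vapply(setdiff(all_pw, sel_pw), function(pw) {
      m <- memb[, pw] > 0 & uncov
      if (!any(m)) NA_real_ else mean(lab[m] == "G")
    }, 0)
    cands <- names(gfrac)[!is.na(gfrac) & gfrac > 0.5]
    ok <- try_candidates(cands,
                         function(pw) list(pathways = c(sel_pw, pw), pairs = sel_pairs),
                         "add-pathway")
    if (!ok) break
    sel_g <- c(sel_g, steps[[length(steps)]]$term)
  }

  # Phase 2: pathways whose uncovered members are majority NG.
  repeat {
    if (n_terms() >= max_terms) break
    uncov <- !covered()
    gfrac <- vapply(setdiff(all_pw, sel_pw), function(pw) {
      m <- memb[, pw] > 0 & uncov
      if (!any(m)) NA_real_ else mean(lab[m] == "G")
    }, 0)
    cands <- names(gfrac)[!is.na(gfrac) & gfrac <= 0.5]
    if (!try_candidates(cands,
                        function(pw) list(pathways = c(sel_pw, pw), pairs = sel_pairs),
                        "add-ng-pathway")) break
  }

  # Phase 3: pairs of (selected G pathway, any other pathway).
  repeat {
    if (n_terms() >= max_terms) break
    have <- vapply(sel_pairs, paste, "", collapse = "&")
    cands <- list()
    for (p in sort(sel_g)) for (q in all_pw) {
      if (q == p) next
      pr <- c(p, q)
      key <- paste(pr, collapse = "&")
      if (key %in% have) next
      if (!any(memb[, p] & memb[, q])) next  # empty interaction column
      cands[[key]] <- pr
    }
    if (!try_candidates(cands[sort(names(cands))],
                        function(pr) list(pathways = sel_pw,
                                          pairs = c(sel_pairs, list(pr))),
                        "add-pair", scope_uncovered = FALSE)) break
  }

  structure(steps, class = "selection_trajectory")
}

#' @export
print.selection_trajectory <- function(x, ...) {
  cat("<selection_trajectory> ", length(x) - 1L, " accepted terms\n", sep = "")
  for (st in x) {
    cat(sprintf("  %-15s %-14s AIC=%8.2f BIC=%8.2f TP=%.3f TN=%.3f\n",
                st$action, ifelse(is.na(st$term), "-", st$term),
                st$score$aic, st$score$bic, st$score$tp_rate, st$score$tn_rate))
  }
  invisible(x)
}

#' Final model of a selection trajectory
#' @param trajectory a [greedy_select()] result.
#' @return the last fitted [logistic_pathway_model()].
#' @export
selected_model <- function(trajectory) {
  trajectory[[length(trajectory)]]$model
}
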