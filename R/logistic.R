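# Logistic pathway model: P(i in G | M) = 1 / (1 + exp(-eta)) with
# eta = beta0 + sum_p beta_p x_ip + sum_(p,q) beta_pq x_ip x_iq,
# where x_ip indicates membership of nutrient i in pathway p.

#' Construct a logistic pathway model
#'
#' Usually produced by [fit_logistic()] or [greedy_select()]; the bare
#' constructor exists so planted ground-truth models can be written down
#' directly in fixtures.
#'
#' @param pathways character vector of pathway ids with linear terms.
#' @param pairs list of length-2 character vectors (pathway pairs with
#'   interaction terms).
#' @param beta0 intercept.
#' @param beta named numeric vector of pathway coefficients (names must
#'   match `pathways`).
#' @param beta_pairs numeric vector of pair coefficients, aligned with
#'   `pairs`.
#' @param capped whether any coefficient sat at the magnitude cap during
#'   fitting (complete separation).
#' @return An object of class `logistic_pathway_model`.
#' @export
logistic_pathway_model <- function(pathways = character(0), pairs = list(),
                                   beta0 = 0, beta = numeric(0),
                                   beta_pairs = numeric(0), capped = FALSE) {
  stopifnot(length(beta) == length(pathways), length(beta_pairs) == length(pairs))
  names(beta) <- pathways
  if (length(pairs)) names(beta_pairs) <- vapply(pairs, paste, "", collapse = "&")
  structure(list(pathways = pathways, pairs = pairs, beta0 = beta0,
                 beta = beta, beta_pairs = beta_pairs, capped = capped),
            class = "logistic_pathway_model")
}

#' @export
print.logistic_pathway_model <- function(x, ...) {
  cat("<logistic_pathway_model> P=", length(x$pathways), " pathways, z=",
      length(x$pairs), " pairs; beta0=", format(x$beta0, digits = 4),
      if (isTRUE(x$capped)) " [capped]" else "", "\n", sep = "")
  if (length(x$beta)) print(round(x$beta, 4))
  if (length(x$beta_pairs)) print(round(x$beta_pairs, 4))
  invisible(x)
}

# Model terms -> design matrix (without intercept) from a membership matrix.
design_matrix <- function(membership, pathways, pairs) {
  n <- nrow(membership)
  X <- matrix(0, n, length(pathways) + length(pairs))
  cn <- character(0)
  if (length(pathways)) {
    miss <- setdiff(pathways, colnames(membership))
    if (length(miss)) stop_catapot("membership matrix lacks pathway(s): ",
                                   paste(miss, collapse = ", "))
    X[, seq_along(pathways)] <- membership[, pathways, drop = FALSE]
    cn <- pathways
  }
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    X[, length(pathways) + k] <- membership[, pr[1]] * membership[, pr[2]]
    cn <- c(cn, paste(pr, collapse = "&"))
  }
  colnames(X) <- cn
  X
}

#' Predicted catabolism probabilities from a logistic pathway model
#'
#' @param model a [logistic_pathway_model()].
#' @param membership 0/1 matrix (rows = nutrients, columns = pathway ids;
#'   see [membership_matrix()]).
#' @return numeric vector of probabilities, one per row.
#' @export
predict_logistic <- function(model, membership) {
  X <- design_matrix(membership, model$pathways, model$pairs)
  eta <- model$beta0 + as.numeric(X %*% c(model$beta, model$beta_pairs))
  logistic(eta)
}

#' Bundle labeled rows and pathway membership into a dataset
#'
#' @param table data frame with columns `nutrient`, `organism`, `label`
#'   (`"G"`/`"NG"`); one row per (nutrient, organism) pair.
#' @param membership 0/1 matrix with one row per `table` row (pathway
#'   membership of the row's nutrient) and pathway ids as column names.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(table, membership) {
  stopifnot(nrow(table) == nrow(membership),
            all(c("nutrient", "organism", "label") %in% names(table)),
            all(table$label %in% c("G", "NG")))
  if (anyDuplicated(paste(table$nutrient, table$organism))) {
    stop_catapot("duplicate (nutrient, organism) rows in dataset")
  }
  structure(list(table = as.data.frame(table), membership = membership),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$table), " rows (",
      sum(x$table$label == "G"), " G / ", sum(x$table$label == "NG"), " NG), ",
      ncol(x$membership), " pathways\n", sep = "")
  invisible(x)
}

#' Assemble the logistic training dataset from cascade-routed nutrients
#'
#' Keeps, for each organism, the (nutrient, organism) pairs that the
#' decision cascade routes to the logistic rule, and attaches their growth
#' labels (e.g. from FBA labeling) and pathway memberships.
#'
#' @param organisms list of [organism_profile()] objects.
#' @param catalog a [nutrient_catalog()].
#' @param labels data frame with columns `nutrient`, `organism`, `label`
#'   covering at least the logistic-routed pairs.
#' @param training_only restrict to organisms with `training_member = TRUE`.
#' @return a [labeled_dataset()].
#' @export
logistic_training_data <- function(organisms, catalog, labels,
                                   training_only = TRUE) {
  rows <- list()
  for (org in organisms) {
    if (training_only && !org$training_member) next
    if (!org$id %in% labels$organism) next  # no labels for this species
    routed <- route_nutrients(org, catalog)
    need <- routed$nutrient[routed$rule == "logistic"]
    for (nid in need) {
      hit <- labels$label[labels$nutrient == nid & labels$organism == org$id]
      if (!length(hit)) stop_catapot("no label for (", nid, ", ", org$id, ")")
      rows[[length(rows) + 1L]] <- data.frame(nutrient = nid, organism = org$id,
                                              label = hit[1], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  labeled_dataset(tab, membership_matrix(catalog, tab$nutrient))
}

#' Fit the logistic pathway model by maximum likelihood
#'
#' Fits via [stats::glm.fit()]; under complete separation (diverging
#' coefficients) the fit is redone as bound-constrained maximum likelihood
#' with every coefficient capped at `|beta| <= cap`, and the model is
#' flagged `capped`.
#'
#' @param dataset a [labeled_dataset()].
#' @param pathways pathway ids to include as linear terms.
#' @param pairs list of pathway-id pairs to include as interactions.
#' @param cap coefficient magnitude cap used under separation.
#' @return a fitted [logistic_pathway_model()].
#' @export
fit_logistic <- function(dataset, pathways = character(0), pairs = list(),
                         cap = 20) {
  X <- design_matrix(dataset$membership, pathways, pairs)
  y <- as.integer(dataset$table$label == "G")
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(glm.fit(Xi, y, family = binomial()))
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop_catapot("design matrix is collinear (aliased terms: ",
                 paste(names(cf)[is.na(cf)], collapse = ", "), ")")
  }
  capped <- FALSE
  if (any(abs(cf) > cap) || !fit$converged) {
    nll <- function(b) {
      eta <- as.numeric(Xi %*% b)
      -sum(y * eta - log1p(exp(eta)))
    }
    grad <- function(b) {
      p <- logistic(as.numeric(Xi %*% b))
      -as.numeric(t(Xi) %*% (y - p))
    }
    start <- pmin(pmax(cf, -cap + 1e-6), cap - 1e-6)
    opt <- optim(start, nll, grad, method = "L-BFGS-B",
                 lower = -cap, upper = cap,
                 control = list(maxit = 500, factr = 1e4))
    cf <- opt$par
    capped <- any(abs(cf) >= cap - 1e-4)
  }
  np <- length(pathways)
  logistic_pathway_model(pathways, pairs,
                         beta0 = unname(cf[1]),
                         beta = unname(cf[1 + seq_len(np)]),
                         beta_pairs = unname(cf[1 + np + seq_along(pairs)]),
                         capped = capped)
}

# Area under the ROC curve by the ranked-sweep construction: rank nutrients
# by predicted probability (highest first), trace the (fraction of NG seen,
# fraction of G seen) curve, and integrate by trapezoids.  Tied
# probabilities are swept as one block, which makes the construction agree
# exactly with the Mann-Whitney U statistic under midrank tie handling.
auc_ranked_sweep <- function(prob, label) {
  g <- label == "G"
  nG <- sum(g); nN <- sum(!g)
  if (nG == 0L || nN == 0L) return(NA_real_)
  ord <- order(prob, decreasing = TRUE)
  p <- prob[ord]; g <- g[ord]
  grp <- cumsum(!duplicated(p))
  dG <- tapply(g, grp, sum) / nG
  dN <- tapply(!g, grp, sum) / nN
  tpr <- cumsum(dG); fpr <- cumsum(dN)
  sum(diff(c(0, fpr)) * (c(0, utils::head(tpr, -1)) + tpr) / 2)
}

#' Score a logistic pathway model on a labeled dataset
#'
#' True positive rate (`G` rows with probability above the threshold),
#' true negative rate, ranked-sweep `AUC`, log-likelihood, and the
#' information criteria `AIC = 2k - 2 ln L` and `BIC = k ln n - 2 ln L`
#' with `k = 1 + P + z` parameters.
#'
#' @param model a fitted [logistic_pathway_model()].
#' @param dataset a [labeled_dataset()].
#' @param threshold decision threshold (probability strictly above counts
#'   as a predicted `G`).
#' @return An object of class `model_score`: list with `tp_rate`,
#'   `tn_rate`, `auc` (`NA` when only one class is present), `aic`, `bic`,
#'   `log_likelihood`, `k`, `n`.
#' @export
score_model <- function(model, dataset, threshold = 0.5) {
  p <- predict_logistic(model, dataset$membership)
  y <- dataset$table$label
  pred_g <- p > threshold
  tp <- sum(pred_g & y == "G"); fn <- sum(!pred_g & y == "G")
  tn <- sum(!pred_g & y == "NG"); fp <- sum(pred_g & y == "NG")
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(ifelse(y == "G", log(pc), log(1 - pc)))
  k <- 1L + length(model$pathways) + length(model$pairs)
  n <- length(y)
  structure(list(tp_rate = if (tp + fn) tp / (tp + fn) else NA_real_,
                 tn_rate = if (tn + fp) tn / (tn + fp) else NA_real_,
                 auc = auc_ranked_sweep(p, y),
                 aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll,
                 log_likelihood = ll, k = k, n = n),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("<model_score> TP=%.3f TN=%.3f AUC=%s AIC=%.2f BIC=%.2f (k=%d, n=%d)\n",
              x$tp_rate, x$tn_rate,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc),
              x$aic, x$bic, x$k, x$n))
  invisible(x)
}

#' Serialize a logistic pathway model (with optional score block) to JSON
#' @param model a [logistic_pathway_model()].
#' @param path output JSON file.
#' @param score optional [score_model()] result stored alongside.
#' @return `model`, invisibly.
#' @export
write_logistic_model <- function(model, path, score = NULL) {
  payload <- list(pathways = model$pathways,
                  pairs = lapply(model$pairs, as.character),
                  beta0 = model$beta0,
                  beta = as.list(model$beta),
                  beta_pairs = as.list(model$beta_pairs),
                  capped = model$capped)
  if (!is.null(score)) payload$score <- unclass(score)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(model)
}

#' Read a logistic pathway model from JSON
#' @param path JSON file written by [write_logistic_model()].
#' @return a [logistic_pathway_model()].
#' @export
read_logistic_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  logistic_pathway_model(as.character(unlist(raw$pathways)),
                         lapply(raw$pairs, function(p) as.character(unlist(p))),
                         raw$beta0,
                         unlist(raw$beta) %||% numeric(0),
                         unlist(raw$beta_pairs) %||% numeric(0),
                         isTRUE(raw$capped))
}
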