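# Shared fixtures built in code: a hand-checkable linear chain network, a
# random small-LP generator for oracle comparisons, and an independent
# Mann-Whitney AUC implementation.

# Three-reaction chain: uptake of G (bound set by the medium), conversion
# G -> 2 P, biomass consuming 1 P per unit of flux.  At uptake 10 the
# optimal biomass flux is 20 and the molar yield is 2.
toy_chain_model <- function() {
  metabolic_model(
    list(
      list(id = "EX_G", stoich = c(G = 1), lb = 0, ub = 0),
      list(id = "CAT",  stoich = c(G = -1, P = 2), lb = 0, ub = 1000),
      list(id = "BIO",  stoich = c(P = -1), lb = 0, ub = 1000)
    ),
    biomass_reaction_id = "BIO",
    exchange_reactions = c(G = "EX_G")
  )
}

# Random small metabolic model with finite bounds and lb <= 0 <= ub, so the
# zero flux vector is always feasible and the optimum finite.
random_toy_model <- function(seed) {
  set.seed(seed)
  nr <- sample(3:6, 1)
  nm <- sample(1:3, 1)
  mets <- paste0("m", seq_len(nm))
  rxns <- lapply(seq_len(nr), function(i) {
    st <- sample(-2:2, nm, replace = TRUE)
    names(st) <- mets
    st <- st[st != 0]
    if (!length(st)) st <- setNames(1, mets[1])
    lb <- if (runif(1) < 0.3) -sample(1:5, 1) else 0
    list(id = paste0("r", i), stoich = st, lb = lb, ub = sample(c(0, 3, 10), 1))
  })
  metabolic_model(rxns, biomass_reaction_id = "r1")
}

# Independent AUC oracle: Mann-Whitney U with midrank tie handling.
mann_whitney_auc <- function(prob, label) {
  g <- label == "G"
  nG <- sum(g); nN <- sum(!g)
  if (nG == 0 || nN == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[g]) - nG * (nG + 1) / 2) / (nG * nN)
}

# Exhaustively fit every logistic model with at most `max_terms` terms
# (linear pathway terms and/or pairs) and return the term-set with the
# lowest AIC.  Brute-force oracle for the greedy selection.
brute_force_best_terms <- function(dataset, max_terms = 3L, cap = 20) {
  pws <- sort(colnames(dataset$membership))
  pair_idx <- utils::combn(pws, 2, simplify = FALSE)
  terms <- c(as.list(pws), pair_idx)
  labels <- vapply(terms, paste, "", collapse = "&")
  best <- list(aic = Inf, terms = character(0))
  for (k in 0:max_terms) {
    for (sel in utils::combn(seq_along(terms), k, simplify = FALSE)) {
      lin <- unlist(terms[sel][lengths(terms[sel]) == 1])
      prs <- terms[sel][lengths(terms[sel]) == 2]
      fit <- tryCatch(fit_logistic(dataset, lin %||% character(0), prs, cap = cap),
                      error = function(e) NULL)
      if (is.null(fit)) next
      sc <- score_model(fit, dataset)
      if (sc$aic < best$aic - 1e-9) {
        best <- list(aic = sc$aic, terms = sort(labels[sel]))
      }
    }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# Term labels ("pw" or "p&q") of a fitted logistic model.
model_term_labels <- function(model) {
  sort(c(model$pathways, vapply(model$pairs, paste, "", collapse = "&")))
}
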