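# Synthetic fixture generators: a desk-scale nutrient catalog spanning all
# twelve classes, organisms with controlled enzyme flags, toy stoichiometric
# networks whose yields are exactly proportional to (effective) carbons, and
# labeled datasets with planted logistic structure.

#' Specification for the synthetic fixture family
#'
#' Collects every knob of the generators in one validated object.  The
#' defaults define the reference conditions used throughout the test
#' suite: a 37-nutrient catalog across all twelve classes (including four
#' complex nutrients with known decompositions), four aerobic organisms
#' (three training, one test) spanning the enzyme-flag combinations, a
#' per-carbon yield of `y0 = 0.1` biomass per carbon, and a planted
#' deterministic logistic truth in which two catabolic pathways carry the
#' growth signal.
#'
#' @param seed RNG seed; mandatory, every generator is deterministic
#'   given it.
#' @param y0 per-carbon biomass yield planted in toy networks.
#' @param synergy plant a shared-cofactor reaction that makes
#'   multi-nutrient media super-additive.
#' @param synergy_gain extra precursor molecules released per paired
#'   cofactor when `synergy` is on.
#' @param anaerobe also generate an anaerobic specialist organism.
#' @param uptake_prob per-organism probability that a nutrient is
#'   transportable.
#' @param n number of rows in planted labeled datasets.
#' @param pathway_ids pathway names of the planted membership matrix.
#' @param membership_prob Bernoulli membership probability per pathway.
#' @param beta0,beta,beta_pairs planted logistic coefficients for labeled
#'   datasets (`beta` named by pathway; `beta_pairs` a named list
#'   `"p&q" = value`).
#' @param overlap_with,overlap_flip optional planted pathway overlap: the
#'   named pathways copy the membership of `overlap_with` with per-row
#'   flip probability `overlap_flip` (emulating heavily overlapping
#'   catalogs).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         y0 = 0.1,
                         synergy = FALSE,
                         synergy_gain = 2,
                         anaerobe = FALSE,
                         uptake_prob = 0.85,
                         n = 2000L,
                         pathway_ids = paste0("pw", 1:6),
                         membership_prob = c(pw1 = 0.5, pw2 = 0.5, pw3 = 0.3,
                                             pw4 = 0.3, pw5 = 0.3, pw6 = 0.3),
                         beta0 = -2,
                         beta = c(pw1 = 4, pw2 = 2),
                         beta_pairs = list(`pw1&pw2` = -2),
                         overlap_with = c(pw5 = "pw1"),
                         overlap_flip = 0.2) {
  if (missing(seed)) stop_catapot("fixture_spec requires an explicit seed")
  stopifnot(y0 > 0, n >= 1, uptake_prob > 0, uptake_prob <= 1)
  structure(list(seed = as.integer(seed), y0 = y0, synergy = isTRUE(synergy),
                 synergy_gain = synergy_gain, anaerobe = isTRUE(anaerobe),
                 uptake_prob = uptake_prob, n = as.integer(n),
                 pathway_ids = pathway_ids, membership_prob = membership_prob,
                 beta0 = beta0, beta = beta, beta_pairs = beta_pairs,
                 overlap_with = overlap_with, overlap_flip = overlap_flip),
            class = "fixture_spec")
}

fixture_nutrient_defs <- function() {
  # id, name, carbons, class; complex entries carry a components string.
  defs <- rbind(
    c("glucose",      "Glucose",            6, "Sugars", ""),
    c("fructose",     "Fructose",           6, "Sugars", ""),
    c("ribose",       "Ribose",             5, "Sugars", ""),
    c("xylose",       "Xylose",             5, "Sugars", ""),
    c("gluconate",    "Gluconate",          6, "Sugar derivatives", ""),
    c("glycerol",     "Glycerol",           3, "Sugar derivatives", ""),
    c("p_ribose",     "Phospho-ribose",     5, "Sugar derivatives", ""),
    c("ala",          "Alanine",            3, "Amino acids", ""),
    c("asp",          "Aspartate",          4, "Amino acids", ""),
    c("glu",          "Glutamate",          5, "Amino acids", ""),
    c("lys",          "Lysine",             6, "Amino acids", ""),
    c("ser",          "Serine",             3, "Amino acids", ""),
    c("trp",          "Tryptophan",        11, "Amino acids", "pyruvate:1;indole:1"),
    c("putrescine",   "Putrescine",         4, "Amino acid derivatives", ""),
    c("gaba",         "4-Aminobutanoate",   4, "Amino acid derivatives", ""),
    c("butyrate",     "Butyrate",           4, "Fatty acids", ""),
    c("hexanoate",    "Hexanoate",          6, "Fatty acids", ""),
    c("octanoate",    "Octanoate",          8, "Fatty acids", ""),
    c("hydroxybut",   "3-Hydroxybutyrate",  4, "Fatty acid derivatives", ""),
    c("glyc3p",       "Glycerol 3-phosphate", 3, "Fatty acid derivatives", ""),
    c("adenine",      "Adenine",            5, "Purines", ""),
    c("guanine",      "Guanine",            5, "Purines", ""),
    c("adenosine",    "Adenosine",         10, "Purines", "ribose:1;adenine:1"),
    c("thymine",      "Thymine",            5, "Pyrimidines", ""),
    c("cytosine",     "Cytosine",           4, "Pyrimidines", ""),
    c("uracil",       "Uracil",             4, "Pyrimidines", ""),
    c("nh4",          "Ammonium",           0, "Inorganic compounds", ""),
    c("co2",          "Carbon dioxide",     1, "Inorganic compounds", ""),
    c("thiamin",      "Thiamin",           12, "Cofactors", ""),
    c("biotin",       "Biotin",            10, "Cofactors", ""),
    c("lipid_a",      "Lipid A analogue",  18, "Cell boundary", "hexanoate:2;glucose:1"),
    c("murein",       "Murein monomer",    20, "Cell boundary", ""),
    c("pyruvate",     "Pyruvate",           3, "Organic compounds", ""),
    c("citrate",      "Citrate",            6, "Organic compounds", ""),
    c("succinate",    "Succinate",          4, "Organic compounds", ""),
    c("glyoxylate",   "Glyoxylate",         2, "Organic compounds", ""),
    c("ethanol",      "Ethanol",            2, "Organic compounds", ""),
    c("indole",       "Indole",             8, "Organic compounds", ""),
    c("thymidine",    "Thymidine",         10, "Organic compounds", "p_ribose:1;thymine:1")
  )
  data.frame(id = defs[, 1], name = defs[, 2], n_carbons = as.numeric(defs[, 3]),
             class = defs[, 4], components = defs[, 5], stringsAsFactors = FALSE)
}

fixture_pathways <- function() {
  list(
    pw_cat1 = c("pyruvate", "citrate", "succinate", "glyoxylate", "ala", "asp", "glu"),
    pw_cat2 = c("ser", "gaba", "hydroxybut"),
    pw_ng1  = c("indole", "putrescine", "ethanol", "thiamin"),
    pw_mix  = c("ethanol", "citrate", "trp", "lys"),
    pw_sug  = c("glucose", "fructose", "ribose", "xylose", "gluconate", "p_ribose")
  )
}

# Planted truth for logistic-routed nutrients: membership in either of the
# two catabolic pathways decides growth, with coefficients far past the
# decision boundary so labels are deterministic.
fixture_planted_model <- function() {
  logistic_pathway_model(pathways = c("pw_cat1", "pw_cat2"),
                         beta0 = -20, beta = c(pw_cat1 = 40, pw_cat2 = 40))
}

#' Generate the synthetic nutrient catalog, pathways and organisms
#'
#' The catalog spans all twelve nutrient classes and contains four complex
#' nutrients with known effective-carbon decompositions (a
#' tryptophan-like amino acid, a thymidine-like nucleoside, an
#' adenosine-like nucleoside, and a lipid-A-like cell-boundary nutrient
#' with a multiplicity-2 component).  Four aerobic organisms cover the
#' enzyme-flag combinations: `org_a` (all gates open, training),
#' `org_b` (no purine enzyme, training), `org_c` (incomplete
#' beta-oxidation, training) and `org_d` (all gates open, held-out test
#' species).  With `spec$anaerobe`, a fifth anaerobic specialist `org_m`
#' is added.  Uptake sets are random (probability `spec$uptake_prob` per
#' nutrient) except that glucose and the minimal-medium component are
#' always transportable.
#'
#' @param spec a [fixture_spec()].
#' @return list with `catalog` (a [nutrient_catalog()]), `organisms`
#'   (named list of [organism_profile()]), and `planted_model` (the
#'   deterministic [logistic_pathway_model()] generating ground truth for
#'   logistic-routed nutrients).
#' @export
make_catalog <- function(spec) {
  defs <- fixture_nutrient_defs()
  comp <- list()
  for (i in which(nzchar(defs$components))) {
    cm <- parse_components_field(defs$components[i])
    comp[[defs$id[i]]] <- data.frame(component = cm$id, mult = cm$mult)
  }
  defs$kegg_id <- paste0("C", sprintf("%05d", seq_len(nrow(defs))))
  catalog <- nutrient_catalog(defs[c("id", "name", "kegg_id", "n_carbons", "class")],
                              fixture_pathways(), comp)
  flags <- list(org_a = c(TRUE, TRUE, TRUE),
                org_b = c(TRUE, TRUE, FALSE),
                org_c = c(TRUE, FALSE, TRUE),
                org_d = c(TRUE, TRUE, TRUE))
  training <- c(org_a = TRUE, org_b = TRUE, org_c = TRUE, org_d = FALSE)
  organisms <- with_seed(spec$seed, {
    out <- list()
    for (oid in names(flags)) {
      upt <- defs$id[runif(nrow(defs)) < spec$uptake_prob]
      upt <- union(upt, c("glucose", "nh4"))
      fl <- flags[[oid]]
      out[[oid]] <- organism_profile(oid, upt,
                                     has_ec_1_1_1_35 = fl[1],
                                     has_ec_2_3_1_16 = fl[2],
                                     has_ec_3_5_2_17 = fl[3],
                                     minimal_medium = c(nh4 = 1000),
                                     training_member = training[[oid]])
    }
    if (spec$anaerobe) {
      upt <- defs$id[defs$class %in% c("Amino acids", "Organic compounds",
                                       "Inorganic compounds")]
      out$org_m <- organism_profile("org_m", union(upt, "nh4"),
                                    minimal_medium = c(nh4 = 1000),
                                    training_member = FALSE, anaerobe = TRUE)
    }
    out
  })
  list(catalog = catalog, organisms = organisms,
       planted_model = fixture_planted_model())
}

# Ground-truth label of the decision cascade for a fixture nutrient, used
# by the network generator so that FBA growth reproduces the cascade.
fixture_truth_label <- function(nutrient, organism, catalog, gate_uptake = TRUE) {
  classify_impl(nutrient, organism, catalog, fixture_planted_model(),
                threshold = 0.5, gate_uptake = gate_uptake)$label
}

#' Build a linear toy stoichiometric network for one organism
#'
#' The network realizes the cascade's ground truth exactly: every
#' catabolizable simple nutrient gets a chain
#' `exchange -> internal pool -> C_eff x precursor`, complex nutrients get
#' a decomposition reaction into their components (with excretion drains
#' for non-catabolizable fragments), purine chains leak a 3-carbon waste,
#' and the biomass reaction converts `1/y0` precursors (plus a trace of
#' ammonium) into one unit of biomass flux.  Yields are therefore exactly
#' `y0 * C_eff` per mole for every growth-supporting nutrient.  With
#' `synergy = TRUE`, sugar and amino-acid chains release distinct cofactor
#' metabolites and a planted reaction converts one of each into
#' `synergy_gain` extra precursors, making mixed media strictly
#' super-additive while leaving single-nutrient yields untouched.
#'
#' @param fix result of [make_catalog()].
#' @param organism one of `fix$organisms`.
#' @param y0 per-carbon yield (defaults to 0.1 as in [fixture_spec()]).
#' @param synergy plant the shared-cofactor boost.
#' @param synergy_gain precursors released per cofactor pair.
#' @param atp_maintenance if positive, adds an `ATPM` drain on the
#'   precursor pool with this lower bound (for maintenance-removal
#'   studies).
#' @return a [metabolic_model()].
#' @export
make_linear_fba_model <- function(fix, organism, y0 = 0.1, synergy = FALSE,
                                  synergy_gain = 2, atp_maintenance = 0) {
  catalog <- fix$catalog
  nut <- catalog$nutrients
  rxns <- list()
  exch <- character(0)
  add <- function(id, stoich, lb = 0, ub = 1000) {
    rxns[[length(rxns) + 1L]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub)
  }
  synergy_group <- function(cls) {
    if (!synergy) return(NULL)
    if (cls == "Sugars") "E1" else if (cls == "Amino acids") "E2" else NULL
  }
  # Catabolic chain for a catabolizable simple nutrient.
  chain <- function(id) {
    row <- catalog_row(catalog, id)
    ceff <- if (row$class == "Purines") max(row$n_carbons - 3, 0) else row$n_carbons
    st <- c(-1, ceff)
    names(st) <- c(paste0("N_", id), "P")
    if (row$class == "Purines" && row$n_carbons > 3) {
      st["WASTE"] <- 1  # the 3 leaked carbons (CO2 + urea)
    }
    eg <- synergy_group(row$class)
    if (!is.null(eg)) st[eg] <- 1
    st <- st[st != 0 | names(st) == "P"]
    add(paste0("CAT_", id), st)
  }
  catabolizable <- function(id) {
    fixture_truth_label(id, organism, catalog, gate_uptake = FALSE) == "G"
  }
  needed_drain <- character(0)
  for (i in seq_len(nrow(nut))) {
    id <- nut$id[i]
    uptakeable <- id %in% organism$uptaken || nut$class[i] == "Fatty acids"
    if (uptakeable) {
      rid <- paste0("EX_", id)
      add(rid, setNames(1, paste0("N_", id)), 0, 0)  # medium opens the bound
      exch[id] <- rid
    }
    if (!uptakeable && !catabolizable(id)) next
    if (nut$is_complex[i]) {
      # Decomposition exists only when the cascade labels the parent G.
      if (fixture_truth_label(id, organism, catalog, gate_uptake = FALSE) != "G") next
      cm <- catalog$components[[id]]
      st <- setNames(c(-1, cm$mult), c(paste0("N_", id), paste0("N_", cm$component)))
      add(paste0("DEC_", id), st)
      for (cid in cm$component) {
        if (!catabolizable(cid)) needed_drain <- union(needed_drain, cid)
      }
    } else if (catabolizable(id)) {
      chain(id)
    }
  }
  # Excretion drains for non-catabolizable decomposition fragments.
  for (cid in needed_drain) add(paste0("DR_", cid), setNames(-1, paste0("N_", cid)))
  if (synergy) {
    add("DR_E1", c(E1 = -1))
    add("DR_E2", c(E2 = -1))
    add("BOOST", c(E1 = -1, E2 = -1, P = synergy_gain))
  }
  add("DR_WASTE", c(WASTE = -1))
  if (atp_maintenance > 0) add("ATPM", c(P = -1), lb = atp_maintenance, ub = 1000)
  add("BIOMASS", c(P = -1 / y0, N_nh4 = -0.01), 0, 1000)
  metabolic_model(rxns, "BIOMASS", exch)
}

#' Minimal medium of a fixture organism as an FBA medium
#' @param organism an [organism_profile()].
#' @return an [medium()].
#' @export
minimal_medium_of <- function(organism) medium(organism$minimal_medium)

#' Generate a labeled dataset with planted logistic structure
#'
#' Pathway memberships are independent Bernoulli draws per pathway (with
#' optional planted overlap: a pathway copying another's column with a
#' small flip probability), and labels are Bernoulli draws from the
#' planted logistic model.  At extreme planted coefficients the labels
#' become a deterministic function of membership.
#'
#' @param spec a [fixture_spec()]; uses `n`, `pathway_ids`,
#'   `membership_prob`, `beta0`, `beta`, `beta_pairs`, `overlap_with`,
#'   `overlap_flip`, `seed`.
#' @return a [labeled_dataset()] whose rows are synthetic nutrients
#'   `nut0001 ...` for a single pseudo-organism `simorg`.
#' @export
make_labeled_dataset <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n
    pws <- spec$pathway_ids
    memb <- matrix(0L, n, length(pws), dimnames = list(NULL, pws))
    for (pw in pws) {
      if (pw %in% names(spec$overlap_with)) next  # filled from its source below
      memb[, pw] <- as.integer(runif(n) < (spec$membership_prob[[pw]] %||% 0.3))
    }
    for (pw in names(spec$overlap_with)) {
      if (!pw %in% pws) next
      base <- memb[, spec$overlap_with[[pw]]]
      flip <- runif(n) < spec$overlap_flip
      memb[, pw] <- ifelse(flip, 1L - base, base)
    }
    eta <- spec$beta0
    for (pw in names(spec$beta)) eta <- eta + spec$beta[[pw]] * memb[, pw]
    for (key in names(spec$beta_pairs)) {
      pr <- strsplit(key, "&", fixed = TRUE)[[1]]
      eta <- eta + spec$beta_pairs[[key]] * memb[, pr[1]] * memb[, pr[2]]
    }
    y <- rbinom(n, 1, logistic(eta))
    tab <- data.frame(nutrient = sprintf("nut%04d", seq_len(n)),
                      organism = "simorg",
                      label = ifelse(y == 1, "G", "NG"),
                      stringsAsFactors = FALSE)
    rownames(memb) <- tab$nutrient
    labeled_dataset(tab, memb)
  })
}
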