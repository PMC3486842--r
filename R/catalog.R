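# Nutrient catalog: nutrient records, class labels, pathway memberships,
# complex-nutrient composition, and organism profiles, with TSV/JSON I/O.

#' The twelve nutrient classes
#'
#' Closed enumeration of structural/functional nutrient classes.  Class
#' drives hard classification rules, so unknown labels are errors, never
#' warnings.
#'
#' @format Character vector of length 12.
#' @export
NUTRIENT_CLASSES <- c(
  "Sugars", "Sugar derivatives",
  "Amino acids", "Amino acid derivatives",
  "Fatty acids", "Fatty acid derivatives",
  "Purines", "Pyrimidines",
  "Inorganic compounds", "Cofactors", "Cell boundary", "Organic compounds"
)

#' Construct a validated nutrient catalog
#'
#' @param nutrients data frame with columns `id`, `name`, `kegg_id`,
#'   `n_carbons`, `class`; one row per nutrient.
#' @param pathways named list: pathway id -> character vector of member
#'   nutrient ids.
#' @param components named list: complex nutrient id -> data frame with
#'   columns `component` (a nutrient id) and `mult` (positive integer
#'   multiplicity).  Nutrients absent from this list are simple.
#'
#' @details Validation enforces: known class labels; non-negative carbon
#'   counts; every component id resolves in the catalog; component carbons
#'   (with multiplicity) sum to at most the parent's carbon count; and
#'   pathway membership lists only known nutrients.
#'
#' @return An object of class `nutrient_catalog`.
#' @export
nutrient_catalog <- function(nutrients, pathways = list(), components = list()) {
  req <- c("id", "name", "kegg_id", "n_carbons", "class")
  miss <- setdiff(req, names(nutrients))
  if (length(miss)) stop_catapot("nutrient table lacks columns: ", paste(miss, collapse = ", "))
  nutrients <- as.data.frame(nutrients, stringsAsFactors = FALSE)
  if (anyDuplicated(nutrients$id)) stop_catapot("duplicate nutrient ids")
  bad <- setdiff(unique(nutrients$class), NUTRIENT_CLASSES)
  if (length(bad)) stop_catapot("unknown nutrient class label(s): ", paste(bad, collapse = ", "))
  if (any(nutrients$n_carbons < 0) || any(nutrients$n_carbons != round(nutrients$n_carbons))) {
    stop_catapot("n_carbons must be non-negative integers")
  }
  components <- components[vapply(components, nrow, 0L) > 0]
  for (id in names(components)) {
    if (!id %in% nutrients$id) stop_catapot("components listed for unknown nutrient: ", id)
    comp <- components[[id]]
    dangling <- setdiff(comp$component, nutrients$id)
    if (length(dangling)) {
      stop_catapot("nutrient ", id, " has dangling component reference(s): ",
                   paste(dangling, collapse = ", "))
    }
    if (any(comp$mult < 1 | comp$mult != round(comp$mult))) {
      stop_catapot("component multiplicities of ", id, " must be positive integers")
    }
    csum <- sum(comp$mult * nutrients$n_carbons[match(comp$component, nutrients$id)])
    if (csum > nutrients$n_carbons[nutrients$id == id]) {
      stop_catapot("component carbons of ", id, " (", csum,
                   ") exceed parent n_carbons")
    }
  }
  nutrients$is_complex <- nutrients$id %in% names(components)
  for (pw in names(pathways)) {
    unknown <- setdiff(pathways[[pw]], nutrients$id)
    if (length(unknown)) {
      stop_catapot("pathway ", pw, " lists nutrient(s) absent from the catalog: ",
                   paste(unknown, collapse = ", "))
    }
  }
  structure(list(nutrients = nutrients,
                 pathways = lapply(pathways, sort),
                 components = components),
            class = "nutrient_catalog")
}

#' @export
print.nutrient_catalog <- function(x, ...) {
  cat("<nutrient_catalog> ", nrow(x$nutrients), " nutrients (",
      sum(x$nutrients$is_complex), " complex), ",
      length(x$pathways), " pathways\n", sep = "")
  print(table(x$nutrients$class)[table(x$nutrients$class) > 0])
  invisible(x)
}

catalog_row <- function(catalog, id) {
  i <- match(id, catalog$nutrients$id)
  if (is.na(i)) stop_catapot("unknown nutrient id: ", id)
  catalog$nutrients[i, , drop = FALSE]
}

#' Pathway ids a nutrient belongs to
#' @param catalog a [nutrient_catalog()].
#' @param id nutrient id.
#' @return character vector of pathway ids (possibly empty).
#' @export
nutrient_pathways <- function(catalog, id) {
  names(catalog$pathways)[vapply(catalog$pathways, function(m) id %in% m, NA)]
}

#' 0/1 pathway-membership matrix for a set of nutrients
#' @param catalog a [nutrient_catalog()].
#' @param ids nutrient ids (rows of the result); defaults to all nutrients.
#' @return integer matrix, nutrients x pathways.
#' @export
membership_matrix <- function(catalog, ids = catalog$nutrients$id) {
  pws <- names(catalog$pathways)
  m <- matrix(0L, length(ids), length(pws), dimnames = list(ids, pws))
  for (pw in pws) m[, pw] <- as.integer(ids %in% catalog$pathways[[pw]])
  m
}

#' Recursively decompose a complex nutrient into simple nutrients
#'
#' Expansion proceeds until every returned nutrient is simple, preserving
#' multiplicities.  The composition graph must be a DAG; cycles are errors.
#'
#' @param id id of a complex nutrient.
#' @param catalog a [nutrient_catalog()].
#' @return data frame with columns `id` (simple nutrient) and `mult`.
#' @export
decompose <- function(id, catalog) {
  row <- catalog_row(catalog, id)
  if (!row$is_complex) stop_catapot("nutrient ", id, " is not complex")
  expand <- function(nid, mult, stack) {
    if (nid %in% stack) {
      stop_catapot("cycle in composition graph at nutrient ", nid)
    }
    i <- match(nid, catalog$nutrients$id)
    if (!catalog$nutrients$is_complex[i]) {
      return(data.frame(id = nid, mult = mult, stringsAsFactors = FALSE))
    }
    comp <- catalog$components[[nid]]
    do.call(rbind, lapply(seq_len(nrow(comp)), function(k) {
      expand(comp$component[k], mult * comp$mult[k], c(stack, nid))
    }))
  }
  out <- expand(id, 1, character(0))
  agg <- stats::aggregate(mult ~ id, out, sum)
  agg[order(agg$id), , drop = FALSE]
}

# ---- catalog I/O -----------------------------------------------------------

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

parse_components_field <- function(x) {
  toks <- split_field(x)
  if (!length(toks)) return(NULL)
  parts <- strsplit(toks, ":", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, "", 1),
             mult = vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 1, 0),
             stringsAsFactors = FALSE)
}

#' Read a nutrient catalog from TSV (or JSON) files
#'
#' The nutrient table is tab-separated with header columns `id`, `name`,
#' `kegg_id`, `n_carbons`, `class`, `pathways` (semicolon-joined pathway
#' ids), and `components` (semicolon-joined `component:multiplicity`,
#' empty for simple nutrients).  The pathway table has columns `pathway`
#' and `nutrients` (semicolon-joined).  A `.json` pair with the identical
#' schema is also accepted.  Pathway membership must agree between the two
#' files; mismatches are errors.
#'
#' @param nutrients_path,pathways_path file paths.
#' @return A [nutrient_catalog()].
#' @export
read_nutrient_catalog <- function(nutrients_path, pathways_path) {
  for (p in c(nutrients_path, pathways_path)) {
    if (!file.exists(p)) stop_catapot("file not found: ", p)
  }
  if (grepl("\\.json$", nutrients_path, ignore.case = TRUE)) {
    nut <- jsonlite::fromJSON(nutrients_path)
  } else {
    nut <- read.delim(nutrients_path, stringsAsFactors = FALSE, na.strings = NULL,
                      colClasses = "character")
    nut$n_carbons <- as.numeric(nut$n_carbons)
  }
  if (grepl("\\.json$", pathways_path, ignore.case = TRUE)) {
    pwtab <- jsonlite::fromJSON(pathways_path)
    pathways <- pwtab
    if (is.data.frame(pwtab)) {
      pathways <- setNames(lapply(pwtab$nutrients, unlist), pwtab$pathway)
    }
  } else {
    pwtab <- read.delim(pathways_path, stringsAsFactors = FALSE, na.strings = NULL,
                        colClasses = "character")
    pathways <- setNames(lapply(pwtab$nutrients, split_field), pwtab$pathway)
  }
  comp <- list()
  nut_pw <- list()
  for (i in seq_len(nrow(nut))) {
    cm <- parse_components_field(nut$components[i] %||% "")
    if (!is.null(cm)) comp[[nut$id[i]]] <- data.frame(component = cm$id, mult = cm$mult)
    nut_pw[[nut$id[i]]] <- sort(split_field(nut$pathways[i] %||% ""))
  }
  catalog <- nutrient_catalog(nut[c("id", "name", "kegg_id", "n_carbons", "class")],
                              pathways, comp)
  # Cross-check: the per-nutrient pathway column against the pathway table.
  for (id in nut$id) {
    from_pw <- sort(nutrient_pathways(catalog, id))
    if (!identical(from_pw, nut_pw[[id]])) {
      stop_catapot("pathway membership mismatch for nutrient ", id,
                   ": nutrient file says {", paste(nut_pw[[id]], collapse = ";"),
                   "}, pathway file says {", paste(from_pw, collapse = ";"), "}")
    }
  }
  catalog
}

#' Write a nutrient catalog to the TSV dialect
#'
#' Inverse of [read_nutrient_catalog()]; writing then reading reproduces the
#' catalog field-for-field.
#'
#' @param catalog a [nutrient_catalog()].
#' @inheritParams read_nutrient_catalog
#' @return `catalog`, invisibly.
#' @export
write_nutrient_catalog <- function(catalog, nutrients_path, pathways_path) {
  nut <- catalog$nutrients
  pw_col <- vapply(nut$id, function(id) paste(sort(nutrient_pathways(catalog, id)), collapse = ";"), "")
  comp_col <- vapply(nut$id, function(id) {
    cm <- catalog$components[[id]]
    if (is.null(cm)) "" else paste(sprintf("%s:%s", cm$component, fmt_num(cm$mult)), collapse = ";")
  }, "")
  out <- data.frame(id = nut$id, name = nut$name, kegg_id = nut$kegg_id,
                    n_carbons = fmt_num(nut$n_carbons), class = nut$class,
                    pathways = pw_col, components = comp_col,
                    stringsAsFactors = FALSE)
  utils::write.table(out, nutrients_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pwout <- data.frame(pathway = names(catalog$pathways),
                      nutrients = vapply(catalog$pathways, paste, "", collapse = ";"),
                      stringsAsFactors = FALSE)
  utils::write.table(pwout, pathways_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(catalog)
}

# ---- organism profiles -----------------------------------------------------

#' Construct an organism profile
#'
#' @param id species id.
#' @param uptaken character vector of nutrient ids the species transports.
#' @param has_ec_1_1_1_35,has_ec_2_3_1_16 presence of the last two
#'   beta-oxidation enzymes (together they gate fatty-acid catabolism).
#' @param has_ec_3_5_2_17 presence of 5-hydroxyisourate hydrolase (gates
#'   purine catabolism).
#' @param minimal_medium named numeric vector of uptake bounds (or bare
#'   character vector of ids, given a default bound of 1000) for the
#'   minimal medium, which on its own must not support growth.
#' @param training_member whether the species belongs to the training set.
#' @param anaerobe flag for obligate anaerobes; the yield model refuses to
#'   fit such species.
#' @param glucose_id catalog id of the organism's glucose entry (the single
#'   sugar allowed in complex media).
#' @return An object of class `organism_profile`.
#' @export
organism_profile <- function(id, uptaken,
                             has_ec_1_1_1_35 = FALSE, has_ec_2_3_1_16 = FALSE,
                             has_ec_3_5_2_17 = FALSE,
                             minimal_medium = numeric(0),
                             training_member = TRUE,
                             anaerobe = FALSE,
                             glucose_id = "glucose") {
  if (is.character(minimal_medium)) {
    minimal_medium <- setNames(rep(1000, length(minimal_medium)), minimal_medium)
  }
  structure(list(id = id, uptaken = sort(unique(uptaken)),
                 has_ec_1_1_1_35 = isTRUE(has_ec_1_1_1_35),
                 has_ec_2_3_1_16 = isTRUE(has_ec_2_3_1_16),
                 has_ec_3_5_2_17 = isTRUE(has_ec_3_5_2_17),
                 minimal_medium = minimal_medium,
                 training_member = isTRUE(training_member),
                 anaerobe = isTRUE(anaerobe),
                 glucose_id = glucose_id),
            class = "organism_profile")
}

#' @export
print.organism_profile <- function(x, ...) {
  cat("<organism_profile> ", x$id, ": ", length(x$uptaken), " uptaken nutrients; ",
      "EC1.1.1.35=", x$has_ec_1_1_1_35, " EC2.3.1.16=", x$has_ec_2_3_1_16,
      " EC3.5.2.17=", x$has_ec_3_5_2_17,
      if (x$anaerobe) " (anaerobe)" else "", "\n", sep = "")
  invisible(x)
}

#' Read organism profiles from JSON
#'
#' Accepts a single profile object or an array of them.  `minimal_medium`
#' may be an array of nutrient ids or an object of `id: bound` pairs.
#'
#' @param path JSON file path.
#' @return list of [organism_profile()] objects, named by id.
#' @export
read_organism_profiles <- function(path) {
  if (!file.exists(path)) stop_catapot("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(raw$id)) raw <- list(raw)
  profs <- lapply(raw, function(p) {
    mm <- p$minimal_medium %||% character(0)
    if (!is.null(names(mm))) mm <- unlist(mm) else mm <- as.character(unlist(mm))
    organism_profile(p$id, as.character(unlist(p$uptaken %||% character(0))),
                     p$has_ec_1_1_1_35 %||% FALSE, p$has_ec_2_3_1_16 %||% FALSE,
                     p$has_ec_3_5_2_17 %||% FALSE, mm,
                     p$training_member %||% TRUE, p$anaerobe %||% FALSE,
                     p$glucose_id %||% "glucose")
  })
  setNames(profs, vapply(profs, `[[`, "", "id"))
}

#' Write organism profiles to JSON
#' @param profiles list of [organism_profile()] objects.
#' @param path output file.
#' @return `profiles`, invisibly.
#' @export
write_organism_profiles <- function(profiles, path) {
  if (inherits(profiles, "organism_profile")) profiles <- list(profiles)
  payload <- lapply(unname(profiles), function(p) {
    list(id = p$id, uptaken = p$uptaken,
         has_ec_1_1_1_35 = p$has_ec_1_1_1_35,
         has_ec_2_3_1_16 = p$has_ec_2_3_1_16,
         has_ec_3_5_2_17 = p$has_ec_3_5_2_17,
         minimal_medium = as.list(p$minimal_medium),
         training_member = p$training_member,
         anaerobe = p$anaerobe,
         glucose_id = p$glucose_id)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(profiles)
}
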