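fix <- make_catalog(fixture_spec(seed = 31))
ctl <- fix$catalog
pm <- fix$planted_model
org <- fix$organisms$org_a
fba <- make_linear_fba_model(fix, org)
mm <- minimal_medium_of(org)
labels <- classify_all(org, ctl, pm)
g_ids <- labels$nutrient[labels$label == "G"]
meas <- data.frame(nutrient = g_ids,
                   biomass = vapply(g_ids, measure_yield, 0, model = fba,
                                    minimal_medium = mm))

test_that("sugar-reference yield averages per-carbon sugar yields", {
  small <- data.frame(nutrient = c("glucose", "ribose"),
                      biomass = c(0.10 * 6, 0.12 * 5))
  y_s <- sugar_reference_yield(small, org, ctl, labels)
  expect_equal(y_s, 0.11)
  one <- data.frame(nutrient = "glucose", biomass = 0.13 * 6)
  expect_equal(sugar_reference_yield(one, org, ctl, labels), 0.13)
  # FBA-built species with uniform per-carbon yield 0.1
  expect_equal(sugar_reference_yield(meas, org, ctl, labels), 0.1,
               tolerance = 1e-9)
  # no growth-supporting sugar: error instructing the fallback
  no_sugar <- organism_profile("ns", "nh4")
  expect_error(sugar_reference_yield(meas, no_sugar, ctl,
                                     data.frame(nutrient = "nh4", label = "NG")),
               "class yield table")
})

test_that("effective carbons follow the decomposition and purine-leak rules", {
  expect_equal(effective_carbons("thymidine", org, ctl, pm), 5)  # ribose part only
  expect_equal(effective_carbons("adenine", org, ctl, pm), 2)    # 5 - 3 leaked
  expect_equal(effective_carbons("glu", org, ctl, pm), 5)        # simple: C_i
  expect_equal(effective_carbons("adenosine", org, ctl, pm), 7)  # 5 + (5 - 3)
  expect_equal(effective_carbons("trp", org, ctl, pm), 3)        # pyruvate part only
  # complex with every component catabolizable: C_eff = C_i
  nut <- rbind(ctl$nutrients[c("id", "name", "kegg_id", "n_carbons", "class")],
               data.frame(id = "disac", name = "Disaccharide", kegg_id = "C90000",
                          n_carbons = 12, class = "Organic compounds"))
  comp <- c(ctl$components, list(disac = data.frame(component = c("glucose", "fructose"),
                                                    mult = c(1, 1))))
  ctl2 <- nutrient_catalog(nut, ctl$pathways, comp)
  expect_equal(effective_carbons("disac", org, ctl2, pm), 12)
  # multiplicity: the lipid-A analogue carries two hexanoate chains
  expect_equal(effective_carbons("lipid_a", org, ctl, pm), 2 * 6 + 6)
})

test_that("single-nutrient predictions are y_s * C_eff, zero for NG", {
  expect_equal(predict_single_nutrient("citrate", 0.11, org, ctl, pm), 0.66)
  expect_equal(predict_single_nutrient("thymine", 0.11, org, ctl, pm), 0)
  # on the linear fixture the prediction equals the FBA measurement exactly
  y_s <- sugar_reference_yield(meas, org, ctl, labels)
  for (nid in g_ids) {
    expect_equal(predict_single_nutrient(nid, y_s, org, ctl, pm),
                 meas$biomass[meas$nutrient == nid],
                 tolerance = 1e-6, info = nid)
  }
})

test_that("yield tables normalize against the sugar envelope", {
  yt <- yield_table(meas, org, ctl, labels, model = pm)
  expect_s3_class(yt, "yield_table")
  expect_equal(attr(yt, "y_s"), 0.1, tolerance = 1e-9)
  sugars <- yt[yt$class == "Sugars", ]
  expect_equal(mean(sugars$normalized_yield), 1, tolerance = 1e-9)
  expect_true(all(yt$c_eff <= yt$n_carbons))
  expect_true(all(yt$c_eff >= 0))
  # effective carbons tighten within-class spread where carbons leak
  pur <- yt[yt$class %in% c("Purines", "Organic compounds"), ]
  v_raw <- stats::var(pur$biomass / (0.1 * pur$n_carbons))
  v_eff <- stats::var(pur$biomass / (0.1 * pur$c_eff))
  expect_lte(v_eff, v_raw + 1e-12)
})

test_that("the yield model refuses anaerobic specialists", {
  fam <- make_catalog(fixture_spec(seed = 31, anaerobe = TRUE))
  expect_error(yield_table(meas, fam$organisms$org_m, fam$catalog, labels),
               "anaerobic")
})
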