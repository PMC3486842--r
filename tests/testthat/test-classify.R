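fix <- make_catalog(fixture_spec(seed = 17))
ctl <- fix$catalog
pm <- fix$planted_model

test_that("class rules fire regardless of enzymes, after the uptake gate", {
  org <- fix$organisms$org_a
  r <- classify("thymine", org, ctl, pm)
  expect_equal(r$label, "NG")
  expect_equal(r$rule, "class-rule")
  expect_true(is.na(r$probability))
  expect_equal(classify("glucose", org, ctl, pm)$label, "G")
  expect_equal(classify("thiamin", org, ctl, pm)$rule,
               if ("thiamin" %in% org$uptaken) "class-rule" else "not-uptaken")
  # not uptaken wins over everything except fatty acids
  no_uptake <- organism_profile("none", character(0), TRUE, TRUE, TRUE)
  expect_equal(classify("glucose", no_uptake, ctl, pm)$rule, "not-uptaken")
  expect_equal(classify("glucose", no_uptake, ctl, pm)$label, "NG")
})

test_that("fatty acids bypass the uptake gate and need both enzymes", {
  both <- organism_profile("b", character(0), TRUE, TRUE, FALSE)
  one <- organism_profile("o", character(0), TRUE, FALSE, FALSE)
  r <- classify("hexanoate", both, ctl, pm)
  expect_equal(r$label, "G")
  expect_equal(r$rule, "fatty-acid-enzyme")
  expect_equal(classify("hexanoate", one, ctl, pm)$label, "NG")
})

test_that("purines are gated by EC 3.5.2.17", {
  with_enz <- organism_profile("w", ctl$nutrients$id, has_ec_3_5_2_17 = TRUE)
  without <- organism_profile("wo", ctl$nutrients$id, has_ec_3_5_2_17 = FALSE)
  expect_equal(classify("adenine", with_enz, ctl, pm)$label, "G")
  r <- classify("adenine", without, ctl, pm)
  expect_equal(r$label, "NG")
  expect_equal(r$rule, "purine-enzyme")
  # the nucleoside is a purine too: same gate, before decomposition
  expect_equal(classify("adenosine", with_enz, ctl, pm)$rule, "purine-enzyme")
})

test_that("complex nutrients decompose; one catabolizable component suffices", {
  org <- organism_profile("o", ctl$nutrients$id, TRUE, TRUE, TRUE)
  r <- classify("thymidine", org, ctl, pm)
  expect_equal(r$label, "G")             # phospho-ribose part is a sugar derivative
  expect_equal(r$rule, "complex-decomposition")
  expect_equal(classify("trp", org, ctl, pm)$label, "G")  # pyruvate part
  # with the planted model, a complex of all-NG parts is NG
  nut <- rbind(ctl$nutrients[c("id", "name", "kegg_id", "n_carbons", "class")],
               data.frame(id = "dipep", name = "Dipeptide", kegg_id = "C99999",
                          n_carbons = 14, class = "Organic compounds"))
  comp <- c(ctl$components, list(dipep = data.frame(component = c("lys", "indole"),
                                                    mult = c(1, 1))))
  ctl2 <- nutrient_catalog(nut, ctl$pathways, comp)
  expect_equal(classify("dipep", organism_profile("o", nut$id), ctl2, pm)$label, "NG")
})

test_that("logistic rule fires last, with ties conservatively NG", {
  org <- organism_profile("o", ctl$nutrients$id)
  r <- classify("pyruvate", org, ctl, pm)
  expect_equal(r$rule, "logistic")
  expect_equal(r$label, "G")
  expect_gt(r$probability, 0.5)
  r2 <- classify("ethanol", org, ctl, pm)   # in no planted catabolic pathway
  expect_equal(r2$label, "NG")
  expect_lt(r2$probability, 0.5)
  # beta0 = 0 and no memberships puts the probability exactly at 0.5 -> NG
  null_model <- logistic_pathway_model(beta0 = 0)
  expect_equal(classify("ethanol", org, ctl, null_model)$label, "NG")
  # unfitted model reaching the logistic step is an error
  expect_error(classify("ethanol", org, ctl, model = NULL), "logistic")
})

test_that("labels are stable under catalog permutation and monotone in enzymes", {
  org <- fix$organisms$org_b
  base <- classify_all(org, ctl, pm)
  perm <- with(fix, {
    idx <- rev(seq_len(nrow(ctl$nutrients)))
    nutrient_catalog(ctl$nutrients[idx, c("id", "name", "kegg_id", "n_carbons", "class")],
                     ctl$pathways, ctl$components)
  })
  shuffled <- classify_all(org, perm, pm)
  expect_equal(setNames(shuffled$label, shuffled$nutrient)[base$nutrient],
               setNames(base$label, base$nutrient))
  # adding enzymes never flips G -> NG
  richer <- organism_profile(org$id, org$uptaken, TRUE, TRUE, TRUE,
                             org$minimal_medium, org$training_member)
  after <- classify_all(richer, ctl, pm)
  expect_false(any(base$label == "G" & after$label == "NG"))
})

test_that("classifier reproduces FBA ground truth on every fixture organism", {
  for (org in fix$organisms) {
    m <- make_linear_fba_model(fix, org)
    mm <- minimal_medium_of(org)
    fba <- vapply(ctl$nutrients$id, label_growth, "", model = m,
                  minimal_medium = mm)
    pred <- classify_all(org, ctl, pm)
    expect_equal(mean(pred$label == fba), 1, info = org$id)
  }
})

test_that("routing mode marks logistic-routed nutrients without a model", {
  org <- fix$organisms$org_a
  routed <- route_nutrients(org, ctl)
  expect_true(all(is.na(routed$label[routed$rule == "logistic"])))
  expect_true(all(!is.na(routed$label[routed$rule %in% c("class-rule", "not-uptaken")])))
  full <- classify_all(org, ctl, pm)
  expect_equal(routed$rule[routed$rule != "complex-decomposition"],
               full$rule[routed$rule != "complex-decomposition"])
})
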