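fix <- make_catalog(fixture_spec(seed = 47))
ctl <- fix$catalog
pm <- fix$planted_model
org <- fix$organisms$org_a
fba <- make_linear_fba_model(fix, org)
mm <- minimal_medium_of(org)
labels <- classify_all(org, ctl, pm)
g_ids <- labels$nutrient[labels$label == "G"]
meas_tab <- data.frame(nutrient = g_ids,
                       biomass = vapply(g_ids, measure_yield, 0, model = fba,
                                        minimal_medium = mm))
yt <- yield_table(meas_tab, org, ctl, labels, model = pm)
cyt <- class_yield_table(list(org_a = yt), ctl)

test_that("class yields are two-level averages over training species", {
  t1 <- yt; t2 <- yt
  t1$biomass <- 0.10 * t1$c_eff
  t2$biomass <- 0.14 * t2$c_eff
  two <- class_yield_table(list(a = t1, b = t2), ctl)
  expect_true(all(abs(two$y_c - 0.12) < 1e-12))
  one <- class_yield_table(list(a = t1), ctl)
  expect_true(all(abs(one$y_c - 0.10) < 1e-12))
  # the uniform fixture yields 0.1 per effective carbon in every class
  expect_true(all(abs(cyt$y_c - 0.1) < 1e-9))
  # pyrimidines are never G, so the class has no entry
  expect_false("Pyrimidines" %in% cyt$class)
})

test_that("media ensembles are Bernoulli draws with a glucose-only sugar slot", {
  ens <- generate_media_ensemble(ctl, p = 0.5, n_media = 1000, seed = 7)
  eligible <- attr(ens, "eligible")
  expect_true("glucose" %in% eligible)
  expect_false(any(c("fructose", "ribose", "xylose") %in% eligible))  # one sugar only
  expect_false(any(c("adenosine", "trp") %in% eligible))  # nucleobases/simple only
  sizes <- lengths(lapply(ens, `[[`, "nutrients"))
  n_el <- length(eligible)
  expect_lt(abs(mean(sizes) - n_el * 0.5), 3 * sqrt(n_el * 0.25 / 1000))
  # p -> 1 limit: everything present
  full <- generate_media_ensemble(ctl, p = 1 - 1e-12, n_media = 5, seed = 1)
  expect_true(all(vapply(full, function(m) length(m$nutrients) == n_el, NA)))
  # reproducibility: same seed, identical ensemble
  expect_identical(generate_media_ensemble(ctl, 0.5, 50, seed = 3),
                   generate_media_ensemble(ctl, 0.5, 50, seed = 3))
  expect_false(identical(generate_media_ensemble(ctl, 0.5, 50, seed = 3),
                         generate_media_ensemble(ctl, 0.5, 50, seed = 4)))
})

test_that("medium predictions are additive with NG nutrients contributing zero", {
  expect_equal(predict_medium(character(0), cyt, org, ctl, pm), 0)
  glc <- predict_medium("glucose", cyt, org, ctl, pm)
  expect_equal(glc, predict_single_nutrient("glucose", 0.1, org, ctl, pm),
               tolerance = 1e-9)
  a <- c("glucose", "ala")
  b <- c("hexanoate", "adenine")
  expect_equal(predict_medium(c(a, b), cyt, org, ctl, pm),
               predict_medium(a, cyt, org, ctl, pm) +
                 predict_medium(b, cyt, org, ctl, pm), tolerance = 1e-12)
  expect_equal(predict_medium(c("glucose", "thymine", "uracil"), cyt, org, ctl, pm),
               glc, tolerance = 1e-12)
  # a G nutrient of a class missing from the table is a named error
  cyt_no_fa <- cyt[cyt$class != "Fatty acids", ]
  expect_error(predict_medium("hexanoate", cyt_no_fa, org, ctl, pm), "hexanoate")
})

test_that("zero-synergy media reproduce the additive model exactly", {
  ens <- generate_media_ensemble(ctl, p = 0.5, n_media = 120, seed = 23)
  pred <- vapply(ens, predict_medium, 0, class_yields = cyt, organism = org,
                 catalog = ctl, model = pm)
  meas <- vapply(ens, measure_medium_biomass, 0, model_fba = fba,
                 minimal_medium = mm)
  expect_lt(max(abs(pred - meas)), 1e-6)
  v <- validate_ensemble(pred, meas)
  expect_equal(v$K, 1, tolerance = 1e-6)
  expect_equal(v$spearman_rho, 1)
})

test_that("planted synergy makes media super-additive, never the reverse", {
  syn <- make_linear_fba_model(fix, org, synergy = TRUE)
  ens <- generate_media_ensemble(ctl, p = 0.5, n_media = 120, seed = 29)
  pred <- vapply(ens, predict_medium, 0, class_yields = cyt, organism = org,
                 catalog = ctl, model = pm)
  meas <- vapply(ens, measure_medium_biomass, 0, model_fba = syn,
                 minimal_medium = mm)
  expect_true(all(meas >= pred - 1e-9))
  expect_gt(sum(meas > pred + 1e-6), 0)  # strict for glucose + amino-acid media
  # single-nutrient yields are untouched by the synergy machinery
  expect_equal(measure_yield(syn, mm, "glucose"), 0.6, tolerance = 1e-9)
  aa <- intersect(c("ala", "asp", "glu", "ser"), org$uptaken)[1]
  ci <- ctl$nutrients$n_carbons[ctl$nutrients$id == aa]
  expect_equal(measure_yield(syn, mm, aa), 0.1 * ci, tolerance = 1e-9)
})

test_that("through-origin slope and Spearman rho behave as advertised", {
  pred <- c(1, 2, 3, 4.5)
  v <- validate_ensemble(pred, 2 * pred)
  expect_equal(v$K, 0.5)
  expect_equal(v$spearman_rho, 1)
  # the closed form agrees with an independent regression fit
  set.seed(99)
  x <- runif(200, 0.5, 3); y <- 1.3 * x + rnorm(200, sd = 0.05)
  v2 <- validate_ensemble(y, x)
  k_lm <- unname(coef(lm(y ~ 0 + x)))
  expect_equal(v2$K, k_lm, tolerance = 1e-12)
  # shuffled series decorrelate
  set.seed(100)
  p1 <- runif(1000)
  v3 <- validate_ensemble(p1, sample(p1))
  expect_lt(abs(v3$spearman_rho), 0.1)
  # constant series: rho undefined, with a warning
  expect_warning(v4 <- validate_ensemble(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v4$spearman_rho))
})

test_that("planted slopes are recovered from noisy ensembles", {
  set.seed(7)
  pred <- runif(800, 0.2, 4)
  K0 <- 0.76
  measd <- pred / K0 * (1 + rnorm(800, sd = 0.01))
  v <- validate_ensemble(pred, measd)
  expect_lt(abs(v$K - K0), 0.02)
})
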