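test_that("planted coefficients are recovered at n = 2000", {
  spec <- fixture_spec(seed = 101)
  ds <- make_labeled_dataset(spec)
  fit <- fit_logistic(ds, c("pw1", "pw2"), list(c("pw1", "pw2")))
  expect_false(fit$capped)
  expect_lt(abs(fit$beta0 - spec$beta0), 0.3)
  expect_lt(abs(fit$beta[["pw1"]] - 4), 0.3)
  expect_lt(abs(fit$beta[["pw2"]] - 2), 0.3)
  expect_lt(abs(fit$beta_pairs[[1]] - (-2)), 0.45)
})

test_that("recovery error shrinks with sample size over seeded replicates", {
  err_at <- function(n, seed) {
    ds <- make_labeled_dataset(fixture_spec(seed = seed, n = n))
    fit <- fit_logistic(ds, c("pw1", "pw2"), list(c("pw1", "pw2")))
    max(abs(c(fit$beta0 - (-2), fit$beta[["pw1"]] - 4,
              fit$beta[["pw2"]] - 2, fit$beta_pairs[[1]] + 2)))
  }
  seeds <- 1:10
  e200 <- vapply(seeds, function(s) err_at(200, s), 0)
  e2000 <- vapply(seeds, function(s) err_at(2000, s), 0)
  expect_lt(median(e2000), median(e200))
})

test_that("complete separation is capped and flagged", {
  tab <- data.frame(nutrient = sprintf("n%02d", 1:40), organism = "o",
                    label = rep("G", 40))
  memb <- matrix(0L, 40, 1, dimnames = list(tab$nutrient, "pwZ"))
  ds <- labeled_dataset(tab, memb)
  fit <- fit_logistic(ds)
  expect_true(fit$capped)
  expect_equal(fit$beta0, 20, tolerance = 1e-6)
  expect_true(all(predict_logistic(fit, memb) > 0.999))
  # membership-determined labels: coefficients at the cap, labels reproduced
  memb2 <- cbind(memb, pwY = rep(0:1, 20))
  tab2 <- tab; tab2$label <- ifelse(memb2[, "pwY"] == 1, "G", "NG")
  fit2 <- fit_logistic(labeled_dataset(tab2, memb2), "pwY")
  expect_true(fit2$capped)
  p <- predict_logistic(fit2, memb2)
  expect_equal(p > 0.5, memb2[, "pwY"] == 1, ignore_attr = TRUE)
})

test_that("null effects stay small on label-independent memberships", {
  ds <- make_labeled_dataset(fixture_spec(seed = 33, beta = c(pw1 = 0),
                                          beta_pairs = list(), beta0 = 0,
                                          overlap_with = c()))
  fit <- fit_logistic(ds, "pw3")
  expect_lt(abs(fit$beta[["pw3"]]), 0.3)
})

test_that("model scores obey the closed forms", {
  # fabricate a model/dataset pair with known probabilities
  tab <- data.frame(nutrient = paste0("n", 1:8), organism = "o",
                    label = c(rep("G", 4), rep("NG", 4)))
  memb <- matrix(c(rep(1L, 4), rep(0L, 4)), 8, 1,
                 dimnames = list(tab$nutrient, "pwA"))
  ds <- labeled_dataset(tab, memb)
  mdl <- logistic_pathway_model("pwA", beta0 = -3, beta = c(pwA = 6))
  sc <- score_model(mdl, ds)
  expect_equal(sc$tp_rate, 1)
  expect_equal(sc$tn_rate, 1)
  expect_equal(sc$auc, 1)
  expect_equal(sc$k, 2)
  expect_equal(sc$n, 8)
  p <- stats::plogis(c(rep(3, 4), rep(-3, 4)))
  ll <- sum(log(c(p[1:4], 1 - p[5:8])))
  expect_equal(sc$log_likelihood, ll)
  expect_equal(sc$aic, 2 * 2 - 2 * ll)
  expect_equal(sc$bic, 2 * log(8) - 2 * ll)
})

test_that("ranked-sweep AUC equals the Mann-Whitney construction, ties included", {
  set.seed(404)
  for (rep in 1:20) {
    n <- 60
    lab <- ifelse(runif(n) < 0.4, "G", "NG")
    p <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    expect_equal(catapot:::auc_ranked_sweep(p, lab), mann_whitney_auc(p, lab))
  }
  # random ranking hovers at 1/2
  n <- 1000
  lab <- rep(c("G", "NG"), n / 2)
  p <- runif(n)
  expect_lt(abs(catapot:::auc_ranked_sweep(p, lab) - 0.5), 0.05)
  # single-class data: AUC undefined
  expect_true(is.na(catapot:::auc_ranked_sweep(runif(5), rep("G", 5))))
})

test_that("logistic models serialize to JSON and back", {
  mdl <- logistic_pathway_model(c("a", "b"), list(c("a", "b")),
                                beta0 = -1.25, beta = c(a = 2.5, b = -0.75),
                                beta_pairs = 0.5)
  path <- tempfile(fileext = ".json")
  write_logistic_model(mdl, path)
  expect_equal(read_logistic_model(path), mdl)
})
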