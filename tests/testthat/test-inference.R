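test_that("submodel enumeration covers all subsets with intact blocks", {
  expect_length(enumerate_submodels(c("a", "b", "c")), 8)
  expect_equal(enumerate_submodels(character(0)), list(character(0)))
  # the nine-block global model enumerates 512 models
  nine <- c("cites_listed", "asr_colour_grey", "log_range",
            "log_n_for_sale", "log_mass", "iucn_not_lc",
            "song_attractiveness", "status", "asr_colour_yellow")
  specs <- enumerate_submodels(nine)
  expect_length(specs, 512)
  expect_equal(length(unique(vapply(
    specs, function(s) paste(sort(s), collapse = "+"), ""))), 512)
  expect_error(enumerate_submodels(paste0("x", 1:21)), "max_blocks")
})

test_that("AICc ranking produces the textbook Akaike weights", {
  # delta = (0, 2) -> weights 1/(1+e^-1), e^-1/(1+e^-1)
  fits <- list(fake_fit(0, K = 3), fake_fit(-1, K = 3))
  set <- rank_models(fits, specs = list("a", c("a", "b")))
  expect_equal(set$models$delta, c(0, 2), tolerance = 1e-12)
  expect_equal(set$models$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-9)
  expect_equal(round(set$models$weight, 4), c(0.7311, 0.2689))

  # equal AICc -> uniform weights; delta min is 0; weights sum to 1
  fits_eq <- list(fake_fit(-5, K = 3), fake_fit(-5, K = 3),
                  fake_fit(-5, K = 3))
  set_eq <- rank_models(fits_eq, specs = list("a", "b", "c"))
  expect_equal(set_eq$models$weight, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(min(set_eq$models$delta), 0)

  # weights invariant to a constant added to every AICc (same K shift)
  fits_shift <- list(fake_fit(-10, K = 3), fake_fit(-11, K = 3))
  w1 <- rank_models(fits_shift, specs = list("a", "b"))$models$weight
  fits_shift2 <- list(fake_fit(-10 - 7, K = 3), fake_fit(-11 - 7, K = 3))
  w2 <- rank_models(fits_shift2, specs = list("a", "b"))$models$weight
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("variable importance sums weights and complements exclusion", {
  fits <- list(fake_fit(0), fake_fit(-0.5), fake_fit(-2), fake_fit(-3))
  specs <- list(c("a"), c("a", "b"), c("b"), character(0))
  set <- rank_models(fits, specs)
  w <- set$models$weight[match(c("a", "a + b", "b", "1"), set$models$terms)]
  expect_equal(variable_importance(set, "a"), w[1] + w[2], tolerance = 1e-12)
  expect_equal(variable_importance(set, "b"), w[2] + w[3], tolerance = 1e-12)
  expect_error(variable_importance(set, "zz"), "unknown")

  # complementarity: importance = 1 - summed weight of excluding models
  imp <- variable_importance(set)
  for (k in seq_len(nrow(imp))) {
    excl <- sum(set$models$weight[!vapply(
      set$specs, function(s) imp$term[k] %in% s, logical(1))])
    expect_equal(imp$importance[k], 1 - excl, tolerance = 1e-12)
  }

  # a predictor in every model has importance exactly 1
  set_all <- rank_models(list(fake_fit(0), fake_fit(-1)),
                         specs = list("a", c("a", "b")))
  expect_equal(variable_importance(set_all, "a"), 1, tolerance = 1e-12)
})

test_that("hand-weighted importance example gives 0.7", {
  # force weights (0.5, 0.2, 0.3) via AICc differences, predictor in the
  # first two models only
  # with equal K and n, weight_i is proportional to exp(loglik_i), so
  # loglik = log(target weight) forces the weights exactly
  ll <- log(c(0.5, 0.2, 0.3))
  fits <- list(fake_fit(ll[1]), fake_fit(ll[2]), fake_fit(ll[3]))
  set <- rank_models(fits, specs = list(c("p"), c("p", "q"), c("q")))
  expect_equal(variable_importance(set, "p"), 0.7, tolerance = 1e-9)
})

test_that("model averaging follows the conditional and full conventions", {
  f1 <- fake_fit(0, beta = c("(Intercept)" = 1, z = 1))
  f2 <- fake_fit(0, beta = c("(Intercept)" = 3, z = 3))
  set <- rank_models(list(f1, f2), specs = list("z", c("z", "w")))
  avg <- model_average(set)
  expect_equal(avg$estimate_conditional[avg$term == "z"], 2)
  expect_equal(avg$estimate_full[avg$term == "z"], 2)

  # single model: its own coefficients
  one <- rank_models(list(f1), specs = list("z"))
  expect_equal(model_average(one)$estimate_conditional, c(1, 1))
})

test_that("conditional average matches a brute-force weighted sum", {
  study <- build_synthetic_study(seed = 9, n_species = 60,
                                 n_trees_univariate = 2,
                                 n_trees_candidate = 1)
  tab <- transform_predictors(study$table)
  set <- dredge_pgls(tab, study$trees[[1]],
                     blocks = c("log_n_for_sale", "log_mass", "status"))
  avg <- model_average(set)
  w <- set$models$weight
  for (tm in avg$term) {
    betas <- vapply(set$fits, function(f) {
      if (tm %in% names(f$beta)) unname(f$beta[tm]) else NA_real_
    }, numeric(1))
    has <- !is.na(betas)
    expect_equal(avg$estimate_conditional[avg$term == tm],
                 sum(w[has] * betas[has]) / sum(w[has]), tolerance = 1e-10)
    expect_equal(avg$estimate_full[avg$term == tm],
                 sum(w[has] * betas[has]), tolerance = 1e-10)
  }
  expect_equal(sum(set$models$weight), 1, tolerance = 1e-9)
})

test_that("candidate flagging respects the strict delta threshold", {
  lls <- -c(0, 3.9, 4.1) / 2
  fits <- list(fake_fit(lls[1]), fake_fit(lls[2]), fake_fit(lls[3]))
  set <- candidate_set(rank_models(fits, specs = list("a", "b", "c")),
                       threshold = 4)
  expect_equal(sum(set$models$candidate), 2)
  expect_equal(attr(set, "n_candidates"), 2)
  set_all <- candidate_set(rank_models(fits, specs = list("a", "b", "c")),
                           threshold = Inf)
  expect_true(all(set_all$models$candidate))
  expect_error(candidate_set(set, threshold = 0), "positive")
})

test_that("Bonferroni calls reproduce the published colour starring", {
  calls <- bonferroni(c(0.004, 0.01, 0.001), m = 11)
  expect_equal(attr(calls, "threshold"), 0.05 / 11, tolerance = 1e-12)
  expect_equal(calls$significant, c(TRUE, FALSE, TRUE))
  one <- bonferroni(0.04, m = 1)
  expect_equal(attr(one, "threshold"), 0.05)
  expect_true(one$significant)
  expect_error(bonferroni(0.5, m = 0), "m must be")
})

test_that("dredging fixes complete cases globally and finds strong effects", {
  study <- build_synthetic_study(seed = 17, n_species = 80,
                                 n_trees_univariate = 2,
                                 n_trees_candidate = 1)
  tab <- transform_predictors(study$table)
  tab$log_mass[5] <- NA
  set <- dredge_pgls(tab, study$trees[[1]],
                     blocks = c("log_n_for_sale", "log_mass", "status",
                                "cites_listed"))
  expect_length(set$fits, 16)
  # one shared n across all submodels (fixed by the global model)
  expect_equal(unique(set$models$n), 79)
  # the designed strong predictor carries essentially all the weight
  expect_gt(variable_importance(set, "log_n_for_sale"), 0.95)
})
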