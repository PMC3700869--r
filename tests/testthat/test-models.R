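test_that("group comparison wiring: pooling t-test, ANOVA, Tukey", {
  set.seed(18)
  # equal samples give t = 0
  y <- rnorm(20)
  area <- c(y, y)
  status <- rep("solitary", 40)
  age <- rep(c("subadult", "adult"), each = 20)
  area[21:40] <- area[1:20]
  gc <- group_compare(c(area, rnorm(10, 2)),
                      c(status, rep("cub_older", 10)),
                      age_class = c(age, rep(NA, 10)))
  expect_equal(gc$t_test$statistic, 0, tolerance = 1e-12)
  expect_true(gc$t_test$pooled)
  expect_identical(gc$t_test$df, 38)

  # programmed separation at the field sample sizes: cub-of-year vs
  # cub >= 1 yr detected in most replicates
  hits <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    la <- c(rnorm(6, log10(294 / 3), 0.25), rnorm(19, log10(617), 0.25),
            rnorm(18, log10(874), 0.25))
    st <- rep(c("cub_of_year", "solitary", "cub_older"), c(6, 19, 18))
    g <- group_compare(la, st)
    pc <- g$tukey[grepl("cub_of_year", g$tukey$contrast) &
                    grepl("cub_older", g$tukey$contrast), "p adj"]
    if (pc < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("under identical group means the ANOVA P-value is uniform", {
  set.seed(19)
  ps <- vapply(1:200, function(i) {
    la <- rnorm(43, 2.5, 0.4)
    st <- rep(c("a", "b", "c"), c(6, 19, 18))
    group_compare(la, st)$anova$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("collinearity screen drops the weaker member of correlated pairs", {
  set.seed(20)
  n <- 43
  x1 <- rnorm(n)
  y <- 2 + x1 + rnorm(n, 0, 0.3)
  # duplicated covariate: r = 1, one excluded
  scr <- collinearity_screen(data.frame(x1 = x1, x2 = x1), y)
  expect_length(scr$kept, 1)
  # the kept one is the stronger univariate correlate
  x_noisy <- x1 + rnorm(n, 0, 0.4)
  scr2 <- collinearity_screen(data.frame(strong = x1, weak = x_noisy), y)
  expect_identical(scr2$kept, "strong")
  # constant covariate excluded with a warning
  expect_warning(scr3 <- collinearity_screen(
    data.frame(x1 = x1, flat = rep(1, n)), y), "constant")
  expect_identical(scr3$excluded$reason[1], "constant")
})

test_that("independent covariates survive the screen nearly always", {
  set.seed(21)
  keeps <- vapply(1:40, function(i) {
    X <- as.data.frame(matrix(rnorm(43 * 4), 43, 4))
    y <- rnorm(43)
    length(collinearity_screen(X, y)$kept)
  }, 0)
  expect_gte(mean(keeps == 4), 0.95)
})

test_that("VIF by auxiliary regression matches the R^2 identity and car", {
  set.seed(22)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- x1 + rnorm(n, 0, 0.1)    # near-duplicate: VIF > 10
  X <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- vif_scores(X)
  expect_gt(v[["x3"]], 10)
  r2 <- summary(lm(x3 ~ x1 + x2, data = X))$r.squared
  expect_equal(v[["x3"]], 1 / (1 - r2), tolerance = 1e-9)
  skip_if_not_installed("car")
  y <- rnorm(n)
  expect_equal(unname(v), unname(car::vif(lm(y ~ x1 + x2 + x3))),
               tolerance = 1e-6)
})

test_that("candidate fits follow the published parameter-count convention", {
  d <- simulate_range_table(seed = 5)
  models <- list("null model" = character(0), rs = "rs",
                 "rs+s1lsi" = c("rs", "s1lsi"),
                 "rs+s1lsi^2" = c("rs", "s1lsi", "I(s1lsi^2)"))
  set <- fit_candidates(d, models)
  rec <- set$records
  expect_identical(rec$k[rec$model == "null model"], 1L)
  expect_identical(rec$k[rec$model == "rs"], 2L)
  expect_identical(rec$k[rec$model == "rs+s1lsi"], 3L)
  expect_identical(rec$k[rec$model == "rs+s1lsi^2"], 4L)
  # the null model reports R^2 = 0
  expect_equal(rec$R2[rec$model == "null model"], 0)
  # exactly one zero Delta-AICc, weights sum to 1
  expect_identical(sum(rec$dAICc == 0), 1L)
  expect_equal(sum(rec$w), 1, tolerance = 1e-9)
  # nested models: adding a term never decreases the log-likelihood
  expect_gte(rec$logL[rec$model == "rs+s1lsi"],
             rec$logL[rec$model == "rs"] - 1e-6)
  expect_gte(rec$logL[rec$model == "rs+s1lsi^2"],
             rec$logL[rec$model == "rs+s1lsi"] - 1e-6)
  # standard counting includes the variance components
  set_std <- fit_candidates(d, models["null model"],
                            k_convention = "standard")
  expect_gt(set_std$records$k[1], 1L)
})

test_that("models built on inflated covariates are rejected by the VIF rule", {
  d <- simulate_range_table(seed = 6)
  d$s1lsi_copy <- d$s1lsi + rnorm(nrow(d), 0, 0.5)
  models <- list("rs+s1lsi" = c("rs", "s1lsi"),
                 bad = c("s1lsi", "s1lsi_copy"))
  set <- fit_candidates(d, models)
  expect_false("bad" %in% set$records$model)
})

test_that("the generating model is recovered as the top-ranked candidate", {
  models <- list("null model" = character(0), rs = "rs", s1lsi = "s1lsi",
                 s1edge = "s1edge", "rs+s1lsi" = c("rs", "s1lsi"),
                 "rs+s1edge" = c("rs", "s1edge"),
                 "s1lsi+s1edge" = c("s1lsi", "s1edge"),
                 "rs+s1edge+s1lsi" = c("rs", "s1edge", "s1lsi"))
  top <- 0L
  for (s in 1:20) {
    set <- fit_candidates(simulate_range_table(seed = s), models)
    top <- top + (set$records$model[1] == "rs+s1lsi")
  }
  expect_gte(top, 16L)
})

test_that("Akaike weights: identities and the shift invariance", {
  aw <- akaike_weights(c(10, 10))
  expect_equal(aw$w, c(0.5, 0.5))
  expect_equal(akaike_weights(100)$w, 1.0)
  a <- c(-74.01, -73.68, -72.11, -60.01)
  expect_equal(akaike_weights(a)$w, akaike_weights(a + 1000)$w,
               tolerance = 1e-12)
})

test_that("confidence sets apply the 10%-of-best-weight rule", {
  rec <- data.frame(model = c("m1", "m2", "m3"), w = c(0.99, 0.005, 0.005))
  expect_identical(confidence_set(rec)$model, "m1")
  rec2 <- data.frame(model = letters[1:4], w = rep(0.25, 4))
  expect_identical(nrow(confidence_set(rec2)), 4L)
})

test_that("importance weights sum member weights per term", {
  conf <- data.frame(model = c("rs+s1lsi", "s1lsi", "rs+s1lsi+wlsi"),
                     w = c(0.45, 0.38, 0.17))
  terms <- list("rs+s1lsi" = c("rs", "s1lsi"), "s1lsi" = "s1lsi",
                "rs+s1lsi+wlsi" = c("rs", "s1lsi", "wlsi"))
  imp <- importance_weights(conf, terms)
  expect_equal(unname(imp["s1lsi"]), 1.00)
  expect_equal(unname(imp["rs"]), 0.62)
  expect_equal(unname(imp["wlsi"]), 0.17)
  # single-model set: every contained term has importance 1
  imp1 <- importance_weights(data.frame(model = "rs+s1lsi", w = 1),
                             terms["rs+s1lsi"])
  expect_equal(unname(imp1), c(1, 1))
})

test_that("model averaging is the weight-renormalized conditional mean", {
  d <- simulate_range_table(seed = 7)
  models <- list("rs+s1lsi" = c("rs", "s1lsi"), s1lsi = "s1lsi",
                 "null model" = character(0))
  set <- fit_candidates(d, models)
  conf <- confidence_set(set, rule = 0)   # keep everything
  avg <- model_average(set, conf)
  # hand-computed weighted mean for the s1lsi coefficient
  w <- conf$w
  b <- vapply(set$fits[conf$model], function(f) {
    cf <- if (inherits(f, "merMod")) lme4::fixef(f) else coef(f)
    if ("s1lsi" %in% names(cf)) cf[["s1lsi"]] else NA_real_
  }, 0)
  has <- !is.na(b)
  expect_equal(avg$average[avg$coefficient == "s1lsi"],
               sum(w[has] * b[has]) / sum(w[has]), tolerance = 1e-9)
  # singleton set: averages equal the best model's coefficients
  avg1 <- model_average(set, set$records[set$records$model == "rs+s1lsi", ])
  expect_equal(avg1$average, avg1$best_model_value, tolerance = 1e-12)
})

test_that("the random-effect check behaves under null, signal and no repeats", {
  # no repeated animals: skipped
  d1 <- simulate_range_table(n_ranges = 20, repeat_fraction = 0, seed = 8)
  expect_identical(random_effect_check(d1, "s1lsi")$status, "skipped")
  # zero between-animal variance: rarely significant (boundary mixture null)
  ps <- vapply(1:100, function(s)
    random_effect_check(simulate_range_table(seed = s,
                                             repeat_fraction = 0.6),
                        c("rs", "s1lsi"))$p, 0)
  expect_gte(mean(ps > 0.05), 0.9)
  # strong animal effects: usually significant
  ps2 <- vapply(1:20, function(s)
    random_effect_check(simulate_range_table(seed = 50 + s, animal_sd = 0.4,
                                             repeat_fraction = 0.8),
                        c("rs", "s1lsi"))$p, 0)
  expect_gte(mean(ps2 < 0.05), 0.9)
})
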