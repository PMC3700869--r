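#' Home-range size comparison among reproductive groups
#'
#' Runs the group-level inference on log10 home-range areas: first a
#' two-sample t-test (pooled variance) comparing solitary subadults with
#' solitary adults, pooling them when P > 0.05; then a one-way ANOVA of
#' log10 area across the three reproductive statuses followed by Tukey's
#' HSD pairwise comparisons (Tukey--Kramer for unbalanced groups, which is
#' what base `TukeyHSD` computes).
#'
#' @param log10_area numeric vector of log10 areas (one per range).
#' @param status factor/character of reproductive status per range.
#' @param age_class optional `"subadult"`/`"adult"` labels for solitary
#'   ranges (others `NA`); when supplied the pooling t-test is run.
#' @param solitary_label status value denoting solitary females.
#' @return list with `t_test` (statistic, df, p, pooled), `anova`
#'   (F, df, p) and `tukey` (pairwise table).
#' @export
group_compare <- function(log10_area, status,
                          age_class = NULL, solitary_label = "solitary") {
  status <- factor(status)
  t_test <- NULL
  if (!is.null(age_class)) {
    sol <- status == solitary_label & !is.na(age_class)
    if (length(unique(age_class[sol])) == 2L) {
      tt <- stats::t.test(log10_area[sol] ~ age_class[sol], var.equal = TRUE)
      t_test <- list(statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value,
                     pooled = tt$p.value > 0.05)
    }
  }
  if (nlevels(status) < 2L) stop("need at least 2 reproductive groups")
  fit <- stats::aov(log10_area ~ status)
  an <- summary(fit)[[1]]
  tukey <- as.data.frame(stats::TukeyHSD(fit)$status)
  tukey$contrast <- rownames(tukey)
  rownames(tukey) <- NULL
  list(t_test = t_test,
       anova = list(F = an[1, "F value"],
                    df = c(an[1, "Df"], an[2, "Df"]),
                    p = an[1, "Pr(>F)"]),
       tukey = tukey[, c("contrast", "diff", "lwr", "upr", "p adj")])
}

#' Variance inflation factors by auxiliary regression
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing
#' covariate j on the remaining covariates.
#'
#' @param x data.frame or matrix of numeric covariates (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif_scores <- function(x) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2L)
  vapply(seq_along(x), function(j) {
    r2 <- summary(stats::lm(x[[j]] ~ ., data = x[-j]))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, 0) |> stats::setNames(names(x))
}

#' Collinearity screen for candidate-model covariates
#'
#' Implements the pre-modelling screen: constant covariates are dropped;
#' for every covariate pair with `|Pearson r| >= r_cut` (default 0.6) the
#' member with the weaker univariate association with the response (larger
#' univariate P) is excluded, so screened pairs never co-occur in a model.
#' VIFs of the surviving set are reported; candidate models containing any
#' covariate with VIF > `vif_cut` should be rejected (see
#' [fit_candidates()]).
#'
#' @param covars data.frame of numeric covariates.
#' @param response response used for the univariate ranking (log10 area).
#' @param r_cut correlation threshold (default 0.6).
#' @param vif_cut VIF threshold reported for downstream use (default 10).
#' @return list: `kept` (names), `excluded` (data.frame name/reason),
#'   `univariate_p`, `cor`, `vif`.
#' @export
collinearity_screen <- function(covars, response, r_cut = 0.6, vif_cut = 10) {
  covars <- as.data.frame(covars)
  excluded <- data.frame(name = character(), reason = character())
  const <- vapply(covars, function(v) stats::sd(v) < 1e-12, TRUE)
  if (any(const)) {
    warning("constant covariate(s) excluded: ",
            paste(names(covars)[const], collapse = ", "))
    excluded <- rbind(excluded, data.frame(name = names(covars)[const],
                                           reason = "constant"))
    covars <- covars[!const]
  }
  up <- vapply(covars, function(v)
    summary(stats::lm(response ~ v))$coefficients[2, 4], 0)
  keep <- names(covars)
  cm <- stats::cor(covars)
  pairs <- which(abs(cm) >= r_cut & upper.tri(cm), arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(cm[pairs]))
    for (i in ord) {
      a <- rownames(cm)[pairs[i, 1]]; b <- colnames(cm)[pairs[i, 2]]
      if (!(a %in% keep) || !(b %in% keep)) next
      drop <- if (up[a] > up[b]) a else b
      keep <- setdiff(keep, drop)
      excluded <- rbind(excluded, data.frame(
        name = drop, reason = sprintf("|r| = %.2f with %s", abs(cm[a, b]),
                                      if (drop == a) b else a)))
    }
  }
  vif <- if (length(keep) >= 2L) vif_scores(covars[keep]) else NULL
  list(kept = keep, excluded = excluded, univariate_p = up, cor = cm,
       vif = vif, vif_cut = vif_cut)
}

aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike differences and weights
#'
#' `delta_i = AICc_i - min(AICc)`; `w_i = exp(-delta_i/2) / sum_j
#' exp(-delta_j/2)`. Invariant to adding a constant to every AICc.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return list with `delta` and `w` (weights summing to 1).
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values, na.rm = TRUE)
  ew <- exp(-delta / 2)
  list(delta = delta, w = ew / sum(ew, na.rm = TRUE))
}

#' Fit a candidate set of home-range-size models
#'
#' Each candidate is a linear model of log10 home-range area on a subset
#' of the screened covariates, fit by maximum likelihood with a per-animal
#' random intercept when any animal contributes more than one range
#' (`lme4::lmer`, `REML = FALSE`, so likelihoods are comparable across
#' fixed-effect structures), otherwise by `lm`.
#'
#' Parameter counts follow the convention that reproduces the published
#' candidate tables: intercept = 1, each named term +1 (reproductive
#' status counts 1 despite its 3 levels; a quadratic term counts 1) and
#' variance components are not counted. `k_convention = "standard"`
#' instead counts every estimated parameter including the residual (and
#' random-intercept) variance. Models whose covariates include a VIF above
#' `vif_cut` are dropped, as are models with `n - k - 1 <= 0`.
#'
#' @param data data.frame with the response, covariates and `animal_id`.
#' @param models named list: model label -> character vector of terms
#'   (columns of `data`; use `"I(x^2)"` for a quadratic). The null model
#'   is an empty character vector.
#' @param response response column (default `"log10_area"`).
#' @param k_convention `"published"` (default, the table-reproducing count) or `"standard"`.
#' @param vif_cut VIF rejection threshold (default 10).
#' @return an `hr_model_set`: `records` (model, k, logL, AICc, dAICc, w,
#'   R2, sorted by AICc), `terms`, `fits`, `n`, `engine`.
#' @export
fit_candidates <- function(data, models, response = "log10_area",
                           k_convention = c("published", "standard"),
                           vif_cut = 10) {
  k_convention <- match.arg(k_convention)
  n <- nrow(data)
  mixed <- anyDuplicated(data$animal_id) > 0L
  fits <- list(); recs <- list()
  for (name in names(models)) {
    terms <- models[[name]]
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    base_cols <- intersect(unique(gsub("^I\\(|\\^2\\)$", "", terms)),
                           names(data))
    num_cols <- base_cols[vapply(base_cols, function(c)
      is.numeric(data[[c]]), TRUE)]
    if (length(num_cols) >= 2L &&
        any(vif_scores(data[num_cols]) > vif_cut)) next
    fit <- if (mixed) {
      suppressWarnings(suppressMessages(lme4::lmer(
        stats::as.formula(paste(response, "~", rhs, "+ (1 | animal_id)")),
        data = data, REML = FALSE)))
    } else {
      stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
    }
    ll <- as.numeric(stats::logLik(fit))
    k <- if (k_convention == "published") 1L + length(terms)
         else attr(stats::logLik(fit), "df")
    ic <- aicc(ll, k, n)
    if (is.na(ic)) next
    y <- data[[response]]
    # population-level predictions: R^2 measures the fixed effects, so the
    # null model scores 0 even when a random intercept is present
    fv <- if (inherits(fit, "merMod")) stats::predict(fit, re.form = NA)
          else stats::fitted(fit)
    r2 <- if (stats::sd(fv) < 1e-12) 0 else stats::cor(fv, y)^2
    fits[[name]] <- fit
    recs[[name]] <- data.frame(model = name, k = k, logL = ll, AICc = ic,
                               R2 = r2)
  }
  records <- do.call(rbind, recs)
  aw <- akaike_weights(records$AICc)
  records$dAICc <- aw$delta
  records$w <- aw$w
  records <- records[order(records$AICc),
                     c("model", "k", "logL", "AICc", "dAICc", "w", "R2")]
  rownames(records) <- NULL
  structure(list(records = records, terms = models[records$model],
                 fits = fits[records$model], n = n,
                 engine = if (mixed) "lmer (ML)" else "lm"),
            class = "hr_model_set")
}

#' @export
print.hr_model_set <- function(x, ...) {
  cat(sprintf("<hr_model_set> %d candidate(s), n = %d, %s\n",
              nrow(x$records), x$n, x$engine))
  out <- x$records
  out$logL <- round(out$logL, 2); out$AICc <- round(out$AICc, 2)
  out$dAICc <- round(out$dAICc, 1); out$w <- round(out$w, 2)
  out$R2 <- round(out$R2, 2)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Confidence set of candidate models
#'
#' The models whose Akaike weights are within `rule` (default 10%) of the
#' best model's weight: `w >= rule * max(w)`. Always contains the best
#' model.
#'
#' @param x an `hr_model_set` or a data.frame with `model` and `w`.
#' @param rule weight fraction (default 0.10).
#' @return the subset of records (data.frame), with the matching `terms`
#'   list attached as an attribute when available.
#' @export
confidence_set <- function(x, rule = 0.10) {
  records <- if (inherits(x, "hr_model_set")) x$records else x
  sel <- records$w >= rule * max(records$w)
  out <- records[sel, , drop = FALSE]
  if (inherits(x, "hr_model_set"))
    attr(out, "terms") <- x$terms[out$model]
  out
}

#' Per-term importance weights over a confidence set
#'
#' `importance(term) = sum of the Akaike weights of the confidence-set
#' models containing the term`; terms absent from every member get 0.
#' `plausibility_ratio` compares two terms' importances.
#'
#' @param conf a [confidence_set()] result (needs a `terms` attribute), or
#'   a data.frame with `model`/`w` plus `terms` as a named list argument.
#' @param terms optional named list model -> term vector (overrides the
#'   attribute).
#' @return named numeric vector of importances.
#' @export
importance_weights <- function(conf, terms = NULL) {
  terms <- terms %||% attr(conf, "terms")
  if (is.null(terms)) stop("term lists are required")
  all_terms <- unique(unlist(terms))
  vapply(all_terms, function(tm)
    sum(conf$w[vapply(conf$model, function(m) tm %in% terms[[m]], TRUE)]),
    0) |> stats::setNames(all_terms)
}

#' @rdname importance_weights
#' @param importance result of `importance_weights`.
#' @param a,b term names to compare.
#' @export
plausibility_ratio <- function(importance, a, b) {
  unname(importance[a] / importance[b])
}

#' Conditional model-averaged coefficients over a confidence set
#'
#' For every fixed-effect coefficient appearing in any confidence-set
#' member, averages the per-model estimates with the members' Akaike
#' weights renormalized over the models containing that coefficient
#' (conditional averaging), and reports sign consistency against the best
#' model.
#'
#' @param set an `hr_model_set`.
#' @param conf a [confidence_set()] of it (default: computed with the 10%
#'   rule).
#' @return data.frame with `coefficient`, `average`, `best_model_value`,
#'   `sign_consistent`.
#' @export
model_average <- function(set, conf = confidence_set(set)) {
  fits <- set$fits[conf$model]
  w <- conf$w
  coefs <- lapply(fits, function(f)
    if (inherits(f, "merMod")) lme4::fixef(f) else stats::coef(f))
  all_names <- unique(unlist(lapply(coefs, names)))
  best <- coefs[[1]]
  out <- lapply(all_names, function(nm) {
    has <- vapply(coefs, function(cf) nm %in% names(cf), TRUE)
    vals <- vapply(coefs[has], function(cf) cf[[nm]], 0)
    ww <- w[has] / sum(w[has])
    avg <- sum(ww * vals)
    data.frame(coefficient = nm, average = avg,
               best_model_value = if (nm %in% names(best)) best[[nm]] else NA,
               sign_consistent = if (nm %in% names(best))
                 sign(avg) == sign(best[[nm]]) else NA)
  })
  do.call(rbind, out)
}

#' Likelihood-ratio check of the per-animal random intercept
#'
#' Tests whether the random-intercept variance of the best model is zero
#' by comparing the mixed fit to the fixed-effects-only fit; the reference
#' distribution is the boundary mixture `0.5*chi2_0 + 0.5*chi2_1`. Both
#' fits use REML: the fixed effects are identical on both sides, and the
#' REML likelihood ratio is the better-calibrated test for a variance
#' component (the ML version is anticonservative when few animals repeat).
#' Skipped (with status `"skipped"`) when no animal contributes more than
#' one range.
#'
#' @param data model data (needs `animal_id`).
#' @param terms character vector of fixed-effect terms of the best model.
#' @param response response column.
#' @return list with `status`, `variance`, `lrt`, `p`.
#' @export
random_effect_check <- function(data, terms, response = "log10_area") {
  if (!anyDuplicated(data$animal_id))
    return(list(status = "skipped", variance = NA, lrt = NA, p = NA))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fm <- suppressWarnings(suppressMessages(lme4::lmer(
    stats::as.formula(paste(response, "~", rhs, "+ (1 | animal_id)")),
    data = data, REML = TRUE)))
  f0 <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
  lrt <- 2 * (as.numeric(stats::logLik(fm)) -
                as.numeric(stats::logLik(f0, REML = TRUE)))
  v <- as.data.frame(lme4::VarCorr(fm))
  var_animal <- v$vcov[v$grp == "animal_id"][1]
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  list(status = "tested", variance = var_animal, lrt = lrt, p = p)
}

#' Simulate a home-range-size covariate table
#'
#' Regression-level generator used to validate the model-comparison
#' machinery: draws reproductive statuses, per-range covariates with
#' realistic locations/scales, and log10 areas from a status +
#' season-1-LSI linear model with Gaussian noise. A fraction of animals
#' contribute two ranges (repeat years), optionally with a shared animal
#' effect.
#'
#' Covariate locations and scales follow the published univariate summary
#' of the field system (season-1 LSI mean 108, sd 42; edge density mean
#' 92, sd 16; proportion mean 0.37, sd 0.11); the default generating
#' coefficients (status contrasts -0.25 / +0.20 on log10 area; 0.01 per
#' LSI unit; residual sd 0.12) give a status effect and an LSI effect of
#' the strength the design presumes.
#'
#' @param n_ranges number of animal-year ranges (default 43).
#' @param repeat_fraction fraction of ranges from repeat-year animals.
#' @param status_effects named contrasts added to the intercept.
#' @param b_s1lsi LSI coefficient on log10 area.
#' @param intercept solitary-female intercept (log10 km^2).
#' @param sigma residual sd.
#' @param animal_sd sd of a shared per-animal effect (default 0: none).
#' @param seed RNG seed.
#' @return data.frame with `animal_id`, `rs`, `s1lsi`, `s1edge`,
#'   `s1prop`, `wlsi`, `shannon`, `log10_area`.
#' @export
simulate_range_table <- function(n_ranges = 43, repeat_fraction = 0.3,
                                 status_effects = c(solitary = 0,
                                                    cub_of_year = -0.25,
                                                    cub_older = 0.20),
                                 b_s1lsi = 0.01, intercept = 1.5,
                                 sigma = 0.12, animal_sd = 0, seed = 1L) {
  set.seed(seed)
  n_repeat <- round(repeat_fraction * n_ranges / 2)
  n_animals <- n_ranges - n_repeat
  ids <- sprintf("A%02d", seq_len(n_animals))
  animal <- c(ids, sample(ids, n_repeat))
  animal <- sort(animal)[seq_len(n_ranges)]
  status <- sample(names(status_effects), n_ranges, replace = TRUE,
                   prob = c(0.44, 0.14, 0.42))
  s1lsi <- pmax(stats::rnorm(n_ranges, 108, 42), 2)
  s1edge <- pmax(stats::rnorm(n_ranges, 92, 16), 1)
  s1prop <- pmin(pmax(stats::rnorm(n_ranges, 0.37, 0.11), 0.01), 0.99)
  wlsi <- pmax(stats::rnorm(n_ranges, 28, 11), 1)
  shannon <- pmin(pmax(stats::rnorm(n_ranges, 1.47, 0.20), 0.1), log(11))
  u <- stats::setNames(stats::rnorm(n_animals, 0, animal_sd), ids)
  y <- intercept + status_effects[status] + b_s1lsi * s1lsi +
    u[animal] + stats::rnorm(n_ranges, 0, sigma)
  data.frame(animal_id = animal, rs = factor(status,
               levels = names(status_effects)),
             s1lsi = s1lsi, s1edge = s1edge, s1prop = s1prop,
             wlsi = wlsi, shannon = shannon, log10_area = as.numeric(y))
}
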