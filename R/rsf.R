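#' Per-animal stratified train/test split
#'
#' Splits each animal's fixes into model-training and model-testing sets
#' following the 80:20 guideline. The training count is `ratio * n`
#' rounded half up; the split is disjoint, exhaustive and deterministic
#' under `seed`. Animals with fewer than 5 fixes contribute everything to
#' the training set, with a warning.
#'
#' @param fixes fix data.frame with `animal_id`.
#' @param ratio training fraction (default 0.80).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
train_test_split <- function(fixes, ratio = 0.80, seed = 1L) {
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_len(nrow(fixes)), fixes$animal_id),
                             function(idx) {
    n <- length(idx)
    if (n < 5L) {
      warning("animal with < 5 fixes: all assigned to training")
      return(idx)
    }
    n_train <- floor(ratio * n + 0.5)  # round half up
    sort(sample(idx, n_train))
  }), use.names = FALSE)
  list(train = fixes[sort(train_idx), , drop = FALSE],
       test = fixes[setdiff(seq_len(nrow(fixes)), train_idx), , drop = FALSE])
}

#' Sample availability points in an animal's multi-annual MCP
#'
#' Uniform random points inside the polygon at the given sampling
#' intensity (default 1 location per square kilometre), with a floor of
#' `min_points` so small ranges still contribute a usable sample.
#'
#' @param mcp a [range_polygon] of kind `"mcp100"` (or any polygon-backed
#'   range).
#' @param density points per km^2 (> 0).
#' @param min_points minimum number of points (default 30).
#' @return data.frame with `x`, `y` (and `animal_id` if the MCP carries one).
#' @export
sample_availability <- function(mcp, density = 1.0, min_points = 30L) {
  if (density <= 0) stop("sampling density must be > 0")
  if (is.null(mcp$coords) || nrow(mcp$coords) < 3L)
    stop("degenerate availability polygon")
  n <- max(round(mcp$area_km2 * density), min_points)
  pts <- runif_in_polygon(n, mcp$coords)
  out <- data.frame(x = pts[, 1], y = pts[, 2])
  if (!is.na(mcp$animal_id)) out$animal_id <- mcp$animal_id
  out
}

#' Relative selection index from a selection coefficient
#'
#' The odds-ratio magnitude `exp(|beta|)` of a cover's log-odds
#' coefficient against the water reference, reported to one decimal. For
#' avoided covers (negative coefficient) the index measures the magnitude
#' of avoidance; the "highly selected" classification therefore also
#' requires a positive coefficient (see [classify_covers()]).
#'
#' @param beta finite log-odds coefficient(s).
#' @return RSI value(s), rounded to 1 decimal.
#' @export
rsi_from_coefficient <- function(beta) {
  if (any(!is.finite(beta))) stop("beta must be finite")
  round(exp(abs(beta)), 1)
}

#' Classify covers from fitted selection effects
#'
#' Applies the three-way reclassification rule: a cover is highly
#' selected (`"h"`) iff its coefficient is positive *and* its RSI is at
#' least `threshold` (default 2.0); water is the reference (`"r"`);
#' everything else -- marginally selected or avoided -- is matrix (`"m"`).
#'
#' @param effects an effects data.frame (from [fit_rsf()]) with columns
#'   `beta`, `rsi`, `is_water`.
#' @param threshold RSI cut-off for high selection.
#' @return the data.frame with a `use_class` column.
#' @export
classify_covers <- function(effects, threshold = 2.0) {
  effects$use_class <- ifelse(effects$is_water, "r",
                       ifelse(!is.na(effects$beta) & effects$beta > 0 &
                              effects$rsi >= threshold, "h", "m"))
  effects
}

#' Fit a seasonal use-availability resource selection function
#'
#' Random-intercept logistic regression of use (1 = GPS fix) against
#' availability (0 = random point in the animal's multi-annual MCP) on
#' cover-class dummies with water as the reference level and the animal as
#' the random intercept (design III: the bear is the unit of replication).
#' Fitting goes through `lme4::glmer` (Laplace approximation); if the
#' mixed fit fails to converge an ordinary logistic fit is used and tagged
#' in `method`.
#'
#' Covers present in the data for only one response arm (complete
#' separation) are flagged and their rows dropped from the fit; covers
#' absent from the data entirely are reported with class `"m"` and a flag.
#'
#' @param used fix data.frame for the season's training split (cover codes
#'   are looked up on `raster` if absent).
#' @param available availability points with `animal_id` (e.g. pooled
#'   [sample_availability()] results).
#' @param raster the [cover_raster()].
#' @param season_id season label stored on the result.
#' @param rsi_threshold high-selection cut-off passed to [classify_covers()].
#' @param per_cover fit one univariate model per cover instead of a single
#'   multi-cover model (default FALSE).
#' @return an `rsf_fit`: `effects` table (one row per non-reference cover
#'   plus the water reference row, ranked most- to least-selected), the
#'   fitted `model`, `method`, `season_id`, `water_code`.
#' @export
fit_rsf <- function(used, available, raster, season_id = NA,
                    rsi_threshold = 2.0, per_cover = FALSE) {
  used$cover_code <- used$cover_code %||% extract_cover(raster, used$x, used$y)
  available$cover_code <- available$cover_code %||%
    extract_cover(raster, available$x, available$y)
  dat <- rbind(
    data.frame(y = 1L, animal_id = used$animal_id, code = used$cover_code),
    data.frame(y = 0L, animal_id = available$animal_id,
               code = available$cover_code))
  dat <- dat[!is.na(dat$code), , drop = FALSE]
  if (length(unique(dat$code)) < 2L)
    stop("need at least 2 covers present to fit a selection model")
  water <- raster$water_code
  # separation screen: covers observed in only one arm cannot be estimated
  arm_counts <- table(factor(dat$code, levels = raster$legend$code), dat$y)
  separated <- raster$legend$code[(arm_counts[, 1] == 0) != (arm_counts[, 2] == 0)]
  absent <- raster$legend$code[rowSums(arm_counts) == 0]
  if (water %in% c(separated, absent))
    stop("the water reference class must be present among both used and ",
         "available points")
  dat <- dat[!dat$code %in% separated, , drop = FALSE]
  estimable <- setdiff(sort(unique(dat$code)), c(separated, absent))
  dat$cover <- stats::relevel(factor(dat$code, levels = estimable),
                              ref = as.character(water))
  fit <- NULL
  method <- "glmer"
  if (!per_cover) {
    fit <- tryCatch(
      lme4::glmer(y ~ cover + (1 | animal_id), data = dat, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      fit <- suppressWarnings(
        lme4::glmer(y ~ cover + (1 | animal_id), data = dat,
                    family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE)))
      if (is.null(fit)) {
        fit <- stats::glm(y ~ cover, data = dat, family = stats::binomial())
        method <- "glm-fallback"
      } else method <- "glmer-nonconverged"
    }
    cf <- extract_cover_effects(fit)
  } else {
    method <- "per-cover glmer"
    rows <- lapply(setdiff(estimable, water), function(code) {
      sub <- dat[dat$code %in% c(code, water), , drop = FALSE]
      sub$cover <- stats::relevel(factor(sub$code), ref = as.character(water))
      m <- suppressWarnings(
        lme4::glmer(y ~ cover + (1 | animal_id), data = sub,
                    family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE)))
      extract_cover_effects(m)
    })
    cf <- do.call(rbind, rows)
    fit <- NULL
  }
  legend <- raster$legend
  eff <- data.frame(code = c(cf$code, water),
                    beta = c(cf$beta, NA), se = c(cf$se, NA))
  # unestimable covers reported flagged
  flagged <- setdiff(legend$code, c(eff$code))
  if (length(flagged))
    eff <- rbind(eff, data.frame(code = flagged, beta = NA, se = NA))
  eff$cover <- legend$label[match(eff$code, legend$code)]
  eff$is_water <- eff$code == water
  eff$z <- eff$beta / eff$se
  eff$ci_lo <- eff$beta - 1.96 * eff$se
  eff$ci_hi <- eff$beta + 1.96 * eff$se
  eff$wald <- eff$z^2
  eff$p <- 2 * stats::pnorm(-abs(eff$z))
  eff$rsi <- ifelse(is.finite(eff$beta), rsi_from_coefficient0(eff$beta), NA)
  eff$flag <- ifelse(eff$code %in% separated, "separation",
              ifelse(eff$code %in% c(absent, flagged) & !eff$is_water,
                     "absent", ""))
  eff <- classify_covers(eff, threshold = rsi_threshold)
  eff <- eff[order(eff$is_water, -ifelse(is.na(eff$beta), -Inf, eff$beta)), ]
  rownames(eff) <- NULL
  structure(list(effects = eff, model = fit, method = method,
                 season_id = season_id, water_code = water),
            class = "rsf_fit")
}

rsi_from_coefficient0 <- function(beta) round(exp(abs(beta)), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

extract_cover_effects <- function(fit) {
  sm <- if (inherits(fit, "merMod")) summary(fit)$coefficients
        else summary(fit)$coefficients
  rows <- grep("^cover", rownames(sm))
  data.frame(code = as.integer(sub("^cover", "", rownames(sm)[rows])),
             beta = sm[rows, 1], se = sm[rows, 2], row.names = NULL)
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> season %s, %s, %d covers\n",
              as.character(x$season_id), x$method, nrow(x$effects)))
  print(format_effects(x$effects), row.names = FALSE)
  invisible(x)
}

format_effects <- function(eff) {
  data.frame(cover = eff$cover, coeff = round(eff$beta, 2),
             se = round(eff$se, 2), z = round(eff$z, 2),
             ci_lo = round(eff$ci_lo, 2), ci_hi = round(eff$ci_hi, 2),
             wald = round(eff$wald, 2), p = signif(eff$p, 2),
             rsi = eff$rsi, use = eff$use_class)
}

#' Write a seasonal effects table as CSV
#' @param fit an `rsf_fit`.
#' @param path output path.
#' @export
write_effects_csv <- function(fit, path) {
  eff <- fit$effects
  out <- data.frame(cover = eff$cover, coeff = eff$beta, se = eff$se,
                    z = eff$z, ci_lo = eff$ci_lo, ci_hi = eff$ci_hi,
                    wald = eff$wald, p = eff$p, rsi = eff$rsi,
                    use_class = eff$use_class)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Reclassify a cover raster into a seasonal selection map
#'
#' Produces the three-class map used for validation and landscape metrics:
#' 1 = highly selected, 2 = matrix, 3 = water (reference). Water cells are
#' identical across seasons by construction.
#'
#' @param raster the original [cover_raster()].
#' @param fit an `rsf_fit` (or any data.frame with `code` and `use_class`).
#' @return a [cover_raster()] with codes 1/2/3 and legend h/m/r roles.
#' @export
selection_map <- function(raster, fit) {
  eff <- if (inherits(fit, "rsf_fit")) fit$effects else fit
  class_of <- stats::setNames(eff$use_class, eff$code)
  class_of[as.character(raster$water_code)] <- "r"
  code_map <- c(h = 1L, m = 2L, r = 3L)
  v <- matrix(code_map[class_of[as.character(raster$values)]],
              nrow(raster$values), ncol(raster$values))
  legend <- data.frame(code = c(1L, 2L, 3L),
                       label = c("highly selected", "matrix", "water"),
                       role = c("cover", "cover", "water"))
  cover_raster(v, cell_size = raster$cell_size, origin = raster$origin,
               legend = legend)
}

#' Manly selection ratios and the no-selection Wald test
#'
#' For each animal, `u_s` is the proportion of its (test-split) fixes on
#' highly selected cells and `a_s` the proportion of available units --
#' selection-map cells with centres inside the animal's multi-annual MCP --
#' that are highly selected; the selection ratio is `w_s = u_s / a_s`.
#' The mean ratio over animals is compared to 1 (no selection) by a Wald
#' F-test from an intercept-only regression of the per-animal ratios,
#' with (1, n-1) degrees of freedom. Animals whose MCP contains no highly
#' selected cells (`a_s = 0`) are excluded with a warning.
#'
#' @param test_fixes the season's test-split fixes (all animals).
#' @param mcps named list of [mcp()] polygons, names = animal ids.
#' @param sel_map a [selection_map()] raster.
#' @param season_id season label stored on the result.
#' @return a `selection_ratio_result`: per-animal table (`u`, `a`, `w`),
#'   `mean_w`, `F`, `df`, `p`.
#' @export
selection_ratio <- function(test_fixes, mcps, sel_map, season_id = NA) {
  ids <- intersect(names(mcps), unique(test_fixes$animal_id))
  rows <- lapply(ids, function(id) {
    fx <- test_fixes[test_fixes$animal_id == id, , drop = FALSE]
    if (!nrow(fx)) return(NULL)
    codes <- extract_cover(sel_map, fx$x, fx$y)
    u <- mean(codes == 1L, na.rm = TRUE)
    a <- mcp_class_fraction(sel_map, mcps[[id]], class_code = 1L)
    data.frame(animal_id = id, u = u, a = a,
               w = if (a > 0) u / a else NA_real_)
  })
  tab <- do.call(rbind, rows)
  drop <- is.na(tab$w)
  if (any(drop))
    warning(sum(drop), " animal(s) excluded: no highly selected cover ",
            "available in the MCP")
  tab_ok <- tab[!drop, , drop = FALSE]
  n <- nrow(tab_ok)
  if (n < 2L) stop("need at least 2 animals with defined selection ratios")
  mw <- mean(tab_ok$w)
  se <- stats::sd(tab_ok$w) / sqrt(n)
  Fstat <- ((mw - 1) / se)^2
  p <- stats::pf(Fstat, 1, n - 1, lower.tail = FALSE)
  structure(list(table = tab, mean_w = mw, se = se, F = Fstat,
                 df = c(1L, n - 1L), p = p, season_id = season_id),
            class = "selection_ratio_result")
}

#' @export
print.selection_ratio_result <- function(x, ...) {
  cat(sprintf(
    "<selection_ratio> season %s: mean w = %.2f (n = %d), F(%d,%d) = %.2f, P = %.3g\n",
    as.character(x$season_id), x$mean_w, nrow(x$table), x$df[1], x$df[2],
    x$F, x$p))
  invisible(x)
}

# fraction of raster cells with centres inside `poly` having class `class_code`
mcp_class_fraction <- function(raster, poly, class_code = 1L) {
  ring <- if (inherits(poly, "range_polygon")) poly$coords else poly
  nr <- nrow(raster$values); nc <- ncol(raster$values); cs <- raster$cell_size
  # restrict to the polygon bounding box for speed
  idx <- cell_index(raster, ring[, 1], ring[, 2])
  rr <- range(pmin(pmax(idx$row, 1L), nr))
  cc <- range(pmin(pmax(idx$col, 1L), nc))
  rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
  cx <- raster$origin[1] + (cols - 0.5) * cs
  cy <- raster$origin[2] + (nr - rows + 0.5) * cs
  gx <- rep(cx, each = length(cy))
  gy <- rep(cy, times = length(cx))
  inside <- point_in_polygon(gx, gy, ring)
  if (!any(inside)) return(0)
  vals <- raster$values[rows, cols, drop = FALSE]
  mean(as.vector(vals)[inside] == class_code, na.rm = TRUE)
}
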