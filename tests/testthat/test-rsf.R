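test_that("train/test split follows the 80:20 round-half-up arithmetic", {
  ts0 <- as.POSIXct("2003-04-01", tz = "UTC")
  mk <- function(n) data.frame(animal_id = "A", timestamp = ts0 + 3600 * (1:n),
                               x = rnorm(n), y = rnorm(n))
  sp10 <- train_test_split(mk(10), seed = 1)
  expect_identical(c(nrow(sp10$train), nrow(sp10$test)), c(8L, 2L))
  # the study's mean fix count
  sp599 <- train_test_split(mk(599), seed = 1)
  expect_identical(c(nrow(sp599$train), nrow(sp599$test)), c(479L, 120L))
  # deterministic, disjoint, exhaustive
  spA <- train_test_split(mk(100), seed = 9)
  spB <- train_test_split(mk(100), seed = 9)
  expect_identical(spA$train, spB$train)
  expect_identical(nrow(spA$train) + nrow(spA$test), 100L)
  expect_length(intersect(rownames(spA$train), rownames(spA$test)), 0)
  # tiny animals go wholly to training, with a warning
  expect_warning(sp3 <- train_test_split(mk(3), seed = 1), "< 5 fixes")
  expect_identical(nrow(sp3$train), 3L)
})

test_that("availability sampling honours density, floor and containment", {
  sq <- mcp(matrix(c(0, 0, 1e4, 0, 1e4, 1e4, 0, 1e4), ncol = 2, byrow = TRUE))
  expect_equal(sq$area_km2, 100)
  set.seed(5)
  pts <- sample_availability(sq, density = 1.0)
  expect_identical(nrow(pts), 100L)
  expect_true(all(pts$x >= 0 & pts$x <= 1e4 & pts$y >= 0 & pts$y <= 1e4))
  expect_error(sample_availability(sq, density = 0), "> 0")
  # small polygons fall back to the 30-point floor
  tiny <- mcp(matrix(c(0, 0, 1000, 0, 0, 1000), ncol = 2, byrow = TRUE))
  expect_identical(nrow(sample_availability(tiny)), 30L)
})

test_that("availability points are uniform over an L-shaped polygon", {
  L <- matrix(c(0, 0, 2, 0, 2, 1, 1, 1, 1, 2, 0, 2), ncol = 2, byrow = TRUE)
  poly <- new_range_polygon("mcp100", area_km2 = 3 / 1e6, coords = L)
  set.seed(8)
  pts <- sample_availability(poly, density = 1, min_points = 10000)
  in_box <- function(x0, x1, y0, y1)
    sum(pts$x >= x0 & pts$x < x1 & pts$y >= y0 & pts$y < y1)
  # three unit sub-squares, each should hold ~1/3 of the points
  for (b in list(c(0, 1, 0, 1), c(1, 2, 0, 1), c(0, 1, 1, 2))) {
    n <- in_box(b[1], b[2], b[3], b[4])
    expect_lt(abs(n - 10000 / 3), 3 * sqrt(10000 * (1 / 3) * (2 / 3)))
  }
})

test_that("RSI is the odds-ratio magnitude to one decimal", {
  expect_equal(rsi_from_coefficient(0), 1.0)
  expect_equal(rsi_from_coefficient(3.20), 24.5)
  expect_equal(rsi_from_coefficient(-1.71), 5.5)
  # symmetric under sign flip
  b <- c(0.3, 1.7, 2.4)
  expect_identical(rsi_from_coefficient(b), rsi_from_coefficient(-b))
  expect_error(rsi_from_coefficient(Inf), "finite")
})

test_that("cover classification needs both a positive effect and RSI >= 2", {
  eff <- data.frame(beta = c(0.78, -0.49, -2.35, NA),
                    rsi = c(2.2, 1.6, 10.4, NA),
                    is_water = c(FALSE, FALSE, FALSE, TRUE))
  out <- classify_covers(eff)
  expect_identical(out$use_class, c("h", "m", "m", "r"))
})

test_that("fitted RSF recovers a programmed +2 preference", {
  r <- shared_landscape()
  pref <- list(c("sparse vegetation" = 2))  # all else (incl. water) at 0
  spec <- movement_spec(n_animals = 20, fixes_per_animal = c(500, 700),
                        seasonal_preference = pref,
                        season_breaks = integer(0), seed = 42)
  fx <- annotate_fixes(simulate_tracks(r, spec)$fixes, r)
  mcps <- lapply(split(fx, fx$animal_id),
                 function(a) mcp(a, animal_id = a$animal_id[1]))
  set.seed(7)
  avail <- do.call(rbind, lapply(mcps, function(m) {
    p <- sample_availability(m); p$animal_id <- m$animal_id; p
  }))
  fit <- fit_rsf(fx, avail, r, season_id = 1)
  eff <- fit$effects
  b <- eff$beta[eff$cover == "sparse vegetation"]
  expect_gt(b, 0)
  expect_lt(abs(b - 2), 0.5)
  expect_identical(eff$use_class[eff$cover == "sparse vegetation"], "h")
  # internal consistency of the reported columns
  ok <- is.finite(eff$beta)
  expect_equal(eff$wald[ok], (eff$beta[ok] / eff$se[ok])^2, tolerance = 1e-9)
  expect_equal(eff$ci_hi[ok] - eff$beta[ok], 1.96 * eff$se[ok],
               tolerance = 1e-9)
  expect_equal(eff$rsi[ok], round(exp(abs(eff$beta[ok])), 1))
  assign("rsf_recovery_fit", fit, envir = .fixture_cache)
})

test_that("with zero random-intercept variance the fit matches plain logistic", {
  set.seed(31)
  n <- 4000
  code <- sample(1:3, n, TRUE)
  beta <- c(0, 1.2, -0.7)[code]
  y <- rbinom(n, 1, plogis(-0.5 + beta))
  dat_used <- data.frame(animal_id = rep(sprintf("A%d", 1:8), length.out = n),
                         x = 0, y = 0, cover_code = code)[y == 1, ]
  dat_avail <- data.frame(animal_id = rep(sprintf("A%d", 1:8), length.out = n),
                          x = 0, y = 0, cover_code = code)[y == 0, ]
  leg <- data.frame(code = 1:3, label = c("water", "a", "b"),
                    role = c("water", "cover", "cover"))
  r <- cover_raster(matrix(c(1L, 2L, 3L, 1L), 2, 2), 10, c(0, 0), leg)
  fit <- fit_rsf(dat_used, dat_avail, r)
  glmfit <- glm(c(rep(1, nrow(dat_used)), rep(0, nrow(dat_avail))) ~
                  relevel(factor(c(dat_used$cover_code, dat_avail$cover_code)),
                          "1"), family = binomial())
  expect_equal(sort(fit$effects$beta[is.finite(fit$effects$beta)]),
               sort(unname(coef(glmfit)[-1])), tolerance = 1e-3)
  # per-cover univariate fits agree with the multi-cover model here, since
  # the covers enter through disjoint dummies
  fit_uni <- fit_rsf(dat_used, dat_avail, r, per_cover = TRUE)
  expect_identical(fit_uni$method, "per-cover glmer")
  eff_m <- fit$effects[order(fit$effects$code), ]
  eff_u <- fit_uni$effects[order(fit_uni$effects$code), ]
  expect_equal(eff_u$beta[is.finite(eff_u$beta)],
               eff_m$beta[is.finite(eff_m$beta)], tolerance = 0.05)
})

test_that("separated and absent covers are flagged, not fatal", {
  leg <- data.frame(code = 1:4,
                    label = c("water", "a", "b", "ghost"),
                    role = c("water", "cover", "cover", "cover"))
  r <- cover_raster(matrix(c(1L, 2L, 3L, 1L), 2, 2), 10, c(0, 0), leg)
  set.seed(2)
  used <- data.frame(animal_id = rep(c("A", "B"), 200), x = 0, y = 0,
                     cover_code = sample(c(1L, 2L, 3L), 400, TRUE))
  avail <- data.frame(animal_id = rep(c("A", "B"), 200), x = 0, y = 0,
                      cover_code = sample(c(1L, 2L), 400, TRUE))
  # cover 3 appears only among used (separation); cover 4 never appears
  fit <- fit_rsf(used, avail, r)
  eff <- fit$effects
  expect_identical(eff$flag[eff$code == 3], "separation")
  expect_identical(eff$flag[eff$code == 4], "absent")
  expect_identical(eff$use_class[eff$code == 4], "m")
  expect_true(is.finite(eff$beta[eff$code == 2]))
})

test_that("selection maps conserve cells and keep water fixed", {
  r <- shared_landscape()
  fit <- get("rsf_recovery_fit", envir = .fixture_cache)
  smap <- selection_map(r, fit)
  expect_identical(dim(smap$values), dim(r$values))
  expect_false(anyNA(smap$values))
  expect_identical(sum(smap$values %in% 1:3), length(smap$values))
  expect_identical(unname(smap$values == 3L), unname(r$values == r$water_code))
})

test_that("selection ratios follow the u/a definition and the Wald test wiring", {
  # two animals with known u and a on a hand-built map
  leg <- data.frame(code = 1:2, label = c("water", "hot"),
                    role = c("water", "cover"))
  v <- matrix(1L, 10, 10); v[, 6:10] <- 2L   # right half 'hot'
  r <- cover_raster(v, cell_size = 10, origin = c(0, 0), legend = leg)
  eff <- data.frame(code = 1:2, use_class = c("m", "h"))
  smap <- selection_map(r, eff)
  sq <- matrix(c(0, 0, 100, 0, 100, 100, 0, 100), ncol = 2, byrow = TRUE)
  mcps <- list(A = new_range_polygon("mcp100", 1e-2, animal_id = "A",
                                     coords = sq),
               B = new_range_polygon("mcp100", 1e-2, animal_id = "B",
                                     coords = sq))
  fx <- data.frame(animal_id = rep(c("A", "B"), each = 4),
                   x = c(75, 75, 75, 25,  75, 25, 25, 25),
                   y = 50)
  sr <- selection_ratio(fx, mcps, smap)
  expect_equal(sr$table$u, c(0.75, 0.25))
  expect_equal(sr$table$a, c(0.5, 0.5))
  expect_equal(sr$table$w, c(1.5, 0.5))  # u = a -> w = 1 identity implied
  expect_equal(sr$mean_w, 1.0)
  expect_identical(sr$df, c(1L, 1L))
})

test_that("strong programmed preference yields mean w > 1 with small P", {
  r <- shared_landscape()
  hits <- 0L
  for (s in 1:5) {
    spec <- movement_spec(n_animals = 10, fixes_per_animal = c(200, 300),
                          seasonal_preference =
                            list(c("sparse vegetation" = 2,
                                   "tall shrub" = 2, "water" = -2)),
                          season_breaks = integer(0),
                          start = "2003-04-01", end = "2003-06-30",
                          seed = 760 + s)
    fxs <- annotate_fixes(simulate_tracks(r, spec)$fixes, r)
    sp <- train_test_split(fxs, seed = s)
    mcps <- lapply(split(fxs, fxs$animal_id),
                   function(a) mcp(a, animal_id = a$animal_id[1]))
    eff <- data.frame(code = r$legend$code,
                      use_class = ifelse(r$legend$label %in%
                        c("sparse vegetation", "tall shrub"), "h", "m"))
    smap <- selection_map(r, eff)
    sr <- suppressWarnings(selection_ratio(sp$test, mcps, smap))
    if (sr$mean_w > 1 && sr$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("effects tables export the published column layout", {
  fit <- get("rsf_recovery_fit", envir = .fixture_cache)
  p <- file.path(tempdir(), "effects.csv")
  write_effects_csv(fit, p)
  tab <- read.csv(p)
  expect_identical(names(tab),
                   c("cover", "coeff", "se", "z", "ci_lo", "ci_hi",
                     "wald", "p", "rsi", "use_class"))
  expect_identical(nrow(tab), nrow(fit$effects))
})
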