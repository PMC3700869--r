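test_that("the LSCV score matches a brute-force double loop", {
  set.seed(2)
  xy <- cbind(rnorm(60, sd = 1000), rnorm(60, sd = 1000))
  for (h in c(200, 500, 1200)) {
    expect_equal(lscv_score(xy, h), brute_lscv(xy, h), tolerance = 1e-10)
  }
})

test_that("the returned bandwidth minimizes the LSCV score over the grid", {
  set.seed(4)
  xy <- rbind(cbind(rnorm(250, 0, 100), rnorm(250, 0, 100)),
              cbind(rnorm(250, 5000, 100), rnorm(250, 0, 100)))
  h <- lscv_bandwidth(xy)
  expect_identical(attr(h, "method"), "lscv")
  href <- href_bandwidth(xy)
  grid <- exp(seq(log(0.05 * href), log(2 * href), length.out = 100))
  scores <- vapply(grid, function(g) lscv_score(xy, g), 0)
  expect_lte(attr(h, "score"), min(scores) + 1e-12)
})

test_that("LSCV lands near the reference bandwidth on Gaussian data", {
  set.seed(3)
  xy <- cbind(rnorm(1000, sd = 1000), rnorm(1000, sd = 1000))
  h <- as.numeric(lscv_bandwidth(xy))
  href <- href_bandwidth(xy)
  expect_gt(h, 0.5 * href)
  expect_lt(h, 1.5 * href)
})

test_that("degenerate and tiny point sets are rejected", {
  xy <- matrix(1, 40, 2)
  expect_error(lscv_bandwidth(xy, jitter = 0), "degenerate")
  expect_error(lscv_bandwidth(matrix(rnorm(20), 10, 2)), "at least 30")
})

test_that("kernel UD: unit mass, symmetry, single-fix mode", {
  set.seed(6)
  xy <- cbind(rnorm(100, sd = 500), rnorm(100, sd = 500))
  ud <- kernel_ud(xy, h = 300, cell = 10)
  expect_equal(sum(ud$density) * ud$cell^2, 1, tolerance = 1e-6)

  # single fix: density maximum at the fix's cell
  ud1 <- kernel_ud(cbind(500, 500), h = 200, cell = 20)
  peak <- which(ud1$density == max(ud1$density), arr.ind = TRUE)
  cx <- ud1$origin[1] + (peak[2] - 0.5) * ud1$cell
  cy <- ud1$origin[2] + (nrow(ud1$density) - peak[1] + 0.5) * ud1$cell
  expect_lt(abs(cx - 500), ud1$cell)
  expect_lt(abs(cy - 500), ud1$cell)

  # two symmetric fixes: density invariant under the swap
  ud2 <- kernel_ud(rbind(c(-500, 0), c(500, 0)), h = 200, cell = 25)
  expect_equal(ud2$density, ud2$density[, rev(seq_len(ncol(ud2$density)))],
               tolerance = 1e-12)
  expect_error(kernel_ud(xy, h = 300, pad = 100), "3h")
})

test_that("isopleths are minimal superlevel sets of the right mass", {
  set.seed(7)
  xy <- cbind(rnorm(150, sd = 400), rnorm(150, sd = 400))
  ud <- kernel_ud(xy, h = 250, cell = 25)
  iso <- isopleth(ud, 0.95)
  mass <- ud$density * ud$cell^2
  inside <- sum(mass[iso$cells])
  expect_gte(inside, 0.95)
  # dropping the lowest included cell takes the mass below the level
  expect_lt(inside - min(mass[iso$cells]), 0.95)
  expect_error(isopleth(ud, 1.2), "level")
  # level -> 1 recovers essentially the whole padded support
  iso99 <- isopleth(ud, 0.999)
  expect_gt(nrow(iso99$cells), nrow(iso$cells))
})

test_that("the 95% kernel area of a Gaussian matches the analytic disk", {
  h <- 1000
  ud <- kernel_ud(cbind(0, 0), h = h, cell = h / 10)
  iso <- isopleth(ud, 0.95)
  analytic <- pi * (h * sqrt(-2 * log(0.05)))^2 / 1e6
  expect_lt(abs(iso$area_km2 - analytic) / analytic, 0.05)
})

test_that("area_95 is non-decreasing in the bandwidth", {
  set.seed(8)
  xy <- cbind(rnorm(120, sd = 600), rnorm(120, sd = 600))
  areas <- vapply(c(200, 350, 500, 800, 1200), function(h)
    isopleth(kernel_ud(xy, h, cell = h / 8), 0.95)$area_km2, 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("MCP areas follow the shoelace formula", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(mcp(sq)$area_km2 * 1e6, 1.0)
  tri <- matrix(c(0, 0, 4, 0, 0, 3), ncol = 2, byrow = TRUE)
  expect_equal(mcp(tri)$area_km2 * 1e6, 6.0)
  expect_error(mcp(matrix(c(0, 0, 1, 1), 2, 2)), "at least 3")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(mcp(coll), "non-collinear")
})

test_that("MCP vertices match a brute-force extreme-point oracle", {
  set.seed(9)
  xy <- cbind(runif(500), runif(500))
  hull <- mcp(xy)
  oracle_idx <- brute_hull_vertices(xy)
  hull_pts <- apply(hull$coords, 1, paste, collapse = "_")
  oracle_pts <- apply(xy[oracle_idx, , drop = FALSE], 1, paste, collapse = "_")
  expect_setequal(hull_pts, oracle_pts)
  # every fix lies inside the (slightly grown, to dodge boundary ties) MCP
  ctr <- colMeans(hull$coords)
  grown <- t(ctr + (1 + 1e-6) * (t(hull$coords) - ctr))
  expect_true(all(point_in_polygon(xy[, 1], xy[, 2], grown)))
})

test_that("study-area filter computes exact overlap fractions", {
  unit_sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  rng <- mcp(unit_sq)
  # fully inside a bigger study area
  big <- matrix(c(-1, -1, 2, -1, 2, 2, -1, 2), ncol = 2, byrow = TRUE)
  res <- study_area_filter(rng, big)
  expect_equal(res$fraction, 1.0)
  expect_true(res$keep)
  # half-overlapping unit squares
  half <- matrix(c(0.5, 0, 1.5, 0, 1.5, 1, 0.5, 1), ncol = 2, byrow = TRUE)
  res2 <- study_area_filter(rng, half)
  expect_equal(res2$fraction, 0.5)
  expect_false(res2$keep)
  # the 60% boundary is kept (>= rule)
  sixty <- matrix(c(0.4, 0, 1.4, 0, 1.4, 1, 0.4, 1), ncol = 2, byrow = TRUE)
  res3 <- study_area_filter(rng, sixty)
  expect_equal(res3$fraction, 0.6)
  expect_true(res3$keep)
  # empty intersection reports fraction 0
  far <- matrix(c(5, 5, 6, 5, 6, 6, 5, 6), ncol = 2, byrow = TRUE)
  expect_equal(study_area_filter(rng, far)$fraction, 0)
})

test_that("log10 transform preserves the ordering of areas", {
  areas <- c(12, 294, 617, 874, 2000)
  expect_identical(order(log10(areas)), order(areas))
})

test_that("range polygons serialize to GeoJSON", {
  tri <- mcp(matrix(c(0, 0, 4, 0, 0, 3), ncol = 2, byrow = TRUE),
             animal_id = "A")
  p <- file.path(tempdir(), "poly.geojson")
  write_polygons_geojson(tri, p)
  gj <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_identical(gj$type, "FeatureCollection")
  expect_identical(gj$features[[1]]$geometry$type, "Polygon")
  expect_equal(gj$features[[1]]$properties$area_km2, tri$area_km2)
})
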