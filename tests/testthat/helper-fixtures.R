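# Shared fixtures, built in code. The heavier simulated objects are
# memoized so several test files can reuse one realization.

two_class_legend <- function() {
  data.frame(code = 1:2, label = c("water", "veg"),
             role = c("water", "cover"))
}

# tiny deterministic raster with a known checkerboard pattern
checkerboard_raster <- function(n = 8, cell = 10) {
  v <- matrix(1L + (outer(seq_len(n), seq_len(n), "+") %% 2L), n, n)
  cover_raster(v, cell_size = cell, origin = c(0, 0),
               legend = two_class_legend())
}

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the default study landscape at test scale
shared_landscape <- function() {
  memoize("landscape", generate_landscape(
    landscape_spec(n_rows = 256, n_cols = 256, aggregation = 6, seed = 3)))
}

# one default-conditions track simulation (30 animals, 3 seasonal regimes)
shared_tracks <- function() {
  memoize("tracks", {
    sim <- simulate_tracks(shared_landscape(), movement_spec(seed = 301))
    sim$fixes <- annotate_fixes(sim$fixes, shared_landscape())
    sim
  })
}

# no-preference simulation used by several null-behaviour tests
flat_preference <- function(weight = 0) list(c("water" = weight))

flat_tracks <- function(n_animals = 10, seed = 901) {
  key <- sprintf("flat_%d_%d", n_animals, seed)
  memoize(key, {
    spec <- movement_spec(n_animals = n_animals,
                          fixes_per_animal = c(300, 500),
                          seasonal_preference = flat_preference(),
                          season_breaks = integer(0),
                          start = "2003-04-01", end = "2003-07-31",
                          seed = seed)
    sim <- simulate_tracks(shared_landscape(), spec)
    sim$fixes <- annotate_fixes(sim$fixes, shared_landscape())
    sim
  })
}

# brute-force 4-neighbour edge-length oracle (cell-by-cell loop)
brute_edge_length <- function(v, code, cs, boundary = TRUE) {
  e <- 0L; nr <- nrow(v); nc <- ncol(v)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j]) || v[i, j] != code) next
    for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + sh[1]; jj <- j + sh[2]
      out <- ii < 1L || ii > nr || jj < 1L || jj > nc
      if (out || is.na(v[ii, jj])) {
        if (boundary) e <- e + 1L
      } else if (v[ii, jj] != code) e <- e + 1L
    }
  }
  e * cs
}

# brute-force double-loop LSCV score (independent of the package's
# pairwise-distance implementation)
brute_lscv <- function(xy, h) {
  n <- nrow(xy)
  int <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    int <- int + exp(-sum((xy[i, ] - xy[j, ])^2) / (4 * h^2)) / (4 * pi * h^2)
  int <- int / n^2
  loo <- 0
  for (i in seq_len(n)) {
    fi <- 0
    for (j in seq_len(n)) if (j != i)
      fi <- fi + exp(-sum((xy[i, ] - xy[j, ])^2) / (2 * h^2)) / (2 * pi * h^2)
    loo <- loo + fi / (n - 1)
  }
  int - 2 * loo / n
}

# brute-force extreme-point convex hull oracle: a point is a hull vertex
# iff some ordered pair of other points has every point on one side and
# the point on the boundary line through them... simpler: for every pair
# (i, j), if all points lie on one side of the line i->j, both ends are
# hull vertices.
brute_hull_vertices <- function(xy) {
  n <- nrow(xy)
  on_hull <- logical(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- xy[j, ] - xy[i, ]
    s <- (xy[, 1] - xy[i, 1]) * d[2] - (xy[, 2] - xy[i, 2]) * d[1]
    if (all(s <= 1e-9) || all(s >= -1e-9)) on_hull[c(i, j)] <- TRUE
  }
  which(on_hull)
}
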