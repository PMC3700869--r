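#' Range polygons: minimum convex polygons and kernel isopleths
#'
#' A `range_polygon` represents one animal-level range outline: either the
#' 100% minimum convex polygon of its fixes (`kind = "mcp100"`) or a kernel
#' utilization-distribution isopleth (`kind = "kernel95"`). MCPs carry an
#' explicit vertex ring; kernel isopleths are unions of evaluation-grid
#' cells and carry the cell set plus grid geometry, which keeps their areas
#' and clips exact (no smoothing).
#'
#' @name range_polygon
NULL

new_range_polygon <- function(kind, area_km2, animal_id = NA, years = NA,
                              coords = NULL, cells = NULL, grid = NULL,
                              level = NA_real_) {
  structure(list(kind = kind, coords = coords, cells = cells, grid = grid,
                 area_km2 = area_km2, animal_id = animal_id, years = years,
                 level = level),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("<range_polygon> %s, area %.2f km2", x$kind, x$area_km2))
  if (!is.na(x$animal_id)) cat(", animal", x$animal_id)
  cat("\n")
  invisible(x)
}

# signed shoelace area (m^2); positive for counter-clockwise rings
signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

shoelace_area <- function(xy) abs(signed_area(xy))

ensure_ccw <- function(xy) if (signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy

# even-odd ray casting, vectorized over points; polygon an open ring matrix
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clipping of `subject` by a convex `clip` polygon.
# Both are open rings; returns the clipped ring (possibly 0 rows).
convex_clip <- function(subject, clip) {
  clip <- ensure_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    # inside = left of directed edge a->b
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(inp)
    sprev <- side(inp[n, ])
    prev <- inp[n, ]
    for (i in seq_len(n)) {
      cur <- inp[i, ]; scur <- side(cur)
      if (scur >= 0) {
        if (sprev < 0) {
          t <- sprev / (sprev - scur)
          out <- rbind(out, prev + t * (cur - prev))
        }
        out <- rbind(out, cur)
      } else if (sprev >= 0) {
        t <- sprev / (sprev - scur)
        out <- rbind(out, prev + t * (cur - prev))
      }
      prev <- cur; sprev <- scur
    }
  }
  out
}

#' 100% minimum convex polygon of an animal's fixes
#'
#' Convex hull of all fix coordinates, with area by the shoelace formula.
#' The "multi-annual" MCP of the selection analysis is simply the MCP of
#' all of an animal's fixes pooled across years.
#'
#' @param fixes a fix table (data.frame with `x`, `y`), or a two-column
#'   coordinate matrix.
#' @param animal_id optional id stored on the result.
#' @return a [range_polygon] of kind `"mcp100"`.
#' @export
mcp <- function(fixes, animal_id = NA) {
  xy <- if (is.matrix(fixes)) fixes else cbind(fixes$x, fixes$y)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 3L) stop("mcp needs at least 3 fixes")
  h <- grDevices::chull(xy[, 1], xy[, 2])
  ring <- xy[h, , drop = FALSE]
  a <- shoelace_area(ring)
  if (a <= 0) stop("mcp needs at least 3 non-collinear fixes")
  new_range_polygon("mcp100", area_km2 = a / 1e6, animal_id = animal_id,
                    coords = ensure_ccw(ring))
}

#' Study-area inclusion filter
#'
#' Computes the fraction of a range polygon lying inside the study-area
#' polygon and applies the inclusion rule: an animal is kept for the
#' selection analyses only if at least `threshold` (default 60%) of its
#' range falls inside the study area. The boundary case sits on the keep
#' side (`>=`).
#'
#' MCP ranges are intersected exactly (convex-convex clipping); cell-based
#' kernel ranges are intersected by counting cells whose centres fall in
#' the study area.
#'
#' @param range a [range_polygon].
#' @param study_area an open-ring matrix of study-area vertices (convex),
#'   or a `range_polygon` whose `coords` are used.
#' @param threshold minimum inside fraction to keep (default 0.60).
#' @return list with `fraction` and `keep`.
#' @export
study_area_filter <- function(range, study_area, threshold = 0.60) {
  sa <- if (inherits(study_area, "range_polygon")) study_area$coords else study_area
  if (is.null(sa) || nrow(sa) < 3L) stop("invalid study-area polygon")
  if (!is.null(range$coords)) {
    inter <- convex_clip(range$coords, sa)
    ia <- if (nrow(inter) >= 3L) shoelace_area(inter) else 0
    frac <- ia / (range$area_km2 * 1e6)
  } else if (!is.null(range$cells)) {
    g <- range$grid
    cx <- g$origin[1] + (range$cells[, "col"] - 0.5) * g$cell_size
    cy <- g$origin[2] + (g$nrow - range$cells[, "row"] + 0.5) * g$cell_size
    frac <- mean(point_in_polygon(cx, cy, sa))
  } else stop("range polygon carries neither coords nor cells")
  frac <- min(max(frac, 0), 1)
  list(fraction = frac, keep = frac >= threshold)
}

# uniform random points inside a polygon by bounding-box rejection
runif_in_polygon <- function(n, poly) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_polygon(px, py, poly)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Write range polygons to GeoJSON
#'
#' MCPs become Polygon features; cell-based kernel isopleths become
#' MultiPolygon features made of their constituent grid cells.
#'
#' @param polys a `range_polygon` or list of them.
#' @param path output file.
#' @export
write_polygons_geojson <- function(polys, path) {
  if (inherits(polys, "range_polygon")) polys <- list(polys)
  feat <- lapply(polys, function(p) {
    props <- list(kind = p$kind, area_km2 = p$area_km2,
                  animal_id = p$animal_id)
    if (!is.null(p$coords)) {
      ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
      geom <- list(type = "Polygon",
                   coordinates = list(lapply(seq_len(nrow(ring)),
                                             function(i) unname(ring[i, ]))))
    } else {
      g <- p$grid; cs <- g$cell_size
      cells <- p$cells
      x0 <- g$origin[1] + (cells[, "col"] - 1) * cs
      y0 <- g$origin[2] + (g$nrow - cells[, "row"]) * cs
      geom <- list(type = "MultiPolygon",
                   coordinates = lapply(seq_len(nrow(cells)), function(i) {
                     xs <- x0[i]; ys <- y0[i]
                     list(list(c(xs, ys), c(xs + cs, ys), c(xs + cs, ys + cs),
                               c(xs, ys + cs), c(xs, ys)))
                   }))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
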