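#' Clip a raster to a range polygon
#'
#' Retains the cells whose centres fall inside the range (an MCP ring or a
#' kernel isopleth cell set); everything else is masked to `NA`. This is
#' the "within each bear's annual kernel home range" operation every
#' landscape metric runs on.
#'
#' @param raster a [cover_raster()] (cover map or selection map).
#' @param range a [range_polygon], or an open-ring vertex matrix.
#' @return the masked [cover_raster()].
#' @export
clip_raster <- function(raster, range) {
  nr <- nrow(raster$values); nc <- ncol(raster$values); cs <- raster$cell_size
  cx <- raster$origin[1] + (seq_len(nc) - 0.5) * cs
  cy <- raster$origin[2] + (nr - seq_len(nr) + 0.5) * cs
  gx <- rep(cx, each = nr)   # column-major order to match as.vector
  gy <- rep(cy, times = nc)
  if (is.matrix(range) || !is.null(range$coords)) {
    ring <- if (is.matrix(range)) range else range$coords
    keep <- point_in_polygon(gx, gy, ring)
  } else if (!is.null(range$cells)) {
    g <- range$grid
    member <- matrix(FALSE, g$nrow, g$ncol)
    member[range$cells] <- TRUE
    kc <- floor((gx - g$origin[1]) / g$cell_size) + 1L
    kr <- g$nrow - floor((gy - g$origin[2]) / g$cell_size)
    ok <- kc >= 1L & kc <= g$ncol & kr >= 1L & kr <= g$nrow
    keep <- logical(length(gx))
    keep[ok] <- member[cbind(kr[ok], kc[ok])]
  } else stop("range carries neither coords nor cells")
  if (!any(keep)) stop("empty clip: no cell centre falls inside the range")
  v <- raster$values
  v[!keep] <- NA_integer_
  out <- raster
  out$values <- v
  out
}

#' Proportion of unmasked cells in a class
#'
#' @param masked a (possibly clipped) [cover_raster()].
#' @param class_code integer class code.
#' @return fraction in `[0, 1]`.
#' @export
class_proportion <- function(masked, class_code) {
  v <- as.vector(masked$values)
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty clip")
  mean(v == class_code)
}

# total length (m) of 4-neighbour edge for a class. An edge segment is a
# cell side between a class cell and either a different class, a masked
# cell, or the landscape boundary (the latter two only when
# `boundary_edges`).
class_edge_length <- function(masked, class_code, boundary_edges = TRUE) {
  v <- masked$values
  isc <- !is.na(v) & v == class_code
  if (!any(isc)) return(0)
  nr <- nrow(v); nc <- ncol(v)
  pad <- matrix(NA_integer_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- v
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  edges <- 0L
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pad[2:(nr + 1L) + sh[1], 2:(nc + 1L) + sh[2]]
    differs <- if (boundary_edges) (is.na(nb) | nb != class_code)
               else (!is.na(nb) & nb != class_code)
    edges <- edges + sum(isc & differs, na.rm = TRUE)
  }
  edges * masked$cell_size
}

#' Landscape shape index of a class
#'
#' `LSI = 0.25 * E / sqrt(A)` with `E` the total class edge length and `A`
#' the class area, the standardized perimeter-to-area ratio: 1 for a
#' single compact square patch, growing as the class becomes patchy and
#' dispersed. Adjacency is 4-neighbour (rook); edges against the clip
#' boundary count by default (`boundary_edges`).
#'
#' @param masked a (clipped) [cover_raster()].
#' @param class_code integer class code.
#' @param boundary_edges count clip/landscape boundary as edge (default
#'   TRUE).
#' @return dimensionless LSI >= 1, or `NA` if the class is absent.
#' @export
landscape_shape_index <- function(masked, class_code, boundary_edges = TRUE) {
  area <- sum(masked$values == class_code, na.rm = TRUE) * masked$cell_size^2
  if (area == 0) return(NA_real_)
  e <- class_edge_length(masked, class_code, boundary_edges)
  0.25 * e / sqrt(area)
}

#' Edge density of a class
#'
#' Total class edge length divided by the clip area, in metres per
#' hectare.
#'
#' @inheritParams landscape_shape_index
#' @return m/ha; 0 if the class is absent.
#' @export
edge_density <- function(masked, class_code, boundary_edges = TRUE) {
  n_cells <- sum(!is.na(masked$values))
  if (!n_cells) stop("empty clip")
  e <- class_edge_length(masked, class_code, boundary_edges)
  area_ha <- n_cells * masked$cell_size^2 / 1e4
  e / area_ha
}

#' Shannon-Wiener diversity of a clip
#'
#' `H = -sum(p_i * log(p_i))` in nats over the classes present in the
#' unmasked cells; 0 for a single class, at most `log(k)` for `k` classes.
#'
#' @param masked a (clipped) [cover_raster()].
#' @return H in nats.
#' @export
shannon_diversity <- function(masked) {
  p <- raster_proportions(masked)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Landscape covariates inside one annual home range
#'
#' Assembles one row of the home-range-size covariate table: per-season
#' proportional amount, landscape shape index and edge density of highly
#' selected cover (class 1 of each season's selection map), landscape
#' shape index and edge density of water, Shannon-Wiener diversity of the
#' original covers, and the log10 home-range area.
#'
#' @param cover the original [cover_raster()].
#' @param sel_maps list of seasonal [selection_map()] rasters (one per
#'   season, in season order).
#' @param range the animal-year's kernel [range_polygon].
#' @param animal_id,year,status identifiers carried into the row.
#' @return one-row data.frame with columns `animal_id`, `year`, `rs`,
#'   `s<i>prop`, `s<i>lsi`, `s<i>edge` per season, `wlsi`, `wedge`,
#'   `shannon`, `hr_area_km2`, `log10_area`.
#' @export
range_metrics <- function(cover, sel_maps, range, animal_id = NA,
                          year = NA, status = NA) {
  clip_cov <- clip_raster(cover, range)
  row <- data.frame(animal_id = animal_id, year = year, rs = status)
  for (s in seq_along(sel_maps)) {
    m <- clip_raster(sel_maps[[s]], range)
    row[[sprintf("s%dprop", s)]] <- class_proportion(m, 1L)
    row[[sprintf("s%dlsi", s)]] <- landscape_shape_index(m, 1L)
    row[[sprintf("s%dedge", s)]] <- edge_density(m, 1L)
  }
  row$wlsi <- landscape_shape_index(clip_cov, cover$water_code)
  row$wedge <- edge_density(clip_cov, cover$water_code)
  row$shannon <- shannon_diversity(clip_cov)
  row$hr_area_km2 <- range$area_km2
  row$log10_area <- log10(range$area_km2)
  row
}
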