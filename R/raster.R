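#' Categorical cover raster
#'
#' A regular grid of integer cover-class codes on a planar (projected,
#' metre-unit) coordinate system. This is the landscape object every other
#' stage of the pipeline queries: fix annotation, selection-map
#' reclassification and landscape metrics all index into it.
#'
#' The grid follows the usual raster convention: `values` is an integer
#' matrix whose first row is the northernmost row; `origin` is the
#' lower-left *outer* corner of the grid. Cells are half-open,
#' `[x0 + i*c, x0 + (i+1)*c)` in both axes, so a point lying exactly on a
#' shared edge belongs to the cell on the +x / +y side.
#'
#' @param values integer matrix of class codes (row 1 = top/north row).
#' @param cell_size cell edge length in metres (scalar > 0).
#' @param origin numeric length-2, `(x0, y0)` of the lower-left corner.
#' @param legend data.frame with columns `code` (integer), `label`
#'   (character) and `role` (`"cover"` or `"water"`); exactly one row must
#'   have role `"water"`.
#' @return An object of class `cover_raster`.
#' @examples
#' leg <- data.frame(code = 1:2, label = c("water", "shrub"),
#'                   role = c("water", "cover"))
#' r <- cover_raster(matrix(c(1L, 2L, 2L, 1L), 2, 2), cell_size = 28.5,
#'                   origin = c(0, 0), legend = leg)
#' r
#' @export
cover_raster <- function(values, cell_size, origin = c(0, 0), legend) {
  if (!is.matrix(values)) stop("`values` must be a matrix of class codes")
  storage.mode(values) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive scalar (metres)")
  if (length(origin) != 2L || anyNA(origin))
    stop("`origin` must be numeric length 2")
  legend <- as.data.frame(legend)
  req <- c("code", "label", "role")
  if (!all(req %in% names(legend)))
    stop("legend needs columns code, label, role")
  if (anyDuplicated(legend$code)) stop("duplicated codes in legend")
  if (sum(legend$role == "water") != 1L)
    stop("legend must contain exactly one water class")
  present <- unique(as.vector(values))
  present <- present[!is.na(present)]
  missing <- setdiff(present, legend$code)
  if (length(missing))
    stop("raster codes absent from legend: ", paste(missing, collapse = ", "))
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), legend = legend,
         water_code = as.integer(legend$code[legend$role == "water"])),
    class = "cover_raster")
}

#' @export
print.cover_raster <- function(x, ...) {
  cat(sprintf("<cover_raster> %d x %d cells, %.4g m resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  origin (%.6g, %.6g); extent %.4g x %.4g km\n",
              x$origin[1], x$origin[2],
              ncol(x$values) * x$cell_size / 1000,
              nrow(x$values) * x$cell_size / 1000))
  p <- raster_proportions(x)
  lab <- x$legend$label[match(as.integer(names(p)), x$legend$code)]
  cat("  classes:",
      paste(sprintf("%s %.1f%%", lab, 100 * p), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cover_raster <- function(object, ...) {
  p <- raster_proportions(object)
  data.frame(code = as.integer(names(p)),
             label = object$legend$label[match(as.integer(names(p)),
                                               object$legend$code)],
             proportion = as.numeric(p), row.names = NULL)
}

#' Realized class proportions of a raster
#'
#' @param raster a [cover_raster()].
#' @param na.rm drop masked (NA) cells before tabulating.
#' @return named numeric vector of cell fractions, names are class codes.
#' @export
raster_proportions <- function(raster, na.rm = TRUE) {
  v <- as.vector(raster$values)
  if (na.rm) v <- v[!is.na(v)]
  tab <- table(v)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Extent of a raster as (xmin, xmax, ymin, ymax)
#' @param raster a [cover_raster()].
#' @export
raster_extent <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  c(xmin = raster$origin[1], xmax = raster$origin[1] + nc * raster$cell_size,
    ymin = raster$origin[2], ymax = raster$origin[2] + nr * raster$cell_size)
}

# row/col of the cells containing planar points, half-open convention.
# Returns a list(row, col, inside); row counts from the TOP row (matrix order),
# 1-based. Points on the outer top/right boundary fall outside.
cell_index <- function(raster, x, y) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cell_size
  col <- floor((x - raster$origin[1]) / cs) + 1L
  row_from_bottom <- floor((y - raster$origin[2]) / cs) + 1L
  row <- nr - row_from_bottom + 1L
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

# planar coordinates of cell centres; rows/cols as in cell_index
cell_centers <- function(raster, row, col) {
  nr <- nrow(raster$values); cs <- raster$cell_size
  list(x = raster$origin[1] + (col - 0.5) * cs,
       y = raster$origin[2] + (nr - row + 0.5) * cs)
}

#' Look up the cover code under planar points
#'
#' @param raster a [cover_raster()].
#' @param x,y numeric coordinate vectors.
#' @return integer vector of codes, `NA` for points outside the grid.
#' @export
extract_cover <- function(raster, x, y) {
  idx <- cell_index(raster, x, y)
  out <- rep(NA_integer_, length(x))
  ok <- idx$inside
  out[ok] <- raster$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Write / read a cover raster as an ESRI ASCII grid
#'
#' The raster band is written in the plain-text ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows from north to south); the class legend travels in a JSON sidecar
#' (`<path>.legend.json`, records of `{"code": int, "label": str,
#' "role": "cover"|"water"}`). `read_raster(write_raster(r, p))` is
#' bit-exact for codes, cell size and origin.
#'
#' @param raster a [cover_raster()].
#' @param path output path (conventionally `.asc`).
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   [cover_raster()].
#' @export
write_raster <- function(raster, path) {
  v <- raster$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$cell_size),
    "NODATA_value -9999"), con)
  vv <- v
  vv[is.na(vv)] <- -9999L
  writeLines(apply(vv, 1L, paste, collapse = " "), con)
  jsonlite::write_json(raster$legend, legend_path(path), dataframe = "rows")
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  body <- scan(path, what = integer(), skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("raster body has ", length(body), " cells, expected ", nr * nc)
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if ("nodata_value" %in% key) as.integer(val[["nodata_value"]]) else -9999L
  v[v == nodata] <- NA_integer_
  lp <- legend_path(path)
  if (!file.exists(lp)) stop("missing legend sidecar: ", lp)
  legend <- jsonlite::fromJSON(lp)
  cover_raster(v, cell_size = val[["cellsize"]],
               origin = c(val[["xllcorner"]], val[["yllcorner"]]),
               legend = legend)
}

legend_path <- function(path) paste0(sub("\\.asc$", "", path), ".legend.json")
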