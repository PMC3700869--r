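#' GPS fix tables
#'
#' Fixes are stored as a plain data.frame with columns `animal_id`
#' (character), `timestamp` (POSIXct, UTC), `x`, `y` (planar metres, same
#' projection as the cover raster). Annotation adds `week_of_year`,
#' `period` (bi-weekly index), `cover_code` and, once seasons are defined,
#' `season_id`.
#'
#' @param animal_id,timestamp,x,y column vectors of equal length.
#' @return validated fix data.frame (class `fix_table`).
#' @export
fix_table <- function(animal_id, timestamp, x, y) {
  fx <- data.frame(animal_id = as.character(animal_id),
                   timestamp = as.POSIXct(timestamp, tz = "UTC"),
                   x = as.numeric(x), y = as.numeric(y))
  validate_fixes(fx)
  class(fx) <- c("fix_table", "data.frame")
  fx
}

validate_fixes <- function(fx) {
  stopifnot(all(c("animal_id", "timestamp", "x", "y") %in% names(fx)))
  if (anyNA(fx$x) || anyNA(fx$y)) stop("fixes contain missing coordinates")
  bad <- tapply(as.numeric(fx$timestamp), fx$animal_id,
                function(t) any(diff(t) <= 0))
  if (any(unlist(bad)))
    stop("timestamps must be strictly increasing within each animal")
  invisible(fx)
}

#' Annotate fixes with cover class and bi-weekly period
#'
#' Each fix is labelled with the code of the raster cell containing it
#' (half-open cell convention, see [cover_raster()]). Fixes falling outside
#' the raster are dropped; the number dropped is recorded in the
#' `"n_dropped"` attribute and reported via a message. Annotation is
#' idempotent: re-annotating an annotated table changes nothing.
#'
#' @param fixes fix data.frame.
#' @param raster a [cover_raster()].
#' @return the annotated fix table (possibly fewer rows).
#' @export
annotate_fixes <- function(fixes, raster) {
  code <- extract_cover(raster, fixes$x, fixes$y)
  drop <- is.na(code)
  if (any(drop))
    message(sum(drop), " fix(es) outside the raster dropped during annotation")
  out <- fixes[!drop, , drop = FALSE]
  out$cover_code <- code[!drop]
  yd <- as.POSIXlt(out$timestamp, tz = "UTC")$yday  # 0-based day of year
  out$week_of_year <- yd %/% 7L + 1L
  # bi-weekly period p spans weeks (2p, 2p+1): period boundaries fall after
  # odd calendar weeks, matching the week-31 / week-39 break style
  out$period <- out$week_of_year %/% 2L
  attr(out, "n_dropped") <- sum(drop)
  rownames(out) <- NULL
  out
}

#' Assign season ids from week breaks
#'
#' `breaks_week` holds the last calendar week of each season except the
#' final one (the style `{"k": 3, "breaks_week": [31, 39]}`: weeks up to 31
#' are season 1, 32--39 season 2, 40 onwards season 3).
#'
#' @param fixes annotated fix table (needs `week_of_year`).
#' @param breaks_week increasing integer vector, possibly empty (one season).
#' @return fixes with a `season_id` column.
#' @export
assign_seasons <- function(fixes, breaks_week) {
  if (is.null(fixes$week_of_year)) stop("fixes must be annotated first")
  if (length(breaks_week) && is.unsorted(breaks_week, strictly = TRUE))
    stop("breaks_week must be strictly increasing")
  fixes$season_id <- 1L + findInterval(fixes$week_of_year - 1L, breaks_week)
  fixes
}

#' Read / write fixes as CSV with ISO-8601 timestamps
#'
#' @param fixes fix data.frame.
#' @param path CSV path.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  df$animal_id <- as.character(df$animal_id)
  validate_fixes(df)
  df
}
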