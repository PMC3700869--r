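#' Synthetic landscape specification
#'
#' Describes a categorical landscape generated by thresholding a smoothed
#' Gaussian random field at the cumulative target proportions. One
#' parameter, `aggregation` (the smoothing length in cells), controls patch
#' clumping: 0 gives i.i.d. cells, larger values give larger, more compact
#' patches; quantile thresholding hits the target class proportions
#' essentially exactly regardless.
#'
#' The default emulates the study system: a low-heterogeneity Arctic
#' landscape of 10 vegetated covers plus water, water covering ~35% of the
#' area, on a 28.5 m grid.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge, metres.
#' @param cover_classes character vector of class labels; exactly one must
#'   be named in `water_class`.
#' @param target_proportions per-class area fractions, summing to 1.
#' @param aggregation smoothing length in cells (>= 0).
#' @param water_class label of the water class.
#' @param seed RNG seed.
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(n_rows = 512, n_cols = 512, cell_size = 28.5,
                           cover_classes = default_cover_labels(),
                           target_proportions = default_cover_proportions(),
                           aggregation = 6, water_class = "water",
                           seed = 1L) {
  if (length(cover_classes) < 2L) stop("need at least 2 cover classes")
  if (length(target_proportions) != length(cover_classes))
    stop("one target proportion per class required")
  if (abs(sum(target_proportions) - 1) > 1e-9)
    stop("target_proportions must sum to 1")
  if (any(target_proportions <= 0)) stop("target proportions must be > 0")
  if (!water_class %in% cover_classes) stop("water_class not among classes")
  if (aggregation < 0) stop("aggregation must be >= 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 cover_classes = cover_classes,
                 target_proportions = target_proportions,
                 aggregation = aggregation, water_class = water_class,
                 seed = seed),
            class = "landscape_spec")
}

#' @rdname landscape_spec
#' @export
default_cover_labels <- function() {
  c("water", "open spruce forest", "closed spruce forest",
    "deciduous forest", "dwarf shrub", "low shrub upland",
    "low shrub lowland", "tall shrub", "sparse vegetation",
    "tussock/lichen", "wet herbaceous")
}

#' @rdname landscape_spec
#' @export
default_cover_proportions <- function() {
  c(0.35, rep(0.65 / 10, 10))
}

# Gaussian smoothing matrix, bandwidth L cells. Rows are normalized to
# unit sum of squares so the smoothed field has variance 1 in every cell,
# including near the edges: with row-sum normalization the edge cells
# keep higher variance and the extreme quantile classes pile up there.
smoothing_matrix <- function(n, L) {
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-0.5 * (d / L)^2)
  K / sqrt(rowSums(K^2))
}

#' Generate a categorical cover raster
#'
#' Thresholds a smoothed standard-normal field into classes at the
#' cumulative `target_proportions` quantiles (class order follows
#' `cover_classes`; codes are 1-based in that order).
#'
#' @param spec a [landscape_spec()].
#' @return a [cover_raster()].
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(spec$n_rows * spec$n_cols), spec$n_rows, spec$n_cols)
  if (spec$aggregation > 0) {
    Kr <- smoothing_matrix(spec$n_rows, spec$aggregation)
    Kc <- smoothing_matrix(spec$n_cols, spec$aggregation)
    z <- Kr %*% z %*% t(Kc)
  }
  qs <- stats::quantile(z, probs = cumsum(spec$target_proportions)[-length(spec$target_proportions)])
  codes <- matrix(1L + findInterval(z, qs, left.open = TRUE),
                  spec$n_rows, spec$n_cols)
  legend <- data.frame(code = seq_along(spec$cover_classes),
                       label = spec$cover_classes,
                       role = ifelse(spec$cover_classes == spec$water_class,
                                     "water", "cover"))
  cover_raster(codes, cell_size = spec$cell_size, origin = c(0, 0),
               legend = legend)
}

#' Synthetic movement specification
#'
#' Parameters of the cover-biased correlated random walk used to emulate
#' GPS-collared bears. Steps are proposed as a correlated random walk --
#' gamma-distributed step lengths (mean `step_scale` metres per 4-h step),
#' wrapped-normal turning angles with concentration `turn_concentration` --
#' and accepted by a Metropolis rule on the combined potential
#' \deqn{W(x) = w[s, cover(x)] - ||x - centre||^2 / (2 rho^2),}
#' i.e. the destination cover's seasonal log-weight plus a Gaussian
#' home-range envelope of scale `rho = range_width * step_scale` around the
#' animal's range centre. A proposal is accepted with probability
#' `min(1, exp(W(x') - W(x)))`; after `max_tries` rejections the animal
#' stays put for that step (a rejected Metropolis move). The walk's
#' stationary space use is therefore exactly proportional to
#' `exp(w) * envelope`: the use-availability structure the resource
#' selection model assumes, inside a stable home range whose size scales
#' with `step_scale`.
#'
#' Defaults mirror the study conditions: ~30 females, 279--959 fixes each,
#' one fix per 4 h over April--November, three seasonal preference regimes
#' switching after weeks 31 and 39, water strongly avoided (log-weight
#' -2.5) in every season, and per-status range-scale multipliers ordered
#' cubs-of-year < solitary < cubs >= 1 yr.
#'
#' @param n_animals number of animals.
#' @param fixes_per_animal integer range (min, max) of retained fixes.
#' @param fix_interval hours between steps (default 4).
#' @param step_scale mean step length, metres.
#' @param turn_concentration >= 0; 0 means uniform turning angles.
#' @param range_width home-range envelope scale as a multiple of
#'   `step_scale` (`rho = range_width * step_scale`).
#' @param seasonal_preference list (one element per season) of named
#'   numeric vectors: cover label -> log selection weight.
#' @param season_breaks last calendar week of each season but the final.
#' @param status_probs named probabilities over reproductive statuses.
#' @param range_scale_by_status named multipliers on `step_scale`.
#' @param start,end simulated collar deployment window (dates).
#' @param max_tries proposals per step (default 1, the exact Metropolis
#'   kernel; larger values move more but attenuate the programmed
#'   selection, because every retry is another chance to leave a good
#'   cell).
#' @param seed RNG seed.
#' @return a `movement_spec` list.
#' @export
movement_spec <- function(n_animals = 30,
                          fixes_per_animal = c(279, 959),
                          fix_interval = 4,
                          step_scale = 250,
                          turn_concentration = 1,
                          range_width = 4,
                          seasonal_preference = default_seasonal_preference(),
                          season_breaks = c(31, 39),
                          status_probs = c(solitary = 0.44,
                                           cub_of_year = 0.14,
                                           cub_older = 0.42),
                          range_scale_by_status = c(solitary = 1,
                                                    cub_of_year = 0.7,
                                                    cub_older = 1.2),
                          start = "2003-04-01", end = "2003-11-30",
                          max_tries = 1L, seed = 1L) {
  if (length(seasonal_preference) != length(season_breaks) + 1L)
    stop("need one preference map per season (length(season_breaks) + 1)")
  w <- unlist(seasonal_preference)
  if (any(!is.finite(w))) stop("seasonal log-weights must be finite")
  if (abs(sum(status_probs) - 1) > 1e-9) stop("status_probs must sum to 1")
  if (step_scale <= 0) stop("step_scale must be positive")
  if (fixes_per_animal[1] > fixes_per_animal[2])
    stop("fixes_per_animal must be an increasing range")
  structure(list(n_animals = n_animals, fixes_per_animal = fixes_per_animal,
                 fix_interval = fix_interval, step_scale = step_scale,
                 turn_concentration = turn_concentration,
                 range_width = range_width,
                 seasonal_preference = seasonal_preference,
                 season_breaks = season_breaks, status_probs = status_probs,
                 range_scale_by_status = range_scale_by_status,
                 start = start, end = end, max_tries = as.integer(max_tries),
                 seed = seed),
            class = "movement_spec")
}

#' @rdname movement_spec
#' @export
default_seasonal_preference <- function() {
  # Three regimes with the seasonal "highly selected" sets of the study
  # system: spring/early summer spreads preference over sparse vegetation,
  # tall shrub, closed spruce, low shrub upland and wet herbaceous; late
  # summer (berries) concentrates on sparse vegetation and low shrub
  # lowland; autumn favours low shrub lowland, closed spruce, tall shrub
  # and sparse vegetation. Magnitudes are kept at |w| <= 2.4 so no single
  # cover's occupancy dwell time dominates the walk, and water is strongly
  # avoided year-round.
  list(
    c("sparse vegetation" = 2.0, "tall shrub" = 1.6,
      "closed spruce forest" = 1.5, "low shrub upland" = 1.4,
      "wet herbaceous" = 1.3, "deciduous forest" = 0.3,
      "open spruce forest" = 0.2, "low shrub lowland" = -0.5,
      "dwarf shrub" = -0.3, "tussock/lichen" = -0.8, "water" = -2.4),
    c("sparse vegetation" = 2.0, "low shrub lowland" = 2.0,
      "tall shrub" = 0.3, "low shrub upland" = 0.2,
      "open spruce forest" = 0.2, "wet herbaceous" = 0,
      "closed spruce forest" = -0.5, "dwarf shrub" = -0.8,
      "deciduous forest" = -0.8, "tussock/lichen" = -1.0, "water" = -2.3),
    c("low shrub lowland" = 1.8, "closed spruce forest" = 1.6,
      "tall shrub" = 1.4, "sparse vegetation" = 1.2,
      "wet herbaceous" = 0.2, "low shrub upland" = 0,
      "open spruce forest" = -0.8, "dwarf shrub" = -1.0,
      "tussock/lichen" = -1.5, "deciduous forest" = -1.8, "water" = -2.0))
}

# seasonal log-weights re-indexed by raster code; covers missing from the
# preference map get weight 0
weights_by_code <- function(pref, legend) {
  lapply(pref, function(w) {
    out <- rep(0, nrow(legend))
    names(out) <- as.character(legend$code)
    hit <- match(names(w), legend$label)
    if (anyNA(hit))
      stop("preference labels not in legend: ",
           paste(names(w)[is.na(hit)], collapse = ", "))
    out[as.character(legend$code[hit])] <- w
    out
  })
}

#' Simulate cover-biased GPS tracks on a landscape
#'
#' Runs the biased correlated random walk of [movement_spec()] for each
#' animal at every `fix_interval`-hour slot of the deployment window, then
#' retains a random subset of slots as the animal's fixes (so every season
#' is represented, as with real collars with missed fixes). Steps proposed
#' off the raster are rejected like any other unfavourable proposal (the
#' boundary acts as an infinite potential wall).
#'
#' @param raster a [cover_raster()].
#' @param spec a [movement_spec()].
#' @return list with `fixes` (fix data.frame) and `truth` (the programmed
#'   per-season log-weights, season breaks, and per-animal status, centre
#'   and step scale).
#' @export
simulate_tracks <- function(raster, spec) {
  stopifnot(inherits(spec, "movement_spec"))
  if (length(raster$values) == 0L) stop("empty raster")
  set.seed(spec$seed)
  ext <- raster_extent(raster)
  times <- seq(from = as.POSIXct(paste(spec$start, "00:00:00"), tz = "UTC"),
               to = as.POSIXct(paste(spec$end, "23:59:59"), tz = "UTC"),
               by = spec$fix_interval * 3600)
  yd <- as.POSIXlt(times, tz = "UTC")$yday
  week <- yd %/% 7L + 1L
  season_of_step <- 1L + findInterval(week - 1L, spec$season_breaks)
  wlist <- weights_by_code(spec$seasonal_preference, raster$legend)

  margin <- 0.12 * c(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
  statuses <- names(spec$status_probs)
  n_steps <- length(times)
  fixes <- vector("list", spec$n_animals)
  truth_animals <- vector("list", spec$n_animals)

  burn_in <- 120L  # pre-recording steps: start the walk near stationarity
  for (a in seq_len(spec$n_animals)) {
    status <- sample(statuses, 1L, prob = spec$status_probs)
    sscale <- spec$step_scale * spec$range_scale_by_status[[status]]
    rho <- spec$range_width * sscale
    centre <- c(stats::runif(1, ext["xmin"] + margin[1], ext["xmax"] - margin[1]),
                stats::runif(1, ext["ymin"] + margin[2], ext["ymax"] - margin[2]))
    xs <- numeric(n_steps); ys <- numeric(n_steps)
    pos <- centre
    heading <- stats::runif(1, 0, 2 * pi)
    turn_sd <- if (spec$turn_concentration > 0)
      1 / sqrt(spec$turn_concentration) else NA_real_
    potential <- function(p, w)
      w[[as.character(extract_cover(raster, p[1], p[2]))]] -
        sum((p - centre)^2) / (2 * rho^2)
    for (t in seq_len(n_steps + burn_in)) {
      w <- wlist[[season_of_step[max(t - burn_in, 1L)]]]
      w_cur <- potential(pos, w)
      for (try in seq_len(spec$max_tries)) {
        turn <- if (is.na(turn_sd)) stats::runif(1, -pi, pi)
                else stats::rnorm(1, 0, turn_sd)
        h <- heading + turn
        len <- stats::rgamma(1, shape = 2, scale = sscale / 2)
        cand <- pos + len * c(cos(h), sin(h))
        # a step off the raster is simply rejected (an infinite potential
        # wall): folding it back instead would pile use onto the boundary
        # ring and bias cover use for edge animals
        if (cand[1] < ext["xmin"] || cand[1] >= ext["xmax"] ||
            cand[2] < ext["ymin"] || cand[2] >= ext["ymax"]) next
        if (stats::runif(1) < exp(potential(cand, w) - w_cur)) {
          pos <- cand
          heading <- h
          break
        }
      }
      # all proposals rejected: the animal stays put this step (a rejected
      # Metropolis move), preserving the programmed stationary use exactly
      if (t > burn_in) {
        xs[t - burn_in] <- pos[1]; ys[t - burn_in] <- pos[2]
      }
    }
    n_fix <- sample(seq(spec$fixes_per_animal[1], spec$fixes_per_animal[2]), 1L)
    n_fix <- min(n_fix, n_steps)
    keep <- sort(sample.int(n_steps, n_fix))
    id <- sprintf("GF%02d", a)
    fixes[[a]] <- data.frame(animal_id = id, timestamp = times[keep],
                             x = xs[keep], y = ys[keep])
    truth_animals[[a]] <- data.frame(animal_id = id, status = status,
                                     centre_x = centre[1], centre_y = centre[2],
                                     step_scale = sscale)
  }
  fx <- do.call(rbind, fixes)
  class(fx) <- c("fix_table", "data.frame")
  truth <- list(seasonal_preference = spec$seasonal_preference,
                season_breaks = spec$season_breaks,
                animals = do.call(rbind, truth_animals))
  list(fixes = fx, truth = truth)
}

#' Serialize a truth record to JSON
#' @param truth the `truth` element of [simulate_tracks()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
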