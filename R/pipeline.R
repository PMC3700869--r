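#' Pipeline configuration
#'
#' Builds the full configuration for [run_pipeline()], with every analysis
#' threshold surfaced as a named key at its conventional default: 95%
#' isopleth, LSCV bandwidth, 60% study-area inclusion, 1 availability
#' point per km^2, 80:20 train:test split, RSI cut-off 2.0, |r| >= 0.6 and
#' VIF > 10 collinearity rules, and the 10% confidence-set rule.
#' `overrides` (a nested list, or a YAML file via
#' [read_pipeline_config()]) is merged recursively over the defaults.
#'
#' @param overrides nested list of settings to override.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1L,
    paths = list(raster = NULL, fixes = NULL, out = NULL),
    stages = list(simulate = TRUE, homerange = TRUE, seasons = TRUE,
                  rsf = TRUE, metrics = TRUE, compare = TRUE),
    landscape = list(),   # landscape_spec() arguments
    movement = list(),    # movement_spec() arguments
    homerange = list(isopleth_level = 0.95, bandwidth = "lscv",
                     cell = NULL, min_fixes = 30L),
    study_area = list(polygon = NULL, inclusion_threshold = 0.60),
    rsf = list(availability_density = 1.0, train_ratio = 0.80,
               rsi_threshold = 2.0),
    compare = list(confidence_rule = 0.10, r_cut = 0.6, vif_cut = 10))
  cfg <- merge_config(defaults, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
      merge_config(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> annotate -> home ranges -> seasons -> RSF ->
#' landscape metrics -> model comparison, writing intermediate artifacts
#' to `config$paths$out` (when set) and returning a run report with
#' per-stage counts. Outputs are a pure function of (inputs, config,
#' seed). Disabled stages make their dependants fail with a dependency
#' error.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list: `counts`, `seasons`, `rsf`,
#'   `selection_ratios`, `metrics`, `comparison`, plus the intermediate
#'   objects in `objects`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  st <- config$stages
  out_dir <- config$paths$out
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(counts = list(), seed = config$seed)
  objects <- list()

  ## landscape + tracks ------------------------------------------------
  if (isTRUE(st$simulate)) {
    lspec <- do.call(landscape_spec,
                     merge_config(list(seed = config$seed), config$landscape))
    raster <- generate_landscape(lspec)
    mspec <- do.call(movement_spec,
                     merge_config(list(seed = config$seed + 1L),
                                  config$movement))
    sim <- simulate_tracks(raster, mspec)
    fixes <- sim$fixes
    objects$truth <- sim$truth
  } else {
    if (is.null(config$paths$raster) || is.null(config$paths$fixes))
      stop("stage 'simulate' disabled: paths$raster and paths$fixes required")
    raster <- read_raster(config$paths$raster)
    fixes <- read_fixes(config$paths$fixes)
  }
  fixes <- annotate_fixes(fixes, raster)
  report$counts$animals <- length(unique(fixes$animal_id))
  report$counts$fixes <- nrow(fixes)
  report$counts$fixes_dropped_annotation <- attr(fixes, "n_dropped")
  objects$raster <- raster

  ## home ranges --------------------------------------------------------
  if (!isTRUE(st$homerange)) stop("stage 'homerange' is required downstream")
  hrc <- config$homerange
  fixes$year <- format(fixes$timestamp, "%Y")
  ay <- split(fixes, interaction(fixes$animal_id, fixes$year, drop = TRUE))
  ay <- ay[vapply(ay, nrow, 0L) >= hrc$min_fixes]
  ranges <- lapply(ay, function(fx)
    kernel_home_range(fx, bandwidth = hrc$bandwidth,
                      level = hrc$isopleth_level,
                      cell = hrc$cell %||% raster$cell_size,
                      animal_id = fx$animal_id[1]))
  mcps <- lapply(split(fixes, fixes$animal_id), mcp_of_animal <- function(fx)
    mcp(fx, animal_id = fx$animal_id[1]))
  report$counts$ranges <- length(ranges)
  ## study-area inclusion filter
  sa <- config$study_area$polygon
  if (is.null(sa)) {  # default: the raster extent
    e <- raster_extent(raster)
    sa <- cbind(c(e["xmin"], e["xmax"], e["xmax"], e["xmin"]),
                c(e["ymin"], e["ymin"], e["ymax"], e["ymax"]))
  } else sa <- matrix(unlist(sa), ncol = 2, byrow = TRUE)
  incl <- vapply(ranges, function(r)
    study_area_filter(r$hr, sa, config$study_area$inclusion_threshold)$keep,
    TRUE)
  kept_ids <- unique(vapply(ranges[incl], function(r) r$hr$animal_id, ""))
  report$counts$ranges_kept <- sum(incl)
  report$counts$animals_excluded_study_area <-
    report$counts$animals - length(kept_ids)
  objects$ranges <- ranges[incl]
  objects$mcps <- mcps[kept_ids]
  area_tab <- do.call(rbind, lapply(objects$ranges, function(r)
    data.frame(animal_id = r$hr$animal_id, area_km2 = r$area_km2,
               log10_area = log10(r$area_km2), h = r$h)))
  rownames(area_tab) <- NULL
  objects$areas <- area_tab

  ## seasons ------------------------------------------------------------
  if (isTRUE(st$seasons)) {
    prof <- build_profiles(fixes)
    part <- choose_k(ward_cluster(prof))
    fixes <- assign_seasons(fixes, part$breaks_week)
    report$seasons <- list(k = part$k, breaks_week = part$breaks_week,
                           agreement = part$agreement)
    objects$season_partition <- part
    if (!is.null(out_dir))
      write_season_partition(part, file.path(out_dir, "seasons.json"))
  }

  ## resource selection -------------------------------------------------
  if (isTRUE(st$rsf)) {
    if (!isTRUE(st$seasons)) stop("stage 'rsf' requires stage 'seasons'")
    fixes_kept <- fixes[fixes$animal_id %in% kept_ids, , drop = FALSE]
    split80 <- train_test_split(fixes_kept, ratio = config$rsf$train_ratio,
                                seed = config$seed + 2L)
    set.seed(config$seed + 3L)
    avail <- do.call(rbind, lapply(objects$mcps, function(m) {
      pts <- sample_availability(m, density = config$rsf$availability_density)
      pts$animal_id <- m$animal_id
      pts
    }))
    seasons <- sort(unique(fixes$season_id))
    objects$rsf <- list(); objects$sel_maps <- list()
    report$rsf <- list(); report$selection_ratios <- list()
    for (s in seasons) {
      used_s <- split80$train[split80$train$season_id == s, , drop = FALSE]
      fit <- fit_rsf(used_s, avail, raster, season_id = s,
                     rsi_threshold = config$rsf$rsi_threshold)
      smap <- selection_map(raster, fit)
      key <- paste0("season", s)
      objects$rsf[[key]] <- fit
      objects$sel_maps[[key]] <- smap
      report$rsf[[key]] <- format_effects(fit$effects)
      test_s <- split80$test[split80$test$season_id == s, , drop = FALSE]
      sr <- tryCatch(
        suppressWarnings(selection_ratio(test_s, objects$mcps, smap,
                                         season_id = s)),
        error = function(e) NULL)
      if (!is.null(sr))
        report$selection_ratios[[key]] <-
          list(mean_w = sr$mean_w, F = sr$F, df = sr$df, p = sr$p,
               n = nrow(sr$table))
      if (!is.null(out_dir))
        write_effects_csv(fit, file.path(out_dir,
                                         sprintf("effects_season%d.csv", s)))
    }
  }

  ## landscape metrics --------------------------------------------------
  if (isTRUE(st$metrics)) {
    if (!isTRUE(st$rsf)) stop("stage 'metrics' requires stage 'rsf'")
    status_of <- if (!is.null(objects$truth))
      stats::setNames(objects$truth$animals$status,
                      objects$truth$animals$animal_id) else NULL
    mtab <- do.call(rbind, lapply(objects$ranges, function(r) {
      id <- r$hr$animal_id
      range_metrics(raster, objects$sel_maps, r$hr, animal_id = id,
                    year = NA,
                    status = if (!is.null(status_of)) status_of[[id]] else NA)
    }))
    rownames(mtab) <- NULL
    objects$metrics <- mtab
    report$counts$metric_rows <- nrow(mtab)
    if (!is.null(out_dir))
      utils::write.csv(mtab, file.path(out_dir, "range_metrics.csv"),
                       row.names = FALSE)
  }

  ## model comparison ---------------------------------------------------
  if (isTRUE(st$compare)) {
    if (!isTRUE(st$metrics)) stop("stage 'compare' requires stage 'metrics'")
    mtab <- objects$metrics
    num_cov <- setdiff(names(mtab)[vapply(mtab, is.numeric, TRUE)],
                       c("hr_area_km2", "log10_area", "year"))
    num_cov <- num_cov[vapply(mtab[num_cov], function(v) !anyNA(v), TRUE)]
    scr <- collinearity_screen(mtab[num_cov], mtab$log10_area,
                               r_cut = config$compare$r_cut,
                               vif_cut = config$compare$vif_cut)
    models <- default_candidate_models(scr$kept,
                                       n_seasons = length(objects$sel_maps))
    dat <- mtab
    dat$rs <- factor(dat$rs)
    n_status <- nlevels(droplevels(dat$rs[!is.na(dat$rs)]))
    if (n_status < 2L) {
      models <- models[!vapply(models, function(tm) "rs" %in% tm, TRUE)]
    } else {
      gcomp <- group_compare(dat$log10_area, dat$rs)
      report$group_comparison <- list(anova = gcomp$anova,
                                      tukey = gcomp$tukey)
    }
    set <- fit_candidates(dat, models, vif_cut = config$compare$vif_cut)
    conf <- confidence_set(set, rule = config$compare$confidence_rule)
    imp <- importance_weights(conf)
    best_terms <- set$terms[[set$records$model[1]]]
    re <- random_effect_check(dat, best_terms)
    # quadratic check: does a squared shape-index term improve the best model?
    poly_check <- NULL
    lsi_terms <- grep("lsi$", best_terms, value = TRUE)
    if (length(lsi_terms)) {
      poly_models <- c(set$terms[set$records$model[1]],
                       lapply(stats::setNames(lsi_terms,
                                paste0(set$records$model[1], "+", lsi_terms, "^2")),
                              function(tm) c(best_terms, sprintf("I(%s^2)", tm))))
      pset <- fit_candidates(dat, poly_models, vif_cut = Inf)
      poly_check <- list(improved = pset$records$model[1] !=
                           set$records$model[1],
                         records = pset$records)
    }
    objects$model_set <- set
    report$comparison <- list(records = set$records,
                              confidence_set = conf$model,
                              importance = as.list(imp),
                              random_effect = re,
                              polynomial_check = poly_check)
    report$counts$models_fit <- nrow(set$records)
    if (!is.null(out_dir))
      utils::write.csv(set$records, file.path(out_dir, "candidates.csv"),
                       row.names = FALSE)
  }

  report$counts <- report$counts
  out <- structure(list(report = report, objects = objects,
                        config = config), class = "pipeline_report")
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows",
                         force = TRUE)
  out
}

#' Default candidate model set
#'
#' Builds the candidate vocabulary from the screened covariates: for each
#' season, models combining reproductive status with that season's
#' surviving selected-cover structure terms; a hydrology block with the
#' water shape index; and the shared null / status-only models.
#'
#' @param kept character vector of screened covariate names.
#' @param n_seasons number of seasons with selection maps.
#' @return named list of term vectors for [fit_candidates()].
#' @export
default_candidate_models <- function(kept, n_seasons = 3L) {
  models <- list("null model" = character(0), rs = "rs")
  add <- function(models, terms) {
    nm <- paste(terms, collapse = "+")
    if (!nm %in% names(models)) models[[nm]] <- terms
    models
  }
  for (s in seq_len(n_seasons)) {
    terms_s <- intersect(sprintf("s%d%s", s, c("lsi", "edge", "prop")), kept)
    for (tm in terms_s) {
      models <- add(models, tm)
      models <- add(models, c("rs", tm))
    }
    if (length(terms_s) >= 2L) {
      models <- add(models, terms_s)
      models <- add(models, c("rs", terms_s))
    }
  }
  if ("wlsi" %in% kept) {
    models <- add(models, "wlsi")
    models <- add(models, c("rs", "wlsi"))
  }
  models
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("<pipeline_report>\n")
  cat("  animals:", r$counts$animals, " fixes:", r$counts$fixes,
      " ranges kept:", r$counts$ranges_kept, "\n")
  if (!is.null(r$seasons))
    cat("  seasons: k =", r$seasons$k, "; breaks after weeks",
        paste(r$seasons$breaks_week, collapse = ", "), "\n")
  if (!is.null(r$comparison)) {
    cat("  best model:", r$comparison$records$model[1], "\n")
    cat("  confidence set:",
        paste(r$comparison$confidence_set, collapse = ", "), "\n")
  }
  invisible(x)
}
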