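#' Bi-weekly cover-use profiles
#'
#' Builds the matrix clustered to define seasons: one row per bi-weekly
#' period, one column per cover class. Entries start as the proportion of
#' that period's fixes falling on each cover (pooled over animals, or the
#' mean of per-animal proportions with `per_animal_mean = TRUE`), then each
#' cover column is standardized (z-scored) across periods so every cover
#' contributes equally to the clustering. Zero-variance columns become
#' all-zero.
#'
#' @param fixes annotated fixes (need `period` and `cover_code`).
#' @param per_animal_mean average per-animal proportions instead of pooling
#'   fixes (default FALSE: pooled).
#' @param min_days periods observed on fewer distinct days than this are
#'   dropped with a warning (default 8, roughly half a bi-weekly period:
#'   partial calendar periods at the deployment edges produce unstable
#'   proportion rows). Periods with no fixes are dropped regardless.
#' @return a `use_profile`: `mat` (standardized periods x covers),
#'   `raw` (the proportions), `periods` (calendar bi-week indices),
#'   `covers` (class codes).
#' @export
build_profiles <- function(fixes, per_animal_mean = FALSE, min_days = 8L) {
  if (is.null(fixes$period) || is.null(fixes$cover_code))
    stop("fixes must be annotated (period, cover_code) first")
  day <- format(fixes$timestamp, "%Y-%m-%d")
  days_per_period <- tapply(day, fixes$period, function(d) length(unique(d)))
  thin <- days_per_period < min_days
  if (any(thin)) {
    warning("dropping partially observed bi-weekly period(s): ",
            paste(names(days_per_period)[thin], collapse = ", "))
    fixes <- fixes[!fixes$period %in%
                     as.integer(names(days_per_period)[thin]), , drop = FALSE]
  }
  periods <- sort(unique(fixes$period))
  if (length(periods) < 4L)
    stop("need fixes spanning at least 4 bi-weekly periods")
  covers <- sort(unique(fixes$cover_code))
  if (per_animal_mean) {
    tab3 <- table(fixes$period, fixes$cover_code, fixes$animal_id)
    per_animal <- sweep(tab3, c(1, 3), pmax(apply(tab3, c(1, 3), sum), 1), "/")
    present <- apply(tab3, c(1, 3), sum) > 0
    raw <- t(sapply(seq_along(periods), function(i) {
      keep <- present[i, ]
      colMeans(t(per_animal[i, , keep, drop = FALSE][1, , ]), na.rm = TRUE)
    }))
  } else {
    tab <- table(fixes$period, fixes$cover_code)
    raw <- sweep(unclass(tab), 1, rowSums(tab), "/")
  }
  dimnames(raw) <- list(period = periods, cover = covers)
  mat <- apply(raw, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s < 1e-12) rep(0, length(col))
    else (col - mean(col)) / s
  })
  dimnames(mat) <- dimnames(raw)
  structure(list(mat = mat, raw = raw, periods = periods, covers = covers),
            class = "use_profile")
}

# within-cluster sum of squares of rows of x under integer memberships
cluster_ess <- function(x, labels) {
  sum(vapply(unique(labels), function(g) {
    rows <- x[labels == g, , drop = FALSE]
    sum(sweep(rows, 2, colMeans(rows))^2)
  }, 0))
}

#' Ward's minimum-variance clustering of period profiles
#'
#' Agglomerative Ward linkage on Euclidean distances between the
#' standardized period rows, with candidate partitions for k = 1..6 and
#' the Wishart objective function: the within-cluster sum-of-squares at
#' each k and the increment absorbed by each successive merge (the
#' increments over all merges sum to the total sum of squares about the
#' grand mean).
#'
#' @param profile a [build_profiles()] result.
#' @param k_max largest candidate number of seasons (default 6).
#' @return a `ward_clustering`: `hclust` tree, `labels` (list: k ->
#'   membership vector), `objective` (ESS at each k), `increments`, and
#'   the `profile`.
#' @export
ward_cluster <- function(profile, k_max = 6L) {
  x <- profile$mat
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 periods to cluster")
  k_max <- min(k_max, n)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- lapply(seq_len(k_max), function(k) stats::cutree(hc, k = k))
  objective <- vapply(seq_len(n), function(k)
    cluster_ess(x, stats::cutree(hc, k = k)), 0)
  structure(list(hclust = hc, labels = labels,
                 objective = objective[seq_len(k_max)],
                 increments = -diff(objective),  # ESS released by split k -> k+1
                 profile = profile),
            class = "ward_clustering")
}

# Duda-Hart Je(2)/Je(1) and pseudo-t^2 for the split taking k clusters to
# k+1: Je(1) is the ESS of the cluster that splits, Je(2) the summed ESS of
# its two children, n_m the cluster size.
duda_hart <- function(x, labels_k, labels_k1) {
  split_of <- tapply(labels_k1, labels_k, function(v) length(unique(v)))
  parent <- as.integer(names(split_of)[split_of > 1L][1])
  members <- labels_k == parent
  rows <- x[members, , drop = FALSE]
  je1 <- sum(sweep(rows, 2, colMeans(rows))^2)
  je2 <- cluster_ess(rows, labels_k1[members])
  n_m <- sum(members)
  if (je1 < 1e-12) return(c(duda = 1, pseudo_t2 = 0, n_m = n_m))
  if (je2 < 1e-12) return(c(duda = 0, pseudo_t2 = Inf, n_m = n_m))
  c(duda = je2 / je1,
    pseudo_t2 = ((je1 - je2) / je2) * (n_m - 2),
    n_m = n_m)
}

#' Choose the number of seasons and force them contiguous
#'
#' Computes the Duda--Hart ratio Je(2)/Je(1) and pseudo-t^2 at every split
#' k -> k+1 (k = 1..k_max-1) and stops at the smallest k whose split is
#' *not* significant under the Duda--Hart test: the ratio is compared to
#' its null mean `1 - 2/(pi*d)` and variance `2*(1 - 8/(pi^2*d))/(m*d)`
#' (`d` = informative profile dimensions, `m` = size of the cluster being
#' split), and a split counts as real only when its standardized ratio
#' falls below `-z_crit` (default 3.20, the conventional critical value
#' for this index). The raw ratio is biased toward splitting small
#' clusters; the standardization is what makes small spurious splits stop
#' the search. `agreement` records whether the chosen k also sits at a
#' local maximum of the ratio and local minimum of the pseudo-t^2 across
#' the k sequence (the informal "agreement of criteria" read-off).
#' Degenerate profiles with no structure (total sum of squares ~ 0) give
#' k = 1.
#'
#' Ward clustering ignores time, but seasons must be contiguous calendar
#' blocks. Periods are therefore relabelled by their cluster, runs of equal
#' labels are formed, and while more runs than seasons remain the shortest
#' run ("island") is merged into the neighbouring run whose profile
#' centroid is closer. Season numbers are then renumbered in calendar
#' order and the breaks reported as the last calendar week of each season
#' but the final one.
#'
#' @param clustering a [ward_cluster()] result.
#' @param z_crit critical value for the standardized Duda--Hart ratio
#'   (default 3.20).
#' @return a `season_partition`: `k`, `breaks_week`, `labels` (period ->
#'   season), `diagnostics` (per-split table with the ratio, its
#'   standardized form, and pseudo-t^2), `agreement`.
#' @export
choose_k <- function(clustering, z_crit = 3.20) {
  x <- clustering$profile$mat
  n <- nrow(x)
  k_max <- length(clustering$labels)
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  if (tss < 1e-12) {
    return(finish_partition(clustering, k = 1L,
                            diagnostics = NULL, agreement = TRUE))
  }
  ks <- seq_len(k_max - 1L)
  stats_tab <- t(vapply(ks, function(k)
    duda_hart(x, clustering$labels[[k]], clustering$labels[[k + 1L]]),
    c(duda = 0, pseudo_t2 = 0, n_m = 0)))
  d <- sum(apply(x, 2, stats::sd) > 1e-12)  # informative dimensions
  d <- max(d, 1L)
  m <- stats_tab[, "n_m"]
  null_mean <- 1 - 2 / (pi * d)
  null_sd <- sqrt(2 * (1 - 8 / (pi^2 * d)) / (m * d))
  duda_z <- (stats_tab[, "duda"] - null_mean) / null_sd
  diagnostics <- data.frame(k = ks, duda = stats_tab[, "duda"],
                            duda_z = duda_z,
                            pseudo_t2 = stats_tab[, "pseudo_t2"],
                            n_split = m,
                            increment = clustering$increments[ks])
  # stop at the first split that is not significantly better than chance
  not_sig <- duda_z > -z_crit
  k <- if (any(not_sig)) ks[which(not_sig)[1]] else k_max
  duda <- diagnostics$duda; t2 <- diagnostics$pseudo_t2
  at <- function(v, i) if (i >= 1L && i <= length(v)) v[i] else NULL
  agreement <- k <= max(ks) &&
    all(duda[k] >= c(at(duda, k - 1L), at(duda, k + 1L))) &&
    all(t2[k] <= c(at(t2, k - 1L), at(t2, k + 1L)))
  finish_partition(clustering, k = k, diagnostics = diagnostics,
                   agreement = agreement)
}

finish_partition <- function(clustering, k, diagnostics, agreement) {
  x <- clustering$profile$mat
  periods <- clustering$profile$periods
  labels <- clustering$labels[[k]]
  season <- contiguous_seasons(x, labels, k)
  last_period <- vapply(seq_len(max(season) - 1L),
                        function(s) max(periods[season == s]), 0)
  breaks_week <- as.integer(2L * last_period + 1L)  # period p = weeks (2p, 2p+1)
  structure(list(k = as.integer(max(season)), breaks_week = breaks_week,
                 labels = stats::setNames(season, periods),
                 diagnostics = diagnostics, agreement = agreement),
            class = "season_partition")
}

# force cluster labels (in period order) into k contiguous blocks
contiguous_seasons <- function(x, labels, k) {
  runs <- function(l) {
    r <- rle(l)
    data.frame(label = r$values, len = r$lengths,
               end = cumsum(r$lengths), start = cumsum(r$lengths) - r$lengths + 1L)
  }
  l <- labels
  repeat {
    rn <- runs(l)
    if (nrow(rn) <= k) break
    i <- which.min(rn$len)  # shortest island
    idx <- rn$start[i]:rn$end[i]
    cand <- c(if (i > 1L) i - 1L, if (i < nrow(rn)) i + 1L)
    cent_dist <- vapply(cand, function(j) {
      rows <- x[rn$start[j]:rn$end[j], , drop = FALSE]
      island <- x[idx, , drop = FALSE]
      sum((colMeans(island) - colMeans(rows))^2)
    }, 0)
    l[idx] <- rn$label[cand[which.min(cent_dist)]]
  }
  rn <- runs(l)
  season <- rep(seq_len(nrow(rn)), rn$len)
  season
}

#' @export
print.season_partition <- function(x, ...) {
  cat(sprintf("<season_partition> k = %d season(s)", x$k))
  if (length(x$breaks_week))
    cat("; breaks after weeks", paste(x$breaks_week, collapse = ", "))
  if (!x$agreement) cat("  [criteria disagreed; best Duda-Hart used]")
  cat("\n")
  invisible(x)
}

#' Serialize a season partition to JSON
#' @param partition a `season_partition`.
#' @param path output path.
#' @export
write_season_partition <- function(partition, path) {
  jsonlite::write_json(list(k = partition$k,
                            breaks_week = partition$breaks_week),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
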