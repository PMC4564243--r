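# Call categorisation: standardized feature matrix and seeded k-means with
# k-means++ initialization, restarts and empty-cluster repair, plus
# silhouette-based selection of the number of call types.

#' Build a standardized feature matrix from call measurements
#'
#' Encodes each call's measurements as the clustering feature vector: the ten
#' numeric parameters in fixed order, the harmonic flag as 0/1, sideband
#' spacing with absent (`NA`) encoded as 0 (tonal calls have no sidebands),
#' and a pulsed-class indicator (1 for `burst_pulse`/`pulsed_middle`/
#' `transition`). All columns are z-scored; columns with zero variance are
#' dropped with a warning. Column means and standard deviations are retained
#' for the inverse transform.
#'
#' @param measurements Tibble with the measurement columns (see
#'   [measure_call()]); an optional `group` column is carried through as true
#'   labels.
#' @return An object of class `call_feature_matrix`: list with `x` (the
#'   standardized matrix), `center`, `scale`, `dropped`, `labels`.
#' @export
build_feature_matrix <- function(measurements) {
  stopifnot(nrow(measurements) > 0)
  if (nrow(measurements) < 2) {
    stop("at least two calls are needed to standardize features", call. = FALSE)
  }
  m <- measurements
  x <- cbind(
    min_f = m$min_f, max_f = m$max_f, start_f = m$start_f, end_f = m$end_f,
    delta_f = m$delta_f, duration = m$duration,
    n_extrema = as.numeric(m$n_extrema), n_inflections = as.numeric(m$n_inflections),
    fm_rate = m$fm_rate,
    has_harmonics = as.numeric(m$has_harmonics),
    sideband_spacing = ifelse(is.na(m$sideband_spacing), 0, m$sideband_spacing),
    pulsed = as.numeric(m$call_class %in% c("burst_pulse", "pulsed_middle", "transition"))
  )
  if (anyNA(x)) stop("measurements contain NA in required feature columns", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[scl == 0]
  if (length(dropped) > 0) {
    warning("dropping constant feature column(s): ", paste(dropped, collapse = ", "))
  }
  keep <- scl > 0
  z <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  structure(list(
    x = z, center = ctr[keep], scale = scl[keep], dropped = dropped,
    labels = if ("group" %in% names(m)) m$group else NULL
  ), class = "call_feature_matrix")
}

#' @export
print.call_feature_matrix <- function(x, ...) {
  cat(sprintf("<call_feature_matrix: %d calls x %d standardized features>\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

squared_dists <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- squared_dists(x, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1) + 1) {
    p <- pmax(d2, 0)
    idx <- if (sum(p) <= 0) sample.int(n, 1) else sample.int(n, 1, prob = p)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, squared_dists(x, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

lloyd <- function(x, centers, max_iter = 100) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_old <- rep(0L, n)
  wss_hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- squared_dists(x, centers)
    assign_new <- max.col(-d2, ties.method = "first") # ties -> lowest index
    # empty-cluster repair: hand the point farthest from its centroid over
    for (j in which(tabulate(assign_new, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), assign_new)])
      assign_new[far] <- j
      d2[far, ] <- Inf # don't move it again this iteration
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    }
    wss_hist <- c(wss_hist, sum(rowSums((x - centers[assign_new, , drop = FALSE])^2)))
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
  }
  list(centers = centers, assignments = assign_new,
       within_ss = wss_hist[length(wss_hist)], wss_history = wss_hist,
       n_iter = length(wss_hist))
}

#' k-means categorisation of calls
#'
#' Groups standardized call feature vectors into `k` categories by minimising
#' the total within-cluster sum of squared Euclidean distances to the cluster
#' centroids (Lloyd iterations, k-means++ initialization, best of `restarts`
#' runs). Nearest-centroid ties break to the lowest centroid index; an empty
#' cluster is repaired by reassigning the point farthest from its centroid.
#' A single integer seed makes the result reproducible, and rows are
#' canonically sorted before any seeded draw so the result does not depend on
#' input row order.
#'
#' @param features A [build_feature_matrix()] result (or a bare numeric
#'   matrix).
#' @param k Number of categories (2 <= k <= rows).
#' @param seed Integer seed.
#' @param restarts Number of independent initializations (>= 1).
#' @return An object of class `call_kmeans`: `k`, `centroids` (standardized
#'   units), `assignments` (original row order), `within_ss`, `wss_history`
#'   (of the winning restart), `n_iter`, `seed`, plus the feature matrix.
#' @export
cluster_calls <- function(features, k, seed = 1L, restarts = 20) {
  x <- if (inherits(features, "call_feature_matrix")) features$x else as.matrix(features)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of calls", call. = FALSE)
  stopifnot(k >= 1, restarts >= 1)
  ord <- do.call(order, as.data.frame(x)) # canonical row order
  xs <- x[ord, , drop = FALSE]
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      fit <- lloyd(xs, kmeanspp_init(xs, k))
      if (is.null(best) || fit$within_ss < best$within_ss) best <- fit
    }
  })
  assignments <- integer(n)
  assignments[ord] <- best$assignments
  structure(list(
    k = k, centroids = best$centers, assignments = assignments,
    within_ss = best$within_ss, wss_history = best$wss_history,
    n_iter = best$n_iter, seed = as.integer(seed), features = features
  ), class = "call_kmeans")
}

#' @export
print.call_kmeans <- function(x, ...) {
  cat(sprintf("<call_kmeans: k = %d, n = %d, within-SS = %.4f (%d iterations)>\n",
              x$k, length(x$assignments), x$within_ss, x$n_iter))
  invisible(x)
}

#' Tidy a call k-means fit: one row per centroid
#' @param x A `call_kmeans`.
#' @param ... Unused.
#' @return A tibble with cluster id, size and centroid coordinates
#'   (standardized units).
#' @export
tidy.call_kmeans <- function(x, ...) {
  ctr <- x$centroids
  if (is.null(colnames(ctr))) colnames(ctr) <- paste0("x", seq_len(ncol(ctr)))
  ctr <- tibble::as_tibble(ctr)
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k),
                   size = tabulate(x$assignments, x$k)),
    ctr
  )
}

#' One-row summary of a call k-means fit
#' @param x A `call_kmeans`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `within_ss`, `n_iter`, `seed`.
#' @export
glance.call_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$assignments),
                 within_ss = x$within_ss, n_iter = x$n_iter, seed = x$seed)
}

#' Attach cluster assignments to the measurement table
#' @param x A `call_kmeans`.
#' @param data The measurement tibble the features were built from.
#' @param ... Unused.
#' @return `data` with a `.cluster` column.
#' @export
augment.call_kmeans <- function(x, data, ...) {
  stopifnot(nrow(data) == length(x$assignments))
  dplyr::mutate(data, .cluster = factor(x$assignments))
}

#' Select the number of call types by mean silhouette
#'
#' Runs [cluster_calls()] for each candidate `k` and returns the `k`
#' maximising the mean silhouette width under Euclidean distance (ties go to
#' the smaller `k`).
#'
#' @param features A [build_feature_matrix()] result or numeric matrix.
#' @param k_range Candidate values of `k` (within `[2, rows - 1]`).
#' @param seed Integer seed.
#' @param restarts Restarts per candidate.
#' @return The selected `k` (integer), with the per-`k` mean silhouettes in
#'   attribute `silhouette`.
#' @export
select_k <- function(features, k_range = 2:12, seed = 1L, restarts = 10) {
  x <- if (inherits(features, "call_feature_matrix")) features$x else as.matrix(features)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(x) - 1]
  stopifnot(length(k_range) > 0)
  d <- stats::dist(x)
  sil <- vapply(k_range, function(k) {
    fit <- cluster_calls(x, k, seed = seed, restarts = restarts)
    mean(cluster::silhouette(fit$assignments, d)[, "sil_width"])
  }, numeric(1))
  best <- k_range[which.max(sil)] # which.max takes the first (smallest) tie
  structure(as.integer(best), silhouette = stats::setNames(sil, k_range))
}

#' Summarise categorised calls as per-group range tables
#'
#' For each group, reports the number of calls and the (min, max) range of
#' every measured parameter in original units — the shape of the published
#' per-call-type summary tables. Groups are ordered by size (descending), then
#' label, and relabelled `G01`, `G02`, ... in that order.
#'
#' @param measurements Measurement tibble (one row per call).
#' @param assignments Integer vector of group assignments covering every row.
#' @return A tibble with `group`, `n` and `<param>_lo`/`<param>_hi` columns.
#' @export
summarize_groups <- function(measurements, assignments) {
  stopifnot(nrow(measurements) == length(assignments))
  params <- c("min_f", "max_f", "start_f", "end_f", "delta_f", "duration",
              "n_extrema", "n_inflections", "fm_rate", "sideband_spacing")
  out <- measurements |>
    dplyr::mutate(.assign = assignments) |>
    dplyr::group_by(.data$.assign) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(params),
                    list(lo = ~ suppressWarnings(min(.x, na.rm = TRUE)),
                         hi = ~ suppressWarnings(max(.x, na.rm = TRUE))),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ replace(.x, is.infinite(.x), NA))) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$.assign)
  out |>
    dplyr::mutate(group = sprintf("G%02d", dplyr::row_number()), .before = 1) |>
    dplyr::select(-".assign")
}
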