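# Benchmark AD methods profiled alongside RDN: ensemble-STD tiers and a
# kernel-density AD on the first principal component of the training
# descriptors.

#' Ensemble-STD tier profile
#'
#' Compounds enter the AD in order of increasing ensemble standard
#' deviation: at tier edge `e` every compound with `STD <= e` is inside.
#' The default edge grid is the sorted unique STD values across all
#' datasets, thinned to at most 50 points.
#'
#' @param std per-compound ensemble STD in [0, 1]; a numeric vector (one
#'   dataset) or a named list of vectors.
#' @param correct matching correctness flags (vector or named list).
#' @param tier_edges increasing numeric vector of STD cutoffs, or `NULL`
#'   for the default grid.
#' @return An [ad_profile()] with method tag `"std"` and
#'   `threshold_param` = tier edge.
#' @export
std_profile <- function(std, correct, tier_edges = NULL) {
  if (!is.list(std)) std <- list(external = std)
  if (!is.list(correct)) correct <- list(external = correct)
  stopifnot(identical(names(std), names(correct)))
  all_std <- unlist(std, use.names = FALSE)
  if (any(all_std < 0 | all_std > 1)) stop("STD values must lie in [0, 1]")
  if (is.null(tier_edges)) {
    edges <- sort(unique(all_std))
    if (length(edges) > 50L)
      edges <- edges[unique(round(seq(1, length(edges), length.out = 50L)))]
  } else {
    edges <- tier_edges
    if (is.unsorted(edges, strictly = TRUE))
      stop("tier edges must be strictly increasing")
  }
  rows <- list()
  for (nm in names(std)) {
    s <- std[[nm]]; cf <- correct[[nm]]
    stopifnot(length(s) == length(cf))
    n_inc <- vapply(edges, function(e) sum(s <= e), integer(1))
    acc <- vapply(edges, function(e)
      if (any(s <= e)) mean(cf[s <= e]) else NA_real_, numeric(1))
    rows[[nm]] <- data.frame(iteration = seq_along(edges),
                             threshold_param = edges, dataset = nm,
                             n_included_cum = n_inc, accuracy_cum = acc)
  }
  ad_profile("std", do.call(rbind, rows),
             vapply(std, length, integer(1)))
}

#' Gaussian kernel density estimate on one dimension
#'
#' Closed-form evaluation of the Gaussian KDE fitted to `train_proj` at
#' arbitrary points.
#'
#' @param train_proj numeric vector of training projections.
#' @param bandwidth kernel bandwidth h > 0.
#' @return function of a numeric vector returning densities.
#' @keywords internal
gaussian_kde <- function(train_proj, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  force(train_proj)
  function(x)
    vapply(x, function(p)
      mean(dnorm((p - train_proj) / bandwidth)) / bandwidth, numeric(1))
}

#' KDE density AD on the first principal component
#'
#' Fits the first principal component of the (standardized) training
#' descriptors, projects every set onto it, and estimates a Gaussian kernel
#' density on the training projection. A compound is inside the AD at
#' percentile `p` when its density is at least the p-th percentile of the
#' training densities; the profile expands along a decreasing percentile
#' grid (a percentile of 0 admits every compound with positive density).
#' The PC sign is fixed so the loading of largest magnitude is positive.
#'
#' @param train a [descriptor_set()] or an already-standardized matrix.
#' @param externals named list of [descriptor_set()]s with `correct` flags,
#'   or of matrices (then supply `correct` as a parallel named list).
#' @param correct optional named list of correctness flags (needed when
#'   `externals` holds bare matrices).
#' @param bandwidth numeric bandwidth, or `"auto"` for Silverman's rule on
#'   the training projection.
#' @param percentile_grid decreasing vector of density percentiles.
#' @return An [ad_profile()] with method tag `"kde"` and
#'   `threshold_param` = percentile.
#' @export
kde_profile <- function(train, externals, correct = NULL,
                        bandwidth = "auto",
                        percentile_grid = seq(95, 0, by = -5)) {
  if (inherits(externals, "descriptor_set"))
    externals <- list(external = externals)
  if (inherits(train, "descriptor_set")) {
    std <- fit_standardizer(train)
    Xt <- apply_standardizer(std, train)
    Xe <- lapply(externals, function(s) apply_standardizer(std, s))
    if (is.null(correct))
      correct <- lapply(externals, function(s) s$correct)
  } else {
    Xt <- as.matrix(train)
    Xe <- lapply(externals, as.matrix)
  }
  if (nrow(Xt) < 2L) stop("need at least 2 training rows")
  if (any(vapply(correct, is.null, logical(1))))
    stop("correct flags required for every external set")
  if (any(diff(percentile_grid) >= 0))
    stop("percentile grid must be strictly decreasing")
  pc <- prcomp(Xt, center = TRUE, scale. = FALSE, rank. = 1)
  if (all(abs(pc$sdev) < 1e-12)) stop("zero-variance training matrix")
  load1 <- pc$rotation[, 1L]
  if (load1[which.max(abs(load1))] < 0) load1 <- -load1
  project <- function(X) drop(scale(X, center = pc$center,
                                    scale = FALSE) %*% load1)
  proj_t <- project(Xt)
  h <- if (identical(bandwidth, "auto")) bw.nrd0(proj_t) else
    as.numeric(bandwidth)
  dens <- gaussian_kde(proj_t, h)
  dens_train <- dens(proj_t)
  rows <- list()
  for (nm in names(Xe)) {
    dq <- dens(project(Xe[[nm]]))
    cf <- correct[[nm]]
    n_inc <- integer(length(percentile_grid))
    acc <- rep(NA_real_, length(percentile_grid))
    for (j in seq_along(percentile_grid)) {
      p <- percentile_grid[j]
      thr <- if (p > 0) quantile(dens_train, p / 100, names = FALSE) else 0
      inside <- dq >= thr & dq > 0
      n_inc[j] <- sum(inside)
      if (n_inc[j] > 0) acc[j] <- mean(cf[inside])
    }
    rows[[nm]] <- data.frame(iteration = seq_along(percentile_grid),
                             threshold_param = percentile_grid,
                             dataset = nm, n_included_cum = n_inc,
                             accuracy_cum = acc)
  }
  ad_profile("kde", do.call(rbind, rows),
             vapply(Xe, nrow, integer(1)))
}
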