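# ReliefF feature weighting for AD-specific descriptor selection.
#
# For each sampled instance the algorithm finds its n_neighbors nearest
# hits (same class) and misses (other class) under the Manhattan distance
# of min-max-scaled features, and moves each feature's weight down by the
# (rank-weighted) mean hit diff and up by the mean miss diff. Features that
# separate classes within local neighbourhoods gain positive weight;
# class-independent features drift to 0. Correlated copies of a relevant
# feature are scored independently and end up with equal weight.

#' ReliefF feature weights
#'
#' Binary-class ReliefF. Features are min-max scaled to [0, 1] on the full
#' dataset before computing diffs, so weights are invariant to any positive
#' rescaling of a feature. Neighbour contributions are rank-weighted by
#' `exp(-(rank/sigma)^2)` (normalised over the neighbours used) when
#' `weight_by_distance` is `TRUE`, the convention of the classical ReliefF
#' implementations; otherwise all neighbours weigh equally.
#'
#' @param X numeric matrix or data.frame (rows = instances, named columns).
#' @param y binary labels, 0/1, at least two instances per class.
#' @param n_neighbors nearest hits and misses consulted per instance
#'   (clamped with a warning if a class is too small).
#' @param sigma decay parameter of the rank-based neighbour weighting.
#' @param weight_by_distance apply the exponential rank weighting?
#' @param n_sample `NULL` for a deterministic full pass over all instances,
#'   or an integer number of instances sampled without replacement.
#' @param seed integer seed used when subsampling.
#' @return Object of class `relieff`: data.frame with columns `feature`,
#'   `weight`, `rank` (1 = best; ties broken by lexicographic feature
#'   name), with run metadata in attributes.
#' @export
relieff_weights <- function(X, y, n_neighbors = 10, sigma = 2,
                            weight_by_distance = TRUE, n_sample = NULL,
                            seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 instances per class")
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2L, function(col) diff(range(col)))
  denom <- ifelse(rng > 0, rng, 1)          # constant feature -> diff 0
  Xs <- sweep(sweep(X, 2L, apply(X, 2L, min)), 2L, denom, "/")
  Xs[, rng == 0] <- 0
  k_class <- pmin(n_neighbors, min(table(y)) - 1L)
  if (k_class < n_neighbors)
    rdn_log("warn", sprintf("n_neighbors clamped to %d (small class)",
                            k_class))
  if (is.null(n_sample)) {
    use <- seq_len(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    use <- sort(sample.int(n, min(n_sample, n)))
  }
  m <- length(use)
  D <- pairwise_manhattan(Xs)
  w <- numeric(p)
  for (i in use) {
    for (cls in c(0L, 1L)) {
      pool <- which(y == cls & seq_len(n) != i)
      k <- min(k_class, length(pool))
      ord <- pool[order(D[i, pool], pool)][seq_len(k)]
      rw <- if (weight_by_distance) {
        e <- exp(-(seq_len(k) / sigma)^2); e / sum(e)
      } else rep(1 / k, k)
      contrib <- colSums(abs(Xs[ord, , drop = FALSE] -
                               rep(Xs[i, ], each = k)) * rw)
      if (cls == y[i]) w <- w - contrib / m else w <- w + contrib / m
    }
  }
  ord <- order(-w, colnames(X))
  rk <- integer(p); rk[ord] <- seq_len(p)
  out <- data.frame(feature = colnames(X), weight = w, rank = rk,
                    stringsAsFactors = FALSE)
  structure(out, class = c("relieff", "data.frame"),
            n_neighbors = k_class, sigma = sigma,
            weight_by_distance = weight_by_distance,
            n_sample = m, seed = seed)
}

pairwise_manhattan <- function(X) {
  as.matrix(dist(X, method = "manhattan"))
}

#' @export
print.relieff <- function(x, ...) {
  cat(sprintf("<relieff> %d features, %d instances sampled, k = %d\n",
              nrow(x), attr(x, "n_sample"), attr(x, "n_neighbors")))
  top <- as.data.frame(x)[order(x$rank), ]
  print(utils::head(top, 10L), row.names = FALSE)
  invisible(x)
}

#' Average feature ranks over repeated ReliefF runs
#'
#' Runs initiated from different subsamples of the data are combined by
#' averaging each feature's rank; the final ordering is by ascending mean
#' rank (ties by lexicographic feature name).
#'
#' @param runs list of [relieff_weights()] results over identical feature
#'   sets.
#' @return data.frame with `feature`, `mean_rank` and final `rank`.
#' @export
average_ranks <- function(runs) {
  if (!length(runs)) stop("no runs supplied")
  feats <- runs[[1L]]$feature
  for (r in runs)
    if (!identical(sort(r$feature), sort(feats)))
      stop("runs cover different feature sets")
  ranks <- vapply(runs, function(r)
    r$rank[match(feats, r$feature)], numeric(length(feats)))
  mean_rank <- rowMeans(matrix(ranks, nrow = length(feats)))
  ord <- order(mean_rank, feats)
  final <- integer(length(feats)); final[ord] <- seq_along(feats)
  data.frame(feature = feats, mean_rank = mean_rank, rank = final,
             stringsAsFactors = FALSE)
}

#' Select the top-k ranked features
#'
#' @param weights a [relieff_weights()] result or an [average_ranks()]
#'   table (anything with `feature` and `rank` columns).
#' @param k number of features to keep, `k <= n_features`.
#' @return Character vector of the k best-ranked feature names.
#' @export
select_top_k <- function(weights, k = 20) {
  stopifnot(all(c("feature", "rank") %in% names(weights)))
  if (k > nrow(weights)) stop("k exceeds the number of features")
  weights$feature[order(weights$rank)][seq_len(k)]
}
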