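# Reliability-density neighbourhood (RDN) applicability domain.
#
# For each neighbour count k the algorithm computes every training
# instance's average distance to its k nearest training neighbours, bounds
# the list by the Tukey outlier fence RefVal = Q3 + 1.5 * IQR, and sets the
# instance's radius D_i to the mean distance to all training neighbours
# within RefVal (0 when none). The radius is then multiplied by a step-size
# factor (small steps near the dense core, full steps in the periphery) and
# by the instance's reliability weight W_i. A query is inside the AD at
# iteration k when it falls within the effective radius of at least
# `min_neighbors` training instances; inclusion accumulates as the union
# over k = 1..k_max. The unweighted, unit-step special case is the density
# k-NN (dk-NN) AD.

#' Pairwise Euclidean distances between two standardized matrices
#'
#' @param A,B numeric matrices with identical column sets (standardized with
#'   the same training parameters).
#' @return `nrow(A)` x `nrow(B)` matrix of Euclidean distances.
#' @export
pairwise_euclidean <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("column count mismatch")
  tA <- t(A)
  # direct differences (not the quadratic expansion): identical rows give
  # an exact 0, so closed-ball boundary tests are reproducible
  out <- vapply(seq_len(nrow(B)),
                function(j) sqrt(colSums((tA - B[j, ])^2)),
                numeric(nrow(A)))
  matrix(out, nrow = nrow(A), ncol = nrow(B))
}

#' Average distance to the k nearest training neighbours
#'
#' Self-distances are excluded. Neighbours are selected by a stable sort on
#' (distance, training index), and only the k first are used, so ties at the
#' k-th distance do not enlarge the neighbour set.
#'
#' @param distmat square training self-distance matrix.
#' @param k neighbour count, `1 <= k < nrow(distmat)`.
#' @return numeric vector, one mean distance per training instance;
#'   non-decreasing in `k` for every instance.
#' @export
avg_knn_distance <- function(distmat, k) {
  n <- nrow(distmat)
  if (k >= n) stop("k must be smaller than the number of training instances")
  vapply(seq_len(n), function(i) {
    d <- distmat[i, -i]
    mean(sort(d, method = "radix")[seq_len(k)])
  }, numeric(1))
}

#' Tukey outlier fence of a distance list
#'
#' `RefVal = Q3 + 1.5 * (Q3 - Q1)` with linear-interpolation quartiles
#' (R's default type 7), declared so distances are reproducible.
#'
#' @param values numeric vector of average k-NN distances.
#' @return The fence value.
#' @export
tukey_refval <- function(values) {
  if (!length(values)) stop("empty distance list")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Per-instance neighbourhood radii bounded by RefVal
#'
#' `D_i` is the mean distance from training instance i to all other training
#' instances at distance `<= RefVal`; 0 when no neighbour qualifies (the
#' instance then contributes no coverage).
#'
#' @param distmat square training self-distance matrix.
#' @param refval the Tukey fence from [tukey_refval()].
#' @return numeric vector of radii `D_i >= 0`.
#' @export
neighborhood_thresholds <- function(distmat, refval) {
  if (refval < 0) stop("RefVal must be non-negative")
  n <- nrow(distmat)
  mask <- distmat <= refval
  diag(mask) <- FALSE
  cnt <- rowSums(mask)
  tot <- rowSums(distmat * mask)
  ifelse(cnt > 0, tot / cnt, 0)
}

#' Distance step-size schedule
#'
#' The neighbourhood radius is scaled down near the model's dense core so
#' the AD expands slowly where small threshold increases would otherwise
#' swallow most of the data. The default schedule uses a third of the
#' neighbourhood distance for k = 1-30, half for k = 31-40, and the full
#' distance beyond k = 40.
#'
#' @param upper integer vector of k upper bounds (last may be `Inf`).
#' @param factor positive scale factor per band.
#' @return An object of class `rdn_schedule`.
#' @export
rdn_schedule <- function(upper = c(30, 40, Inf), factor = c(1/3, 1/2, 1)) {
  if (length(upper) != length(factor) || !length(upper))
    stop("upper and factor must have equal positive length")
  if (is.unsorted(upper, strictly = TRUE))
    stop("schedule upper bounds must be strictly increasing")
  if (any(factor <= 0)) stop("schedule factors must be positive")
  if (!is.infinite(upper[length(upper)])) {
    upper <- c(upper, Inf)
    factor <- c(factor, factor[length(factor)])
  }
  structure(list(upper = upper, factor = factor), class = "rdn_schedule")
}

#' Step factor at a given k
#'
#' @param k neighbour count, `k >= 1`.
#' @param schedule an [rdn_schedule()].
#' @return The scale factor applied to neighbourhood radii at this k.
#' @export
step_scale <- function(k, schedule = rdn_schedule()) {
  if (any(k < 1)) stop("k must be >= 1")
  stopifnot(inherits(schedule, "rdn_schedule"))
  idx <- vapply(k, function(kk) which(kk <= schedule$upper)[1L], integer(1))
  schedule$factor[idx]
}

#' Unit step schedule (radii used as computed)
#' @return An [rdn_schedule()] with a single factor of 1.
#' @export
unit_schedule <- function() rdn_schedule(Inf, 1)

#' Coverage of queries at one iteration's radii
#'
#' A query is inside the AD when it falls within the effective radius of at
#' least `min_neighbors` training instances. Inclusion uses the closed ball
#' (`<=`), but an instance with radius 0 offers no coverage. Equals a
#' brute-force double loop over all query/training pairs.
#'
#' @param ext_train_distmat `n_query` x `n_train` distance matrix.
#' @param effective_radii per-training-instance radii (same ordering as the
#'   matrix columns).
#' @param min_neighbors minimum number of covering training instances.
#' @return list with `included` (logical) and `n_covering` (integer).
#' @export
coverage_at_iteration <- function(ext_train_distmat, effective_radii,
                                  min_neighbors = 1) {
  if (min_neighbors < 1) stop("min_neighbors must be >= 1")
  if (ncol(ext_train_distmat) != length(effective_radii))
    stop("radius vector does not match distance matrix columns")
  hit <- sweep(ext_train_distmat, 2L, effective_radii, "<=") &
    rep(effective_radii > 0, each = nrow(ext_train_distmat))
  n_cov <- rowSums(hit)
  list(included = n_cov >= min_neighbors, n_covering = as.integer(n_cov))
}

# ---- the fitted-model interface ---------------------------------------------

#' Fit a reliability-density neighbourhood applicability domain
#'
#' Standardizes the training descriptors, precomputes training
#' self-distances, and derives the effective neighbourhood radius of every
#' training instance at every iteration k = 1..k_max: the RefVal-bounded
#' density radius D_i, scaled by the step schedule and the reliability
#' weight. With `weights = NULL` and `schedule = unit_schedule()` the fit is
#' the unweighted dk-NN AD.
#'
#' @param train a [descriptor_set()] (raw descriptors; standardization is
#'   fitted here and reused for every external set).
#' @param weights per-training-instance reliability weights W in [0, 1], or
#'   `NULL` for the unweighted method (W = 1).
#' @param k_max largest neighbour count scanned (must be < n_train).
#' @param schedule an [rdn_schedule()] of radius step factors.
#' @param min_neighbors minimum covering training instances for inclusion.
#' @return Object of class `rdn`: the standardizer, the radius matrix
#'   (`k_max` x `n_train`), and the fit parameters.
#' @seealso [rdn_profile()], [dknn_profile()], [predict.rdn()]
#' @export
rdn <- function(train, weights = NULL, k_max = 65,
                schedule = rdn_schedule(), min_neighbors = 1) {
  stopifnot(inherits(train, "descriptor_set"))
  n <- nrow(train$X)
  if (k_max >= n) stop("k_max must be smaller than the training set size")
  if (min_neighbors < 1) stop("min_neighbors must be >= 1")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("one weight per training instance required")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  std <- fit_standardizer(train)
  Xs <- apply_standardizer(std, train)
  D <- pairwise_euclidean(Xs, Xs)
  # sorted neighbour distances once; per-k means via cumulative sums
  sorted <- vapply(seq_len(n),
                   function(i) sort(D[i, -i], method = "radix"),
                   numeric(n - 1L))            # (n-1) x n
  csum <- apply(sorted, 2L, cumsum)
  radii <- matrix(0, nrow = k_max, ncol = n)
  refvals <- numeric(k_max)
  d_core <- matrix(0, nrow = k_max, ncol = n)
  for (k in seq_len(k_max)) {
    avg_k <- csum[k, ] / k
    refvals[k] <- tukey_refval(avg_k)
    d_core[k, ] <- neighborhood_thresholds(D, refvals[k])
    radii[k, ] <- d_core[k, ] * step_scale(k, schedule) * weights
  }
  structure(
    list(standardizer = std, X_train = Xs, train_ids = train$ids,
         weights = weights, k_max = k_max, schedule = schedule,
         min_neighbors = min_neighbors, refvals = refvals,
         D_i = d_core, radii = radii),
    class = "rdn")
}

#' @export
print.rdn <- function(x, ...) {
  unweighted <- all(x$weights == 1)
  cat(sprintf("<rdn> %s applicability domain\n",
              if (unweighted) "density k-NN (unweighted)" else
                "reliability-density neighbourhood"))
  cat(sprintf("  training instances: %d; descriptors: %d\n",
              ncol(x$radii), length(x$standardizer$center)))
  cat(sprintf("  k = 1..%d; min covering neighbours: %d\n",
              x$k_max, x$min_neighbors))
  if (!unweighted)
    cat(sprintf("  reliability weights: median %.3f [%.3f, %.3f]\n",
                stats::median(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' @export
summary.rdn <- function(object, ...) {
  print(object)
  cat("  RefVal by iteration band:\n")
  show_k <- unique(pmin(c(1, 10, 30, 40, object$k_max), object$k_max))
  for (k in show_k)
    cat(sprintf("    k = %2d: RefVal %.4f, median radius %.4f\n",
                k, object$refvals[k], stats::median(object$radii[k, ])))
  invisible(object)
}

#' Per-compound AD membership of new data under a fitted AD
#'
#' @param object an [rdn()] fit.
#' @param newdata a [descriptor_set()] or descriptor matrix (raw scale; the
#'   training standardizer is applied).
#' @param ... unused.
#' @return data.frame with, per compound: `first_k` (iteration of first
#'   inclusion, NA if never included), `included` (inside the AD at
#'   `k_max`), and `n_covering` at `k_max`.
#' @export
predict.rdn <- function(object, newdata, ...) {
  Xq <- apply_standardizer(object$standardizer, newdata)
  Dq <- pairwise_euclidean(Xq, object$X_train)
  first_k <- rep(NA_integer_, nrow(Xq))
  n_cov_last <- integer(nrow(Xq))
  for (k in seq_len(object$k_max)) {
    cov <- coverage_at_iteration(Dq, object$radii[k, ], object$min_neighbors)
    newly <- cov$included & is.na(first_k)
    first_k[newly] <- k
    if (k == object$k_max) n_cov_last <- cov$n_covering
  }
  data.frame(first_k = first_k, included = !is.na(first_k),
             n_covering = n_cov_last)
}

#' Plot the training radii of a fitted AD across iterations
#'
#' @param x an [rdn()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rdn <- function(x, ...) {
  graphics::matplot(seq_len(x$k_max), x$radii, type = "l", lty = 1,
                    col = grDevices::grey(0.2, alpha = 0.25),
                    xlab = "k (iteration)",
                    ylab = "effective neighbourhood radius", ...)
  graphics::lines(seq_len(x$k_max), apply(x$radii, 1L, stats::median),
                  lwd = 2)
  invisible(x)
}

#' Accuracy-versus-coverage AD profile of external sets
#'
#' Runs the fitted AD over its k iterations and, for each external set,
#' accumulates inclusion as the union over iterations and cumulative
#' accuracy (fraction of included compounds with a correct model
#' prediction) over that union. External sets must carry `correct` flags.
#'
#' @param object an [rdn()] fit.
#' @param externals a named list of [descriptor_set()]s with `correct`
#'   flags (a single set is accepted and named "external").
#' @return An [ad_profile()] (method tag `"rdn"`, or `"dknn"` when the fit
#'   is unweighted with a unit schedule).
#' @export
ad_profile_rdn <- function(object, externals) {
  stopifnot(inherits(object, "rdn"))
  if (inherits(externals, "descriptor_set"))
    externals <- list(external = externals)
  if (is.null(names(externals)) || any(!nzchar(names(externals))))
    names(externals) <- paste0("external_", seq_along(externals))
  for (ds in externals)
    if (is.null(ds$correct))
      stop("external sets need `correct` flags to profile accuracy")
  unweighted <- all(object$weights == 1) &&
    all(step_scale(seq_len(object$k_max), object$schedule) == 1)
  rows <- list()
  n_total <- vapply(externals, function(s) nrow(s$X), integer(1))
  for (nm in names(externals)) {
    set <- externals[[nm]]
    Xq <- apply_standardizer(object$standardizer, set)
    Dq <- pairwise_euclidean(Xq, object$X_train)
    inside <- rep(FALSE, nrow(Xq))
    n_inc <- integer(object$k_max)
    acc <- rep(NA_real_, object$k_max)
    for (k in seq_len(object$k_max)) {
      cov <- coverage_at_iteration(Dq, object$radii[k, ],
                                   object$min_neighbors)
      inside <- inside | cov$included
      n_inc[k] <- sum(inside)
      if (n_inc[k] > 0) acc[k] <- mean(set$correct[inside])
    }
    rows[[nm]] <- data.frame(iteration = seq_len(object$k_max),
                             threshold_param = seq_len(object$k_max),
                             dataset = nm, n_included_cum = n_inc,
                             accuracy_cum = acc)
  }
  ad_profile(if (unweighted) "dknn" else "rdn",
             do.call(rbind, rows), n_total)
}

#' RDN accuracy-versus-coverage profile (one-call interface)
#'
#' Fits [rdn()] on the training set with the supplied reliability weights
#' and profiles the external sets.
#'
#' @inheritParams rdn
#' @param externals named list of [descriptor_set()]s with `correct` flags.
#' @return An [ad_profile()].
#' @export
rdn_profile <- function(train, weights, externals, k_max = 65,
                        schedule = rdn_schedule(), min_neighbors = 1) {
  fit <- rdn(train, weights = weights, k_max = k_max, schedule = schedule,
             min_neighbors = min_neighbors)
  ad_profile_rdn(fit, externals)
}

#' Density k-NN profile: the unweighted special case
#'
#' Identical machinery to [rdn_profile()] with all weights 1 and radii used
#' as computed (unit step schedule).
#'
#' @inheritParams rdn_profile
#' @return An [ad_profile()] with method tag `"dknn"`.
#' @export
dknn_profile <- function(train, externals, k_max = 65, min_neighbors = 1) {
  rdn_profile(train, weights = rep(1, nrow(train$X)), externals,
              k_max = k_max, schedule = unit_schedule(),
              min_neighbors = min_neighbors)
}
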