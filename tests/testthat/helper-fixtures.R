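# Shared fixtures and independent oracles, built in code at test time.

# random labelled descriptor set with correctness flags
random_set <- function(n, d, seed, p_correct = 0.8) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("d", seq_len(d))))
  descriptor_set(ids = sprintf("c%03d", seq_len(n)), X = X,
                 y_observed = rbinom(n, 1, 0.5),
                 correct = rbinom(n, 1, p_correct) == 1)
}

# three collinear points at coordinates 0, 1, 3: the worked neighbourhood
# example (distances d12 = 1, d13 = 3, d23 = 2)
line_set <- function() {
  descriptor_set(ids = c("a", "b", "c"),
                 X = matrix(c(0, 1, 3), ncol = 1,
                            dimnames = list(NULL, "x")),
                 y_observed = c(0, 1, 0))
}

# Independent naive oracle: full-profile recomputation with plain loops and
# no shared code path beyond base R. Returns, per external compound, the
# iteration of first inclusion, and the cumulative inclusion counts.
naive_rdn_oracle <- function(Xtr, Xq, W, k_max, factors, min_neighbors) {
  n <- nrow(Xtr); m <- nrow(Xq)
  dtr <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    dtr[i, j] <- sqrt(sum((Xtr[i, ] - Xtr[j, ])^2))
  dq <- matrix(0, m, n)
  for (q in seq_len(m)) for (j in seq_len(n))
    dq[q, j] <- sqrt(sum((Xq[q, ] - Xtr[j, ])^2))
  first_k <- rep(NA_integer_, m)
  n_cum <- integer(k_max)
  for (k in seq_len(k_max)) {
    avg <- numeric(n)
    for (i in seq_len(n)) {
      d <- sort(dtr[i, -i])
      avg[i] <- mean(d[seq_len(k)])
    }
    qs <- stats::quantile(avg, c(0.25, 0.75), names = FALSE, type = 7)
    refval <- qs[2] + 1.5 * (qs[2] - qs[1])
    radius <- numeric(n)
    for (i in seq_len(n)) {
      nb <- dtr[i, -i][dtr[i, -i] <= refval]
      di <- if (length(nb)) mean(nb) else 0
      radius[i] <- di * factors[k] * W[i]
    }
    for (q in seq_len(m)) {
      cov <- 0L
      for (i in seq_len(n))
        if (radius[i] > 0 && dq[q, i] <= radius[i]) cov <- cov + 1L
      if (cov >= min_neighbors && is.na(first_k[q])) first_k[q] <- k
    }
    n_cum[k] <- sum(!is.na(first_k) & first_k <= k)
  }
  list(first_k = first_k, n_included_cum = n_cum)
}

# independently permute the defined accuracies of a profile curve
shuffle_curve_accuracy <- function(curve, seed) {
  set.seed(seed)
  filled <- which(curve$n_included_cum > 0)
  curve$accuracy_cum[filled] <- sample(curve$accuracy_cum[filled])
  curve
}

# random strictly-decreasing accuracy curve over a random coverage pattern
random_decreasing_curve <- function(seed, n_iter = NULL) {
  set.seed(seed)
  P <- if (is.null(n_iter)) sample(3:12, 1) else n_iter
  n_total <- sample(20:200, 1)
  first <- sample(1:5, 1)
  adds <- sample(0:8, P - 1, replace = TRUE)
  if (all(adds == 0)) adds[sample(P - 1, 1)] <- 1L
  counts <- pmin(cumsum(c(first, adds)), n_total)
  acc <- sort(runif(P, 0.3, 1), decreasing = TRUE)
  acc <- acc - seq(0, 1e-3, length.out = P)   # guarantee strict decrease
  df <- data.frame(iteration = seq_len(P), n_included_cum = counts,
                   accuracy_cum = acc)
  attr(df, "n_total") <- n_total
  df
}
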