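# Ensemble reliability: precision (1 - STD), bias (agreement) and their
# product W, the weight that shrinks a training instance's neighbourhood
# radius in the RDN applicability domain.

#' Ensemble standard deviation of a compound's predictions
#'
#' Sample standard deviation (denominator M - 1) of the M ensemble members'
#' predictions for one compound. For predictions restricted to [0, 1] the
#' result lies in [0, 1]; values exceeding 1 through floating-point noise
#' are clipped and logged.
#'
#' @param predictions numeric vector of one compound's member predictions
#'   (class labels 0/1 or class-1 probabilities), or a matrix with one row
#'   per compound.
#' @return STD per compound (scalar for a vector input).
#' @export
ensemble_std <- function(predictions) {
  if (is.matrix(predictions)) {
    if (ncol(predictions) < 2L) stop("need at least 2 ensemble members")
    out <- apply(predictions, 1L, sd)
  } else {
    if (length(predictions) < 2L) stop("need at least 2 ensemble members")
    out <- sd(predictions)
  }
  over <- out > 1
  if (any(over)) {
    rdn_log("warn", sprintf("clipped %d STD value(s) > 1", sum(over)))
    out[over] <- 1
  }
  out
}

#' Vote agreement: fraction of ensemble members predicting the observed class
#'
#' Member predictions given as probabilities are converted to class calls at
#' a 0.5 threshold; a prediction of exactly 0.5 is called class 1.
#'
#' @param predictions numeric vector (one compound) or matrix (rows =
#'   compounds) of member predictions in [0, 1].
#' @param observed observed class, 0/1 (recycled along matrix rows).
#' @return Agreement in [0, 1] per compound.
#' @export
agreement_vote <- function(predictions, observed) {
  if (!all(observed %in% c(0, 1))) stop("observed class must be 0/1")
  calls <- as.integer(predictions >= 0.5)
  if (is.matrix(predictions)) {
    calls <- matrix(calls, nrow = nrow(predictions))
    rowMeans(calls == observed)
  } else {
    mean(calls == observed)
  }
}

#' Probability agreement: one minus the distance from the mean probability
#' to the observed class
#'
#' `1 - |observed - mean_prob|`. More conservative than the vote variant:
#' high agreement requires the average predicted probability itself to sit
#' close to the observed class, not merely on the right side of 0.5.
#'
#' @param mean_prob mean ensemble class-1 probability per compound, in
#'   [0, 1].
#' @param observed observed class, 0/1.
#' @return Agreement in [0, 1].
#' @export
agreement_probability <- function(mean_prob, observed) {
  if (any(mean_prob < 0 | mean_prob > 1)) stop("mean_prob must be in [0, 1]")
  if (!all(observed %in% c(0, 1))) stop("observed class must be 0/1")
  1 - abs(observed - mean_prob)
}

#' Reliability weight W = (1 - STD) x agreement
#'
#' The first factor measures precision (accordance among the ensemble), the
#' second bias (accordance with the observed class). Both lie in [0, 1], so
#' W does too; the weight multiplies a training instance's neighbourhood
#' radius, i.e. W = 0.105 shrinks coverage by 89.5%.
#'
#' @param std ensemble standard deviation(s) in [0, 1].
#' @param agreement agreement value(s) in [0, 1].
#' @return W in [0, 1].
#' @export
reliability_weight <- function(std, agreement) {
  if (any(std < 0 | std > 1) || any(agreement < 0 | agreement > 1))
    stop("std and agreement must be in [0, 1]")
  (1 - std) * agreement
}

#' Per-compound reliability table from an ensemble prediction matrix
#'
#' Convenience wrapper computing STD, agreement (either variant) and W for
#' every compound.
#'
#' @param predictions n x M matrix of member predictions in [0, 1].
#' @param observed observed class per compound, 0/1.
#' @param variant `"vote"` (fraction of members calling the observed class)
#'   or `"probability"` (1 - |observed - mean prediction|).
#' @return data.frame with columns `std`, `agreement`, `W` and the variant
#'   as an attribute.
#' @export
reliability_table <- function(predictions, observed,
                              variant = c("vote", "probability")) {
  variant <- match.arg(variant)
  predictions <- as.matrix(predictions)
  if (any(predictions < 0 | predictions > 1))
    stop("member predictions must be in [0, 1]")
  if (nrow(predictions) != length(observed))
    stop("one observed class per prediction row required")
  std <- ensemble_std(predictions)
  agr <- if (variant == "vote") {
    agreement_vote(predictions, observed)
  } else {
    agreement_probability(rowMeans(predictions), observed)
  }
  out <- data.frame(std = std, agreement = agr,
                    W = reliability_weight(std, agr))
  attr(out, "variant") <- variant
  out
}

#' Bootstrap-bagged ensemble around a user-supplied base learner
#'
#' Fits `n_models` copies of a base learner, each on an independent
#' bootstrap resample of `sample_frac` of the training rows (drawn with
#' replacement by default). The learner contract is a function `f(X, y)`
#' returning a prediction function `g(newX)` that yields class-1
#' probabilities. A resample containing a single class is redrawn (at most
#' 100 attempts, logged).
#'
#' @param train a [descriptor_set()].
#' @param learner function `(X, y) -> function(newX) -> probabilities`.
#' @param n_models number of ensemble members.
#' @param sample_frac fraction of training rows drawn per resample.
#' @param replace draw with replacement?
#' @param seed integer seed; fixing it makes the ensemble reproducible.
#' @return Object of class `bagged_ensemble`.
#' @export
bag_ensemble <- function(train, learner, n_models = 10, sample_frac = 0.8,
                         replace = TRUE, seed = NULL) {
  stopifnot(inherits(train, "descriptor_set"))
  if (!is.function(learner)) stop("learner must be a function(X, y)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(train$X)
  size <- max(1L, round(sample_frac * n))
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, size, replace = replace)
      if (length(unique(train$y_observed[idx])) > 1L) break
      if (attempt == 100L)
        stop("could not draw a two-class resample in 100 attempts")
      rdn_log("debug", "single-class resample redrawn")
    }
    fitted <- learner(train$X[idx, , drop = FALSE], train$y_observed[idx])
    if (!is.function(fitted))
      stop("learner must return a prediction function(newX)")
    models[[m]] <- fitted
  }
  structure(list(models = models, n_models = n_models,
                 sample_frac = sample_frac, replace = replace),
            class = "bagged_ensemble")
}

#' @export
print.bagged_ensemble <- function(x, ...) {
  cat(sprintf(
    "<bagged_ensemble> %d members, %.0f%% resamples (%s replacement)\n",
    x$n_models, 100 * x$sample_frac, if (x$replace) "with" else "without"))
  invisible(x)
}

#' Predict with a bagged ensemble
#'
#' @param object a [bag_ensemble()] result.
#' @param newdata a [descriptor_set()] or descriptor matrix.
#' @param ... unused.
#' @return n x M matrix of member class-1 probabilities.
#' @export
predict.bagged_ensemble <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "descriptor_set")) newdata$X else
    as.matrix(newdata)
  preds <- vapply(object$models, function(g) {
    p <- g(X)
    if (length(p) != nrow(X)) stop("learner prediction length mismatch")
    as.numeric(p)
  }, numeric(nrow(X)))
  matrix(preds, nrow = nrow(X),
         dimnames = list(NULL, paste0("m", seq_len(object$n_models))))
}

#' Read / write a prediction table
#'
#' CSV layout: `id`, `observed`, then either member columns `m1..mM` or a
#' single `mean_prob` column.
#'
#' @param path CSV path.
#' @return list with `ids`, `observed`, and `predictions` (matrix) or
#'   `mean_prob` (vector).
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "observed") %in% names(df)))
    stop("prediction table needs 'id' and 'observed' columns")
  member_cols <- grep("^m[0-9]+$", names(df), value = TRUE)
  out <- list(ids = as.character(df$id), observed = as.integer(df$observed))
  if (length(member_cols) >= 2L) {
    out$predictions <- as.matrix(df[member_cols])
  } else if ("mean_prob" %in% names(df)) {
    out$mean_prob <- as.numeric(df$mean_prob)
  } else {
    stop("prediction table needs member columns m1..mM or a mean_prob column")
  }
  out
}
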