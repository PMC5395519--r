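# AD robustness score: compares the accuracy-versus-coverage curves that
# one AD expansion produces on two external datasets Y and Z. Each segment
# between consecutive iterations receives a slope-mismatch penalty (SMP,
# the product of per-curve penalties 1/2/4 for negative/null/positive
# accuracy slope), weighted by the fraction of combined data newly added in
# the segment; the |y - z| accuracy gap enters as a coefficient of the
# weighted penalty, and the sum is normalised by F_added, the fraction of
# combined data added between the first and last iteration (rewarding
# resolution at the model's core). Lower is better; two identical strictly
# decreasing curves score exactly 1.

#' Penalty of a single accuracy slope
#'
#' Accuracy should fall as the AD expands, so a negative slope carries no
#' penalty (1), a null slope doubles it (2) and a positive slope doubles it
#' again (4).
#'
#' @param m segment slope (accuracy against combined fraction included).
#' @param tol slopes with `|m| <= tol` count as null.
#' @return 1, 2 or 4 (vectorised over `m`).
#' @export
segment_slope_penalty <- function(m, tol = 1e-9) {
  if (any(!is.finite(m))) stop("slope must be finite")
  ifelse(m < -tol, 1, ifelse(m > tol, 4, 2))
}

#' Slope-mismatch penalty of a matched segment pair
#'
#' The product of the two curves' individual penalties: 1 (both falling)
#' up to 16 (both rising).
#'
#' @param mY,mZ segment slopes of the two curves.
#' @param tol null-slope tolerance.
#' @return SMP in \{1, 2, 4, 8, 16\}.
#' @export
pairwise_smp <- function(mY, mZ, tol = 1e-9) {
  segment_slope_penalty(mY, tol) * segment_slope_penalty(mZ, tol)
}

#' Extract one dataset's curve from an AD profile
#'
#' @param profile an [ad_profile()].
#' @param dataset dataset name within the profile.
#' @return data.frame of the curve rows with an `n_total` attribute.
#' @export
profile_dataset <- function(profile, dataset) {
  stopifnot(inherits(profile, "ad_profile"))
  nt <- attr(profile, "n_total")
  if (!dataset %in% names(nt)) stop("no dataset named ", dataset)
  out <- as.data.frame(profile[profile$dataset == dataset, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_total") <- unname(nt[dataset])
  out
}

#' AD robustness score of two external accuracy curves
#'
#' Both curves must come from the same AD expansion (identical iteration
#' grids). Leading iterations in which either dataset has no included
#' compound are dropped, since cumulative accuracy is undefined there; at
#' least two iterations, with data added after the first, must remain.
#'
#' Slopes are measured on accuracy against the combined cumulative fraction
#' of included data. Segments in which no compound is added contribute
#' nothing (their weight is 0). Alongside the difference form of the
#' normaliser (combined data added between the first and the last retained
#' iteration) the total coverage at the last iteration is also reported as
#' `f_total_coverage`.
#'
#' @param prof_y,prof_z curves from [profile_dataset()], or an
#'   [ad_profile()] holding exactly the one dataset each.
#' @param n_total_y,n_total_z dataset sizes; defaults taken from the curve
#'   attributes.
#' @param slope_tol tolerance declaring a slope null.
#' @return Object of class `ad_score`: `score`, `f_added`,
#'   `f_total_coverage`, and a per-segment breakdown.
#' @export
ad_score <- function(prof_y, prof_z, n_total_y = NULL, n_total_z = NULL,
                     slope_tol = 1e-9) {
  cy <- .as_curve(prof_y, n_total_y)
  cz <- .as_curve(prof_z, n_total_z)
  if (!identical(cy$df$iteration, cz$df$iteration))
    stop("the two curves must share the same iteration grid")
  keep <- cy$df$n_included_cum > 0 & cz$df$n_included_cum > 0
  if (!any(keep)) stop("no iteration with data included in both curves")
  first <- which(keep)[1L]
  idx <- seq(first, nrow(cy$df))
  y <- cy$df$accuracy_cum[idx];  z <- cz$df$accuracy_cum[idx]
  ny <- cy$df$n_included_cum[idx]; nz <- cz$df$n_included_cum[idx]
  P <- length(idx)
  if (P < 2L) stop("need at least two iterations with included data")
  n_total <- cy$n_total + cz$n_total
  comb <- ny + nz
  frac <- comb / n_total
  f_added <- (comb[P] - comb[1L]) / n_total
  if (f_added <= 0) stop("no instance added after the first iteration")
  seg <- data.frame(segment = idx[-1L],
                    n_added = diff(comb),
                    m_y = NA_real_, m_z = NA_real_,
                    smp = NA_real_, wp = 0,
                    acc_gap = abs(y - z)[-1L], summand = 0)
  for (s in seq_len(P - 1L)) {
    if (seg$n_added[s] == 0) next       # WP = 0, contributes nothing
    dx <- frac[s + 1L] - frac[s]
    seg$m_y[s] <- (y[s + 1L] - y[s]) / dx
    seg$m_z[s] <- (z[s + 1L] - z[s]) / dx
    seg$smp[s] <- pairwise_smp(seg$m_y[s], seg$m_z[s], slope_tol)
    seg$wp[s] <- seg$smp[s] * seg$n_added[s] / n_total
    seg$summand[s] <- seg$wp[s] * (1 + seg$acc_gap[s])
  }
  structure(
    list(score = sum(seg$summand) / f_added,
         f_added = f_added,
         f_total_coverage = comb[P] / n_total,
         n_total = n_total, p = P, segments = seg),
    class = "ad_score")
}

.as_curve <- function(prof, n_total) {
  if (inherits(prof, "ad_profile")) {
    nt <- attr(prof, "n_total")
    if (length(nt) != 1L)
      stop("profile holds several datasets; use profile_dataset()")
    prof <- profile_dataset(prof, names(nt))
  }
  if (is.null(n_total)) n_total <- attr(prof, "n_total")
  if (is.null(n_total)) stop("dataset size (n_total) unknown")
  req <- c("iteration", "n_included_cum", "accuracy_cum")
  stopifnot(all(req %in% names(prof)))
  list(df = prof[order(prof$iteration), , drop = FALSE],
       n_total = as.numeric(n_total))
}

#' @export
print.ad_score <- function(x, ...) {
  cat(sprintf("<ad_score> %.4f (lower is better)\n", x$score))
  cat(sprintf("  F_added = %.3f (total coverage at last iteration %.3f)\n",
              x$f_added, x$f_total_coverage))
  cat(sprintf("  %d iterations, %d contributing segments\n",
              x$p, sum(x$segments$n_added > 0)))
  invisible(x)
}

#' JSON breakdown of an AD score
#'
#' @param x an [ad_score()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ad_score <- function(x, path) {
  stopifnot(inherits(x, "ad_score"))
  jsonlite::write_json(
    list(score = x$score, f_added = x$f_added,
         f_total_coverage = x$f_total_coverage,
         n_total = x$n_total, segments = x$segments),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
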