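# Domain containers and delimited-text IO.
#
# Dialect: comma-separated, mandatory header, UTF-8, "." decimal.
# Missing descriptor values drop the row (never imputed); exclusions are
# reported through the package logger.

#' Construct a labelled descriptor set
#'
#' The basic container for a QSAR dataset: a numeric descriptor matrix with
#' compound identifiers, an observed binary class, and (optionally) a
#' per-compound flag saying whether the deployed QSAR model predicted it
#' correctly. The `correct` flags drive all accuracy profiling.
#'
#' @param ids character vector of compound identifiers.
#' @param X numeric matrix, rows = compounds, named columns = descriptors.
#' @param y_observed observed class per compound, coded 0/1.
#' @param correct optional logical vector: was the external model's
#'   prediction for this compound correct?
#' @return An object of class `descriptor_set`.
#' @export
descriptor_set <- function(ids, X, y_observed, correct = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  ids <- as.character(ids)
  if (nrow(X) != length(ids) || nrow(X) != length(y_observed))
    stop("ids, X rows and y_observed must have equal length")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("descriptor names must be present and unique")
  if (anyNA(X)) stop("descriptor matrix contains missing values")
  if (!all(y_observed %in% c(0, 1)))
    stop("y_observed must be coded 0/1")
  if (!is.null(correct)) {
    correct <- as.logical(correct)
    if (length(correct) != nrow(X) || anyNA(correct))
      stop("correct flags must be logical, one per compound, no NA")
  }
  structure(
    list(ids = ids, X = X, y_observed = as.integer(y_observed),
         correct = correct),
    class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d compounds x %d descriptors\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  class balance: %d / %d (1/0)",
              sum(x$y_observed == 1), sum(x$y_observed == 0)))
  if (!is.null(x$correct))
    cat(sprintf("; model accuracy on set: %.3f", mean(x$correct)))
  cat("\n")
  invisible(x)
}

#' @export
dim.descriptor_set <- function(x) dim(x$X)

#' Read a descriptor table from CSV
#'
#' Reads one row per compound: an identifier column, an observed-class
#' column (0/1), optionally a correctness column (0/1 or TRUE/FALSE), and
#' numeric descriptor columns. Rows with missing or unparseable descriptor
#' values are dropped and counted in a log message.
#'
#' @param path CSV file path.
#' @param id_col,class_col names of the identifier and class columns.
#' @param correct_col optional name of the prediction-correctness column.
#' @return A [descriptor_set()].
#' @export
read_descriptor_table <- function(path, id_col = "id", class_col = "class",
                                  correct_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(id_col, class_col, correct_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  desc_cols <- setdiff(names(raw), need)
  if (!length(desc_cols)) stop("no descriptor columns in ", path)
  X <- suppressWarnings(
    vapply(raw[desc_cols], function(col) as.numeric(col),
           numeric(nrow(raw))))
  X <- matrix(X, nrow = nrow(raw),
              dimnames = list(NULL, desc_cols))
  keep <- !apply(X, 1L, anyNA)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    rdn_log("info", sprintf(
      "%s: excluded %d row(s) with missing/unparseable descriptors", path, n_drop))
  if (!any(keep)) stop("no usable rows in ", path)
  y <- raw[[class_col]][keep]
  if (!all(y %in% c(0, 1)))
    stop("class column must be coded 0/1; found: ",
         paste(unique(setdiff(y, c(0, 1))), collapse = ", "))
  correct <- NULL
  if (!is.null(correct_col)) {
    cc <- raw[[correct_col]][keep]
    if (is.character(cc)) cc <- toupper(cc) %in% c("TRUE", "T", "1")
    correct <- as.logical(as.numeric(cc))
  }
  descriptor_set(ids = raw[[id_col]][keep], X = X[keep, , drop = FALSE],
                 y_observed = y, correct = correct)
}

#' Write a descriptor set to CSV
#'
#' @param set a [descriptor_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(set, path) {
  stopifnot(inherits(set, "descriptor_set"))
  df <- data.frame(id = set$ids, class = set$y_observed,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(set$correct)) df$correct <- as.integer(set$correct)
  df <- cbind(df, as.data.frame(set$X, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- standardization --------------------------------------------------------

#' Fit a z-score standardizer on a training set
#'
#' Estimates per-descriptor mean and standard deviation (sample SD, n - 1
#' denominator) on the training set. Descriptors with zero training variance
#' are dropped and logged: they carry no distance information. External sets
#' must always be transformed with the training parameters, never their own.
#'
#' @param train a [descriptor_set()] or numeric matrix.
#' @return An object of class `standardizer` with elements `center`, `scale`
#'   and `dropped`.
#' @export
fit_standardizer <- function(train) {
  X <- if (inherits(train, "descriptor_set")) train$X else as.matrix(train)
  if (!nrow(X)) stop("training set is empty")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  keep <- scl > 0
  if (!any(keep)) stop("all descriptors have zero training variance")
  if (any(!keep))
    rdn_log("info", sprintf("dropping %d zero-variance descriptor(s): %s",
                            sum(!keep),
                            paste(colnames(X)[!keep], collapse = ", ")))
  structure(list(center = ctr[keep], scale = scl[keep],
                 dropped = colnames(X)[!keep]),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param params a `standardizer` from [fit_standardizer()].
#' @param set a [descriptor_set()] or numeric matrix with (at least) the
#'   descriptors the standardizer retained.
#' @return The standardized numeric matrix.
#' @export
apply_standardizer <- function(params, set) {
  stopifnot(inherits(params, "standardizer"))
  X <- if (inherits(set, "descriptor_set")) set$X else as.matrix(set)
  nm <- names(params$center)
  if (!all(nm %in% colnames(X)))
    stop("set lacks descriptors the standardizer was fitted on")
  X <- X[, nm, drop = FALSE]
  scale(X, center = params$center, scale = params$scale)[, , drop = FALSE]
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("<standardizer> %d descriptors retained, %d dropped\n",
              length(x$center), length(x$dropped)))
  invisible(x)
}

# ---- AD profile container and TSV round-trip --------------------------------

#' Construct an AD profile
#'
#' An AD profile records, for an ordered sequence of iterations of an
#' expanding applicability domain, the threshold parameter (k value, STD
#' cutoff or density percentile), and per evaluated dataset the cumulative
#' number of compounds included and their cumulative accuracy (fraction of
#' included compounds whose model prediction was correct). Accuracy is `NA`
#' while the included count is zero, never 0.
#'
#' @param method one of `"rdn"`, `"dknn"`, `"std"`, `"kde"`.
#' @param data data.frame with columns `iteration`, `threshold_param`,
#'   `dataset`, `n_included_cum`, `accuracy_cum`.
#' @param n_total named integer vector: total size of each evaluated dataset.
#' @return A data.frame of class `ad_profile` with attributes `method` and
#'   `n_total`.
#' @export
ad_profile <- function(method, data, n_total) {
  method <- match.arg(method, c("rdn", "dknn", "std", "kde"))
  req <- c("iteration", "threshold_param", "dataset", "n_included_cum",
           "accuracy_cum")
  if (!all(req %in% names(data)))
    stop("profile data must have columns: ", paste(req, collapse = ", "))
  if (!nrow(data)) stop("empty profile")
  data <- data[order(data$dataset, data$iteration), req, drop = FALSE]
  rownames(data) <- NULL
  for (ds in unique(data$dataset)) {
    rows <- data[data$dataset == ds, ]
    if (is.unsorted(rows$n_included_cum))
      stop("cumulative included counts must be non-decreasing (dataset ",
           ds, ")")
    if (!ds %in% names(n_total))
      stop("n_total missing entry for dataset ", ds)
    bad <- !is.na(rows$accuracy_cum) &
      (rows$accuracy_cum < 0 | rows$accuracy_cum > 1)
    if (any(bad)) stop("accuracies must lie in [0, 1]")
    if (any(is.na(rows$accuracy_cum) != (rows$n_included_cum == 0)))
      stop("accuracy must be NA exactly while the included count is 0")
  }
  structure(data, method = method,
            n_total = n_total[unique(data$dataset)],
            class = c("ad_profile", "data.frame"))
}

#' @export
print.ad_profile <- function(x, ...) {
  nt <- attr(x, "n_total")
  cat(sprintf("<ad_profile> method=%s, %d iterations, datasets: %s\n",
              attr(x, "method"), length(unique(x$iteration)),
              paste(sprintf("%s (n=%d)", names(nt), nt), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Plot an AD profile as accuracy versus fraction of included data
#'
#' @param x an `ad_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ad_profile <- function(x, ...) {
  nt <- attr(x, "n_total")
  dss <- names(nt)
  cols <- seq_along(dss)
  plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "fraction of data inside AD",
       ylab = "cumulative accuracy",
       main = paste(toupper(attr(x, "method")), "AD profile"), ...)
  for (j in seq_along(dss)) {
    rows <- x[x$dataset == dss[j] & x$n_included_cum > 0, ]
    lines(rows$n_included_cum / nt[dss[j]], rows$accuracy_cum,
          type = "b", pch = 20, col = cols[j])
  }
  legend("bottomleft", legend = dss, col = cols, lty = 1, pch = 20, bty = "n")
  invisible(x)
}

#' Write / read an AD profile as TSV
#'
#' The file is tab-separated with a header row and two leading comment
#' lines (`# method:` and `# n_total:`) so that the round trip preserves the
#' method tag and dataset sizes. `read_profile(write_profile(p)) == p`.
#'
#' @param profile an [ad_profile()].
#' @param path file path.
#' @return `path` invisibly, or the profile for the reader.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ad_profile"))
  nt <- attr(profile, "n_total")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", attr(profile, "method")),
               sprintf("# n_total: %s",
                       paste(names(nt), nt, sep = "=", collapse = ","))), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  method <- sub("^# method:\\s*", "", grep("^# method:", hdr, value = TRUE))
  ntline <- sub("^# n_total:\\s*", "", grep("^# n_total:", hdr, value = TRUE))
  if (!length(method) || !length(ntline))
    stop("malformed profile file: missing method/n_total header")
  kv <- strsplit(strsplit(ntline, ",")[[1]], "=")
  n_total <- vapply(kv, function(p) as.integer(p[2]), integer(1))
  names(n_total) <- vapply(kv, `[`, character(1), 1L)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("empty profile file")
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ad_profile(method, df, n_total)
}

# ---- logging ----------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Package logger
#'
#' Writes timestamped messages to stderr. The threshold is controlled by
#' `options(rdnad.log_level = "info")`; levels are debug < info < warn <
#' error.
#'
#' @param level one of "debug", "info", "warn", "error".
#' @param msg message string.
#' @return `NULL`, invisibly.
#' @export
rdn_log <- function(level = "info", msg) {
  lv <- .log_levels[[match.arg(level, names(.log_levels))]]
  thr <- .log_levels[[getOption("rdnad.log_level", "info")]]
  if (lv >= thr)
    message(sprintf("[%s] %s %s", toupper(level),
                    format(Sys.time(), "%H:%M:%S"), msg))
  invisible(NULL)
}
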