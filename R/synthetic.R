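# Synthetic fixture generator: a training set and two i.i.d. external sets
# drawn from a Gaussian-mixture descriptor space with three planted
# regimes -- a dense reliable core, a dense pocket where the ensemble is
# precisely but systematically wrong (high precision, high bias), and a
# sparse noisy fringe -- plus per-compound ensemble prediction matrices
# with controlled precision (member dispersion) and bias (distance of the
# mean prediction from the observed class).

#' Region specification for the synthetic generator
#'
#' @param name region label.
#' @param n_train,n_external compounds drawn per set (each external set
#'   gets `n_external`).
#' @param centroid numeric vector: region centre in the informative
#'   descriptor dimensions.
#' @param spread standard deviation of the Gaussian cloud.
#' @param class_balance probability that a compound's true class is 1.
#' @param flip_rate probability that the observed label is flipped from the
#'   true label (label noise).
#' @param mean_correct_prob target mean ensemble probability mass on the
#'   observed class; values below 0.5 plant systematic bias.
#' @param dispersion standard deviation of the ensemble members around the
#'   target (precision control).
#' @return list of class `synthetic_region`.
#' @export
synthetic_region <- function(name, n_train, n_external, centroid,
                             spread = 1, class_balance = 0.5,
                             flip_rate = 0, mean_correct_prob = 0.85,
                             dispersion = 0.05) {
  if (flip_rate < 0 || flip_rate > 1) stop("flip rate must lie in [0, 1]")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (n_train < 1) stop("empty region")
  structure(list(name = name, n_train = n_train, n_external = n_external,
                 centroid = as.numeric(centroid), spread = spread,
                 class_balance = class_balance, flip_rate = flip_rate,
                 mean_correct_prob = mean_correct_prob,
                 dispersion = dispersion),
            class = "synthetic_region")
}

#' Default three-regime study configuration
#'
#' A dense reliable core, a dense high-precision/high-bias pocket (the
#' regime an STD-only AD mistakes for reliable), and a sparse noisy fringe.
#' Three informative descriptor dimensions plus `n_noise_features`
#' class-independent ones; a 10-member ensemble. The low dimensionality
#' keeps neighbour distances graded rather than concentrated, so the AD
#' expands gradually over k as it does on real descriptor sets.
#'
#' @param n_noise_features number of pure-noise descriptors appended.
#' @param n_members ensemble size M.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_noise_features = 2, n_members = 10) {
  regions <- list(
    core = synthetic_region(
      "core", n_train = 120, n_external = 40,
      centroid = c(0, 0, 0), spread = 1, flip_rate = 0.05,
      mean_correct_prob = 0.85, dispersion = 0.05),
    biased = synthetic_region(
      "biased", n_train = 40, n_external = 15,
      centroid = c(4, 4, 0), spread = 1, flip_rate = 0.05,
      mean_correct_prob = 0.15, dispersion = 0.03),
    sparse = synthetic_region(
      "sparse", n_train = 15, n_external = 8,
      centroid = c(-5, 3, -4), spread = 2.5, flip_rate = 0.30,
      mean_correct_prob = 0.55, dispersion = 0.30))
  structure(list(regions = regions, n_noise_features = n_noise_features,
                 n_members = n_members),
            class = "synthetic_config")
}

.sim_one_set <- function(config, n_field, prefix) {
  d_inf <- length(config$regions[[1L]]$centroid)
  rows <- list(); labs <- list(); region <- list()
  for (rg in config$regions) {
    n <- rg[[n_field]]
    y_true <- rbinom(n, 1L, rg$class_balance)
    # class-1 compounds shift along the first informative axis so labels
    # are geometrically meaningful, without affecting the AD machinery
    shift <- outer((y_true - 0.5) * 2, c(1, rep(0, d_inf - 1L)))
    Xi <- matrix(rnorm(n * d_inf, sd = rg$spread), n, d_inf)
    Xi <- sweep(Xi + shift, 2L, rg$centroid, "+")
    flip <- rbinom(n, 1L, rg$flip_rate) == 1L
    y_obs <- ifelse(flip, 1L - y_true, y_true)
    rows[[rg$name]] <- Xi
    labs[[rg$name]] <- y_obs
    region[[rg$name]] <- rep(rg$name, n)
  }
  X <- do.call(rbind, rows)
  n_all <- nrow(X)
  if (config$n_noise_features > 0)
    X <- cbind(X, matrix(rnorm(n_all * config$n_noise_features),
                         n_all, config$n_noise_features))
  colnames(X) <- c(paste0("d", seq_len(d_inf)),
                   if (config$n_noise_features > 0)
                     paste0("noise", seq_len(config$n_noise_features)))
  region <- unlist(region, use.names = FALSE)
  set <- descriptor_set(
    ids = sprintf("%s_%s_%03d", prefix, region, seq_len(n_all)),
    X = X, y_observed = unlist(labs, use.names = FALSE))
  attr(set, "region") <- region
  set
}

#' Simulate a training set and two i.i.d. external sets
#'
#' Descriptors are Gaussian clouds per region; observed labels are the true
#' labels flipped at the region's label-noise rate; noise features are
#' class-independent. Both external sets are drawn independently from the
#' same mixture, the premise under which an AD's accuracy profile should
#' look alike on both.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; fully determines the output.
#' @return list with [descriptor_set()]s `train`, `external_1`,
#'   `external_2`, each carrying a `region` attribute.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!length(config$regions)) stop("config has no regions")
  set.seed(seed)
  list(train = .sim_one_set(config, "n_train", "tr"),
       external_1 = .sim_one_set(config, "n_external", "e1"),
       external_2 = .sim_one_set(config, "n_external", "e2"))
}

#' Simulate ensemble predictions with controlled precision and bias
#'
#' Each compound's target class-1 probability puts `mean_correct_prob` mass
#' on its observed class; the M member probabilities are drawn Normal
#' around the target with the region's dispersion and truncated to [0, 1].
#' The correctness flag calls the compound correct when the mean member
#' probability, thresholded at 0.5 (ties to class 1), matches the observed
#' class. Biased regions thus yield low-STD, low-agreement rows -- the
#' failure mode an STD-only AD cannot see.
#'
#' @param dataset a [descriptor_set()] from [simulate_dataset()] (carries
#'   the `region` attribute).
#' @param config the [synthetic_config()] used to generate it.
#' @param seed integer seed.
#' @return list with `predictions` (n x M matrix), `mean_prob`, `correct`
#'   (logical), `observed`, and `region`.
#' @export
simulate_ensemble_predictions <- function(dataset, config = synthetic_config(),
                                          seed = 1) {
  stopifnot(inherits(dataset, "descriptor_set"))
  region <- attr(dataset, "region")
  if (is.null(region)) stop("dataset lacks a region attribute")
  set.seed(seed)
  n <- nrow(dataset$X); M <- config$n_members
  pars <- do.call(rbind, lapply(config$regions, function(rg)
    data.frame(name = rg$name, mcp = rg$mean_correct_prob,
               disp = rg$dispersion)))
  mcp <- pars$mcp[match(region, pars$name)]
  disp <- pars$disp[match(region, pars$name)]
  target_p1 <- ifelse(dataset$y_observed == 1L, mcp, 1 - mcp)
  preds <- matrix(rnorm(n * M, mean = rep(target_p1, M),
                        sd = rep(disp, M)), n, M)
  preds <- pmin(pmax(preds, 0), 1)
  colnames(preds) <- paste0("m", seq_len(M))
  mean_prob <- rowMeans(preds)
  correct <- (mean_prob >= 0.5) == (dataset$y_observed == 1L)
  list(predictions = preds, mean_prob = mean_prob, correct = correct,
       observed = dataset$y_observed, region = region)
}

#' One-call synthetic study: datasets, ensembles, weights and flags
#'
#' Convenience wrapper producing everything an AD profiling run needs:
#' the three descriptor sets with `correct` flags attached, the training
#' reliability weights W (vote agreement), and external STD values for the
#' STD comparator.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (sub-seeds are derived deterministically).
#' @return list with `train`, `external_1`, `external_2` (with `correct`),
#'   `weights` (training W), `ensembles` (per-set simulation output).
#' @export
simulate_study <- function(config = synthetic_config(), seed = 1) {
  sets <- simulate_dataset(config, seed = seed)
  ens <- list()
  offs <- c(train = 101L, external_1 = 102L, external_2 = 103L)
  for (nm in names(sets)) {
    ens[[nm]] <- simulate_ensemble_predictions(sets[[nm]], config,
                                               seed = seed + offs[[nm]])
    sets[[nm]]$correct <- ens[[nm]]$correct
  }
  rel <- reliability_table(ens$train$predictions, ens$train$observed,
                           variant = "vote")
  c(sets, list(weights = rel$W, ensembles = ens))
}
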