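#' Downsample epochs by within-bin averaging
#'
#' Consecutive groups of `ratio` samples are averaged; a trailing partial
#' bin averages the remaining samples. Averaging (rather than decimation)
#' doubles as a crude low-pass and is deterministic. 501 samples at ratio
#' 10 therefore yield 51 bins.
#'
#' @param epochs Numeric array `[vertices, times, trials]` (a matrix is
#'   treated as one trial).
#' @param ratio Positive integer downsampling ratio.
#' @return Array `[vertices, ceiling(times/ratio), trials]`.
#' @export
downsample_epochs <- function(epochs, ratio) {
  if (length(ratio) != 1L || is.na(ratio) || ratio != round(ratio) || ratio <= 0)
    stop("config error: downsampling ratio must be a positive integer")
  if (is.matrix(epochs)) epochs <- array(epochs, c(dim(epochs), 1L))
  d <- dim(epochs)
  if (ratio == 1L) return(epochs)
  nb <- ceiling(d[2L] / ratio)
  out <- array(0, c(d[1L], nb, d[3L]))
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * ratio + 1L):min(b * ratio, d[2L])
    out[, b, ] <- if (length(idx) > 1L)
      apply(epochs[, idx, , drop = FALSE], c(1L, 3L), mean)
    else epochs[, idx, ]
  }
  out
}

# Bin centres corresponding to downsample_epochs on a given time axis.
bin_times <- function(time_ms, ratio) {
  nb <- ceiling(length(time_ms) / ratio)
  vapply(seq_len(nb), function(b) {
    idx <- ((b - 1L) * ratio + 1L):min(b * ratio, length(time_ms))
    mean(time_ms[idx])
  }, numeric(1L))
}

#' Average trials into pseudo-trials
#'
#' Randomly permutes the trial indices and partitions them into `k`
#' near-equal disjoint groups (the first `n mod k` groups receive one extra
#' trial); each pseudo-trial is the arithmetic mean of its group. With
#' 50-80 trials and `k = 10` the group sizes are 5 to 8. Conditions with
#' fewer than `min_trials` trials raise a `condition_excluded` error
#' condition carrying the offending condition's identity.
#'
#' @param trials Numeric array `[vertices, times, n]`.
#' @param k Number of pseudo-trials.
#' @param min_trials Inclusion threshold on `n`.
#' @param label Condition label used in the exclusion signal.
#' @return List with `pseudo` (array `[k, vertices, times]`), `group_sizes`
#'   and `groups` (list of source-trial index vectors).
#' @export
make_pseudotrials <- function(trials, k = 10L, min_trials = 50L,
                              label = "condition") {
  d <- dim(trials)
  n <- d[3L]
  if (n < min_trials) {
    cond <- structure(
      class = c("condition_excluded", "error", "condition"),
      list(message = sprintf(
        "condition '%s' excluded: %d trials < min_trials = %d",
        label, n, min_trials), call = NULL, label = label, n_trials = n))
    stop(cond)
  }
  if (k > n) stop("config error: more pseudo-trials than trials")
  perm <- sample.int(n)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  groups <- lapply(seq_len(k), function(g) perm[starts[g]:ends[g]])
  # group means via one matrix product: (V*T x n) %*% (n x k)
  ind <- matrix(0, n, k)
  for (g in seq_len(k)) ind[groups[[g]], g] <- 1 / sizes[g]
  flat <- matrix(trials, ncol = n) %*% ind          # (V*T) x k
  pseudo <- aperm(array(flat, c(d[1L], d[2L], k)), c(3L, 1L, 2L))
  list(pseudo = pseudo, group_sizes = sizes, groups = groups)
}

#' Per-region principal-component features
#'
#' Fits one PCA on the vertex dimension per subject x region, pooling the
#' pseudo-trials of all conditions across all fitting timebins, so that
#' every condition and timebin is expressed in one shared low-dimensional
#' space — a prerequisite for comparing discriminant directions across time
#' and conditions. Scores are then computed for every timebin (including
#' pre-stimulus bins outside the fitting window).
#'
#' @param pseudo_list Named list (by condition) of pseudo-trial arrays
#'   `[k, vertices, timebins]`.
#' @param n_pc Number of components retained.
#' @param fit_bins Integer indices of the timebins entering the PCA fit
#'   (default: all).
#' @return Object of class `region_features`: list with `basis`
#'   (`vertices x n_pc`, orthonormal columns), `center`, `scores` (named
#'   list of `[k, timebins, n_pc]` arrays), `explained_variance`
#'   (variances of all PCs, non-increasing).
#' @export
extract_region_features <- function(pseudo_list, n_pc = 3L, fit_bins = NULL) {
  stopifnot(length(pseudo_list) >= 1L)
  get_arr <- function(x) if (is.list(x)) x$pseudo else x
  d <- dim(get_arr(pseudo_list[[1L]]))
  V <- d[2L]
  nT <- d[3L]
  if (V < n_pc) stop("config error: fewer vertices than requested components")
  if (is.null(fit_bins)) fit_bins <- seq_len(nT)
  rows <- lapply(pseudo_list, function(x) {
    a <- get_arr(x)[, , fit_bins, drop = FALSE]
    # samples = pseudo x bin, variables = vertices
    matrix(aperm(a, c(1L, 3L, 2L)), ncol = V)
  })
  X <- do.call(rbind, rows)
  if (nrow(X) < n_pc) stop("config error: too few samples for PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  basis <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  center <- pc$center
  scores <- lapply(pseudo_list, function(x) {
    a <- get_arr(x)
    k <- dim(a)[1L]
    flat <- matrix(aperm(a, c(1L, 3L, 2L)), ncol = V)   # (k*nT) x V
    sc <- sweep(flat, 2L, center) %*% basis
    array(sc, c(k, nT, n_pc))
  })
  structure(list(basis = basis, center = center, scores = scores,
                 explained_variance = pc$sdev^2),
            class = "region_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a two-class LDA classifier
#'
#' Fisher discriminant with pooled within-class covariance and a small
#' relative ridge; the boundary lies midway between the projected class
#' means and the normal `w` points toward the first class. A projected
#' score exactly on the boundary is assigned to the first class.
#'
#' @param features_a,features_b Numeric matrices `[samples, features]`.
#' @param ridge_frac Relative ridge (`ridge_frac * trace(S)/p` added to the
#'   diagonal).
#' @param class_order Character vector of length 2 naming the classes.
#' @return Object of class `trained_lda`: list with `w`, `b`, `class_order`.
#' @export
train_lda <- function(features_a, features_b, ridge_frac = 1e-6,
                      class_order = c("A", "B")) {
  A <- as.matrix(features_a); B <- as.matrix(features_b)
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 2L, nrow(B) >= 2L)
  p <- ncol(A)
  muA <- colMeans(A); muB <- colMeans(B)
  SA <- crossprod(sweep(A, 2L, muA))
  SB <- crossprod(sweep(B, 2L, muB))
  S <- (SA + SB) / (nrow(A) + nrow(B) - 2L)
  lam <- ridge_frac * sum(diag(S)) / p
  w <- tryCatch(solve(S + diag(lam, p), muA - muB),
                error = function(e) stop("singular pooled covariance even after ridge"))
  if (sqrt(sum(w^2)) == 0) stop("degenerate discriminant: identical class means")
  b <- sum(w * (muA + muB) / 2)
  structure(list(w = as.numeric(w), b = b, class_order = class_order),
            class = "trained_lda")
}

#' Classify samples with a trained LDA
#' @param fit A [train_lda()] object.
#' @param x Matrix `[samples, features]`.
#' @return Character vector of class labels.
#' @export
predict_lda <- function(fit, x) {
  s <- as.matrix(x) %*% fit$w - fit$b
  ifelse(s >= 0, fit$class_order[1L], fit$class_order[2L])
}

#' Leave-one-per-class-out cross-validated accuracy
#'
#' Enumerates all `k^2` splits that hold out exactly one pseudo-trial per
#' class (with `k = 10`: 18 training and 2 test pseudo-trials, 100 folds),
#' trains the LDA on the remainder and reports the mean proportion of
#' correctly classified held-out pseudo-trials.
#'
#' @param pseudo_a,pseudo_b Matrices `[k, n_features]`, equal `k`.
#' @param ridge_frac Relative covariance ridge.
#' @return Accuracy in `[0, 1]`.
#' @export
cross_validated_accuracy <- function(pseudo_a, pseudo_b, ridge_frac = 1e-6) {
  A <- as.matrix(pseudo_a); B <- as.matrix(pseudo_b)
  if (nrow(A) != nrow(B)) stop("config error: unequal pseudo-trial counts")
  cpp_cv_accuracy(A, B, ridge_frac)
}

# Build pseudo-trial sets and PCA features for every subject x region.
# Returns list(features[[subject]][[region]], bins, analysis_bins,
# baseline_bins, excluded), where `excluded` records subjects dropped by the
# min-trials rule.
extract_features <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "source_dataset"),
            inherits(config, "pipeline_config"))
  ratio <- config$time_bin_ms / dataset$sampling_step_ms
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("config error: time_bin_ms must be a positive integer multiple of the sampling step")
  ratio <- as.integer(round(ratio))
  bins <- bin_times(dataset$time_ms, ratio)
  analysis_bins <- which(bins >= config$analysis_window_ms[1L] &
                           bins <= config$analysis_window_ms[2L])
  baseline_bins <- which(bins >= config$baseline_window_ms[1L] &
                           bins <= config$baseline_window_ms[2L])
  set.seed(config$rng_seed)
  features <- list()
  excluded <- character(0)
  for (s in dataset$subjects) {
    sub <- list()
    dropped <- FALSE
    for (r in dataset$regions) {
      pseudo <- tryCatch(
        lapply(stats::setNames(nm = names(dataset$epochs[[s]][[r]])), function(cl) {
          ds <- downsample_epochs(dataset$epochs[[s]][[r]][[cl]], ratio)
          make_pseudotrials(ds, k = config$n_pseudotrials,
                            min_trials = config$min_trials,
                            label = paste(s, cl, sep = "/"))
        }),
        condition_excluded = function(e) e)
      if (inherits(pseudo, "condition_excluded")) {
        message("subject ", s, " excluded: ", conditionMessage(pseudo))
        excluded <- c(excluded, s)
        dropped <- TRUE
        break
      }
      sub[[r]] <- extract_region_features(pseudo, n_pc = config$n_pc,
                                          fit_bins = analysis_bins)
    }
    if (!dropped) features[[s]] <- sub
  }
  if (!length(features)) stop("all subjects excluded")
  list(features = features, bins = bins, analysis_bins = analysis_bins,
       baseline_bins = baseline_bins, excluded = excluded,
       design = dataset$design, config = config)
}

#' Empirical RDMs from pairwise decoding
#'
#' For every subject, region and analysis timebin, computes the
#' leave-one-per-class-out cross-validated LDA accuracy for each of the 28
#' condition pairs, assembled in canonical pair order. Accuracy plays the
#' role of a dissimilarity: conditions evoking more distinct patterns
#' decode better. Subjects with any condition below the trial-count
#' threshold are dropped from the analysis (and listed in `excluded`).
#'
#' @param dataset A [source_dataset()].
#' @param config A [pipeline_config()].
#' @param features Optional precomputed result of the internal feature
#'   extraction (reused across analyses to keep the pseudo-trial partition
#'   identical); when `NULL` it is computed here.
#' @return Object of class `empirical_rdms`: list with `acc` (array
#'   `[subject, region, pair, timebin]`), `pairs` (canonical pair table),
#'   `bin_ms` (timebin centres, analysis window only), `excluded`, and the
#'   feature set in `features`.
#' @export
compute_empirical_rdms <- function(dataset, config = pipeline_config(),
                                   features = NULL) {
  fs <- features %||% extract_features(dataset, config)
  pairs <- condition_pairs(fs$design)
  subj <- names(fs$features)
  regions <- names(fs$features[[1L]])
  nb <- length(fs$analysis_bins)
  acc <- array(NA_real_,
               c(length(subj), length(regions), nrow(pairs), nb),
               dimnames = list(subj, regions, NULL, NULL))
  for (si in seq_along(subj)) {
    for (ri in seq_along(regions)) {
      sc <- fs$features[[si]][[ri]]$scores
      for (pi in seq_len(nrow(pairs))) {
        a <- sc[[pairs$member_a[pi]]][, fs$analysis_bins, , drop = FALSE]
        b <- sc[[pairs$member_b[pi]]][, fs$analysis_bins, , drop = FALSE]
        acc[si, ri, pi, ] <- cpp_cv_accuracy_tc(a, b, config$ridge_frac)
      }
    }
  }
  structure(list(acc = acc, pairs = pairs,
                 bin_ms = fs$bins[fs$analysis_bins],
                 excluded = fs$excluded, features = fs,
                 config = config),
            class = "empirical_rdms")
}

#' @export
print.empirical_rdms <- function(x, ...) {
  d <- dim(x$acc)
  cat("<empirical_rdms>", d[1L], "subjects x", d[2L], "regions x", d[3L],
      "pairs x", d[4L], "timebins\n")
  if (length(x$excluded))
    cat("  excluded subjects:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
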