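#' Named condition groups for generalization analyses
#'
#' Convenience accessor returning the condition labels of the standard
#' groups: `"pre_objects"` (naively unrecognizable), `"post_objects"`
#' (induced recognition), `"nonsense_s1"`, `"nonsense_s2"` and `"nonsense"`
#' (both sessions).
#'
#' @param design A [condition_design()].
#' @param group Group name.
#' @return Character vector of condition labels.
#' @export
condition_group <- function(design, group = c("pre_objects", "post_objects",
                                              "nonsense_s1", "nonsense_s2",
                                              "nonsense")) {
  group <- match.arg(group)
  cond <- design$conditions
  switch(group,
         pre_objects = cond$label[cond$state == "pre"],
         post_objects = cond$label[cond$state == "post"],
         nonsense_s1 = cond$label[cond$state == "s1"],
         nonsense_s2 = cond$label[cond$state == "s2"],
         nonsense = cond$label[cond$stim_class == "nonsense"])
}

#' Specification of a temporal cross-category generalization
#'
#' A classifier is trained to separate group A from group B (one image per
#' group at a time) at a train time, and tested on group C vs group D at a
#' test time, with the class correspondence A-C and B-D.
#'
#' @param design A [condition_design()].
#' @param train_a,train_b,test_a,test_b Character vectors of condition
#'   labels (e.g. from [condition_group()]).
#' @return Object of class `generalization_spec`.
#' @export
generalization_spec <- function(design, train_a, train_b, test_a, test_b) {
  cond <- design$conditions
  groups <- list(train_a = train_a, train_b = train_b,
                 test_a = test_a, test_b = test_b)
  for (g in names(groups)) {
    if (!length(groups[[g]])) stop("spec error: group ", g, " is empty")
    bad <- setdiff(groups[[g]], cond$label)
    if (length(bad))
      stop("spec error: unknown condition(s) ", paste(bad, collapse = ", "))
  }
  images <- lapply(groups, function(g)
    unique(cond$stimulus_id[match(g, cond$label)]))
  structure(list(design = design, groups = groups, images = images),
            class = "generalization_spec")
}

#' Admissible image combinations for a generalization spec
#'
#' Enumerates the cross product of one-image-per-group choices for the
#' training and testing pairs. When a testing group coincides with a
#' training group (same condition set), combinations in which the same
#' image is chosen from that group for both training and testing are
#' dropped — testing must never reuse a training image from a shared
#' group. With no shared group, train/test independence holds
#' automatically and all combinations are kept.
#'
#' @param spec A [generalization_spec()].
#' @return Data frame with columns `train_a`, `train_b`, `test_a`,
#'   `test_b` (stimulus ids), one row per admissible combination.
#' @export
admissible_combinations <- function(spec) {
  stopifnot(inherits(spec, "generalization_spec"))
  combos <- expand.grid(train_a = spec$images$train_a,
                        train_b = spec$images$train_b,
                        test_a = spec$images$test_a,
                        test_b = spec$images$test_b,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  shared <- list()
  for (tr in c("train_a", "train_b")) {
    for (te in c("test_a", "test_b")) {
      if (setequal(spec$groups[[tr]], spec$groups[[te]]))
        shared[[length(shared) + 1L]] <- c(tr, te)
    }
  }
  keep <- rep(TRUE, nrow(combos))
  for (sh in shared)
    keep <- keep & combos[[sh[1L]]] != combos[[sh[2L]]]
  combos <- combos[keep, , drop = FALSE]
  if (!nrow(combos))
    stop("spec error: the image-exclusion rule leaves no admissible combination")
  rownames(combos) <- NULL
  combos
}

# scores for the conditions of `group` restricted to stimulus `img`,
# concatenated along pseudo-trials, analysis bins only: k' x T x p cube
group_scores <- function(sc, design, group, img, bins) {
  labs <- intersect(group,
                    design$conditions$label[design$conditions$stimulus_id == img])
  if (!length(labs)) stop("spec error: image ", img, " absent from group")
  parts <- lapply(labs, function(l) sc[[l]][, bins, , drop = FALSE])
  if (length(parts) == 1L) return(parts[[1L]])
  k <- vapply(parts, function(a) dim(a)[1L], integer(1L))
  out <- array(0, c(sum(k), length(bins), dim(parts[[1L]])[3L]))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Temporal generalization matrices
#'
#' For each subject and each admissible image combination, trains an LDA on
#' all pseudo-trials of the training pair at every train timebin and tests
#' it on the testing pair at every test timebin (class correspondence
#' train-A to test-A). When the restricted test pair is identical to the
#' restricted training pair, diagonal cells (train time = test time) are
#' replaced by the leave-one-per-class-out cross-validated accuracy so the
#' classifier is never scored on its own training samples. Accuracies are
#' averaged over combinations.
#'
#' @param fs Feature set from the internal extraction (e.g.
#'   `rdms$features`).
#' @param region Region label.
#' @param spec A [generalization_spec()].
#' @return Object of class `generalization_matrix`: list with `accuracy`
#'   (array `[subject, train bin, test bin]`), `bin_ms` (analysis bins),
#'   `combos` (the admissible combination table).
#' @export
generalization_matrix <- function(fs, region, spec) {
  combos <- admissible_combinations(spec)
  bins <- fs$analysis_bins
  subj <- names(fs$features)
  nT <- length(bins)
  acc <- array(0, c(length(subj), nT, nT),
               dimnames = list(subj, NULL, NULL))
  design <- spec$design
  for (si in seq_along(subj)) {
    sc <- fs$features[[subj[si]]][[region]]$scores
    total <- matrix(0, nT, nT)
    for (ci in seq_len(nrow(combos))) {
      A <- group_scores(sc, design, spec$groups$train_a, combos$train_a[ci], bins)
      B <- group_scores(sc, design, spec$groups$train_b, combos$train_b[ci], bins)
      C <- group_scores(sc, design, spec$groups$test_a, combos$test_a[ci], bins)
      D <- group_scores(sc, design, spec$groups$test_b, combos$test_b[ci], bins)
      same_pair <- identical(dim(A), dim(C)) && identical(dim(B), dim(D)) &&
        combos$train_a[ci] == combos$test_a[ci] &&
        combos$train_b[ci] == combos$test_b[ci] &&
        setequal(spec$groups$train_a, spec$groups$test_a) &&
        setequal(spec$groups$train_b, spec$groups$test_b)
      total <- total + cpp_generalization(A, B, C, D, fs$config$ridge_frac,
                                          same_pair)
    }
    acc[si, , ] <- total / nrow(combos)
  }
  structure(list(accuracy = acc, bin_ms = fs$bins[bins], combos = combos),
            class = "generalization_matrix")
}

#' Cross-exemplar temporal generalization
#'
#' Trains on one object exemplar (pre-training state) against the nonsense
#' group and tests on the *other* exemplar (post-training state) against
#' the nonsense group, averaging both exemplar assignments. The nonsense
#' group spans both sessions, so the shared-group image-exclusion rule
#' forces the testing pair to use a different nonsense image than training;
#' since stimulus-specific patterns do not transfer across exemplars,
#' accuracy above chance at (t_train, t_test) isolates activity components
#' shared across the category — e.g. a component that reappears with a
#' latency shift once recognition is induced shows up as an off-diagonal
#' cluster at test times shifted by that delay.
#'
#' @param fs Feature set from the internal extraction.
#' @param region Region label.
#' @param design A [condition_design()] (defaults to the feature set's).
#' @return A `generalization_matrix` (accuracy averaged over the two
#'   exemplar assignments and their admissible nonsense combinations).
#' @export
cross_exemplar_generalization <- function(fs, region, design = fs$design) {
  cond <- design$conditions
  obj <- unique(cond$stimulus_id[cond$stim_class == "object"])
  stopifnot(length(obj) == 2L)
  non <- condition_group(design, "nonsense")
  mats <- lapply(1:2, function(i) {
    tr <- obj[i]; te <- obj[3L - i]
    sp <- generalization_spec(
      design,
      train_a = paste0(tr, "_pre"),
      train_b = non,
      test_a = paste0(te, "_post"),
      test_b = non)
    generalization_matrix(fs, region, sp)
  })
  out <- mats[[1L]]
  out$accuracy <- (mats[[1L]]$accuracy + mats[[2L]]$accuracy) / 2
  out$combos <- rbind(mats[[1L]]$combos, mats[[2L]]$combos)
  out
}

#' Cluster-based sign-flip permutation test on generalization matrices
#'
#' Cell-wise one-sample t-tests of accuracy against chance define
#' suprathreshold cells (two-sided pointwise threshold
#' `cluster_definition_p`); 4-connected clusters of same-sign cells are
#' scored by their size. The null distribution of the maximal cluster size
#' is built by randomly flipping the sign of each subject's whole
#' (accuracy - chance) matrix, preserving within-subject correlation
#' structure. Clusters larger than the `1 - cluster_alpha` quantile of that
#' distribution are reported significant.
#'
#' @param gm A [generalization_matrix()] result (or an array
#'   `[subject, t1, t2]`).
#' @param config A [pipeline_config()].
#' @param chance Chance accuracy (default 0.5).
#' @return Object of class `cluster_result`: list with `clusters` (data
#'   frame `id`, `sign`, `size`, `p`, `significant`), `cells` (list of cell
#'   index matrices), `tmap`, `threshold`, `null_max` (permutation
#'   distribution).
#' @export
cluster_permutation_2d <- function(gm, config = pipeline_config(),
                                   chance = 0.5) {
  X3 <- if (inherits(gm, "generalization_matrix")) gm$accuracy else gm
  stopifnot(length(dim(X3)) == 3L)
  n <- dim(X3)[1L]
  if (n < 2L) stop("cluster test needs at least 2 subjects")
  nperm <- config$n_permutations
  if (nperm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  d1 <- dim(X3)[2L]; d2 <- dim(X3)[3L]
  X <- matrix(X3, nrow = n) - chance          # n x (d1*d2)
  thr <- stats::qt(1 - config$cluster_definition_p / 2, df = n - 1L)
  ssq <- colSums(X^2)
  tmap_of <- function(m) {
    v <- (ssq - n * m^2) / (n - 1L)
    t <- m / sqrt(v / n)
    t[v <= 0] <- 0
    t
  }
  tobs <- matrix(tmap_of(colMeans(X)), d1, d2)

  observed_clusters <- function(tm) {
    out <- list()
    for (sgn in c(1, -1)) {
      mask <- matrix(as.integer(sgn * tm > thr), d1, d2)
      lab <- cpp_label_clusters(mask)
      for (id in setdiff(unique(as.vector(lab)), 0L)) {
        cells <- which(lab == id, arr.ind = TRUE)
        out[[length(out) + 1L]] <- list(sign = sgn, cells = cells,
                                        size = nrow(cells))
      }
    }
    out
  }
  obs <- observed_clusters(tobs)

  set.seed((config$rng_seed %% 2147483600L) + 17L)
  null_max <- integer(nperm)
  chunk <- 500L
  done <- 0L
  while (done < nperm) {
    m <- min(chunk, nperm - done)
    S <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
    M <- (S %*% X) / n
    for (r in seq_len(m)) {
      tm <- matrix(tmap_of(M[r, ]), d1, d2)
      mx <- max(cpp_max_cluster_size(matrix(as.integer(tm > thr), d1, d2)),
                cpp_max_cluster_size(matrix(as.integer(tm < -thr), d1, d2)))
      null_max[done + r] <- mx
    }
    done <- done + m
  }

  sizes <- vapply(obs, `[[`, numeric(1L), "size")
  pvals <- vapply(sizes, function(sz)
    (1 + sum(null_max >= sz)) / (nperm + 1), numeric(1L))
  clusters <- data.frame(
    id = seq_along(obs),
    sign = vapply(obs, `[[`, numeric(1L), "sign"),
    size = sizes,
    p = pvals,
    significant = pvals < config$cluster_alpha)
  structure(list(clusters = clusters,
                 cells = lapply(obs, `[[`, "cells"),
                 tmap = tobs, threshold = thr, null_max = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$clusters), "suprathreshold cluster(s),",
      sum(x$clusters$significant), "significant\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
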