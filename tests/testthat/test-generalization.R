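des <- condition_design("face")

test_that("admissible combinations follow the shared-group image-exclusion rule", {
  # fully disjoint groups: all 16 combinations survive
  sp1 <- generalization_spec(des,
                             train_a = condition_group(des, "pre_objects"),
                             train_b = condition_group(des, "nonsense_s1"),
                             test_a = condition_group(des, "post_objects"),
                             test_b = condition_group(des, "nonsense_s2"))
  expect_equal(nrow(admissible_combinations(sp1)), 16L)

  # shared nonsense group: drop same-nonsense-image reuse, object reuse allowed
  non <- condition_group(des, "nonsense")
  sp2 <- generalization_spec(des,
                             train_a = condition_group(des, "post_objects"),
                             train_b = non,
                             test_a = condition_group(des, "pre_objects"),
                             test_b = non)
  cmb <- admissible_combinations(sp2)
  expect_equal(nrow(cmb), 2 * 2 * 2 * 1)
  expect_true(all(cmb$train_b != cmb$test_b))
  expect_true(any(cmb$train_a == cmb$test_a))

  # train pair = test pair: both groups shared
  sp3 <- generalization_spec(des,
                             train_a = condition_group(des, "post_objects"),
                             train_b = non,
                             test_a = condition_group(des, "post_objects"),
                             test_b = non)
  cmb3 <- admissible_combinations(sp3)
  expect_true(all(cmb3$train_a != cmb3$test_a & cmb3$train_b != cmb3$test_b))
  expect_equal(nrow(cmb3), 4L)
})

test_that("admissible combinations equal the brute-force filter for many group layouts", {
  non <- condition_group(des, "nonsense")
  layouts <- list(
    list(train_a = condition_group(des, "pre_objects"), train_b = non,
         test_a = condition_group(des, "post_objects"), test_b = non),
    list(train_a = condition_group(des, "post_objects"), train_b = non,
         test_a = condition_group(des, "post_objects"), test_b = non),
    list(train_a = condition_group(des, "pre_objects"),
         train_b = condition_group(des, "nonsense_s1"),
         test_a = condition_group(des, "post_objects"),
         test_b = condition_group(des, "nonsense_s2")))
  for (ly in layouts) {
    sp <- do.call(generalization_spec, c(list(des), ly))
    got <- admissible_combinations(sp)
    want <- oracle_admissible(sp$groups, sp$images)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("generalization matrices are square over analysis bins; same-group diagonals test only unseen images", {
  # a strong-signal dataset so that within-pair decoding is clearly above
  # the cross-exemplar transfer the same-group diagonal measures
  cfg <- tiny_config(n_subjects = 2, n_vertices = 20, rng_seed = 51,
                     snr = 0.5)
  ds <- simulate_dataset(cfg)
  pcfg <- pipeline_config(analysis_window_ms = c(0, 100), rng_seed = 51)
  rd <- compute_empirical_rdms(ds, pcfg)
  fs <- rd$features
  sp <- generalization_spec(des,
                            train_a = condition_group(des, "post_objects"),
                            train_b = condition_group(des, "nonsense_s2"),
                            test_a = condition_group(des, "post_objects"),
                            test_b = condition_group(des, "nonsense_s2"))
  gm <- generalization_matrix(fs, "r1", sp)
  nb <- length(fs$analysis_bins)
  expect_equal(dim(gm$accuracy), c(2L, nb, nb))
  expect_true(all(gm$accuracy >= 0 & gm$accuracy <= 1))

  # the image-exclusion rule means diagonal cells classify exemplars the
  # classifier never saw: with stimulus-specific patterns this transfer
  # stays near chance while within-pair CV decoding (the RDM) is high
  rn_pairs <- which(rd$pairs$component == "RN")
  late <- fs$bins[fs$analysis_bins] >= 60       # evoked part of the window
  for (si in 1:2) {
    diag_gm <- diag(gm$accuracy[si, , ])[late]
    rdm_mean <- apply(rd$acc[si, "r1", rn_pairs, ], 2, mean)[late]
    # (projections of distinct random patterns into 3 PCs overlap at this
    # vertex count, so cross-exemplar transfer sits above chance but well
    # below within-pair decoding)
    expect_gt(mean(rdm_mean), mean(diag_gm) + 0.1)
    expect_lt(mean(diag_gm), 0.8)
  }
})

test_that("transposing the train/test roles transposes the expected effect support", {
  cfg <- sim_config(n_subjects = 4, regions = "r1", n_vertices = 24,
                    n_trials = 50, rng_seed = 55, snr = 0.5,
                    effects = list(effect_spec("delayed_shared_pattern", "r1",
                                               c(60, 100), 80)))
  ds <- simulate_dataset(cfg)
  pcfg <- pipeline_config(analysis_window_ms = c(0, 200), rng_seed = 55)
  fs <- sourcemvpa:::extract_features(ds, pcfg)
  fwd <- cross_exemplar_generalization(fs, "r1")          # pre->post
  # reversed roles: train on post (bump at 140-180), test on pre (60-100)
  des1 <- ds$design
  obj <- unique(des1$conditions$stimulus_id[des1$conditions$stim_class == "object"])
  rev_mats <- lapply(1:2, function(i) {
    sp <- generalization_spec(des1,
                              train_a = paste0(obj[i], "_post"),
                              train_b = condition_group(des1, "nonsense_s2"),
                              test_a = paste0(obj[3 - i], "_pre"),
                              test_b = condition_group(des1, "nonsense_s1"))
    generalization_matrix(fs, "r1", sp)$accuracy
  })
  bwd <- (rev_mats[[1]] + rev_mats[[2]]) / 2
  bins <- fs$bins[fs$analysis_bins]
  w1 <- bins >= 60 & bins <= 100       # shared pattern in pre state
  w2 <- bins >= 140 & bins <= 180      # shared pattern in post state
  fwd_eff <- mean(fwd$accuracy[, w1, w2])     # train pre@W, test post@W+dt
  bwd_eff <- mean(bwd[, w2, w1])              # train post@W+dt, test pre@W
  fwd_off <- mean(fwd$accuracy[, w2, w1])
  expect_gt(fwd_eff, 0.55)
  expect_gt(bwd_eff, 0.55)
  expect_lt(fwd_off, fwd_eff - 0.03)
})

test_that("cluster permutation finds a single broad injected effect and nothing in pure noise", {
  set.seed(52)
  n <- 8; d <- 15
  base <- array(0.5, c(n, d, d))
  eff <- base
  eff[, 4:8, 6:10] <- 0.62
  eff <- eff + array(rnorm(n * d * d, sd = 0.03), c(n, d, d))
  cfg <- pipeline_config(n_permutations = 500, rng_seed = 52)
  cr <- cluster_permutation_2d(eff, cfg)
  expect_gte(sum(cr$clusters$significant), 1L)
  top <- cr$cells[[which.max(cr$clusters$size)]]
  expect_true(all(top[, 1] %in% 3:9) && all(top[, 2] %in% 5:11))

  quiet <- base + array(rnorm(n * d * d, sd = 0.03), c(n, d, d))
  cr0 <- cluster_permutation_2d(quiet, cfg)
  expect_equal(sum(cr0$clusters$significant), 0L)

  flat <- base
  crf <- cluster_permutation_2d(flat, cfg)
  expect_equal(nrow(crf$clusters), 0L)
})

test_that("cluster p-values are monotone non-increasing in cluster size", {
  set.seed(53)
  n <- 6; d <- 12
  x <- array(0.5 + rnorm(n * d * d, sd = 0.05), c(n, d, d))
  x[, 2:5, 2:5] <- x[, 2:5, 2:5] + 0.1
  x[, 9:10, 9:10] <- x[, 9:10, 9:10] + 0.1
  cr <- cluster_permutation_2d(x, pipeline_config(n_permutations = 300,
                                                  rng_seed = 53))
  cl <- cr$clusters
  if (nrow(cl) >= 2) {
    o <- order(cl$size)
    expect_true(all(diff(cl$p[o]) <= 1e-12))
  }
  expect_warning(cluster_permutation_2d(x, pipeline_config(n_permutations = 50,
                                                           rng_seed = 1)),
                 "100 permutations")
})

test_that("cluster labelling matches a reference flood fill with 4-connectivity", {
  ref_label <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    cur <- 0L
    for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
      if (mask[i, j] == 0 || lab[i, j] != 0) next
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        cell <- queue[[1]]; queue <- queue[-1]
        for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          r <- cell[1] + dd[1]; c2 <- cell[2] + dd[2]
          if (r >= 1 && r <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask) &&
              mask[r, c2] != 0 && lab[r, c2] == 0) {
            lab[r, c2] <- cur
            queue[[length(queue) + 1]] <- c(r, c2)
          }
        }
      }
    }
    lab
  }
  set.seed(54)
  for (i in 1:10) {
    mask <- matrix(as.integer(runif(80) < 0.4), 8, 10)
    got <- sourcemvpa:::cpp_label_clusters(mask)
    want <- ref_label(mask)
    # same partition: sizes agree and labels are a relabelling
    expect_equal(sort(table(got[got > 0])), sort(table(want[want > 0])),
                 ignore_attr = TRUE)
    expect_equal(got > 0, want > 0, ignore_attr = TRUE)
    expect_equal(sourcemvpa:::cpp_max_cluster_size(mask),
                 max(0, table(want[want > 0])))
  }
})
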