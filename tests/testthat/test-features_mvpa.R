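test_that("downsampling averages within bins: 501 samples at ratio 10 give 51 bins", {
  x <- array(rnorm(2 * 501 * 3), c(2, 501, 3))
  y <- downsample_epochs(x, 10)
  expect_equal(dim(y), c(2, 51, 3))
  # last bin is the mean of the single remaining sample
  expect_equal(y[, 51, ], x[, 501, ])
  expect_equal(y[1, 1, 1], mean(x[1, 1:10, 1]))

  const <- array(3.7, c(1, 40, 2))
  expect_true(all(downsample_epochs(const, 10) == 3.7))

  ramp <- array(0:9, c(1, 10, 1))
  expect_equal(as.numeric(downsample_epochs(ramp, 10)), 4.5)
  expect_error(downsample_epochs(ramp, 0), "positive integer")
})

test_that("pseudo-trial partitions are disjoint, cover all trials, and have near-equal sizes for any seed", {
  x <- array(rnorm(4 * 5 * 75), c(4, 5, 75))
  for (seed in 1:10) {
    set.seed(seed)
    pt <- make_pseudotrials(x, k = 10, min_trials = 50)
    expect_equal(sort(unlist(pt$groups)), 1:75)
    expect_equal(sum(pt$group_sizes), 75L)
    expect_equal(sort(unique(pt$group_sizes)), c(7L, 8L))
    expect_equal(sum(pt$group_sizes == 8L), 5L)
  }
  # each pseudo-trial is the mean of its group
  set.seed(1)
  pt <- make_pseudotrials(x, k = 10, min_trials = 50)
  g1 <- pt$groups[[1]]
  expect_equal(pt$pseudo[1, , ],
               apply(x[, , g1, drop = FALSE], c(1, 2), mean))
})

test_that("50 trials give ten groups of five; 49 trials raise the exclusion signal", {
  x50 <- array(0, c(2, 3, 50))
  set.seed(2)
  pt <- make_pseudotrials(x50, k = 10, min_trials = 50)
  expect_true(all(pt$group_sizes == 5L))

  x49 <- array(0, c(2, 3, 49))
  err <- tryCatch(make_pseudotrials(x49, k = 10, min_trials = 50,
                                    label = "sub01/O1_pre"),
                  condition_excluded = function(e) e)
  expect_s3_class(err, "condition_excluded")
  expect_match(conditionMessage(err), "sub01/O1_pre")
  expect_equal(err$n_trials, 49L)
})

test_that("region PCA yields an orthonormal basis with non-increasing variance and exact low-rank recovery", {
  set.seed(3)
  k <- 10; V <- 12; nT <- 6
  # rank-1 data in vertex space
  u <- rnorm(V)
  p1 <- lapply(1:2, function(i) {
    a <- array(0, c(k, V, nT))
    for (g in 1:k) for (t in 1:nT) a[g, , t] <- rnorm(1) * u
    a
  })
  names(p1) <- c("c1", "c2")
  f1 <- extract_region_features(p1, n_pc = 3)
  expect_gt(f1$explained_variance[1] / sum(f1$explained_variance), 0.99)

  # orthonormality
  G <- crossprod(f1$basis)
  expect_equal(G, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(f1$explained_variance) <= 1e-10))

  # rank-3 data reconstruct exactly from 3 PCs
  B <- qr.Q(qr(matrix(rnorm(V * 3), V, 3)))
  p3 <- list(c1 = array(0, c(k, V, nT)))
  for (g in 1:k) for (t in 1:nT) p3$c1[g, , t] <- B %*% rnorm(3)
  f3 <- extract_region_features(p3, n_pc = 3)
  for (t in 1:nT) {
    orig <- p3$c1[, , t]
    centred <- sweep(orig, 2, f3$center)
    recon <- f3$scores$c1[, t, ] %*% t(f3$basis)
    expect_equal(recon, centred, tolerance = 1e-8)
  }
  expect_error(extract_region_features(p3, n_pc = 20), "fewer vertices")
})

test_that("train_lda matches the closed form and its conventions", {
  set.seed(4)
  # isotropic classes, mean difference along first axis -> w parallel (1,0,0)
  A <- matrix(rnorm(300 * 3, sd = 1), 300, 3); A[, 1] <- A[, 1] + 8
  B <- matrix(rnorm(300 * 3, sd = 1), 300, 3)
  fit <- train_lda(A, B)
  wn <- fit$w / sqrt(sum(fit$w^2))
  expect_gt(abs(wn[1]), 0.99)
  # w points toward the first class
  expect_gt(mean(predict_lda(fit, A) == "A"), 0.99)
  expect_gt(mean(predict_lda(fit, B) == "B"), 0.99)

  # exact closed form on a hand covariance
  A2 <- rbind(c(1, 0), c(2, 1), c(3, -1), c(2, 0))
  B2 <- rbind(c(-1, 0), c(-2, 1), c(-3, -1), c(-2, 0))
  muA <- colMeans(A2); muB <- colMeans(B2)
  S <- (crossprod(sweep(A2, 2, muA)) + crossprod(sweep(B2, 2, muB))) / 6
  lam <- 1e-6 * sum(diag(S)) / 2
  w_ref <- solve(S + diag(lam, 2), muA - muB)
  fit2 <- train_lda(A2, B2)
  expect_equal(fit2$w, as.numeric(w_ref), tolerance = 1e-10)
  expect_equal(fit2$b, sum(w_ref * (muA + muB) / 2), tolerance = 1e-10)
})

test_that("cross-validated accuracy enumerates k^2 folds and equals the brute-force oracle", {
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(rnorm(30), 10, 3) + 0.8
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(cross_validated_accuracy(A, B),
                 oracle_cv_accuracy(A, B), tolerance = 1e-12)
  }
  # fold count: accuracies are multiples of 1/(2 * k^2)
  A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
  acc <- cross_validated_accuracy(A, B)
  expect_equal(acc * 200, round(acc * 200), tolerance = 1e-9)
  expect_error(cross_validated_accuracy(A, B[1:9, ]), "unequal")

  # separable classes decode perfectly
  expect_equal(cross_validated_accuracy(A + 100, B), 1)
})

test_that("accuracy is invariant under a common invertible affine map of the feature space", {
  set.seed(6)
  A <- matrix(rnorm(30), 10, 3) + 1
  B <- matrix(rnorm(30), 10, 3)
  M <- matrix(c(2, 0.5, 0, -1, 3, 0.2, 0.4, 0, 1.5), 3, 3)
  shift <- c(5, -2, 7)
  tA <- A %*% M + matrix(shift, 10, 3, byrow = TRUE)
  tB <- B %*% M + matrix(shift, 10, 3, byrow = TRUE)
  # ridge breaks exact equivariance; use ridge ~ 0
  expect_equal(cross_validated_accuracy(tA, tB, ridge_frac = 1e-14),
               cross_validated_accuracy(A, B, ridge_frac = 1e-14),
               tolerance = 1e-9)
})

test_that("null-feature accuracy is symmetric about chance", {
  set.seed(7)
  accs <- replicate(200, {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    cross_validated_accuracy(A, B)
  })
  # mean within binomial-style CI around 0.5
  expect_lt(abs(mean(accs) - 0.5), 3 * stats::sd(accs) / sqrt(200))
  # symmetry: skew of the accuracy distribution is small
  expect_lt(abs(mean((accs - mean(accs))^3)) / stats::sd(accs)^3, 0.6)
})

test_that("empirical RDMs have canonical geometry and drop subjects failing the trial threshold", {
  cfg <- tiny_config(n_subjects = 2, n_trials = 50, rng_seed = 12)
  ds <- simulate_dataset(cfg)
  # sabotage one condition of subject 2: too few trials
  ds$epochs$sub02$r1$O1_pre <- ds$epochs$sub02$r1$O1_pre[, , 1:49]
  pcfg <- pipeline_config(analysis_window_ms = c(0, 100), rng_seed = 12)
  expect_message(rd <- compute_empirical_rdms(ds, pcfg), "sub02 excluded")
  expect_equal(dim(rd$acc)[1], 1L)
  expect_equal(rd$excluded, "sub02")
  expect_equal(dim(rd$acc)[3], 28L)
  expect_equal(dim(rd$acc)[4], 11L)   # 0..100 ms inclusive at 10 ms
  expect_true(all(rd$acc >= 0 & rd$acc <= 1))
})

test_that("LDA cross-check: package discriminant direction agrees with MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(8)
  A <- matrix(rnorm(60), 20, 3) + 1.5
  B <- matrix(rnorm(60), 20, 3)
  fit <- train_lda(A, B, ridge_frac = 1e-12)
  m <- MASS::lda(rbind(A, B), grouping = rep(c("A", "B"), each = 20))
  wm <- as.numeric(m$scaling)
  cosang <- abs(sum(fit$w * wm)) / sqrt(sum(fit$w^2) * sum(wm^2))
  expect_gt(cosang, 1 - 1e-6)
})
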