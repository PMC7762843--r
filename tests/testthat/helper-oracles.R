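# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's own implementations.

# Leave-one-per-class-out CV by explicit double loop over held-out indices,
# with LDA solved from first principles at each fold.
oracle_cv_accuracy <- function(A, B, ridge_frac = 1e-6) {
  k <- nrow(A); p <- ncol(A)
  folds <- 0; acc <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      trA <- A[-i, , drop = FALSE]; trB <- B[-j, , drop = FALSE]
      muA <- colMeans(trA); muB <- colMeans(trB)
      S <- (crossprod(sweep(trA, 2, muA)) + crossprod(sweep(trB, 2, muB))) /
        (nrow(trA) + nrow(trB) - 2)
      S <- S + diag(ridge_frac * sum(diag(S)) / p, p)
      w <- solve(S, muA - muB)
      b <- sum(w * (muA + muB) / 2)
      ok <- (sum(w * A[i, ]) - b >= 0) + (sum(w * B[j, ]) - b < 0)
      acc <- acc + ok / 2
      folds <- folds + 1
    }
  }
  acc / folds
}

# Rule-table classification of a condition pair's profile component, written
# directly from the pairwise-comparison definitions.
oracle_pair_component <- function(cond, la, lb) {
  a <- cond[cond$label == la, ]; b <- cond[cond$label == lb, ]
  if (a$stim_class == "object" && b$stim_class == "object") {
    if (a$state == "pre" && b$state == "pre") return("dU")
    if (a$state == "post" && b$state == "post") return("dR")
    if (a$stimulus_id == b$stimulus_id) return("sRU") else return("dRU")
  }
  if (a$stim_class == "nonsense" && b$stim_class == "nonsense") {
    if (a$stimulus_id == b$stimulus_id) return("sNa")
    if (a$state == b$state) return("dN") else return("dNa")
  }
  st <- c(a$state, b$state)
  if ("pre" %in% st) "UN" else "RN"
}

# Benjamini-Hochberg step-up rule coded directly from its definition.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * q)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# Brute-force filter over the full image cross product for generalization
# combinations: drop a combination iff some group occurs in both the train
# and the test pair (same condition set) and contributes the same image to
# both.
oracle_admissible <- function(groups, images) {
  grid <- expand.grid(train_a = images$train_a, train_b = images$train_b,
                      test_a = images$test_a, test_b = images$test_b,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ok <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    drop <- FALSE
    for (tr in c("train_a", "train_b")) {
      for (te in c("test_a", "test_b")) {
        if (setequal(groups[[tr]], groups[[te]]) &&
            grid[r, tr] == grid[r, te]) drop <- TRUE
      }
    }
    ok[r] <- !drop
  }
  grid[ok, , drop = FALSE]
}

# Spearman rho from first principles: Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Tiny deterministic dataset builder for structural tests.
tiny_config <- function(..., n_subjects = 2, regions = "r1", n_vertices = 8,
                        n_trials = 50, rng_seed = 1) {
  sim_config(n_subjects = n_subjects, regions = regions,
             n_vertices = n_vertices, n_trials = n_trials,
             rng_seed = rng_seed, ...)
}

fast_pipeline_config <- function(...) {
  pipeline_config(analysis_window_ms = c(0, 100), n_permutations = 500, ...)
}
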