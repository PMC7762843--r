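#' Analysis pipeline configuration
#'
#' Collects the tunable constants of the decoding/RSA pipeline. Defaults
#' reproduce the canonical settings: a 0-500 ms analysis window binned at
#' 10 ms (51 bins), 10 pseudo-trials per condition with a 50-trial
#' inclusion threshold, 3 principal components per region, FDR level
#' q = 0.05 over all region x timebin tests, and a 10,000-permutation
#' sign-flip cluster test with a pointwise cluster-definition threshold of
#' p < 0.05.
#'
#' @param analysis_window_ms `(start, end)` of the decoding window in ms.
#' @param time_bin_ms Width of one analysis timebin in ms; the downsampling
#'   ratio is `time_bin_ms / sampling_step_ms` of the dataset and must be a
#'   positive integer.
#' @param n_pseudotrials Pseudo-trials per condition (`k`); cross-validation
#'   enumerates `k^2` leave-one-per-class-out folds.
#' @param min_trials Minimum retained trials for a condition; below this the
#'   condition (and with it the subject, for RDM analyses) is excluded.
#' @param n_pc Principal components per region used as LDA features.
#' @param ridge_frac Relative ridge added to the pooled covariance,
#'   `ridge_frac * trace(S)/n_pc`.
#' @param fdr_q Benjamini-Hochberg FDR level for the effect map.
#' @param n_permutations Sign-flip permutations of the 2D cluster test.
#' @param cluster_alpha Familywise significance level of the cluster test.
#' @param cluster_definition_p Pointwise (two-sided) threshold that defines
#'   cluster membership.
#' @param baseline_window_ms `(start, end)` of the pre-stimulus baseline.
#' @param rng_seed Integer seed for the pseudo-trial partitions and the
#'   permutation draws.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(analysis_window_ms = c(0, 500),
                            time_bin_ms = 10,
                            n_pseudotrials = 10L,
                            min_trials = 50L,
                            n_pc = 3L,
                            ridge_frac = 1e-6,
                            fdr_q = 0.05,
                            n_permutations = 10000L,
                            cluster_alpha = 0.05,
                            cluster_definition_p = 0.05,
                            baseline_window_ms = c(-200, 0),
                            rng_seed = 1L) {
  stopifnot(length(analysis_window_ms) == 2L,
            analysis_window_ms[1L] < analysis_window_ms[2L],
            time_bin_ms > 0, n_pseudotrials >= 2L, n_pc >= 1L,
            fdr_q > 0, fdr_q < 1, cluster_definition_p > 0,
            cluster_definition_p < 1)
  structure(list(analysis_window_ms = analysis_window_ms,
                 time_bin_ms = time_bin_ms,
                 n_pseudotrials = as.integer(n_pseudotrials),
                 min_trials = as.integer(min_trials),
                 n_pc = as.integer(n_pc),
                 ridge_frac = ridge_frac,
                 fdr_q = fdr_q,
                 n_permutations = as.integer(n_permutations),
                 cluster_alpha = cluster_alpha,
                 cluster_definition_p = cluster_definition_p,
                 baseline_window_ms = baseline_window_ms,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}
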