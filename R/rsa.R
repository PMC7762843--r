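#' Spearman correlation of an empirical RDM with the model RDM
#'
#' Spearman rank correlation with average ranks for ties (the model vector
#' is binary, so its ties are structural), Fisher-transformed via
#' [fisher_z()]. An empirical vector with zero variance has no defined
#' correlation; it is reported as `rho = 0` with `degenerate = TRUE` so the
#' caller can exclude it from group statistics rather than silently
#' propagate an `NA`.
#'
#' @param empirical Numeric vector of 28 pairwise decoding accuracies in
#'   canonical pair order.
#' @param model Binary vector from [model_rdm()].
#' @return List with `rho`, `z`, `degenerate`.
#' @export
rsa_correlation <- function(empirical, model) {
  stopifnot(length(empirical) == length(model))
  if (stats::sd(empirical) == 0 || stats::sd(model) == 0)
    return(list(rho = 0, z = 0, degenerate = TRUE))
  rho <- stats::cor(empirical, model, method = "spearman")
  list(rho = rho, z = as.numeric(fisher_z(rho)), degenerate = FALSE)
}

#' Nine-component profile of an empirical RDM
#'
#' Averages the 28 RDM entries within each of the nine pairwise-comparison
#' components and forms the entry-count-weighted averages of the six
#' low-dissimilarity components (dU, dR, dN, dNa, sNa, UN) and the three
#' high-dissimilarity components (RN, sRU, dRU) of the model.
#'
#' @param empirical Numeric vector of 28 entries in canonical pair order.
#' @param pairs Canonical pair table from [condition_pairs()].
#' @return List with `component_means` (named, length 9), `weights`,
#'   `low_avg`, `high_avg`.
#' @export
compute_profile <- function(empirical, pairs) {
  stopifnot(length(empirical) == nrow(pairs))
  comp <- profile_components()
  means <- vapply(comp, function(cm)
    mean(empirical[pairs$component == cm]), numeric(1L))
  w <- profile_weights()
  low <- comp[1:6]; high <- comp[7:9]
  list(component_means = means,
       weights = w,
       low_avg = sum(means[low] * w[low]) / sum(w[low]),
       high_avg = sum(means[high] * w[high]) / sum(w[high]))
}

profile_contrast_defs <- list(
  "dR-dU"   = c(plus = "dR",  minus = "dU"),
  "dNa-dN"  = c(plus = "dNa", minus = "dN"),
  "sNa"     = c(plus = "sNa", minus = NA),
  "RN-UN"   = c(plus = "RN",  minus = "UN"),
  "sRU-sNa" = c(plus = "sRU", minus = "sNa")
)

#' Profile contrasts across subjects
#'
#' Computes one of the canonical profile contrasts per subject and tests it
#' across subjects: `dR-dU` (recognition-induced within-category
#' differentiation), `dNa-dN` and `sNa` (session-change controls; `sNa` is
#' tested against chance level 0.5), `RN-UN` (recognition gain in decoding
#' objects against nonsense) and `sRU-sNa` (decoding the same image pre vs
#' post, controlling for session changes).
#'
#' @param profiles Matrix `[subjects, 9]` of per-subject component means
#'   (columns in [profile_components()] order), e.g. averaged over a
#'   region and time window.
#' @param contrast One of `"dR-dU"`, `"dNa-dN"`, `"sNa"`, `"RN-UN"`,
#'   `"sRU-sNa"`.
#' @param alternative Sidedness of the t-test.
#' @return List with `values` (per subject), `t` (a [one_sample_t()]
#'   record) and `contrast`.
#' @export
profile_contrast <- function(profiles, contrast,
                             alternative = "two.sided") {
  if (!contrast %in% names(profile_contrast_defs))
    stop("config error: unknown contrast '", contrast, "'")
  profiles <- as.matrix(profiles)
  stopifnot(ncol(profiles) == 9L, nrow(profiles) >= 2L)
  colnames(profiles) <- profile_components()
  def <- profile_contrast_defs[[contrast]]
  vals <- if (is.na(def["minus"]))
    profiles[, def["plus"]] - 0.5
  else profiles[, def["plus"]] - profiles[, def["minus"]]
  list(values = unname(vals),
       t = one_sample_t(vals, mu = 0, alternative = alternative),
       contrast = contrast)
}

#' Per-subject RDM profiles in a region x window
#'
#' Helper over [compute_empirical_rdms()] output: averages each subject's
#' RDM entries over the timebins of `window_ms` in `region`, then reduces
#' to the nine component means.
#'
#' @param rdms An `empirical_rdms` object.
#' @param region Region label.
#' @param window_ms `(start, end)` in ms.
#' @return Matrix `[subjects, 9]` of component means.
#' @export
window_profiles <- function(rdms, region, window_ms) {
  stopifnot(inherits(rdms, "empirical_rdms"))
  bins <- which(rdms$bin_ms >= window_ms[1L] & rdms$bin_ms <= window_ms[2L])
  if (!length(bins)) stop("config error: window contains no timebins")
  subj <- dimnames(rdms$acc)[[1L]]
  out <- t(vapply(subj, function(s) {
    entry <- apply(rdms$acc[s, region, , bins, drop = FALSE], 3L, mean)
    compute_profile(entry, rdms$pairs)$component_means
  }, numeric(9L)))
  colnames(out) <- profile_components()
  out
}

#' Region x time effect map of model-RDM correlations
#'
#' For each region and analysis timebin, Fisher-z model correlations are
#' tested against zero across subjects (one-sided by default: the model
#' RDM predicts a positive rank correlation); p-values are
#' Benjamini-Hochberg corrected jointly across all region x timebin cells
#' of the analysis.
#'
#' @param rdms An `empirical_rdms` object.
#' @param config A [pipeline_config()] (supplies `fdr_q`).
#' @param alternative Sidedness of the cell-wise t-test (default
#'   `"greater"`).
#' @return Object of class `effect_map`: data frame with columns `region`,
#'   `bin_ms`, `mean_z`, `t`, `p`, `significant`, plus attributes `q` and
#'   `n_subjects`. Degenerate (zero-variance) subject RDMs are excluded
#'   cell-wise.
#' @export
searchlight_effect_map <- function(rdms, config = rdms$config,
                                   alternative = "greater") {
  stopifnot(inherits(rdms, "empirical_rdms"))
  d <- dim(rdms$acc)
  if (d[1L] < 2L) stop("effect map needs at least 2 subjects")
  model <- model_rdm(rdms$pairs)
  regions <- dimnames(rdms$acc)[[2L]]
  rows <- list()
  for (ri in seq_along(regions)) {
    for (bi in seq_len(d[4L])) {
      zs <- vapply(seq_len(d[1L]), function(si) {
        rc <- rsa_correlation(rdms$acc[si, ri, , bi], model)
        if (rc$degenerate) NA_real_ else rc$z
      }, numeric(1L))
      zs <- zs[!is.na(zs)]
      tt <- if (length(zs) < 2L)
        list(statistic = 0, p = 1)   # all subject RDMs degenerate: no evidence
      else one_sample_t(zs, mu = 0, alternative = alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        region = regions[ri], bin_ms = rdms$bin_ms[bi],
        mean_z = if (length(zs)) mean(zs) else 0,
        t = tt$statistic, p = tt$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- fdr_bh(out$p, config$fdr_q)
  attr(out, "q") <- config$fdr_q
  attr(out, "n_subjects") <- d[1L]
  class(out) <- c("effect_map", class(out))
  out
}

#' Window summary of an effect map
#'
#' Flags a region in a window when at least half of the window's timebins
#' are FDR-significant.
#'
#' @param emap An [searchlight_effect_map()] result.
#' @param windows Named list of `(start, end)` windows in ms.
#' @return Data frame `region`, `window`, `n_bins`, `n_significant`,
#'   `flagged`.
#' @export
effect_map_windows <- function(emap, windows) {
  stopifnot(inherits(emap, "effect_map"))
  rows <- list()
  for (wn in names(windows)) {
    w <- windows[[wn]]
    sub <- emap[emap$bin_ms >= w[1L] & emap$bin_ms <= w[2L], ]
    agg <- stats::aggregate(significant ~ region, data = sub,
                            FUN = function(x) c(n = length(x), k = sum(x)))
    rows[[wn]] <- data.frame(region = agg$region, window = wn,
                             n_bins = agg$significant[, "n"],
                             n_significant = agg$significant[, "k"],
                             flagged = agg$significant[, "k"] >=
                               agg$significant[, "n"] / 2,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
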