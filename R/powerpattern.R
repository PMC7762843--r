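#' RMS power of the principal-component scores
#'
#' Per timebin, the root-mean-square over the `n_pc` scores is computed for
#' each pseudo-trial and then averaged over pseudo-trials. Computing RMS
#' per pseudo-trial before averaging keeps the measure robust to pattern
#' cancellation across pseudo-trials.
#'
#' @param feat A `region_features` object.
#' @param condition Condition label.
#' @return Numeric vector of RMS power per timebin (all bins, including
#'   pre-stimulus ones).
#' @export
rms_power_timecourse <- function(feat, condition) {
  sc <- feat$scores[[condition]]
  if (is.null(sc)) stop("no features for condition '", condition, "'")
  apply(sc, 2L, function(m) mean(sqrt(rowMeans(m^2))))
}

#' Session x group power table for the repeated-measures ANOVA
#'
#' Builds the per-subject 2 x 2 cell means of RMS power in a region and
#' time window, with factors SESSION (first: object pre / nonsense session
#' 1; second: object post / nonsense session 2) and GROUP (objects vs
#' nonsense).
#'
#' @param fs Feature set from the internal extraction (e.g.
#'   `rdms$features`).
#' @param region Region label.
#' @param window_ms `(start, end)` in ms.
#' @return Long data frame `subject`, `session`, `group`, `rms`.
#' @export
subject_power_table <- function(fs, region, window_ms) {
  bins <- which(fs$bins >= window_ms[1L] & fs$bins <= window_ms[2L])
  if (!length(bins)) stop("config error: window contains no timebins")
  cond <- fs$design$conditions
  cells <- list(
    c(session = "first",  group = "object",   state = "pre"),
    c(session = "second", group = "object",   state = "post"),
    c(session = "first",  group = "nonsense", state = "s1"),
    c(session = "second", group = "nonsense", state = "s2"))
  rows <- list()
  for (s in names(fs$features)) {
    feat <- fs$features[[s]][[region]]
    for (cell in cells) {
      labs <- cond$label[cond$state == cell[["state"]]]
      rms <- mean(vapply(labs, function(l)
        mean(rms_power_timecourse(feat, l)[bins]), numeric(1L)))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, session = cell[["session"]], group = cell[["group"]],
        rms = rms, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Session x group repeated-measures ANOVA on RMS power
#'
#' @param power_table Output of [subject_power_table()].
#' @return [rm_anova()] table with effects SESSION, GROUP and their
#'   interaction. A recognition-specific power gain appears as the
#'   SESSION x GROUP interaction: objects gain power from the first to the
#'   second session while nonsense images do not.
#' @export
power_anova <- function(power_table) {
  rm_anova(power_table, dv = "rms", subject = "subject",
           factors = c("session", "group"))
}

#' Angle between two discriminant normals
#'
#' `acos` of the normalized inner product, in degrees, orientation
#' preserved (not folded to `<= 90` degrees) — both normals must follow the
#' same class-order convention for the angle to be interpretable.
#'
#' @param w_pre,w_post Numeric vectors (same length, nonzero norm).
#' @return Angle in degrees in `[0, 180]`.
#' @export
pattern_angle <- function(w_pre, w_post) {
  n1 <- sqrt(sum(w_pre^2)); n2 <- sqrt(sum(w_post^2))
  if (n1 == 0 || n2 == 0) stop("numerical error: zero-norm discriminant normal")
  acos(max(-1, min(1, sum(w_pre * w_post) / (n1 * n2)))) * 180 / pi
}

#' Alpha-angle timecourse and baseline comparison
#'
#' For every subject and timebin, trains two LDA classifiers on all
#' pseudo-trials — post-state object vs nonsense and pre-state object vs
#' nonsense, object class first, the nonsense stimulus session-matched to
#' the object state (pre with session 1, post with session 2) — and
#' measures the angle alpha between their discriminant normals, averaged
#' over the four (object stimulus, nonsense stimulus) choices. A small
#' alpha means the discriminative pattern survived recognition training; a
#' large alpha means it reorganized. The chance level of alpha is estimated
#' from the pre-stimulus baseline bins, where both normals are noise-driven,
#' and the window mean is compared to the baseline mean with a paired
#' t-test across subjects.
#'
#' @param fs Feature set from the internal extraction (e.g.
#'   `rdms$features`).
#' @param region Region label.
#' @param window_ms Effect window `(start, end)` in ms.
#' @param alternative Sidedness of the paired t-test (default two-sided).
#' @return Object of class `pattern_angle_result`: list with `alpha`
#'   (matrix subjects x all timebins), `bin_ms`, `window_alpha`,
#'   `baseline_alpha` (per-subject means), `t` (paired t record).
#' @export
angle_timecourse_vs_baseline <- function(fs, region, window_ms,
                                         alternative = "two.sided") {
  if (!length(fs$baseline_bins))
    stop("config error: no baseline timebins in the dataset")
  cond <- fs$design$conditions
  obj <- unique(cond$stimulus_id[cond$stim_class == "object"])
  non <- unique(cond$stimulus_id[cond$stim_class == "nonsense"])
  subj <- names(fs$features)
  nb <- length(fs$bins)
  ridge <- fs$config$ridge_frac
  alpha <- matrix(NA_real_, length(subj), nb,
                  dimnames = list(subj, NULL))
  for (s in subj) {
    sc <- fs$features[[s]][[region]]$scores
    acc <- matrix(0, length(obj) * length(non), nb)
    row <- 0L
    for (o in obj) {
      for (n in non) {
        row <- row + 1L
        w_pre <- cpp_lda_normals(sc[[paste0(o, "_pre")]],
                                 sc[[paste0(n, "_s1")]], ridge)
        w_post <- cpp_lda_normals(sc[[paste0(o, "_post")]],
                                  sc[[paste0(n, "_s2")]], ridge)
        dots <- rowSums(w_pre * w_post) /
          (sqrt(rowSums(w_pre^2)) * sqrt(rowSums(w_post^2)))
        acc[row, ] <- acos(pmin(1, pmax(-1, dots))) * 180 / pi
      }
    }
    alpha[s, ] <- colMeans(acc)
  }
  wbins <- which(fs$bins >= window_ms[1L] & fs$bins <= window_ms[2L])
  if (!length(wbins)) stop("config error: window contains no timebins")
  window_alpha <- rowMeans(alpha[, wbins, drop = FALSE])
  baseline_alpha <- rowMeans(alpha[, fs$baseline_bins, drop = FALSE])
  structure(list(alpha = alpha, bin_ms = fs$bins,
                 window_alpha = window_alpha,
                 baseline_alpha = baseline_alpha,
                 t = paired_t(window_alpha, baseline_alpha,
                              alternative = alternative)),
            class = "pattern_angle_result")
}

#' Per-subject recognition decoding gain (RN - UN)
#'
#' Mean decoding accuracy of post-state objects vs nonsense minus pre-state
#' objects vs nonsense, averaged over a region and window.
#'
#' @param rdms An `empirical_rdms` object.
#' @param region Region label.
#' @param window_ms `(start, end)` in ms.
#' @return Named numeric vector per subject.
#' @export
recognition_decoding_gain <- function(rdms, region, window_ms) {
  bins <- which(rdms$bin_ms >= window_ms[1L] & rdms$bin_ms <= window_ms[2L])
  rn <- which(rdms$pairs$component == "RN")
  un <- which(rdms$pairs$component == "UN")
  subj <- dimnames(rdms$acc)[[1L]]
  vapply(subj, function(s)
    mean(rdms$acc[s, region, rn, bins]) - mean(rdms$acc[s, region, un, bins]),
    numeric(1L))
}

#' Per-subject recognition power change
#'
#' Mean RMS power of post-state object conditions minus pre-state object
#' conditions in a region and window.
#'
#' @inheritParams subject_power_table
#' @return Named numeric vector per subject.
#' @export
recognition_power_delta <- function(fs, region, window_ms) {
  bins <- which(fs$bins >= window_ms[1L] & fs$bins <= window_ms[2L])
  cond <- fs$design$conditions
  post <- cond$label[cond$state == "post"]
  pre <- cond$label[cond$state == "pre"]
  vapply(names(fs$features), function(s) {
    feat <- fs$features[[s]][[region]]
    mean(vapply(post, function(l) mean(rms_power_timecourse(feat, l)[bins]),
                numeric(1L))) -
      mean(vapply(pre, function(l) mean(rms_power_timecourse(feat, l)[bins]),
                  numeric(1L)))
  }, numeric(1L))
}

#' Across-subject association of decoding gain and power change
#'
#' Spearman correlation across subjects between the recognition-induced
#' decoding gain and the recognition-induced power change; the p-value is
#' exact for n <= 12 without ties and uses the t approximation otherwise.
#'
#' @param decoding_gain,power_delta Numeric vectors, one value per subject.
#' @return List with `rho`, `p`, `n`.
#' @export
decoding_power_association <- function(decoding_gain, power_delta) {
  stopifnot(length(decoding_gain) == length(power_delta))
  n <- length(decoding_gain)
  if (n < 5L) stop("correlation across fewer than 5 subjects is meaningless")
  use_exact <- n <= 12L && !anyDuplicated(decoding_gain) &&
    !anyDuplicated(power_delta)
  ct <- suppressWarnings(stats::cor.test(decoding_gain, power_delta,
                                         method = "spearman",
                                         exact = use_exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
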