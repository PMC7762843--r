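#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic source-data
#' generator: a multi-subject pre/post perceptual-training design with two
#' object and two nonsense stimuli per analysis category, region-specific
#' evoked spatial patterns, spatially and temporally smooth sensor noise
#' projected to source space, and optional injectable recognition effects.
#'
#' Per (subject, region, stimulus) a unit-norm spatial pattern over vertices
#' is drawn independently — there is no vertex correspondence across
#' subjects, mirroring the fact that region-based decoding needs no
#' inter-subject vertex alignment. Object stimuli evoke the same pattern in
#' the pre and post state unless an effect changes that; nonsense stimuli
#' evoke the same pattern in both sessions unless `session_drift > 0`
#' perturbs the session-2 pattern.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param regions Character vector of region labels (default 6 regions).
#' @param n_vertices Vertices per region (default 50).
#' @param n_trials Trials per condition (default 75).
#' @param time_ms Time axis in ms (default -200 to 500 in 10 ms steps, i.e.
#'   71 samples at the analysis resolution).
#' @param peak_ms,shape Gamma-shaped evoked envelope: unit peak at `peak_ms`
#'   (default 120 ms), `shape` controls its width (default 3: the response
#'   rises from stimulus onset, peaks near 120 ms and decays through
#'   ~300 ms, emulating the sustained tail of evoked source activity).
#' @param snr Signal-to-noise ratio: per-vertex RMS of the evoked signal at
#'   the envelope peak divided by per-vertex noise RMS (default 0.2; see the
#'   methods vignette for the calibration rationale — this places pairwise
#'   decoding of distinct stimuli in the 0.6-0.8 accuracy range typical of
#'   source-space MEG decoding).
#' @param session_drift In `[0, 1]`: fraction by which the session-2
#'   nonsense pattern is rotated toward a random orthogonal direction
#'   (default 0, i.e. stable sessions).
#' @param effects List of [effect_spec()] objects.
#' @param effect_sd Relative between-subject spread of effect magnitudes:
#'   each subject's power-gain factor is the nominal `magnitude` scaled by
#'   `max(0, 1 + effect_sd * z)`, `z` standard normal (default 1, i.e.
#'   pronounced individual differences in training benefit, some subjects
#'   barely profiting). Rotation angles and delays are held fixed across
#'   subjects.
#' @param rng_seed Integer seed; identical configs (incl. seed) produce
#'   bit-identical datasets.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16L,
                       regions = c("rIO", "rMO", "rInsula", "rOF", "rFG", "rSTSp"),
                       n_vertices = 50L,
                       n_trials = 75L,
                       time_ms = seq(-200, 500, by = 10),
                       peak_ms = 120,
                       shape = 3,
                       snr = 0.2,
                       session_drift = 0,
                       effects = list(),
                       effect_sd = 1,
                       rng_seed = 1L) {
  stopifnot(n_subjects >= 1L, n_vertices >= 4L, n_trials >= 1L,
            snr > 0, session_drift >= 0, session_drift <= 1)
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("effects must be effect_spec objects")
    if (!e$region %in% regions)
      stop("config error: effect region '", e$region, "' not in cfg regions")
  }
  structure(list(n_subjects = as.integer(n_subjects), regions = regions,
                 n_vertices = as.integer(n_vertices),
                 n_trials = as.integer(n_trials),
                 time_ms = as.numeric(time_ms), peak_ms = peak_ms,
                 shape = shape, snr = snr, session_drift = session_drift,
                 effects = effects, effect_sd = effect_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Injectable recognition effect
#'
#' Three effect kinds dissociate power- from pattern-driven recognition
#' changes:
#' \describe{
#'   \item{`power_gain`}{inside `window_ms` the post-state amplitude of the
#'     target objects is `(1 + magnitude)` times the pre-state amplitude;
#'     the spatial pattern is untouched.}
#'   \item{`pattern_rotation`}{inside `window_ms` the post-state pattern is
#'     the pre-state pattern rotated by `magnitude` degrees (Givens rotation
#'     in the plane spanned by the pre pattern and a random direction
#'     orthogonal to all of the region's stimulus patterns); amplitude is
#'     untouched, so signal power is invariant.}
#'   \item{`delayed_shared_pattern`}{a dedicated unit pattern, shared by all
#'     target objects, is added with amplitude `amplitude` to the pre-state
#'     target objects during `window_ms` and to the post-state target
#'     objects during `window_ms + magnitude` (a latency shift of
#'     `magnitude` ms), emulating a dominant category-specific component
#'     (an N170m analogue) that reappears with a delay once recognition is
#'     induced.}
#' }
#'
#' @param kind One of `"power_gain"`, `"pattern_rotation"`,
#'   `"delayed_shared_pattern"`.
#' @param region Region label the effect applies to.
#' @param window_ms Length-2 numeric `(start, end)` in ms.
#' @param magnitude Gain factor beta (> -1) for `power_gain`; angle theta in
#'   degrees in `[0, 90]` for `pattern_rotation`; delay in ms for
#'   `delayed_shared_pattern`.
#' @param target_category `"face"`, `"tool"` or `"both"`.
#' @param amplitude Amplitude of the shared pattern relative to the
#'   stimulus-specific patterns (`delayed_shared_pattern` only; default 3,
#'   a category component dominating the regional response the way the
#'   face-specific N170m dominates the fusiform evoked field).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(kind = c("power_gain", "pattern_rotation",
                                 "delayed_shared_pattern"),
                        region, window_ms, magnitude,
                        target_category = c("both", "face", "tool"),
                        amplitude = 3) {
  kind <- match.arg(kind)
  target_category <- match.arg(target_category)
  stopifnot(length(window_ms) == 2L, window_ms[1L] < window_ms[2L])
  if (kind == "power_gain" && magnitude <= -1)
    stop("power_gain magnitude (beta) must exceed -1")
  if (kind == "pattern_rotation" && (magnitude < 0 || magnitude > 90))
    stop("pattern_rotation magnitude (theta, degrees) must lie in [0, 90]")
  structure(list(kind = kind, region = region,
                 window_ms = as.numeric(window_ms), magnitude = magnitude,
                 target_category = target_category, amplitude = amplitude),
            class = "effect_spec")
}

# Gamma-shaped evoked envelope with unit peak at peak_ms; zero pre-stimulus.
evoked_envelope <- function(time_ms, peak_ms = 120, shape = 6) {
  g <- numeric(length(time_ms))
  pos <- time_ms > 0
  r <- time_ms[pos] / peak_ms
  g[pos] <- r^shape * exp(shape * (1 - r))
  g
}

unit_vec <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

# Unit vector exactly orthogonal to the span of the columns of basis.
orth_unit <- function(n, basis) {
  Q <- qr.Q(qr(basis))
  v <- stats::rnorm(n)
  v <- v - Q %*% crossprod(Q, v)
  as.numeric(v / sqrt(sum(v^2)))
}

# Givens rotation of unit vector p by theta degrees toward unit u (u _|_ p).
rotate_pattern <- function(p, u, theta_deg) {
  th <- theta_deg * pi / 180
  cos(th) * p + sin(th) * u
}

#' Generate a synthetic multi-subject source dataset
#'
#' Each trial of condition c is `a_c(t) * g(t) * p_c(t) + noise`, with the
#' evoked envelope `g`, a unit-norm spatial pattern `p_c` per subject x
#' region x stimulus, and zero-mean Gaussian noise that is correlated across
#' vertices (random spatial covariance with a decaying eigenspectrum) and
#' smoothed over time. Effects listed in the config modulate `a_c(t)` and
#' `p_c(t)` as described in [effect_spec()]. The noise scale is set so that
#' the per-vertex RMS of the evoked signal at the envelope peak over the
#' per-vertex noise RMS equals `cfg$snr`.
#'
#' @param cfg A [sim_config()].
#' @param category Analysis category of the generated design.
#' @return A [source_dataset()].
#' @export
simulate_dataset <- function(cfg, category = "face") {
  stopifnot(inherits(cfg, "sim_config"))
  design <- condition_design(category = category)
  cond <- design$conditions
  tms <- cfg$time_ms
  nT <- length(tms)
  V <- cfg$n_vertices
  N <- cfg$n_trials
  g <- evoked_envelope(tms, cfg$peak_ms, cfg$shape)
  set.seed(cfg$rng_seed)
  subjects <- sprintf("sub%02d", seq_len(cfg$n_subjects))

  active <- vapply(cfg$effects, function(e)
    e$target_category %in% c("both", category), logical(1L))
  effects <- cfg$effects[active]

  # per-vertex noise SD so that peak signal RMS / noise RMS = snr
  # (unit-amplitude signal at peak has per-vertex RMS 1/sqrt(V))
  sigma <- 1 / (cfg$snr * sqrt(V))

  epochs <- vector("list", cfg$n_subjects)
  names(epochs) <- subjects
  for (si in seq_along(subjects)) {
    # per-subject effect magnitudes (individual differences in gain)
    betas <- lapply(effects, function(e) {
      if (e$kind == "power_gain")
        e$magnitude * max(0, 1 + cfg$effect_sd * stats::rnorm(1L))
      else e$magnitude
    })
    sub <- vector("list", length(cfg$regions))
    names(sub) <- cfg$regions
    for (r in cfg$regions) {
      stim_ids <- unique(cond$stimulus_id)
      pat <- vapply(stim_ids, function(s) unit_vec(V), numeric(V))
      colnames(pat) <- stim_ids
      reff <- Filter(function(e) e$region == r, effects)
      rbeta <- betas[vapply(effects, function(e) e$region == r, logical(1L))]

      # noise mixing: random orthonormal basis with decaying spectrum
      Q <- qr.Q(qr(matrix(stats::rnorm(V * V), V, V)))
      spec <- (seq_len(V))^(-0.5)
      spec <- spec / sqrt(mean(spec^2))       # keep per-vertex variance = sigma^2
      mix <- Q %*% (spec * t(Q)) * sigma      # Q diag(spec) Q' * sigma

      # session-2 nonsense pattern drift
      pat2 <- pat
      if (cfg$session_drift > 0) {
        for (s in stim_ids[cond$stim_class[match(stim_ids, cond$stimulus_id)] == "nonsense"]) {
          u <- orth_unit(V, pat)
          d <- cfg$session_drift
          pat2[, s] <- sqrt(1 - d^2) * pat[, s] + d * u
        }
      }

      # precompute rotation targets / shared patterns per effect
      rot_post <- list()
      shared <- NULL
      for (k in seq_along(reff)) {
        e <- reff[[k]]
        if (e$kind == "pattern_rotation") {
          for (s in stim_ids[cond$stim_class[match(stim_ids, cond$stimulus_id)] == "object"]) {
            u <- orth_unit(V, pat)
            rot_post[[s]] <- rotate_pattern(pat[, s], u, e$magnitude)
          }
        } else if (e$kind == "delayed_shared_pattern") {
          shared <- orth_unit(V, pat)
        }
      }

      regdat <- vector("list", nrow(cond))
      names(regdat) <- cond$label
      for (ci in seq_len(nrow(cond))) {
        cc <- cond[ci, ]
        base_pat <- if (cc$stim_class == "nonsense" && cc$state == "s2")
          pat2[, cc$stimulus_id] else pat[, cc$stimulus_id]
        # signal matrix V x T
        P <- outer(base_pat, g)               # amplitude 1 baseline
        for (k in seq_along(reff)) {
          e <- reff[[k]]
          win <- tms >= e$window_ms[1L] & tms <= e$window_ms[2L]
          if (cc$stim_class != "object") next
          if (e$kind == "power_gain" && cc$state == "post") {
            P[, win] <- P[, win] * (1 + rbeta[[k]])
          } else if (e$kind == "pattern_rotation" && cc$state == "post") {
            P[, win] <- outer(rot_post[[cc$stimulus_id]], g[win])
          } else if (e$kind == "delayed_shared_pattern") {
            dwin <- if (cc$state == "pre") e$window_ms else e$window_ms + e$magnitude
            h <- bump_envelope(tms, dwin)
            P <- P + e$amplitude * outer(shared, h)
          }
        }
        noise <- array(mix %*% matrix(stats::rnorm(V * nT * N), V), c(V, nT, N))
        # short temporal kernel (variance-preserving), trial-wise, edges replicated
        k <- c(0.25, 0.5, 0.25) / sqrt(sum(c(0.25, 0.5, 0.25)^2))
        ip <- c(1L, seq_len(nT - 1L)); im <- c(seq.int(2L, nT), nT)
        noise <- k[1L] * noise[, ip, , drop = FALSE] + k[2L] * noise +
          k[3L] * noise[, im, , drop = FALSE]
        regdat[[cc$label]] <- as.vector(P) + noise
      }
      sub[[r]] <- regdat
    }
    epochs[[si]] <- sub
  }
  source_dataset(epochs, tms, design)
}

# Raised-cosine bump with unit peak supported on window (ms).
bump_envelope <- function(time_ms, window_ms) {
  h <- numeric(length(time_ms))
  inside <- time_ms >= window_ms[1L] & time_ms <= window_ms[2L]
  if (any(inside)) {
    x <- (time_ms[inside] - window_ms[1L]) / diff(window_ms)
    h[inside] <- 0.5 - 0.5 * cos(2 * pi * x)
  }
  h
}

#' Generate a null dataset (no recognition effects)
#'
#' Convenience wrapper: [simulate_dataset()] with the effect list and
#' session drift forced empty/zero, so that pre and post states of every
#' object (and the two sessions of every nonsense stimulus) are
#' statistically exchangeable.
#'
#' @inheritParams simulate_dataset
#' @export
null_dataset <- function(cfg, category = "face") {
  cfg$effects <- list()
  cfg$session_drift <- 0
  simulate_dataset(cfg, category = category)
}
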