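# Study-condition replicate procedures used by the validation suite and the
# acceptance script. The simulation sizes here are the package's chosen
# desk-scale study conditions: the full 16-subject design with 75 trials per
# condition, three effect-carrying regions at 30 vertices, and the 10 ms
# analysis grid restricted to the windows the effects live in.

#' One effect-recovery replicate
#'
#' Simulates one dataset of the default pre/post design carrying all three
#' canonical recognition effects — a power gain (beta = 0.8, 80-160 ms, an
#' early extrastriate-like region), a power-preserving pattern rotation
#' (theta = 60 degrees, 100-200 ms, a value-system-like region) and a
#' delayed shared category pattern (140-180 ms reappearing at +100 ms, a
#' fusiform-like region) — and runs the full dissociation battery on it.
#'
#' @param seed Integer seed for this replicate.
#' @param n_permutations Permutations for the generalization cluster test.
#' @return Named list of detection statistics (see source for fields).
#' @export
recovery_replicate <- function(seed, n_permutations = 1000L) {
  power_win <- c(80, 160)
  rot_win <- c(100, 200)
  del_win <- c(140, 180)
  dt <- 100
  theta <- 60
  cfg <- sim_config(
    n_subjects = 16L, regions = c("rIO", "rInsula", "rFG"),
    n_vertices = 30L, n_trials = 75L, rng_seed = seed,
    effects = list(
      effect_spec("power_gain", "rIO", power_win, 0.8),
      effect_spec("pattern_rotation", "rInsula", rot_win, theta),
      effect_spec("delayed_shared_pattern", "rFG", del_win, dt)))
  ds <- simulate_dataset(cfg)

  # RDM battery on the two RDM-carrying regions over the early window
  ds_rdm <- ds
  ds_rdm$regions <- c("rIO", "rInsula")
  ds_rdm$epochs <- lapply(ds_rdm$epochs, function(s) s[c("rIO", "rInsula")])
  pc <- pipeline_config(analysis_window_ms = c(0, 220), rng_seed = seed)
  rd <- compute_empirical_rdms(ds_rdm, pc)
  fs <- rd$features

  # --- power gain region ---
  prof_p <- window_profiles(rd, "rIO", power_win)
  rn_un <- profile_contrast(prof_p, "RN-UN", alternative = "greater")
  assoc_p <- decoding_power_association(
    recognition_decoding_gain(rd, "rIO", power_win),
    recognition_power_delta(fs, "rIO", power_win))
  an_p <- power_anova(subject_power_table(fs, "rIO", power_win))
  ang_p <- angle_timecourse_vs_baseline(fs, "rIO", power_win,
                                        alternative = "less")

  # --- pattern rotation region ---
  prof_r <- window_profiles(rd, "rInsula", rot_win)
  sru_sna <- profile_contrast(prof_r, "sRU-sNa", alternative = "greater")
  assoc_r <- decoding_power_association(
    recognition_decoding_gain(rd, "rInsula", rot_win),
    recognition_power_delta(fs, "rInsula", rot_win))
  an_r <- power_anova(subject_power_table(fs, "rInsula", rot_win))
  ang_r_up <- angle_timecourse_vs_baseline(fs, "rInsula", rot_win,
                                           alternative = "greater")

  # --- delayed shared pattern: cross-exemplar generalization ---
  ds_gen <- ds
  ds_gen$regions <- c("rFG", "rIO")
  ds_gen$epochs <- lapply(ds_gen$epochs, function(s) s[c("rFG", "rIO")])
  # focal expected support (5 x 5 bins): a stricter cluster-forming
  # threshold than the map default keeps the max-size null sensitive to
  # compact clusters on the smooth accuracy surface
  pc_gen <- pipeline_config(analysis_window_ms = c(0, 300),
                            n_permutations = n_permutations,
                            cluster_definition_p = 0.01,
                            rng_seed = seed)
  fs_gen <- extract_features(ds_gen, pc_gen)
  gm_eff <- cross_exemplar_generalization(fs_gen, "rFG")
  cl_eff <- cluster_permutation_2d(gm_eff, pc_gen)
  gm_ctl <- cross_exemplar_generalization(fs_gen, "rIO")
  cl_ctl <- cluster_permutation_2d(gm_ctl, pc_gen)

  bins <- gm_eff$bin_ms
  test_sup <- bins >= del_win[1L] + dt & bins <= del_win[2L] + dt
  train_sup <- bins >= del_win[1L] & bins <= del_win[2L]
  sig_eff <- which(cl_eff$clusters$significant)
  # a significant cluster covering the shifted support with off-diagonal
  # placement (test times later than train times)
  covers <- FALSE
  shift_est <- NA_real_
  for (i in sig_eff) {
    cells <- cl_eff$cells[[i]]
    inside <- train_sup[cells[, 1L]] & test_sup[cells[, 2L]]
    if (sum(inside) >= 4L) {
      covers <- TRUE
      shift_est <- mean(bins[cells[inside, 2L]]) - mean(bins[cells[inside, 1L]])
    }
  }
  ctl_covers <- FALSE
  for (i in which(cl_ctl$clusters$significant)) {
    cells <- cl_ctl$cells[[i]]
    if (sum(train_sup[cells[, 1L]] & test_sup[cells[, 2L]]) >= 4L)
      ctl_covers <- TRUE
  }

  p_int_p <- an_p$p[an_p$effect == "session x group"]
  p_int_r <- an_r$p[an_r$effect == "session x group"]
  list(
    power = list(
      rn_un_t = rn_un$t$statistic, rn_un_p = rn_un$t$p,
      assoc_rho = assoc_p$rho, assoc_p_onesided = assoc_p$p / 2,
      interaction_p = p_int_p,
      alpha_window = mean(ang_p$window_alpha),
      alpha_baseline = mean(ang_p$baseline_alpha),
      alpha_below_p = ang_p$t$p),
    rotation = list(
      sru_sna_t = sru_sna$t$statistic, sru_sna_p = sru_sna$t$p,
      assoc_rho = assoc_r$rho, assoc_p_onesided = assoc_r$p / 2,
      interaction_p = p_int_r,
      alpha_window = mean(ang_r_up$window_alpha),
      alpha_baseline = mean(ang_r_up$baseline_alpha),
      alpha_above_p = ang_r_up$t$p,
      theta_true = theta),
    delayed = list(
      n_significant = length(sig_eff),
      covers_shifted_support = covers,
      shift_estimate_ms = shift_est,
      control_covers = ctl_covers,
      dt_true = dt),
    classification = list(
      # effect-type calls from the dissociation signatures alone
      power_called_power =
        p_int_p < 0.05 && assoc_p$rho > 0 && assoc_p$p / 2 < 0.05,
      rotation_called_power =
        p_int_r < 0.05 && assoc_r$rho > 0 && assoc_r$p / 2 < 0.05,
      rotation_detected = sru_sna$t$p < 0.05,
      power_detected = rn_un$t$p < 0.05)
  )
}

#' One null-calibration replicate
#'
#' Simulates a small effect-free group dataset (6 subjects, one region,
#' 12 vertices, 50 trials, 0-50 ms analysis window) and returns the
#' quantities whose false-positive behaviour the calibration suite checks:
#' the mean decoding accuracy of the exchangeable same-stimulus pairs, the
#' per-subject model-RDM correlations, and whether the FDR-corrected effect
#' map rejects anywhere.
#'
#' @param seed Integer seed.
#' @return List with `mean_exchangeable_acc`, `mean_all_acc`, `rsa_p`
#'   (one-sample t p-value of the subject z values), `any_fdr_hit`.
#' @export
null_calibration_replicate <- function(seed) {
  cfg <- sim_config(n_subjects = 6L, regions = "r1", n_vertices = 12L,
                    n_trials = 50L, rng_seed = seed)
  ds <- null_dataset(cfg)
  pc <- pipeline_config(analysis_window_ms = c(0, 50), rng_seed = seed)
  rd <- compute_empirical_rdms(ds, pc)
  ex <- rd$pairs$component %in% c("sRU", "sNa")
  model <- model_rdm(rd$pairs)
  zs <- vapply(seq_len(dim(rd$acc)[1L]), function(si) {
    entry <- apply(rd$acc[si, 1L, , , drop = FALSE], 3L, mean)
    rsa_correlation(entry, model)$z
  }, numeric(1L))
  em <- searchlight_effect_map(rd)
  list(mean_exchangeable_acc = mean(rd$acc[, , ex, ]),
       mean_all_acc = mean(rd$acc),
       rsa_p = one_sample_t(zs)$p,
       any_fdr_hit = any(em$significant))
}
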