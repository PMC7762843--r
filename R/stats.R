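#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(rho)` with `rho` clipped to `±(1 - 1e-6)` so that structurally
#' perfect correlations map to a large finite value rather than `±Inf`.
#'
#' @param rho Correlation(s) in `[-1, 1]`.
#' @return Numeric vector of z values; values that required clipping carry
#'   the attribute `clipped`.
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("domain error: |rho| > 1")
  clip <- 1 - 1e-6
  clipped <- !is.na(rho) & abs(rho) > clip
  z <- atanh(pmin(pmax(rho, -clip), clip))
  if (any(clipped)) attr(z, "clipped") <- which(clipped)
  z
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up rule at level `q`, applied jointly to the supplied p-value
#' family; decisions are returned in the input order.
#'
#' @param p Numeric vector of p-values.
#' @param q FDR level.
#' @return Logical vector of rejections (empty input gives an empty vector).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH") <= q
}

#' One-sample and paired t-tests
#'
#' Thin wrappers around the standard t statistic with `n - 1` degrees of
#' freedom, returning a flat record. A zero-variance sample with nonzero
#' mean yields an infinite statistic flagged `degenerate`; an identically
#' zero sample yields `t = 0`, also flagged.
#'
#' @param x Numeric vector (differences, for the paired case).
#' @param y Optional second vector for a paired test (`x - y` is tested).
#' @param mu Null value.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `statistic`, `df`, `p`, `sided`, `degenerate`.
#' @export
one_sample_t <- function(x, mu = 0, alternative = "two.sided") {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0) {
    stat <- if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
    p <- if (stat == 0) 1 else 0
    return(list(statistic = stat, df = n - 1, p = p,
                sided = alternative, degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = mu, alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, sided = alternative, degenerate = FALSE)
}

#' @rdname one_sample_t
#' @export
paired_t <- function(x, y, mu = 0, alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  one_sample_t(x - y, mu = mu, alternative = alternative)
}

#' Repeated-measures ANOVA (within-subject factors)
#'
#' Full-factorial repeated-measures ANOVA with subject as the random
#' factor: each effect is tested against its own subject-by-effect error
#' stratum (`aov` with `Error(subject/(f1*f2*...))`). No sphericity
#' correction is applied. The design must be complete and balanced: exactly
#' one observation per subject per factor-level cell.
#'
#' @param data Data frame in long format.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param factors Character vector (1-3) of within-subject factor columns.
#' @return Data frame with one row per effect: `effect`, `df`, `df_error`,
#'   `ss`, `ss_error`, `F`, `p`.
#' @export
rm_anova <- function(data, dv, subject, factors) {
  stopifnot(is.data.frame(data), length(factors) >= 1L, length(factors) <= 3L,
            all(c(dv, subject, factors) %in% names(data)))
  df <- data
  df[[subject]] <- factor(df[[subject]])
  for (f in factors) df[[f]] <- factor(df[[f]])
  counts <- table(df[c(subject, factors)])
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    stop("unbalanced design: subject ",
         dimnames(counts)[[1L]][bad[1L, 1L]],
         " does not have exactly one observation per cell")
  }
  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(
    sprintf("%s ~ %s + Error(%s/(%s))", dv, rhs, subject, rhs))
  fit <- stats::aov(form, data = df)
  out <- do.call(rbind, lapply(summary(fit), function(stratum) {
    tab <- stratum[[1L]]
    eff <- trimws(rownames(tab))
    resid_row <- eff == "Residuals"
    if (all(resid_row)) return(NULL)
    data.frame(effect = gsub(":", " x ", eff[!resid_row]),
               df = tab$Df[!resid_row],
               df_error = tab$Df[resid_row],
               ss = tab$`Sum Sq`[!resid_row],
               ss_error = tab$`Sum Sq`[resid_row],
               F = tab$`F value`[!resid_row],
               p = tab$`Pr(>F)`[!resid_row],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  # a stratum whose effect and error sums of squares both vanish (data
  # constant within subject across cells) carries no evidence: F := 0
  scale_ss <- sum(df[[dv]]^2) + 1e-300
  degen <- (out$ss + out$ss_error) < 1e-12 * scale_ss
  if (any(degen)) {
    out$F[degen] <- 0
    out$p[degen] <- 1
  }
  out
}
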