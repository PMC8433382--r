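# Dependence-corrected inference: units recorded on consecutive days are not
# independent samples, so every seventh unit is conservatively treated as
# independent. Degrees of freedom are computed from n/7 (floored) and
# bootstrap SDs are scaled by sqrt(7).

#' Dependence-correction policy
#'
#' @param dependence_factor how many observed units correspond to one
#'   independent sample (default 7; 1 disables the correction).
#' @param applies_to which procedures the correction applies to.
#' @return object of class `correction_policy`.
#' @export
correction_policy <- function(dependence_factor = 7L,
                              applies_to = c("ttest", "anova", "pearson",
                                             "bootstrap")) {
  if (dependence_factor < 1) stopf("dependence_factor must be >= 1")
  structure(list(dependence_factor = as.integer(dependence_factor),
                 applies_to = applies_to),
            class = "correction_policy")
}

#' Two-sample t-test with dependence-corrected degrees of freedom
#'
#' Computes the classical pooled-variance two-sample t statistic (or the
#' paired statistic), but evaluates it against a t distribution whose
#' degrees of freedom are based on the effective sample sizes
#' `floor(n / dependence_factor)` per group. With factor 1 this reproduces
#' `t.test(..., var.equal = TRUE)` exactly.
#'
#' @param sample_a,sample_b numeric samples (for the paired test, equal
#'   length).
#' @param policy a [correction_policy()].
#' @param paired paired test (default FALSE).
#' @return list with `statistic`, `p_value`, `df_effective`, `n_effective`.
#' @export
corrected_ttest <- function(sample_a, sample_b, policy = correction_policy(),
                            paired = FALSE) {
  stopifnot(inherits(policy, "correction_policy"))
  if (!length(sample_a) || !length(sample_b)) stopf("samples must be non-empty")
  f <- if ("ttest" %in% policy$applies_to) policy$dependence_factor else 1L
  if (paired) {
    stopifnot(length(sample_a) == length(sample_b))
    d <- sample_a - sample_b
    n <- length(d)
    n_eff <- floor(n / f)
    df <- n_eff - 1L
    if (df < 1) stopf("effective df < 1 (n = %d, factor = %d)", n, f)
    stat <- mean(d) / (stats::sd(d) / sqrt(n))
  } else {
    na <- length(sample_a); nb <- length(sample_b)
    na_eff <- floor(na / f); nb_eff <- floor(nb / f)
    df <- na_eff + nb_eff - 2L
    if (df < 1) stopf("effective df < 1 (n = %d/%d, factor = %d)", na, nb, f)
    sp2 <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) /
      (na + nb - 2)
    stat <- (mean(sample_a) - mean(sample_b)) /
      sqrt(sp2 * (1 / na + 1 / nb))
    n_eff <- c(na_eff, nb_eff)
  }
  if (!is.finite(stat)) stat <- 0
  list(statistic = stat,
       p_value = 2 * stats::pt(-abs(stat), df),
       df_effective = df,
       n_effective = if (paired) n_eff else n_eff)
}

#' One-way ANOVA with dependence-corrected degrees of freedom
#'
#' Standard one-way F statistic (via [stats::aov()]) evaluated with the
#' residual degrees of freedom computed from the effective total count
#' `floor(n / dependence_factor)`.
#'
#' @param values numeric response.
#' @param groups factor of group labels.
#' @param policy a [correction_policy()].
#' @return list with `statistic`, `p_value`, `df1`, `df2_effective`.
#' @export
corrected_anova <- function(values, groups, policy = correction_policy()) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  fit <- stats::aov(values ~ groups)
  Fstat <- summary(fit)[[1]][["F value"]][1]
  df1 <- k - 1L
  f <- if ("anova" %in% policy$applies_to) policy$dependence_factor else 1L
  df2 <- floor(n / f) - k
  if (df2 < 1) stopf("effective residual df < 1")
  list(statistic = Fstat, p_value = stats::pf(Fstat, df1, df2,
                                              lower.tail = FALSE),
       df1 = df1, df2_effective = df2)
}

#' Segment bootstrap of a statistic over a time series
#'
#' Splits the series into `n_segments` contiguous equal segments, resamples
#' segments with replacement, recomputes the statistic on the concatenated
#' resample for each repetition, and reports the distribution and its SD.
#' When the policy applies to bootstraps, the reported SD is multiplied by
#' `sqrt(dependence_factor)`.
#'
#' @param values numeric series.
#' @param statistic function of a numeric vector (default [mean()]).
#' @param n_segments number of segments (default 100).
#' @param n_reps repetitions (>= 10; default 1000).
#' @param policy a [correction_policy()] or NULL for no scaling.
#' @param seed integer seed (fixed seed gives bit-reproducible output).
#' @return list with `distribution`, `sd` (scaled), `sd_raw`, `scale`.
#' @export
segment_bootstrap <- function(values, statistic = mean, n_segments = 100,
                              n_reps = 1000, policy = correction_policy(),
                              seed = 1) {
  if (n_reps < 10) stopf("n_reps must be >= 10")
  if (n_segments < 2 || n_segments > length(values))
    stopf("n_segments must be in 2..length(values)")
  set.seed(as.integer(seed))
  bounds <- floor(seq(0, length(values), length.out = n_segments + 1L))
  segs <- lapply(seq_len(n_segments), function(s)
    values[(bounds[s] + 1L):bounds[s + 1L]])
  dist <- vapply(seq_len(n_reps), function(r) {
    pick <- sample.int(n_segments, n_segments, replace = TRUE)
    statistic(unlist(segs[pick], use.names = FALSE))
  }, 0)
  scale <- if (!is.null(policy) && "bootstrap" %in% policy$applies_to)
    sqrt(policy$dependence_factor) else 1
  sd_raw <- stats::sd(dist)
  list(distribution = dist, sd = scale * sd_raw, sd_raw = sd_raw,
       scale = scale)
}

#' Bonferroni multiplier for a small family of comparisons
#'
#' @param p p-value(s).
#' @param n_comparisons family size.
#' @return `min(1, p * n_comparisons)` elementwise.
#' @export
bonferroni_adjust <- function(p, n_comparisons) pmin(1, p * n_comparisons)
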