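#' Fixel-wise percentage difference
#'
#' Percentage difference (%) = 100 * (travelled - initial) / initial,
#' per fixel. Fixels with `initial == 0` yield `NaN` and are excluded from
#' downstream summaries (their count is reported via the `n_undefined`
#' attribute).
#'
#' @param initial,travelled Numeric vectors of equal length (e.g. per-fixel
#'   group means of the reference and travelled arms).
#' @return Numeric vector of percentages.
#' @export
percentage_difference <- function(initial, travelled) {
  if (length(initial) != length(travelled))
    fh_shape_error("initial and travelled must have equal length")
  out <- 100 * (travelled - initial) / initial
  out[initial == 0] <- NaN
  n_undef <- sum(initial == 0)
  if (n_undef > 0)
    message(sprintf("percentage_difference: %d fixel(s) with zero reference value", n_undef))
  attr(out, "n_undefined") <- n_undef
  out
}

#' Paired permutation test with max-statistic FWE control
#'
#' Per fixel, the statistic is the paired t on the subject differences
#' d_j = arm2 - arm1. The null distribution is built by random whole-row
#' sign flips of each subject's difference vector (preserving the spatial
#' correlation across fixels). The family-wise-error-corrected p-value of
#' fixel f is the proportion of permutations whose maximum |t| over all
#' fixels reaches the observed |t_f|, with the observed labelling included
#' (the (b+1)/(B+1) estimator, so p-values are never 0). This max-statistic
#' correction provides valid FWE control without a template tractogram; it
#' is not equivalent to connectivity-based fixel enhancement.
#'
#' @param Y_arm1,Y_arm2 N x M matrices (or [fixel_matrix]), rows aligned by
#'   subject.
#' @param n_perm Number of permutations (at least 100; analyses typically
#'   use 5000).
#' @param seed Optional integer seed for the sign flips.
#' @return List with `stat` (per-fixel paired t), `pvals_fwe`,
#'   `significant` (at `alpha`), `alpha`, `n_perm`.
#' @param alpha Significance threshold for the `significant` indicator
#'   (default 0.05, FWE-corrected).
#' @export
paired_permutation_test <- function(Y_arm1, Y_arm2, n_perm = 5000L,
                                    seed = NULL, alpha = 0.05) {
  if (inherits(Y_arm1, "fixel_matrix")) Y_arm1 <- Y_arm1$values
  if (inherits(Y_arm2, "fixel_matrix")) Y_arm2 <- Y_arm2$values
  if (!all(dim(Y_arm1) == dim(Y_arm2)))
    fh_shape_error("arm matrices must have identical dimensions")
  N <- nrow(Y_arm1); M <- ncol(Y_arm1)
  if (N < 3L) fh_validation_error("paired test needs at least 3 subjects")
  if (n_perm < 100L) fh_validation_error("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)

  D <- Y_arm2 - Y_arm1
  ss <- colSums(D^2)                    # invariant under sign flips
  tstat_from_mean <- function(mu) {
    v <- (ss - N * mu^2) / (N - 1)      # per-fixel variance of d
    v[v < 0] <- 0
    se <- sqrt(v / N)
    t <- mu / se
    t[se == 0] <- ifelse(mu[se == 0] == 0, 0, Inf)
    t
  }
  t_obs <- tstat_from_mean(colMeans(D))
  S <- matrix(sample(c(-1, 1), n_perm * N, replace = TRUE), n_perm, N)
  mu_perm <- (S %*% D) / N              # n_perm x M
  v_perm <- sweep(-N * mu_perm^2, 2, ss, "+") / (N - 1)
  v_perm[v_perm < 0] <- 0
  t_perm <- mu_perm / sqrt(v_perm / N)
  t_perm[!is.finite(t_perm)] <- ifelse(mu_perm[!is.finite(t_perm)] == 0, 0, Inf)
  max_t <- apply(abs(t_perm), 1, max)
  pvals <- (1 + vapply(abs(t_obs), function(t) sum(max_t >= t), numeric(1))) /
    (n_perm + 1)
  if (all(abs(t_obs) == abs(t_obs)[1]))
    warning("degenerate differences: all fixels share the same |t|")
  list(stat = t_obs, pvals_fwe = pvals, significant = pvals < alpha,
       alpha = alpha, n_perm = as.integer(n_perm))
}

#' Two-sample permutation test with max-statistic FWE control
#'
#' Group comparison analogue of [paired_permutation_test()]: per fixel, an
#' unpaired two-sample t statistic with pooled variance, null built by
#' permuting the group labels. When covariates are supplied they are
#' regressed out of every fixel column (with an intercept) before
#' permutation; this simple residualisation scheme is not a full
#' Freedman-Lane procedure.
#'
#' @param Y N x M matrix (or [fixel_matrix]).
#' @param group Two-level factor or character vector of length N; the
#'   statistic is mean(level 1) - mean(level 2) scaled by the pooled SD.
#' @param covars Optional numeric matrix/data.frame of nuisance covariates.
#' @inheritParams paired_permutation_test
#' @return List with `stat`, `pvals_fwe`, `significant`, `alpha`, `n_perm`.
#' @export
group_permutation_test <- function(Y, group, covars = NULL, n_perm = 5000L,
                                   seed = NULL, alpha = 0.05) {
  if (inherits(Y, "fixel_matrix")) Y <- Y$values
  group <- factor(as.character(group), levels = unique(as.character(group)))
  if (nlevels(group) != 2L)
    fh_validation_error("group must have exactly 2 levels")
  N <- nrow(Y)
  if (length(group) != N) fh_shape_error("group length must match nrow(Y)")
  if (n_perm < 100L) fh_validation_error("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(covars)) {
    Xc <- cbind(1, as.matrix(covars))
    Y <- stats::lm.fit(Xc, Y)$residuals
  }
  g1 <- group == levels(group)[1]
  n1 <- sum(g1); n2 <- N - n1
  if (n1 < 2L || n2 < 2L) fh_validation_error("each group needs at least 2 scans")
  ss_tot <- colSums(Y^2)
  tot <- colSums(Y)
  tstat_from_sum <- function(s1) {
    m1 <- s1 / n1
    m2 <- (tot - s1) / n2
    sp2 <- (ss_tot - n1 * m1^2 - n2 * m2^2) / (N - 2)
    sp2[sp2 < 0] <- 0
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t <- (m1 - m2) / se
    t[se == 0] <- ifelse((m1 - m2)[se == 0] == 0, 0, Inf)
    t
  }
  t_obs <- tstat_from_sum(colSums(Y[g1, , drop = FALSE]))
  G <- matrix(0, n_perm, N)
  for (b in seq_len(n_perm)) G[b, sample.int(N, n1)] <- 1
  S1 <- G %*% Y
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, tot, "+") / n2
  sp2 <- sweep(-(n1 * m1^2 + n2 * m2^2), 2, ss_tot, "+") / (N - 2)
  sp2[sp2 < 0] <- 0
  t_perm <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t_perm[!is.finite(t_perm)] <- 0
  max_t <- apply(abs(t_perm), 1, max)
  pvals <- (1 + vapply(abs(t_obs), function(t) sum(max_t >= t), numeric(1))) /
    (n_perm + 1)
  list(stat = t_obs, pvals_fwe = pvals, significant = pvals < alpha,
       alpha = alpha, n_perm = as.integer(n_perm))
}

#' Cohen's d with pooled standard deviation
#'
#' \deqn{d = (\bar x_a - \bar x_b) / s_p, \quad s_p^2 = \frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a + n_b - 2}.}
#' The sign follows `group_a - group_b`: with controls as `group_a` and
#' patients as `group_b`, a patient-group reduction yields positive d.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return Cohen's d (scalar).
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) fh_validation_error("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) fh_numeric_error("pooled standard deviation is 0; effect size undefined")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Mean metric over a tract
#'
#' @param values Length-M numeric vector (one scan's fixel data).
#' @param tract_mask Logical length-M mask selecting at least one fixel.
#' @return Arithmetic mean over the masked fixels.
#' @export
tract_mean <- function(values, tract_mask) {
  if (length(values) != length(tract_mask))
    fh_shape_error("values and tract_mask must have equal length")
  if (!any(tract_mask)) fh_validation_error("tract mask selects no fixel")
  mean(values[tract_mask])
}

#' OLS regression of a cognitive score on a tract metric, with bootstrap CI
#'
#' Fits score ~ intercept + predictor + covariates by ordinary least
#' squares and reports the predictor's coefficient, its two-sided p-value,
#' the model R-squared, and a percentile 95% confidence interval of
#' R-squared from case-resampling bootstrap replicates (rows resampled with
#' replacement; rank-deficient replicates are redrawn and counted).
#'
#' @param score Response vector, length N (e.g. MMSE or MoCA).
#' @param predictor Length-N tract-mean metric.
#' @param covars Optional N x q matrix/data.frame of adjustment covariates
#'   (age, sex, ICV).
#' @param n_boot Number of bootstrap replicates (analyses typically use
#'   10000).
#' @param seed Optional integer seed.
#' @return List with `coefficient`, `p_value`, `r_squared`, `ci95`
#'   (length-2), `n_boot`, `n_redrawn`.
#' @export
ols_bootstrap <- function(score, predictor, covars = NULL, n_boot = 10000L,
                          seed = NULL) {
  N <- length(score)
  X <- cbind(`(Intercept)` = 1, predictor = predictor)
  if (!is.null(covars)) X <- cbind(X, as.matrix(covars))
  q <- ncol(X) - 2L
  if (N <= q + 2L) fh_validation_error("too few observations for the design")
  if (qr(X)$rank < ncol(X))
    fh_design_error("collinear regression design")
  if (!is.null(seed)) set.seed(seed)

  r2_of <- function(Xb, yb) {
    fit <- stats::lm.fit(Xb, yb)
    1 - sum(fit$residuals^2) / sum((yb - mean(yb))^2)
  }
  fit <- stats::lm.fit(X, score)
  rss <- sum(fit$residuals^2)
  tss <- sum((score - mean(score))^2)
  r2 <- 1 - rss / tss
  df <- N - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(XtXinv[2, 2] * rss / df)
  tval <- fit$coefficients["predictor"] / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)

  r2_boot <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(N, N, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank == ncol(X) && stats::var(score[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot)
        fh_numeric_error("bootstrap cannot find full-rank resamples")
    }
    r2_boot[b] <- r2_of(Xb, score[idx])
  }
  ci <- unname(stats::quantile(r2_boot, c(0.025, 0.975), type = 7))
  list(coefficient = unname(fit$coefficients["predictor"]),
       p_value = unname(pval), r_squared = r2, ci95 = ci,
       n_boot = as.integer(n_boot), n_redrawn = n_redrawn)
}

#' Between-batch variability summary
#'
#' Per fixel, the mean absolute pairwise percentage difference between
#' batch means, each ordered pair (a, b) with a earlier than b in batch
#' level order contributing 100 |mean_b - mean_a| / |mean_a| (the
#' travelled-versus-initial convention); fixels with a zero reference mean
#' are excluded. Globally, the distribution of the per-fixel values is
#' summarised (mean, median, 95th percentile), restricted to significant
#' fixels when a FWE p-value vector is supplied.
#'
#' @param Y N x M matrix or [fixel_matrix].
#' @param batch Batch labels, length N.
#' @param pvals Optional per-fixel p-values; with `alpha`, restricts the
#'   global summary to fixels with `pvals < alpha`.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `per_fixel` (length M) and `global`
#'   (mean/median/q95/n_fixels).
#' @export
batch_variability_summary <- function(Y, batch, pvals = NULL, alpha = 0.05) {
  if (inherits(Y, "fixel_matrix")) Y <- Y$values
  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  if (nlevels(batch) < 2L) fh_validation_error("need at least 2 batches")
  means <- t(vapply(levels(batch),
                    function(b) colMeans(Y[batch == b, , drop = FALSE]),
                    numeric(ncol(Y))))
  B <- nrow(means)
  acc <- matrix(NA_real_, B * (B - 1) / 2, ncol(Y))
  k <- 0L
  for (a in seq_len(B - 1)) for (b in seq.int(a + 1, B)) {
    k <- k + 1L
    pd <- 100 * abs(means[b, ] - means[a, ]) / abs(means[a, ])
    pd[means[a, ] == 0] <- NaN
    acc[k, ] <- pd
  }
  per_fixel <- colMeans(acc)
  sel <- is.finite(per_fixel)
  if (!is.null(pvals)) sel <- sel & (pvals < alpha)
  vals <- per_fixel[sel]
  glob <- if (length(vals))
    list(mean = mean(vals), median = stats::median(vals),
         q95 = unname(stats::quantile(vals, 0.95)), n_fixels = length(vals))
  else list(mean = NA_real_, median = NA_real_, q95 = NA_real_, n_fixels = 0L)
  list(per_fixel = per_fixel, global = glob)
}
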