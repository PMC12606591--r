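#' Fit the ComBat location-scale harmonisation model
#'
#' Fits, per template fixel f, the model
#' \deqn{Y_{i,j,f} = \alpha_f + X_{i,j}\beta_f + \gamma_{i,f} + \delta_{i,f}\,\varepsilon_{i,j,f},
#'   \qquad \varepsilon_{i,j,f} \sim N(0, \sigma_f^2),}
#' where i indexes the batch (site, scanner model or protocol), j the scan,
#' \eqn{\alpha_f} is the overall fixel mean, \eqn{\beta_f} the coefficients of
#' the biological covariates, and \eqn{\gamma_{i,f}}, \eqn{\delta_{i,f}} the
#' additive and multiplicative batch effects. Batch locations are estimated
#' under the sample-size-weighted identifiability constraint
#' \eqn{\sum_i n_i \hat\gamma_{i,f} = 0}, so \eqn{\hat\alpha_f} is the pooled
#' mean after covariate adjustment. With `method = "eb"` the per-batch
#' effects are shrunk across fixels by parametric empirical Bayes: a normal
#' prior \eqn{\gamma_{i,f} \sim N(\bar\gamma_i, \tau_i^2)} for locations and
#' an inverse-gamma prior \eqn{\delta_{i,f}^2 \sim \mathrm{InvGamma}(\lambda_i,
#' \theta_i)} for scales, hyperparameters estimated by moment matching across
#' fixels, and the conditional posterior modes found by fixed-point
#' iteration. With `method = "direct"` the raw per-batch estimates are used
#' unshrunk.
#'
#' The residual scale \eqn{\hat\sigma_f} uses divisor N, and the per-batch
#' scale estimates \eqn{\hat\delta^2_{i,f}} use divisor \eqn{n_i}; with these
#' conventions a single-batch fit is an exact identity transform.
#'
#' Fixels whose values are constant within some batch (or with zero pooled
#' residual variance) are excluded from the model via the mask and pass
#' through [combat_apply()] unchanged.
#'
#' @param Y N x M numeric matrix or a [fixel_matrix] (rows = scans,
#'   columns = fixels).
#' @param data Data frame with one row per scan, aligned with the rows of
#'   `Y`; must contain the `batch` column and all `covariates` columns.
#' @param batch Name of the batch column in `data` (default `"batch"`).
#' @param covariates Character vector of covariate column names (numeric or
#'   0/1 coded), e.g. `c("age", "sex", "icv")`. May be `NULL` for a
#'   covariate-free fit.
#' @param method `"eb"` (empirical-Bayes shrinkage, default) or `"direct"`.
#' @param mask Optional logical length-M mask of fixels eligible for
#'   harmonisation; intersected with the internally computed degeneracy mask.
#' @param eb_tol Absolute convergence tolerance of the EB fixed-point
#'   iteration (default 1e-4).
#' @param eb_maxit Iteration cap (default 100); non-converged fixels are
#'   counted and the last iterate is used.
#' @return An object of class `combat_fit`; see Details for fields. Use
#'   [combat_apply()] or [predict.combat_fit()] to harmonise data, and
#'   [harmonize()] for the one-call pipeline.
#' @seealso [harmonize()], [combat_apply()], [combat_save()]
#' @export
combat_fit <- function(Y, data, batch = "batch", covariates = c("age", "sex", "icv"),
                       method = c("eb", "direct"), mask = NULL,
                       eb_tol = 1e-4, eb_maxit = 100L) {
  method <- match.arg(method)
  if (inherits(Y, "fixel_matrix")) {
    if (is.null(mask)) mask <- Y$mask
    Y <- Y$values
  }
  Y <- as.matrix(Y)
  N <- nrow(Y); M <- ncol(Y)
  if (nrow(data) != N)
    fh_shape_error("data must have one row per row of Y")
  if (!batch %in% names(data))
    fh_schema_error(sprintf("batch column '%s' not found", batch))
  bf <- factor(as.character(data[[batch]]),
               levels = unique(as.character(data[[batch]])))
  B <- nlevels(bf)
  n_i <- as.vector(table(bf))
  if (any(n_i < 2L))
    fh_validation_error("every batch needs at least 2 scans")

  Xc <- .covariate_matrix(data, covariates)
  p <- ncol(Xc)
  if (N <= p + B)
    fh_validation_error(sprintf(
      "need more scans (%d) than model parameters (%d batches + %d covariates)",
      N, B, p))

  # design: one indicator column per batch plus covariates (no intercept);
  # the weighted-constraint parameterisation is recovered afterwards
  Xb <- vapply(levels(bf), function(l) as.numeric(bf == l), numeric(N))
  design <- cbind(Xb, Xc)
  colnames(design) <- c(paste0("batch:", levels(bf)), colnames(Xc))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    fh_design_error(sprintf(
      "rank-deficient design; collinear column(s): %s", paste(bad, collapse = ", ")))
  }
  kappa_d <- kappa(design, exact = FALSE)
  if (is.finite(kappa_d) && kappa_d > 1e12)
    warning(sprintf("ill-conditioned design matrix (condition number %.2g); consider rescaling covariates", kappa_d))

  B_hat <- qr.coef(qrd, Y)                       # (B+p) x M
  batch_coef <- B_hat[seq_len(B), , drop = FALSE]
  beta <- B_hat[-seq_len(B), , drop = FALSE]
  w <- n_i / N
  alpha <- as.vector(crossprod(w, batch_coef))   # weighted grand mean, length M
  stand_mean <- matrix(alpha, N, M, byrow = TRUE)
  if (p > 0) stand_mean <- stand_mean + Xc %*% beta
  resid <- Y - design %*% B_hat
  sigma2 <- colMeans(resid^2)                    # divisor N
  sigma <- sqrt(sigma2)

  # mask: supplied mask AND no degenerate scales
  degenerate <- sigma2 <= 0
  for (b in levels(bf)) {
    rows <- which(bf == b)
    degenerate <- degenerate | (matrixStats_colVar(Y[rows, , drop = FALSE]) <= 0)
  }
  mask <- (mask %||% rep(TRUE, M)) & !degenerate
  m_idx <- which(mask)
  if (!length(m_idx))
    fh_validation_error("no fixel passes the degeneracy mask")

  Z <- matrix(0, N, M)
  Z[, m_idx] <- sweep(Y[, m_idx, drop = FALSE] - stand_mean[, m_idx, drop = FALSE],
                      2, sigma[m_idx], "/")

  gamma_hat <- matrix(0, B, M, dimnames = list(levels(bf), NULL))
  delta2_hat <- matrix(1, B, M, dimnames = list(levels(bf), NULL))
  for (b in seq_len(B)) {
    rows <- which(bf == levels(bf)[b])
    Zb <- Z[rows, m_idx, drop = FALSE]
    mu <- colMeans(Zb)
    gamma_hat[b, m_idx] <- mu
    delta2_hat[b, m_idx] <- colMeans(Zb^2) - mu^2   # divisor n_i
  }

  if (length(m_idx) >= 3L) {
    hyper <- estimate_hyperparameters(gamma_hat[, m_idx, drop = FALSE],
                                      delta2_hat[, m_idx, drop = FALSE])
  } else {
    if (method == "eb")
      fh_validation_error("empirical-Bayes shrinkage needs at least 3 masked fixels")
    hyper <- data.frame(gamma_bar = rowMeans(gamma_hat[, m_idx, drop = FALSE]),
                        tau2 = NA_real_, lambda = NA_real_, theta = NA_real_,
                        degenerate = TRUE)
  }
  hyper$batch <- levels(bf)
  hyper$n <- n_i

  if (method == "eb") {
    sh <- eb_shrink(Z[, m_idx, drop = FALSE], bf, hyper,
                    gamma_hat[, m_idx, drop = FALSE],
                    delta2_hat[, m_idx, drop = FALSE],
                    tol = eb_tol, maxit = eb_maxit)
    gamma_star <- gamma_hat; delta_star <- sqrt(delta2_hat)
    gamma_star[, m_idx] <- sh$gamma_star
    delta_star[, m_idx] <- sh$delta_star
    n_nonconverged <- sh$n_nonconverged
  } else {
    gamma_star <- gamma_hat
    delta_star <- sqrt(delta2_hat)
    n_nonconverged <- 0L
  }
  if (any(!is.finite(gamma_star[, m_idx])) || any(delta_star[, m_idx] <= 0))
    fh_numeric_error("non-finite or non-positive shrunken batch effects")

  structure(list(
    alpha = alpha, beta = beta, sigma = sigma,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    hyper = hyper,
    batch_levels = levels(bf), n_per_batch = n_i,
    covariate_names = colnames(Xc) %||% character(),
    mask = mask, method = method,
    batch_column = batch,
    eb_tol = eb_tol, eb_maxit = as.integer(eb_maxit),
    n_nonconverged = n_nonconverged,
    n_scans = N, n_fixels = M
  ), class = "combat_fit")
}

.covariate_matrix <- function(data, covariates) {
  if (is.null(covariates) || !length(covariates))
    return(matrix(numeric(0), nrow(data), 0))
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols))
    fh_schema_error(sprintf("covariate column(s) not found: %s",
                            paste(missing_cols, collapse = ", ")))
  Xc <- sapply(covariates, function(nm) as.double(data[[nm]]))
  Xc <- matrix(Xc, nrow = nrow(data),
               dimnames = list(NULL, covariates))
  if (anyNA(Xc)) fh_validation_error("missing values in covariates")
  Xc
}

#' Moment-matched empirical-Bayes hyperparameters
#'
#' Per batch i, estimates the normal prior of the additive effects
#' (`gamma_bar` = mean over fixels of \eqn{\hat\gamma_{i,f}}, `tau2` = their
#' variance, divisor M-1) and the inverse-gamma prior of the squared
#' multiplicative effects by moment matching: with m and V the mean and
#' variance over fixels of \eqn{\hat\delta^2_{i,f}},
#' \eqn{\lambda = (m^2 + 2V)/V} and \eqn{\theta = (m^3 + mV)/V}, so that
#' \eqn{\mathrm{InvGamma}(\lambda, \theta)} has mean m and variance V.
#' A batch with V = 0 has a degenerate prior; it is flagged (`degenerate`)
#' and falls back to the unshrunk estimates with a warning.
#'
#' @param gamma_hat B x M matrix of per-batch standardized location
#'   estimates (masked fixels only).
#' @param delta2_hat B x M matrix of per-batch scale estimates.
#' @return Data frame with one row per batch: `gamma_bar`, `tau2`, `lambda`,
#'   `theta`, `degenerate`.
#' @export
estimate_hyperparameters <- function(gamma_hat, delta2_hat) {
  gamma_hat <- rbind(gamma_hat); delta2_hat <- rbind(delta2_hat)
  M <- ncol(gamma_hat)
  if (M < 3L)
    fh_validation_error("need at least 3 fixels to estimate hyperparameters")
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  m <- rowMeans(delta2_hat)
  V <- apply(delta2_hat, 1, stats::var)
  degenerate <- V <= 0
  lambda <- ifelse(degenerate, NA_real_, (m^2 + 2 * V) / V)
  theta  <- ifelse(degenerate, NA_real_, (m^3 + m * V) / V)
  if (any(degenerate))
    warning(sprintf("%d batch(es) with degenerate scale prior (zero variance across fixels); using unshrunk estimates there",
                    sum(degenerate)))
  data.frame(gamma_bar = gamma_bar, tau2 = tau2,
             lambda = lambda, theta = theta, degenerate = degenerate)
}

#' Empirical-Bayes shrinkage of batch effects
#'
#' Iterates, per batch i and fixel f, the coupled conditional posterior
#' updates
#' \deqn{\gamma^*_{i,f} = \frac{n_i \tau_i^2 \hat\gamma_{i,f} + \delta^{*2}_{i,f}\, \bar\gamma_i}{n_i \tau_i^2 + \delta^{*2}_{i,f}}, \qquad
#'  \delta^{*2}_{i,f} = \frac{\theta_i + \tfrac12 \sum_{j \in i} (Z_{i,j,f} - \gamma^*_{i,f})^2}{n_i/2 + \lambda_i - 1},}
#' starting from the raw estimates, until the largest absolute parameter
#' change drops below `tol` or `maxit` iterations are reached (non-converged
#' fixels are counted and the last iterate kept). Batches with a degenerate
#' prior keep their raw estimates.
#'
#' @param Z N x M standardized data matrix (masked fixels).
#' @param batch Factor of batch labels, length N.
#' @param hyper Hyperparameter table from [estimate_hyperparameters()].
#' @param gamma_hat,delta2_hat Raw per-batch estimates (B x M).
#' @param tol,maxit Convergence tolerance and iteration cap.
#' @return List with `gamma_star`, `delta_star` (B x M) and
#'   `n_nonconverged`.
#' @export
eb_shrink <- function(Z, batch, hyper, gamma_hat, delta2_hat,
                      tol = 1e-4, maxit = 100L) {
  batch <- as.factor(batch)
  B <- nrow(gamma_hat); M <- ncol(gamma_hat)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  n_nonconverged <- 0L
  for (b in seq_len(B)) {
    if (isTRUE(hyper$degenerate[b])) next
    rows <- which(batch == levels(batch)[b])
    n <- length(rows)
    Zb <- Z[rows, , drop = FALSE]
    S1 <- colSums(Zb)            # sum_j Z
    SS <- colSums(Zb^2)          # sum_j Z^2
    tau2 <- hyper$tau2[b]; gbar <- hyper$gamma_bar[b]
    lam <- hyper$lambda[b]; th <- hyper$theta[b]
    g <- gamma_hat[b, ]; d2 <- delta2_hat[b, ]
    converged <- FALSE
    for (it in seq_len(maxit)) {
      g_new <- (n * tau2 * gamma_hat[b, ] + d2 * gbar) / (n * tau2 + d2)
      ss_dev <- SS - 2 * g_new * S1 + n * g_new^2
      d2_new <- (th + 0.5 * ss_dev) / (n / 2 + lam - 1)
      if (any(!is.finite(g_new)) || any(!is.finite(d2_new)))
        fh_numeric_error(sprintf(
          "non-finite EB update in batch %s (fixel %d)",
          levels(batch)[b],
          which(!is.finite(g_new) | !is.finite(d2_new))[1]))
      delta_max <- max(abs(g_new - g), abs(d2_new - d2))
      g <- g_new; d2 <- d2_new
      if (delta_max < tol) { converged <- TRUE; break }
    }
    if (!converged) n_nonconverged <- n_nonconverged + 1L
    gamma_star[b, ] <- g
    delta2_star[b, ] <- d2
  }
  list(gamma_star = gamma_star, delta_star = sqrt(delta2_star),
       n_nonconverged = n_nonconverged)
}

#' Standardize data under a fitted ComBat model
#'
#' Returns \eqn{Z_{i,j,f} = (Y_{i,j,f} - \hat\alpha_f - X_{i,j}\hat\beta_f)/\hat\sigma_f}
#' on masked fixels (0 elsewhere). The inverse transform is
#' `Y = sigma * Z + alpha + X beta`, exact to floating-point rounding.
#'
#' @param Y Matrix or [fixel_matrix] with the same column layout as the fit.
#' @param model A `combat_fit`.
#' @param data Covariate table aligned with the rows of `Y`.
#' @return N x M matrix of standardized residuals.
#' @export
combat_standardize <- function(Y, model, data) {
  if (inherits(Y, "fixel_matrix")) Y <- Y$values
  sm <- .stand_mean(model, data, nrow(Y))
  m_idx <- which(model$mask)
  if (any(model$sigma[m_idx] <= 0))
    fh_numeric_error("zero residual scale on a masked fixel")
  Z <- matrix(0, nrow(Y), ncol(Y))
  Z[, m_idx] <- sweep(Y[, m_idx, drop = FALSE] - sm[, m_idx, drop = FALSE],
                      2, model$sigma[m_idx], "/")
  Z
}

.stand_mean <- function(model, data, N) {
  M <- model$n_fixels
  sm <- matrix(model$alpha, N, M, byrow = TRUE)
  if (length(model$covariate_names)) {
    Xc <- .covariate_matrix(data, model$covariate_names)
    sm <- sm + Xc %*% model$beta
  }
  sm
}

#' Apply a fitted ComBat adjustment
#'
#' Computes, on masked fixels,
#' \deqn{Y^{ComBat}_{i,j,f} = \hat\sigma_f \frac{Z_{i,j,f} - \gamma^*_{i,f}}{\delta^*_{i,f}} + \hat\alpha_f + X_{i,j}\hat\beta_f,}
#' and copies unmasked fixels unchanged. Rows may come from held-out scans,
#' provided their batch labels are among the fitted batch levels.
#'
#' @param Y Matrix or [fixel_matrix], same column layout as the fit.
#' @param model A `combat_fit`.
#' @param data Covariate table aligned with the rows of `Y` (must contain
#'   the fitted batch column and covariates).
#' @return Harmonised matrix (or [fixel_matrix], matching the input type),
#'   same shape and row order as the input.
#' @export
combat_apply <- function(Y, model, data) {
  is_fm <- inherits(Y, "fixel_matrix")
  Ym <- if (is_fm) Y$values else as.matrix(Y)
  bf <- as.character(data[[model$batch_column]])
  unknown <- setdiff(unique(bf), model$batch_levels)
  if (length(unknown))
    fh_validation_error(sprintf("batch level(s) not in the fitted model: %s",
                                paste(unknown, collapse = ", ")))
  bidx <- match(bf, model$batch_levels)
  Z <- combat_standardize(Ym, model, data)
  m_idx <- which(model$mask)
  out <- Ym
  sm <- .stand_mean(model, data, nrow(Ym))
  adj <- (Z[, m_idx, drop = FALSE] -
            model$gamma_star[bidx, m_idx, drop = FALSE]) /
         model$delta_star[bidx, m_idx, drop = FALSE]
  out[, m_idx] <- sweep(adj, 2, model$sigma[m_idx], "*") +
    sm[, m_idx, drop = FALSE]
  if (is_fm) fixel_matrix(out, scan_ids = Y$scan_ids, metric = Y$metric,
                          mask = Y$mask)
  else out
}

#' Harmonise fixel data in one call
#'
#' Runs the full pipeline (per-fixel model fit, standardization,
#' empirical-Bayes shrinkage, adjustment). When `group` names a column of
#' `data`, the pipeline runs independently within each group level (the
#' design used for case-control cohorts, where patients and controls are
#' harmonised separately) and the rows are re-stacked in input order; a
#' group containing a single batch passes through unharmonised with a
#' warning.
#'
#' Harmonised fibre-density values may go slightly negative; they are
#' counted (`n_negative` attribute) and, only if `clip_negative = TRUE`,
#' clipped at 0.
#'
#' @inheritParams combat_fit
#' @param group Optional name of a grouping column in `data`.
#' @param clip_negative Clip negative harmonised values at 0
#'   (default `FALSE`: clipping changes the moments of the data).
#' @param ... Passed to [combat_fit()].
#' @return List with `values` (harmonised matrix or [fixel_matrix],
#'   input row order) carrying an `n_negative` attribute, and `model`
#'   (a `combat_fit`, or a named list of per-group fits).
#' @export
harmonize <- function(Y, data, batch = "batch",
                      covariates = c("age", "sex", "icv"),
                      method = c("eb", "direct"), group = NULL,
                      clip_negative = FALSE, ...) {
  method <- match.arg(method)
  is_fm <- inherits(Y, "fixel_matrix")
  Ym <- if (is_fm) Y$values else as.matrix(Y)
  if (is.null(group)) {
    model <- combat_fit(Y, data, batch = batch, covariates = covariates,
                        method = method, ...)
    out <- combat_apply(Ym, model, data)
  } else {
    if (!group %in% names(data))
      fh_schema_error(sprintf("group column '%s' not found", group))
    gf <- factor(as.character(data[[group]]),
                 levels = unique(as.character(data[[group]])))
    out <- Ym
    model <- stats::setNames(vector("list", nlevels(gf)), levels(gf))
    for (g in levels(gf)) {
      rows <- which(gf == g)
      dg <- data[rows, , drop = FALSE]
      if (length(unique(as.character(dg[[batch]]))) < 2L) {
        warning(sprintf("group '%s' contains a single batch; passed through unharmonised", g))
        next
      }
      fit_g <- combat_fit(Ym[rows, , drop = FALSE], dg, batch = batch,
                          covariates = covariates, method = method, ...)
      out[rows, ] <- combat_apply(Ym[rows, , drop = FALSE], fit_g, dg)
      model[[g]] <- fit_g
    }
  }
  n_negative <- sum(out < 0 & Ym >= 0)
  if (clip_negative) out[out < 0] <- 0
  if (is_fm) {
    out <- fixel_matrix(out, scan_ids = Y$scan_ids, metric = Y$metric,
                        mask = Y$mask)
  }
  attr(out, "n_negative") <- n_negative
  list(values = out, model = model)
}
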