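#' @export
print.combat_fit <- function(x, ...) {
  cat("ComBat fixel harmonisation model\n")
  cat(sprintf("  scans: %d, fixels: %d (%d harmonised, %d passed through)\n",
              x$n_scans, x$n_fixels, sum(x$mask), sum(!x$mask)))
  cat(sprintf("  batches (%s): %s\n", x$batch_column,
              paste(sprintf("%s (n=%d)", x$batch_levels, x$n_per_batch),
                    collapse = ", ")))
  cat(sprintf("  covariates: %s\n",
              if (length(x$covariate_names))
                paste(x$covariate_names, collapse = ", ") else "<none>"))
  cat(sprintf("  method: %s", x$method))
  if (x$method == "eb")
    cat(sprintf(" (tol %g, max %d iterations; %d batch(es) not converged)",
                x$eb_tol, x$eb_maxit, x$n_nonconverged))
  cat("\n")
  invisible(x)
}

#' Summarise a fitted ComBat model
#'
#' Reports, per batch, the empirical-Bayes prior (location mean and
#' variance, inverse-gamma shape and scale) together with the across-fixel
#' means of the raw and shrunken batch effects.
#'
#' @param object A `combat_fit`.
#' @param ... Unused.
#' @return A `summary.combat_fit` object (printed as a per-batch table).
#' @export
summary.combat_fit <- function(object, ...) {
  m <- which(object$mask)
  tab <- data.frame(
    batch = object$batch_levels,
    n = object$n_per_batch,
    gamma_bar = object$hyper$gamma_bar,
    tau2 = object$hyper$tau2,
    lambda = object$hyper$lambda,
    theta = object$hyper$theta,
    mean_gamma_hat = rowMeans(object$gamma_hat[, m, drop = FALSE]),
    mean_delta2_hat = rowMeans(object$delta2_hat[, m, drop = FALSE]),
    mean_gamma_star = rowMeans(object$gamma_star[, m, drop = FALSE]),
    mean_delta_star = rowMeans(object$delta_star[, m, drop = FALSE])
  )
  structure(list(table = tab, method = object$method,
                 n_scans = object$n_scans, n_fixels = object$n_fixels,
                 n_masked = sum(object$mask)),
            class = "summary.combat_fit")
}

#' @export
print.summary.combat_fit <- function(x, digits = 4, ...) {
  cat(sprintf("ComBat model summary (%s method): %d scans, %d/%d fixels harmonised\n",
              x$method, x$n_scans, x$n_masked, x$n_fixels))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Model coefficients of a ComBat fit
#'
#' @param object A `combat_fit`.
#' @param ... Unused.
#' @return A (1 + p) x M matrix: the overall fixel means (`alpha`) stacked
#'   over the covariate coefficient rows.
#' @export
coef.combat_fit <- function(object, ...) {
  rbind(alpha = object$alpha, object$beta)
}

#' Harmonise (new) data with a fitted ComBat model
#'
#' Thin wrapper around [combat_apply()]; rows may be held-out scans from
#' the fitted batches.
#'
#' @param object A `combat_fit`.
#' @param Y Data matrix or [fixel_matrix] with the fitted column layout.
#' @param data Covariate table aligned with the rows of `Y`.
#' @param ... Unused.
#' @return Harmonised values, same shape as `Y`.
#' @export
predict.combat_fit <- function(object, Y, data, ...) {
  combat_apply(Y, object, data)
}

#' Standardized residuals of a ComBat fit
#'
#' @param object A `combat_fit`.
#' @param Y,data The data the model was fitted on (the model stores no
#'   data copy).
#' @param ... Unused.
#' @return N x M matrix of standardized residuals Z.
#' @export
residuals.combat_fit <- function(object, Y, data, ...) {
  combat_standardize(Y, object, data)
}

#' Save a ComBat model to a self-contained JSON archive
#'
#' All model arrays plus batch/covariate labels, method, tolerances and the
#' package version are written as one JSON document at full double
#' precision, so [combat_apply()] can later harmonise held-out scans from
#' the same batches.
#'
#' @param model A `combat_fit`.
#' @param path Output path (conventionally `.json`).
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return `path`, invisibly.
#' @export
combat_save <- function(model, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    fh_io_error(sprintf("refusing to overwrite existing file %s", path))
  payload <- list(
    format = "fixelharm-combat-model",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("fixelharm")),
    alpha = model$alpha,
    beta = model$beta,
    sigma = model$sigma,
    gamma_hat = model$gamma_hat,
    delta2_hat = model$delta2_hat,
    gamma_star = model$gamma_star,
    delta_star = model$delta_star,
    hyper = model$hyper,
    batch_levels = model$batch_levels,
    n_per_batch = model$n_per_batch,
    covariate_names = model$covariate_names,
    mask = model$mask,
    method = model$method,
    batch_column = model$batch_column,
    eb_tol = model$eb_tol,
    eb_maxit = model$eb_maxit,
    n_nonconverged = model$n_nonconverged,
    n_scans = model$n_scans,
    n_fixels = model$n_fixels
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(path)
}

#' Load a ComBat model saved by [combat_save()]
#'
#' @param path Path to the JSON archive.
#' @return A `combat_fit`.
#' @export
combat_load <- function(path) {
  if (!file.exists(path))
    fh_format_error(sprintf("model file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "fixelharm-combat-model"))
    fh_format_error("not a fixelharm ComBat model archive")
  as_mat <- function(m, lv) {
    m <- rbind(m)
    rownames(m) <- lv
    m
  }
  lv <- as.character(x$batch_levels)
  model <- list(
    alpha = as.double(x$alpha),
    beta = if (length(x$covariate_names)) {
      b <- rbind(x$beta); rownames(b) <- as.character(x$covariate_names); b
    } else matrix(numeric(0), 0, x$n_fixels),
    sigma = as.double(x$sigma),
    gamma_hat = as_mat(x$gamma_hat, lv),
    delta2_hat = as_mat(x$delta2_hat, lv),
    gamma_star = as_mat(x$gamma_star, lv),
    delta_star = as_mat(x$delta_star, lv),
    hyper = as.data.frame(x$hyper),
    batch_levels = lv,
    n_per_batch = as.integer(x$n_per_batch),
    covariate_names = as.character(x$covariate_names),
    mask = as.logical(x$mask),
    method = x$method,
    batch_column = x$batch_column,
    eb_tol = x$eb_tol,
    eb_maxit = as.integer(x$eb_maxit),
    n_nonconverged = as.integer(x$n_nonconverged),
    n_scans = as.integer(x$n_scans),
    n_fixels = as.integer(x$n_fixels)
  )
  structure(model, class = "combat_fit")
}
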