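test_that("per-fixel GLM matches an independent normal-equations solution", {
  d <- random_dataset(N = 8L, M = 3L, with_covars = TRUE, seed = 10)
  fit <- combat_fit(d$Y, d$data, covariates = "age", method = "direct")
  bf <- factor(d$data$batch, levels = unique(d$data$batch))
  D <- cbind(sapply(levels(bf), function(b) as.numeric(bf == b)),
             age = d$data$age)
  n_b <- as.vector(table(bf))
  for (f in 1:3) {
    bhat <- solve(t(D) %*% D, t(D) %*% d$Y[, f])
    alpha_f <- sum(n_b / nrow(d$Y) * bhat[1:2])
    expect_equal(fit$alpha[f], alpha_f, tolerance = 1e-10)
    expect_equal(unname(fit$beta["age", f]), unname(bhat[3]), tolerance = 1e-10)
    res <- d$Y[, f] - drop(D %*% bhat)
    expect_equal(fit$sigma[f], sqrt(mean(res^2)), tolerance = 1e-10)
  }
})

test_that("two equal batches with means 0 and 2 give alpha 1 and gamma -1/+1", {
  Y <- matrix(c(rep(0, 4), rep(2, 4)), ncol = 1)
  Y <- Y + rep(c(-0.01, 0.01), 4)  # symmetric within-batch jitter
  df <- data.frame(batch = rep(c("a", "b"), each = 4))
  fit <- combat_fit(Y, df, covariates = NULL, method = "direct")
  expect_equal(fit$alpha, 1, tolerance = 1e-10)
  gamma_metric <- fit$gamma_hat[, 1] * fit$sigma  # back to metric units
  expect_equal(unname(gamma_metric), c(-1, 1), tolerance = 1e-10)
})

test_that("weighted batch location estimates satisfy the sum-to-zero constraint", {
  d <- random_dataset(N = 11L, M = 5L, seed = 3)
  fit <- combat_fit(d$Y, d$data, covariates = "age")
  wsum <- colSums(fit$gamma_hat * fit$n_per_batch)[fit$mask]
  expect_lt(max(abs(wsum)), 1e-8)
})

test_that("standardization is exact and invertible", {
  set.seed(4)
  N <- 12L; M <- 6L
  df <- data.frame(batch = rep(c("a", "b"), each = 6), age = runif(N, 20, 60))
  alpha <- runif(M, 0.4, 0.6); sigma <- runif(M, 0.05, 0.1)
  z <- matrix(rnorm(N * M), N, M)
  Y <- matrix(alpha, N, M, byrow = TRUE) + 0.002 * df$age +
    matrix(sigma, N, M, byrow = TRUE) * z
  fit <- combat_fit(Y, df, covariates = "age")
  Z <- combat_standardize(Y, fit, df)
  # pooled mean of each column is 0
  expect_lt(max(abs(colMeans(Z)[fit$mask])), 1e-6)
  # round trip
  back <- sweep(Z, 2, fit$sigma, "*") +
    matrix(fit$alpha, N, M, byrow = TRUE) + df$age %*% fit$beta["age", , drop = FALSE]
  expect_equal(back[, fit$mask], Y[, fit$mask], tolerance = 1e-8)
})

test_that("inverse-gamma moment matching recovers the stated closed form", {
  # m = 2, V = 1 -> lambda = 6, theta = 10; InvGamma(6,10) has mean
  # theta/(lambda-1) = 2 and variance theta^2/((lambda-1)^2 (lambda-2)) = 1
  d2 <- c(1, 2, 3)  # mean 2, var 1
  hyper <- estimate_hyperparameters(rbind(c(0, 0, 0)), rbind(d2))
  expect_equal(hyper$lambda, 6)
  expect_equal(hyper$theta, 10)
  expect_equal(10 / (6 - 1), 2)
  expect_equal(10^2 / ((6 - 1)^2 * (6 - 2)), 1)
  # constant gamma row: gamma_bar = g, tau2 = 0
  hyper2 <- estimate_hyperparameters(rbind(rep(0.7, 3)), rbind(c(1, 2, 3)))
  expect_equal(hyper2$gamma_bar, 0.7)
  expect_equal(hyper2$tau2, 0)
  # degenerate scale prior falls back with a warning
  expect_warning(h3 <- estimate_hyperparameters(rbind(c(0, 0.1, 0.2)),
                                                rbind(c(1, 1, 1))),
                 "degenerate")
  expect_true(h3$degenerate)
})

test_that("EB shrinkage limits behave as the posterior formulas dictate", {
  set.seed(8)
  N <- 10L; M <- 12L
  batch <- factor(rep("a", N))
  Z <- matrix(rnorm(N * M), N, M)
  gamma_hat <- rbind(colMeans(Z))
  delta2_hat <- rbind(colMeans(Z^2) - colMeans(Z)^2)
  base <- data.frame(gamma_bar = 0.3, tau2 = 0, lambda = 5, theta = 4,
                     degenerate = FALSE)
  # tau2 = 0: complete shrinkage to the prior mean
  sh0 <- eb_shrink(Z, batch, base, gamma_hat, delta2_hat)
  expect_equal(unname(sh0$gamma_star[1, ]), rep(0.3, M))
  # tau2 huge: no location shrinkage
  base$tau2 <- 1e12
  sh1 <- eb_shrink(Z, batch, base, gamma_hat, delta2_hat)
  expect_equal(sh1$gamma_star, gamma_hat, tolerance = 1e-4)
})

test_that("EB fixed point agrees with a 1000-iteration brute-force oracle", {
  set.seed(15)
  N <- 20L; M <- 50L
  batch <- factor(rep(c("a", "b"), each = 10))
  Z <- matrix(rnorm(N * M), N, M)
  gamma_hat <- delta2_hat <- matrix(0, 2, M)
  for (b in 1:2) {
    rows <- which(batch == levels(batch)[b])
    gamma_hat[b, ] <- colMeans(Z[rows, ]) + rnorm(M, 0.5, 0.3)
    delta2_hat[b, ] <- colMeans(Z[rows, ]^2)
  }
  hyper <- estimate_hyperparameters(gamma_hat, delta2_hat)
  got <- eb_shrink(Z, batch, hyper, gamma_hat, delta2_hat,
                   tol = 1e-10, maxit = 5000L)
  want <- oracle_eb_fixed_point(Z, batch, hyper, gamma_hat, delta2_hat)
  expect_equal(got$gamma_star, want$gamma_star, tolerance = 1e-8)
  expect_equal(got$delta_star, want$delta_star, tolerance = 1e-8)
})

test_that("identity adjustments leave the data untouched", {
  d <- random_dataset(N = 10L, M = 4L, seed = 21)
  fit <- combat_fit(d$Y, d$data, covariates = "age", method = "direct")
  fit$gamma_star[] <- 0
  fit$delta_star[] <- 1
  out <- combat_apply(d$Y, fit, d$data)
  expect_equal(out, d$Y, tolerance = 1e-10)
})

test_that("single-batch data pass through unchanged", {
  set.seed(30)
  Y <- matrix(rnorm(40, 0.5, 0.1), 10, 4)
  df <- data.frame(batch = rep("only", 10), age = runif(10, 20, 60))
  h <- suppressWarnings(harmonize(Y, df, covariates = "age", method = "eb"))
  expect_equal(h$values, Y, tolerance = 1e-8, ignore_attr = TRUE)
  hd <- harmonize(Y, df, covariates = "age", method = "direct")
  expect_equal(hd$values, Y, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("direct harmonisation equalises batch means exactly", {
  d <- random_dataset(N = 12L, M = 6L, with_covars = FALSE, seed = 5)
  h <- harmonize(d$Y, d$data, covariates = NULL, method = "direct")
  pooled <- colMeans(h$values)
  for (b in unique(d$data$batch)) {
    bm <- colMeans(h$values[d$data$batch == b, ])
    expect_equal(bm, pooled, tolerance = 1e-8)
  }
})

test_that("row-order permutation commutes with harmonisation", {
  d <- random_dataset(N = 10L, M = 5L, seed = 77)
  h1 <- harmonize(d$Y, d$data, covariates = "age")$values
  set.seed(1); perm <- sample(10)
  h2 <- harmonize(d$Y[perm, ], d$data[perm, , drop = FALSE],
                  covariates = "age")$values
  expect_equal(h2, h1[perm, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("direct and EB methods agree under a flat prior", {
  d <- random_dataset(N = 12L, M = 6L, seed = 9)
  fit <- combat_fit(d$Y, d$data, covariates = "age", method = "direct")
  hyper <- fit$hyper
  hyper$tau2[] <- 1e12          # flat location prior
  hyper$lambda[] <- 1 + 1e-9    # flat scale prior: posterior ~ data term
  hyper$theta[] <- 0
  sh <- eb_shrink(combat_standardize(d$Y, fit, d$data)[, fit$mask],
                  factor(d$data$batch, levels = unique(d$data$batch)),
                  hyper, fit$gamma_hat[, fit$mask], fit$delta2_hat[, fit$mask],
                  tol = 1e-10, maxit = 5000L)
  expect_equal(sh$gamma_star, fit$gamma_hat[, fit$mask], tolerance = 1e-3)
})

test_that("harmonised output agrees with the genomics reference implementation", {
  skip_if_not_installed("sva")
  set.seed(99)
  n_i <- 50L; N <- 2L * n_i; M <- 60L
  df <- data.frame(batch = rep(c("a", "b"), each = n_i),
                   age = runif(N, 20, 60))
  alpha <- runif(M, 0.3, 0.8); sig <- runif(M, 0.02, 0.06)
  g <- rbind(rnorm(M, 0, 0.5), rnorm(M, 1.5, 0.5))
  Y <- matrix(0, N, M)
  for (b in 1:2) {
    rows <- which(df$batch == c("a", "b")[b])
    Y[rows, ] <- matrix(alpha + sig * g[b, ], n_i, M, byrow = TRUE) +
      0.003 * df$age[rows] +
      matrix(sig, n_i, M, byrow = TRUE) * matrix(rnorm(n_i * M), n_i, M)
  }
  mine <- harmonize(Y, df, covariates = "age", method = "eb")$values
  ref <- t(sva::ComBat(dat = t(Y), batch = df$batch,
                       mod = stats::model.matrix(~age, df),
                       par.prior = TRUE, prior.plots = FALSE))
  # the reference uses the unbiased (n-1) within-batch variance estimator;
  # the divisor-n convention here differs by O(1/n)
  expect_lt(max(abs(mine - ref)), 0.01)
  expect_gt(stats::cor(as.vector(mine), as.vector(ref)), 0.9999)
})

test_that("refitting on harmonised output finds almost no batch effect", {
  cfg <- sim_config("scanner_diff", grid_shape = c(8L, 8L, 4L),
                    n_subjects = 30L, seed = 13L)
  ds <- simulate_dataset(cfg)
  h <- harmonize(ds$Y, ds$covariates, method = "eb")
  refit <- combat_fit(h$values$values, ds$covariates, method = "eb")
  m <- refit$mask
  # batch-level residual effects: across-fixel means of the refit estimates
  expect_lt(max(abs(rowMeans(refit$gamma_hat[, m]))), 0.05)
  expect_lt(max(abs(rowMeans(refit$delta2_hat[, m]) - 1)), 0.1)
})

test_that("rank-deficient designs are reported with the offending columns", {
  d <- random_dataset(N = 8L, M = 3L, seed = 2)
  d$data$dup <- d$data$age
  expect_error(combat_fit(d$Y, d$data, covariates = c("age", "dup")),
               class = "fixelharm_design_error")
  # batch perfectly confounded with a covariate
  d$data$indicator <- as.numeric(d$data$batch == "a")
  expect_error(combat_fit(d$Y, d$data, covariates = "indicator"),
               class = "fixelharm_design_error")
})

test_that("model archives round-trip through JSON and still harmonise new scans", {
  d <- random_dataset(N = 12L, M = 5L, seed = 31)
  fit <- combat_fit(d$Y, d$data, covariates = "age")
  path <- withr::local_tempfile(fileext = ".json")
  combat_save(fit, path, overwrite = TRUE)
  back <- combat_load(path)
  new <- random_dataset(N = 6L, M = 5L, seed = 32)
  expect_equal(combat_apply(new$Y, back, new$data),
               combat_apply(new$Y, fit, new$data), tolerance = 1e-8)
  expect_error(combat_save(fit, path), class = "fixelharm_io_error")
})

test_that("per-group harmonisation keeps single-batch groups untouched", {
  set.seed(41)
  Y <- matrix(rnorm(60, 0.5, 0.1), 12, 5)
  df <- data.frame(batch = c(rep(c("a", "b"), 4), rep("c", 4)),
                   group = c(rep("g1", 8), rep("g2", 4)),
                   age = runif(12, 20, 60))
  expect_warning(h <- harmonize(Y, df, covariates = "age", group = "group"),
                 "single batch")
  rows_g2 <- df$group == "g2"
  expect_equal(h$values[rows_g2, ], Y[rows_g2, ])
  expect_null(h$model$g2)
  expect_s3_class(h$model$g1, "combat_fit")
})
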