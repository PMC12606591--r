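# Shared fixtures: tiny templates, random datasets, and independently coded
# oracles used to cross-check the package implementation.

tiny_template <- function(seed = 1L) make_template(c(2L, 2L, 1L), c(1L, 2L), seed)

# random two-batch dataset on the location-scale model
random_dataset <- function(N = 8L, M = 4L, with_covars = TRUE, seed = 1L) {
  set.seed(seed)
  n1 <- max(2L, N %/% 2L)
  batch <- c(rep("a", n1), rep("b", N - n1))
  df <- data.frame(batch = batch)
  if (with_covars) df$age <- runif(N, 20, 70)
  Y <- matrix(rnorm(N * M, mean = 0.5, sd = 0.1), N, M)
  Y[batch == "b", ] <- Y[batch == "b", ] + 0.05
  if (with_covars) Y <- Y + 0.002 * df$age
  list(Y = Y, data = df,
       covariates = if (with_covars) "age" else NULL)
}

# Independent per-fixel location-scale adjustment oracle (direct method):
# explicit normal equations per fixel, per-batch moments on the standardized
# residuals, no shared code with the package internals.
oracle_direct_combat <- function(Y, batch, X = NULL) {
  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  N <- nrow(Y)
  lv <- levels(batch)
  n_b <- sapply(lv, function(b) sum(batch == b))
  D <- sapply(lv, function(b) as.numeric(batch == b))
  if (!is.null(X)) D <- cbind(D, X)
  out <- Y
  for (f in seq_len(ncol(Y))) {
    y <- Y[, f]
    bhat <- solve(t(D) %*% D, t(D) %*% y)
    mu_b <- bhat[seq_along(lv)]
    beta <- if (is.null(X)) numeric(0) else bhat[-seq_along(lv)]
    alpha <- sum(n_b / N * mu_b)
    covpart <- if (is.null(X)) 0 else drop(X %*% beta)
    res <- y - drop(D %*% bhat)
    sigma <- sqrt(mean(res^2))
    if (sigma == 0) next
    z <- (y - alpha - covpart) / sigma
    adj <- z
    skip <- FALSE
    for (b in lv) {
      rows <- batch == b
      gb <- mean(z[rows])
      db <- sqrt(mean((z[rows] - gb)^2))
      if (db == 0) { skip <- TRUE; break }
      adj[rows] <- (z[rows] - gb) / db
    }
    if (skip) next
    out[, f] <- sigma * adj + alpha + covpart
  }
  out
}

# brute-force EB fixed-point iteration (long-run oracle)
oracle_eb_fixed_point <- function(Z, batch, hyper, gamma_hat, delta2_hat,
                                  n_iter = 1000L) {
  batch <- as.factor(batch)
  g_star <- gamma_hat; d2_star <- delta2_hat
  for (b in seq_len(nrow(gamma_hat))) {
    rows <- which(batch == levels(batch)[b])
    n <- length(rows)
    for (f in seq_len(ncol(gamma_hat))) {
      g <- gamma_hat[b, f]; d2 <- delta2_hat[b, f]
      for (it in seq_len(n_iter)) {
        g <- (n * hyper$tau2[b] * gamma_hat[b, f] + d2 * hyper$gamma_bar[b]) /
          (n * hyper$tau2[b] + d2)
        d2 <- (hyper$theta[b] + 0.5 * sum((Z[rows, f] - g)^2)) /
          (n / 2 + hyper$lambda[b] - 1)
      }
      g_star[b, f] <- g; d2_star[b, f] <- d2
    }
  }
  list(gamma_star = g_star, delta_star = sqrt(d2_star))
}

write_sim_yaml <- function(path, mode = "scanner_diff", seed = 5L,
                           grid = c(3L, 3L, 2L), n_subjects = 6L) {
  yaml::write_yaml(list(mode = mode, seed = seed,
                        grid_shape = grid, n_subjects = n_subjects), path)
  path
}
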