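test_that("generated templates obey the range and pass integrity checks", {
  tpl <- make_template(c(2L, 2L, 1L), c(1L, 1L), seed = 5)
  expect_equal(tpl$n_fixels, 4L)
  expect_true(all(tpl$counts == 1L))
  tpl2 <- make_template(c(5L, 5L, 5L), c(1L, 3L), seed = 7)
  expect_silent(validate_fixel_template(tpl2))
  # determinism
  expect_identical(make_template(c(5L, 5L, 5L), c(1L, 3L), seed = 7), tpl2)
})

test_that("scan-rescan arms are identical when noise is switched off", {
  cfg <- sim_config("scan_rescan", grid_shape = c(3L, 3L, 2L),
                    n_subjects = 5L, noise_sd_range = c(0, 0), seed = 2)
  ds <- simulate_travelling(make_template(c(3L, 3L, 2L), c(1L, 2L), 3L), cfg)
  n <- 5L
  expect_identical(ds$Y$values[1:n, ], ds$Y$values[n + 1:n, ])
})

test_that("a configured 10% scanner shift appears as a ~10% arm difference", {
  cfg <- sim_config("scanner_diff", grid_shape = c(3L, 3L, 2L),
                    n_subjects = 6L, noise_sd_range = c(1e-8, 1e-8),
                    subject_sd = 0,
                    batches = list(
                      list(label = "A", g = 0, tau = 0, lambda = 1e7, theta = 1e7),
                      list(label = "B", g = 0.10, tau = 0, lambda = 1e7, theta = 1e7)),
                    covariate_effects = list(age = 0, sex = 0, icv = 0),
                    seed = 4)
  ds <- simulate_dataset(cfg)
  n <- 6L
  pd <- percentage_difference(colMeans(ds$Y$values[1:n, ]),
                              colMeans(ds$Y$values[n + 1:n, ]))
  expect_equal(unname(pd), rep(10, length(pd)), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("arm-level batch effects reproduce their configured moments", {
  cfg <- sim_config("scanner_diff", grid_shape = c(16L, 16L, 8L), seed = 42)
  ds <- simulate_dataset(cfg)
  M <- length(ds$ground_truth$alpha)
  for (a in 1:2) {
    g_cfg <- cfg$batches[[a]]$g
    fr <- ds$ground_truth$frac[a, ]
    se <- cfg$batches[[a]]$tau / sqrt(M)
    expect_lt(abs(mean(fr) - g_cfg), 3 * se)
  }
  # and the realised mean fractional shift matches g
  shift_frac <- ds$ground_truth$frac[2, ]
  expect_equal(mean(shift_frac), cfg$batches[[2]]$g, tolerance = 0.01)
})

test_that("null case-control simulations show no spurious tract effect", {
  # a single draw of d at n = 56 has sampling SD ~0.27, so average a few
  d <- sapply(1:5, function(r) {
    cfg <- sim_config("case_control", grid_shape = c(6L, 6L, 3L),
                      group_effect = 0, seed = 6L + r)
    ds <- simulate_case_control(make_template(c(6L, 6L, 3L), c(1L, 3L), 11L), cfg)
    g <- ds$covariates$group
    tm <- rowMeans(ds$ground_truth$Y_nobatch[, ds$ground_truth$tract_label])
    cohens_d(tm[g == "CN"], tm[g == "AD"])
  })
  expect_lt(abs(mean(d)), 0.3)
})

test_that("a 15% tract reduction and the cognitive link are constructed faithfully", {
  cfg <- sim_config("case_control", grid_shape = c(6L, 6L, 3L),
                    noise_sd_range = c(1e-8, 1e-8), subject_sd = 0,
                    covariate_effects = list(age = 0, sex = 0, icv = 0),
                    cognitive_link = list(
                      mmse = list(intercept = -13.7, slope = 77.6, sd = 1e-9),
                      moca = list(intercept = -37.0, slope = 115.2, sd = 1e-9)),
                    seed = 8)
  ds <- simulate_case_control(make_template(c(6L, 6L, 3L), c(1L, 3L), 12L), cfg)
  g <- ds$covariates$group
  tract <- ds$ground_truth$tract_label
  m_ad <- colMeans(ds$ground_truth$Y_nobatch[g == "AD", tract])
  m_cn <- colMeans(ds$ground_truth$Y_nobatch[g == "CN", tract])
  expect_equal(unname(m_ad / m_cn), rep(0.85, sum(tract)), tolerance = 1e-3)
  # off-tract fixels are unaffected
  m_ad0 <- colMeans(ds$ground_truth$Y_nobatch[g == "AD", !tract])
  m_cn0 <- colMeans(ds$ground_truth$Y_nobatch[g == "CN", !tract])
  expect_equal(m_ad0, m_cn0, tolerance = 1e-3)
  # noise-free cognitive link is essentially deterministic before truncation
  tmb <- rowMeans(ds$ground_truth$Y_nobatch[, tract])
  expect_gt(cor(tmb, ds$ground_truth$score_latent$mmse), 0.99)
  expect_true(all(ds$covariates$mmse >= 0 & ds$covariates$mmse <= 30))
})

test_that("tract labels form one contiguous run", {
  cfg <- sim_config("case_control", grid_shape = c(6L, 6L, 3L), seed = 3)
  ds <- simulate_case_control(make_template(c(6L, 6L, 3L), c(1L, 3L), 9L), cfg)
  idx <- which(ds$ground_truth$tract_label)
  expect_equal(idx, seq(min(idx), max(idx)))
  expect_equal(length(idx), round(0.10 * length(ds$ground_truth$tract_label)))
})

test_that("simulation is deterministic and structure/noise seeds are separable", {
  cfg <- sim_config("scanner_diff", grid_shape = c(3L, 3L, 2L),
                    n_subjects = 4L, seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$Y$values, d2$Y$values)
  # same structure seed, different noise seed: biology fixed, noise differs
  cfg3 <- sim_config("scanner_diff", grid_shape = c(3L, 3L, 2L),
                     n_subjects = 4L, seed = 5, noise_seed = 999L)
  d3 <- simulate_dataset(cfg3)
  expect_identical(d3$ground_truth$alpha, d1$ground_truth$alpha)
  expect_identical(d3$ground_truth$frac, d1$ground_truth$frac)
  expect_identical(d3$ground_truth$subjects$age, d1$ground_truth$subjects$age)
  expect_false(identical(d3$Y$values, d1$Y$values))
})

test_that("exported datasets re-ingest losslessly at float32 precision", {
  cfg <- sim_config("scanner_diff", grid_shape = c(3L, 3L, 2L),
                    n_subjects = 4L, seed = 16)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  export_dataset(ds, dir, overwrite = TRUE)
  tpl <- read_fixel_template(dir)
  covs <- read_covariates(file.path(dir, "covariates.csv"))
  fm <- assemble_matrix(tpl, covs, dir)
  expect_equal(fm$values, ds$Y$values, tolerance = 1e-6, ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_true(all(c("alpha", "sigma", "beta", "frac", "gamma_true",
                    "delta_true", "subjects", "Y_nobatch") %in% names(gt)))
  # refusal to clobber a populated directory without overwrite
  expect_error(export_dataset(ds, dir), class = "fixelharm_io_error")
})
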