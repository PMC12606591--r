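#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic fixel-data generator.
#' Two study designs are emulated. Travelling-subject (TS) modes
#' (`scan_rescan`, `site_diff`, `scanner_diff`, `protocol_diff`) scan every
#' subject once per arm with identical latent biology, so any systematic
#' arm difference is batch effect by construction; the four modes mirror a
#' four-group TS design with 23/10/23/31 subjects. `case_control` mode
#' generates an Alzheimer's-disease-versus-control cohort (27 patients,
#' 29 controls by default) scanned on six scanner models, with a
#' contiguous "tract" fixel subset carrying a fractional fibre-density
#' reduction in the patient group, and integer cognitive scores (MMSE,
#' MoCA, range 0-30) linked to the tract-mean signal.
#'
#' Data are generated as
#' \deqn{Y_{i,j,f} = \alpha_f (1 + u_j) + X_j \beta + \alpha_f\, c_{i,f} + \sigma_f\, \delta_{i,f}\, \varepsilon_{i,j,f},}
#' where \eqn{u_j \sim N(0, \mathrm{subject\_sd}^2)} is a global
#' between-subject biological deviation, the additive batch effect
#' \eqn{c_{i,f} \sim N(g_i, \tau_i^2)} is expressed as a fraction of the
#' fixel baseline (so `g = 0.10` produces a ~10% shift irrespective of the
#' noise level), and \eqn{\delta^2_{i,f} \sim \mathrm{InvGamma}(\lambda_i,
#' \theta_i)} scales the noise. The ground truth records the additive
#' effects both on the fraction scale and on the standardized scale
#' (\eqn{\alpha_f c_{i,f} / \sigma_f}) used by the harmonisation model.
#'
#' Structural draws (template geometry, per-fixel baselines and noise
#' scales, subjects, batch assignment, tract labels, batch-effect
#' realisations) are controlled by `structure_seed`; measurement noise and
#' cognitive-score noise by `noise_seed`. Both default to deterministic
#' functions of `seed`.
#'
#' @param mode One of `"scan_rescan"`, `"site_diff"`, `"scanner_diff"`,
#'   `"protocol_diff"`, `"case_control"`.
#' @param ... Named overrides of any default field (see Details and the
#'   field list in the returned object).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(mode = c("scanner_diff", "scan_rescan", "site_diff",
                                "protocol_diff", "case_control"), ...) {
  mode <- match.arg(mode)
  ts_n <- c(scan_rescan = 23L, site_diff = 10L, scanner_diff = 23L,
            protocol_diff = 31L)
  arm_labels <- switch(mode,
    scan_rescan   = c("siteA", "siteA"),
    site_diff     = c("siteA", "siteB"),
    scanner_diff  = c("Prisma_fit", "Verio"),
    protocol_diff = c("HARP", "CRHD"),
    case_control  = c("Prisma", "Prisma_fit", "Skyra", "Ingenia",
                      "MR750", "MR750w"))
  g_default <- switch(mode,
    scan_rescan   = c(0, 0),
    case_control  = c(0.00, 0.08, -0.08, 0.12, -0.12, 0.10),
    c(0, 0.10))
  batches <- lapply(seq_along(arm_labels), function(k) {
    list(label = arm_labels[k], g = g_default[k], tau = 0.02,
         lambda = 51, theta = 50)
  })
  g <- vapply(batches, `[[`, numeric(1), "g")
  rng <- diff(range(g))
  conf_w <- if (rng > 0) (g - min(g)) / rng else rep(0.5, length(g))
  cfg <- list(
    mode = mode,
    grid_shape = c(6L, 6L, 4L),
    fixels_per_voxel_range = c(1L, 3L),
    n_subjects = if (mode == "case_control") NA_integer_ else ts_n[[mode]],
    n_ad = 27L, n_cn = 29L,
    batches = batches,
    covariate_effects = list(age = -0.002, sex = 0.01, icv = 2e-8),
    age_range = c(27, 36),
    age_mean_sd = c(72.4, 7),
    sex_p_female = 0.45,
    icv_mean_sd = c(1.45e6, 1.3e5),
    baseline_range = c(0.3, 0.8),
    noise_sd_range = c(0.02, 0.06),
    subject_sd = 0.10,
    effect_tract = 0.10,
    group_effect = 0.15,
    cognitive_link = list(
      mmse = list(intercept = -13.7, slope = 77.6, sd = 1.5),
      moca = list(intercept = -37.0, slope = 115.2, sd = 2.5)),
    ad_weights = 1 + 2 * conf_w,
    cn_weights = 1 + 2 * (1 - conf_w),
    seed = 1L, structure_seed = NULL, noise_seed = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    fh_schema_error(sprintf("unknown sim_config field(s): %s",
                            paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg$structure_seed <- cfg$structure_seed %||% (as.integer(cfg$seed) * 2L + 11L)
  cfg$noise_seed <- cfg$noise_seed %||% (as.integer(cfg$seed) * 2L + 12L)
  validate_sim_config(structure(cfg, class = "sim_config"))
}

#' @rdname sim_config
#' @param cfg A `sim_config` (or plain list) to validate.
#' @export
validate_sim_config <- function(cfg) {
  taus <- vapply(cfg$batches, `[[`, numeric(1), "tau")
  if (any(taus < 0) || any(cfg$noise_sd_range < 0) || cfg$subject_sd < 0)
    fh_schema_error("all standard deviations must be >= 0")
  if (cfg$group_effect < 0 || cfg$group_effect >= 1)
    fh_schema_error("group_effect must lie in [0, 1)")
  if (cfg$effect_tract <= 0 || cfg$effect_tract > 1)
    fh_schema_error("effect_tract must lie in (0, 1]")
  if (cfg$mode != "case_control") {
    if (length(cfg$batches) != 2L)
      fh_schema_error("travelling-subject modes use exactly 2 batch arms")
    if (is.na(cfg$n_subjects) || cfg$n_subjects < 2L)
      fh_validation_error("n_subjects must be at least 2")
  } else {
    if (length(cfg$batches) < 2L)
      fh_schema_error("case_control mode needs at least 2 batches")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds named fields of [sim_config()]; `mode` is required.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    fh_format_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path),
    error = function(e) fh_schema_error(sprintf("cannot parse config %s: %s",
                                                path, conditionMessage(e))))
  if (!is.list(raw) || is.null(raw$mode))
    fh_schema_error("config must be a mapping with a 'mode' field")
  if (!is.null(raw$batches)) {
    raw$batches <- lapply(seq_len(if (is.data.frame(raw$batches))
      nrow(raw$batches) else length(raw$batches)), function(k) {
        b <- if (is.data.frame(raw$batches)) as.list(raw$batches[k, ])
             else raw$batches[[k]]
        list(label = as.character(b$label), g = as.double(b$g),
             tau = as.double(b$tau %||% 0.02),
             lambda = as.double(b$lambda %||% 51),
             theta = as.double(b$theta %||% 50))
      })
  }
  args <- raw
  args$mode <- NULL
  do.call(sim_config, c(list(mode = raw$mode), args))
}

#' Generate a random fixel template
#'
#' Per-voxel fixel counts are drawn uniformly from
#' `fixels_per_voxel_range`, directions uniformly on the sphere, and
#' offsets assigned cumulatively; deterministic given `seed`.
#'
#' @param grid_shape Integer triple of voxel grid dimensions.
#' @param fixels_per_voxel_range Integer pair within `[1, 4]`.
#' @param seed Integer seed.
#' @return A valid `fixel_template`.
#' @export
make_template <- function(grid_shape = c(6L, 6L, 4L),
                          fixels_per_voxel_range = c(1L, 3L), seed = 1L) {
  r <- as.integer(fixels_per_voxel_range)
  if (length(r) != 2L || r[1] < 1L || r[2] > 4L || r[1] > r[2])
    fh_schema_error("fixels_per_voxel_range must be an increasing pair within [1, 4]")
  set.seed(seed)
  nvox <- prod(grid_shape)
  counts <- sample(seq.int(r[1], r[2]), nvox, replace = TRUE)
  M <- sum(counts)
  offsets <- c(0L, cumsum(counts))[seq_len(nvox)]
  dirs <- matrix(stats::rnorm(M * 3L), M, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  fixel_template(grid_shape, counts, offsets, dirs)
}

.rinvgamma <- function(n, lambda, theta) 1 / stats::rgamma(n, shape = lambda, rate = theta)

# shared structural draws: per-fixel biology and per-batch effect fields
.sim_structure <- function(cfg, M, B) {
  alpha <- stats::runif(M, cfg$baseline_range[1], cfg$baseline_range[2])
  sigma <- stats::runif(M, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
  frac <- matrix(0, B, M)    # additive batch effect, fraction of baseline
  delta <- matrix(1, B, M)   # multiplicative batch effect on sigma
  for (b in seq_len(B)) {
    spec <- cfg$batches[[b]]
    frac[b, ] <- stats::rnorm(M, spec$g, spec$tau)
    delta[b, ] <- sqrt(.rinvgamma(M, spec$lambda, spec$theta))
  }
  list(alpha = alpha, sigma = sigma, frac = frac, delta = delta)
}

.sim_covariate_signal <- function(cfg, subjects, alpha) {
  be <- cfg$covariate_effects
  X <- cbind(age = subjects$age, sex = subjects$sex, icv = subjects$icv)
  beta <- c(age = be$age, sex = be$sex, icv = be$icv)
  drop(X %*% beta)  # scalar per subject, constant across fixels
}

#' Simulate a travelling-subject dataset
#'
#' Every subject is scanned once per arm with identical latent biology
#' (baseline, covariate signal and individual deviation shared across
#' arms); arms differ only in batch effects and independent noise. In
#' `scan_rescan` mode both arms share one batch label and one batch-effect
#' realisation, so arms differ by noise alone.
#'
#' @param template A `fixel_template`.
#' @param config A `sim_config` with a travelling-subject `mode`.
#' @return List with `Y` (a [fixel_matrix], rows = arm 1 scans then arm 2
#'   scans), `covariates` (data frame with `subject_id`, `batch`, `arm`,
#'   `age`, `sex`, `icv`, `datafile`), and `ground_truth`.
#' @export
simulate_travelling <- function(template, config) {
  cfg <- validate_sim_config(config)
  if (cfg$mode == "case_control")
    fh_schema_error("use simulate_case_control() for case_control mode")
  M <- template$n_fixels
  n <- cfg$n_subjects
  rescan <- cfg$mode == "scan_rescan"

  set.seed(cfg$structure_seed)
  st <- .sim_structure(cfg, M, B = 2L)
  if (rescan) {  # one batch spec: effects forced equal across arms
    st$frac[2, ] <- st$frac[1, ]
    st$delta[2, ] <- st$delta[1, ]
  }
  subjects <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    age = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
    sex = stats::rbinom(n, 1L, cfg$sex_p_female),
    icv = stats::rnorm(n, cfg$icv_mean_sd[1], cfg$icv_mean_sd[2]),
    u   = stats::rnorm(n, 0, cfg$subject_sd)
  )
  cov_sig <- .sim_covariate_signal(cfg, subjects, st$alpha)
  bio <- outer(1 + subjects$u, st$alpha) + cov_sig  # n x M latent biology

  set.seed(cfg$noise_seed)
  eps <- array(stats::rnorm(2L * n * M), dim = c(2L, n, M))

  arm_label <- vapply(cfg$batches, `[[`, character(1), "label")
  Y <- matrix(0, 2L * n, M)
  nobatch <- matrix(0, 2L * n, M)
  for (a in 1:2) {
    rows <- (a - 1L) * n + seq_len(n)
    shift <- matrix(st$alpha * st$frac[a, ], n, M, byrow = TRUE)
    noise_sd <- matrix(st$sigma * st$delta[a, ], n, M, byrow = TRUE)
    Y[rows, ] <- bio + shift + noise_sd * eps[a, , ]
    nobatch[rows, ] <- bio +
      matrix(st$sigma, n, M, byrow = TRUE) * eps[a, , ]
  }
  scan_ids <- c(paste0(subjects$subject_id, "_arm1"),
                paste0(subjects$subject_id, "_arm2"))
  covs <- data.frame(
    subject_id = rep(subjects$subject_id, 2L),
    batch = rep(arm_label, each = n),
    arm = rep(1:2, each = n),
    age = rep(subjects$age, 2L),
    sex = rep(subjects$sex, 2L),
    icv = rep(subjects$icv, 2L),
    datafile = paste0(scan_ids, ".nii.gz")
  )
  gt <- list(
    alpha = st$alpha, sigma = st$sigma,
    beta = unlist(cfg$covariate_effects),
    frac = st$frac,
    gamma_true = st$frac * matrix(st$alpha / st$sigma, 2L, M, byrow = TRUE),
    delta_true = st$delta,
    subjects = subjects,
    Y_nobatch = nobatch,
    mode = cfg$mode, structure_seed = cfg$structure_seed,
    noise_seed = cfg$noise_seed
  )
  list(Y = fixel_matrix(Y, scan_ids = scan_ids, metric = "FD",
                        mask = fixel_mask(Y, covs$batch)),
       covariates = covs, ground_truth = gt)
}

#' Simulate a case-control multi-scanner dataset
#'
#' Patients (group `AD`) and controls (`CN`) are assigned to scanner
#' batches with every batch containing both groups (one scan of each group
#' is placed in every batch first; the rest follow the per-group assignment
#' weights, which by default confound group with the scanners' additive
#' shifts). A contiguous run of `effect_tract * M` fixels is labelled as
#' the target tract; the patient group's baseline is reduced there by
#' `group_effect`. Cognitive scores are generated from the subject's
#' noise-free tract-mean signal, plus noise, rounded and truncated to
#' 0-30.
#'
#' @param template A `fixel_template`.
#' @param config A `sim_config` with `mode = "case_control"`.
#' @return List with `Y` (a [fixel_matrix]), `covariates` (including
#'   `group`, `mmse`, `moca`), and `ground_truth` (including the
#'   `tract_label` mask and the batch-effect-free matrix `Y_nobatch`).
#' @export
simulate_case_control <- function(template, config) {
  cfg <- validate_sim_config(config)
  if (cfg$mode != "case_control")
    fh_schema_error("config mode must be 'case_control'")
  M <- template$n_fixels
  B <- length(cfg$batches)
  n <- cfg$n_ad + cfg$n_cn
  group <- c(rep("AD", cfg$n_ad), rep("CN", cfg$n_cn))

  set.seed(cfg$structure_seed)
  st <- .sim_structure(cfg, M, B)
  tract_n <- max(1L, round(cfg$effect_tract * M))
  tract_start <- sample.int(M - tract_n + 1L, 1L)
  tract <- logical(M)
  tract[seq.int(tract_start, tract_start + tract_n - 1L)] <- TRUE

  subjects <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = group,
    age = pmin(pmax(stats::rnorm(n, cfg$age_mean_sd[1], cfg$age_mean_sd[2]), 55), 90),
    sex = stats::rbinom(n, 1L, cfg$sex_p_female),
    icv = stats::rnorm(n, cfg$icv_mean_sd[1], cfg$icv_mean_sd[2]),
    u   = stats::rnorm(n, 0, cfg$subject_sd)
  )
  subjects$batch <- .assign_batches(group, B, cfg$ad_weights, cfg$cn_weights)

  # group effect: fractional baseline reduction on tract fixels for AD
  red <- outer(as.integer(group == "AD"), ifelse(tract, cfg$group_effect, 0))
  alpha_mat <- matrix(st$alpha, n, M, byrow = TRUE) * (1 - red)
  cov_sig <- .sim_covariate_signal(cfg, subjects, st$alpha)
  bio <- alpha_mat * (1 + subjects$u) + cov_sig

  set.seed(cfg$noise_seed)
  eps <- matrix(stats::rnorm(n * M), n, M)
  noise_sd <- matrix(st$sigma, n, M, byrow = TRUE) *
    st$delta[subjects$batch, , drop = FALSE]
  shift <- matrix(st$alpha, n, M, byrow = TRUE) *
    st$frac[subjects$batch, , drop = FALSE]
  Y <- bio + shift + noise_sd * eps
  nobatch <- bio + matrix(st$sigma, n, M, byrow = TRUE) * eps

  tract_mean_bio <- rowMeans(bio[, tract, drop = FALSE])
  score <- function(link) {
    latent <- link$intercept + link$slope * tract_mean_bio +
      stats::rnorm(n, 0, link$sd)
    list(latent = latent,
         score = as.integer(round(pmin(pmax(latent, 0), 30))))
  }
  mmse <- score(cfg$cognitive_link$mmse)
  moca <- score(cfg$cognitive_link$moca)

  batch_labels <- vapply(cfg$batches, `[[`, character(1), "label")
  scan_ids <- subjects$subject_id
  covs <- data.frame(
    subject_id = subjects$subject_id,
    batch = batch_labels[subjects$batch],
    group = group,
    age = subjects$age, sex = subjects$sex, icv = subjects$icv,
    mmse = mmse$score, moca = moca$score,
    datafile = paste0(scan_ids, ".nii.gz")
  )
  per_group_single <- any(vapply(split(covs$batch, covs$group),
                                 function(b) length(unique(b)) < 2L, logical(1)))
  if (per_group_single)
    warning("a group is confined to a single batch; per-group harmonisation will pass it through")
  gt <- list(
    alpha = st$alpha, sigma = st$sigma,
    beta = unlist(cfg$covariate_effects),
    frac = st$frac,
    gamma_true = st$frac * matrix(st$alpha / st$sigma, B, M, byrow = TRUE),
    delta_true = st$delta,
    tract_label = tract,
    group_effect = cfg$group_effect,
    subjects = subjects,
    score_latent = list(mmse = mmse$latent, moca = moca$latent),
    Y_nobatch = nobatch,
    mode = cfg$mode, structure_seed = cfg$structure_seed,
    noise_seed = cfg$noise_seed
  )
  list(Y = fixel_matrix(Y, scan_ids = scan_ids, metric = "FD",
                        mask = fixel_mask(Y, covs$batch)),
       covariates = covs, ground_truth = gt)
}

# batch assignment: every batch gets at least two scans of each group
# (matching the design rule that each scanner model is used for at least two
# participants per group); the remainder follows the per-group weights
.assign_batches <- function(group, B, ad_w, cn_w) {
  n <- length(group)
  out <- integer(n)
  for (g in c("AD", "CN")) {
    idx <- which(group == g)
    w <- if (g == "AD") ad_w else cn_w
    n_seed <- min(2L * B, length(idx))
    first <- sample(idx, n_seed)
    out[first] <- rep_len(sample.int(B), n_seed)
    rest <- setdiff(idx, first)
    if (length(rest))
      out[rest] <- sample.int(B, length(rest), replace = TRUE, prob = w)
  }
  out
}

#' Export a simulated dataset as a fixel directory
#'
#' Writes the template (`index.nii.gz`, `directions.nii.gz`), one float32
#' data image per scan, `covariates.csv`, and `ground_truth.json` under
#' `out_dir`. Re-ingestion with [read_fixel_template()],
#' [read_covariates()] and [assemble_matrix()] reproduces the value matrix
#' to float32 precision.
#'
#' @param dataset Output of [simulate_travelling()] or
#'   [simulate_case_control()], together with its `template` field (added
#'   automatically by [simulate_dataset()]) or supplied via `template`.
#' @param out_dir Output directory.
#' @param template The `fixel_template` used for simulation (optional if
#'   present in `dataset`).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return `out_dir`, invisibly.
#' @export
export_dataset <- function(dataset, out_dir, template = dataset$template,
                           overwrite = FALSE) {
  if (is.null(template))
    fh_schema_error("export_dataset needs the fixel template")
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)))
    fh_io_error(sprintf("output directory %s is not empty (use overwrite)", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fixel_template(template, out_dir)
  Y <- dataset$Y$values
  for (k in seq_len(nrow(Y)))
    write_fixel_data(template, Y[k, ],
                     file.path(out_dir, dataset$covariates$datafile[k]),
                     overwrite = TRUE)
  utils::write.csv(dataset$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor",
                       dataframe = "columns")
  invisible(out_dir)
}

#' Simulate a dataset from a configuration
#'
#' Convenience wrapper: builds the template with the structural seed and
#' dispatches on the configured mode; the returned dataset carries its
#' template for [export_dataset()].
#'
#' @param config A `sim_config`.
#' @return A dataset list (`template`, `Y`, `covariates`, `ground_truth`).
#' @export
simulate_dataset <- function(config) {
  cfg <- validate_sim_config(config)
  template <- make_template(cfg$grid_shape, cfg$fixels_per_voxel_range,
                            seed = cfg$structure_seed)
  ds <- if (cfg$mode == "case_control") simulate_case_control(template, cfg)
        else simulate_travelling(template, cfg)
  ds$template <- template
  ds
}
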