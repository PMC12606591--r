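#' Fixel directory input/output
#'
#' Functions for reading and writing the fixel directory layout used by
#' fixel-based analysis (FBA) pipelines, restricted to the NIfTI-1 dialect:
#' an `index` image (4-D, last dimension 2: volume 0 holds the per-voxel
#' fixel count, volume 1 the 0-based offset of the voxel's first fixel), a
#' `directions` image (M x 1 x 1 x 3, unit vectors), and one scalar data
#' image (M x 1 x 1) per subject and metric.
#'
#' @name fixel_io
NULL

.find_nifti <- function(dir_path, stem) {
  for (ext in c(".nii.gz", ".nii")) {
    p <- file.path(dir_path, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Construct and validate a fixel template
#'
#' A fixel template describes the shared fixel geometry of a study: the voxel
#' grid, how many fixels each voxel contains and where they sit in the
#' template-wide fixel list, and the unit direction of every fixel. All
#' per-subject scalar data are vectors over this common fixel list, so a
#' valid template is what guarantees one-to-one fixel correspondence across
#' subjects.
#'
#' @param grid_shape Integer triple, voxel grid dimensions.
#' @param counts Integer vector (one per voxel, column-major order),
#'   non-negative fixel counts.
#' @param offsets Integer vector, 0-based index of each voxel's first fixel.
#'   Ignored (and may be `NULL`) for voxels with `counts == 0`.
#' @param directions M x 3 numeric matrix of unit vectors.
#' @param affine 4 x 4 voxel-to-world transform (mm); defaults to a unit
#'   spacing transform.
#' @return An object of class `fixel_template` with fields `grid_shape`,
#'   `affine`, `counts`, `offsets`, `directions`, `n_fixels`.
#' @export
fixel_template <- function(grid_shape, counts, offsets, directions,
                           affine = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    fh_format_error("grid_shape must be three positive integers")
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    fh_format_error("directions must be an M x 3 matrix")
  if (is.null(affine)) {
    affine <- diag(4)
  }
  out <- structure(list(
    grid_shape = grid_shape,
    affine     = affine,
    counts     = as.integer(counts),
    offsets    = as.integer(offsets),
    directions = directions,
    n_fixels   = nrow(directions)
  ), class = "fixel_template")
  validate_fixel_template(out)
  out
}

#' Validate fixel template integrity
#'
#' Checks the structural invariants of a fixel template: every direction is
#' a unit vector (norm within 1e-4 of 1, zero rows forbidden), the per-voxel
#' `[offset, offset + count)` ranges are disjoint and jointly cover the whole
#' fixel list, and the counts sum to the number of fixels.
#'
#' @param template A `fixel_template`.
#' @return The template, invisibly; raises an integrity error otherwise.
#' @export
validate_fixel_template <- function(template) {
  t <- template
  M <- t$n_fixels
  if (length(t$counts) != prod(t$grid_shape) ||
      length(t$offsets) != prod(t$grid_shape))
    fh_integrity_error("counts/offsets length must equal the number of voxels")
  if (any(t$counts < 0L))
    fh_integrity_error("negative fixel count")
  if (sum(t$counts) != M)
    fh_integrity_error(sprintf(
      "counts sum to %d but there are %d fixels", sum(t$counts), M))
  nrm <- sqrt(rowSums(t$directions^2))
  if (M > 0 && any(abs(nrm - 1) > 1e-4))
    fh_integrity_error("direction rows must be unit vectors (norm within 1e-4 of 1)")
  occ <- t$counts > 0L
  if (any(occ)) {
    starts <- t$offsets[occ]
    ends <- starts + t$counts[occ]
    if (any(starts < 0L) || any(ends > M))
      fh_integrity_error("fixel offset range outside [0, n_fixels)")
    covered <- logical(M)
    for (k in seq_along(starts)) {
      idx <- seq.int(starts[k] + 1L, ends[k])
      if (any(covered[idx]))
        fh_integrity_error("overlapping fixel offset ranges")
      covered[idx] <- TRUE
    }
    if (!all(covered))
      fh_integrity_error("fixel offset ranges do not cover the fixel list")
  } else if (M > 0) {
    fh_integrity_error("no voxel has a positive fixel count")
  }
  invisible(template)
}

#' Read a fixel template from a fixel directory
#'
#' @param dir_path Directory containing `index.nii[.gz]` and
#'   `directions.nii[.gz]`.
#' @return A `fixel_template`.
#' @export
read_fixel_template <- function(dir_path) {
  if (!dir.exists(dir_path))
    fh_format_error(sprintf("fixel directory not found: %s", dir_path))
  idx_path <- .find_nifti(dir_path, "index")
  dir_path_f <- .find_nifti(dir_path, "directions")
  if (is.null(idx_path))
    fh_format_error(sprintf("missing index image in %s", dir_path))
  if (is.null(dir_path_f))
    fh_format_error(sprintf("missing directions image in %s", dir_path))
  idx <- RNifti::readNifti(idx_path)
  affine <- structure(RNifti::xform(idx), code = NULL)
  idx <- as.array(idx)
  if (length(dim(idx)) != 4L || dim(idx)[4] != 2L)
    fh_format_error("index image must be 4-D with last dimension 2 (count, offset)")
  dirs <- as.array(RNifti::readNifti(dir_path_f))
  dd <- dim(dirs)
  if (dd[length(dd)] != 3L)
    fh_format_error("directions image must have last dimension 3")
  dirs <- matrix(dirs, nrow = prod(dd[-length(dd)]), ncol = 3L)
  fixel_template(
    grid_shape = dim(idx)[1:3],
    counts     = as.integer(round(idx[, , , 1])),
    offsets    = as.integer(round(idx[, , , 2])),
    directions = dirs,
    affine     = affine
  )
}

#' Write a fixel template to a fixel directory
#'
#' Writes `index.nii.gz` (int32) and `directions.nii.gz` (float32).
#'
#' @param template A `fixel_template`.
#' @param dir_path Output directory (created if necessary).
#' @return `dir_path`, invisibly.
#' @export
write_fixel_template <- function(template, dir_path) {
  validate_fixel_template(template)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  idx <- array(0L, dim = c(template$grid_shape, 2L))
  idx[, , , 1] <- array(template$counts, dim = template$grid_shape)
  idx[, , , 2] <- array(template$offsets, dim = template$grid_shape)
  RNifti::writeNifti(RNifti::asNifti(idx, datatype = "int32"),
                     file.path(dir_path, "index.nii.gz"))
  M <- template$n_fixels
  dirs <- array(template$directions, dim = c(M, 1L, 1L, 3L))
  RNifti::writeNifti(RNifti::asNifti(dirs, datatype = "double"),
                     file.path(dir_path, "directions.nii.gz"))
  invisible(dir_path)
}

#' Read one scan's fixel data image
#'
#' @param template The study's `fixel_template`.
#' @param file_path Path to a scalar fixel data image (first dimension M).
#' @return Numeric vector of length `template$n_fixels`, in template fixel
#'   order.
#' @export
read_fixel_data <- function(template, file_path) {
  if (!file.exists(file_path))
    fh_format_error(sprintf("fixel data file not found: %s", file_path))
  x <- as.array(RNifti::readNifti(file_path))
  d1 <- if (is.null(dim(x))) length(x) else dim(x)[1]
  if (d1 != template$n_fixels)
    fh_shape_error(sprintf(
      "fixel data %s has first dimension %d; template has %d fixels",
      file_path, d1, template$n_fixels))
  as.double(x)
}

#' Write one scan's fixel data image
#'
#' Values are stored as 32-bit float with dimensions M x 1 x 1, the scalar
#' fixel data convention.
#'
#' @param template The study's `fixel_template`.
#' @param values Numeric vector of length `template$n_fixels`.
#' @param file_path Output path (`.nii` or `.nii.gz`).
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return `file_path`, invisibly.
#' @export
write_fixel_data <- function(template, values, file_path, overwrite = FALSE) {
  if (length(values) != template$n_fixels)
    fh_shape_error(sprintf(
      "values has length %d; template has %d fixels",
      length(values), template$n_fixels))
  if (file.exists(file_path) && !overwrite)
    fh_io_error(sprintf("refusing to overwrite existing file %s", file_path))
  arr <- array(as.double(values), dim = c(template$n_fixels, 1L, 1L))
  ok <- tryCatch({
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), file_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fh_io_error(sprintf("could not write %s", file_path))
  invisible(file_path)
}

#' Read a per-scan covariate table
#'
#' The covariate CSV has one row per scan with required columns `subject_id`,
#' `batch`, `age`, `sex`, `icv`, `datafile`, and optional `group`, `mmse`,
#' `moca`. `sex` is accepted as M/F or 0/1 and stored as a 0/1 indicator
#' with female = 1. `batch` is stored as a factor whose level order is the
#' order of first appearance. Every batch level must contain at least two
#' scans (per-batch location and scale cannot be estimated from one scan).
#'
#' @param csv_path Path to the CSV file.
#' @return A `data.frame` with typed columns; extra columns are preserved.
#' @export
read_covariates <- function(csv_path) {
  if (!file.exists(csv_path))
    fh_format_error(sprintf("covariate file not found: %s", csv_path))
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  validate_covariates(df)
}

#' Validate and type a covariate table
#'
#' @param df A data.frame with the columns described in [read_covariates()].
#' @return The typed, validated data.frame.
#' @export
validate_covariates <- function(df) {
  required <- c("subject_id", "batch", "age", "sex", "icv", "datafile")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    fh_schema_error(sprintf("covariate table missing required column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  df$subject_id <- as.character(df$subject_id)
  df$batch <- factor(as.character(df$batch),
                     levels = unique(as.character(df$batch)))
  sex_raw <- as.character(df$sex)
  sex <- ifelse(sex_raw %in% c("F", "f", "1"), 1L,
                ifelse(sex_raw %in% c("M", "m", "0"), 0L, NA_integer_))
  if (any(is.na(sex)))
    fh_schema_error("sex must be coded M/F or 0/1")
  df$sex <- sex
  df$age <- as.double(df$age)
  df$icv <- as.double(df$icv)
  core <- c("batch", "age", "sex", "icv")
  if (anyNA(df[core]))
    fh_validation_error("missing values in batch/age/sex/icv")
  tab <- table(df$batch)
  if (any(tab < 2L))
    fh_validation_error(sprintf(
      "batch level(s) with a single scan: %s; per-batch location and scale cannot be estimated",
      paste(names(tab)[tab < 2L], collapse = ", ")))
  df
}

#' Assemble a subjects-by-fixels data matrix
#'
#' Reads every scan listed in the covariate table (column `datafile`,
#' resolved under `data_dir`) and stacks the fixel vectors into an N x M
#' matrix, row order matching the covariate table. Absent fibre populations
#' encoded as `NaN`/`NA` in a data file are set to 0, preserving one-to-one
#' fixel correspondence across scans; the number of converted values is
#' recorded in the `n_zero_filled` attribute. The valid-fixel `mask`
#' excludes any fixel whose values are constant within some batch (its
#' per-batch scale would be degenerate); masked-out fixels pass through
#' harmonisation unchanged.
#'
#' @param template The study's `fixel_template`.
#' @param covariates A validated covariate table (see [read_covariates()]).
#' @param data_dir Directory containing the scan data images.
#' @param metric Optional metric label stored with the matrix
#'   (`"FD"`, `"logFC"`, `"FDC"`).
#' @return A `fixel_matrix`: list with `values` (N x M), `scan_ids`,
#'   `metric`, `mask`.
#' @export
assemble_matrix <- function(template, covariates, data_dir, metric = NA_character_) {
  covariates <- validate_covariates(covariates)
  scan_ids <- tools::file_path_sans_ext(basename(covariates$datafile),
                                        compression = TRUE)
  if (anyDuplicated(scan_ids))
    fh_validation_error(sprintf("duplicate scan id(s): %s",
      paste(unique(scan_ids[duplicated(scan_ids)]), collapse = ", ")))
  N <- nrow(covariates)
  M <- template$n_fixels
  Y <- matrix(NA_real_, N, M)
  for (k in seq_len(N)) {
    path <- file.path(data_dir, covariates$datafile[k])
    v <- tryCatch(read_fixel_data(template, path),
                  fixelharm_shape_error = function(e)
                    fh_shape_error(sprintf("scan %s: %s", scan_ids[k],
                                           conditionMessage(e))))
    Y[k, ] <- v
  }
  n_zero <- sum(!is.finite(Y))
  if (n_zero > 0) {
    message(sprintf("assemble_matrix: %d absent fixel value(s) set to 0", n_zero))
    Y[!is.finite(Y)] <- 0
  }
  fixel_matrix(Y, scan_ids = scan_ids, metric = metric,
               mask = fixel_mask(Y, covariates$batch))
}

#' Compute the valid-fixel mask
#'
#' A fixel is eligible for harmonisation only if its values vary within
#' every batch; a within-batch-constant fixel has a degenerate per-batch
#' scale estimate and is passed through unchanged.
#'
#' @param Y N x M data matrix.
#' @param batch Factor of batch labels, length N.
#' @return Logical vector of length M.
#' @export
fixel_mask <- function(Y, batch) {
  batch <- as.factor(batch)
  mask <- rep(TRUE, ncol(Y))
  for (b in levels(batch)) {
    rows <- which(batch == b)
    if (length(rows) < 2L) next
    rng <- matrixStats_colVar(Y[rows, , drop = FALSE])
    mask <- mask & (rng > 0)
  }
  mask
}

# column variances, divisor n-1 (small helper; avoids apply() overhead)
matrixStats_colVar <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' Fixel data matrix container
#'
#' @param values N x M numeric matrix (rows = scans, columns = fixels).
#' @param scan_ids Character vector of length N.
#' @param metric Metric name (`"FD"`, `"logFC"`, `"FDC"`, or `NA`).
#' @param mask Logical length-M valid-fixel mask (default all `TRUE`).
#' @return An object of class `fixel_matrix`.
#' @export
fixel_matrix <- function(values, scan_ids = rownames(values),
                         metric = NA_character_, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(scan_ids)) scan_ids <- sprintf("scan%03d", seq_len(nrow(values)))
  if (length(scan_ids) != nrow(values))
    fh_shape_error("scan_ids length must match the number of rows")
  if (is.null(mask)) mask <- rep(TRUE, ncol(values))
  if (length(mask) != ncol(values))
    fh_shape_error("mask length must match the number of fixels")
  structure(list(values = values, scan_ids = as.character(scan_ids),
                 metric = metric, mask = as.logical(mask)),
            class = "fixel_matrix")
}

#' @export
as.matrix.fixel_matrix <- function(x, ...) x$values

#' @export
dim.fixel_matrix <- function(x) dim(x$values)

#' @export
print.fixel_matrix <- function(x, ...) {
  cat(sprintf("fixel_matrix: %d scans x %d fixels (%d masked in), metric %s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              ifelse(is.na(x$metric), "<unset>", x$metric)))
  invisible(x)
}
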