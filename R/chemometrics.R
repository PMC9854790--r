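# Feature-table preprocessing and PCA data fusion.
#
# The enforced pipeline order mirrors common metabolomics practice:
#   raw peak areas -> total-signal normalization (per sample, over LC-MS
#   feature columns only) -> optional fusion with assay variables
#   (PV, TPC, RSA, AUC) -> Pareto scaling -> PCA.
# Pareto scaling divides each centered column by the square root of its
# standard deviation, tempering (without equalizing) the dominance of
# high-intensity features.

#' Construct a sample-by-feature peak-area matrix
#'
#' @param values numeric matrix, samples in rows, features in columns;
#'   row and column names required.  Peak areas must be non-negative
#'   (appended assay columns are exempt).
#' @param sample_info data frame with one row per sample; must contain a
#'   `method` column (extraction-method group label).  Row order matches
#'   `values`.
#' @return An object of class `feature_matrix` with `scaling_state`
#'   `"raw"`.
#' @export
feature_matrix <- function(values, sample_info) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have row (sample) and column (feature) names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("sample and feature ids must be unique")
  stopifnot(is.data.frame(sample_info), nrow(sample_info) == nrow(values),
            "method" %in% names(sample_info))
  if (any(values < 0)) stop("raw peak areas must be non-negative")
  structure(
    list(values = values, sample_info = sample_info,
         assay_cols = character(0), scaling_state = "raw"),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples x %d features (%d assay), state = %s\n",
    nrow(x$values), ncol(x$values), length(x$assay_cols), x$scaling_state))
  invisible(x)
}

.feature_cols <- function(fm) setdiff(colnames(fm$values), fm$assay_cols)

#' Normalize each sample to unit total signal
#'
#' Divides every row by its total over the LC-MS feature columns (assay
#' columns, if already fused, are excluded from the total but divided by
#' the same factor is NOT applied to them — they are left untouched).
#' Must be applied to a `raw` matrix.
#'
#' @param fm a [feature_matrix()] in state `"raw"`.
#' @return The matrix with state `"total-normalized"`; feature-column row
#'   sums equal 1.
#' @export
normalize_total_signal <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$scaling_state != "raw")
    stop("normalize_total_signal expects a raw matrix (got state '",
         fm$scaling_state, "'); pipeline order is normalize -> fuse -> pareto -> pca")
  fcols <- .feature_cols(fm)
  totals <- rowSums(fm$values[, fcols, drop = FALSE])
  if (any(totals <= 0)) {
    bad <- rownames(fm$values)[which(totals <= 0)[1]]
    stop("sample '", bad, "' has zero total signal")
  }
  fm$values[, fcols] <- fm$values[, fcols, drop = FALSE] / totals
  fm$scaling_state <- "total-normalized"
  fm
}

#' Append assay variables (PV, TPC, RSA, AUC) as extra columns
#'
#' Fuses the block of four assay variables with the LC-MS features so
#' that they participate in Pareto scaling and PCA like any feature.
#' Must happen before Pareto scaling.
#'
#' @param fm a [feature_matrix()] not yet Pareto-scaled.
#' @param assay_table data frame with row names matching the sample ids
#'   and columns `PV`, `TPC`, `RSA`, `AUC`; every sample must be present.
#' @param block_weight scalar multiplier applied to the assay block
#'   (default 1 = no block weighting).
#' @return The matrix with four assay columns appended.
#' @export
fuse_variables <- function(fm, assay_table, block_weight = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$scaling_state == "pareto")
    stop("cannot fuse after Pareto scaling; pipeline order is ",
         "normalize -> fuse -> pareto -> pca")
  need <- c("PV", "TPC", "RSA", "AUC")
  if (!all(need %in% colnames(assay_table)))
    stop("assay_table must contain columns PV, TPC, RSA, AUC")
  ids <- rownames(fm$values)
  missing <- setdiff(ids, rownames(assay_table))
  if (length(missing))
    stop("assay values missing for sample(s): ",
         paste(missing, collapse = ", "))
  block <- as.matrix(assay_table[ids, need, drop = FALSE]) * block_weight
  fm$values <- cbind(fm$values, block)
  fm$assay_cols <- need
  fm
}

#' Drop fused assay columns
#'
#' @param fm a [feature_matrix()] with fused assay columns.
#' @return The matrix restricted to its LC-MS feature columns.
#' @export
unfuse_variables <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm$values <- fm$values[, .feature_cols(fm), drop = FALSE]
  fm$assay_cols <- character(0)
  fm
}

#' Pareto-scale all columns
#'
#' Per column: subtract the mean and divide by the square root of the
#' sample standard deviation.  A Pareto-scaled column has variance equal
#' to the original column's standard deviation.  Constant columns are
#' left centered (i.e. zero) with a warning.
#'
#' @param fm a [feature_matrix()] with >= 2 samples, not yet scaled.
#' @return The matrix with state `"pareto"`; the centering and scaling
#'   vectors are stored in attributes `center` and `scale`.
#' @export
pareto_scale <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$scaling_state == "pareto") stop("matrix is already Pareto-scaled")
  if (nrow(fm$values) < 2L) stop("at least 2 samples are required")
  mu <- colMeans(fm$values)
  sdv <- apply(fm$values, 2, stats::sd)
  const <- sdv == 0
  if (any(const))
    warning(sum(const), " constant column(s) left centered, not scaled")
  scl <- ifelse(const, 1, sqrt(sdv))
  fm$values <- sweep(sweep(fm$values, 2, mu), 2, scl, `/`)
  fm$center <- mu
  fm$scale <- scl
  fm$scaling_state <- "pareto"
  fm
}

#' Principal component analysis of a scaled feature matrix
#'
#' Singular value decomposition of the (already centered and scaled)
#' matrix.  Explained variance per component is `r2x_k = d_k^2 / sum(d^2)`
#' on the scaled matrix, matching the R2X convention of common
#' chemometrics software.  Component signs are fixed by making each
#' component's largest-magnitude loading positive.
#'
#' @param fm a [feature_matrix()]; a warning is raised if it is not in
#'   state `"pareto"`.
#' @param n_components number of components, at most
#'   `min(n_samples - 1, n_features)`.
#' @return An object of class `pca_model`: `scores` (samples x
#'   components), `loadings` (features x components, orthonormal
#'   columns), `r2x` (non-increasing fractions), `center`, `scale`.
#' @export
pca <- function(fm, n_components = 2L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$scaling_state != "pareto")
    warning("PCA on a matrix in state '", fm$scaling_state,
            "'; Pareto scaling is the expected input")
  X <- fm$values
  kmax <- min(nrow(X) - 1L, ncol(X))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be in [1, ", kmax, "]")
  sv <- svd(X)
  keep <- seq_len(n_components)
  d <- sv$d
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d[keep], n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (k in keep) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", keep))
  dimnames(loadings) <- list(colnames(X), paste0("PC", keep))
  structure(
    list(scores = scores, loadings = loadings,
         r2x = d[keep]^2 / sum(d^2),
         center = fm$center, scale = fm$scale,
         sample_info = fm$sample_info),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>\n")
  for (k in seq_along(x$r2x))
    cat(sprintf("  PC%d: R2X = %.4f\n", k, x$r2x[k]))
  invisible(x)
}
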