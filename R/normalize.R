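# Transformation, imputation and normalization of QC-passed matrices.
#
# Proteome convention: log2 -> kNN imputation -> median centering.
# Phosphoproteome convention: quantile normalization (raw scale) -> low-rank
# imputation -> log2 (configurable to log-first).

.as_mat <- function(t) if (inherits(t, "intensity_table")) t$mat else t

#' Log2-transform observed intensities
#'
#' @param t numeric matrix or [intensity_table()]; observed values must be
#'   strictly positive. Missing entries pass through.
#' @return matrix of the same shape on the log2 scale.
#' @export
log2_transform <- function(t) {
  m <- .as_mat(t)
  if (any(m[!is.na(m)] <= 0))
    stop("non-positive observed intensity; cannot log2-transform")
  log2(m)
}

#' k-nearest-neighbour imputation
#'
#' For each missing cell, the k nearest rows (Euclidean distance over
#' co-observed columns, normalized by the number of co-observed columns) that
#' are observed at that column supply the imputed value as their mean.
#' Rows missing in more than `rowmax` of their columns fall back to column
#' means, mirroring the behaviour of the classic microarray kNN imputer whose
#' defaults (k = 10, rowmax = 0.5, colmax = 0.8) are adopted here.
#'
#' @param t numeric matrix (features x samples) with `NA` missing entries.
#' @param k number of neighbours (< number of rows).
#' @param rowmax maximum fraction of missing values per row before the
#'   column-mean fallback is used.
#' @param colmax maximum fraction of missing values allowed in any column
#'   (exceeding it is an error, as the neighbour pool is too thin).
#' @return complete matrix; observed cells are never modified.
#' @export
knn_impute <- function(t, k = 10, rowmax = 0.5, colmax = 0.8) {
  m <- .as_mat(t)
  if (k >= nrow(m)) stop("k must be smaller than the number of rows")
  if (!anyNA(m)) return(m)
  colmiss <- colMeans(is.na(m))
  if (any(colmiss > colmax))
    stop("column(s) exceed colmax missingness: ",
         paste(colnames(m)[colmiss > colmax], collapse = ", "))
  col_means <- colMeans(m, na.rm = TRUE)
  rowmiss <- rowMeans(is.na(m))
  out <- m
  fallback <- rowmiss > rowmax
  for (i in which(fallback & rowmiss > 0)) {
    na_j <- which(is.na(m[i, ]))
    out[i, na_j] <- col_means[na_j]
  }
  todo <- which(!fallback & rowmiss > 0)
  for (i in todo) {
    xi <- m[i, ]
    na_j <- which(is.na(xi))
    d2 <- rowMeans((sweep(m, 2, xi))^2, na.rm = TRUE)  # NA pairs dropped
    d2[i] <- Inf
    for (j in na_j) {
      cand <- which(!is.na(m[, j]) & is.finite(d2))
      if (!length(cand)) { out[i, j] <- col_means[j]; next }
      nb <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(m[nb, j])
    }
  }
  out
}

#' Median-center sample columns
#'
#' Subtracts each column's median so every sample has median 0 (applied on
#' the log2 scale after imputation).
#' @param t complete numeric matrix.
#' @return centered matrix.
#' @export
median_center <- function(t) {
  m <- .as_mat(t)
  sweep(m, 2, apply(m, 2, stats::median))
}

#' Quantile normalization
#'
#' Forces every sample column onto the common rank-mean reference
#' distribution (ties averaged). Missing entries are ignored when the
#' reference is built and remain missing. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param t numeric matrix with >= 2 sample columns.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(t) {
  m <- .as_mat(t)
  if (ncol(m) < 2) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Low-rank approximation imputation
#'
#' Iterative truncated-SVD matrix completion: missing entries are initialized
#' with row means, then repeatedly overwritten by the rank-`rank`
#' reconstruction of the current complete matrix until the relative change of
#' the imputed entries (Frobenius norm of the update over the norm of the
#' current imputed values) falls below `tol` or `max_iter` is reached.
#' Observed entries are never modified.
#'
#' @param t numeric matrix with `NA` missing entries.
#' @param rank target rank; default `min(5, ncol - 1)`.
#' @param max_iter,tol convergence controls.
#' @return complete matrix with attribute `"converged"` (logical) and
#'   `"iterations"`. Non-convergence returns the best iterate with a warning.
#' @export
lowrank_impute <- function(t, rank = NULL, max_iter = 200, tol = 1e-4) {
  m <- .as_mat(t)
  if (is.null(rank)) rank <- min(5L, ncol(m) - 1L)
  if (rank >= min(dim(m))) stop("rank must be < min(dim)")
  if (!anyNA(m)) {
    attr(m, "converged") <- TRUE
    attr(m, "iterations") <- 0L
    return(m)
  }
  na_idx <- is.na(m)
  rmeans <- rowMeans(m, na.rm = TRUE)
  if (anyNA(rmeans)) stop("row(s) with no observed value cannot be imputed")
  x <- m
  x[na_idx] <- rmeans[row(m)[na_idx]]
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    sv <- svd(x, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    new_vals <- recon[na_idx]
    delta <- sqrt(sum((new_vals - x[na_idx])^2) /
                    max(sum(x[na_idx]^2), .Machine$double.xmin))
    x[na_idx] <- new_vals
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("low-rank imputation did not converge in ", max_iter,
            " iterations (last rel. change ", signif(delta, 3), ")")
  attr(x, "converged") <- converged
  attr(x, "iterations") <- it
  x
}

#' Preprocess a QC-passed proteome table
#'
#' log2 transform, kNN imputation, median centering — in that order.
#' @param t QC-passed protein [intensity_table()] or raw-scale matrix.
#' @param k neighbours for [knn_impute()].
#' @return complete, centered log2 matrix.
#' @export
preprocess_proteome <- function(t, k = 10) {
  median_center(knn_impute(log2_transform(t), k = k))
}

#' Preprocess a QC-passed phosphosite table
#'
#' Default order: quantile normalization on raw intensities, then low-rank
#' imputation, then differential analysis on the log2 scale. The SVD
#' completion itself runs on log2-transformed values — a monotone reparametrization
#' that leaves observed entries untouched but conditions the completion
#' (raw LFQ intensities span orders of magnitude and make the truncated-SVD
#' iteration ill-behaved). `order = "log_first"` instead quantile-normalizes
#' the log2 values.
#' @param t QC-passed site [intensity_table()] or raw-scale matrix.
#' @param rank,max_iter,tol passed to [lowrank_impute()].
#' @param order `"quantile_first"` (default) or `"log_first"`.
#' @return complete log2 matrix.
#' @export
preprocess_phospho <- function(t, rank = NULL, max_iter = 200, tol = 1e-4,
                               order = c("quantile_first", "log_first")) {
  order <- match.arg(order)
  m <- .as_mat(t)
  if (order == "quantile_first") {
    lowrank_impute(log2_transform(quantile_normalize(m)), rank, max_iter, tol)
  } else {
    lowrank_impute(quantile_normalize(log2_transform(m)), rank, max_iter, tol)
  }
}
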