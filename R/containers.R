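#' Intensity table container
#'
#' Lightweight container pairing a features-by-samples abundance matrix with
#' per-feature metadata (QC flags and, for phosphosites, gene/residue/position
#' annotation). Missing observations are stored as `NA`; on the raw scale an
#' intensity of zero at read time denotes non-detection and is recoded to `NA`.
#'
#' @param mat numeric matrix, features in rows, samples in columns; rownames
#'   are feature ids and colnames sample ids.
#' @param features data.frame with one row per matrix row. Must contain a
#'   `feature_id` column and logical flag columns `contaminant`, `reverse`,
#'   `only_site`. Site tables additionally carry `gene`, `residue`, `position`.
#' @param type `"protein"` or `"site"`.
#' @return an object of class `intensity_table`: a list with elements `mat`,
#'   `features` and `type`.
#' @export
intensity_table <- function(mat, features = NULL, type = c("protein", "site")) {
  type <- match.arg(type)
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("`mat` must be a numeric matrix")
  if (nrow(mat) > 0 && is.null(rownames(mat)))
    stop("`mat` must have rownames (feature ids)")
  if (is.null(features)) {
    features <- data.frame(
      feature_id = rownames(mat),
      contaminant = FALSE, reverse = FALSE, only_site = FALSE,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(features) != nrow(mat))
    stop("`features` must have one row per matrix row")
  for (fl in c("contaminant", "reverse", "only_site"))
    if (is.null(features[[fl]])) features[[fl]] <- FALSE
  if (any(mat[!is.na(mat)] < 0))
    stop("intensities must be non-negative")
  structure(list(mat = mat, features = features, type = type),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf(
    "intensity_table [%s]: %d features x %d samples (%.1f%% missing)\n",
    x$type, nrow(x$mat), ncol(x$mat), 100 * mean(is.na(x$mat))))
  nf <- sum(x$features$contaminant | x$features$reverse | x$features$only_site)
  if (nf > 0) cat(sprintf("  %d flagged decoy/contaminant rows\n", nf))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$mat)

#' Number of samples with an observed value, per feature
#' @param x an `intensity_table` or numeric matrix
#' @return integer vector of per-row observed counts
#' @export
observed_counts <- function(x) {
  m <- if (inherits(x, "intensity_table")) x$mat else x
  rowSums(!is.na(m))
}

#' Validate a sample design table
#'
#' A design table maps each sample to its sex, genotype and treatment arm.
#' The group label is the `genotype-treatment` compound (one of WT-CTRL,
#' WT-OE, TG-CTRL, TG-OE).
#'
#' @param design data.frame with columns `sample_id`, `sex`, `genotype`,
#'   `treatment` (and optionally `group`, which is recomputed).
#' @return the validated design with a `group` column, invisibly classed.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "sex", "genotype", "treatment")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample ids in design")
  if (!all(design$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (!all(design$genotype %in% c("WT", "TG")))
    stop("genotype must be 'WT' or 'TG'")
  if (!all(design$treatment %in% c("CTRL", "OE")))
    stop("treatment must be 'CTRL' or 'OE'")
  design$group <- paste(design$genotype, design$treatment, sep = "-")
  design
}

group_levels <- function() c("WT-CTRL", "WT-OE", "TG-CTRL", "TG-OE")
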